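# End-to-end orchestration: extract -> featurize -> preprocess -> balance
# -> train -> predict -> negative control -> enrichment -> ranking.

#' Pipeline parameters
#'
#' All stage parameters in one place, with defaults equal to the method's
#' canonical configuration: 60-nt windows, |r| > 0.55 feature pruning,
#' a 5,000 : 12,500 balanced training set (2.5:1) with SMOTE k = 300
#' (clamped to the available minority neighbors), a degree-2 polynomial
#' kernel with 2:1 positive:negative class costs, posterior threshold 0.5,
#' ranking threshold 0.05 and ortholog-group FDR 0.05.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of parameters; unknown names are rejected.
#' @export
ires_params <- function(...) {
  defaults <- list(width = 60L, cor_threshold = 0.55,
                   n_pos_out = 5000L, n_neg_out = 12500L, smote_k = 300L,
                   gamma = 0.125, coef0 = 1, cost = 1, degree = 2,
                   class_weights = c(positive = 2, negative = 1),
                   ranking_threshold = 0.05, og_fdr = 0.05,
                   backend = "internal", tune = FALSE, grid = NULL,
                   folds = 10L, repeats = 30L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stopf("unknown parameter(s): %s",
                             paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  defaults
}

#' Run the complete IRES prediction pipeline
#'
#' Computes the 29-feature matrix for every gene's upstream window,
#' standardizes per organism, prunes correlated features, builds the
#' SMOTE-balanced training set from the supplied positive gene ids, trains
#' the polynomial-kernel SVM with Platt calibration (optionally after a
#' cross-validated grid search), predicts over all windows, scores the
#' negative-control windows for an empirical FDR, tests ortholog-group
#' enrichment of the positive predictions and ranks them by
#' `(1 - posterior) * group_p`.
#'
#' @param assemblies one `organism_assembly` or a list of them.
#' @param genes gene-model data.frame for all organisms.
#' @param og_table an `ortholog_table` (or `NULL`).
#' @param training_positives gene ids of the experimentally supported
#'   positive training cases (>= 2 with an extractable window).
#' @param params an [ires_params()] list.
#' @param seed master seed for SMOTE, undersampling and any CV folds.
#' @return list of class `ires_run`: `features`, `std` (standardization),
#'   `retained` (feature set), `training` (balanced set), `cv` (grid
#'   search report or `NULL`), `model`, `predictions`, `negctrl`
#'   (predictions on the control windows), `empirical_fdr_pct`,
#'   `enrichment`, `ranked`, `params`, `seed`.
#' @export
run_ires_pipeline <- function(assemblies, genes, og_table,
                              training_positives, params = ires_params(),
                              seed = 1L) {
  feats <- compute_feature_matrix(assemblies, genes, og_table,
                                  kind = "utr60", width = params$width,
                                  backend = params$backend)
  x <- feature_matrix(feats)
  std <- standardize_features(x, feats$organism_id)
  retained <- prune_correlated(std$x, threshold = params$cor_threshold)
  xr <- std$x[, retained$kept, drop = FALSE]

  pos <- rownames(xr) %in% training_positives
  missing_pos <- setdiff(training_positives, rownames(xr))
  if (length(missing_pos)) {
    warnf("%d training positive(s) had no extractable window and were dropped",
          length(missing_pos))
  }
  training <- build_training_set(xr, pos, n_pos_out = params$n_pos_out,
                                 n_neg_out = params$n_neg_out,
                                 k = params$smote_k, seed = seed)

  cv <- NULL
  gamma <- params$gamma; cost <- params$cost
  if (isTRUE(params$tune)) {
    cv <- grid_search_cv(training$x, training$y,
                         grid = params$grid %||% ires_default_grid(),
                         folds = params$folds, repeats = params$repeats,
                         seed = seed, coef0 = params$coef0,
                         degree = params$degree,
                         class_weights = params$class_weights)
    gamma <- cv$best$gamma; cost <- cv$best$cost
  }
  model <- train_ires_svm(training$x, training$y, gamma = gamma,
                          coef0 = params$coef0, cost = cost,
                          degree = params$degree,
                          class_weights = params$class_weights)

  predictions <- predict_ires(model, xr)
  predictions$organism_id <- feats$organism_id

  nc_feats <- compute_feature_matrix(assemblies, genes, og_table,
                                     kind = "negctrl60",
                                     width = params$width,
                                     backend = params$backend)
  xnc <- apply_standardization(feature_matrix(nc_feats),
                               nc_feats$organism_id, std$params)
  negctrl <- predict_ires(model, xnc[, retained$kept, drop = FALSE])

  n_pos_utr <- sum(predictions$label == "positive")
  empirical_fdr <- if (n_pos_utr > 0) {
    estimate_empirical_fdr(sum(negctrl$label == "positive"), n_pos_utr)
  } else NA_real_

  enrichment <- og_enrichment(predictions$gene_id[predictions$label == "positive"],
                              og_table, universe = feats$gene_id,
                              alpha = params$og_fdr)
  ranked <- rank_predictions(predictions, enrichment, og_table,
                             threshold = params$ranking_threshold)

  structure(list(features = feats, std = std, retained = retained,
                 training = training, cv = cv, model = model,
                 predictions = predictions, negctrl = negctrl,
                 empirical_fdr_pct = empirical_fdr,
                 enrichment = enrichment, ranked = ranked,
                 params = params, seed = seed),
            class = "ires_run")
}

#' @export
print.ires_run <- function(x, ...) {
  cat(sprintf("<ires_run> %d genes analyzed; %d positive predictions; %d enriched group(s) at FDR < %g; %d top-ranked; empirical FDR %.2f%%\n",
              nrow(x$features), sum(x$predictions$label == "positive"),
              sum(x$enrichment$significant), x$params$og_fdr,
              sum(x$ranked$is_top),
              x$empirical_fdr_pct))
  invisible(x)
}

#' Write the run manifest (parameters, seeds, retained features) as JSON
#'
#' @param run an `ires_run`.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(run, path) {
  manifest <- list(
    seed = run$seed,
    params = run$params[setdiff(names(run$params), "grid")],
    smote = list(requested_k = run$training$requested_k,
                 effective_k = run$training$effective_k),
    retained_features = run$retained$kept,
    platt = as.list(run$model$platt),
    n_genes = nrow(run$features),
    n_positive_predictions = sum(run$predictions$label == "positive"),
    empirical_fdr_pct = run$empirical_fdr_pct)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
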