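# Degree-2 polynomial-kernel SVM with asymmetric class costs, Platt
# posterior calibration, repeated stratified cross-validation, and the
# empirical-FDR estimate from the negative-control window set.

#' Default SVM parameter grid
#'
#' 32 combinations: 8 kernel scales (gamma) times 4 misclassification
#' costs, the grid searched by [grid_search_cv()].
#' @return data.frame with columns `gamma` and `cost`.
#' @export
ires_default_grid <- function() {
  expand.grid(gamma = 2^seq(-7, 0), cost = c(0.25, 1, 4, 16))
}

#' Train the IRES support vector machine
#'
#' Fits a soft-margin SVM with a polynomial kernel of degree 2
#' (`(gamma * <x, x'> + coef0)^2`) and per-class misclassification costs of
#' 2 (positive) : 1 (negative), which shifts the boundary toward the
#' negative class and raises sensitivity on the rare positive class. The
#' decision values on the training data are then Platt-calibrated into
#' posterior probabilities.
#'
#' @param x numeric matrix of retained, standardized features.
#' @param y factor with levels `negative`, `positive` (both present).
#' @param gamma,coef0,cost polynomial kernel scale, offset and cost.
#' @param degree polynomial degree (default 2).
#' @param class_weights named per-class cost multipliers,
#'   default `c(positive = 2, negative = 1)`.
#' @return object of class `ires_svm`: the fitted `e1071::svm` model, the
#'   Platt coefficients `A`, `B`, the retained feature names, and the
#'   kernel parameters.
#' @export
train_ires_svm <- function(x, y, gamma = 0.125, coef0 = 1, cost = 1,
                           degree = 2,
                           class_weights = c(positive = 2, negative = 1)) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L) stopf("training data contain a single class")
  fit <- e1071::svm(x, y, kernel = "polynomial", degree = degree,
                    gamma = gamma, coef0 = coef0, cost = cost,
                    class.weights = class_weights, scale = FALSE,
                    probability = FALSE)
  f <- decision_values(fit, x)
  platt <- platt_calibrate(f, y == "positive")
  structure(list(svm = fit, platt = platt, features = colnames(x),
                 params = list(gamma = gamma, coef0 = coef0, cost = cost,
                               degree = degree,
                               class_weights = class_weights)),
            class = "ires_svm")
}

# Decision values oriented so the sign convention is stable; orientation is
# absorbed by the Platt slope A at calibration time.
decision_values <- function(fit, x) {
  p <- predict(fit, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

#' Platt calibration of decision values into posterior probabilities
#'
#' Fits the sigmoid `P(positive | f) = 1 / (1 + exp(A f + B))` by
#' regularized maximum likelihood with Platt's smoothed targets
#' `t+ = (N+ + 1) / (N+ + 2)` and `t- = 1 / (N- + 2)`, using Newton
#' iterations with backtracking until the gradient norm falls below 1e-8.
#' For a correctly oriented classifier (larger decision value = more
#' positive) the fitted slope `A` is negative.
#'
#' @param f numeric decision values.
#' @param positive logical vector, `TRUE` for positive examples.
#' @param max_iter maximum Newton iterations (default 200).
#' @return named numeric vector `c(A, B)`.
#' @export
platt_calibrate <- function(f, positive, max_iter = 200L) {
  if (!any(positive) || all(positive)) stopf("Platt calibration needs both classes")
  np <- sum(positive); nn <- sum(!positive)
  t <- ifelse(positive, (np + 1) / (np + 2), 1 / (nn + 2))
  A <- 0; B <- log((nn + 1) / (np + 1))
  obj <- function(A, B) {
    z <- A * f + B
    # stable -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z))
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                      # dF/dz per observation
    g <- c(sum(d1 * f), sum(d1))     # gradient wrt (A, B)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < 1e-8) break
    w <- p * (1 - p)
    h11 <- sum(w * f * f) + 1e-12
    h12 <- sum(w * f)
    h22 <- sum(w) + 1e-12
    det <- h11 * h22 - h12^2
    dA <- -(h22 * g[1] - h12 * g[2]) / det
    dB <- -(-h12 * g[1] + h11 * g[2]) / det
    step <- 1
    repeat {
      nv <- obj(A + step * dA, B + step * dB)
      if (nv <= val + 1e-4 * step * (g[1] * dA + g[2] * dB) || step < 1e-10) break
      step <- step / 2
    }
    if (step < 1e-10) break  # line search stalled: at numerical optimum
    A <- A + step * dA; B <- B + step * dB
    val <- obj(A, B)
  }
  # warn only when the residual gradient is large relative to problem scale
  # (a stalled flat surface near optimum is ordinary for noise-like inputs)
  if (gnorm >= 1e-5 * length(f)) {
    warnf("Platt calibration stopped at gradient norm %.2g after %d iterations",
          gnorm, it)
  }
  c(A = A, B = B)
}

#' Posterior probability from calibrated decision values
#' @param f decision values.
#' @param platt `c(A, B)` from [platt_calibrate()].
#' @return posterior probabilities of the positive class, in (0, 1).
#' @export
platt_posterior <- function(f, platt) {
  1 / (1 + exp(platt[["A"]] * f + platt[["B"]]))
}

#' Predict IRES labels and posteriors
#'
#' @param model an `ires_svm`.
#' @param x numeric matrix already standardized with the training
#'   parameters and restricted to the model's retained features.
#' @return data.frame `gene_id` (rownames of `x`), `label`
#'   (`positive` iff posterior >= 0.5), `posterior`.
#' @export
predict_ires <- function(model, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), model$features)) {
    if (!all(model$features %in% colnames(x))) {
      stopf("prediction matrix lacks model feature '%s'",
            setdiff(model$features, colnames(x))[1])
    }
    x <- x[, model$features, drop = FALSE]
  }
  f <- decision_values(model$svm, x)
  post <- platt_posterior(f, model$platt)
  data.frame(gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             label = ifelse(post >= 0.5, "positive", "negative"),
             posterior = post, decision = f, stringsAsFactors = FALSE)
}

#' Confusion-matrix performance metrics
#'
#' @param y_true,y_pred equal-length vectors coercible to
#'   `negative`/`positive` factors.
#' @return named numeric vector: `accuracy`, `kappa` (Cohen's, chance
#'   corrected from the marginals), `sensitivity` (TP / (TP + FN)),
#'   `specificity` (TN / (TN + FP)).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stopf("empty label vectors")
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  lv <- c("negative", "positive")
  y_true <- factor(as.character(y_true), levels = lv)
  y_pred <- factor(as.character(y_pred), levels = lv)
  tp <- sum(y_true == "positive" & y_pred == "positive")
  tn <- sum(y_true == "negative" & y_pred == "negative")
  fp <- sum(y_true == "negative" & y_pred == "positive")
  fn <- sum(y_true == "positive" & y_pred == "negative")
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  c(accuracy = po, kappa = kappa,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Repeated stratified cross-validated grid search
#'
#' For every parameter combination, runs `repeats` rounds of stratified
#' `folds`-fold cross-validation (each round on a fresh random
#' stratification) and records the mean accuracy and mean Cohen's kappa
#' over all folds x repeats. The chosen combination maximizes mean
#' accuracy, with mean kappa and then grid order as tie-breaks.
#'
#' @param x,y training matrix and `negative`/`positive` factor.
#' @param grid data.frame of `gamma`, `cost` combinations
#'   (default [ires_default_grid()]).
#' @param folds,repeats CV geometry (defaults 10 and 30).
#' @param seed integer seed controlling all fold assignments.
#' @param ... further arguments to [train_ires_svm()] (e.g. `coef0`,
#'   `class_weights`).
#' @return object of class `cv_report`: list with `report` (one row per
#'   combination: `gamma`, `cost`, `accuracy`, `kappa`), `best` (chosen
#'   row), `folds`, `repeats`, `seed`.
#' @export
grid_search_cv <- function(x, y, grid = ires_default_grid(), folds = 10L,
                           repeats = 30L, seed = 1L, ...) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("negative", "positive"))
  if (nrow(grid) == 0L) stopf("empty parameter grid")
  if (min(table(y)) < folds) stopf("fold count %d exceeds smallest class size %d",
                                   folds, min(table(y)))
  set.seed(seed)
  assignments <- lapply(seq_len(repeats), function(r) stratified_folds(y, folds))
  res <- lapply(seq_len(nrow(grid)), function(gi) {
    acc <- kap <- numeric(0)
    for (r in seq_len(repeats)) {
      fold <- assignments[[r]]
      for (fo in seq_len(folds)) {
        te <- fold == fo
        fit <- train_ires_svm(x[!te, , drop = FALSE], y[!te],
                              gamma = grid$gamma[gi], cost = grid$cost[gi], ...)
        pred <- predict_ires(fit, x[te, , drop = FALSE])
        m <- confusion_metrics(y[te], pred$label)
        acc <- c(acc, m[["accuracy"]]); kap <- c(kap, m[["kappa"]])
      }
    }
    c(accuracy = mean(acc), kappa = mean(kap))
  })
  report <- cbind(grid, do.call(rbind, res))
  best_i <- order(-report$accuracy, -report$kappa)[1]
  structure(list(report = report, best = report[best_i, , drop = FALSE],
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_report")
}

# Stratified fold labels: within each class, a random permutation of
# 1..folds recycled to the class size.
stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (lv in levels(y)) {
    i <- which(y == lv)
    out[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d combination(s), %d-fold x %d repeats; best: gamma = %g, cost = %g (accuracy %.3f, kappa %.3f)\n",
              nrow(x$report), x$folds, x$repeats,
              x$best$gamma, x$best$cost, x$best$accuracy, x$best$kappa))
  invisible(x)
}

#' Empirical false discovery rate from the negative-control set
#'
#' The negative-control windows (coding sequence upstream of the stop
#' codon) are assumed IRES-free, so positive calls there are false
#' positives. When the control set has the same size as the analyzed UTR
#' set, the empirical FDR of the UTR predictions is
#' `100 * n_pos_calls_on_negative_control / n_pos_calls_on_utrs` percent.
#'
#' @param n_pos_calls_on_negative_control,n_pos_calls_on_utrs counts.
#' @return percentage.
#' @export
estimate_empirical_fdr <- function(n_pos_calls_on_negative_control,
                                   n_pos_calls_on_utrs) {
  if (n_pos_calls_on_negative_control < 0 || n_pos_calls_on_utrs <= 0) {
    stopf("counts must be >= 0 with a positive denominator")
  }
  100 * n_pos_calls_on_negative_control / n_pos_calls_on_utrs
}

#' Per-feature mean gap between predicted positives and the negative set
#'
#' A descriptive report of each feature's contribution: the difference of
#' its mean over the positive rows and its mean over the negative rows.
#'
#' @param x feature matrix.
#' @param positive logical vector marking positive rows.
#' @return data.frame `feature`, `mean_positive`, `mean_negative`, `gap`,
#'   sorted by decreasing `|gap|`.
#' @export
feature_mean_gap <- function(x, positive) {
  x <- as.matrix(x)
  mp <- colMeans(x[positive, , drop = FALSE])
  mn <- colMeans(x[!positive, , drop = FALSE])
  out <- data.frame(feature = colnames(x), mean_positive = unname(mp),
                    mean_negative = unname(mn), gap = unname(mp - mn),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$gap)), ]
}
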