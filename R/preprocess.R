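# Per-organism feature standardization and correlation-based pruning.

#' Standardize features within each organism
#'
#' Rescales every feature to mean 0 and unit variance separately within
#' each organism, making inter-species attributes comparable. Features
#' that are constant within an organism are mapped to 0 (with a warning).
#' The fitted means and standard deviations are returned so that
#' prediction-time data can be transformed with the same parameters.
#'
#' @param x numeric feature matrix (genes x features).
#' @param organism character vector of organism ids, one per row.
#' @return list with `x` (standardized matrix) and `params` (data.frame
#'   `organism`, `feature`, `mean`, `sd`), of class
#'   `standardization_params` on the `params` element.
#' @export
standardize_features <- function(x, organism) {
  x <- as.matrix(x)
  if (nrow(x) != length(organism)) stopf("organism labels do not match rows")
  degenerate <- 0L
  params <- list()
  out <- x
  for (org in unique(organism)) {
    i <- which(organism == org)
    if (length(i) < 2L) stopf("organism '%s' has a single gene; per-organism variance is undefined", org)
    mu <- colMeans(x[i, , drop = FALSE])
    sg <- apply(x[i, , drop = FALSE], 2, sd)
    zero <- sg == 0
    degenerate <- degenerate + sum(zero)
    sg_safe <- ifelse(zero, 1, sg)
    out[i, ] <- sweep(sweep(x[i, , drop = FALSE], 2, mu), 2, sg_safe, "/")
    out[i, zero] <- 0
    params[[org]] <- data.frame(organism = org, feature = colnames(x),
                                mean = unname(mu), sd = unname(sg),
                                stringsAsFactors = FALSE)
  }
  if (degenerate > 0L) {
    warnf("%d organism-level constant feature(s) mapped to 0", degenerate)
  }
  params <- do.call(rbind, params)
  rownames(params) <- NULL
  class(params) <- c("standardization_params", class(params))
  list(x = out, params = params)
}

#' Apply previously fitted standardization parameters
#'
#' @param x numeric feature matrix.
#' @param organism organism id per row; every organism must appear in
#'   `params`.
#' @param params `standardization_params` from [standardize_features()].
#' @return standardized matrix.
#' @export
apply_standardization <- function(x, organism, params) {
  x <- as.matrix(x)
  out <- x
  for (org in unique(organism)) {
    p <- params[params$organism == org, , drop = FALSE]
    if (nrow(p) == 0L) stopf("no standardization parameters for organism '%s'", org)
    p <- p[match(colnames(x), p$feature), , drop = FALSE]
    if (anyNA(p$feature)) stopf("standardization parameters lack feature '%s'",
                                colnames(x)[is.na(p$feature)][1])
    i <- which(organism == org)
    sg <- ifelse(p$sd == 0, 1, p$sd)
    out[i, ] <- sweep(sweep(x[i, , drop = FALSE], 2, p$mean), 2, sg, "/")
    out[i, p$sd == 0] <- 0
  }
  out
}

#' Drop correlated features at a fixed threshold
#'
#' Computes Pearson correlations between all feature pairs on the pooled
#' (already standardized) matrix and makes one deterministic greedy pass in
#' canonical column order: for each ordered pair (i < j) with
#' `|r| > threshold`, the later feature j is dropped if both are still
#' retained. Pairs involving a constant column (undefined correlation) are
#' treated as uncorrelated.
#'
#' @param x standardized numeric feature matrix.
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.55).
#' @return object of class `retained_feature_set`: list with `kept`
#'   (ordered character vector), `dropped` (data.frame `dropped`, `kept`,
#'   `r`) and `threshold`.
#' @export
prune_correlated <- function(x, threshold = 0.55) {
  x <- as.matrix(x)
  cm <- suppressWarnings(cor(x))
  cm[is.na(cm)] <- 0
  nm <- colnames(x)
  retained <- rep(TRUE, ncol(x))
  log <- list()
  for (i in seq_len(ncol(x) - 1L)) {
    if (!retained[i]) next
    for (j in seq((i + 1L), ncol(x))) {
      if (!retained[j]) next
      if (abs(cm[i, j]) > threshold) {
        retained[j] <- FALSE
        log[[length(log) + 1L]] <- data.frame(dropped = nm[j], kept = nm[i],
                                              r = cm[i, j],
                                              stringsAsFactors = FALSE)
      }
    }
  }
  dropped <- if (length(log)) do.call(rbind, log) else
    data.frame(dropped = character(0), kept = character(0), r = numeric(0))
  structure(list(kept = nm[retained], dropped = dropped,
                 threshold = threshold),
            class = "retained_feature_set")
}

#' @export
print.retained_feature_set <- function(x, ...) {
  cat(sprintf("<retained_feature_set> %d kept, %d dropped (|r| > %.2f)\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  invisible(x)
}
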