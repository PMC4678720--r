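# Class balancing: SMOTE oversampling of the minority (IRES) class and
# undersampling of the majority class to a fixed ratio.

#' SMOTE: synthetic minority oversampling
#'
#' Generates `n_synthetic` synthetic minority rows. Each synthetic row is
#' `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`, where `x_i` cycles
#' through the minority rows and `x_nn` is drawn uniformly from the
#' `k_eff` Euclidean nearest minority neighbors of `x_i`, with
#' `k_eff = min(k, n_minority - 1)`. Distances are Euclidean on the
#' (standardized, pruned) feature space supplied.
#'
#' @param x numeric matrix of minority-class rows (>= 2 rows).
#' @param k requested neighbor count; clamped to `n_minority - 1`. Both the
#'   requested and the effective value are recorded as attributes.
#' @param n_synthetic number of synthetic rows to generate.
#' @return numeric matrix of synthetic rows with attributes `requested_k`
#'   and `effective_k`.
#' @export
smote_oversample <- function(x, k, n_synthetic) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stopf("SMOTE needs at least 2 minority rows")
  k_eff <- as.integer(min(k, n - 1L))
  if (n_synthetic == 0L) {
    out <- x[0, , drop = FALSE]
    attr(out, "requested_k") <- k
    attr(out, "effective_k") <- k_eff
    return(out)
  }
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n),
                              function(i) order(d[i, ])[seq_len(k_eff)]))
  base <- rep_len(seq_len(n), n_synthetic)
  pick <- nn[cbind(base, sample.int(k_eff, n_synthetic, replace = TRUE))]
  u <- runif(n_synthetic)
  out <- x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  rownames(out) <- paste0("synthetic_", seq_len(n_synthetic))
  attr(out, "requested_k") <- k
  attr(out, "effective_k") <- k_eff
  out
}

#' Uniform undersampling of the majority class
#'
#' @param x numeric matrix of majority-class rows.
#' @param n number of rows to keep, sampled uniformly without replacement.
#' @return row-subset of `x`.
#' @export
undersample_majority <- function(x, n) {
  x <- as.matrix(x)
  if (n > nrow(x)) stopf("cannot undersample %d rows from %d", n, nrow(x))
  x[sample.int(nrow(x), n), , drop = FALSE]
}

#' Build the balanced training set
#'
#' Combines the original positive rows with SMOTE-synthesized positives to
#' reach exactly `n_pos_out` positive rows, and undersamples the negatives
#' to exactly `n_neg_out`, giving the configured class ratio (the default
#' 5,000 : 12,500 is a 2.5:1 negative:positive ratio, 17,500 rows in
#' total). All randomness derives from `seed`.
#'
#' @param x numeric feature matrix (standardized, pruned).
#' @param labels logical or factor; `TRUE`/`"positive"` marks minority rows.
#' @param n_pos_out,n_neg_out output class sizes (defaults 5000, 12500).
#' @param k requested SMOTE neighbor count (default 300; clamped to the
#'   available minority neighbors).
#' @param seed integer seed.
#' @return object of class `balanced_training_set`: list with `x`, `y`
#'   (factor `negative`/`positive`), `provenance` (`original`,
#'   `synthetic`, `sampled_negative`), `seed`, `requested_k`,
#'   `effective_k`.
#' @export
build_training_set <- function(x, labels, n_pos_out = 5000L,
                               n_neg_out = 12500L, k = 300L, seed = 1L) {
  x <- as.matrix(x)
  pos <- if (is.logical(labels)) labels else labels %in% c("positive", "pos", "TRUE")
  if (sum(pos) < 2L) stopf("need at least 2 labeled positives")
  if (sum(pos) > n_pos_out) stopf("more original positives (%d) than requested output (%d)",
                                  sum(pos), n_pos_out)
  set.seed(seed)
  xp <- x[pos, , drop = FALSE]
  syn <- smote_oversample(xp, k, n_pos_out - nrow(xp))
  neg <- undersample_majority(x[!pos, , drop = FALSE], n_neg_out)
  out_x <- rbind(xp, syn, neg)
  y <- factor(rep(c("positive", "negative"), c(n_pos_out, n_neg_out)),
              levels = c("negative", "positive"))
  prov <- rep(c("original", "synthetic", "sampled_negative"),
              c(nrow(xp), nrow(syn), nrow(neg)))
  structure(list(x = out_x, y = y, provenance = prov, seed = seed,
                 requested_k = attr(syn, "requested_k"),
                 effective_k = attr(syn, "effective_k")),
            class = "balanced_training_set")
}

#' @export
print.balanced_training_set <- function(x, ...) {
  cat(sprintf("<balanced_training_set> %d rows (%d positive: %d original + %d synthetic; %d negative), ratio %.2g:1, k = %d (requested %d), seed %d\n",
              nrow(x$x), sum(x$y == "positive"),
              sum(x$provenance == "original"),
              sum(x$provenance == "synthetic"),
              sum(x$y == "negative"),
              sum(x$y == "negative") / sum(x$y == "positive"),
              x$effective_k, x$requested_k, x$seed))
  invisible(x)
}
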