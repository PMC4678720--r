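# Fisher exact enrichment of predictions in orthologous groups, BH
# correction, the combined ranking score, set-overlap tests and generic
# flat-map term enrichment.

#' One-sided Fisher (hypergeometric upper-tail) over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` successes in a sample of size `n` from a
#' universe of `N` with `K` total successes. Computed via the stable
#' log-space upper-tail hypergeometric sum. Vectorized over all arguments.
#'
#' @param k observed successes in the sample.
#' @param n sample (e.g. ortholog-group) size.
#' @param K total successes (e.g. positive predictions) in the universe.
#' @param N universe size.
#' @return p-value(s) in (0, 1].
#' @export
fisher_upper_tail <- function(k, n, K, N) {
  bad <- k < 0 | k > n | n > N | K > N | k > K | (n - k) > (N - K)
  if (any(bad)) stopf("inconsistent 2x2 table: k=%s n=%s K=%s N=%s",
                      k[bad][1], n[bad][1], K[bad][1], N[bad][1])
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; invariant under
#' permutations of the input order. The family size `m` defaults to the
#' number of tests supplied but may be set larger when only a subset of a
#' wider family is being adjusted.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  if (length(p) == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / rev(seq_along(p))))[ro]
}

#' Ortholog-group enrichment of positive predictions
#'
#' For each group with at least one positive prediction, a one-sided
#' Fisher test of over-representation of predictions among the group's
#' members present in the universe, BH-corrected. The universe is the set
#' of all genes with an analyzable upstream window.
#'
#' @param positive_genes character vector of genes predicted positive.
#' @param og_table an `ortholog_table`.
#' @param universe character vector of all analyzed genes.
#' @param alpha FDR significance level (default 0.05).
#' @param family `"tested"` (default): BH family = groups carrying >= 1
#'   positive; `"all"`: family = all groups with >= 1 member in the
#'   universe.
#' @return data.frame `og_id`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_raw`.
#' @export
og_enrichment <- function(positive_genes, og_table, universe, alpha = 0.05,
                          family = c("tested", "all")) {
  family <- match.arg(family)
  positive_genes <- intersect(positive_genes, universe)
  K <- length(positive_genes)
  N <- length(universe)
  members <- lapply(og_table$groups, intersect, universe)
  n <- lengths(members)
  k <- vapply(members, function(g) length(intersect(g, positive_genes)),
              integer(1))
  present <- n > 0L
  tested <- k > 0L
  m <- if (family == "tested") sum(tested) else sum(present)
  out <- data.frame(og_id = names(members)[tested], k = k[tested],
                    n = n[tested], K = K, N = N, stringsAsFactors = FALSE)
  out$p_raw <- fisher_upper_tail(out$k, out$n, K, N)
  out$p_adj <- bh_adjust(out$p_raw, m = m)
  out$significant <- out$p_adj < alpha
  out[order(out$p_raw), ]
}

#' Rank positive predictions by posterior and group enrichment
#'
#' The ranking score of an SVM-positive gene is the product of the
#' complement of its class posterior and its ortholog group's enrichment
#' p-value: `score = (1 - posterior) * group_p`. Lower is better: a gene
#' must look like an IRES (posterior near 1) and sit in a conserved,
#' prediction-enriched group for a small score. Genes whose group has no
#' enrichment record, and ungrouped genes, use `group_p = 1`. SVM-negative
#' genes are excluded outright to avoid compounding misclassification.
#'
#' @param predictions data.frame from [predict_ires()] (columns `gene_id`,
#'   `label`, `posterior`).
#' @param enrichment data.frame from [og_enrichment()].
#' @param og_table an `ortholog_table`.
#' @param threshold top-set cutoff on the score (default 0.05).
#' @param use_adjusted use BH-adjusted group p-values (default `TRUE`).
#' @param complement use `1 - posterior` (default `TRUE`); `FALSE` gives
#'   the literal posterior-times-p variant.
#' @return data.frame `gene_id`, `posterior`, `og_id`, `group_p`, `score`,
#'   `is_top`, sorted by ascending score.
#' @export
rank_predictions <- function(predictions, enrichment, og_table,
                             threshold = 0.05, use_adjusted = TRUE,
                             complement = TRUE) {
  pos <- predictions[predictions$label == "positive", , drop = FALSE]
  og <- og_of(og_table, pos$gene_id)
  pcol <- if (use_adjusted) "p_adj" else "p_raw"
  gp <- enrichment[[pcol]][match(og, enrichment$og_id)]
  gp[is.na(gp)] <- 1
  base <- if (complement) 1 - pos$posterior else pos$posterior
  out <- data.frame(gene_id = pos$gene_id, posterior = pos$posterior,
                    og_id = og, group_p = gp, score = base * gp,
                    stringsAsFactors = FALSE)
  out$is_top <- out$score <= threshold
  out[order(out$score), ]
}

#' Fisher overlap test between two gene sets
#'
#' Tests whether the overlap of `setA` and `setB` within a universe of
#' `universe_size` genes is larger than expected at random, via
#' [fisher_upper_tail()] with `k = |A intersect B|`, `n = |B|`,
#' `K = |A|`, `N = universe_size`.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe_size size of the common universe.
#' @return one-sided p-value.
#' @export
set_overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(union(setA, setB)) > universe_size) {
    stopf("universe smaller than |A union B|")
  }
  fisher_upper_tail(length(intersect(setA, setB)), length(setB),
                    length(setA), universe_size)
}

#' Generic term enrichment over a flat gene-to-term map
#'
#' Per-term one-sided Fisher over-representation of a foreground gene set,
#' BH-corrected. The term map is flat: no ontology-graph propagation is
#' performed.
#'
#' @param foreground character vector of genes of interest.
#' @param term_map data.frame with columns `gene_id`, `term` (a gene may
#'   carry many terms).
#' @param universe character vector of background genes.
#' @param fdr significance level on the adjusted p (default 0.1).
#' @return data.frame `term`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_raw`.
#' @export
term_enrichment <- function(foreground, term_map, universe, fdr = 0.1) {
  foreground <- intersect(unique(foreground), universe)
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(term_map$gene_id, term_map$term)
  n <- lengths(lapply(terms, unique))
  k <- vapply(terms, function(g) length(intersect(unique(g), foreground)),
              integer(1))
  out <- data.frame(term = names(terms), k = k, n = n,
                    K = length(foreground), N = length(universe),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_raw <- fisher_upper_tail(out$k, out$n, out$K, out$N)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < fdr
  out[order(out$p_raw), ]
}
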