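# Independent oracles and tiny fixture builders shared across test files.

# Exhaustive folding oracle: recursively enumerates every nested secondary
# structure with a minimum hairpin loop of 3 unpaired nt and returns the
# negated maximum total pair weight (GC = 3, AU = 2, GU = 1). Tree
# recursion, no memoization: independent of the package's dynamic program.
enum_fold_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 3
    else if (p %in% c("AT", "TA")) 2
    else if (p %in% c("GT", "TG")) 1
    else 0
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)
    for (k in (i + 4):j) {
      wk <- w(ch[i], ch[k])
      if (wk > 0) best <- max(best, wk + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  -rec(1, length(ch))
}

# Brute-force hypergeometric upper-tail sum via log binomial coefficients
# (log space keeps the terms finite for large universes).
fisher_oracle <- function(k, n, K, N) {
  i <- seq(k, min(n, K))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Minimal assembly constructor for hand-built chromosomes.
make_assembly <- function(chromosomes, organism_id = "orgA") {
  structure(list(organism_id = organism_id, chromosomes = chromosomes),
            class = "organism_assembly")
}

# Minimal gene-model row(s).
make_genes <- function(gene_id, chromosome, strand, cds_start, cds_end,
                       organism_id = "orgA", og_id = NA_character_) {
  data.frame(gene_id = gene_id, organism_id = organism_id,
             chromosome = chromosome, strand = strand,
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
             og_id = og_id, stringsAsFactors = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
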