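# Synthetic multi-organism genomes, ortholog tables, labeled feature
# clouds and planted-partition graphs with the statistical structure the
# prediction method assumes. First-class, tested code: every pipeline
# stage can be exercised offline against a known truth manifest.

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the study conditions the pipeline targets: a handful
#' of fungal-sized organisms, an extreme class imbalance (tens of true
#' IRES-bearing windows among tens of thousands of candidate genes), and a
#' positive class whose 60-nt upstream windows are A-enriched and
#' GC-depleted — hence weakly structured, with near-zero folding energy —
#' concentrated in a small set of planted ortholog groups. Background
#' base composition is A = T = 0.30, G = C = 0.20; positive windows use
#' A = 0.45, T = 0.25, G = C = 0.15.
#'
#' @param n_organisms number of organisms (default 3).
#' @param chromosomes_per_organism chromosomes per organism (default 2).
#' @param genes_per_chromosome genes per chromosome (default 5000, i.e.
#'   10,000 genes per organism).
#' @param background_comp,positive_comp named base compositions
#'   (`A`, `C`, `G`, `T`), each summing to 1.
#' @param n_ortholog_groups number of ortholog groups spanning organisms
#'   (default 1/10 of the total gene count).
#' @param n_planted_groups ortholog groups planted with positive windows
#'   (default 8).
#' @param planted_positive_fraction fraction of a planted group's members
#'   that carry a positive window (default 0.8).
#' @param ungrouped_fraction fraction of genes left out of any ortholog
#'   group (default 0.1).
#' @param seed master seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_organisms = 3L,
                             chromosomes_per_organism = 2L,
                             genes_per_chromosome = 5000L,
                             background_comp = c(A = 0.30, C = 0.20,
                                                 G = 0.20, T = 0.30),
                             positive_comp = c(A = 0.45, C = 0.15,
                                               G = 0.15, T = 0.25),
                             n_ortholog_groups = NULL,
                             n_planted_groups = 8L,
                             planted_positive_fraction = 0.8,
                             ungrouped_fraction = 0.1,
                             seed = 1L) {
  for (comp in list(background_comp, positive_comp)) {
    if (!setequal(names(comp), c("A", "C", "G", "T")) ||
        abs(sum(comp) - 1) > 1e-9 || any(comp < 0)) {
      stopf("base compositions must be named A/C/G/T probabilities summing to 1")
    }
  }
  total_genes <- n_organisms * chromosomes_per_organism * genes_per_chromosome
  n_ortholog_groups <- n_ortholog_groups %||% max(1L, total_genes %/% 10L)
  if (n_planted_groups > n_ortholog_groups) {
    stopf("planted groups exceed total ortholog groups")
  }
  structure(list(n_organisms = n_organisms,
                 chromosomes_per_organism = chromosomes_per_organism,
                 genes_per_chromosome = genes_per_chromosome,
                 background_comp = background_comp[c("A", "C", "G", "T")],
                 positive_comp = positive_comp[c("A", "C", "G", "T")],
                 n_ortholog_groups = n_ortholog_groups,
                 n_planted_groups = n_planted_groups,
                 planted_positive_fraction = planted_positive_fraction,
                 ungrouped_fraction = ungrouped_fraction,
                 seed = seed),
            class = "synthetic_config")
}

rand_seq <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

#' Generate synthetic genomes, annotations, ortholog table and truth
#'
#' Lays protein-coding genes with random strands and spacings along
#' random-composition chromosomes, assigns genes to ortholog groups that
#' span organisms, plants a subset of groups as positive, and overwrites
#' the 60-nt sense-strand window immediately upstream of every positive
#' gene's start codon with a draw from the A-rich positive composition.
#' Fully reproducible from `config$seed`. Optionally writes the artifacts
#' (FASTA, annotation TSV, ortholog TSV, truth JSON) to `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @return list with `assemblies` (list of `organism_assembly`), `genes`
#'   (gene-model data.frame), `og_table` (`ortholog_table`), `truth`
#'   (list: `labels` named logical per gene, `planted_groups`), `config`.
#' @export
generate_genomes <- function(config, dir = NULL) {
  set.seed(config$seed)
  assemblies <- list()
  genes <- list()
  for (o in seq_len(config$n_organisms)) {
    org <- sprintf("org%02d", o)
    chrs <- character(config$chromosomes_per_organism)
    names(chrs) <- sprintf("chr%d", seq_len(config$chromosomes_per_organism))
    for (ci in seq_len(config$chromosomes_per_organism)) {
      ng <- config$genes_per_chromosome
      gaps <- sample(120:400, ng, replace = TRUE)
      lens <- sample(seq(150L, 900L, by = 3L), ng, replace = TRUE)
      starts <- 200L + cumsum(gaps) + c(0L, cumsum(lens[-ng]))
      ends <- starts + lens - 1L
      chrlen <- ends[ng] + 200L
      chrs[ci] <- rand_seq(chrlen, config$background_comp)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("%s_c%d_g%04d", org, ci, seq_len(ng)),
        organism_id = org, chromosome = names(chrs)[ci],
        strand = sample(c("+", "-"), ng, replace = TRUE),
        cds_start = starts, cds_end = ends, og_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    assemblies[[org]] <- structure(list(organism_id = org, chromosomes = chrs),
                                   class = "organism_assembly")
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  # Ortholog groups spanning organisms: grouped genes get a uniformly
  # random group id; a fraction stays ungrouped.
  grouped <- runif(nrow(genes)) >= config$ungrouped_fraction
  og_ids <- sprintf("OG%05d", seq_len(config$n_ortholog_groups))
  genes$og_id[grouped] <- sample(og_ids, sum(grouped), replace = TRUE)
  og_table <- ortholog_table(genes$gene_id[grouped], genes$og_id[grouped])

  # Plant positive groups among groups that actually received members.
  occupied <- names(og_table$groups)
  planted <- sample(occupied, min(config$n_planted_groups, length(occupied)))
  labels <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  for (g in planted) {
    members <- og_table$groups[[g]]
    n_pos <- max(1L, round(config$planted_positive_fraction * length(members)))
    labels[sample(members, n_pos)] <- TRUE
  }

  # Overwrite positive genes' upstream windows with the A-rich composition.
  for (org in names(assemblies)) {
    asm <- assemblies[[org]]
    g <- genes[genes$organism_id == org & labels[genes$gene_id], , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      win <- rand_seq(60L, config$positive_comp)
      chrom <- g$chromosome[i]
      if (g$strand[i] == "+") {
        from <- g$cds_start[i] - 60L
        substr(asm$chromosomes[[chrom]], from, from + 59L) <- win
      } else {
        from <- g$cds_end[i] + 1L
        substr(asm$chromosomes[[chrom]], from, from + 59L) <- revcomp(win)
      }
    }
    assemblies[[org]] <- asm
  }

  truth <- list(labels = labels, planted_groups = planted)
  out <- list(assemblies = assemblies, genes = genes, og_table = og_table,
              truth = truth, config = config)
  if (!is.null(dir)) write_synthetic(out, dir)
  out
}

write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (org in names(sim$assemblies)) {
    asm <- sim$assemblies[[org]]
    ss <- Biostrings::DNAStringSet(asm$chromosomes)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(org, ".fa")))
    g <- sim$genes[sim$genes$organism_id == org,
                   c("gene_id", "chromosome", "strand", "cds_start", "cds_end")]
    write.table(g, file.path(dir, paste0(org, "_annotation.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  og <- data.frame(og_id = unname(sim$og_table$forward),
                   gene_id = names(sim$og_table$forward))
  write.table(og, file.path(dir, "ortholog_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(labels = as.list(sim$truth$labels),
                            planted_groups = sim$truth$planted_groups),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Generate a two-class Gaussian feature cloud
#'
#' Two multivariate spherical Gaussian classes whose means differ by
#' `separation` standard deviations along a random direction; used for
#' classifier unit and calibration tests where the decision geometry must
#' be known exactly.
#'
#' @param n_pos,n_neg class sizes.
#' @param separation mean separation in sd units.
#' @param dims dimensionality (default 5).
#' @param seed integer seed.
#' @return list with `x` (matrix) and `y` (factor `negative`/`positive`).
#' @export
generate_labeled_features <- function(n_pos, n_neg, separation, dims = 5L,
                                      seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stopf("class sizes must be >= 1")
  set.seed(seed)
  dir <- rnorm(dims)
  dir <- dir / sqrt(sum(dir^2))
  xn <- matrix(rnorm(n_neg * dims), n_neg, dims)
  xp <- matrix(rnorm(n_pos * dims), n_pos, dims) +
    matrix(separation * dir, n_pos, dims, byrow = TRUE)
  x <- rbind(xn, xp)
  colnames(x) <- paste0("f", seq_len(dims))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  list(x = x, y = factor(rep(c("negative", "positive"), c(n_neg, n_pos)),
                         levels = c("negative", "positive")))
}

#' Generate a planted-partition (stochastic block model) graph
#'
#' Within-block edges appear with probability `p_in`, between-block edges
#' with `p_out`; the block memberships form the truth for community
#' recovery benchmarks.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1` (equal
#'   values give an Erdos-Renyi graph with no community signal).
#' @param seed integer seed.
#' @return list with `graph` (igraph, vertex names `n1..nN`) and
#'   `membership` (named integer vector).
#' @export
generate_planted_partition <- function(block_sizes, p_in, p_out, seed = 1L) {
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stopf("need 0 <= p_out <= p_in <= 1")
  }
  set.seed(seed)
  n <- sum(block_sizes)
  pref <- matrix(p_out, length(block_sizes), length(block_sizes))
  diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = block_sizes)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  memb <- setNames(rep(seq_along(block_sizes), block_sizes),
                   igraph::V(g)$name)
  list(graph = g, membership = memb)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a detected partition and a reference
#' partition, 1 for identical partitions and about 0 for independent ones.
#'
#' @param a,b equal-length membership vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
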