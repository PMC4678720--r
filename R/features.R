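# The 29 per-gene features feeding the classifier.
#
# Canonical order: folding energy, the two relative-GC ratios, relative
# chromosomal position, the 16 dinucleotide frequencies, the 8 ortholog-
# group dispersion statistics (mean/mode/sd/skewness of relGCintergenic and
# of the folding energy), and the intergenic length.

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          function(a, b) paste0(a, b)))

#' Canonical names of the 29 classifier features
#' @return character vector of length 29, in canonical column order.
#' @export
ires_feature_names <- function() {
  c("mfe", "relGCintergenic", "relGCchr", "relPosChr",
    paste0("dinuc_", DINUCS),
    "og_mean_relGC", "og_mode_relGC", "og_sd_relGC", "og_skew_relGC",
    "og_mean_mfe", "og_mode_mfe", "og_sd_mfe", "og_skew_mfe",
    "intergenic_length")
}

#' Overlapping dinucleotide frequencies
#'
#' Counts the 16 unambiguous dinucleotides at every overlapping position
#' and divides by the number of unambiguous positions; positions touching
#' an `N` are excluded from both numerator and denominator. A sequence with
#' no unambiguous position gets all-zero frequencies.
#'
#' @param seqs character vector of A/C/G/T/N sequences, each of length >= 2.
#' @return numeric matrix, one row per sequence, 16 columns `dinuc_AA` ..
#'   `dinuc_TT`.
#' @export
dinucleotide_frequencies <- function(seqs) {
  if (any(nchar(seqs) < 2L)) stopf("dinucleotide frequencies need length >= 2")
  counts <- Biostrings::dinucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              step = 1L)
  counts <- counts[, DINUCS, drop = FALSE]
  denom <- rowSums(counts)  # each unambiguous position hits exactly one cell
  freq <- counts / ifelse(denom == 0, 1, denom)
  colnames(freq) <- paste0("dinuc_", DINUCS)
  freq
}

#' GC fraction with an optional pseudocount
#'
#' With the pseudocount (default) the fraction is
#' `(#G + #C + 1) / (#unambiguous + 2)`, which keeps downstream ratios
#' finite for GC-free or all-`N` sequences; without it, the plain ratio
#' over unambiguous bases.
#'
#' @param seqs character vector of non-empty A/C/G/T/N sequences.
#' @param pseudocount logical, default `TRUE`.
#' @return numeric vector of fractions.
#' @export
gc_fraction <- function(seqs, pseudocount = TRUE) {
  if (any(nchar(seqs) == 0L)) stopf("gc_fraction: empty sequence")
  lf <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                    letters = c("A", "C", "G", "T"))
  gc <- unname(lf[, "C"] + lf[, "G"])
  tot <- unname(rowSums(lf))
  if (pseudocount) (gc + 1) / (tot + 2) else gc / tot
}

#' Relative GC content of a window against a reference sequence
#'
#' The ratio of pseudocounted GC fractions, used for GC content of the
#' upstream window relative to its intergenic region (`relGCintergenic`)
#' and relative to its chromosome (`relGCchr`).
#'
#' @param utr_seqs,reference_seqs equal-length character vectors.
#' @return numeric vector of ratios.
#' @export
rel_gc <- function(utr_seqs, reference_seqs) {
  gc_fraction(utr_seqs, pseudocount = TRUE) /
    gc_fraction(reference_seqs, pseudocount = TRUE)
}

#' Relative gene position in the chromosome
#'
#' Normalized distance from the gene midpoint to the nearest chromosome
#' end: `min(midpoint - 1, L - midpoint) / L`, in `[0, 0.5]`. Captures
#' subtelomeric proximity symmetrically for both chromosome arms.
#'
#' @param cds_start,cds_end 1-based inclusive gene coordinates.
#' @param chromosome_length chromosome length `L` in nt.
#' @return numeric vector in `[0, 0.5]`.
#' @export
rel_position_chromosome <- function(cds_start, cds_end, chromosome_length) {
  mid <- (cds_start + cds_end) / 2
  pmax(0, pmin(mid - 1, chromosome_length - mid) / chromosome_length)
}

#' Folding energy of RNA sequences
#'
#' The internal backend is a Nussinov-style dynamic program that maximizes
#' total base-pair weight (GC = 3, AU = 2, GU = 1) subject to a minimum
#' hairpin loop of 3 unpaired nucleotides, and returns the negated maximum
#' weight (arbitrary units, <= 0; `N` pairs with nothing). The external
#' backend shells out to the thermodynamic `RNAfold` engine and returns
#' kcal/mol. Features are standardized per organism downstream, so the two
#' backends' unit systems are interchangeable for classification.
#'
#' @param seqs character vector of A/C/G/T/N sequences.
#' @param backend `"internal"` (default) or `"external"`.
#' @return numeric vector of energies (lower = more stable).
#' @export
fold_mfe <- function(seqs, backend = c("internal", "external")) {
  backend <- match.arg(backend)
  if (any(nchar(seqs) < 1L)) stopf("fold_mfe: empty sequence")
  if (backend == "internal") return(.fold_mfe_internal(seqs))
  if (Sys.which("RNAfold") == "") stopf("external backend requires RNAfold on PATH")
  out <- system2("RNAfold", c("--noPS"), input = paste(seqs, collapse = "\n"),
                 stdout = TRUE)
  en <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
}

#' Dispersion statistics of a feature within an ortholog group
#'
#' Returns the arithmetic mean, a histogram mode, the sample standard
#' deviation and the moment skewness of a vector of per-gene feature
#' values. The mode of continuous values is the midpoint of the most
#' populated bin of a 10-bin histogram spanning `[min, max]` (the lowest
#' bin wins ties); when all values coincide it is that value. `sd` uses the
#' n-1 denominator and is 0 for n < 2; skewness is `m3 / m2^(3/2)` on
#' population moments and 0 for n < 3 or zero variance.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector `c(mean, mode, sd, skew)`.
#' @export
group_statistics <- function(values) {
  if (length(values) == 0L) stopf("group_statistics: empty value list")
  m <- mean(values)
  if (length(unique(values)) == 1L) {
    return(c(mean = m, mode = values[1], sd = 0, skew = 0))
  }
  breaks <- seq(min(values), max(values), length.out = 11L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = 10L)
  b <- which.max(counts)  # which.max takes the lowest bin on ties
  mode <- (breaks[b] + breaks[b + 1L]) / 2
  s <- if (length(values) >= 2L) sd(values) else 0
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  skew <- if (length(values) >= 3L && m2 > 0) m3 / m2^1.5 else 0
  c(mean = m, mode = mode, sd = s, skew = skew)
}

#' Compute the full 29-feature matrix for a set of genes
#'
#' Runs window extraction (upstream `utr60` by default, or the
#' negative-control window), intergenic-region computation, per-window
#' sequence features and ortholog-group dispersion statistics, and
#' assembles the canonical 29-column feature table. Ortholog-group
#' statistics pool group members across all supplied organisms; genes
#' without a group (or whose group-mates lack an extractable window) fall
#' back to singleton statistics (sd = skewness = 0). Genes whose
#' intergenic region is empty fall back to the chromosome as the
#' `relGCintergenic` reference.
#'
#' @param assemblies a single `organism_assembly` or a list of them.
#' @param genes gene-model data.frame covering all organisms involved.
#' @param og_table an `ortholog_table`, or `NULL` for no grouping.
#' @param kind `"utr60"` (default) or `"negctrl60"`: which 60-nt window the
#'   sequence features are computed on.
#' @param width window width, default 60.
#' @param backend folding backend passed to [fold_mfe()].
#' @return data.frame with `gene_id`, `organism_id`, `og_id` and the 29
#'   feature columns of [ires_feature_names()], one row per gene with an
#'   extractable window; skipped genes in `attr(, "skipped")`.
#' @export
compute_feature_matrix <- function(assemblies, genes, og_table = NULL,
                                   kind = c("utr60", "negctrl60"),
                                   width = 60L,
                                   backend = c("internal", "external")) {
  kind <- match.arg(kind)
  backend <- match.arg(backend)
  if (inherits(assemblies, "organism_assembly")) assemblies <- list(assemblies)
  names(assemblies) <- vapply(assemblies, `[[`, "", "organism_id")
  unknown <- setdiff(unique(genes$organism_id), names(assemblies))
  if (length(unknown)) stopf("no assembly supplied for organism '%s'", unknown[1])

  per_org <- lapply(names(assemblies), function(org) {
    g <- genes[genes$organism_id == org, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    asm <- assemblies[[org]]
    win <- if (kind == "utr60") extract_upstream_windows(asm, g, width)
           else extract_negative_control_windows(asm, g, width)
    skipped <- attr(win, "skipped")
    g <- g[match(win$gene_id, g$gene_id), , drop = FALSE]
    inter <- compute_intergenic_regions(asm, g)
    chrlen <- nchar(asm$chromosomes)[g$chromosome]

    # Chromosome GC computed once per chromosome, not once per gene.
    gc_chr <- setNames(gc_fraction(asm$chromosomes),
                       names(asm$chromosomes))[g$chromosome]
    gc_win <- gc_fraction(win$sequence)
    empty_inter <- inter$length == 0L
    if (any(empty_inter)) {
      warnf("%d gene(s) in %s have an empty intergenic region; using the chromosome as relGCintergenic reference",
            sum(empty_inter), org)
    }
    gc_inter <- gc_chr
    gc_inter[!empty_inter] <- gc_fraction(inter$sequence[!empty_inter])

    feats <- data.frame(gene_id = win$gene_id, organism_id = org,
                        og_id = NA_character_, stringsAsFactors = FALSE)
    feats$mfe <- fold_mfe(win$sequence, backend)
    feats$relGCintergenic <- gc_win / gc_inter
    feats$relGCchr <- gc_win / gc_chr
    feats$relPosChr <- rel_position_chromosome(g$cds_start, g$cds_end, chrlen)
    feats <- cbind(feats, as.data.frame(dinucleotide_frequencies(win$sequence)))
    feats$intergenic_length <- inter$length
    list(feats = feats, skipped = skipped)
  })
  per_org <- Filter(Negate(is.null), per_org)
  feats <- do.call(rbind, lapply(per_org, `[[`, "feats"))
  skipped <- do.call(rbind, lapply(per_org, `[[`, "skipped"))
  rownames(feats) <- NULL

  if (!is.null(og_table)) feats$og_id <- og_of(og_table, feats$gene_id)

  # Ortholog-group dispersion statistics, pooled across organisms over the
  # members that obtained a window of this kind; ungrouped genes are their
  # own singleton group.
  grp <- ifelse(is.na(feats$og_id), paste0(".self.", feats$gene_id), feats$og_id)
  for (src in c("relGCintergenic", "mfe")) {
    tag <- if (src == "mfe") "mfe" else "relGC"
    stats <- lapply(split(feats[[src]], grp), group_statistics)
    sm <- do.call(rbind, stats)[match(grp, names(stats)), , drop = FALSE]
    feats[[paste0("og_mean_", tag)]] <- sm[, "mean"]
    feats[[paste0("og_mode_", tag)]] <- sm[, "mode"]
    feats[[paste0("og_sd_", tag)]] <- sm[, "sd"]
    feats[[paste0("og_skew_", tag)]] <- sm[, "skew"]
  }

  feats <- feats[, c("gene_id", "organism_id", "og_id", ires_feature_names())]
  attr(feats, "skipped") <- skipped
  feats
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features data.frame from [compute_feature_matrix()].
#' @return numeric matrix (rownames = gene ids) with the 29 canonical
#'   columns, or however many remain after pruning.
#' @export
feature_matrix <- function(features) {
  cols <- intersect(ires_feature_names(), names(features))
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$gene_id
  m
}

#' Write / read a feature table as TSV
#'
#' Columns: `gene_id`, `organism_id`, `og_id`, then the feature columns in
#' canonical order.
#' @param features feature data.frame.
#' @param path file path.
#' @export
write_feature_tsv <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(og_id = "character"))
}
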