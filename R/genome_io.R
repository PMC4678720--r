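# Genome, annotation and ortholog-table I/O plus window extraction.
#
# Coordinate convention: 1-based, inclusive on both ends (GFF convention),
# everywhere in this package. The only place genomic coordinates are turned
# into string offsets is substr() in the extractors below, which is itself
# 1-based inclusive, so no conversion arithmetic is needed.

#' Read a genome FASTA file into an organism assembly
#'
#' Chromosome names are taken from the FASTA header token before the first
#' whitespace. Sequences are uppercased, `U` is mapped to `T` and IUPAC
#' ambiguity codes other than `N` are collapsed to `N`; any other character
#' is a fatal parse error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param organism_id short identifier for the organism the file belongs to.
#' @return an object of class `organism_assembly`: a list with elements
#'   `organism_id` and `chromosomes` (named character vector).
#' @export
read_genome_fasta <- function(path, organism_id) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stopf("cannot parse FASTA %s: %s",
                                             path, conditionMessage(e)))
  if (length(seqs) == 0L) stopf("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stopf("duplicate chromosome name '%s' in %s", nm[duplicated(nm)][1], path)
  }
  chr <- normalize_nt(as.character(seqs), what = nm)
  if (any(nchar(chr) == 0L)) {
    stopf("empty sequence for chromosome '%s' in %s", nm[nchar(chr) == 0L][1], path)
  }
  names(chr) <- nm
  structure(list(organism_id = organism_id, chromosomes = chr),
            class = "organism_assembly")
}

#' @export
print.organism_assembly <- function(x, ...) {
  cat(sprintf("<organism_assembly> %s: %d chromosome(s), %s nt total\n",
              x$organism_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

#' Read a gene annotation into a table of gene models
#'
#' Two dialects are supported. `"tsv"` expects a header line with columns
#' `gene_id`, `chromosome`, `strand`, `cds_start`, `cds_end`. `"gff3"`
#' expects GFF3 `CDS` features; the CDS span of a multi-exon gene is taken
#' as `min(start)..max(end)` over its CDS parts (introns are ignored: the
#' method treats genes as single spans, which is adequate for intron-poor
#' fungal genomes). Gene identity in GFF3 comes from the `Parent` attribute
#' when present, else `ID`.
#'
#' @param path annotation file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param organism_id organism the annotation belongs to.
#' @param assembly optional `organism_assembly`; when given, coordinates are
#'   checked against chromosome bounds.
#' @return data.frame with columns `gene_id`, `organism_id`, `chromosome`,
#'   `strand`, `cds_start`, `cds_end`, `og_id` (initialized `NA`).
#' @export
read_annotation <- function(path, dialect = c("tsv", "gff3"),
                            organism_id, assembly = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (dialect == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "strand", "cds_start", "cds_end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stopf("annotation TSV lacks column(s): %s",
                            paste(miss, collapse = ", "))
    genes <- tab[need]
  } else {
    raw <- rtracklayer::readGFF(path)
    cds <- as.data.frame(raw[raw$type == "CDS",
                             intersect(c("seqid", "type", "start", "end",
                                         "strand", "ID", "Parent"),
                                       names(raw))])
    if (nrow(cds) == 0L) stopf("no CDS features in GFF3 %s", path)
    first_or_na <- function(x) if (length(x)) as.character(x)[1] else NA_character_
    par <- if ("Parent" %in% names(cds)) {
      vapply(cds$Parent, first_or_na, character(1), USE.NAMES = FALSE)
    } else rep(NA_character_, nrow(cds))
    if ("ID" %in% names(cds)) {
      par[is.na(par)] <- as.character(cds$ID)[is.na(par)]
    }
    if (anyNA(par)) stopf("GFF3 CDS feature without Parent or ID attribute in %s", path)
    cds$seqid <- as.character(cds$seqid)
    cds$strand <- as.character(cds$strand)
    genes <- do.call(rbind, lapply(split(seq_len(nrow(cds)), par), function(i) {
      data.frame(gene_id = par[i[1]],
                 chromosome = cds$seqid[i[1]],
                 strand = cds$strand[i[1]],
                 cds_start = min(cds$start[i]),
                 cds_end = max(cds$end[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stopf("unknown strand symbol '%s' for gene '%s'",
          genes$strand[!genes$strand %in% c("+", "-")][1],
          genes$gene_id[!genes$strand %in% c("+", "-")][1])
  }
  genes$cds_start <- as.integer(genes$cds_start)
  genes$cds_end <- as.integer(genes$cds_end)
  bad <- is.na(genes$cds_start) | is.na(genes$cds_end) |
    genes$cds_start > genes$cds_end
  if (any(bad)) stopf("invalid CDS coordinates for gene '%s'",
                      genes$gene_id[bad][1])
  short <- (genes$cds_end - genes$cds_start + 1L) < 6L
  if (any(short)) stopf("CDS of gene '%s' is shorter than 6 nt",
                        genes$gene_id[short][1])
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene_id '%s' in %s",
          genes$gene_id[duplicated(genes$gene_id)][1], path)
  }
  if (!is.null(assembly)) {
    len <- nchar(assembly$chromosomes)
    unknown <- !genes$chromosome %in% names(len)
    if (any(unknown)) stopf("gene '%s' on unknown chromosome '%s'",
                            genes$gene_id[unknown][1],
                            genes$chromosome[unknown][1])
    out <- genes$cds_start < 1L | genes$cds_end > len[genes$chromosome]
    if (any(out)) stopf("gene '%s' outside chromosome bounds",
                        genes$gene_id[out][1])
  }
  data.frame(gene_id = genes$gene_id, organism_id = organism_id,
             chromosome = genes$chromosome, strand = genes$strand,
             cds_start = genes$cds_start, cds_end = genes$cds_end,
             og_id = NA_character_, stringsAsFactors = FALSE)
}

# Shared machinery: take windows [start, end] (genomic, 1-based inclusive)
# and return sense-strand sequences, reverse-complementing minus-strand rows.
extract_windows <- function(assembly, genes, start, end, kind) {
  chrlen <- nchar(assembly$chromosomes)[genes$chromosome]
  ok <- start >= 1L & end <= chrlen
  seqs <- rep(NA_character_, nrow(genes))
  seqs[ok] <- substr(assembly$chromosomes[genes$chromosome[ok]],
                     start[ok], end[ok])
  minus <- ok & genes$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  alln <- ok & !is.na(seqs) & grepl("^N+$", seqs)
  keep <- ok & !alln
  skipped <- data.frame(
    gene_id = genes$gene_id[!keep],
    reason = ifelse(!ok[!keep], "insufficient_flank", "all_N_window"),
    stringsAsFactors = FALSE)
  out <- data.frame(gene_id = genes$gene_id[keep],
                    organism_id = genes$organism_id[keep],
                    kind = rep(kind, sum(keep)), sequence = seqs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Extract the 60-nt windows immediately upstream of translation starts
#'
#' For a plus-strand gene the window is
#' `chromosome[cds_start - width .. cds_start - 1]`; for a minus-strand gene
#' it is the reverse complement of
#' `chromosome[cds_end + 1 .. cds_end + width]`, so the returned sequence is
#' always the sense (mRNA-equivalent) strand. Genes with less than `width`
#' nt of flank to the contig edge, and windows consisting entirely of `N`,
#' are skipped; the skipped set is recorded in the `"skipped"` attribute.
#'
#' @param assembly an `organism_assembly`.
#' @param genes gene-model data.frame (see [read_annotation()]).
#' @param width window width in nt (default 60).
#' @return data.frame `gene_id`, `organism_id`, `kind = "utr60"`,
#'   `sequence`; skipped genes in `attr(, "skipped")`.
#' @export
extract_upstream_windows <- function(assembly, genes, width = 60L) {
  start <- ifelse(genes$strand == "+", genes$cds_start - width, genes$cds_end + 1L)
  end <- ifelse(genes$strand == "+", genes$cds_start - 1L, genes$cds_end + width)
  extract_windows(assembly, genes, as.integer(start), as.integer(end), "utr60")
}

#' Extract the negative-control windows upstream of stop codons
#'
#' The negative control is the `width` coding nucleotides immediately 5' of
#' the translation termination codon, a region where IRES elements are
#' expected to be absent. For a plus-strand gene this is
#' `chromosome[cds_end - width - 2 .. cds_end - 3]`; minus-strand genes are
#' handled by strand mirroring. Genes whose CDS is shorter than
#' `width + 3` nt are skipped.
#'
#' @inheritParams extract_upstream_windows
#' @return data.frame as for [extract_upstream_windows()] with
#'   `kind = "negctrl60"`.
#' @export
extract_negative_control_windows <- function(assembly, genes, width = 60L) {
  long_enough <- (genes$cds_end - genes$cds_start + 1L) >= width + 3L
  start <- ifelse(genes$strand == "+", genes$cds_end - width - 2L, genes$cds_start + 3L)
  end <- ifelse(genes$strand == "+", genes$cds_end - 3L, genes$cds_start + width + 2L)
  # Force short-CDS genes onto the skip path with an impossible window.
  start[!long_enough] <- 0L
  end[!long_enough] <- -1L
  out <- extract_windows(assembly, genes, as.integer(start), as.integer(end),
                         "negctrl60")
  sk <- attr(out, "skipped")
  sk$reason[sk$gene_id %in% genes$gene_id[!long_enough]] <- "cds_too_short"
  attr(out, "skipped") <- sk
  out
}

#' Compute upstream intergenic regions
#'
#' For each gene, the span between its translation start and the nearest
#' annotated CDS boundary upstream of it on the gene's sense strand
#' (boundaries of genes on either strand count). If no feature lies
#' upstream, the span runs to the contig edge. Overlapping annotations can
#' make the span empty; the length is then 0 and the sequence `""`.
#'
#' @inheritParams extract_upstream_windows
#' @return data.frame `gene_id`, `organism_id`, `kind = "intergenic"`,
#'   `sequence`, `length`.
#' @export
compute_intergenic_regions <- function(assembly, genes) {
  chrlen <- nchar(assembly$chromosomes)
  n <- nrow(genes)
  from <- integer(n)
  to <- integer(n)
  for (chrom in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == chrom)
    sb <- sort(c(genes$cds_start[idx], genes$cds_end[idx]))
    L <- chrlen[[chrom]]
    plus <- genes$strand[idx] == "+"
    ip <- idx[plus]; im <- idx[!plus]
    # plus strand: nearest boundary strictly left of cds_start
    pos <- findInterval(genes$cds_start[ip] - 1L, sb)
    b <- ifelse(pos >= 1L, sb[pmax(pos, 1L)], 0L)
    from[ip] <- b + 1L
    to[ip] <- genes$cds_start[ip] - 1L
    # minus strand: nearest boundary strictly right of cds_end
    pos <- findInterval(genes$cds_end[im], sb) + 1L
    b <- ifelse(pos <= length(sb), sb[pmin(pos, length(sb))], L + 1L)
    from[im] <- genes$cds_end[im] + 1L
    to[im] <- b - 1L
  }
  nonempty <- to >= from
  seqs <- character(n)
  seqs[nonempty] <- substr(assembly$chromosomes[genes$chromosome[nonempty]],
                           from[nonempty], to[nonempty])
  minus <- nonempty & genes$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  data.frame(gene_id = genes$gene_id, organism_id = genes$organism_id,
             kind = "intergenic", sequence = seqs,
             length = ifelse(nonempty, to - from + 1L, 0L),
             stringsAsFactors = FALSE)
}

#' Read an OrthoDB-style ortholog-group table
#'
#' Expects a tab-separated file with at least a group-id and a gene-id
#' column (names configurable). Builds the forward map gene -> group and
#' the reverse index group -> members (members may span organisms). A gene
#' listed in two different groups is an error.
#'
#' @param path tab-separated file with a header line.
#' @param og_col,gene_col column names holding group and gene identifiers.
#' @return an object of class `ortholog_table`: list with `forward`
#'   (named character vector gene -> group) and `groups` (named list
#'   group -> character vector of member genes).
#' @export
read_ortholog_groups <- function(path, og_col = "og_id", gene_col = "gene_id") {
  if (!file.exists(path)) stopf("ortholog table not found: %s", path)
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("cannot parse ortholog table %s: %s",
                                            path, conditionMessage(e)))
  if (nrow(tab) == 0L) {
    warnf("ortholog table %s is empty", path)
    return(ortholog_table(character(0), character(0)))
  }
  miss <- setdiff(c(og_col, gene_col), names(tab))
  if (length(miss)) stopf("ortholog table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  og <- as.character(tab[[og_col]])
  gene <- as.character(tab[[gene_col]])
  bad <- which(is.na(og) | is.na(gene) | og == "" | gene == "")
  if (length(bad)) stopf("malformed ortholog table line %d (header is line 1)",
                         bad[1] + 1L)
  ortholog_table(gene, og)
}

#' Build an ortholog table from parallel gene/group vectors
#'
#' @param gene_ids,og_ids equal-length character vectors; duplicated
#'   (gene, group) rows are collapsed, a gene in two distinct groups errors.
#' @return an `ortholog_table` (see [read_ortholog_groups()]).
#' @export
ortholog_table <- function(gene_ids, og_ids) {
  if (length(gene_ids) == 0L) {
    return(structure(list(forward = setNames(character(0), character(0)),
                          groups = list()),
                     class = "ortholog_table"))
  }
  keep <- !duplicated(paste0(gene_ids, "\r", og_ids))
  gene_ids <- gene_ids[keep]; og_ids <- og_ids[keep]
  dup <- duplicated(gene_ids)
  if (any(dup)) stopf("gene '%s' assigned to more than one ortholog group",
                      gene_ids[dup][1])
  forward <- setNames(og_ids, gene_ids)
  groups <- split(gene_ids, og_ids)
  structure(list(forward = forward, groups = groups), class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("<ortholog_table> %d genes in %d groups\n",
              length(x$forward), length(x$groups)))
  invisible(x)
}

#' Look up ortholog-group ids for a vector of genes
#'
#' @param og_table an `ortholog_table`.
#' @param gene_ids character vector.
#' @return character vector of group ids, `NA` for ungrouped genes.
#' @export
og_of <- function(og_table, gene_ids) {
  out <- unname(og_table$forward[gene_ids])
  out[!gene_ids %in% names(og_table$forward)] <- NA_character_
  out
}

#' Write extracted windows to FASTA
#'
#' Headers follow the convention `gene_id|organism_id|kind`.
#'
#' @param windows window data.frame from an extractor.
#' @param path output path.
#' @export
write_windows_fasta <- function(windows, path) {
  ss <- Biostrings::DNAStringSet(windows$sequence)
  names(ss) <- paste(windows$gene_id, windows$organism_id, windows$kind,
                     sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
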