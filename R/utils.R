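# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of ACGTN character vectors (vectorized, batch call).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Normalize raw sequence text to the A/C/G/T/N alphabet used throughout:
# uppercase, U -> T, other IUPAC ambiguity codes -> N. Any character outside
# the IUPAC nucleotide alphabet is a fatal error; `what` names the records.
normalize_nt <- function(x, what = rep("sequence", length(x))) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", x)
  if (any(bad)) {
    stopf("non-IUPAC nucleotide character in record '%s'", what[bad][1])
  }
  gsub("[RYSWKMBDHV]", "N", x)
}
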