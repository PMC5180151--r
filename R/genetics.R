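#' Mitochondrial genetic code tables
#'
#' Returns the codon-to-amino-acid table for the vertebrate (NCBI table 2)
#' or invertebrate (NCBI table 5) mitochondrial code. The two differ at
#' AGA/AGG, which are stop codons only under the vertebrate code.
#'
#' @param which `"invertebrate"` or `"vertebrate"`.
#' @return named character vector mapping codons to amino acids ("*" = stop).
#' @export
mito_code <- function(which = c("invertebrate", "vertebrate")) {
  which <- match.arg(which)
  Biostrings::getGeneticCode(if (which == "invertebrate") "5" else "2")
}

# Codons (no stops) usable to build translatable barcodes.
non_stop_codons <- function(which = "invertebrate") {
  code <- mito_code(which)
  names(code)[code != "*"]
}

#' Which reading frames are free of stop codons?
#'
#' Frames are offsets 0, 1, 2 on the given strand; a trailing partial codon
#' is ignored.
#'
#' @param seq single nucleotide string.
#' @param which genetic code, see [mito_code()].
#' @return logical vector of length 3 (frames 0, 1, 2).
#' @export
stop_free_frames <- function(seq, which = "invertebrate") {
  code <- mito_code(which)
  n <- nchar(seq)
  vapply(0:2, function(f) {
    k <- (n - f) %/% 3
    if (k < 1) return(TRUE)
    starts <- f + 1 + 3 * (seq_len(k) - 1)
    codons <- substring(seq, starts, starts + 2)
    aa <- code[codons]
    !any(aa == "*", na.rm = TRUE)
  }, logical(1))
}

#' Mitochondrial translation filter
#'
#' A sequence is kept when at least one reading frame (offsets 0, 1, 2 on the
#' given strand) translates without stop codons under the vertebrate *or* the
#' invertebrate mitochondrial code. Since the invertebrate code's stops
#' (TAA, TAG) are a subset of the vertebrate code's (TAA, TAG, AGA, AGG),
#' a stop-free invertebrate frame suffices.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return logical vector: `TRUE` = translatable (keep).
#' @export
translation_filter <- function(seqs) {
  if (length(seqs) == 0) return(logical(0))
  # the invertebrate stop set {TAA, TAG} is a subset of the vertebrate one
  # {TAA, TAG, AGA, AGG}, so "translatable under either code" reduces to
  # "some frame free of TAA/TAG"; computed vectorised per length group
  inv_stops <- c("TAA", "TAG")
  out <- logical(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    keep <- rep(FALSE, length(idx))
    for (f in 0:2) {
      k <- (L - f) %/% 3
      if (k < 1) { keep[] <- TRUE; break }
      has_stop <- rep(FALSE, length(idx))
      for (s in f + 1 + 3 * (seq_len(k) - 1)) {
        has_stop <- has_stop |
          substr(seqs[idx], s, s + 2) %in% inv_stops
      }
      keep <- keep | !has_stop
      if (all(keep)) break
    }
    out[idx] <- keep
  }
  out
}
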