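#' Merge a read pair by overlap
#'
#' Aligns the 3' end of the forward read against the 5' end of the
#' reverse-complemented reverse read at every overlap length from
#' `min_overlap` up to the full read, and keeps the candidate with the
#' lowest mismatch fraction (largest overlap on ties). Forward-read bases
#' are taken at mismatching overlap positions.
#'
#' @param fwd forward read (5'->3').
#' @param rev reverse read (5'->3', opposite strand).
#' @param min_overlap minimum acceptable overlap length.
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return list with `merged` (logical), `sequence` (character or NA),
#'   `overlap` and `mismatch_frac`. Rejection is a return state, not an
#'   error.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 50,
                        max_mismatch_frac = 0.1) {
  stopifnot(nchar(fwd) > 0, nchar(rev) > 0)
  rc <- revcomp(rev)
  nf <- nchar(fwd); nr <- nchar(rc)
  max_o <- min(nf, nr)
  if (max_o < min_overlap)
    return(list(merged = FALSE, sequence = NA_character_,
                overlap = NA_integer_, mismatch_frac = NA_real_))
  fc <- strsplit(fwd, "", fixed = TRUE)[[1]]
  rcc <- strsplit(rc, "", fixed = TRUE)[[1]]
  best <- NULL
  for (o in min_overlap:max_o) {
    mm <- sum(fc[(nf - o + 1):nf] != rcc[1:o])
    frac <- mm / o
    if (frac <= max_mismatch_frac &&
        (is.null(best) || frac < best$frac ||
         (frac == best$frac && o > best$o)))
      best <- list(o = o, frac = frac)
  }
  if (is.null(best))
    return(list(merged = FALSE, sequence = NA_character_,
                overlap = NA_integer_, mismatch_frac = NA_real_))
  merged <- paste0(fwd, substring(rc, best$o + 1, nr))
  list(merged = TRUE, sequence = merged, overlap = best$o,
       mismatch_frac = best$frac)
}

#' Demultiplex reads by their 9-bp tag pair
#'
#' A read's forward tag is its first `tag_length` bases and its reverse tag
#' the reverse complement of its last `tag_length` bases. Matching is exact:
#' a read is binned iff its tag pair equals exactly one map entry;
#' everything else lands in the discard bin with reason `"tag_unknown"`.
#' Counts are conserved (binned + discarded = input).
#'
#' @param seqs character vector of read sequences (optionally named).
#' @param tag_map data frame sample_id/replicate/fwd_tag/rev_tag; duplicate
#'   tag pairs are an error at load time.
#' @param tag_length tag length in nt.
#' @return data frame read_id/sequence/sample_id/replicate/reason;
#'   `sample_id` is NA and `reason` is set for discarded reads.
#' @export
demultiplex <- function(seqs, tag_map, tag_length = 9) {
  key_map <- paste(tag_map$fwd_tag, tag_map$rev_tag, sep = "|")
  if (anyDuplicated(key_map))
    stop("duplicate tag pair(s) in tag map: ",
         paste(unique(key_map[duplicated(key_map)]), collapse = ", "))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(seqs))
  seqs <- unname(seqs)
  L <- nchar(seqs)
  fwd <- substr(seqs, 1, tag_length)
  rev_tag <- revcomp(substring(seqs, L - tag_length + 1, L))
  idx <- match(paste(fwd, rev_tag, sep = "|"), key_map)
  out <- data.frame(
    read_id = ids, sequence = seqs,
    sample_id = tag_map$sample_id[idx],
    replicate = tag_map$replicate[idx],
    reason = ifelse(is.na(idx), "tag_unknown", NA_character_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_binned") <- sum(!is.na(idx))
  attr(out, "n_discarded") <- sum(is.na(idx))
  out
}

primer_pattern <- function(primer) {
  Biostrings::DNAString(gsub("I", "N", toupper(primer)))
}

#' Trim degenerate primers from reads
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer in each read (IUPAC degeneracy honoured; inosine matched as N;
#' up to `max_mismatches` mismatches allowed at non-degenerate positions)
#' and returns the insert between them. Reads are tried in the given
#' orientation first, then as their reverse complement.
#'
#' @param seqs character vector of read sequences.
#' @param primers list with `forward` and `reverse`, see [coi_primers()].
#' @param max_mismatches mismatch allowance outside degenerate positions.
#' @return data frame insert/orientation/reason; `insert` is NA with reason
#'   `"primer_not_found"` for rejected reads.
#' @export
trim_primers <- function(seqs, primers = coi_primers(), max_mismatches = 2) {
  fp <- primer_pattern(primers$forward)
  rp <- Biostrings::reverseComplement(primer_pattern(primers$reverse))
  find_inserts <- function(sv) {
    subj <- Biostrings::DNAStringSet(sv)
    mf <- Biostrings::vmatchPattern(fp, subj, max.mismatch = max_mismatches,
                                    fixed = "subject")
    mr <- Biostrings::vmatchPattern(rp, subj, max.mismatch = max_mismatches,
                                    fixed = "subject")
    ef <- Biostrings::endIndex(mf)
    sr <- Biostrings::startIndex(mr)
    start <- vapply(ef, function(e) if (length(e)) min(e) + 1L else NA_integer_,
                    integer(1))
    end <- vapply(sr, function(s) if (length(s)) max(s) - 1L else NA_integer_,
                  integer(1))
    ins <- rep(NA_character_, length(sv))
    ok <- !is.na(start) & !is.na(end) & end >= start
    ins[ok] <- substring(sv[ok], start[ok], end[ok])
    ins
  }
  ins <- find_inserts(seqs)
  orientation <- rep("forward", length(seqs))
  miss <- which(is.na(ins))
  if (length(miss) > 0) {
    ins_rc <- find_inserts(revcomp(seqs[miss]))
    found <- !is.na(ins_rc)
    ins[miss[found]] <- ins_rc[found]
    orientation[miss[found]] <- "reverse"
  }
  data.frame(insert = ins, orientation = orientation,
             reason = ifelse(is.na(ins), "primer_not_found", NA_character_),
             stringsAsFactors = FALSE)
}
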