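#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of mismatched positions among compared sites. For
#' equal-length inputs positions are compared directly, excluding any
#' position with a gap (`-`) or `N` in either sequence (pairwise deletion).
#' Unequal-length inputs are globally aligned (ends free) first and the
#' distance computed over non-gap alignment columns.
#'
#' @param a,b nucleotide strings.
#' @return distance in `[0, 1]`; `NA` (with a warning) when no position is
#'   comparable.
#' @export
p_distance <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) != nchar(b)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "overlap", substitutionMatrix = align_submat(),
      gapOpening = 5, gapExtension = 2)
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  usable <- !(ca %in% c("-", "N")) & !(cb %in% c("-", "N"))
  if (!any(usable)) {
    warning("no comparable positions; p-distance undefined")
    return(NA_real_)
  }
  sum(ca[usable] != cb[usable]) / sum(usable)
}

#' All-pairs p-distance matrix
#'
#' Equal-length pure-ACGT inputs use a vectorised positional comparison;
#' other pairs fall back to [p_distance()].
#'
#' @param seqs character vector of sequences (names kept as dimnames).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1 && all(is_pure_acgt(seqs))) {
    d <- mismatch_count_matrix(unname(seqs)) / lens[1]
  } else {
    d <- matrix(0, n, n)
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- suppressWarnings(p_distance(seqs[i], seqs[j]))
      }
    }
  }
  d <- matrix(as.numeric(d), n, n)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# connected components of the (d <= threshold) graph
threshold_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  if (n > 1) {
    und <- is.na(d)
    if (any(und[upper.tri(und)]))
      message("undefined pairwise distance(s) treated as above threshold")
    edge <- which(!is.na(d) & d <= threshold & upper.tri(d), arr.ind = TRUE)
    if (nrow(edge) > 0) for (k in seq_len(nrow(edge))) {
      ri <- uf_find(parent, edge[k, 1]); rj <- uf_find(parent, edge[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

#' Objective clustering: delimit MOTUs at a p-distance threshold
#'
#' Single-linkage semantics: two sequences share a MOTU iff they are
#' connected by a chain of pairwise p-distances at or below the threshold
#' (connected components of the threshold graph). The partition is
#' invariant to input order: MOTU ids are canonicalised by their
#' representative sequence. Representatives are the member with the highest
#' total read count, ties broken by lexicographically smaller sequence.
#'
#' @param seqs character vector of sequences; names are used as sequence
#'   ids (defaults to seq1..seqN).
#' @param threshold p-distance threshold in (0, 1); default 0.03.
#' @param counts optional numeric vector of total read counts per sequence.
#' @return object of class `motu_partition`: list with `membership`
#'   (data frame sequence_id/sequence/motu_id/representative) and
#'   `representatives` (data frame motu_id/sequence_id/sequence).
#' @export
objective_cluster <- function(seqs, threshold = 0.03, counts = NULL) {
  stopifnot(length(seqs) > 0, threshold > 0, threshold < 1)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  if (is.null(counts)) counts <- rep(1, length(seqs))
  stopifnot(length(counts) == length(seqs))
  d <- p_distance_matrix(seqs)
  comp <- threshold_components(d, threshold)
  rep_of <- vapply(split(seq_along(seqs), comp), function(members) {
    members[order(-counts[members], seqs[members])][1]
  }, integer(1))
  # canonical MOTU order: representative sequence, lexicographic
  comp_ids <- names(rep_of)[order(seqs[rep_of])]
  motu_ids <- setNames(sprintf("MOTU_%04d", seq_along(comp_ids)), comp_ids)
  membership <- data.frame(
    sequence_id = ids, sequence = unname(seqs),
    motu_id = unname(motu_ids[as.character(comp)]),
    representative = seq_along(seqs) %in% rep_of,
    count = counts, stringsAsFactors = FALSE
  )
  reps <- membership[membership$representative,
                     c("motu_id", "sequence_id", "sequence")]
  reps <- reps[order(reps$motu_id), ]
  rownames(reps) <- NULL
  structure(list(membership = membership, representatives = reps,
                 threshold = threshold),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("MOTU partition:", nrow(x$representatives), "MOTUs from",
      nrow(x$membership), "sequences at threshold", x$threshold, "\n")
  invisible(x)
}

#' MOTU counts across a ladder of clustering thresholds
#'
#' The distance matrix is computed once; the MOTU count is the number of
#' connected components at each threshold, which is non-increasing in the
#' threshold.
#'
#' @param seqs character vector of sequences.
#' @param thresholds numeric vector, sorted ascending.
#' @return named integer vector of MOTU counts per threshold.
#' @export
threshold_scan <- function(seqs, thresholds) {
  stopifnot(length(seqs) > 0, !is.unsorted(thresholds))
  d <- p_distance_matrix(seqs)
  counts <- vapply(thresholds, function(t)
    length(unique(threshold_components(d, t))), integer(1))
  setNames(counts, format(thresholds))
}
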