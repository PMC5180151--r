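# Shared pairwise-identity engine for the reference prescreen and taxonomic
# assignment. Identity = matches / aligned columns excluding end gaps;
# overlap = number of those columns. Equal-length pure-ACGT sequences are
# compared positionally (exact for fixed-length amplicons); anything else
# goes through an ends-free global alignment
# (match +1, mismatch -1, gap open -5, gap extend -2).

align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# identity/overlap of one query against one reference via alignment
align_identity_pair <- function(query, ref) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "overlap", substitutionMatrix = align_submat(),
    gapOpening = 5, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  n <- length(a)
  if (n == 0) return(c(identity = NA_real_, overlap = 0))
  c(identity = sum(a == b & a != "-") / n, overlap = n)
}

# identity and overlap matrices (queries x refs)
identity_matrix <- function(queries, refs) {
  nq <- length(queries); nr <- length(refs)
  id <- matrix(NA_real_, nq, nr)
  ov <- matrix(0L, nq, nr)
  lens_q <- nchar(queries); lens_r <- nchar(refs)
  pure_q <- is_pure_acgt(queries); pure_r <- is_pure_acgt(refs)
  for (Lq in unique(lens_q)) {
    qi <- which(lens_q == Lq & pure_q)
    ri <- which(lens_r == Lq & pure_r)
    if (length(qi) > 0 && length(ri) > 0) {
      mm <- mismatch_count_matrix(queries[qi], refs[ri])
      id[qi, ri] <- 1 - mm / Lq
      ov[qi, ri] <- Lq
    }
  }
  # remaining combinations (length mismatch or ambiguity codes): align
  todo <- which(is.na(id), arr.ind = TRUE)
  if (nrow(todo) > 0) {
    for (k in seq_len(nrow(todo))) {
      st <- align_identity_pair(queries[todo[k, 1]], refs[todo[k, 2]])
      id[todo[k, 1], todo[k, 2]] <- st[["identity"]]
      ov[todo[k, 1], todo[k, 2]] <- st[["overlap"]]
    }
  }
  list(identity = id, overlap = ov)
}

# index of the best reference per query: identity desc, then overlap desc,
# then lexicographic ref id
best_reference_index <- function(id, ov, ref_ids) {
  ord <- order(ref_ids)
  vapply(seq_len(nrow(id)), function(i) {
    cand <- ord[order(-id[i, ord], -ov[i, ord])]
    cand[1]
  }, integer(1))
}
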