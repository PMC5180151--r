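#' Dereplicate demultiplexed reads into a replicate table
#'
#' Exact string dereplication of trimmed inserts within each
#' (sample, replicate) bin. Counts are conserved.
#'
#' @param bins data frame with columns `sequence`, `sample_id`, `replicate`
#'   (one row per read).
#' @return a `replicate_table`: data frame `sequence`, `sample_id`,
#'   `replicate`, `count`.
#' @export
dereplicate <- function(bins) {
  if (nrow(bins) == 0)
    return(structure(data.frame(sequence = character(0),
                                sample_id = character(0),
                                replicate = integer(0), count = integer(0)),
                     class = c("replicate_table", "data.frame")))
  key <- paste(bins$sequence, bins$sample_id, bins$replicate, sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(
    sequence = vapply(parts, `[`, character(1), 1),
    sample_id = vapply(parts, `[`, character(1), 2),
    replicate = as.integer(vapply(parts, `[`, character(1), 3)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("replicate_table", "data.frame"))
}

# pairs of unique sequences within edit distance <= max_edit, as an
# adjacency list (neighbors[[i]] = integer indices)
neighbor_adjacency <- function(useqs, max_edit) {
  n <- length(useqs)
  nb <- vector("list", n)
  lens <- nchar(useqs)
  pure <- is_pure_acgt(useqs)
  add_pairs <- function(pi, pj) {
    for (k in seq_along(pi)) {
      nb[[pi[k]]] <<- c(nb[[pi[k]]], pj[k])
      nb[[pj[k]]] <<- c(nb[[pj[k]]], pi[k])
    }
  }
  groups <- split(seq_len(n), lens)
  glens <- as.integer(names(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    # within-length pairs
    if (length(idx) > 1) {
      if (all(pure[idx])) {
        mm <- mismatch_count_matrix(useqs[idx])
        hit <- which(mm <= max_edit & upper.tri(mm), arr.ind = TRUE)
      } else {
        d <- adist(useqs[idx])
        hit <- which(d <= max_edit & upper.tri(d), arr.ind = TRUE)
      }
      if (nrow(hit) > 0) add_pairs(idx[hit[, 1]], idx[hit[, 2]])
    }
    # cross-length pairs (indels): only lengths within max_edit can qualify
    for (h in seq_along(groups)) {
      if (glens[h] <= glens[g] || glens[h] - glens[g] > max_edit) next
      d <- adist(useqs[idx], useqs[groups[[h]]])
      hit <- which(d <= max_edit, arr.ind = TRUE)
      if (nrow(hit) > 0) add_pairs(idx[hit[, 1]], groups[[h]][hit[, 2]])
    }
  }
  nb
}

#' Absorb putative PCR/sequencing error variants into abundant parents
#'
#' Within each (sample, replicate), a sequence is absorbed into a parent
#' when their edit distance is at most `max_edit` and the parent's count is
#' at least `abundance_ratio` times the child's. Absorption adds the child's
#' count to the parent; absorption passes repeat to a fixpoint, children
#' processed in ascending-count order and ties among eligible parents broken
#' by higher count then lexicographically smaller sequence. Row count never
#' increases and total read count is conserved.
#'
#' @param table a `replicate_table` from [dereplicate()].
#' @param max_edit maximum edit distance child-to-parent (>= 1).
#' @param abundance_ratio minimum parent:child count ratio (> 1).
#' @return pruned `replicate_table`.
#' @export
prune_errors <- function(table, max_edit = 1, abundance_ratio = 10) {
  stopifnot(max_edit >= 1, abundance_ratio > 1)
  if (nrow(table) == 0) return(table)
  grp <- paste(table$sample_id, table$replicate, sep = "\t")
  keep_rows <- logical(nrow(table))
  new_count <- table$count
  for (rows in split(seq_len(nrow(table)), grp)) {
    seqs <- table$sequence[rows]
    # neighbours are only ever consulted within one replicate, so the
    # adjacency is computed per group
    nb <- neighbor_adjacency(seqs, max_edit)
    cnt <- new_count[rows]
    alive <- rep(TRUE, length(rows))
    repeat {
      changed <- FALSE
      for (k in order(cnt, seqs)) {
        if (!alive[k]) next
        lp <- nb[[k]]
        if (length(lp) == 0) next
        lp <- lp[alive[lp] & cnt[lp] >= abundance_ratio * cnt[k]]
        if (length(lp) == 0) next
        parent <- lp[order(-cnt[lp], seqs[lp])][1]
        cnt[parent] <- cnt[parent] + cnt[k]
        cnt[k] <- 0L
        alive[k] <- FALSE
        changed <- TRUE
      }
      if (!changed) break
    }
    keep_rows[rows] <- alive
    new_count[rows] <- cnt
  }
  out <- table[keep_rows, , drop = FALSE]
  out$count <- new_count[keep_rows]
  rownames(out) <- NULL
  structure(out, class = c("replicate_table", "data.frame"))
}

#' Reference-identity prescreen with non-metazoan exclusion
#'
#' Computes each sequence's best hit over the whole reference collection
#' (exhaustive pairwise comparison). A sequence is discarded when its
#' overall best hit is to a non-metazoan reference, or when its best
#' identity to any metazoan reference is below `min_identity`.
#'
#' @param seqs character vector of unique sequences.
#' @param refdb reference data frame with columns `ref_id`, `sequence`,
#'   `species`, `phylum`, `is_metazoan` (see [read_reference_fasta()]).
#' @param min_identity minimum metazoan best-hit identity (default 0.80).
#' @return data frame `sequence`, `keep`, `reason`
#'   (`identity_lt_80`/`nonmetazoan_besthit`/NA), `best_ref_id`, `identity`,
#'   `overlap`.
#' @export
identity_prescreen <- function(seqs, refdb, min_identity = 0.80) {
  if (nrow(refdb) == 0) stop("reference database is empty")
  if (length(seqs) == 0)
    return(data.frame(sequence = character(0), keep = logical(0),
                      reason = character(0), best_ref_id = character(0),
                      identity = numeric(0), overlap = integer(0)))
  im <- identity_matrix(seqs, refdb$sequence)
  best <- best_reference_index(im$identity, im$overlap, refdb$ref_id)
  best_id <- im$identity[cbind(seq_along(seqs), best)]
  best_ov <- im$overlap[cbind(seq_along(seqs), best)]
  meta_cols <- which(refdb$is_metazoan)
  best_meta_id <- if (length(meta_cols) > 0) {
    apply(im$identity[, meta_cols, drop = FALSE], 1, max, na.rm = TRUE)
  } else rep(-Inf, length(seqs))
  nonmeta_best <- !refdb$is_metazoan[best]
  reason <- rep(NA_character_, length(seqs))
  reason[best_meta_id < min_identity] <- "identity_lt_80"
  reason[nonmeta_best] <- "nonmetazoan_besthit"
  data.frame(sequence = seqs, keep = is.na(reason), reason = reason,
             best_ref_id = refdb$ref_id[best], identity = best_id,
             overlap = best_ov, stringsAsFactors = FALSE)
}

#' PCR-replicate consistency filter
#'
#' Retains a sequence for a sample iff it was observed (count > 0) in at
#' least `min_replicates` of that sample's `n_replicates` replicate PCRs.
#'
#' @param table a `replicate_table`.
#' @param min_replicates minimum replicates a sequence must appear in.
#' @param n_replicates nominal replicates per sample; a sample whose
#'   observed replicate set differs triggers a warning and the threshold is
#'   applied to the available replicates.
#' @return data frame `sequence`, `sample_id`, `n_detected`, `count`
#'   (summed reads over replicates) of retained sequences.
#' @export
replicate_filter <- function(table, min_replicates = 3, n_replicates = 5) {
  stopifnot(min_replicates <= n_replicates)
  if (nrow(table) == 0)
    return(data.frame(sequence = character(0), sample_id = character(0),
                      n_detected = integer(0), count = integer(0)))
  obs <- tapply(table$replicate, table$sample_id,
                function(r) length(unique(r)))
  if (any(obs != n_replicates))
    warning("sample(s) with replicate count != ", n_replicates, ": ",
            paste(names(obs)[obs != n_replicates], collapse = ", "),
            "; threshold applied to available replicates")
  key <- paste(table$sequence, table$sample_id, sep = "\t")
  pos <- table$count > 0
  ndet <- tapply(pos, key, sum)
  tot <- tapply(table$count, key, sum)
  keep <- names(ndet)[ndet >= min_replicates]
  parts <- strsplit(keep, "\t", fixed = TRUE)
  out <- data.frame(
    sequence = vapply(parts, `[`, character(1), 1),
    sample_id = vapply(parts, `[`, character(1), 2),
    n_detected = as.integer(ndet[keep]),
    count = as.integer(tot[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the full retention-rule cascade on demultiplexed reads
#'
#' Applies, in order: length filter, error pruning, reference-identity
#' prescreen with non-metazoan exclusion, mitochondrial translation check,
#' and the replicate-consistency rule. Produces a per-sample filter report
#' whose per-rule discard counts plus retained uniques reconstruct the
#' input uniques exactly.
#'
#' @param bins read-level data frame `sequence`, `sample_id`, `replicate`
#'   (e.g. trimmed inserts of demultiplexed reads).
#' @param refdb reference data frame, see [identity_prescreen()].
#' @param insert_length,length_tolerance accepted insert length band.
#' @param max_edit,abundance_ratio see [prune_errors()].
#' @param min_identity see [identity_prescreen()].
#' @param min_replicates,n_replicates see [replicate_filter()].
#' @return list with `retained` (data frame sequence/sample_id/n_detected/
#'   count), `report` (per-sample rule counts), `prescreen` (best-hit table
#'   of prescreened sequences), and `table` (pruned replicate table).
#' @export
filter_sequences <- function(bins, refdb, insert_length = 313,
                             length_tolerance = 0, max_edit = 1,
                             abundance_ratio = 10, min_identity = 0.80,
                             min_replicates = 3, n_replicates = 5) {
  table0 <- dereplicate(bins)
  samples <- sort(unique(table0$sample_id))
  uniq_by_sample <- function(tab)
    lapply(setNames(samples, samples), function(s)
      unique(tab$sequence[tab$sample_id == s]))
  u_in <- uniq_by_sample(table0)

  # stage 1: length
  len_ok <- abs(nchar(table0$sequence) - insert_length) <= length_tolerance
  table1 <- table0[len_ok, , drop = FALSE]
  u1 <- uniq_by_sample(table1)

  # stage 2: error pruning (per replicate)
  table2 <- prune_errors(table1, max_edit = max_edit,
                         abundance_ratio = abundance_ratio)
  u2 <- uniq_by_sample(table2)

  # stage 3: reference-identity prescreen (per unique sequence)
  useqs <- unique(table2$sequence)
  pre <- identity_prescreen(useqs, refdb, min_identity = min_identity)
  keep3 <- pre$sequence[pre$keep]
  table3 <- table2[table2$sequence %in% keep3, , drop = FALSE]
  u3 <- uniq_by_sample(table3)

  # stage 4: translation filter
  useqs3 <- unique(table3$sequence)
  transl_ok <- translation_filter(useqs3)
  table4 <- table3[table3$sequence %in% useqs3[transl_ok], , drop = FALSE]
  u4 <- uniq_by_sample(table4)

  # stage 5: replicate consistency
  retained <- replicate_filter(table4, min_replicates = min_replicates,
                               n_replicates = n_replicates)
  u5 <- lapply(setNames(samples, samples), function(s)
    retained$sequence[retained$sample_id == s])

  reason_counts <- function(before, after)
    vapply(samples, function(s) length(setdiff(before[[s]], after[[s]])),
           integer(1))
  pre_reason <- setNames(pre$reason, pre$sequence)
  count_pre <- function(code)
    vapply(samples, function(s) {
      gone <- setdiff(u2[[s]], u3[[s]])
      sum(pre_reason[gone] == code, na.rm = TRUE)
    }, integer(1))

  report <- data.frame(
    sample_id = samples,
    input_uniques = lengths(u_in),
    length = reason_counts(u_in, u1),
    error_pruned = reason_counts(u1, u2),
    identity_lt_80 = count_pre("identity_lt_80"),
    nonmetazoan_besthit = count_pre("nonmetazoan_besthit"),
    untranslatable = reason_counts(u3, u4),
    replicate_lt_3 = reason_counts(u4, u5),
    retained = lengths(u5),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(retained = retained, report = report, prescreen = pre, table = table4)
}
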