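# shared fixtures and independent oracles, built in code at test time

# a small two-habitat design + pool + noiseless simulation
small_design <- function(seed = 1, n_sites = 2, n_replicates = 5) {
  study_design(n_sites = n_sites, n_replicates = n_replicates, seed = seed)
}

small_pool <- function(seed = 2, design = small_design(),
                       n = c(4, 3, 2), n_contaminant = 0, ...) {
  generate_species_pool(n[1], n[2], n[3], n_contaminant = n_contaminant,
                        seed = seed, design = design, ...)
}

random_acgt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# independent single-linkage oracle: boolean transitive closure of the
# (d <= threshold) adjacency matrix
closure_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # component label = smallest connected index
  apply(adj, 1, function(row) min(which(row)))
}

# partitions are equal up to relabelling
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# replicate-table constructor for hand-traced filter examples
rt <- function(sequence, count, sample_id = "S1", replicate = 1) {
  structure(data.frame(sequence = sequence, sample_id = sample_id,
                       replicate = replicate, count = count,
                       stringsAsFactors = FALSE),
            class = c("replicate_table", "data.frame"))
}

ref_row <- function(ref_id, sequence, species = ref_id,
                    phylum = "Arthropoda", is_metazoan = TRUE) {
  data.frame(ref_id = ref_id, sequence = sequence, species = species,
             phylum = phylum, is_metazoan = is_metazoan,
             stringsAsFactors = FALSE)
}

# mutate exactly k positions of a sequence (deterministic positions)
mutate_at <- function(seq, pos, to = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(pos)) {
    p <- pos[i]
    repl <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), chars[p])[1]
    else to[i]
    chars[p] <- repl
  }
  paste(chars, collapse = "")
}
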