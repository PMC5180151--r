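#' Degenerate metazoan COI primer pair
#'
#' The universal metazoan primer pair amplifying a 313-bp fragment of COI
#' (forward mlCOIintF-style, reverse jgHCO2198-style). Degenerate IUPAC
#' positions are retained; inosine is written as "I" and matched as N.
#'
#' @return list with `forward` and `reverse` primer strings (5'->3').
#' @export
coi_primers <- function() {
  list(forward = "GGWACWGGWTGAACWGTWTAYCCYCC",
       reverse = "TAIACYTCIGGRTGICCRAARAAYCA")
}

# realize a degenerate primer into n concrete A/C/G/T strings
realize_primer <- function(primer, n) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  cols <- lapply(chars, function(code) {
    set <- IUPAC_SETS[[code]]
    if (length(set) == 1) rep(set, n) else sample(set, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# apply k substitution errors to each sequence (k may be 0)
apply_substitutions <- function(seqs, n_errors) {
  idx <- which(n_errors > 0)
  if (length(idx) == 0) return(seqs)
  if (length(unique(nchar(seqs[idx]))) == 1) {
    # vectorised path for fixed-length inserts
    M <- seq_raw_matrix(seqs[idx])
    L <- ncol(M); n <- nrow(M)
    pos <- unlist(lapply(seq_along(idx), function(i)
      sample.int(L, n_errors[idx[i]])))
    cells <- cbind(rep(seq_along(idx), n_errors[idx]), pos)
    old <- rawToChar(M[cells], multiple = TRUE)
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3, length(old), replace = TRUE)
    base_idx <- match(old, DNA_BASES)
    M[cells] <- charToRaw(paste(
      DNA_BASES[((base_idx - 1 + shift) %% 4) + 1], collapse = ""))
    big <- rawToChar(as.vector(t(M)))
    seqs[idx] <- substring(big, seq(1, n * L, L), seq(L, n * L, L))
    return(seqs)
  }
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_errors[i])
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a tagged amplicon sequencing run
#'
#' Emits merged-orientation reads of the form
#' `fwd_tag + fwd_primer + insert + revcomp(rev_primer) + revcomp(rev_tag)`
#' for every (sample, replicate) PCR in the design, together with the ground
#' truth needed to verify the downstream pipeline. Noise processes:
#' per-(species, replicate) dropout, per-base substitution errors on the
#' insert, and single-breakpoint PCR chimeras between two parents amplified
#' in the same replicate. Read counts per surviving species are one
#' guaranteed read plus a multinomial draw weighted by relative abundance,
#' so that detection failures are governed by `dropout_prob` alone.
#'
#' @param pool a [generate_species_pool()] result.
#' @param design a [study_design()]; defaults to the pool's design.
#' @param error_rate per-base substitution probability on the insert.
#' @param dropout_prob per-(species, replicate) amplification failure
#'   probability.
#' @param chimera_rate per-read probability of being replaced by a chimera.
#' @param depth_per_replicate reads per replicate PCR; must be at least the
#'   number of species present in the replicate.
#' @param paired also emit 250-bp read pairs (read2 reverse-complemented)
#'   for exercising pair merging.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return object of class `edna_sim`: list with `reads` (data frame
#'   read_id/sample_id/replicate/species_id/sequence), `truth` (list with
#'   `replicate_presence` data frame and `incidence` species x sample
#'   matrix), `tag_map`, and optionally `pairs`.
#' @export
simulate_reads <- function(pool, design = pool$design, error_rate = 0,
                           dropout_prob = 0, chimera_rate = 0,
                           depth_per_replicate = 100, paired = FALSE,
                           seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            depth_per_replicate >= 0)
  primers <- coi_primers()
  tag_map <- design$tag_map
  occ <- pool$occupancy
  abund <- pool$species$relative_abundance
  names(abund) <- pool$species$species_id
  hap_by_sp <- split(pool$haplotypes$sequence, pool$haplotypes$species_id)
  single_hap <- all(lengths(hap_by_sp) == 1)
  hap1 <- vapply(hap_by_sp, `[`, character(1), 1)

  with_seed(seed, {
    rows <- vector("list", nrow(tag_map))
    presence <- vector("list", nrow(tag_map))
    for (j in seq_len(nrow(tag_map))) {
      s <- tag_map$sample_id[j]; r <- tag_map$replicate[j]
      occupied <- rownames(occ)[occ[, s] == 1]
      survived <- if (dropout_prob > 0 && length(occupied) > 0) {
        occupied[runif(length(occupied)) >= dropout_prob]
      } else occupied
      presence[[j]] <- if (length(occupied) > 0)
        data.frame(species_id = occupied, sample_id = s, replicate = r,
                   present = occupied %in% survived,
                   stringsAsFactors = FALSE)
      n_p <- length(survived)
      if (n_p == 0 || depth_per_replicate == 0) next
      if (depth_per_replicate < n_p)
        stop("depth_per_replicate (", depth_per_replicate,
             ") below the number of species present (", n_p, ") in ",
             s, " replicate ", r)
      extra <- as.vector(rmultinom(1, depth_per_replicate - n_p,
                                   abund[survived]))
      counts <- 1L + extra
      sp_of_read <- rep(survived, counts)
      inserts <- if (single_hap) unname(hap1[sp_of_read])
      else vapply(sp_of_read, function(sp) {
        h <- hap_by_sp[[sp]]
        if (length(h) == 1) h else sample(h, 1)
      }, character(1), USE.NAMES = FALSE)

      if (chimera_rate > 0 && n_p >= 2) {
        n_c <- rbinom(1, length(inserts), chimera_rate)
        if (n_c > 0) {
          slots <- sample.int(length(inserts), n_c)
          for (k in slots) {
            par <- sample(survived, 2)
            bp <- sample(50:263, 1)
            p1 <- hap_by_sp[[par[1]]][1]; p2 <- hap_by_sp[[par[2]]][1]
            inserts[k] <- paste0(substr(p1, 1, bp),
                                 substr(p2, bp + 1, nchar(p2)))
            sp_of_read[k] <- paste0("chimera:", par[1], "+", par[2])
          }
        }
      }
      if (error_rate > 0) {
        n_err <- rbinom(length(inserts), nchar(inserts), error_rate)
        inserts <- apply_substitutions(inserts, n_err)
      }

      n_reads <- length(inserts)
      fwd_p <- realize_primer(primers$forward, n_reads)
      rev_p <- realize_primer(primers$reverse, n_reads)
      seqs <- paste0(tag_map$fwd_tag[j], fwd_p, inserts, revcomp(rev_p),
                     revcomp(tag_map$rev_tag[j]))
      rows[[j]] <- data.frame(sample_id = s, replicate = r,
                              species_id = sp_of_read, sequence = seqs,
                              stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(reads))
      reads <- data.frame(sample_id = character(0), replicate = integer(0),
                          species_id = character(0), sequence = character(0))
    if (nrow(reads) > 0)
      reads <- cbind(read_id = sprintf("read%07d", seq_len(nrow(reads))),
                     reads, stringsAsFactors = FALSE)
    else reads$read_id <- character(0)
    presence <- do.call(rbind, presence)

    # true incidence = occupancy restricted to species with any surviving
    # replicate recorded separately; occupancy itself is the design truth
    out <- list(reads = reads,
                truth = list(replicate_presence = presence,
                             incidence = occ),
                tag_map = tag_map, design = design)
    if (paired && nrow(reads) > 0) {
      L <- nchar(reads$sequence)
      out$pairs <- data.frame(
        read_id = reads$read_id,
        fwd = substr(reads$sequence, 1, pmin(250, L)),
        rev = revcomp(substring(reads$sequence, pmax(1, L - 249), L)),
        stringsAsFactors = FALSE
      )
    }
    class(out) <- "edna_sim"
    out
  })
}

#' @export
print.edna_sim <- function(x, ...) {
  cat("Simulated run:", nrow(x$reads), "reads over",
      length(unique(x$reads$sample_id)), "samples\n")
  invisible(x)
}

#' Write reads as FASTQ (Phred+33, constant Q37)
#'
#' @param x `edna_sim` object, or a named character vector of sequences.
#' @param path output file; a `.gz` suffix enables gzip compression.
#' @export
write_fastq <- function(x, path) {
  if (inherits(x, "edna_sim")) {
    ids <- x$reads$read_id; seqs <- x$reads$sequence
  } else {
    ids <- names(x); seqs <- unname(x)
  }
  qual <- vapply(nchar(seqs), function(n)
    strrep(rawToChar(as.raw(37 + 33)), n), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file (optionally gzipped).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file (optionally gzipped).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Write simulation ground truth and tag map as TSV
#' @param sim `edna_sim` object.
#' @param dir output directory (created if needed).
#' @export
write_ground_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$truth$replicate_presence,
                     file.path(dir, "replicate_presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inc <- as.data.frame(sim$truth$incidence)
  inc <- cbind(species_id = rownames(sim$truth$incidence), inc)
  utils::write.table(inc, file.path(dir, "incidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tag_map, file.path(dir, "tag_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
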