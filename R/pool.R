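#' Study design: habitats, sites, depths, PCR replicates, tag map
#'
#' Emulates a two-reservoir water eDNA survey: by default 2 habitats x
#' 7 sites x 2 depths (surface, benthic), each DNA extract amplified in 5
#' replicate PCRs, and every (sample, replicate) PCR carrying a unique pair
#' of 9-bp tags at the primer 5' ends.
#'
#' @param habitats two habitat labels.
#' @param n_sites sites per habitat.
#' @param depths depth labels per site.
#' @param n_replicates replicate PCRs per DNA extract.
#' @param tag_length tag length in nt.
#' @param seed integer seed for tag generation.
#' @return object of class `study_design`: list with `samples` (data frame
#'   sample_id/habitat/site/depth) and `tag_map` (data frame
#'   sample_id/replicate/fwd_tag/rev_tag).
#' @export
study_design <- function(habitats = c("A", "B"), n_sites = 7,
                         depths = c("surface", "benthic"),
                         n_replicates = 5, tag_length = 9, seed = 1) {
  stopifnot(length(habitats) >= 1, n_sites >= 1, n_replicates >= 1)
  samples <- expand.grid(depth = depths, site = seq_len(n_sites),
                         habitat = habitats, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("habitat", "site", "depth")]
  samples$sample_id <- sprintf("%s_S%d_%s", samples$habitat, samples$site,
                               samples$depth)
  samples <- samples[, c("sample_id", "habitat", "site", "depth")]
  rownames(samples) <- NULL

  n_pcr <- nrow(samples) * n_replicates
  tags <- with_seed(seed, {
    # draw distinct tags; 4^9 = 262144 sequences so collisions are rare
    out <- character(0)
    while (length(out) < 2 * n_pcr) {
      cand <- vapply(seq_len(2 * n_pcr - length(out)), function(i)
        paste(sample(DNA_BASES, tag_length, replace = TRUE), collapse = ""),
        character(1))
      out <- unique(c(out, cand))
    }
    out
  })
  tag_map <- data.frame(
    sample_id = rep(samples$sample_id, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = nrow(samples)),
    fwd_tag = tags[seq_len(n_pcr)],
    rev_tag = tags[n_pcr + seq_len(n_pcr)],
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, tag_map = tag_map,
                 habitats = habitats, n_sites = n_sites, depths = depths,
                 n_replicates = n_replicates),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$habitats), "habitats x", x$n_sites,
      "sites x", length(x$depths), "depths;", x$n_replicates,
      "replicate PCRs (", nrow(x$tag_map), "tag pairs )\n")
  invisible(x)
}

# one random codon-clean 313-nt barcode: 104 codons (invertebrate
# mitochondrial code, no stops) + 1 trailing nt, frame offset 0
random_barcode <- function(n, length_nt = 313) {
  codons <- non_stop_codons("invertebrate")
  n_codons <- length_nt %/% 3
  tail_len <- length_nt - 3 * n_codons
  vapply(seq_len(n), function(i) {
    s <- paste(sample(codons, n_codons, replace = TRUE), collapse = "")
    if (tail_len > 0)
      s <- paste0(s, paste(sample(DNA_BASES, tail_len, replace = TRUE),
                           collapse = ""))
    s
  }, character(1))
}

# mutate up to `k` positions of a barcode, keeping frame 0 stop-free
mutate_barcode <- function(barcode, k) {
  for (attempt in 1:50) {
    pos <- sample.int(nchar(barcode), k)
    chars <- strsplit(barcode, "", fixed = TRUE)[[1]]
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    out <- paste(chars, collapse = "")
    if (stop_free_frames(out, "invertebrate")[1]) return(out)
  }
  stop("could not place haplotype mutations without creating stop codons")
}

#' Generate a ground-truthed species pool
#'
#' Builds a pool of species with codon-clean 313-nt COI-like barcodes,
#' split into habitat-A-only, habitat-B-only and shared species, plus
#' optional non-metazoan contaminants. Barcodes are mutually divergent
#' (pairwise p-distance > `min_divergence`), haplotypes of one species are
#' close (at most `max_haplotype_mutations` substitutions from the primary
#' barcode), and each species receives a lognormal relative abundance and a
#' per-sample occupancy pattern over the study design.
#'
#' @param n_a_only,n_b_only,n_shared,n_contaminant species counts per class.
#' @param seed integer seed.
#' @param design a [study_design()]; defaults to `study_design(seed = seed)`.
#' @param n_haplotypes haplotypes per species (>= 1).
#' @param occupancy per-(species, sample) presence probability within the
#'   species' habitat(s); each species is guaranteed at least one sample.
#' @param min_divergence minimum inter-species barcode p-distance.
#' @param max_haplotype_mutations cap on substitutions per extra haplotype.
#' @param barcode_length barcode length in nt.
#' @return object of class `species_pool`: list with `species` (data frame),
#'   `haplotypes` (data frame species_id/haplotype_id/sequence), `occupancy`
#'   (species x sample 0/1 matrix) and `design`.
#' @export
generate_species_pool <- function(n_a_only, n_b_only, n_shared,
                                  n_contaminant = 0, seed = 1,
                                  design = NULL, n_haplotypes = 1,
                                  occupancy = 0.6, min_divergence = 0.08,
                                  max_haplotype_mutations = 4,
                                  barcode_length = 313) {
  stopifnot(n_a_only >= 0, n_b_only >= 0, n_shared >= 0, n_contaminant >= 0,
            n_haplotypes >= 1, occupancy > 0, occupancy <= 1)
  n_meta <- n_a_only + n_b_only + n_shared
  if (n_meta < 1) stop("at least one metazoan species is required")
  if (is.null(design)) design <- study_design(seed = seed)

  metazoan_phyla <- c("Arthropoda", "Chordata", "Mollusca", "Annelida",
                      "Rotifera", "Cnidaria", "Nematoda")
  contaminant_phyla <- c("Chlorophyta", "Bacillariophyta", "Ascomycota")

  with_seed(seed, {
    n_total <- n_meta + n_contaminant
    barcodes <- random_barcode(n_total, barcode_length)
    # enforce inter-species spacing; random codon sequences are ~0.7 apart,
    # so resampling is a safety valve, not the common path
    for (round in 1:50) {
      mm <- mismatch_count_matrix(barcodes)
      pd <- mm / barcode_length
      diag(pd) <- 1
      bad <- which(apply(pd, 1, min) <= min_divergence)
      if (length(bad) == 0) break
      if (round == 50)
        stop("cannot space ", n_total, " species barcodes at p-distance > ",
             min_divergence, " for length ", barcode_length)
      barcodes[bad] <- random_barcode(length(bad), barcode_length)
    }

    membership <- c(rep("A-only", n_a_only), rep("B-only", n_b_only),
                    rep("shared", n_shared), rep("shared", n_contaminant))
    is_meta <- c(rep(TRUE, n_meta), rep(FALSE, n_contaminant))
    species_id <- c(sprintf("sp%04d", seq_len(n_meta)),
                    if (n_contaminant > 0)
                      sprintf("cont%02d", seq_len(n_contaminant)))
    phylum <- ifelse(is_meta,
                     sample(metazoan_phyla, n_total, replace = TRUE),
                     sample(contaminant_phyla, n_total, replace = TRUE))
    species <- data.frame(
      species_id = species_id,
      phylum = phylum,
      is_metazoan = is_meta,
      habitat_membership = membership,
      relative_abundance = rlnorm(n_total, 0, 1),
      barcode = barcodes,
      stringsAsFactors = FALSE
    )

    # haplotypes: primary barcode plus close variants (< threshold apart)
    hap <- do.call(rbind, lapply(seq_len(n_total), function(i) {
      seqs <- barcodes[i]
      if (n_haplotypes > 1) {
        extra <- vapply(seq_len(n_haplotypes - 1), function(j)
          mutate_barcode(barcodes[i],
                         sample.int(max_haplotype_mutations, 1)),
          character(1))
        seqs <- c(seqs, extra)
      }
      data.frame(species_id = species_id[i],
                 haplotype_id = sprintf("%s_h%d", species_id[i],
                                        seq_along(seqs)),
                 sequence = seqs, stringsAsFactors = FALSE)
    }))

    # occupancy: Bernoulli(occupancy) over the samples of the species'
    # habitat(s); rows drawn all-zero are redrawn so every species occurs
    samples <- design$samples
    occ <- matrix(0L, n_total, nrow(samples),
                  dimnames = list(species_id, samples$sample_id))
    hab_a <- design$habitats[1]; hab_b <- design$habitats[2]
    for (i in seq_len(n_total)) {
      eligible <- switch(membership[i],
        "A-only" = samples$habitat == hab_a,
        "B-only" = samples$habitat == hab_b,
        "shared" = rep(TRUE, nrow(samples)))
      repeat {
        draw <- rbinom(sum(eligible), 1, occupancy)
        if (any(draw == 1)) break
      }
      occ[i, eligible] <- draw
    }

    structure(list(species = species, haplotypes = hap, occupancy = occ,
                   design = design, barcode_length = barcode_length),
              class = "species_pool")
  })
}

#' @export
print.species_pool <- function(x, ...) {
  tab <- table(x$species$habitat_membership[x$species$is_metazoan])
  cat("Species pool:", nrow(x$species), "species (",
      sum(!x$species$is_metazoan), "non-metazoan contaminants );",
      "metazoan membership:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
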