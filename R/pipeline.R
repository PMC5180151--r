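#' Pipeline configuration
#'
#' All stage parameters of [run_pipeline()] with their defaults. The
#' configuration round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param ... parameter overrides, see Details.
#' @details Parameters: `threshold` (MOTU p-distance threshold, 0.03),
#'   `scan_thresholds` (stability scan ladder, c(0.02, 0.03, 0.04)),
#'   `insert_length`/`length_tolerance` (313 / 0), `max_edit` and
#'   `abundance_ratio` (error pruning, 1 / 10), `min_identity` (prescreen,
#'   0.80), `min_replicates`/`n_replicates` (3 / 5),
#'   `min_species_identity`/`min_overlap`/`min_higher_identity`
#'   (taxonomy bands, 0.97 / 310 / 0.90), `common_min_samples` (4),
#'   `max_primer_mismatches` (2), `do_nmds` (FALSE), `seed` (1).
#' @return object of class `edna_config` (named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    threshold = 0.03,
    scan_thresholds = c(0.02, 0.03, 0.04),
    insert_length = 313,
    length_tolerance = 0,
    max_edit = 1,
    abundance_ratio = 10,
    min_identity = 0.80,
    min_replicates = 3,
    n_replicates = 5,
    min_species_identity = 0.97,
    min_overlap = 310,
    min_higher_identity = 0.90,
    common_min_samples = 4,
    max_primer_mismatches = 2,
    do_nmds = FALSE,
    seed = 1
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  structure(modifyList(defaults, override), class = "edna_config")
}

#' @rdname pipeline_config
#' @param config an `edna_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full eDNA metabarcoding pipeline
#'
#' Composes the stages end to end: demultiplexing by tag pair, primer
#' trimming, the retention-rule cascade ([filter_sequences()]), objective
#' MOTU clustering with a threshold-stability scan, identity-band taxonomy,
#' the MOTU x sample table, per-habitat richness estimates and sample
#' dissimilarities, and the habitat-signature analysis. A machine-readable
#' manifest records parameters and per-stage record counts; samples flagged
#' `control = TRUE` in the metadata must end with zero retained sequences
#' for the run to be marked clean (violations warn, not abort).
#'
#' @param reads named character vector of read sequences, a FASTQ path, or
#'   an `edna_sim` object (whose tag map and design metadata are reused).
#' @param tag_map data frame sample_id/replicate/fwd_tag/rev_tag.
#' @param metadata data frame sample_id/habitat/site/depth, optional
#'   `control` column.
#' @param refdb reference data frame, see [read_reference_fasta()].
#' @param config an [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/FASTA/JSON artifacts.
#' @return object of class `edna_run`: list with `demux`, `filter`,
#'   `partition`, `scan`, `assignments`, `motu_table`, `ecology`,
#'   `habitat`, `manifest`.
#' @export
run_pipeline <- function(reads, tag_map = NULL, metadata = NULL, refdb,
                         config = pipeline_config(), out_dir = NULL) {
  if (inherits(reads, "edna_sim")) {
    sim <- reads
    if (is.null(tag_map)) tag_map <- sim$tag_map
    if (is.null(metadata)) metadata <- sim$design$samples
    reads <- setNames(sim$reads$sequence, sim$reads$read_id)
  } else if (is.character(reads) && length(reads) == 1 &&
             file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.null(tag_map) || is.null(metadata))
    stop("tag_map and metadata are required unless reads is an edna_sim")
  if (is.null(metadata$control)) metadata$control <- FALSE

  manifest <- list(parameters = unclass(config),
                   stages = list(reads_in = length(reads)))

  # stage: demultiplex
  demux <- demultiplex(reads, tag_map)
  binned <- demux[!is.na(demux$sample_id), , drop = FALSE]
  manifest$stages$reads_binned <- nrow(binned)
  manifest$stages$reads_tag_discarded <- sum(is.na(demux$sample_id))

  # stage: primer trimming
  trims <- trim_primers(binned$sequence,
                        max_mismatches = config$max_primer_mismatches)
  bins <- data.frame(sequence = trims$insert,
                     sample_id = binned$sample_id,
                     replicate = binned$replicate,
                     stringsAsFactors = FALSE)
  bins <- bins[!is.na(bins$sequence), , drop = FALSE]
  manifest$stages$reads_trimmed <- nrow(bins)
  manifest$stages$reads_primer_rejected <- sum(is.na(trims$insert))

  # stage: retention-rule cascade
  filt <- filter_sequences(
    bins, refdb, insert_length = config$insert_length,
    length_tolerance = config$length_tolerance,
    max_edit = config$max_edit, abundance_ratio = config$abundance_ratio,
    min_identity = config$min_identity,
    min_replicates = config$min_replicates,
    n_replicates = config$n_replicates)
  manifest$stages$uniques_in <- length(unique(bins$sequence))
  manifest$stages$uniques_retained <- length(unique(filt$retained$sequence))
  manifest$stages$filter_report <- filt$report

  # negative controls must come out empty
  control_samples <- metadata$sample_id[metadata$control]
  dirty <- intersect(unique(filt$retained$sample_id), control_samples)
  manifest$negative_controls_clean <- length(dirty) == 0
  if (length(dirty) > 0)
    warning("negative control sample(s) with retained sequences: ",
            paste(dirty, collapse = ", "))

  # stage: clustering (+ threshold stability scan)
  useqs <- unique(filt$retained$sequence)
  if (length(useqs) == 0) stop("no sequences retained; nothing to cluster")
  tot <- tapply(filt$retained$count, filt$retained$sequence, sum)
  partition <- objective_cluster(setNames(useqs, sprintf(
    "uniq%05d", seq_along(useqs))), threshold = config$threshold,
    counts = as.numeric(tot[useqs]))
  scan <- threshold_scan(useqs, config$scan_thresholds)
  manifest$stages$n_motus <- nrow(partition$representatives)
  manifest$stages$threshold_scan <- as.list(scan)

  # stage: taxonomy on MOTU representatives
  reps <- setNames(partition$representatives$sequence,
                   partition$representatives$motu_id)
  assignments <- assign_taxa(
    best_match(reps, refdb),
    min_species_identity = config$min_species_identity,
    min_overlap = config$min_overlap,
    min_higher_identity = config$min_higher_identity)
  manifest$stages$n_species_assigned <-
    sum(assignments$level == "species")

  # stage: MOTU table and ecology statistics (controls excluded)
  non_control <- metadata[!metadata$control, , drop = FALSE]
  retained_nc <- filt$retained[!filt$retained$sample_id %in%
                                 control_samples, , drop = FALSE]
  table <- build_motu_table(partition, retained_nc, non_control)
  inc <- motu_incidence(table)
  habs <- unique(non_control$habitat)
  richness <- lapply(setNames(habs, habs), function(h) {
    cols <- non_control$sample_id[non_control$habitat == h]
    sub <- inc[, cols, drop = FALSE]
    s <- incidence_summary(sub)
    list(S_obs = s$S_obs, chao2 = chao2(s), ice = ice(s))
  })
  ecology <- list(richness = richness,
                  jaccard = dissimilarity_matrix(table, "jaccard"))
  if (isTRUE(config$do_nmds))
    ecology$nmds <- nmds(ecology$jaccard, seed = config$seed)

  # stage: habitat signatures
  habitat <- habitat_signature(table)

  run <- structure(list(demux = demux, filter = filt,
                        partition = partition, scan = scan,
                        assignments = assignments, motu_table = table,
                        ecology = ecology, habitat = habitat,
                        manifest = manifest),
                   class = "edna_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.edna_run <- function(x, ...) {
  st <- x$manifest$stages
  cat("eDNA pipeline run:\n",
      " reads: ", st$reads_in, " in -> ", st$reads_binned, " binned -> ",
      st$reads_trimmed, " trimmed\n",
      " uniques: ", st$uniques_in, " -> ", st$uniques_retained,
      " retained\n",
      " MOTUs: ", st$n_motus, " (species-assigned: ",
      st$n_species_assigned, ")\n", sep = "")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write pipeline artifacts to a directory
#' @param run an `edna_run`.
#' @param dir output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$filter$report, file.path(dir, "filter_report.tsv"))
  write_tsv(run$partition$membership, file.path(dir, "motu_membership.tsv"))
  write_fasta(setNames(run$partition$representatives$sequence,
                       run$partition$representatives$motu_id),
              file.path(dir, "motu_representatives.fasta"))
  write_tsv(run$assignments, file.path(dir, "assignments.tsv"))
  counts <- as.data.frame(run$motu_table$counts)
  counts <- cbind(motu_id = rownames(run$motu_table$counts), counts)
  write_tsv(counts, file.path(dir, "motu_table.tsv"))
  write_tsv(run$motu_table$meta, file.path(dir, "metadata.tsv"))
  diss <- as.data.frame(run$habitat$dissimilarities)
  diss <- cbind(sample_id = rownames(run$habitat$dissimilarities), diss)
  write_tsv(diss, file.path(dir, "habitat_dissimilarities.tsv"))
  write_tsv(run$habitat$assignments, file.path(dir,
                                               "habitat_assignments.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
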