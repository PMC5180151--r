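#' Build a reference barcode collection from a species pool
#'
#' Uses each species' primary barcode as its reference sequence; useful for
#' closed-reference runs on simulated data.
#'
#' @param pool a [generate_species_pool()] result.
#' @return data frame `ref_id`, `sequence`, `species`, `phylum`,
#'   `is_metazoan`.
#' @export
reference_db <- function(pool) {
  sp <- pool$species
  data.frame(ref_id = sp$species_id, sequence = sp$barcode,
             species = sp$species_id, phylum = sp$phylum,
             is_metazoan = sp$is_metazoan, stringsAsFactors = FALSE)
}

#' Read/write reference barcodes with header-encoded taxonomy
#'
#' FASTA headers follow the dialect `>id|species|phylum|metazoan={0,1}`.
#'
#' @param path FASTA file.
#' @return data frame `ref_id`, `sequence`, `species`, `phylum`,
#'   `is_metazoan`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0)
    stop("malformed reference header(s): ",
         paste(head(names(seqs)[bad], 3), collapse = ", "))
  meta <- vapply(parts, `[`, character(1), 4)
  if (!all(grepl("^metazoan=[01]$", meta)))
    stop("reference headers must end in metazoan=0 or metazoan=1")
  data.frame(
    ref_id = vapply(parts, `[`, character(1), 1),
    sequence = unname(seqs),
    species = vapply(parts, `[`, character(1), 2),
    phylum = vapply(parts, `[`, character(1), 3),
    is_metazoan = meta == "metazoan=1",
    stringsAsFactors = FALSE
  )
}

#' @rdname read_reference_fasta
#' @param refdb reference data frame.
#' @export
write_reference_fasta <- function(refdb, path) {
  headers <- sprintf("%s|%s|%s|metazoan=%d", refdb$ref_id, refdb$species,
                     refdb$phylum, as.integer(refdb$is_metazoan))
  write_fasta(setNames(refdb$sequence, headers), path)
}

#' Best reference hit per query sequence
#'
#' Exhaustive pairwise comparison against the reference collection;
#' identity is matches over aligned non-end-gap columns and overlap the
#' number of those columns. Ties on identity are broken by larger overlap,
#' then lexicographically smaller reference id.
#'
#' @param queries character vector of query sequences (names kept).
#' @param refdb reference data frame, see [read_reference_fasta()].
#' @return data frame `query_id`, `ref_id`, `species`, `phylum`,
#'   `is_metazoan`, `identity`, `overlap`.
#' @export
best_match <- function(queries, refdb) {
  if (nrow(refdb) == 0) stop("reference database is empty")
  ids <- names(queries)
  if (is.null(ids)) ids <- sprintf("query%d", seq_along(queries))
  im <- identity_matrix(unname(queries), refdb$sequence)
  best <- best_reference_index(im$identity, im$overlap, refdb$ref_id)
  data.frame(
    query_id = ids,
    ref_id = refdb$ref_id[best],
    species = refdb$species[best],
    phylum = refdb$phylum[best],
    is_metazoan = refdb$is_metazoan[best],
    identity = im$identity[cbind(seq_along(best), best)],
    overlap = im$overlap[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE
  )
}

#' Identity-band taxonomic assignment
#'
#' Species-level assignment requires identity >= 0.97 *and* overlap >= 310
#' aligned bases (the rule is conjunctive, so a high-identity short-overlap
#' hit falls through). Identities in `[0.90, 0.97)` -- or >= 0.97 with
#' insufficient overlap -- are flagged to a higher taxon carrying the best
#' hit's phylum (a deterministic stand-in recorded in the `provenance`
#' column). Everything below 0.90 stays unidentified but is retained.
#'
#' @param matches output of [best_match()].
#' @param min_species_identity,min_overlap species-band thresholds.
#' @param min_higher_identity lower edge of the higher-taxon band.
#' @return data frame `motu_id`, `level`
#'   (`species`/`higher_taxon_flag`/`unidentified`), `taxon_label`,
#'   `identity`, `overlap`, `provenance`.
#' @export
assign_taxa <- function(matches, min_species_identity = 0.97,
                        min_overlap = 310, min_higher_identity = 0.90) {
  level <- ifelse(
    matches$identity >= min_species_identity &
      matches$overlap >= min_overlap, "species",
    ifelse(matches$identity >= min_higher_identity, "higher_taxon_flag",
           "unidentified"))
  taxon <- ifelse(level == "species", matches$species,
                  ifelse(level == "higher_taxon_flag", matches$phylum,
                         NA_character_))
  provenance <- ifelse(level == "higher_taxon_flag",
                       "besthit_phylum_propagation",
                       ifelse(level == "species", "barcode_match",
                              NA_character_))
  data.frame(motu_id = matches$query_id, level = level,
             taxon_label = taxon, identity = matches$identity,
             overlap = matches$overlap, provenance = provenance,
             stringsAsFactors = FALSE)
}
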