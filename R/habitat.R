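#' Habitat-specific binary reference profile
#'
#' The profile assigns 1 to every MOTU present in at least one sample of
#' the habitat and 0 otherwise, over the full MOTU universe of the table.
#'
#' @param table a `motu_table`.
#' @param habitat habitat label present in the metadata.
#' @param common_only restrict the MOTU universe with
#'   [common_motu_filter()] first.
#' @return named 0/1 vector over MOTUs.
#' @export
build_reference_profile <- function(table, habitat, common_only = FALSE) {
  if (!habitat %in% table$meta$habitat)
    stop("unknown habitat: ", habitat)
  if (common_only) table <- common_motu_filter(table)
  inc <- motu_incidence(table)
  cols <- table$meta$sample_id[table$meta$habitat == habitat]
  (rowSums(inc[, cols, drop = FALSE]) > 0) * 1L
}

#' All habitat profiles of a MOTU table
#' @inheritParams build_reference_profile
#' @return MOTU x habitat 0/1 matrix.
#' @export
habitat_profiles <- function(table, common_only = FALSE) {
  if (common_only) table <- common_motu_filter(table)
  habs <- unique(table$meta$habitat)
  sapply(setNames(habs, habs), function(h)
    build_reference_profile(table, h))
}

#' Jaccard dissimilarity of each sample to each habitat profile
#'
#' Each sample's presence-absence profile is compared against every
#' habitat's reference profile. With `leave_one_out`, the focal sample's
#' presences are removed from its own habitat's profile before comparison
#' (the default mirrors the reference construction that includes the focal
#' sample, which is the convention the profiles were designed under).
#'
#' @param table a `motu_table`.
#' @param common_only build profiles (and sample profiles) from common
#'   MOTUs only.
#' @param leave_one_out recompute the own-habitat profile without the focal
#'   sample.
#' @return sample x habitat matrix of Jaccard dissimilarities.
#' @export
sample_dissimilarities <- function(table, common_only = FALSE,
                                   leave_one_out = FALSE) {
  if (common_only) table <- common_motu_filter(table)
  inc <- motu_incidence(table)
  meta <- table$meta
  profiles <- habitat_profiles(table)
  habs <- colnames(profiles)
  d <- matrix(NA_real_, ncol(inc), length(habs),
              dimnames = list(colnames(inc), habs))
  for (i in seq_len(ncol(inc))) {
    for (h in habs) {
      prof <- profiles[, h]
      if (leave_one_out && meta$habitat[i] == h) {
        others <- meta$sample_id[meta$habitat == h &
                                   meta$sample_id != meta$sample_id[i]]
        prof <- (rowSums(inc[, others, drop = FALSE]) > 0) * 1L
      }
      d[i, h] <- jaccard_dissimilarity(inc[, i], prof)
    }
  }
  d
}

#' Assign each sample to the habitat with the closest profile
#'
#' @param d sample x habitat dissimilarity matrix (or a single row).
#' @return character vector of habitat labels; exact ties give
#'   `"ambiguous"`, never a silent choice.
#' @export
assign_habitat <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, 1, dimnames = list(NULL, names(d)))
  if (ncol(d) < 2) stop("at least two habitats are required")
  apply(d, 1, function(row) {
    best <- which(row == min(row))
    if (length(best) > 1) "ambiguous" else colnames(d)[best]
  })
}

#' Compare own-habitat and other-habitat dissimilarity groups
#'
#' Two-sided Mann-Whitney U test (default) of the dissimilarities of a
#' habitat's own samples to its profile against those of the other
#' habitat's samples to the same profile; group means and standard errors
#' are reported alongside.
#'
#' @param own,other numeric dissimilarity vectors.
#' @param test `"wilcoxon"` (Mann-Whitney U) or `"t"`.
#' @return list with `statistic`, `p_value`, `mean_own`, `mean_other`,
#'   `se_own`, `se_other`, `test`.
#' @export
compare_groups <- function(own, other, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(length(own) > 0, length(other) > 0)
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  if (length(unique(c(own, other))) == 1) {
    warning("all dissimilarities tied; p = 1")
    return(list(statistic = NA_real_, p_value = 1,
                mean_own = mean(own), mean_other = mean(other),
                se_own = sem(own), se_other = sem(other), test = test))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(wilcox.test(own, other, alternative = "two.sided"))
  } else {
    t.test(own, other, alternative = "two.sided")
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_own = mean(own), mean_other = mean(other),
       se_own = sem(own), se_other = sem(other), test = test)
}

#' Habitat-signature analysis of a MOTU table
#'
#' For every habitat, computes each sample's Jaccard dissimilarity to the
#' habitat profiles, classifies samples by nearest profile, and tests
#' whether the habitat's own samples are closer to its profile than the
#' other samples are.
#'
#' @inheritParams sample_dissimilarities
#' @param test see [compare_groups()].
#' @return list with `dissimilarities` (sample x habitat), `assignments`
#'   (data frame sample_id/habitat/call/correct) and `tests` (per-habitat
#'   [compare_groups()] results).
#' @export
habitat_signature <- function(table, common_only = FALSE,
                              leave_one_out = FALSE, test = "wilcoxon") {
  d <- sample_dissimilarities(table, common_only = common_only,
                              leave_one_out = leave_one_out)
  calls <- assign_habitat(d)
  meta <- table$meta
  assignments <- data.frame(sample_id = rownames(d),
                            habitat = meta$habitat[match(rownames(d),
                                                         meta$sample_id)],
                            call = calls, stringsAsFactors = FALSE)
  assignments$correct <- assignments$call == assignments$habitat
  tests <- lapply(setNames(colnames(d), colnames(d)), function(h) {
    own <- d[assignments$habitat == h, h]
    other <- d[assignments$habitat != h, h]
    compare_groups(own, other, test = test)
  })
  list(dissimilarities = d, assignments = assignments, tests = tests)
}
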