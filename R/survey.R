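# species labels are matched exactly after canonicalization
canonical_species <- function(x) tolower(trimws(x))

#' Reconcile detected species labels against a checklist
#'
#' @param detected character vector of detected species labels.
#' @param checklist character vector of checklist species labels.
#' @return list with `matched` (canonical labels in both) and `unmatched`
#'   (detected labels absent from the checklist, surfaced rather than
#'   silently dropped).
#' @export
reconcile_names <- function(detected, checklist) {
  det <- unique(canonical_species(detected))
  chk <- unique(canonical_species(checklist))
  list(matched = intersect(det, chk), unmatched = setdiff(det, chk))
}

#' Fraction of a species checklist detected
#'
#' @param detected character vector of detected species labels.
#' @param checklist character vector of known species (non-empty).
#' @return list with `k` (checklist species detected), `n` (checklist
#'   size) and `percent` (`100 k / n`, rounded to the nearest integer,
#'   halves away from zero).
#' @export
detection_fraction <- function(detected, checklist) {
  chk <- unique(canonical_species(checklist))
  if (length(chk) == 0) stop("checklist is empty")
  k <- length(intersect(unique(canonical_species(detected)), chk))
  list(k = k, n = length(chk),
       percent = round_half_away(100 * k / length(chk)))
}

#' Site-by-site detection table across methods
#'
#' @param detections data frame with columns `site`, `method`, `species`
#'   (one row per detection).
#' @param checklist character vector of known species.
#' @return data frame `site` x `method` with detection percentages; the
#'   `overall` row is the union of detections across sites per method.
#' @export
site_by_site <- function(detections, checklist) {
  sites <- unique(detections$site)
  methods <- unique(detections$method)
  rows <- lapply(c(sites, "overall"), function(s) {
    vals <- vapply(methods, function(m) {
      sel <- detections$method == m &
        (s == "overall" | detections$site == s)
      detection_fraction(detections$species[sel], checklist)$percent
    }, numeric(1))
    as.data.frame(c(list(site = s), as.list(vals)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent excess richness of one community over another
#'
#' `100 (a - b) / b`, rounded to the nearest integer percent (halves away
#' from zero).
#'
#' @param a,b richness counts; `b` must be at least 1.
#' @return percent excess of `a` over `b`.
#' @export
percent_excess_richness <- function(a, b) {
  if (b < 1) stop("reference richness must be at least 1")
  round_half_away(100 * (a - b) / b)
}
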