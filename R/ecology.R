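#' Build the MOTU x sample table
#'
#' MOTU read count per sample is the sum of the retained member sequences'
#' counts in that sample; incidence is `count > 0`.
#'
#' @param partition a [objective_cluster()] result over the retained
#'   sequences.
#' @param retained data frame `sequence`, `sample_id`, `count` (e.g. from
#'   [replicate_filter()] or [filter_sequences()]).
#' @param metadata data frame with `sample_id`, `habitat`, `site`, `depth`
#'   and optionally `control` (logical).
#' @return object of class `motu_table`: list with `counts` (MOTU x sample
#'   matrix) and `meta`.
#' @export
build_motu_table <- function(partition, retained, metadata) {
  if (!all(retained$sample_id %in% metadata$sample_id))
    stop("retained sequences reference sample(s) missing from metadata: ",
         paste(setdiff(retained$sample_id, metadata$sample_id),
               collapse = ", "))
  motu_of <- setNames(partition$membership$motu_id,
                      partition$membership$sequence)
  if (any(!retained$sequence %in% names(motu_of)))
    stop("retained sequence(s) not covered by the MOTU partition")
  motus <- sort(unique(partition$membership$motu_id))
  samples <- metadata$sample_id
  counts <- matrix(0, length(motus), length(samples),
                   dimnames = list(motus, samples))
  agg <- tapply(retained$count,
                list(motu_of[retained$sequence], retained$sample_id), sum)
  counts[rownames(agg), colnames(agg)] <-
    ifelse(is.na(agg), 0, agg)
  structure(list(counts = counts, meta = metadata), class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  cat("MOTU table:", nrow(x$counts), "MOTUs x", ncol(x$counts),
      "samples;", sum(x$counts), "reads\n")
  invisible(x)
}

#' Incidence (presence-absence) matrix of a MOTU table
#' @param table a `motu_table`.
#' @return MOTU x sample 0/1 matrix.
#' @export
motu_incidence <- function(table) {
  (table$counts > 0) * 1L
}

#' Restrict a MOTU table to common MOTUs
#'
#' A MOTU is common when, in at least one habitat, it occurs in at least
#' `min_samples` of that habitat's surface samples or at least
#' `min_samples` of its benthic samples (strata are habitat x depth).
#'
#' @param table a `motu_table`.
#' @param min_samples per-stratum occurrence threshold (default 4 of 7).
#' @return filtered `motu_table`.
#' @export
common_motu_filter <- function(table, min_samples = 4) {
  inc <- motu_incidence(table)
  meta <- table$meta
  stratum <- paste(meta$habitat, meta$depth, sep = "\t")
  per_stratum <- sapply(unique(stratum), function(st)
    rowSums(inc[, stratum == st, drop = FALSE]))
  keep <- apply(per_stratum >= min_samples, 1, any)
  structure(list(counts = table$counts[keep, , drop = FALSE],
                 meta = meta), class = "motu_table")
}

#' Incidence summary for richness estimation
#'
#' @param incidence MOTU x sampling-unit 0/1 matrix (units = columns).
#' @return object of class `incidence_summary`: `S_obs`, `m`, `Q` (Q\[k\] =
#'   number of MOTUs found in exactly k units) and the matrix itself (used
#'   by [ice()] for the infrequent-unit count).
#' @export
incidence_summary <- function(incidence) {
  incidence <- (incidence > 0) * 1L
  freq <- rowSums(incidence)
  m <- ncol(incidence)
  Q <- vapply(seq_len(m), function(k) sum(freq == k), integer(1))
  structure(list(S_obs = sum(freq > 0), m = m, Q = Q,
                 incidence = incidence),
            class = "incidence_summary")
}

as_incidence_summary <- function(x) {
  if (inherits(x, "incidence_summary")) x else incidence_summary(x)
}

#' Chao2 incidence-based richness estimator
#'
#' With Q1 uniques and Q2 duplicates over m sampling units:
#' `S_obs + ((m-1)/m) * Q1^2 / (2 Q2)` when `Q2 > 0`, and the
#' bias-corrected `S_obs + ((m-1)/m) * Q1 (Q1 - 1) / 2` when `Q2 = 0`.
#' Always at least `S_obs`.
#'
#' @param x an incidence matrix or [incidence_summary()].
#' @return estimated total richness.
#' @export
chao2 <- function(x) {
  s <- as_incidence_summary(x)
  if (s$m < 2) stop("Chao2 requires at least 2 sampling units")
  Q1 <- s$Q[1]; Q2 <- s$Q[2]
  corr <- (s$m - 1) / s$m
  if (Q2 > 0) s$S_obs + corr * Q1^2 / (2 * Q2)
  else s$S_obs + corr * Q1 * (Q1 - 1) / 2
}

#' ICE incidence-based coverage estimator
#'
#' Splits MOTUs into infrequent (found in at most `infrequent_cutoff`
#' units) and frequent ones, estimates sample coverage
#' `C = 1 - Q1 / N_infr` from the infrequent group, and inflates the
#' infrequent richness by the coefficient of variation of incidence
#' frequencies. Falls back to [chao2()] when coverage is zero (all
#' infrequent MOTUs are uniques).
#'
#' @param x an incidence matrix or [incidence_summary()].
#' @param infrequent_cutoff frequency cutoff for the infrequent group.
#' @return estimated total richness.
#' @export
ice <- function(x, infrequent_cutoff = 10) {
  s <- as_incidence_summary(x)
  if (s$m < 2) stop("ICE requires at least 2 sampling units")
  kmax <- min(infrequent_cutoff, s$m)
  k <- seq_len(kmax)
  Qk <- s$Q[k]
  S_infr <- sum(Qk)
  S_freq <- s$S_obs - S_infr
  if (S_infr == 0) return(s$S_obs)
  N_infr <- sum(k * Qk)
  Q1 <- s$Q[1]
  C_ice <- 1 - Q1 / N_infr
  if (C_ice == 0) return(chao2(s))
  # units containing at least one infrequent MOTU
  m_infr <- if (!is.null(s$incidence)) {
    freq <- rowSums(s$incidence)
    infr <- freq >= 1 & freq <= kmax
    sum(colSums(s$incidence[infr, , drop = FALSE]) > 0)
  } else s$m
  gamma2 <- if (m_infr > 1) {
    max((S_infr / C_ice) * (m_infr / (m_infr - 1)) *
          sum(k * (k - 1) * Qk) / N_infr^2 - 1, 0)
  } else 0
  S_freq + S_infr / C_ice + (Q1 / C_ice) * gamma2
}

#' Sample-based MOTU accumulation curve
#'
#' Mean and standard deviation over random sample orderings of the
#' cumulative richness after the first k units; `exhaustive = TRUE`
#' enumerates all orderings (m <= 8).
#'
#' @param incidence MOTU x sampling-unit 0/1 matrix.
#' @param n_permutations number of random orderings.
#' @param seed integer seed.
#' @param exhaustive average over all `m!` orderings instead.
#' @return data frame `k`, `mean_richness`, `sd_richness`.
#' @export
accumulation_curve <- function(incidence, n_permutations = 100, seed = 1,
                               exhaustive = FALSE) {
  stopifnot(n_permutations >= 1)
  incidence <- (incidence > 0) * 1L
  m <- ncol(incidence)
  rich_along <- function(ord) {
    seen <- rep(FALSE, nrow(incidence))
    out <- integer(m)
    for (k in seq_len(m)) {
      seen <- seen | incidence[, ord[k]] > 0
      out[k] <- sum(seen)
    }
    out
  }
  perms <- if (exhaustive) {
    if (m > 8) stop("exhaustive enumeration limited to m <= 8")
    all_perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(all_perms(v[-i]), function(p) c(v[i], p))))
    }
    all_perms(seq_len(m))
  } else {
    with_seed(seed, lapply(seq_len(n_permutations),
                           function(i) sample.int(m)))
  }
  mat <- matrix(vapply(perms, rich_along, integer(m)), nrow = m)
  data.frame(k = seq_len(m),
             mean_richness = rowMeans(mat),
             sd_richness = apply(mat, 1, sd))
}

#' Jaccard dissimilarity of two presence-absence vectors
#'
#' `1 - |intersection| / |union|`; 0 when both vectors are empty.
#'
#' @param a,b binary vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0) return(0)
  1 - sum(a & b) / un
}

#' Morisita-Horn dissimilarity of two count vectors
#'
#' `1 - 2 * sum(x_i y_i) / ((d_x + d_y) X Y)` with `d_x = sum(x_i^2) / X^2`
#' and `X = sum(x)`; invariant to positive rescaling of either vector.
#'
#' @param x,y non-negative count vectors of equal length and positive sum.
#' @return dissimilarity in `[0, 1]`.
#' @export
morisita_horn_dissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("count vectors must have positive sums")
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  1 - 2 * sum(x * y) / ((dx + dy) * X * Y)
}

#' Renkonen (percentage) similarity of two count vectors
#'
#' `p = sum_i min(x_i / X, y_i / Y)`: 1 iff the relative abundance
#' profiles are identical, 0 iff the supports are disjoint.
#'
#' @param x,y non-negative count vectors of equal length and positive sum.
#' @param use_ranks replace counts by their mid-ranks (computed over the
#'   positive entries of each vector) before normalising.
#' @return similarity in `[0, 1]`.
#' @export
renkonen_similarity <- function(x, y, use_ranks = FALSE) {
  stopifnot(length(x) == length(y))
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("count vectors must have positive sums")
  if (use_ranks) {
    rankify <- function(v) {
      out <- numeric(length(v))
      out[v > 0] <- rank(v[v > 0])
      out
    }
    x <- rankify(x); y <- rankify(y)
  }
  sum(pmin(x / sum(x), y / sum(y)))
}

#' Pool MOTU counts by sample groups
#'
#' @param table a `motu_table`.
#' @param by metadata grouping: `"habitat"` or `"sampling_point"`
#'   (site x depth within habitat).
#' @return MOTU x group count matrix.
#' @export
pool_counts <- function(table, by = c("habitat", "sampling_point")) {
  by <- match.arg(by)
  meta <- table$meta
  grp <- if (by == "habitat") meta$habitat
         else paste(meta$habitat, meta$site, meta$depth, sep = "_")
  sapply(unique(grp), function(g)
    rowSums(table$counts[, grp == g, drop = FALSE]))
}

#' Pairwise sample dissimilarity matrix of a MOTU table
#'
#' @param table a `motu_table`.
#' @param method `"jaccard"` (on incidence) or `"morisita_horn"` (on
#'   counts).
#' @return symmetric sample x sample dissimilarity matrix.
#' @export
dissimilarity_matrix <- function(table,
                                 method = c("jaccard", "morisita_horn")) {
  method <- match.arg(method)
  x <- if (method == "jaccard") motu_incidence(table) else table$counts
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d[i, j] <- d[j, i] <- if (method == "jaccard")
      jaccard_dissimilarity(x[, i], x[, j])
    else morisita_horn_dissimilarity(x[, i], x[, j])
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimisation (monotone regression with iterative
#' improvement, best of `n_restarts` random starts), deterministic given
#' the seed. Backed by vegan's metaMDS engine.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k embedding dimension.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param maxit iterations per start.
#' @return list with `points` (n x k coordinates) and `stress`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1, maxit = 500) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("NMDS requires at least 3 samples")
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  fit <- with_seed(seed,
    vegan::metaMDS(stats::as.dist(d), k = k, try = n_restarts,
                   trymax = n_restarts, maxit = maxit, trace = 0,
                   autotransform = FALSE, wascores = FALSE))
  list(points = fit$points, stress = fit$stress)
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param u,v numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`; `NA` with a warning for constant input.
#' @export
spearman_rho <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 3)
  if (length(unique(u)) == 1 || length(unique(v)) == 1) {
    warning("constant vector: Spearman's rho undefined")
    return(NA_real_)
  }
  cor(u, v, method = "spearman")
}
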