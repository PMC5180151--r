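make_table <- function(counts, habitat, site = NULL, depth = "surface") {
  n <- ncol(counts)
  if (is.null(site)) site <- seq_len(n)
  meta <- data.frame(sample_id = colnames(counts), habitat = habitat,
                     site = site, depth = depth)
  structure(list(counts = counts, meta = meta), class = "motu_table")
}

test_that("the MOTU table sums member counts per sample", {
  part <- objective_cluster(c(s1 = "AAAA", s2 = "AAAT", s3 = "GGGG"),
                            threshold = 0.3, counts = c(3, 4, 2))
  retained <- data.frame(sequence = c("AAAA", "AAAT", "GGGG"),
                         sample_id = c("S", "S", "T"), count = c(3, 4, 2))
  meta <- data.frame(sample_id = c("S", "T"), habitat = c("A", "B"),
                     site = 1, depth = "surface")
  tab <- build_motu_table(part, retained, meta)
  motu_ab <- part$membership$motu_id[1]
  expect_equal(tab$counts[motu_ab, "S"], 7)   # {rep counts 3, 4} summed
  expect_equal(tab$counts[motu_ab, "T"], 0)
  inc <- motu_incidence(tab)
  expect_equal(inc[motu_ab, ], c(S = 1L, T = 0L))
  expect_error(build_motu_table(part, transform(retained, sample_id = "X"),
                                meta), "missing from metadata")
})

test_that("common-MOTU rule keeps >= 4-of-7 per stratum with OR semantics", {
  samples <- paste0("s", 1:28)
  counts <- matrix(0, 3, 28, dimnames = list(paste0("m", 1:3), samples))
  habitat <- rep(c("A", "B"), each = 14)
  depth <- rep(rep(c("surface", "benthic"), each = 7), 2)
  # m1: 5 of 7 A-surface samples
  counts[1, which(habitat == "A" & depth == "surface")[1:5]] <- 1
  # m2: 3 of 7 in every stratum
  for (h in c("A", "B")) for (d in c("surface", "benthic"))
    counts[2, which(habitat == h & depth == d)[1:3]] <- 1
  # m3: exactly 4 of 7 B-benthic samples
  counts[3, which(habitat == "B" & depth == "benthic")[1:4]] <- 1
  tab <- make_table(counts, habitat, site = rep(1:7, 4), depth = depth)
  kept <- rownames(common_motu_filter(tab)$counts)
  expect_setequal(kept, c("m1", "m3"))
})

test_that("Chao2 reproduces hand-evaluated values and its floor", {
  # Q1 = 0: estimator equals observed richness
  inc <- rbind(c(1, 1), c(1, 1))
  expect_equal(chao2(inc), 2)
  # S_obs=10, m=14, Q1=4, Q2=2: 10 + (13/14) * 16/4
  s <- structure(list(S_obs = 10, m = 14,
                      Q = c(4, 2, rep(0, 11), 4), incidence = NULL),
                 class = "incidence_summary")
  expect_equal(chao2(s), 10 + (13 / 14) * 16 / 4, tolerance = 1e-12)
  # bias-corrected branch: Q2 = 0
  s2 <- structure(list(S_obs = 5, m = 10,
                       Q = c(3, rep(0, 8), 2), incidence = NULL),
                  class = "incidence_summary")
  expect_equal(chao2(s2), 7.7, tolerance = 1e-12)
  expect_error(chao2(matrix(1, 2, 1)), "at least 2")
})

test_that("ICE matches a direct spreadsheet-style evaluation", {
  # all MOTUs frequent: ICE = S_obs
  inc_freq <- matrix(1, 3, 12)
  expect_equal(ice(inc_freq), 3)
  # all infrequent MOTUs are uniques: falls back to Chao2
  inc_fb <- diag(1, 4, 4)
  expect_equal(ice(inc_fb), chao2(inc_fb))
  # hand dataset: m=12, Q1=5, Q2=3, Q3=2, 4 frequent (11 of 12 units)
  set.seed(71)
  m <- 12
  inc <- matrix(0, 14, m)
  r <- 0
  for (k in c(rep(1, 5), rep(2, 3), rep(3, 2), rep(11, 4))) {
    r <- r + 1
    inc[r, sample.int(m, k)] <- 1
  }
  # independent evaluation of the classic ICE formula
  freq <- rowSums(inc)
  infr <- freq <= 10
  S_inf <- sum(infr); S_frq <- sum(!infr)
  N_inf <- sum(freq[infr])
  Q1 <- sum(freq == 1)
  C <- 1 - Q1 / N_inf
  m_inf <- sum(colSums(inc[infr, ]) > 0)
  Qk <- vapply(1:10, function(k) sum(freq == k), numeric(1))
  g2 <- max((S_inf / C) * (m_inf / (m_inf - 1)) *
              sum((1:10) * (0:9) * Qk) / N_inf^2 - 1, 0)
  expected <- S_frq + S_inf / C + (Q1 / C) * g2
  expect_equal(ice(inc), expected, tolerance = 1e-12)
})

test_that("estimators never fall below observed richness", {
  set.seed(72)
  for (i in 1:30) {
    inc <- matrix(rbinom(20 * 8, 1, runif(1, 0.1, 0.9)), 20, 8)
    s <- incidence_summary(inc)
    expect_gte(chao2(s), s$S_obs)
    expect_gte(ice(s), s$S_obs)
  }
})

test_that("accumulation curve matches exhaustive enumeration and vegan", {
  set.seed(73)
  inc <- matrix(rbinom(10 * 4, 1, 0.4), 10, 4)
  colnames(inc) <- paste0("u", 1:4)
  exh <- accumulation_curve(inc, exhaustive = TRUE)
  # independent oracle 1: manual enumeration of all 24 orderings
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rich <- apply(perms, 1, function(p) {
    vapply(1:4, function(k)
      sum(rowSums(inc[, unlist(p[1:k]), drop = FALSE]) > 0), numeric(1))
  })
  expect_equal(exh$mean_richness, rowMeans(rich), tolerance = 1e-12)
  # independent oracle 2: vegan's analytic exact mean
  sac <- suppressWarnings(vegan::specaccum(t(inc), method = "exact"))
  expect_equal(exh$mean_richness, as.numeric(sac$richness),
               tolerance = 1e-10)
  # properties: monotone mean, endpoint = total richness
  expect_true(all(diff(exh$mean_richness) >= 0))
  expect_equal(exh$mean_richness[4], sum(rowSums(inc) > 0))
  # degenerate cases
  one <- accumulation_curve(inc[, 1, drop = FALSE])
  expect_equal(one$mean_richness, sum(inc[, 1]))
  flat <- accumulation_curve(cbind(inc[, 1], inc[, 1]), n_permutations = 10)
  expect_true(all(flat$sd_richness == 0))
})

test_that("Jaccard dissimilarity matches hand values and vegan", {
  expect_equal(jaccard_dissimilarity(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(jaccard_dissimilarity(c(0, 0), c(0, 0)), 0)
  # the two-habitat Venn structure: shared 95 of union 516
  a <- c(rep(1, 376), rep(0, 140))
  b <- c(rep(0, 281), rep(1, 235))
  expect_equal(jaccard_dissimilarity(a, b), 1 - 95 / 516)
  set.seed(74)
  x <- matrix(rbinom(40, 1, 0.5), 2, 20)
  x[1, 1] <- x[2, 2] <- 1  # both non-empty
  expect_equal(jaccard_dissimilarity(x[1, ], x[2, ]),
               as.numeric(vegan::vegdist(x, method = "jaccard",
                                         binary = TRUE)))
})

test_that("Jaccard satisfies the triangle inequality on random vectors", {
  set.seed(75)
  for (i in 1:50) {
    v <- matrix(rbinom(30, 1, 0.5), 3, 10)
    d12 <- jaccard_dissimilarity(v[1, ], v[2, ])
    d13 <- jaccard_dissimilarity(v[1, ], v[3, ])
    d23 <- jaccard_dissimilarity(v[2, ], v[3, ])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("Morisita-Horn matches hand values, vegan, and scale invariance", {
  expect_equal(morisita_horn_dissimilarity(c(2, 3), c(2, 3)), 0)
  expect_equal(morisita_horn_dissimilarity(c(5, 0), c(0, 7)), 1)
  expect_equal(morisita_horn_dissimilarity(c(1, 1), c(1, 3)), 1 - 8 / 9,
               tolerance = 1e-12)
  expect_error(morisita_horn_dissimilarity(c(0, 0), c(1, 1)), "positive")
  set.seed(76)
  x <- matrix(rpois(20, 5) + 1, 2, 10)
  expect_equal(morisita_horn_dissimilarity(x[1, ], x[2, ]),
               as.numeric(vegan::vegdist(x, method = "horn")),
               tolerance = 1e-12)
  for (i in 1:20) {
    u <- rpois(8, 4) + 1; v <- rpois(8, 4) + 1
    cc <- runif(1, 0.1, 50)
    expect_equal(morisita_horn_dissimilarity(u, v),
                 morisita_horn_dissimilarity(cc * u, v),
                 tolerance = 1e-12)
  }
})

test_that("Renkonen similarity matches hand values in both modes", {
  expect_equal(renkonen_similarity(c(2, 2), c(4, 4)), 1)
  expect_equal(renkonen_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(renkonen_similarity(c(3, 1), c(1, 3)), 0.5)
  expect_equal(renkonen_similarity(c(3, 1), c(1, 3), use_ranks = TRUE),
               2 / 3, tolerance = 1e-12)
  expect_error(renkonen_similarity(c(0, 0), c(1, 1)), "positive")
})

test_that("Spearman's rho uses mid-ranks and flags constant input", {
  u <- c(1, 2, 3, 4)
  expect_equal(spearman_rho(u, u), 1)
  expect_equal(spearman_rho(u, -u), -1)
  expect_equal(spearman_rho(u, c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("NMDS embeds exact configurations and is seed-deterministic", {
  d3 <- matrix(0.5, 3, 3); diag(d3) <- 0
  fit <- suppressWarnings(nmds(d3, seed = 5))
  expect_lt(fit$stress, 1e-4)
  side <- as.matrix(dist(fit$points))
  off <- side[upper.tri(side)]
  expect_lt(diff(range(off)) / mean(off), 0.01)  # equilateral
  # duplicate samples land on coincident points
  d4 <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 1, 1, 0, 0.2,
                 1, 1, 0.2, 0), 4, 4)
  fit4 <- suppressWarnings(nmds(d4, seed = 5))
  expect_lt(sqrt(sum((fit4$points[1, ] - fit4$points[2, ])^2)), 1e-3)
  expect_identical(fit$points, suppressWarnings(nmds(d3, seed = 5))$points)
  expect_error(nmds(matrix(0, 2, 2)), "at least 3")
})

test_that("habitat structure separates in NMDS space", {
  set.seed(77)
  # 60 MOTUs: 25 A-only, 25 B-only, 10 shared; 8 samples per habitat
  prof <- function(own, shared) {
    v <- numeric(60)
    v[own] <- rbinom(length(own), 1, 0.7)
    v[shared] <- rbinom(length(shared), 1, 0.7)
    v
  }
  counts <- cbind(
    sapply(1:8, function(i) prof(1:25, 51:60)),
    sapply(1:8, function(i) prof(26:50, 51:60)))
  colnames(counts) <- paste0("s", 1:16)
  rownames(counts) <- paste0("m", 1:60)
  tab <- make_table(counts, rep(c("A", "B"), each = 8))
  fit <- suppressWarnings(nmds(dissimilarity_matrix(tab, "jaccard"), seed = 6))
  cen_a <- colMeans(fit$points[1:8, ])
  cen_b <- colMeans(fit$points[9:16, ])
  sep <- sqrt(sum((cen_a - cen_b)^2))
  spread <- mean(c(
    apply(fit$points[1:8, ], 1, function(p) sqrt(sum((p - cen_a)^2))),
    apply(fit$points[9:16, ], 1, function(p) sqrt(sum((p - cen_b)^2)))))
  expect_gt(sep, spread)
})
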