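test_that("dereplication counts exact duplicates and conserves reads", {
  bins <- data.frame(sequence = c("ACGT", "ACGT", "GGGG"),
                     sample_id = "S1", replicate = 1)
  tab <- dereplicate(bins)
  expect_equal(sort(tab$sequence), c("ACGT", "GGGG"))
  expect_equal(tab$count[tab$sequence == "ACGT"], 2)
  expect_equal(sum(tab$count), nrow(bins))
  # empty bin
  expect_equal(nrow(dereplicate(bins[0, ])), 0)
  # generator truth: noiseless replicates contain exactly the present species
  design <- study_design(n_sites = 1, depths = "surface",
                         n_replicates = 2, seed = 3)
  pool <- generate_species_pool(0, 0, 3, seed = 4, design = design,
                                occupancy = 1)
  sim <- simulate_reads(pool, depth_per_replicate = 200, seed = 5)
  tr <- trim_primers(sim$reads$sequence)
  tab2 <- dereplicate(data.frame(sequence = tr$insert,
                                 sample_id = sim$reads$sample_id,
                                 replicate = sim$reads$replicate))
  per_rep <- table(tab2$sample_id, tab2$replicate)
  expect_true(all(per_rep == 3))
})

test_that("error pruning follows the absorption rule exactly", {
  # child absorbed: edit distance 1, ratio 100/2 >= 10
  out <- prune_errors(rt(c("AAAA", "AAAT"), c(100L, 2L)))
  expect_equal(out$sequence, "AAAA")
  expect_equal(out$count, 102L)
  # edit distance 4: untouched
  out2 <- prune_errors(rt(c("AAAA", "TTTT"), c(100L, 90L)))
  expect_equal(nrow(out2), 2)
  # ratio unmet: untouched
  out3 <- prune_errors(rt(c("AAAA", "AAAT"), c(10L, 9L)))
  expect_equal(nrow(out3), 2)
  # chained absorption reaches a fixpoint and conserves reads
  out4 <- prune_errors(rt(c("AAAA", "AAAT", "AATT"), c(1000L, 50L, 5L)))
  expect_equal(sum(out4$count), 1055L)
  expect_lte(nrow(out4), 3)
  # absorption is confined to a replicate
  tab <- rbind(rt("AAAA", 100L, replicate = 1), rt("AAAT", 2L, replicate = 2))
  out5 <- prune_errors(tab)
  expect_equal(nrow(out5), 2)
})

test_that("identity prescreen applies the 80% metazoan rule", {
  barcode <- random_acgt(1, 313)
  refdb <- rbind(ref_row("m1", barcode),
                 ref_row("p1", random_acgt(1, 313), phylum = "Chlorophyta",
                         is_metazoan = FALSE))
  # equal to a metazoan reference: keep at identity 1
  res <- identity_prescreen(barcode, refdb)
  expect_true(res$keep)
  expect_equal(res$identity, 1)
  expect_equal(res$best_ref_id, "m1")
  # equal to the flagged non-metazoan reference: discard
  res2 <- identity_prescreen(refdb$sequence[2], refdb)
  expect_false(res2$keep)
  expect_equal(res2$reason, "nonmetazoan_besthit")
  # random query below 80% to everything, confirmed by brute force
  set.seed(31)
  q <- random_acgt(1, 313)
  ids <- vapply(refdb$sequence, function(r) 1 - p_distance(q, r), 0)
  expect_true(all(ids < 0.8))
  res3 <- identity_prescreen(q, refdb)
  expect_false(res3$keep)
  expect_equal(res3$reason, "identity_lt_80")
  expect_error(identity_prescreen(q, refdb[0, ]), "empty")
})

test_that("identity prescreen boundary sits exactly at 80%", {
  ref <- random_acgt(1, 300)
  refdb <- ref_row("m1", ref)
  at_80 <- mutate_at(ref, 1:60)        # 240/300 = 0.80
  below <- mutate_at(ref, 1:61)        # 239/300 < 0.80
  res <- identity_prescreen(c(at_80, below), refdb)
  expect_true(res$keep[1])
  expect_false(res$keep[2])
})

test_that("translation filter honours both mitochondrial codes", {
  # generator barcodes are codon-clean by construction
  pool <- small_pool(seed = 2, n = c(2, 0, 0))
  expect_true(all(translation_filter(pool$species$barcode)))
  # TAA placed in-frame in all three frames: discarded
  all_stop <- paste0("TAAATAAATAAA", strrep("A", 12))
  expect_false(translation_filter(all_stop))
  # in-frame AGA: stop under the vertebrate code only
  aga <- "ATGAGAGCTGCTGCT"
  expect_false(stop_free_frames(aga, "vertebrate")[1])
  expect_true(stop_free_frames(aga, "invertebrate")[1])
  expect_true(translation_filter(aga))
  # AGG likewise diverges between the codes
  expect_equal(unname(mito_code("vertebrate")[c("AGA", "AGG")]),
               c("*", "*"))
  expect_false(any(mito_code("invertebrate")[c("AGA", "AGG")] == "*"))
})

test_that("replicate filter retains sequences seen in >= 3 of 5 PCRs", {
  filler <- lapply(1:5, function(r) rt("CCCC", 5L, replicate = r))
  tab3 <- do.call(rbind, c(filler, lapply(1:3, function(r)
    rt("AAAA", 1L, replicate = r))))
  out <- replicate_filter(tab3)
  expect_setequal(out$sequence, c("AAAA", "CCCC"))
  expect_equal(out$count[out$sequence == "AAAA"], 3L)
  tab2 <- do.call(rbind, c(filler, lapply(1:2, function(r)
    rt("AAAA", 1L, replicate = r))))
  expect_equal(replicate_filter(tab2)$sequence, "CCCC")
  tab5 <- do.call(rbind, lapply(1:5, function(r) rt("AAAA", 1L,
                                                    replicate = r)))
  expect_equal(replicate_filter(tab5)$sequence, "AAAA")
  # deviating replicate structure warns but still filters
  expect_warning(replicate_filter(rt("AAAA", 1L)), "replicate count")
})

test_that("filter report reconstructs input uniques per sample", {
  pool <- small_pool(seed = 12, n = c(3, 2, 2), n_contaminant = 2)
  sim <- simulate_reads(pool, error_rate = 0.005, dropout_prob = 0.3,
                        depth_per_replicate = 60, seed = 13)
  tr <- trim_primers(sim$reads$sequence)
  bins <- data.frame(sequence = tr$insert,
                     sample_id = sim$reads$sample_id,
                     replicate = sim$reads$replicate)
  bins <- bins[!is.na(bins$sequence), ]
  # dropout can leave a sample short of replicates, which warns by design
  filt <- suppressWarnings(filter_sequences(bins, reference_db(pool)))
  rep <- filt$report
  expect_true(all(rep$input_uniques ==
                    rep$length + rep$error_pruned + rep$identity_lt_80 +
                    rep$nonmetazoan_besthit + rep$untranslatable +
                    rep$replicate_lt_3 + rep$retained))
  # contaminants never survive the prescreen
  cont <- pool$species$barcode[!pool$species$is_metazoan]
  expect_false(any(filt$retained$sequence %in% cont))
})

test_that("no rule discards a true species sequence on noiseless data", {
  pool <- small_pool(seed = 2, n = c(3, 2, 2))
  sim <- simulate_reads(pool, depth_per_replicate = 40, seed = 14)
  tr <- trim_primers(sim$reads$sequence)
  bins <- data.frame(sequence = tr$insert,
                     sample_id = sim$reads$sample_id,
                     replicate = sim$reads$replicate)
  filt <- filter_sequences(bins, reference_db(pool))
  rep <- filt$report
  expect_true(all(rep$length == 0))
  expect_true(all(rep$identity_lt_80 == 0))
  expect_true(all(rep$nonmetazoan_besthit == 0))
  expect_true(all(rep$untranslatable == 0))
  expect_true(all(rep$replicate_lt_3 == 0))
  # retained incidence equals occupancy
  for (s in unique(filt$retained$sample_id)) {
    got <- sort(filt$retained$sequence[filt$retained$sample_id == s])
    want <- sort(pool$species$barcode[pool$occupancy[, s] == 1])
    expect_identical(got, want)
  }
})

test_that("chimeras survive the filters more rarely than true sequences", {
  pool <- small_pool(seed = 16, n = c(4, 3, 3))
  sim <- simulate_reads(pool, chimera_rate = 0.05,
                        depth_per_replicate = 80, seed = 17)
  tr <- trim_primers(sim$reads$sequence)
  bins <- data.frame(sequence = tr$insert,
                     sample_id = sim$reads$sample_id,
                     replicate = sim$reads$replicate)
  filt <- filter_sequences(bins, reference_db(pool))
  truth <- pool$species$barcode
  chimeric_inserts <- setdiff(unique(bins$sequence), truth)
  expect_gt(length(chimeric_inserts), 0)
  chim_survival <- mean(chimeric_inserts %in% filt$retained$sequence)
  true_survival <- mean(truth %in% filt$retained$sequence)
  expect_lt(chim_survival, true_survival)
})
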