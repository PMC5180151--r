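# ednapipe

Desk-scale community eDNA metabarcoding in R: from tagged COI amplicon
reads to molecular operational taxonomic units (MOTUs), richness
estimates, and habitat-specific community signatures.

## What it is for

Water eDNA amplified with degenerate metazoan COI primers can
characterise whole freshwater communities from a few hundred millilitres
of water. The analysis between the sequencer and the ecology, however,
involves many small, consequential rules: demultiplexing by 9-bp primer
tags, trimming degenerate primers, pruning PCR/sequencing errors,
excluding non-metazoan and untranslatable sequences, requiring each
sequence in at least 3 of 5 replicate PCRs, clustering at a 3%
uncorrected p-distance threshold, and assigning taxonomy by identity
bands. `ednapipe` implements that whole chain as tested R functions,
together with a ground-truthed simulator of tagged amplicon runs so that
every stage can be verified without touching a sequencer.

The core quantities it computes:

* **MOTU delimitation** by objective (single-linkage) clustering: two
  sequences share a MOTU iff they are connected by a chain of pairwise
  p-distances ≤ t (default t = 0.03), i.e. connected components of the
  threshold graph, with a 2/3/4% stability scan.
* **Incidence-based richness**: Chao2,
  `S_obs + ((m-1)/m) Q1² / (2 Q2)` (bias-corrected form when Q2 = 0),
  and ICE with coverage `C = 1 - Q1/N_infr`; sample-based accumulation
  curves.
* **Community structure**: Jaccard (presence–absence), Morisita–Horn
  (read counts), Renkonen percentage similarity
  `p = Σ min(x_i/X, y_i/Y)`, NMDS ordination, Spearman's ρ.
* **Habitat signatures**: binary reference profiles per habitat (1 iff a
  MOTU occurs in ≥ 1 sample of the habitat), per-sample Jaccard
  dissimilarities to each profile, nearest-profile assignment, and a
  Mann–Whitney U comparison of own- versus other-habitat dissimilarities.
* **Survey comparison**: detection fractions of conventional-survey
  checklists (k of n species, integer percent) and richness-excess
  summaries.

## Worked example

Simulate a small two-reservoir survey (2 habitats × 7 sites × 2 depths ×
5 replicate PCRs) with 13 metazoan species (6 A-only, 4 B-only, 3
shared) plus 2 non-metazoan contaminants, then run the pipeline:

```r
library(ednapipe)

design <- study_design(seed = 1)
pool <- generate_species_pool(6, 4, 3, n_contaminant = 2, seed = 2,
                              design = design)
sim <- simulate_reads(pool, error_rate = 0.005, dropout_prob = 0.2,
                      depth_per_replicate = 60, seed = 3)
run <- run_pipeline(sim, refdb = reference_db(pool))
print(run)
#> eDNA pipeline run:
#>  reads: 8280 in -> 8280 binned -> 8280 trimmed
#>  uniques: 6251 -> 14 retained
#>  MOTUs: 13 (species-assigned: 13)
run$scan
#> 0.02 0.03 0.04
#>   13   13   13
```

Of 8,280 reads, 6,251 unique sequences survive dereplication (most are
singleton error variants), but the retention cascade keeps only 14 —
the 13 true species plus one surviving variant that the clustering then
absorbs, giving exactly 13 MOTUs, all species-assigned; the two
contaminants were removed by the non-metazoan best-hit rule. The MOTU
count is stable across the 2/3/4% threshold ladder.

```r
run$ecology$richness$A
#> $S_obs  9        # observed MOTUs in habitat A's 14 samples
#> $chao2  9        # no uniques left: estimator equals S_obs
#> $ice    9.35

head(run$habitat$assignments, 3)
#>                 sample_id habitat call correct
#> A_S1_surface A_S1_surface       A    A    TRUE
#> A_S1_benthic A_S1_benthic       A    A    TRUE
#> A_S2_surface A_S2_surface       A    A    TRUE
sapply(run$habitat$tests, function(t) signif(t$p_value, 3))
#>        A        B
#> 6.14e-06 1.84e-05
```

All 28 samples classify to their habitat of origin, and each habitat's
own samples are significantly closer to its reference profile than the
other habitat's samples are (Mann–Whitney U).

Worked-example statistics from printed survey counts behave as reported
in the field's tables:

```r
percent_excess_richness(376, 235)
#> [1] 60
detection_fraction(sprintf("fish%02d", 1:19), sprintf("fish%02d", 1:27))
#> $k 19   $n 27   $percent 70
```

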