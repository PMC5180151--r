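---
title: "Community eDNA metabarcoding: from tagged COI reads to habitat signatures"
author: "ednapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community eDNA metabarcoding: from tagged COI reads to habitat signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednapipe)
```

## The problem

Conventional freshwater bioassessment — electrofishing, emergence traps,
morphological sorting — is invasive, slow, and rarely resolves
invertebrates to species. Community metabarcoding of environmental DNA
(eDNA) offers an alternative: amplify a 313-bp fragment of mitochondrial
COI from water samples with degenerate metazoan primers, sequence the
pooled amplicons, and delimit molecular operational taxonomic units
(MOTUs) as putative species. `ednapipe` implements this workflow at desk
scale: a ground-truthed simulator of tagged amplicon runs stands in for
the sequencing instrument, and every downstream stage — demultiplexing,
filtering, clustering, taxonomy, community statistics, habitat
classification, survey comparison — is ordinary, testable R.

The study design the package emulates is a two-reservoir survey: 2
habitats x 7 sites x 2 depths (surface and benthic), one DNA extract per
water sample, and 5 replicate PCRs per extract, each PCR carrying a
unique pair of 9-bp tags on the primer 5' ends (280 tagged PCRs in all).

## The simulator and what it does (not) emulate

`generate_species_pool()` builds species with codon-clean barcodes:
104 codons drawn uniformly from the 62 non-stop codons of the
invertebrate mitochondrial code plus one trailing base (313 nt, frame
offset 0). This guarantees that every true species passes the
translation filter, so any translation-stage discard on simulated data is
a pipeline defect, not generator noise. Species are spaced at pairwise
p-distance > 0.08 (verified, with resampling and an explicit failure when
spacing is impossible), i.e. more than twice the 3% clustering threshold;
optional haplotypes sit within 4 substitutions of the primary barcode, so
intra-species distances stay below the threshold and each species should
come back as exactly one MOTU. Habitat structure mirrors a two-reservoir
survey: A-only, B-only and shared species, per-sample occupancy drawn at
probability 0.6 within the species' habitat(s) (each species is
guaranteed at least one sample), and lognormal(0, 1) relative abundances
to produce the skewed read-count distributions typical of metabarcoding.

`simulate_reads()` emits merged-orientation reads
`tag + primer + insert + revcomp(primer) + revcomp(tag)`, with degenerate
primer positions realised per read. Noise processes:

* **dropout** — each (species, replicate) pair fails to amplify with
  probability `dropout_prob`; this is the process the 3-of-5 replicate
  filter is designed against;
* **substitution errors** — per-base rate on the insert (binomially
  distributed per read);
* **chimeras** — single-breakpoint splices of two parents amplified in
  the same replicate, breakpoint uniform on positions 50–263.

Read counts per surviving species are one guaranteed read plus a
multinomial draw weighted by relative abundance. This floor makes
detection failures attributable to `dropout_prob` alone, which keeps the
noiseless-closure property exact; the cost is that sampling-depth
limitation as an independent dropout mechanism is not modelled. Other
things the simulator deliberately does not emulate: polymerase bias,
realistic quality scores (constant Q37), indels, and tag jumping.
Passing tests on simulated data therefore show that the pipeline's logic
is correct under the stated noise model — not that real high-throughput sequencing data would
behave as cleanly.

## The retention-rule cascade

Unique sequences are filtered per sample in a fixed order; cheap
sequence-intrinsic rules run before the replicate rule so every discard
has a single attributed reason and the per-sample report reconstructs the
input exactly:

1. **length** — inserts must be 313 nt (tolerance 0 by default);
2. **error pruning** — within each replicate, a sequence is absorbed into
   a parent at edit distance <= 1 whose count is >= 10x its own,
   iterated to a fixpoint (children in ascending-count order). The 1/10
   defaults are explicit stand-ins for an unpublished denoising
   configuration and are exposed as parameters;
3. **reference-identity prescreen** — best hit over the whole reference
   collection; discard if the best hit is non-metazoan or the best
   metazoan identity is < 80%;
4. **translation** — keep if any reading frame is stop-free under the
   vertebrate *or* invertebrate mitochondrial code. Because the
   invertebrate stop set (TAA, TAG) is a subset of the vertebrate one
   (TAA, TAG, AGA, AGG), the union reduces to the invertebrate check;
   the per-code tables remain available via `stop_free_frames()`;
5. **replicate consistency** — a sequence is retained for a sample only
   if seen in >= 3 of its 5 replicate PCRs. This acts on exact unique
   sequences, before clustering, so chimeras and surviving error variants
   (which rarely recur across independent PCRs) are removed without any
   abundance modelling.

## MOTU delimitation

`objective_cluster()` uses single-linkage semantics: two sequences share
a MOTU iff a chain of pairwise p-distances at or below the threshold
(default 3%) connects them — the connected components of the threshold
graph. Single linkage is the declared choice because it is the only
linkage under which the threshold scan (`threshold_scan()`, default
ladder 2/3/4%) is provably monotone non-increasing, which is the
stability argument the scan exists to support. p-distance is the
uncorrected mismatch proportion with pairwise deletion of gap/N columns;
fixed-length 313-nt amplicons are compared positionally (exact and
equivalent to alignment for equal-length, indel-free sequences), while
unequal lengths go through an ends-free global alignment (match +1,
mismatch -1, gap open -5, gap extend -2). All-pairs computation is the
complexity contract: post-filter sequence counts are a few thousand at
most, and the mismatch matrices are computed as four per-base indicator
matrix products, which keeps even the 516-species closure run in
milliseconds. Representatives are the highest-count member, ties broken
lexicographically, and MOTU ids are canonicalised by representative so
the partition is invariant to input order (property-tested against a
brute-force transitive-closure oracle).

## Taxonomy bands

`assign_taxa()` applies a conjunctive species rule: identity >= 97% *and*
overlap >= 310 aligned bases. High-identity hits with short overlap fall
through to the higher-taxon band, as do identities in [90%, 97%); the
higher-taxon call propagates the best hit's phylum deterministically and
is marked as such in a provenance column (a stand-in for a Bayesian
assignment engine, which would require live database access). Matches in
[80%, 90%) are retained but unidentified — the band between the prescreen
floor and the higher-taxon band is not named, which is the conservative
reading when no rule is stated for it.

## Community statistics

Chao2 uses the small-sample corrected form in both branches:
`S_obs + ((m-1)/m) Q1^2 / (2 Q2)` when duplicates exist, else
`S_obs + ((m-1)/m) Q1 (Q1-1) / 2`. ICE estimates coverage from the
infrequent group (frequency <= 10), with the infrequent-unit count
`m_infr` taken from the incidence matrix when available, and falls back
to Chao2 at zero coverage. The sampling unit for richness estimation is
one water sample (site x depth), m = 14 per habitat. Both estimators are
tested for their `>= S_obs` floor and Chao2 for a bias-reduction property
on detection simulations. Accumulation curves average cumulative richness
over random sample orderings (an exhaustive mode enumerates all orderings
for m <= 8 and matches vegan's analytic exact curve).

Dissimilarities: Jaccard on presence–absence, Morisita–Horn on read
counts (scale-invariant by construction), and Renkonen percentage
similarity on relative read counts pooled per habitat or per sampling
point. Because it is ambiguous whether rank-transformed read counts
change conclusions, `renkonen_similarity()` exposes `use_ranks` as an
option rather than deciding silently. NMDS is delegated to vegan's
metaMDS (20 restarts, 500 iterations, seed-pinned); the package does not
re-derive ordination machinery that a standard tool already provides.

## Habitat signatures

`build_reference_profile()` scores each MOTU 0/1 by presence anywhere in
a habitat; `sample_dissimilarities()` compares every sample profile to
every habitat profile by Jaccard. The default keeps the focal sample
inside its own habitat's profile — matching how such reference profiles
are usually constructed — which makes the own-habitat dissimilarity
algebraically `1 - |sample| / |profile|` (the sample's presences are a
subset of its profile). Because that construction is circular as a
classification claim, `leave_one_out = TRUE` removes the focal sample
from its own profile; both modes are tested. Group comparison uses a
two-sided Mann–Whitney U test by default (dissimilarities are bounded and
non-normal; the test behind the study-style p-values is not otherwise
determined), with a t-test option for sensitivity. Exact ties in the
nearest-profile call return `"ambiguous"`, never a silent choice.

## Numerical and design choices

* Coordinates are 0-based half-open internally; tags are matched exactly
  (9-bp tags are short and no mismatch tolerance is stated for them);
  primers tolerate <= 2 mismatches outside degenerate positions, with
  inosine treated as N.
* Reported percentages round halves away from zero (70% from 19/27, 56%
  from 9/16), matching how such tables are conventionally printed;
  `round()`'s banker's rounding would not.
* Undefined p-distances (no comparable positions) are treated as above
  threshold and logged, so degenerate inputs cannot silently merge MOTUs.
* All stochastic steps take explicit integer seeds and restore the
  caller's RNG state; identical seeds give byte-identical FASTQ and TSV
  artifacts.

## Problem sizes used in the checks

The verification suite exercises three scales, chosen once as the
package's own study conditions: (i) the full noiseless closure uses the
complete design — 281 + 140 + 95 = 516 species, 28 samples x 5
replicates at depth 400 (56,000 reads) — and must recover exactly 516
MOTUs, the true incidence matrix, and 100% species-level taxonomy;
(ii) the habitat-signature check runs 100 seeded read-level simulations
at a scaled pool of 33 + 17 + 12 = 62 species and depth 100 with
dropout 0.3 and error rate 0.005, requiring all 28 samples correctly
assigned and both habitat tests below p = 1e-4 in at least 95 of 100
seeds; (iii) clustering is compared against a brute-force
transitive-closure oracle on 200 random instances of up to 12 sequences.
The scaled pool preserves the study's structure (about 60% richness
excess of habitat A over B, about one fifth of species shared).

## Known limitations

Identity in the prescreen and taxonomy is computed against the supplied
reference collection only — there is no online database search, so
assignment quality is bounded by the references given. The replicate
filter assumes equal replicate counts per sample; deviating samples warn
and are filtered against their available replicates. The error-pruning
rule is a deliberate simplification of production denoisers; on data with
substantial indel error it will under-absorb, though the downstream
replicate filter removes most of what survives. Multi-habitat (> 2)
classification and abundance-weighted profiles are out of scope.
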