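---
title: "Methods: quantifying and simulating TE invasions from Pool-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and simulating TE invasions from Pool-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teinvasion)
```

This vignette documents the models behind each stage of the package, the
parameters that matter, the assumptions baked into the synthetic-data
generator, and the numerical and design choices that were genuinely open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## Copy-number estimation by SCG normalization

A pooled library sequenced to fold-coverage `d` per haploid genome covers a
single-copy gene (SCG) at depth `d` and a TE present at `n` copies per
haploid genome at depth `n * d`. The estimator is therefore the ratio of
unweighted mean per-position coverages,

$$\hat n \;=\; \frac{\overline{\mathrm{cov}}_{TE}}{\overline{\mathrm{cov}}_{SCG}},$$

with the SCG mean pooled over all positions of all SCGs (not per-gene
means), matching the "average coverage" convention. Per-site copy numbers
divide each TE position's coverage by the same SCG normalizer; internal
deletions (e.g. the KP-element's, which removes consensus site 2040) then
appear as a proportional drop of per-site copies over the deleted interval.

Open choices, exposed as options and defaulted as follows:

- `scg_stat`: mean (default) or median SCG coverage. The mean matches the
  verbal definition; the median is more robust to coverage spikes in real
  data.
- `te_zero`: zero-coverage TE positions are *included* in the TE mean by
  default. Excluding them would overestimate copy number for partially
  deleted or truncated elements.
- Edge positions (within a read length of a sequence end) are included in
  all means. Coverage falls off linearly there because reads are not
  allowed to overhang, which depresses a sequence's mean coverage by a
  factor `(L - r + 1)/L`. The TE/SCG *ratio* is unaffected when both
  references are long relative to the read length, which is why the
  synthetic fixtures use ~3 kb SCGs against a ~2.9 kb TE (real *rhi*,
  *tj* and *RpL32* are kb-scale too); with very short references the
  ratio would inherit the differential falloff.

Allele frequencies are per-position nucleotide counts over coverage.
Positions below `min_coverage` (default 10; the source workflow states no
threshold, so it is configurable) are *missing*, not zero — downstream
consumers must distinguish "no signal" from "allele absent". `N` bases
count toward neither allele nor coverage.

## The synthetic Pool-Seq generator

The generator emulates pooled sequencing of `n` diploid individuals:

- TE copies per individual are Poisson with mean `2 * copy_number_mean`
  (dispersed, unlinked insertions; a `fixed` mode exists for exact-count
  tests).
- Each copy draws an allele at every profiled consensus site from the
  stated `allele_profile`, independently per copy — the pooled frequency
  then fluctuates binomially around the profile, which is the error model
  the recovery tests assume.
- With probability `deletion_fraction` a copy carries the internal
  deletion `deletion_interval`; it emits reads only from its two flanks
  and never across the junction. This mirrors what a gapless aligner
  retains from reads of a KP-like derivative and makes the deletion
  visible purely as a per-site coverage drop.
- Reads are single-end, uniformly positioned, never overhanging the
  sequence ends; per-copy read counts are Poisson with the rate chosen so
  every interior base of a haploid-genome copy has expected coverage
  `depth / (2 n)`. Summed over individuals, expected SCG coverage is
  `depth` and expected TE coverage `depth * copy_number_mean`.
- Substitution errors hit each base independently at `error_rate`
  (default 0.001, the scale of post-trimming Illumina error); there are
  no indels, no quality model, no GC bias, no duplicates — the pipeline
  uses none of that information.
- Contamination replaces `round(fraction * total)` reads with reads from
  an SCG-only pool of the other species. At `fraction = 1` the output is
  exactly the contaminant pool; between 0 and 1, if the contaminant pool
  is smaller than the requested count, reads are drawn with replacement.

Read names encode individual, source sequence, copy id and true position,
so every oracle check (coverage recovery, alignment truth, allele tallies,
contamination counts) runs without auxiliary lookups. What a green test
does *not* establish: robustness to indels, paired-end artifacts, mapping
bias between diverged references, or non-uniform insert distributions —
none of which the generator produces.

## The internal aligner

The internal aligner exists only to make synthetic tests self-contained;
real data should be aligned externally and ingested as SAM. It is gapless
seed-and-extend: exact k-mer seeds (default 20 bp) taken at the start,
middle and end of each read are looked up in an index of the target
(TE + one species' SCGs), and each candidate placement is scored by total
mismatches. The placement is reported only if it is unique and has at most
`max_mismatches` (default 3); ties are reported unaligned. Three seed
offsets matter: with a single 5' seed, reads carrying a true variant
inside the seed window are systematically lost, which biases allele
frequencies at polymorphic sites and the contamination screen. With three
disjoint seeds a read is lost only when variants/errors hit all three,
which is negligible at the densities the generator produces (planted
diagnostic SNPs are spaced ≥ 120 bp in the fixtures, so a 100 bp read
spans at most one).

## Diagnostic SNPs and the contamination screen

A site is diagnostic when every reference strain of species A is fixed for
one allele and every strain of species B for a different allele. "Fixed"
means major-allele frequency ≥ `fixity_threshold`, default 0.99 rather
than 1.0 to tolerate sequencing error in the strain data; sites showing a
third allele above `1 - fixity_threshold` in either species are excluded
as tri-allelic. Sites uncovered in any strain are excluded and counted.

The screen statistic is the unweighted mean, over covered diagnostic
sites, of the frequency of the other species' allele — a direct estimate
of the contaminating read fraction, since at each diagnostic site foreign
reads and only foreign reads carry the foreign allele (up to sequencing
error). On error-free two-species mixtures the two directional screens sum
to exactly 1. The pass/fail gate defaults to 0.01; the source workflow
states no cutoff, so this is a package decision and configurable.

## Invasion time series

`plateau_estimate` reads "plateau" as: the earliest sampled generation
from which the least-squares slope over the `window` consecutive points
starting there is within `slope_tol`, with the plateau level averaged from
that generation to the series end, and a no-plateau flag when the
criterion is never met. Defaults (`window = 3`, `slope_tol = 0.1`
copies/generation) suit trajectories sampled every ~10 generations, as in
the experimental design; densely sampled simulator output is noisier
per-point and is assessed with a wider window (10) in the tests.

`compare_groups` tests latest-generation copy numbers with a two-sided
two-sample t-test; Welch (unequal variance) is the default because
replicate counts are small and variances need not match, with the pooled
variant behind a flag — the source analysis says only "t-test".
Replicates ending at different final generations are compared at their own
final generation. Zero-variance degenerate groups return statistic 0 and
p = 1 when the means agree, and ±Inf with the limiting p = 0 otherwise.

## Origin of a horizontal transfer

`build_snp_table` averages allele frequencies per species *over samples*
covering each site (never pooling reads across samples, so deep samples do
not dominate), and retains sites whose mean absolute frequency difference,
summed over alleles and halved, exceeds the threshold (default 0.01).
The "simulans allele" of a retained site is the major allele of the
simulans panel; at a tri-allelic site it is still a single allele and
contributes a single factor.

`composite_likelihood` multiplies the sample's frequencies of those
alleles. It is a descriptive score, not a calibrated probability: values
are comparable between samples only when computed over the same SNPs,
which is why the covered-SNP count is reported and the default
`missing_policy = "skip"` flags dropped sites; `impute-panel-mean`
substitutes the panel-mean frequency instead. How sites deleted in many
copies should enter L is genuinely open — the frequency at such a site is
computed from the copies that retain it — and `absolute_allele_copies`
(frequency × per-site copies) is provided as the deletion-aware
complement.

`rank_origins` orders samples by L; the regional summary reports both the
maximum L and the count of samples above a quantile threshold (default
0.9) of all L values, separating regions where several samples score high
from regions carried by a single outlier.

## The trap-model simulator

One generation of `run_invasion`, in order: (1) fitness-weighted
multinomial choice of two parents per offspring, fitness `(1 - s)^n`
multiplicative in total copy number; (2) free recombination — each
parental insertion transmitted independently with probability 1/2; (3)
excision, removing `Poisson(x n)` uniformly chosen copies; (4)
transposition, `Poisson(u n)` new insertions at uniform slots, but only in
individuals carrying *no* cluster insertion (dominant, individual-level
silencing — the simplest trap-model reading). The genome is `L_sites`
discrete slots (default 10,000) of which a fraction `cluster_fraction` are
cluster slots; founders are seeded outside clusters. The per-generation
output is mean copies per haploid genome; TE loss and population
extinction are reported as attributes, not errors.

Consequences used by the tests: with `u = x = s = 0` the mean copy number
is a martingale — constant in expectation but jittered by segregation
drift, so the "no-dynamics" check is statistical, not exact; with no
clusters and no selection the early mean grows like `n_0 (1 + u)^t`
(branching approximation, checked at t = 20 within 3 SE over 50
replicates); plateaus decrease with `cluster_fraction` (more traps are hit
sooner); and at small `N` with few seeded founders the TE is frequently
lost outright, the stochastic early phase of real invasions. The module
reproduces these qualitative expectations only; it is not calibrated to
any particular experimental trajectory.

## Numerical conventions and degenerate inputs

- All TE positions are 1-based on the consensus; intervals are closed.
- Allele-profile fractions must sum to 1 within 1e-9.
- `estimate_copy_number` raises an error on zero SCG coverage rather than
  returning Inf; `contamination_screen` and `composite_likelihood` raise
  on zero usable sites (undefined, distinct from a value of 0).
- Pileup rejects (with a warning and a count) alignments that would
  overhang the reference; trimming truncates from the 3' end only.
- Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state, so pipelines are reproducible end to end.

## Known limitations

- The aligner is gapless: reads spanning deletion junctions are not
  placed, so breakpoints are inferred only via coverage drops, and indel
  polymorphism is outside the model.
- The composite likelihood has no uncertainty interval; regional rankings
  with few samples rest on the reported high-scorer counts.
- The simulator ignores piRNA abundance dynamics, maternal effects,
  paramutation and temperature (temperature enters only through the
  user's choice of `u`).
- With a single reference strain per species, diagnostic-SNP discovery
  cannot separate fixed differences from strain-private variants; three
  strains per species, as in the intended design, is the sensible minimum.
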