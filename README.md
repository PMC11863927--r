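# teinvasion

Tools for tracking transposable element (TE) invasions from pooled
sequencing (Pool-Seq) data, built around the workflow used to monitor
P-element invasions in *Drosophila* populations.

## The problem

When a TE invades a population, the quantity of interest is the number of
insertions per haploid genome and how it changes over generations — until
the host's piRNA defense halts the invasion at a plateau. Pool-Seq makes
this measurable without assembling individual genomes: reads from a pooled
population sample are aligned to a small reference set consisting of the TE
consensus plus a few single-copy genes (SCGs, e.g. *rhi*, *tj*, *RpL32*).
Because each SCG occurs exactly once per haploid genome, its coverage
calibrates sequencing depth, and

```
copies per haploid genome = mean TE coverage / mean SCG coverage
```

so a TE coverage of 30 over an SCG coverage of 5 means roughly 6 insertions
per haploid genome. The same pileup yields per-site TE allele frequencies
(e.g. the diagnostic G/A difference at consensus site 2040 that separates
the *D. melanogaster* and *D. simulans* P-element), and SCG sites fixed for
alternative alleles between two species act as diagnostic SNPs that expose
cross-species read contamination.

Given allele profiles from many population samples, the package also ranks
candidate geographic origins of a horizontal transfer (HT) event with the
composite likelihood

```
L = prod_i f_i^sim
```

over segregating TE SNPs *i*, where `f_i^sim` is the sample's frequency of
the allele fixed in the recipient species: the region whose samples carry
the recipient-species alleles at the highest joint frequency is the most
plausible source of the transfer.

Finally, a Wright–Fisher simulator implements the piRNA-cluster trap model
(an individual is transposition-silenced once any TE copy sits in a cluster
slot; fitness is `(1 - s)^n`) to generate invasion trajectories and test
qualitative expectations, e.g. that larger cluster fractions produce lower
plateaus and that TEs are frequently lost by drift in small populations.

Every stage is testable without external data: a synthetic Pool-Seq
generator emits reads from diploid individuals with known per-copy alleles,
optional KP-like internal deletions and controlled contamination, and
records the full ground truth per read.

## Worked example

```r
library(teinvasion)
set.seed(20)
rand_seq <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")
refs <- reference_set("PPI251", rand_seq(2907),
  data.frame(gene = c("rhi", "tj", "RpL32"), species = "melanogaster",
             sequence = replicate(3, rand_seq(3000))))

## a pool of 50 flies, ~10 TE copies per haploid genome, 40%/60% A/G at
## site 2040, 30% of copies carrying an internal deletion over 1900-2200
spec <- pool_spec("melanogaster", n_individuals = 50, copy_number_mean = 10,
                  allele_profile = list("2040" = c(A = 0.4, G = 0.6)),
                  deletion_fraction = 0.3, deletion_interval = c(1900, 2200),
                  depth = 50, seed = 42)
pool <- simulate_pool(spec, refs)       # 18069 reads with ground truth
res <- quantify_pool(pool$reads, refs, "melanogaster")
res$copy_number
#> copy_number_estimate: 9.835 copies per haploid genome
#>   TE mean coverage 472.72 / SCG mean coverage 48.07
profile_freq(res$profile, 2040, "A")
#> [1] 0.409
samp <- population_sample("demo", "melanogaster", "lab",
                          res$profile, res$copy_number)
absolute_allele_copies(samp, 2040, "A")
#> [1] 2.89
```

The realized truth of this pool is 10.5 copies per haploid genome, so the
normalization recovers it to ~6% in a single sample (unbiased over seeds);
the allele frequency at site 2040 recovers the 0.4 target; and the
deletion-aware absolute count (frequency x per-site copies) reports ~2.9
A-copies per haploid genome — insensitive to the 30% of copies whose
deletion removes site 2040, because those contribute neither to the
frequency nor to the site's coverage.

Other entry points: `find_diagnostic_snps()` / `contamination_screen()`,
`latest_generation_mean()` / `plateau_estimate()` / `compare_groups()`,
`build_snp_table()` / `composite_likelihood()` / `rank_origins()`,
`sim_params()` / `run_invasion()`. A command-line front end is installed as
`exec/teinvasion` (subcommands `quant`, `diagsnps-find`, `diagsnps-screen`,
`timeseries`, `origin`, `simulate-invasion`, `simulate-pool`).

## Layout

- `R/simdata.R` — synthetic Pool-Seq generator with truth records
- `R/aligner.R` — read trimming, minimal gapless seed-and-extend test
  aligner, pileup, SAM/TSV interchange
- `R/quant.R` — SCG-normalized copy number, allele profiles
- `R/diagsnps.R` — diagnostic SNP discovery and contamination screen
- `R/timeseries.R` — plateau detection, end-point means, group tests
- `R/origin.R` — segregating-SNP table, composite likelihood, ranking
- `R/invsim.R` — Wright–Fisher trap-model invasion simulator
- `vignettes/te-invasion-methods.Rmd` — models, assumptions, parameter
  choices and limitations
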