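Package: teinvasion
Title: Tracking Transposable Element Invasions from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Pool-Seq", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking transposable element (TE) invasions in
    experimental and natural populations from pooled sequencing (Pool-Seq)
    data.  Estimates haploid TE copy numbers by normalizing TE coverage to
    the coverage of single-copy genes, profiles per-site TE allele
    frequencies, screens samples for cross-species contamination using
    diagnostic SNPs in single-copy genes, summarizes invasion trajectories
    (plateau level and timing, group comparisons), infers the likely
    geographic origin of a horizontal transfer event with a composite
    likelihood over segregating TE SNPs, and simulates TE invasions under a
    Wright-Fisher piRNA-cluster trap model.  Includes a synthetic Pool-Seq
    read generator with known ground truth so that every stage of the
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
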