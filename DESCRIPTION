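Package: edpairs
Title: Evolutionary Dependency of Cancer Gene Pairs from Context-Stratified dN/dS
Version: 1.0.0
Authors@R:
    person("EDpairs", "Developers", email = "edpairs@example.org",
           role = c("aut", "cre"))
Description: Infers the evolutionary dependency (ED) of cancer gene pairs from
    somatic mutation profiles. Per-gene, per-class dN/dS ratios (missense,
    truncating, indel) are estimated with a synonymous-calibrated Poisson model
    at configurable substitution-rate granularity (uniform to strand-collapsed
    trinucleotide). Cohorts are split by mutation context (samples with and
    without non-silent mutations in a context gene), the context-dependent
    dN/dS (cdNS) score log2(dNdS[context+]/dNdS[context-]) is computed per
    pair, and significance is assessed by label permutation (plus a
    sample-size-corrected Fisher test for pan-cancer antagonistic pairs).
    Pairs are filtered into synergistic (SYN) and antagonistic (ANT) calls.
    Downstream analyses cover variant-allele-frequency and mutation-burden
    differentials with permuted baselines, pathway co-membership z-scores, and
    effect sizes linking ED to knockout viability and drug IC50 in cell-line
    panels. A synthetic-data module generates MAF cohorts and cell-line panels
    with known ground truth (true per-gene selection, true cdNS, clonality
    structure, programmed effect sizes) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
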