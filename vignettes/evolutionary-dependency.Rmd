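---
title: "Context-dependent dN/dS: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent dN/dS: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edpairs)
```

## The model

`edpairs` treats somatic selection inference as a rate-calibration
problem. For a gene with coding sequence $S$, every one of the $3L$
possible single-nucleotide substitutions is enumerated and classified by
translating the mutated codon: synonymous, missense, or nonsense
(`build_opportunity_table()`). Synonymous mutations are taken as selection-
free, so per-category mutation rates are fitted from synonymous counts
alone by maximum likelihood:

$$\hat r_c = \frac{n^{syn}_c}{L^{syn}_c \, N},$$

where $c$ indexes rate categories, $L^{syn}_c$ the synonymous opportunity
in that category across the gene panel, and $N$ the number of genomes in
the fitted subset. Expected non-silent counts follow as
$n_{exp} = N \sum_c \hat r_c \, L^{class}_c$, and
$\omega = n_{obs} / n_{exp}$ per gene and class. Truncating pools nonsense
and essential-splice observations (synthetic single-exon genes carry zero
splice opportunity; real gene models may declare one, which enters through
the mean synonymous rate). Indels have no synonymous analogue; their ratio
is per-length against a background panel excluding the tested gene:
$\omega_{ind} = (n_g / L_g) / (n_{bg} / L_{bg})$.

This is a deliberate simplification of covariate-shrunk driver-discovery
estimators: no negative-binomial regression, no epigenomic covariates, no
per-site hotspot model. The package's claims concern the *contrast* of two
$\omega$ estimates, which only needs a consistent estimator applied
identically to both arms, and the simplification is fully testable against
closed forms (with uniform rates, $\omega$ reduces exactly to
$(n_N/L_N)/(n_S/L_S)$; the suite asserts agreement to $10^{-9}$).

### The cdNS score

For an ordered pair (context gene A, partner gene B) the roster is split
into genomes with and without a non-silent A mutation, each subset gets
its own synonymous calibration (so burden differences between the arms are
absorbed), and

$$\mathrm{cdNS} = \log_2 \frac{\omega_{B|A+}}{\omega_{B|A-}}.$$

Per-subset calibration has an important algebraic consequence: the subset
size cancels, and $\omega$ over a subset is a ratio of two per-sample
sums. The permutation engine exploits this — reshuffling context labels
only redistributes samples between two running sums, which is what makes
1000-permutation tests over hundreds of pairs cheap.

Both orientations of every pair are evaluated and reported separately;
the dependency of B on A's context is not the dependency of A on B's.

## Statistical choices

**Permutation p.** Context-positive labels are reassigned to uniformly
random subsets of the observed size; the p-value uses the add-one
correction $p = (1 + \#\,\mathrm{extreme}) / (n_{perm} + 1)$, so $p = 0$
is impossible and the resolution floor is $1/(n_{perm}+1)$. Sidedness is
explicit: the default used in pair calling (`alternative = "auto"`) counts
permutations at least as extreme *in the direction of the observed
score's sign*, which is the natural quantity for a caller that labels SYN
and ANT by that sign — but, because the direction adapts to the data, this
composite p is bounded near 0.5 under the null and its nominal level
doubles. The fixed tails (`"greater"`, `"less"`) are proper one-sided
p-values, approximately uniform under no dependence; the null-calibration
acceptance test asserts uniformity and the ~1% rejection rate on the fixed
SYN tail. Permutations whose cdNS is undefined (zero counts in an arm)
count as non-exceeding and are tallied separately.

**Undefined scores.** $\omega = 0$ in either arm leaves cdNS undefined,
flagged with a reason code, and the pair is excluded from calling rather
than imputed. An opt-in pseudocount was considered and rejected as a
default: the published minimum-mutation filters (SYN ≥ 3, ANT ≥ 1 partner
mutations in the context-positive arm) make most such pairs ineligible
anyway, and explicit exclusion beats silent shrinkage.

**Sample-size correction for pan-cancer ANT.** Apparent mutual
exclusivity can arise purely from tumor-type specificity of two genes. The
mitigation rescales the context-negative count by
$w = \mathrm{logistic}(k (f - m))$ of the context-positive fraction $f$,
giving a corrected 2×2 table for a one-sided Fisher test for depletion of
double mutants. The published "recommended parameters" live in an external
reference and are not printed in the source analysis; the defaults here
($m = 0.05$, $k = 50$) are this package's own choice, exposed in
configuration, with `w_override = 1` recovering the uncorrected test. The
mechanism (monotonicity, the $w = 1$ limit, agreement with direct
hypergeometric summation) is what the tests pin down, not the constants.

**Pair filters.** $P < 0.01$ (permutation for SYN and for all
tumor-type-specific pairs; corrected Fisher for pan-cancer ANT),
$n^{mut}_{+} \ge 3$ for SYN / $\ge 1$ for ANT, and ED ratio
$> 3$ or $< 0.3$. The ratio filter is applied per (pair, class) record;
whether the source analysis applied it jointly across classes is not
stated, and per-record is the conservative reading.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per sample: a lognormal burden multiplier
(mean fixed at 1; optional hypermutator fraction with a burden factor),
context status per context gene as Bernoulli(prevalence) *realized as an
actual non-silent record* (so splitting the emitted MAF reproduces truth
exactly — the real interface is what gets tested), then per-gene,
per-class Poisson counts with mean
$\text{burden} \times \text{rate} \times \text{opportunity} \times
\omega_{eff}$, where $\omega_{eff} = \omega_{true} \cdot 2^{\mathrm{cdNS}_{true}}$
for the partner class in context-positive genomes. The multiplicative
construction makes the programmed cdNS the estimand by definition — that
identity is the module's central contract. Context genes carry only
synonymous background so that realized prevalence equals the programmed
one. Sites are drawn from the opportunity table (category-weighted when a
spectrum is configured); read counts come from Beta-distributed VAFs
(clonal Beta(20, 20), subclonal Beta(4, 16)) at Poisson(80) depth,
MC3-like values.

Not modeled, deliberately: genomic coordinates on a reference assembly,
copy number and rearrangements, kataegis-like simultaneous acquisition
(acquisition is strictly sequential, matching the method's stated
assumption), signature-specific spectra beyond category weights, purity or
subclonal deconvolution. A green test on synthetic data therefore
establishes estimator correctness and calibration under the stated
generative model — not robustness to mapping artifacts, germline leakage,
or covariate-driven rate variation in real cohorts.

## Stated worlds for the acceptance fixtures

Chosen once, before measurement, and not revisited:

- Default cohort: 1,000 samples, 50 genes of 500 codons, substitution
  rate 2e-5 per opportunity per sample (a typical exome-wide burden),
  indel rate 2e-6 per coding base, burden sdlog 0.5.
- High-burden fixtures (neutral calibration, recovery, end-to-end
  calling): rate 1e-4 (≈30 mutations/Mb, MSI/melanoma-grade), which is
  what yields the ≥ 500 pooled synonymous mutations those criteria
  themselves stipulate; indel rate 2e-5 in the neutral fixture so the
  pooled indel ratio is informative.
- Permutation-null fixture: rate 5e-5, 200 pairs programmed with
  cdNS_true = 0 at prevalence 0.2 (null by construction with realistic
  context sizes).
- Recovery and end-to-end fixtures: partner $\omega_{base} = 2$,
  prevalence 0.2, programmed cdNS ±1, ±2.
- Feature fixtures: SYN pairs with clonal contexts and subclonal
  partners (ANT mirrored) for ΔVAF; 15% hypermutators at 10× burden for
  ΔTMB.

## Numerical details

- Terminal stop codons are excluded from opportunity counting (the
  conservation law is $\sum_{class} = 3 \times$ coding length);
  substitutions in the stop codon are not modeled.
- Trinucleotide context at the two CDS boundary positions is completed by
  padding with `A`; synthetic genes have no genomic flanks, and the choice
  is deterministic and shared by simulation and estimation.
- Strand collapsing maps purine-reference substitutions to their
  pyrimidine reverse complement (96 = 32 contexts × 3 alternates).
- Rate categories with zero synonymous opportunity get an `NA` rate and
  are excluded from expectations; $n_{exp} = 0$ yields a flagged `NA`
  estimate, never a silent zero.
- `delta_tmb()` summarizes groups by the median (mean by flag) and
  reports the log10 difference; the singleton group pools genomes mutated
  in exactly one of the two genes.
- Gene shuffles in `permuted_baseline()` preserve the pair-list length and
  gene multiset and redraw on self-pair collisions; the group-mean
  baseline (`null_means`, one mean per permutation) is the reference band
  for group-level direction checks, while the pooled per-pair null feeds
  the t-tests.

## Known limitations

- The estimator does not reproduce covariate-based shrinkage, so absolute
  $\omega$ values on real cohorts will differ from dNdScv's; only the
  documented estimator contract is claimed.
- The ΔTMB direction for SYN pairs is not guaranteed by this generator:
  double mutants of strong SYN pairs saturate quickly and their burden
  coupling depends on rates, so the suite asserts the ANT direction
  (positive, outside the permuted baseline) and SYN < ANT, not
  ΔTMB(SYN) < 0.
- Pan-cancer ANT discovery inherits the tumor-type confounding the
  correction factor only mitigates; the logistic constants are package
  defaults, not published values.
- Cell-line analyses consume binary mutation flags; hotspot-restricted
  definitions of "mutated" are available only as a user-side filter.
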