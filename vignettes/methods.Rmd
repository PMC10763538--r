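---
title: "Methods: models, procedures and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, procedures and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaivar)
```

# Scope

`rnaivar` implements the quantitative core of studies asking why wild
*Caenorhabditis elegans* strains differ in germline RNA-interference
(RNAi) competence: whether RNAi-pathway genes are unusually variable in
expression across strains, whether their alleles are pseudogenized or
functionally diverged in the wild population, how penetrant the
RNAi-induced embryonic-lethality phenotype is per genotype, and how
per-embryo transcript counts respond to knockdown. Every analysis takes
tidy tabular input (tibbles) and returns tibbles or classed result
objects with `tidy()`, `glance()` and `autoplot()` methods.

Because the real inputs of such a study (bulk RNA-seq of wild isolates, a
population-scale variant call set, plate-level lethality assays, smFISH
transcript counts) are external data, the package ships a first-class,
seeded synthetic-data generator (`sim_config()` and the `sim_*()`
functions) whose defaults mirror the designs the statistics were built
for. The generator is used to calibrate and test every procedure end to
end.

# Expression variance and matched resampling

## Normalization and the per-gene strain term

Counts are filtered (`filter_low_counts()`, total count > 10 across all
samples) and transformed by `normalize_vst()`: per-sample size factors by
the median-of-ratios method over genes with a nonzero geometric mean,
followed by `log2(count / sf + 1)`. The contract of this transform is
variance stabilization in rank — on negative-binomial counts with fixed
dispersion the per-gene spread becomes approximately independent of the
mean — not numeric equality with any external normalization tool. A
count-model likelihood-ratio test is deliberately out of scope; the
differential-expression stand-in (`de_test()`) is a vectorized one-way
ANOVA F-test across strains with Benjamini–Hochberg adjustment and a
flag at FDR < 0.1, and the enrichment machinery also accepts externally
computed flags.

The per-gene statistic of interest is the between-strain sum of squares
of the normalized values (`strain_variance()`), i.e. the strain term of a
one-way ANOVA: `SS = sum_s n_s (mean_s - grand_mean)^2`.

## Expression-matched null sets

`match_expression_sets()` builds, for each focal gene, a candidate pool
of all non-focal genes whose expression quantile (average ranks for
ties, scaled to (0, 1]) lies within ±0.005 of the focal gene's quantile
— one percentile. Each of B null sets (default 10,000) draws one pool
member uniformly and independently per focal slot.
`resampling_enrichment()` then compares the focal set's median strain SS
(and its DE-flag proportion) to the null sets' medians. Two permutation
p-value conventions are reported side by side:

* `perm_p = #(null >= observed) / B` — ties count toward the p-value, and
  `frac_null_below + perm_p = 1` holds exactly;
* the add-one variant `(count + 1) / (B + 1)`, which can never be zero.

An exact upper-tail hypergeometric probability of the focal set's
DE-flag enrichment (`hypergeom_enrichment()`, log-space summation) is
reported alongside. Per-null-set one-tailed Mann–Whitney tests are
optional (`mw_tests = FALSE` skips them in large calibration runs); the
loop uses a tie-corrected normal approximation with continuity
correction, while the user-facing `mw_test()` enumerates all
arrangements exactly (tie-safe) when both sides have at most 10 values.

Calibration, built into the acceptance tests: under a self-null in which
the "focal" set is itself drawn by the matching procedure, `perm_p` is
uniform; with focal strain-effect SD at 3 times background (the
generator's default contrast), `frac_null_below >= 0.95` in at least 90%
of replicates at B = 1,000.

# Allele fates from population variants

Variant tables are sparse and haploid: one row per non-reference call
(`gt = "alt"`) or missed call (`gt = "missing"`); strains with no row at
a site implicitly carry the reference. Selfing isotypes justify the
haploid view; heterozygous calls are converted to missing at read time
with a warning.

* `gene_pi()`: nucleotide diversity
  `pi = (1/L) * sum_sites (n_s / (n_s - 1)) (1 - sum_a p_a^2)` with
  missing-aware per-site sample sizes; the denominator is the full gene
  length, and sites with fewer than two called strains are skipped and
  counted.
* `classify_allele()` applies the rule set: *pseudogenized* if the
  strain carries ≥ 1 high-confidence HIGH-impact variant and ≥ 1% of
  sites are diverged or missing, **or** if > 50% of sites are missed
  calls; *functionally diverged* if it carries ≥ 5 MODERATE missense
  substitutions, ≥ 1% divergence, and no HIGH-impact call; otherwise
  *reference-like*. Alleles with > 75% of sites uncalled are additionally
  flagged `possibly_missing` (the gene may be absent entirely). All
  thresholds are overridable parameters.
* `haplotypes()` drops strains with missed calls at the gene, collapses
  identical allele vectors, reports the small-sample-corrected
  haplotype diversity `H = (n/(n-1))(1 - sum p_i^2)` and a Hamming
  distance matrix between distinct haplotypes.
* `exclude_hyperdiverse()` flags genes overlapping masked intervals.
  Conventions are centralized: gene spans are 1-based inclusive, BED
  masks 0-based half-open; a gene `[s, e]` overlaps a mask `[bs, be)`
  iff `s <= be` and `e >= bs + 1`.

The variant generator realizes each (gene, strain) cell under one of
five scenarios (conserved, sub-threshold, functionally diverged,
pseudogenized, possibly-missing) constructed to satisfy the quantitative
definition of its truth label, so classifier branch coverage is testable
exactly; the acceptance suite requires 100% agreement over 5,000 cells.

# Penetrance models

`fit_penetrance()` binds plate-level dead/hatched counts as a binomial
response with a logit link and a free dispersion parameter
(quasibinomial): `phi` is the Pearson chi-squared over residual degrees
of freedom, and all standard errors scale by `sqrt(phi)`. Complete
separation (a genotype with all-dead or all-hatched plates) is detected
and the fitted proportion reported at the bound `0.5 / (n + 1)` or its
complement. Pairwise genotype contrasts (`pairwise_contrasts()`) are
Tukey-style all-pairs comparisons on the logit scale using the joint
max-|t| (single-step) adjustment over the fitted covariance, computed
via the `multcomp` machinery and seeded so the randomized
multivariate-t quadrature is reproducible; Bonferroni and unadjusted
variants are deterministic alternatives.

Penetrance over reproductive lifespan (`fit_lifespan_model()`) is
ordinary least squares on the plate-level dead proportion with strain,
age, their interaction, and worm-within-strain terms, tested
sequentially (type I); heteroscedasticity of the proportion response is
accepted and documented rather than modeled.

`classify_complementation()` calls one of four patterns from a
three-genotype design (parent P, F1 carrying the functional Argonaute
H+, F1 carrying its deletion HΔ): no rescue; ppw-1-dependent rescue
(H+ > P and H+ > HΔ); ppw-1-dependent suppression (HΔ > H+ and HΔ > P);
ppw-1-independent rescue (both F1s > P, F1s indistinguishable). When
rules conflict or none applies the call falls back in that priority
order and is flagged ambiguous.

The plate generator is beta-binomial, parameterized by the mean
proportion and the intra-plate correlation ρ, degenerating exactly to
binomial at ρ = 0; acceptance calibration shows Wald-type interval
coverage of 95% ± 2% at ρ = 0.1 with 8 plates per genotype and a
dispersion estimate that increases monotonically in ρ.

# Transcript response

`compare_groups()` applies a Welch t-test, an F variance-ratio test and
the tie-safe Mann–Whitney test to treated-vs-control transcript counts
of early embryos (stage ≤ 4 by default). `ancova()` widens the window
(stage ≤ 30) and fits the nested models `count ~ stage`,
`+ treatment`, `* treatment`, reporting nested-F p-values for the
treatment effect and slope change, per-term omega-squared
`(SS - df * MS_err) / (SS_tot + MS_err)` (unclipped — slightly negative
values are possible under the null), and per-condition slopes and R².

`bimodality_test()` implements the excess-mass test of multimodality:
`D = max_lambda [E(2, lambda) - E(1, lambda)]`, where `E(m, lambda)` is
the maximal excess probability mass attainable with m clusters. Over
the alternating weight sequence (point mass 1/n at each sorted
observation, −λ·gap between neighbors), E(1) is the maximum-sum
contiguous segment and E(2) the best pair of disjoint segments, both
computed by vectorized prefix-sum scans in O(n) per λ. The λ grid is 50
log-spaced values spanning 1/100th to the maximum of a kernel density
estimate (Sheather–Jones bandwidth, falling back to the normal
reference rule when the SJ equation has no solution). The p-value is a
bootstrap under the best-fitting unimodal rearrangement of the data:
the empirical CDF is replaced by its greatest convex minorant left of
the estimated mode and least concave majorant right of it, and samples
are drawn by inverse transform. Two deliberate numerical choices:
bootstrap replicates reuse the observed sample's λ grid (the grid is a
fixed feature of the statistic, not re-estimated per replicate), and
the p-value uses the add-one convention `(1 + #{boot >= obs}) / (B + 1)`.
This calibration is conservative — the unimodal rearrangement is the
least-favorable unimodal fit, so the null rejection rate sits below the
nominal level — which we accept; what the acceptance suite enforces is
that the level is controlled (not anticonservative) and that power
against a well-separated two-component mixture at n = 60 exceeds 90% at
p < 0.01. A named R package implements related tests; numeric equality
with it is not claimed.

# Generator defaults and what they emulate

Defaults of `sim_config()` mirror the supported study designs: 18,589
genes × 5 strains × 3 replicates with a 61-gene focal set; 403 isotypes
and 62 RNAi-pathway genes in the variant table; 8 plates per genotype
with 100–200 embryos each; transcript counts declining with embryonic
stage, with knockdown factors and on/off mixture weights per strain and
treatment. Effect-size knobs that no experimental design fixes —
strain-effect SDs (0.2 background, 0.6 focal), negative-binomial
dispersion (0.05), intra-plate correlation (0.1) — are calibration
defaults, not estimates of any real data set. Each generator stage draws
from its own seed stream (`seed + stage offset`), so enabling one stage
never perturbs another's draws.

The generator does **not** emulate: read-level sequencing artifacts,
linkage structure between variant sites, batch effects, image-derived
count error in smFISH, or library-composition biases beyond global size
factors.

# Problem sizes

The sizes used in the shipped tests and calibration runs (18k-gene
tables, B = 500–1,000 resampling sets, a few hundred simulation
replicates) are the package's own choices, picked to make the test
suite informative at interactive timescales; every routine accepts
larger B and more replicates unchanged.

# Limitations

* The DE stand-in is an ANOVA F-test on transformed counts, not a count
  model; at very low expression its p-values are only approximately
  uniform under the null.
* The lifespan model treats proportions as Gaussian; inference on
  near-boundary proportions is approximate.
* The excess-mass bootstrap is conservative (see above); treat its
  p-values as upper bounds near the rejection threshold.
* Allele-fate rules depend on annotation impact classes as given; the
  package does not re-annotate variants.
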