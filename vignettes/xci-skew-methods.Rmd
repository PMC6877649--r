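---
title: "Quantifying X-inactivation skew and its heritability: models and methods"
author: "xciskew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying X-inactivation skew and its heritability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciskew)
```

## The measurement model

Early in female development each cell silences one of its two X
chromosomes, and the choice is inherited by all somatic descendants. A
tissue is therefore a mosaic: a fraction $p$ of cells keep haplotype 1
inactive and $1-p$ keep haplotype 2 inactive. *XIST*, the long noncoding
RNA that initiates silencing, is expressed exclusively from the inactive X,
so in bulk RNA-seq the fraction of *XIST* reads carrying the haplotype-1
allele at a heterozygous SNP estimates $p$ directly.

The package's core statistic averages phase-aligned allele fractions over a
sample's informative *XIST* SNPs,

$$\mathrm{XIST_{ASE}} = \frac{1}{n}\sum_{i=1}^{n} f_i,$$

where $f_i$ is the haplotype-1 read fraction at SNP $i$ and $n$ the number
of heterozygous *XIST* SNPs passing filters. The degree of skewing is its
absolute deviation from the balanced mosaic,

$$\mathrm{DS} = \left|\,0.5 - \mathrm{XIST_{ASE}}\,\right| \in [0, 0.5],$$

and a sample is classified *skewed* when $\mathrm{DS} \ge 0.3$
(equivalently $\mathrm{XIST_{ASE}} \le 0.2$ or $\ge 0.8$, an 80:20 or more
extreme mosaic), *random* otherwise.

Two details matter here. First, per-site fractions are re-oriented by phase
*before* averaging: raw reference-allele fractions at SNPs with opposite
phase would cancel, destroying the signal, so `site_ase()` maps each
reference fraction to the haplotype-1 fraction using the phased genotype.
Second, the mean is unweighted by default — sites with very different
depths count equally — with a depth-weighted variant available behind the
`weighted` flag of `quantify_skew()`.

### Site filters

`filter_sites()` retains heterozygous SNVs with

* total depth $\ge$ 10 reads (`min_depth`, configurable), and
* both alleles observed at least once, guarding against genotyping errors
  that would masquerade as complete monoallelic expression.

Samples with at least one informative *XIST* SNP receive a call; the rest
are flagged non-informative. Base-quality filtering and mapping-bias
correction are upstream of this package's input format: the allelic count
tables are consumed in the GATK ASEReadCounter layout, and depths are
recomputed as `refCount + altCount` so reads carrying a third base never
count.

### The non-PAR alternative estimator

`nonpar_ase()` estimates skew from all non-pseudo-autosomal sites outside
*XIST*. For a gene fully subject to XCI the expected haplotype-1 fraction
is $1-p$ (the allele on the *active* X is the one expressed); a gene
escaping silencing at level $e \in [0,1]$ dilutes this to
$((1-p) + pe)/(1+e)$, which collapses to $0.5$ at $e = 1$ regardless of
$p$ — which is why pseudo-autosomal and escape genes are excluded (the
escape list is configurable). The estimator phase-aligns and averages, and
requires at least 5 informative sites by default. It is exposed for
benchmarking against the *XIST*-based statistic; on simulated fully
silenced data their per-sample deviations agree with rank correlation
above 0.9.

## Cohort statistics

* **Prevalence** (`prevalence_table()`): per-tissue percent of skewed
  samples, rounded half-up to integer percent (base R's `round()` rounds
  half to even, which would print 12.5% as 12%).
* **Tissue concordance and longitudinal stability**: Spearman rank
  correlations of $\mathrm{XIST_{ASE}}$ over the individuals shared by two
  tissues or two time points; ties get average ranks and all rank tests
  are invariant to monotone transforms.
* **Age association** (`age_regression()`, `age_group_tests()`): OLS of DS
  on age, plus a comparison of the younger (< 55 years) and older
  ($\ge$ 55) groups with a Welch two-sample $t$ test (pooled variance
  behind a flag; the choice is not determined by the analyses this package
  reproduces) and a chi-square test of skewed/random counts without
  continuity correction by default (the 2x2 counts involved are large).
  Co-twins are treated as independent observations in these regressions —
  naive OLS — and the output notes when related individuals are present.
* **Lowess inflection** (`lowess_inflection()`): DS is smoothed against
  age (`stats::lowess`, span 2/3 by default) and the onset of the
  age-related rise is located as the breakpoint of the best-fitting hinge
  (flat-then-linear) model of the smoothed curve. A first-crossing rule on
  smoothed slopes — report the first age whose slope exceeds a threshold —
  was rejected: smoothing leaks slope below the true onset, so any
  globally increasing smooth makes that rule return the minimum age. The
  hinge breakpoint is reported only when the post-breakpoint slope exceeds
  `slope_threshold` (default 1e-3 DS/year), so flat trends return `NA` and
  a rise from the start returns the minimum age.
* **Disease-discordant identical twins** (`discordant_pair_test()`):
  paired Wilcoxon signed-rank of DS in affected versus unaffected MZ
  co-twins. The exact two-sided null tail is computed in-package by
  convolution over the $2^n$ sign assignments of the observed
  absolute-difference ranks (ties handled by average ranks on a doubled
  integer lattice), because `wilcox.test` silently falls back to a normal
  approximation under ties; the normal approximation is used above 25
  non-zero pairs. Zero differences are dropped, and a majority of zeros
  flags the test degenerate.
* **Smoking** (`smoking_association()`): OLS of DS on a binary
  never/current indicator with age as covariate, fitted separately in the
  younger and older strata; samples with unknown status are excluded.

## The twin model

`fit_ace()` implements the classical ACE decomposition by maximum
likelihood. Pair trait vectors are bivariate normal with common mean
$\mu$, variance $a^2 + c^2 + e^2$ and covariance $a^2 + c^2$ (MZ) or
$\tfrac12 a^2 + c^2$ (DZ, additive correlation fixed at 0.5; no
assortative-mating adjustment). Rotating each pair to its sum and
difference contrasts diagonalises the covariance, so the likelihood is a
product of univariate normals and is exactly symmetric in within-pair
order.

Numerical choices:

* parameters are standard deviations bounded below at zero
  (`L-BFGS-B`), so boundary solutions such as $\hat h^2 = 0$ or
  $\hat c^2 = 0$ are ordinary outcomes; $e$ has a small positive floor
  (1e-4 of the trait SD) because the MZ likelihood is unbounded as
  $e \to 0$ on within-pair-identical data;
* multi-start: the Falconer closed form
  ($h^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2r_{DZ} - r_{MZ}$,
  $e^2 = 1 - r_{MZ}$, clipped and renormalized — also exposed as
  `falconer()` and used as an independent oracle in the tests), equal
  thirds, a near-pure-E start, and the optimum of the nested CE model.
  Seeding with the CE optimum guarantees the nesting inequality
  $\ell_{ACE} \ge \ell_{CE}$;
* the significance of A is the likelihood ratio of ACE against CE
  referred to the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the
  standard reference distribution for a variance component tested on its
  boundary.

`intraclass_spearman()` complements the model fit with a rank-based
within-pair resemblance: each pair enters in both orders and ranks are
taken on the doubled set, making the statistic exactly invariant to twin
labels; its p-value is a two-sided permutation test that reshuffles
individuals into pseudo-pairs (default 10,000 permutations, seeded).
`stratified_heritability()` assembles complete pairs per tissue (both
co-twins informative, shared pair age — co-twins share a birth date, so a
differing age indicates a data problem and the pair is skipped with a
warning) and reports ACE and IC per age stratum split at 55.

The heritability trait is DS itself, as in the analyses this package
reproduces, although DS is bounded and non-normal. This has a quantifiable
consequence discussed below.

## The synthetic cohort generator

`sim_config()`/`simulate_cohort()` generate the full input set — phased
multi-sample VCF, per-sample allelic count tables, metadata, and a ground
truth table — from one integer seed (all randomness flows from a single
generator; the pipeline derives per-stage substreams so stages can be
rerun in isolation).

The latent trait is $z = \mathrm{logit}(p)$, built as
$z = \sigma\,(\sqrt{a^2} A + \sqrt{c^2} C + \sqrt{e^2} E)$ with $A$ shared
within MZ pairs and correlated 0.5 within DZ pairs, $C$ shared within every
pair, and $E$ independent with configurable between-tissue correlation.
Working on the logit scale keeps $p \in (0,1)$ while giving the twin model
an exactly multivariate-normal trait for recovery tests. Defaults and
their reasoning:

* `variance_components = (0.34, 0, 0.66)` — the older-blood decomposition
  the cohort analyses revolve around;
* `latent_sd = 1.2` — with the default age drift this places roughly a
  third of blood-like samples past the 80:20 skew threshold, the
  prevalence regime of interest, while primary tissues without drift sit
  near a quarter;
* `age_drift = 0.015` latent units per year above `age_threshold = 55`,
  applied to $|z|$ in blood-like tissues only: over the 30 years above the
  threshold this adds roughly 0.45 latent units, about 0.05 DS for a
  mid-range sample, matching the size of age effects these analyses
  detect. The drift models acquired (secondary) skew, e.g. age-related
  clonal haematopoiesis, which is why it is restricted to blood-like
  tissues;
* ages are drawn uniformly on 38–85 per family (co-twins share their
  age);
* reads: per-site depth is negative binomial (`depth_mean = 50`,
  `depth_size = 5`, a realistic overdispersed RNA-seq depth profile) and
  allele counts are beta-binomial with intraclass correlation
  `overdispersion_rho = 0.02` (mild extra-binomial noise typical of
  allelic counts; `rho = 0` reduces exactly to binomial and is used
  wherever tests need a clean binomial oracle). Counts are independent
  across sites, consistent with short-read data in which no retained read
  spans two heterozygous positions;
* non-PAR genes escape XCI with probability 0.23 at Beta(1, 3) escape
  levels — roughly a quarter of X-linked genes escape, mostly partially;
  pseudo-autosomal sites behave as full escape;
* optional effect switches (`ra_pairs`/`ra_effect`,
  `smoking_prevalence`/`smoking_effect`, `variance_components_older`)
  default to *no* association, so the generator is a null machine for
  calibration unless an effect is explicitly requested.

What the generator does **not** emulate: mapping bias and its correction,
base-quality error, linkage between sites (each site's counts are
independent given $p$), phasing error, biopsy patch-size effects, cell-type
composition, and the clonal dynamics that produce acquired skew in real
blood (the drift is a deterministic stand-in). Passing tests therefore
demonstrate the correctness of the estimators and tests under a faithful
sampling model of allelic counts — not robustness to the upstream
artefacts of real RNA-seq.

## Scale attenuation: latent skew versus DS

Because $\mathrm{DS} = |p - 0.5|$ folds the latent trait at zero, twin
correlations on the DS scale are substantially smaller than on the latent
scale: folding discards the direction of skew, which is where much of the
familial resemblance lives. Measured on large simulated cohorts (drift
off), a latent additive share of 0.34 induces a DS-scale Falconer
$h^2$ of only about 0.15, and a latent share of about 0.6 is needed before
the DS-scale heritability reaches the mid-0.3 range. The folding also
pushes $r_{DZ}$ below $r_{MZ}/2$, mimicking non-additivity.

Consequently the age-gated heritability experiment (genetics active only
above 55) generates `variance_components_older = (0.6, 0, 0.4)` so that
the *observable* DS-scale heritability contrast matches the magnitude the
cohort analyses report, and parameter-recovery tests of `fit_ace()` itself
simulate pairs directly on the trait scale with `simulate_twin_pairs()`.
Analyses of real data should read DS-scale $h^2$ as a lower bound on the
latent genetic control of skew direction and magnitude.

## Numerical edge cases

* `classify_skew()` applies a 1e-9 tolerance at the DS $\ge$ 0.3 boundary:
  accumulated floating-point error (e.g. a grid value 0.200…04) must not
  flip a boundary sample's class.
* Prevalence percentages round half-up, not half-even.
* Degenerate designs are reported, not crashed on: zero within-group
  variance in the $t$ test, a single smoking level in a stratum, fewer
  than 3 pairs for correlations, all-zero Wilcoxon differences, and
  strata without complete twin pairs all yield flagged
  insufficient-data/degenerate results.
* Duplicate samples per (individual, tissue, time point) keep the first by
  sample id with a warning.

## Problem sizes used by the test-suite experiments

The simulation experiments are sized to make their Monte-Carlo error small
relative to the asserted tolerances: estimator calibration uses 200
samples at depth 1000; twin-covariance checks use 10,000 pairs per
zygosity; ACE recovery uses 100 replicates of 500 MZ + 500 DZ pairs; the
null-calibration study uses 1000 replicates per test (cohorts of a few
hundred; intraclass p-values use 199 permutations per replicate, which is
a valid permutation test with attainable level exactly 0.05); the
age-gated heritability experiment uses 100 replicates of 500 + 500 pairs;
and the inflection experiment uses a 3000-sample tissue with lowess span
0.4 — the default span 2/3 over-smooths a kink located two-thirds into the
age range and biases the hinge breakpoint early.

## Limitations

* The non-PAR estimator's aggregation (phase-aligned mean after escape
  exclusion) is one defensible construction; published
  variants of this estimator differ in site weighting and escape handling,
  so numerical agreement with any particular external implementation is
  not guaranteed.
* The ACE fit assumes bivariate normality of pair traits; DS violates this
  by construction (bounded, folded), which attenuates components as
  described above. An age-residualisation preprocessing step and
  latent-scale fitting are available for simulation studies.
* Age regressions ignore twin relatedness (naive OLS with a note); a
  mixed-model treatment is out of scope.
* The lowess span and the hinge slope threshold are smoothing choices; the
  inflection age is a descriptive localisation, not an inferential
  estimate with a confidence interval.
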