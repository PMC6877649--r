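# xciskew

Quantification of X-chromosome inactivation (XCI) skew from allele-specific
expression of *XIST*, with the downstream cohort and twin analyses.

## The problem

In female tissues one of the two X chromosomes is epigenetically silenced
in every cell, producing a mosaic in which a fraction *p* of cells
inactivate one parental X and 1 − *p* the other. Departures from the
balanced 50:50 mosaic — *skewed* XCI — shift the functional dosage of every
heterozygous X-linked locus in a tissue and are linked to ageing, clonal
haematopoiesis, and autoimmune disease. Because *XIST* is expressed
exclusively from the inactive X, the allelic ratio of *XIST* RNA-seq reads
at phased heterozygous SNPs measures *p* in bulk tissue.

`xciskew` is aimed at analysts with phased X-chromosome genotypes (VCF),
GATK ASEReadCounter-style allelic count tables and sample metadata — or at
methodologists who want a fully synthetic twin cohort with known ground
truth. It computes, per sample,

    XIST_ASE = (1/n) * sum_i f_i        phase-aligned mean over n XIST SNPs
    DS       = | 0.5 - XIST_ASE |       degree of skewing, in [0, 0.5]

with sites filtered to depth ≥ 10 and both alleles observed, and classifies
a sample *skewed* when DS ≥ 0.3 (XIST_ASE ≤ 0.2 or ≥ 0.8). On top of the
per-sample calls it provides:

* per-tissue prevalence of skewed XCI, tissue–tissue and longitudinal
  Spearman concordance;
* age analyses: OLS of DS on age, lowess smoothing with inflection
  localisation, younger/older comparisons (Welch *t*, chi-square) split at
  age 55;
* paired Wilcoxon tests of DS in disease-discordant identical twins (exact
  null distribution up to 25 pairs, computed in-package);
* smoking association (OLS with age covariate, stratified at 55);
* a from-scratch maximum-likelihood ACE twin model (`fit_ace()`, a classed
  model object with `print`/`summary`/`coef`/`logLik`/`simulate` methods),
  Falconer closed-form cross-checks, double-entry intraclass Spearman
  correlations with permutation p-values, and age-stratified heritability
  tables;
* a seeded synthetic twin-cohort generator (latent logit-scale skew with
  ACE covariance, tissue correlation, age drift in blood-like tissues,
  beta-binomial read sampling) that writes every pipeline input plus the
  ground truth.

## Worked example

Simulate a two-tissue twin cohort, run the quantification from the written
files, and fit the age-stratified twin model:

```r
library(xciskew)
cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 60, n_singletons = 30,
                  tissues = c(LCL = 1, fat = 0.5), seed = 42)
paths <- simulate_cohort(cfg, "demo_cohort")

counts    <- do.call(rbind, lapply(list.files(paths$counts_dir,
                       full.names = TRUE), read_allelic_counts))
genotypes <- read_phased_vcf(paths$vcf)
metadata  <- read_sample_metadata(paths$metadata)

calls <- quantify_skew(counts, genotypes, metadata)
calls
#> XCI skew calls: 539 sample(s); skewed 178 (33%)
#> non-informative samples: 1
#>          sample_id tissue n_snps xist_ase      ds classification
#> 1  F0001_T1_fat_t1    fat      3   0.3270 0.17303         random
#> 2  F0001_T1_LCL_t1    LCL      3   0.1065 0.39346         skewed
#> ...

cohort <- cohort_table(calls, metadata)
prevalence_table(cohort)
#>   tissue n_informative n_skewed prevalence_percent
#> 1    fat           270       78                 29
#> 2    LCL           269      100                 37

tissue_concordance(cohort, "LCL", "fat")
#>   statistic stratum  estimate      p_value   n note
#> 1  spearman LCL-fat 0.6899708 2.353977e-39 269
```

Each row of the skew table is one sample: `xist_ase` is the estimated
fraction of cells inactivating haplotype 1, `ds` its deviation from the
balanced mosaic, and `classification` the 80:20 rule. Here 37% of the
blood-like LCL samples are skewed versus 29% of fat, and the two tissues'
skew levels correlate at ρ = 0.69 across the 269 individuals with calls in
both — the latent tissue correlation configured in the generator plus
shared genetic and family variance.

```r
stratified_heritability(cohort, "LCL", n_perm = 1000, seed = 1)
#>   age_group n_mz n_dz         h2       c2        e2 p_value_A     ic_mz
#> 1   younger   17   19 0.01472963 0.000000 0.9852704 0.4725632 0.1336898
#> 2     older   43   40 0.00000000 0.194431 0.8055690 1.0000000 0.2179820
```

With only ~20–40 pairs per stratum the component estimates are noisy (the
generator's latent additive share is 0.34; folding to DS attenuates it —
see the methods vignette), but the output shows the full contract: ACE
shares summing to one, the boundary likelihood-ratio p-value for dropping
A, and the double-entry intraclass correlations per zygosity.

A single-command orchestration of simulate → quantify → statistics →
heritability, with a manifest and per-stage logs, is available as
`run_xci_pipeline()` (YAML-configurable; see `inst/cli/xci-pipeline.R` for
a thin command-line wrapper with `simulate`, `quantify`, `stats`,
`heritability` and `run-all` subcommands).

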