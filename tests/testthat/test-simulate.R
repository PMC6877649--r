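test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(variance_components = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(sim_config(overdispersion_rho = 1), "\\[0, 1\\)")
  expect_error(sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 0),
               "at least one individual")
  expect_error(sim_config(tissues = c(LCL = 0.9)), "reference")
  expect_error(sim_config(ra_pairs = 5, n_mz_pairs = 2), "ra_pairs")
})

test_that("latent twin covariance matches the ACE structure", {
  # pure A: MZ co-twins identical on the latent scale
  cfg_a <- sim_config(n_mz_pairs = 50, n_dz_pairs = 0, n_singletons = 0,
                      tissues = c(LCL = 1),
                      variance_components = c(1, 0, 0), age_drift = 0,
                      seed = 3)
  lat <- simulate_latent_skew(cfg_a)
  t1 <- lat[grepl("_T1$", lat$individual_id), ]
  t2 <- lat[grepl("_T2$", lat$individual_id), ]
  expect_equal(t1$z, t2$z)

  # pure E: MZ co-twins uncorrelated
  cfg_e <- sim_config(n_mz_pairs = 2000, n_dz_pairs = 0, n_singletons = 0,
                      tissues = c(LCL = 1),
                      variance_components = c(0, 0, 1), age_drift = 0,
                      seed = 4)
  lat <- simulate_latent_skew(cfg_e)
  t1 <- lat[grepl("_T1$", lat$individual_id), ]
  t2 <- lat[grepl("_T2$", lat$individual_id), ]
  expect_lt(abs(cor(t1$z, t2$z)), 3 / sqrt(2000))

  # (0.34, 0, 0.66): rMZ ~ 0.34, rDZ ~ 0.17 within 3 standard errors
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, n_singletons = 0,
                    tissues = c(LCL = 1),
                    variance_components = c(0.34, 0, 0.66), age_drift = 0,
                    seed = 5)
  lat <- simulate_latent_skew(cfg)
  lat$tw <- sub("^.*_(T[12])$", "\\1", lat$individual_id)
  for (zy in c("MZ", "DZ")) {
    sub <- lat[lat$zygosity == zy, ]
    r <- cor(sub$z[sub$tw == "T1"], sub$z[sub$tw == "T2"])
    expected <- if (zy == "MZ") 0.34 else 0.17
    expect_lt(abs(r - expected), 3 / sqrt(10000))
  }
})

test_that("binomial sampling is recovered exactly at rho = 0", {
  set.seed(8)
  draws <- xciskew:::rbetabinom(10000, size = 30, prob = 0.3, rho = 0)
  expected <- dbinom(0:30, 30, 0.3) * 10000
  obs <- tabulate(draws + 1L, nbins = 31L)
  keep <- expected > 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE), 0.001)
  # and overdispersion inflates the variance beyond binomial
  set.seed(8)
  od <- xciskew:::rbetabinom(10000, size = 30, prob = 0.3, rho = 0.15)
  expect_gt(var(od), 1.5 * 30 * 0.3 * 0.7)
})

test_that("allelic count sampling follows the XIST and escape models", {
  cfg <- sim_config(overdispersion_rho = 0, depth_mean = 100,
                    depth_size = 1e6)
  sites <- data.frame(contig = "X", position = 1:200,
                      ref_allele = "A", alt_allele = "G",
                      hap1_allele = "A", region = "xist",
                      escape = NA_real_, gene = "XIST",
                      stringsAsFactors = FALSE)
  # degenerate binomial: p = 1 puts every XIST read on haplotype 1
  set.seed(9)
  cc <- simulate_allelic_counts(1.0, sites, cfg)
  expect_true(all(cc$ref_count == cc$total_count))

  # fully silenced non-PAR gene at p = 0.5: balanced expression
  sites$region <- "nonpar"; sites$escape <- 0
  set.seed(9)
  cc <- simulate_allelic_counts(0.5, sites, cfg)
  expect_equal(mean(cc$ref_count / cc$total_count), 0.5, tolerance = 0.02)

  # full escape: balanced regardless of p (here p = 0.95)
  sites$escape <- 1
  set.seed(9)
  cc <- simulate_allelic_counts(0.95, sites, cfg)
  expect_equal(mean(cc$ref_count / cc$total_count), 0.5, tolerance = 0.02)

  sites$contig <- "7"
  expect_error(simulate_allelic_counts(0.5, sites, cfg), "chromosome")
})

test_that("the expected-fraction formula is exact at its corner cases", {
  expect_equal(xciskew:::expected_hap1_fraction(0.9, FALSE, 0), 0.1)
  expect_equal(xciskew:::expected_hap1_fraction(0.9, FALSE, 1), 0.5)
  expect_equal(xciskew:::expected_hap1_fraction(0.9, TRUE, 0), 0.9)
  expect_equal(xciskew:::expected_hap1_fraction(0.5, FALSE, 0.3), 0.5)
})

test_that("cohort files are byte-identical across runs with the same seed", {
  cfg <- sim_config(n_mz_pairs = 3, n_dz_pairs = 3, n_singletons = 1,
                    tissues = c(LCL = 1, fat = 0.5), n_nonpar_snps = 5,
                    n_par_snps = 2, seed = 17)
  d1 <- file.path(tempdir(), "cohort_run1")
  d2 <- file.path(tempdir(), "cohort_run2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  files <- c("cohort.vcf", "metadata.tsv", "truth.tsv", "panel.tsv")
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  counts1 <- list.files(file.path(d1, "counts"))
  expect_identical(counts1, list.files(file.path(d2, "counts")))
  for (f in counts1)
    expect_identical(readLines(file.path(d1, "counts", f)),
                     readLines(file.path(d2, "counts", f)))
})

test_that("written cohort files round-trip through the package readers", {
  cfg <- sim_config(n_mz_pairs = 4, n_dz_pairs = 4, n_singletons = 2,
                    tissues = c(LCL = 1), n_nonpar_snps = 4, n_par_snps = 1,
                    depth_mean = 60, seed = 23)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  paths <- simulate_cohort(cfg, dir)
  gt <- suppressMessages(read_phased_vcf(paths$vcf))
  # the VCF reader reproduces exactly the simulated heterozygous genotypes
  truth_gt <- paths$data$genotypes
  key <- function(df) sort(paste(df$individual_id, df$position,
                                 df$hap1_allele))
  expect_identical(key(gt), key(truth_gt))

  f1 <- list.files(paths$counts_dir, full.names = TRUE)[1]
  counts <- read_allelic_counts(f1)
  sid <- sub("\\.tsv$", "", basename(f1))
  orig <- paths$data$counts[paths$data$counts$sample_id == sid, ]
  expect_equal(counts$ref_count, orig$ref_count)
  expect_equal(counts$in_xist, orig$in_xist)
  md <- read_sample_metadata(paths$metadata)
  expect_identical(sort(md$sample_id), sort(paths$data$metadata$sample_id))
})

test_that("true skew tail probability matches the logistic-normal quadrature", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 20000,
                    tissues = c(LCL = 1),
                    variance_components = c(0, 0, 1), latent_sd = 1,
                    age_drift = 0, seed = 31)
  lat <- simulate_latent_skew(cfg)
  frac <- mean(abs(0.5 - lat$p) >= 0.3)
  # oracle: P(|0.5 - logistic(Z)| >= 0.3) for Z ~ N(0, 1) by 1-D quadrature
  oracle <- integrate(function(z) dnorm(z) *
                        (abs(0.5 - plogis(z)) >= 0.3),
                      -Inf, Inf, subdivisions = 2000L)$value
  expect_equal(oracle, 2 * pnorm(qlogis(0.8), lower.tail = FALSE),
               tolerance = 1e-4)
  se <- sqrt(oracle * (1 - oracle) / 20000)
  expect_lt(abs(frac - oracle), 3 * se)
})

test_that("XIST_ASE converges to the true skew as depth grows", {
  run_mae <- function(depth, seed) {
    cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 250,
                      tissues = c(LCL = 1), n_xist_snps = 3,
                      n_nonpar_snps = 0, n_par_snps = 0,
                      depth_mean = depth, depth_size = 1e6,
                      overdispersion_rho = 0, age_drift = 0, seed = seed)
    d <- simulate_cohort_data(cfg)
    calls <- quantify_skew(d$counts, d$genotypes, d$metadata)
    truth <- d$truth$p[match(
      d$metadata$individual_id[match(calls$sample_id,
                                     d$metadata$sample_id)],
      d$truth$individual_id)]
    mean(abs(calls$xist_ase - truth))
  }
  mae_low <- run_mae(20, 41)
  mae_high <- run_mae(1000, 41)
  expect_lt(mae_high, mae_low)
  expect_lt(mae_high, 0.02)
})

test_that("zero XIST SNPs leaves samples out of the informative set", {
  cfg <- sim_config(n_mz_pairs = 2, n_dz_pairs = 0, n_singletons = 0,
                    tissues = c(LCL = 1), n_xist_snps = 0,
                    n_nonpar_snps = 5, n_par_snps = 0, seed = 13)
  d <- simulate_cohort_data(cfg)
  calls <- quantify_skew(d$counts, d$genotypes, d$metadata)
  expect_equal(nrow(calls), 0L)
  expect_setequal(attr(calls, "non_informative"), d$metadata$sample_id)
})

test_that("age drift pushes blood-like skew upward only above the threshold", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 4000,
                    tissues = c(LCL = 1, fat = 0.5), blood_like = "LCL",
                    variance_components = c(0, 0, 1),
                    age_drift = 0.03, age_threshold = 55, seed = 19)
  lat <- simulate_latent_skew(cfg)
  ds_true <- abs(0.5 - lat$p)
  older <- lat$age >= 70
  younger <- lat$age < 55
  lcl <- lat$tissue == "LCL"
  expect_gt(mean(ds_true[lcl & older]), mean(ds_true[lcl & younger]) + 0.02)
  # non-blood tissue is untouched by the drift
  expect_lt(abs(mean(ds_true[!lcl & older]) - mean(ds_true[!lcl & younger])),
            0.015)
})
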