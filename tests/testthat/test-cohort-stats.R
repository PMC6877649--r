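test_that("prevalence percentages use half-up rounding", {
  # 1/8 = 12.5% must round up to 13, not to even
  calls <- make_cohort(ds = c(rep(0.4, 1), rep(0.1, 7)), age = 60,
                       tissue = "T")
  expect_equal(prevalence_table(calls)$prevalence_percent, 13)
  none <- make_cohort(ds = rep(0.1, 5), age = 60, tissue = "T")
  expect_equal(prevalence_table(none)$prevalence_percent, 0)
})

test_that("per-tissue skewed counts add up to the cohort total", {
  set.seed(21)
  calls <- rbind(make_cohort(r_null_ds(80), sample(38:85, 80, TRUE), "LCL"),
                 make_cohort(r_null_ds(60), sample(38:85, 60, TRUE), "fat"),
                 make_cohort(r_null_ds(40), sample(38:85, 40, TRUE), "skin"))
  tab <- prevalence_table(calls)
  expect_equal(sum(tab$n_skewed), sum(calls$classification == "skewed"))
  expect_equal(sum(tab$n_informative), nrow(calls))
})

test_that("tissue concordance is a rank correlation on shared individuals", {
  set.seed(2)
  ase <- runif(30, 0.1, 0.9)
  a <- make_cohort(abs(0.5 - ase), age = 60, tissue = "A")
  a$xist_ase <- ase
  b <- a
  b$tissue <- "B"
  b$sample_id <- sub("_A_", "_B_", b$sample_id)
  res <- tissue_concordance(rbind(a, b), "A", "B")
  expect_equal(res$estimate, 1)
  expect_equal(res$n, 30)

  b$xist_ase <- 1 - b$xist_ase
  res <- tissue_concordance(rbind(a, b), "A", "B")
  expect_equal(res$estimate, -1)

  # monotone transforms leave the rank correlation unchanged
  b$xist_ase <- plogis(5 * qlogis(1 - b$xist_ase))
  res2 <- tissue_concordance(rbind(a, b), "A", "B")
  expect_equal(res2$estimate, 1)

  small <- rbind(a[1:2, ], b[1:2, ])
  expect_match(tissue_concordance(small, "A", "B")$note, "insufficient")
})

test_that("tissue concordance tracks the generator's latent correlation", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 200,
                    tissues = c(LCL = 1, blood = 0.8),
                    blood_like = character(),
                    variance_components = c(0, 0, 1),
                    n_xist_snps = 3, n_nonpar_snps = 0, n_par_snps = 0,
                    depth_mean = 500, depth_size = 1e6,
                    overdispersion_rho = 0, age_drift = 0, seed = 77)
  d <- simulate_cohort_data(cfg)
  calls <- quantify_skew(d$counts, d$genotypes, d$metadata)
  cohort <- cohort_table(calls, d$metadata)
  res <- tissue_concordance(cohort, "LCL", "blood")
  expect_gt(res$n, 150)
  expect_lt(abs(res$estimate - 0.8), 0.1)
})

test_that("age regression recovers a linear DS trend", {
  set.seed(3)
  age <- sample(38:85, 400, replace = TRUE)
  ds <- pmin(pmax(0.001 * age + rnorm(400, 0, 0.05), 0), 0.5)
  calls <- make_cohort(ds, age)
  res <- age_regression(calls)
  se <- 0.05 / (sd(age) * sqrt(400))
  expect_lt(abs(res$estimate - 0.001), 3 * se)
  expect_lt(res$p_value, 0.01)

  flat <- make_cohort(rep(0.2, 10), rep(60, 10))
  expect_error(age_regression(flat), "degenerate")
  expect_match(age_regression(calls[1:2, ])$note, "insufficient")
})

test_that("lowess inflection detection handles flat, monotone and kinked trends", {
  set.seed(4)
  age <- rep(38:85, length.out = 200)
  flat <- make_cohort(rep(0.2, 200), age)
  expect_true(is.na(lowess_inflection(flat)$inflection_age))

  mono <- make_cohort(pmin(0.002 * (age - 30), 0.5), age)
  res <- lowess_inflection(mono)
  expect_equal(res$inflection_age, min(age))

  expect_error(lowess_inflection(mono, span = 0), "span")
  expect_error(lowess_inflection(mono[1:10, ]), ">= 20")
})

test_that("lowess inflection localises the generator's drift threshold", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 1500,
                    tissues = c(LCL = 1), variance_components = c(0, 0, 1),
                    n_xist_snps = 3, n_nonpar_snps = 0, n_par_snps = 0,
                    depth_mean = 500, depth_size = 1e6,
                    overdispersion_rho = 0,
                    age_drift = 0.03, age_threshold = 55, seed = 101)
  d <- simulate_cohort_data(cfg)
  calls <- quantify_skew(d$counts, d$genotypes, d$metadata)
  cohort <- cohort_table(calls, d$metadata)
  res <- lowess_inflection(cohort, span = 0.4)
  expect_false(is.na(res$inflection_age))
  expect_gte(res$inflection_age, 50)
  expect_lte(res$inflection_age, 60)
})

test_that("age-group split places the threshold age in the older group", {
  calls <- make_cohort(c(0.1, 0.2, 0.35, 0.4), c(54, 54, 55, 56))
  res <- age_group_tests(calls, threshold = 55)
  # both members aged >= 55 are skewed, both younger are random
  expect_equal(res$mean_ds_older, mean(c(0.35, 0.4)))
  expect_equal(res$mean_ds_younger, mean(c(0.1, 0.2)))
  expect_lt(res$chisq$p_value, 0.05)
})

test_that("clear group separation drives the chi-square p toward zero", {
  calls <- make_cohort(c(rep(0.05, 50), rep(0.45, 50)),
                       c(rep(40, 50), rep(70, 50)))
  res <- age_group_tests(calls)
  expect_lt(res$chisq$p_value, 1e-10)
  expect_lt(res$t_test$p_value, 1e-10)
  bins <- res$decade_bins
  expect_equal(bins$skew_frequency[bins$age_bin == "40-50"], 0)
  expect_equal(bins$skew_frequency[bins$age_bin == ">70"], 1)
})

test_that("discordant-pair Wilcoxon matches exact sign-assignment enumeration", {
  # 8 MZ pairs, affected DS exactly 0.14 above the unaffected co-twin:
  # all differences positive, so the two-sided exact p is the extreme tail
  ds_un <- seq(0.05, 0.26, length.out = 8)
  ds_af <- ds_un + 0.14
  cohort <- rbind(
    make_cohort(ds_af, 60, individual_id = sprintf("I%02dA", 1:8),
                family_id = sprintf("F%02d", 1:8), zygosity = "MZ",
                disease = "RA"),
    make_cohort(ds_un, 60, individual_id = sprintf("I%02dB", 1:8),
                family_id = sprintf("F%02d", 1:8), zygosity = "MZ",
                disease = "none"))
  res <- discordant_pair_test(cohort)
  # independent oracle: enumerate all 2^8 sign assignments of the ranks
  n <- 8
  w_obs <- sum(rank(abs(ds_af - ds_un)))
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rank(abs(ds_af - ds_un))
  p_exact <- mean(w_all >= w_obs | w_all <= sum(rank(abs(ds_af - ds_un))) -
                    w_obs) # symmetric two-sided tail
  expect_equal(p_exact, 2 / 2^8)
  expect_equal(res$p_value, p_exact)
  expect_equal(attr(res, "n_affected_more_skewed"), 8L)
  expect_equal(res$estimate, 0.14)
})

test_that("degenerate and insufficient discordant designs are flagged", {
  same <- rbind(
    make_cohort(rep(0.2, 4), 60, individual_id = paste0("A", 1:4),
                family_id = paste0("F", 1:4), zygosity = "MZ",
                disease = "RA"),
    make_cohort(rep(0.2, 4), 60, individual_id = paste0("B", 1:4),
                family_id = paste0("F", 1:4), zygosity = "MZ",
                disease = "none"))
  res <- discordant_pair_test(same)
  expect_match(res$note, "degenerate")
  expect_equal(res$p_value, 1)

  empty <- make_cohort(r_null_ds(10), 60)
  expect_match(discordant_pair_test(empty)$note, "insufficient")
})

test_that("smoking association recovers a simulated additive effect", {
  set.seed(6)
  n <- 300
  age <- sample(56:85, n, replace = TRUE)
  smoking <- sample(c("never", "current"), n, replace = TRUE)
  ds <- pmin(pmax(0.15 + 0.05 * (smoking == "current") +
                    0.001 * age + rnorm(n, 0, 0.08), 0), 0.5)
  cohort <- make_cohort(ds, age, smoking = smoking)
  res <- smoking_association(cohort)
  older <- res[res$stratum == "older", ]
  expect_lt(abs(older$estimate - 0.05), 3 * 0.08 / sqrt(n / 4))
  freqs <- attr(res, "skew_frequencies")
  expect_true(all(c("never", "current") %in% freqs$smoking))

  # a stratum with a single smoking level is insufficient
  only <- make_cohort(r_null_ds(20), rep(40, 20), smoking = "current")
  res2 <- smoking_association(only)
  expect_match(res2$note[res2$stratum == "younger"], "insufficient")
  # unknown smoking status is excluded entirely
  unk <- make_cohort(r_null_ds(20), rep(40, 20), smoking = "unknown")
  expect_null(smoking_association(unk))
})

test_that("longitudinal concordance reflects latent-skew stability", {
  # identical calls at both time points: perfect concordance
  set.seed(10)
  base <- make_cohort(r_null_ds(20), 60)
  t2 <- base
  t2$time_point <- 2L
  res <- longitudinal_concordance(rbind(base, t2))
  expect_equal(res$estimate, 1)

  # independently re-simulated counts from the same latent p stay concordant
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 100,
                    tissues = c(blood = 1), n_xist_snps = 3,
                    n_nonpar_snps = 0, n_par_snps = 0, depth_mean = 500,
                    depth_size = 1e6, overdispersion_rho = 0,
                    n_time_points = 2, age_drift = 0, seed = 55)
  d <- simulate_cohort_data(cfg)
  calls <- quantify_skew(d$counts, d$genotypes, d$metadata)
  cohort <- cohort_table(calls, d$metadata)
  res <- longitudinal_concordance(cohort)
  expect_gt(res$estimate, 0.9)

  # unrelated values at time 2: correlation near zero
  t2r <- t2
  t2r$xist_ase <- runif(20, 0.1, 0.9)
  res0 <- longitudinal_concordance(rbind(base, t2r))
  expect_lt(abs(res0$estimate), 0.5)
  expect_match(longitudinal_concordance(base)$note, "insufficient")
})

test_that("cohort_table joins metadata and deduplicates repeat samples", {
  calls <- data.frame(sample_id = c("S1", "S2", "S3"), tissue = NA,
                      n_snps = 3L, xist_ase = c(0.5, 0.8, 0.9),
                      ds = c(0, 0.3, 0.4),
                      classification = c("random", "skewed", "skewed"),
                      stringsAsFactors = FALSE)
  class(calls) <- c("skew_calls", "data.frame")
  md <- data.frame(sample_id = c("S1", "S2", "S3"),
                   individual_id = c("I1", "I2", "I2"),
                   family_id = "F1", zygosity = "MZ", age = 60,
                   tissue = "LCL", smoking = "never", disease = "none",
                   time_point = 1L, stringsAsFactors = FALSE)
  expect_warning(tab <- cohort_table(calls, md), "duplicate")
  expect_equal(nrow(tab), 2L)
  # first by sample id kept for the duplicated individual
  expect_equal(tab$xist_ase[tab$individual_id == "I2"], 0.8)
  expect_error(cohort_table(calls[1, ], md[2:3, ]), "missing from metadata")
})
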