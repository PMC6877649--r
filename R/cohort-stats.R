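# Uniform container for test outputs: one row per statistic.
assoc_result <- function(statistic, estimate, p_value, n, stratum = NA_character_,
                         note = "") {
  data.frame(statistic = statistic, stratum = stratum,
             estimate = estimate, p_value = p_value, n = n, note = note,
             stringsAsFactors = FALSE)
}

#' Join skew calls to sample metadata
#'
#' Produces the cohort table the downstream analyses consume: one row per
#' sample with the skew call plus individual, family, zygosity, age,
#' tissue, smoking, disease and time point. When an individual contributes
#' multiple samples for the same tissue and time point, the first by sample
#' id is kept and a warning is issued.
#'
#' @param calls a `skew_calls` data frame.
#' @param metadata a metadata table (see [read_sample_metadata()]).
#' @return A data frame of class `cohort_table`.
#' @export
cohort_table <- function(calls, metadata) {
  m <- match(calls$sample_id, metadata$sample_id)
  if (anyNA(m))
    stop("samples missing from metadata: ",
         paste(calls$sample_id[is.na(m)], collapse = ", "))
  md <- metadata[m, setdiff(names(metadata), c("sample_id", "tissue")),
                 drop = FALSE]
  out <- cbind(as.data.frame(calls), md)
  out$tissue <- metadata$tissue[m]
  out <- out[order(out$sample_id), , drop = FALSE]
  key <- paste(out$individual_id, out$tissue, out$time_point)
  dup <- duplicated(key)
  if (any(dup)) {
    warning("dropping ", sum(dup),
            " duplicate sample(s) per (individual, tissue, time point); ",
            "first by sample_id kept")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-tissue prevalence of skewed XCI
#'
#' Counts informative and skewed samples per tissue and reports the
#' prevalence as a half-up-rounded integer percent.
#'
#' @param calls a cohort table or any data frame with `tissue` and
#'   `classification` columns (one call per individual and tissue).
#' @return Data frame with columns `tissue`, `n_informative`, `n_skewed`,
#'   `prevalence_percent`.
#' @export
prevalence_table <- function(calls) {
  tissues <- sort(unique(calls$tissue))
  rows <- lapply(tissues, function(tt) {
    sub <- calls[calls$tissue == tt, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub$classification == "skewed")
    data.frame(tissue = tt, n_informative = n, n_skewed = k,
               prevalence_percent = round_half_up(100 * k / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round() in R rounds half to even; prevalence percentages are printed with
# half-up rounding.
round_half_up <- function(x) floor(x + 0.5)

#' Between-tissue concordance of XCI skew
#'
#' Spearman rank correlation of the XIST allelic fraction between two
#' tissues, over the individuals with calls in both (first time point).
#'
#' @param cohort a cohort table.
#' @param tissue_a,tissue_b tissue labels.
#' @return An association row with `estimate` (rho), `p_value` (two-sided)
#'   and `n` (shared individuals); an insufficient-data row below 3 shared
#'   individuals.
#' @export
tissue_concordance <- function(cohort, tissue_a, tissue_b) {
  pick <- function(tt) {
    sub <- cohort[cohort$tissue == tt, , drop = FALSE]
    if ("time_point" %in% names(sub) && nrow(sub) > 0L)
      sub <- sub[sub$time_point == min(sub$time_point), , drop = FALSE]
    sub[!duplicated(sub$individual_id), c("individual_id", "xist_ase")]
  }
  a <- pick(tissue_a)
  b <- pick(tissue_b)
  shared <- intersect(a$individual_id, b$individual_id)
  stratum <- paste(tissue_a, tissue_b, sep = "-")
  if (length(shared) < 3L)
    return(assoc_result("spearman", NA_real_, NA_real_, length(shared),
                        stratum, "insufficient data (<3 shared individuals)"))
  x <- a$xist_ase[match(shared, a$individual_id)]
  y <- b$xist_ase[match(shared, b$individual_id)]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  assoc_result("spearman", unname(ct$estimate), ct$p.value, length(shared),
               stratum)
}

#' Linear association between degree of skewing and age
#'
#' Ordinary least squares of DS on age for one tissue's calls. Co-twins are
#' treated as independent observations (naive OLS); family structure, when
#' present, is noted in the output so readers can judge the
#' non-independence.
#'
#' @param calls single-tissue cohort table rows with `ds` and `age`.
#' @return An association row with the slope estimate and two-sided
#'   p-value.
#' @export
age_regression <- function(calls) {
  if (nrow(calls) < 3L)
    return(assoc_result("ols_slope_age", NA_real_, NA_real_, nrow(calls),
                        note = "insufficient data (<3 samples)"))
  if (stats::var(calls$age) == 0)
    stop("age is constant; regression design is degenerate")
  fit <- stats::lm(ds ~ age, data = calls)
  sm <- summary(fit)$coefficients
  note <- ""
  if ("family_id" %in% names(calls) &&
      anyDuplicated(calls$family_id) > 0L)
    note <- "contains related individuals (co-twins); naive OLS"
  assoc_result("ols_slope_age", sm["age", "Estimate"],
               sm["age", "Pr(>|t|)"], nrow(calls), note = note)
}

#' Lowess smooth of DS against age, with inflection detection
#'
#' Smooths the degree of skewing against age with `stats::lowess`, then
#' locates the inflection as the breakpoint of the best-fitting hinge
#' (flat-then-linear) model of the smoothed curve: for each candidate age
#' `a` the curve is regressed on `max(0, age - a)` and the `a` minimising
#' the residual sum of squares is chosen. An inflection is only reported
#' when the fitted post-breakpoint slope exceeds `slope_threshold`, so flat
#' or non-increasing trends return `NA`; a trend rising from the start
#' returns the minimum age.
#'
#' @param calls single-tissue cohort table rows with `ds` and `age`
#'   (at least 20 samples).
#' @param span lowess smoother span in (0, 1\]; default 2/3.
#' @param slope_threshold minimum post-breakpoint smoothed slope, in DS
#'   units per year; default 1e-3.
#' @return A list with `curve` (data frame `age`, `ds_smooth`),
#'   `inflection_age` (numeric or `NA`) and `post_slope` (fitted slope
#'   after the breakpoint).
#' @export
lowess_inflection <- function(calls, span = 2/3, slope_threshold = 1e-3) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (nrow(calls) < 20L) stop("lowess_inflection requires >= 20 samples")
  lo <- stats::lowess(calls$age, calls$ds, f = span)
  # collapse duplicate ages so the curve is a function of age
  agg <- tapply(lo$y, lo$x, mean)
  ages <- as.numeric(names(agg))
  vals <- as.numeric(agg)
  best <- list(rss = Inf, age = NA_real_, slope = NA_real_)
  for (a in ages[-length(ages)]) {
    hinge <- pmax(0, ages - a)
    fit <- stats::lm.fit(cbind(1, hinge), vals)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss - 1e-15)
      best <- list(rss = rss, age = a, slope = fit$coefficients[2])
  }
  inflection <- if (is.finite(best$slope) && !is.na(best$slope) &&
                    best$slope > slope_threshold) best$age else NA_real_
  list(curve = data.frame(age = ages, ds_smooth = vals),
       inflection_age = inflection,
       post_slope = unname(best$slope))
}

#' Age-stratified tests of DS and skew frequency
#'
#' Splits one tissue's samples at `threshold` (a sample aged exactly at the
#' threshold lands in the older group), then compares mean DS between
#' groups with a two-sample t-test (Welch by default) and the
#' skewed/random counts with a chi-square test (no continuity correction by
#' default). Also returns skewed-XCI frequencies in decade bins for
#' plotting.
#'
#' @param calls single-tissue cohort table rows.
#' @param threshold age cut in years; default 55.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @param correct apply the chi-square continuity correction.
#' @return A list with `t_test` and `chisq` association rows, group means
#'   (`mean_ds_younger`, `mean_ds_older`), and `decade_bins` (data frame of
#'   per-bin skew frequencies).
#' @export
age_group_tests <- function(calls, threshold = 55, pooled = FALSE,
                            correct = FALSE) {
  older <- calls$age >= threshold
  n_y <- sum(!older); n_o <- sum(older)
  if (n_y == 0L || n_o == 0L)
    stop("both age groups must be non-empty at threshold ", threshold)
  ds_y <- calls$ds[!older]; ds_o <- calls$ds[older]
  if (n_y < 2L || n_o < 2L) {
    tt_row <- assoc_result("t_test_ds", NA_real_, NA_real_, n_y + n_o,
                           note = "insufficient data (<2 per group)")
  } else {
    tt <- tryCatch(stats::t.test(ds_o, ds_y, var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # zero within-group variance: t statistic is unbounded
      diff <- mean(ds_o) - mean(ds_y)
      tt_row <- assoc_result("t_test_ds", diff, as.numeric(diff == 0),
                             n_y + n_o, note = "degenerate: zero variance")
    } else {
      tt_row <- assoc_result("t_test_ds",
                             unname(tt$estimate[1] - tt$estimate[2]),
                             tt$p.value, n_y + n_o)
    }
  }
  counts <- rbind(younger = table(factor(calls$classification[!older],
                                         levels = c("random", "skewed"))),
                  older = table(factor(calls$classification[older],
                                       levels = c("random", "skewed"))))
  cs <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  cs_row <- assoc_result("chisq_skew_freq", unname(cs$statistic), cs$p.value,
                         n_y + n_o)
  bins <- cut(calls$age, breaks = c(-Inf, 40, 50, 60, 70, Inf),
              labels = c("<40", "40-50", "50-60", "60-70", ">70"),
              right = FALSE)
  bt <- table(bins, factor(calls$classification, levels = c("random", "skewed")))
  decade <- data.frame(age_bin = rownames(bt),
                       n = as.integer(rowSums(bt)),
                       n_skewed = as.integer(bt[, "skewed"]),
                       skew_frequency = ifelse(rowSums(bt) > 0,
                                               bt[, "skewed"] / rowSums(bt),
                                               NA_real_),
                       stringsAsFactors = FALSE)
  rownames(decade) <- NULL
  list(t_test = tt_row, chisq = cs_row,
       mean_ds_younger = mean(ds_y), mean_ds_older = mean(ds_o),
       decade_bins = decade[decade$n > 0, , drop = FALSE])
}

#' Paired test of DS in disease-discordant identical twins
#'
#' Finds MZ pairs discordant for `disease` with calls in the supplied
#' (single-tissue) cohort table and runs a paired Wilcoxon signed-rank test
#' of the affected against the unaffected co-twin's DS. The exact null
#' distribution is used up to 25 non-zero differences, the normal
#' approximation above. Zero differences are dropped (standard signed-rank
#' handling); if more than half the pairs are zeros the result is flagged
#' degenerate and reported non-significant.
#'
#' @param cohort single-tissue cohort table rows.
#' @param disease disease label; default `"RA"`.
#' @return An association row (estimate = mean affected DS minus mean
#'   unaffected DS) with attributes `mean_ds_affected`,
#'   `mean_ds_unaffected` and `n_affected_more_skewed`, plus a `note` for
#'   degenerate or insufficient data.
#' @export
discordant_pair_test <- function(cohort, disease = "RA") {
  mz <- cohort[cohort$zygosity == "MZ", , drop = FALSE]
  if ("time_point" %in% names(mz) && nrow(mz) > 0L)
    mz <- mz[mz$time_point == min(mz$time_point), , drop = FALSE]
  fams <- split(mz, mz$family_id)
  pairs <- lapply(fams, function(f) {
    f <- f[!duplicated(f$individual_id), , drop = FALSE]
    if (nrow(f) != 2L) return(NULL)
    aff <- f$disease == disease
    una <- f$disease == "none"
    if (sum(aff) != 1L || sum(una) != 1L) return(NULL)
    data.frame(ds_affected = f$ds[aff], ds_unaffected = f$ds[una])
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) < 2L) {
    n <- if (is.null(pairs)) 0L else nrow(pairs)
    return(assoc_result("paired_wilcoxon_ds", NA_real_, NA_real_, n,
                        note = "insufficient data (<2 discordant pairs)"))
  }
  diffs <- pairs$ds_affected - pairs$ds_unaffected
  nonzero <- diffs != 0
  est <- mean(pairs$ds_affected) - mean(pairs$ds_unaffected)
  if (sum(!nonzero) > nrow(pairs) / 2 || !any(nonzero)) {
    out <- assoc_result("paired_wilcoxon_ds", est, 1, nrow(pairs),
                        note = "degenerate: majority of zero differences")
  } else if (sum(nonzero) <= 25L) {
    p <- exact_signed_rank_p(diffs[nonzero])
    out <- assoc_result("paired_wilcoxon_ds", est, p, nrow(pairs))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      pairs$ds_affected, pairs$ds_unaffected, paired = TRUE, exact = FALSE))
    out <- assoc_result("paired_wilcoxon_ds", est, wt$p.value, nrow(pairs))
  }
  attr(out, "mean_ds_affected") <- mean(pairs$ds_affected)
  attr(out, "mean_ds_unaffected") <- mean(pairs$ds_unaffected)
  attr(out, "n_affected_more_skewed") <- sum(diffs > 0)
  out
}

# Exact two-sided p of the Wilcoxon signed-rank statistic by convolution
# over the 2^n equiprobable sign assignments of the observed (possibly
# tied) absolute-difference ranks. Doubling makes tied average ranks
# integer so the distribution lives on a small lattice.
exact_signed_rank_p <- function(diffs) {
  r2 <- as.integer(round(2 * rank(abs(diffs))))
  w_obs2 <- sum(r2[diffs > 0])
  total <- sum(r2)
  # generating-function coefficients of P(2W = k)
  dist <- c(1, rep(0, total))
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  upper <- sum(dist[(w_obs2 + 1):(total + 1)])
  lower <- sum(dist[1:(w_obs2 + 1)])
  min(1, 2 * min(upper, lower))
}

#' Age-stratified association between DS and smoking
#'
#' Restricts to samples with known smoking status (never/current), splits
#' at the age threshold, and within each stratum fits OLS of DS on a
#' binary smoking indicator (never = 0, current = 1) with age as a
#' covariate. Also reports skewed-XCI frequencies by smoking group per
#' stratum. Strata with only one smoking level yield an insufficient-data
#' row.
#'
#' @param cohort single-tissue cohort table rows with `smoking` and `age`.
#' @param threshold age cut; default 55.
#' @return A data frame of association rows (one per stratum) with
#'   attribute `skew_frequencies` (per stratum and smoking group).
#' @export
smoking_association <- function(cohort, threshold = 55) {
  cc <- cohort[cohort$smoking %in% c("never", "current"), , drop = FALSE]
  cc$smoker <- as.integer(cc$smoking == "current")
  cc$stratum <- ifelse(cc$age >= threshold, "older", "younger")
  rows <- list()
  freqs <- list()
  for (grp in c("younger", "older")) {
    sub <- cc[cc$stratum == grp, , drop = FALSE]
    if (nrow(sub) == 0L) next
    tab <- tapply(sub$classification == "skewed",
                  factor(sub$smoking, levels = c("never", "current")), mean)
    freqs[[grp]] <- data.frame(stratum = grp,
                               smoking = names(tab),
                               skew_frequency = as.numeric(tab),
                               stringsAsFactors = FALSE)
    if (length(unique(sub$smoker)) < 2L || nrow(sub) < 4L) {
      rows[[grp]] <- assoc_result("ols_smoking", NA_real_, NA_real_,
                                  nrow(sub), grp,
                                  "insufficient data (one smoking level)")
      next
    }
    fit <- stats::lm(ds ~ smoker + age, data = sub)
    sm <- summary(fit)$coefficients
    rows[[grp]] <- assoc_result("ols_smoking", sm["smoker", "Estimate"],
                                sm["smoker", "Pr(>|t|)"], nrow(sub), grp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skew_frequencies") <- do.call(rbind, freqs)
  out
}

#' Longitudinal concordance of XIST allelic fraction
#'
#' Spearman correlation of the per-individual XIST allelic fraction between
#' two time points of the same tissue.
#'
#' @param cohort cohort table rows for one tissue with a `time_point`
#'   column.
#' @param time_points length-2 vector of the two time points to compare;
#'   default `c(1, 2)`.
#' @return An association row (rho, two-sided p, n individuals); an
#'   insufficient-data row below 3 shared individuals.
#' @export
longitudinal_concordance <- function(cohort, time_points = c(1, 2)) {
  pick <- function(tp) {
    sub <- cohort[cohort$time_point == tp, , drop = FALSE]
    sub[!duplicated(sub$individual_id), c("individual_id", "xist_ase")]
  }
  a <- pick(time_points[1])
  b <- pick(time_points[2])
  shared <- intersect(a$individual_id, b$individual_id)
  stratum <- paste0("t", time_points[1], "-t", time_points[2])
  if (length(shared) < 3L)
    return(assoc_result("spearman_longitudinal", NA_real_, NA_real_,
                        length(shared), stratum,
                        "insufficient data (<3 individuals)"))
  x <- a$xist_ase[match(shared, a$individual_id)]
  y <- b$xist_ase[match(shared, b$individual_id)]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  assoc_result("spearman_longitudinal", unname(ct$estimate), ct$p.value,
               length(shared), stratum)
}
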