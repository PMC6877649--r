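#' Twin pair trait container
#'
#' One row per twin pair with both co-twins' trait values and the pair's
#' zygosity. The likelihood in [fit_ace()] is symmetric in the two trait
#' columns, so which co-twin is "twin 1" does not matter.
#'
#' @param trait1,trait2 numeric trait values of the two co-twins.
#' @param zygosity character, `"MZ"` or `"DZ"` per pair.
#' @param age_group optional stratum label carried along.
#' @return A data frame of class `twin_pairs`.
#' @export
twin_pairs <- function(trait1, trait2, zygosity, age_group = NULL) {
  if (length(trait1) != length(trait2) ||
      length(trait1) != length(zygosity))
    stop("trait1, trait2 and zygosity must have equal length")
  bad <- setdiff(unique(zygosity), c("MZ", "DZ"))
  if (length(bad))
    stop("zygosity must be MZ or DZ; found: ", paste(bad, collapse = ", "))
  out <- data.frame(trait1 = as.numeric(trait1),
                    trait2 = as.numeric(trait2),
                    zygosity = as.character(zygosity),
                    stringsAsFactors = FALSE)
  if (!is.null(age_group)) out$age_group <- age_group
  class(out) <- c("twin_pairs", "data.frame")
  out
}

# Negative log-likelihood of bivariate-normal twin pairs under variance
# components (a, c, e are standard deviations). Each pair (x1, x2) has
# common mean mu, variance a^2+c^2+e^2 and covariance r*a^2+c^2 with
# r = 1 (MZ) or 0.5 (DZ). Rotating to the within/between-pair contrasts
# u = (x1+x2)/sqrt(2), w = (x1-x2)/sqrt(2) diagonalises the covariance, so
# the likelihood is a product of univariate normals and is symmetric in
# pair order by construction.
ace_negll <- function(par, su_mz, sw_mz, su_dz, sw_dz) {
  mu <- par[1]; a2 <- par[2]^2; c2 <- par[3]^2; e2 <- par[4]^2
  v <- a2 + c2 + e2
  ll <- 0
  groups <- list(list(s = su_mz, w = sw_mz, cov = a2 + c2),
                 list(s = su_dz, w = sw_dz, cov = 0.5 * a2 + c2))
  for (g in groups) {
    if (length(g$s) == 0L) next
    vu <- v + g$cov
    vw <- v - g$cov
    if (vu <= 0 || vw <= 0) return(1e10)
    ll <- ll + sum(stats::dnorm(g$s - sqrt(2) * mu, 0, sqrt(vu), log = TRUE)) +
      sum(stats::dnorm(g$w, 0, sqrt(vw), log = TRUE))
  }
  -ll
}

optimise_ace <- function(starts, lower, su_mz, sw_mz, su_dz, sw_dz) {
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, ace_negll, method = "L-BFGS-B",
                   lower = lower, upper = c(Inf, Inf, Inf, Inf),
                   control = list(factr = 10),
                   su_mz = su_mz, sw_mz = sw_mz,
                   su_dz = su_dz, sw_dz = sw_dz),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0L) conv <- TRUE
  }
  if (is.null(best)) stop("ACE optimisation failed from every start")
  best$converged <- conv
  best
}

#' Fit the ACE twin model by maximum likelihood
#'
#' Decomposes trait variance into additive genetic (A), common-environment
#' (C) and unique-environment (E) components from MZ and DZ twin pairs.
#' Pair vectors are modelled as bivariate normal with common mean, total
#' variance `a2 + c2 + e2`, and covariance `a2 + c2` within MZ pairs and
#' `0.5 a2 + c2` within DZ pairs (DZ additive correlation fixed at 0.5).
#' Optimisation runs from multiple starts, including the Falconer
#' closed-form estimate and the nested CE optimum, with components bounded
#' below at zero, so boundary solutions are permitted and the ACE
#' log-likelihood can never fall below the CE one.
#'
#' The significance of A is the likelihood-ratio statistic of ACE against
#' CE, referred to the 50:50 mixture of a point mass at zero and a
#' 1-degree-of-freedom chi-square (the standard reference distribution for
#' a variance component tested on its boundary).
#'
#' @param pairs a [twin_pairs()] data frame with at least 2 MZ and 2 DZ
#'   pairs.
#' @return An object of class `ace_fit` with standardized shares `h2`,
#'   `c2`, `e2`, nuisance parameters `mean` and `total_variance`,
#'   `p_value_A`, log-likelihoods of the ACE and CE fits, pair counts and a
#'   convergence flag. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `simulate`.
#' @examples
#' set.seed(1)
#' pr <- simulate_twin_pairs(200, 200, a2 = 0.5, c2 = 0.1, e2 = 0.4)
#' fit <- fit_ace(pr)
#' coef(fit)
#' @export
fit_ace <- function(pairs) {
  stopifnot(inherits(pairs, "data.frame"))
  if (!all(c("trait1", "trait2", "zygosity") %in% names(pairs)))
    stop("pairs must have columns trait1, trait2, zygosity")
  if (any(!is.finite(pairs$trait1)) || any(!is.finite(pairs$trait2)))
    stop("trait values must be finite")
  mz <- pairs[pairs$zygosity == "MZ", , drop = FALSE]
  dz <- pairs[pairs$zygosity == "DZ", , drop = FALSE]
  if (nrow(mz) < 2L || nrow(dz) < 2L)
    stop("fit_ace requires at least 2 MZ and 2 DZ pairs")

  su_mz <- (mz$trait1 + mz$trait2) / sqrt(2)
  sw_mz <- (mz$trait1 - mz$trait2) / sqrt(2)
  su_dz <- (dz$trait1 + dz$trait2) / sqrt(2)
  sw_dz <- (dz$trait1 - dz$trait2) / sqrt(2)

  x <- c(pairs$trait1, pairs$trait2)
  mu0 <- mean(x)
  v0 <- max(stats::var(x), .Machine$double.eps)
  sd0 <- sqrt(v0)
  eps <- 1e-4 * sd0
  lower <- c(-Inf, 0, 0, eps)

  r_mz <- suppressWarnings(stats::cor(mz$trait1, mz$trait2))
  r_dz <- suppressWarnings(stats::cor(dz$trait1, dz$trait2))
  if (!is.finite(r_mz)) r_mz <- 0
  if (!is.finite(r_dz)) r_dz <- 0
  falc <- falconer(r_mz, r_dz)
  start_falc <- c(mu0, sqrt(pmax(falc, 1e-4) * v0))
  start_eq <- c(mu0, rep(sqrt(v0 / 3), 3L))
  start_e <- c(mu0, sqrt(0.02 * v0), sqrt(0.02 * v0), sqrt(0.96 * v0))

  # CE fit first: its optimum (a = 0) seeds the ACE fit, guaranteeing the
  # nesting inequality logLik(ACE) >= logLik(CE).
  ce_starts <- lapply(list(start_falc, start_eq, start_e), function(s) {
    s[2] <- 0; s
  })
  negll_ce <- function(par3, ...) ace_negll(c(par3[1], 0, par3[2], par3[3]), ...)
  best_ce <- NULL
  for (st in ce_starts) {
    fit <- tryCatch(
      stats::optim(st[c(1, 3, 4)], negll_ce, method = "L-BFGS-B",
                   lower = c(-Inf, 0, eps), control = list(factr = 10),
                   su_mz = su_mz, sw_mz = sw_mz, su_dz = su_dz,
                   sw_dz = sw_dz),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best_ce) || fit$value < best_ce$value))
      best_ce <- fit
  }
  if (is.null(best_ce)) stop("CE optimisation failed from every start")

  ce_as_ace <- c(best_ce$par[1], 0, best_ce$par[2], best_ce$par[3])
  best <- optimise_ace(list(start_falc, start_eq, start_e, ce_as_ace),
                       lower, su_mz, sw_mz, su_dz, sw_dz)
  # guard against the optimiser drifting above the CE start value
  if (best$value > best_ce$value) {
    best$par <- ce_as_ace
    best$value <- ace_negll(ce_as_ace, su_mz, sw_mz, su_dz, sw_dz)
  }

  par <- best$par
  comp <- par[2:4]^2
  v <- sum(comp)
  shares <- comp / v
  ll <- -best$value
  ll_ce <- -best_ce$value
  lrt <- max(0, 2 * (ll - ll_ce))
  p_a <- if (lrt < 1e-8) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                    lower.tail = FALSE)
  out <- list(h2 = unname(shares[1]), c2 = unname(shares[2]),
              e2 = unname(shares[3]),
              mean = unname(par[1]), total_variance = unname(v),
              logLik = ll, logLik_ce = ll_ce, lrt_A = lrt, p_value_A = p_a,
              n_mz = nrow(mz), n_dz = nrow(dz),
              r_mz = r_mz, r_dz = r_dz,
              converged = isTRUE(best$converged),
              call = match.call())
  class(out) <- "ace_fit"
  out
}

#' @exportS3Method base::print
print.ace_fit <- function(x, digits = 3, ...) {
  cat("ACE twin model (maximum likelihood)\n")
  cat(sprintf("  h2 = %.*f  c2 = %.*f  e2 = %.*f\n", digits, x$h2,
              digits, x$c2, digits, x$e2))
  cat(sprintf("  P(A) = %.3g  (LRT vs CE, 50:50 chi2_0/chi2_1 mixture)\n",
              x$p_value_A))
  cat(sprintf("  pairs: %d MZ, %d DZ\n", x$n_mz, x$n_dz))
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
summary.ace_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ace_fit")
}

#' @exportS3Method base::print
print.summary.ace_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  mean = %.4g  total variance = %.4g\n", f$mean,
              f$total_variance))
  cat(sprintf("  logLik ACE = %.4f, CE = %.4f, LRT = %.4f\n",
              f$logLik, f$logLik_ce, f$lrt_A))
  cat(sprintf("  sample twin correlations: rMZ = %.3f, rDZ = %.3f\n",
              f$r_mz, f$r_dz))
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) {
  c(h2 = unname(object$h2), c2 = unname(object$c2), e2 = unname(object$e2))
}

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$logLik, df = 4L,
            nobs = 2L * (object$n_mz + object$n_dz), class = "logLik")
}

#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_twin_pairs(
    object$n_mz, object$n_dz, object$h2, object$c2, object$e2,
    mean = object$mean, sd = sqrt(object$total_variance)),
    simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' Falconer closed-form variance components
#'
#' The moment estimators `h2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`,
#' `e2 = 1 - rMZ`, each clipped to \[0, 1\] and renormalized to sum to 1.
#' Used as an independent cross-check and as a starting point for
#' [fit_ace()].
#'
#' @param r_mz,r_dz MZ and DZ twin correlations in \[-1, 1\].
#' @return Named numeric vector `(h2, c2, e2)` summing to 1, with logical
#'   attribute `clipped` indicating whether any component was clipped.
#' @export
falconer <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("correlations must lie in [-1, 1]")
  raw <- c(h2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
  clipped <- pmin(pmax(raw, 0), 1)
  was_clipped <- any(abs(clipped - raw) > 1e-12)
  s <- sum(clipped)
  out <- if (s > 0) clipped / s else c(h2 = 0, c2 = 0, e2 = 1)
  attr(out, "clipped") <- was_clipped
  out
}

# Double-entry intraclass Spearman: each pair contributes both orderings
# and ranks are taken on the doubled set, making the statistic exactly
# invariant to swapping twin labels.
ic_statistic <- function(t1, t2) {
  x <- c(t1, t2)
  y <- c(t2, t1)
  stats::cor(rank(x), rank(y))
}

#' Intraclass Spearman correlation of twin pairs
#'
#' Rank-based within-pair resemblance, computed with double entry (each
#' pair contributes both orderings). The p-value is obtained by permutation:
#' individuals are reshuffled into pseudo-pairs and the absolute statistic
#' compared with the observed one (two-sided; `(1 + #{|IC*| >= |IC|}) /
#' (n_perm + 1)`).
#'
#' @param pairs a data frame with columns `trait1`, `trait2` (one zygosity
#'   at a time), or a [twin_pairs()] object.
#' @param n_perm number of permutations; default 10000.
#' @param seed optional seed for the permutation stream.
#' @return A data frame row with `statistic = "intraclass_spearman"`,
#'   `estimate`, `p_value` and `n` (pairs); an insufficient-data row when
#'   fewer than 3 pairs are supplied.
#' @export
intraclass_spearman <- function(pairs, n_perm = 10000, seed = NULL) {
  n <- nrow(pairs)
  if (n < 3L)
    return(assoc_result("intraclass_spearman", NA_real_, NA_real_, n,
                        note = "insufficient data (<3 pairs)"))
  if (!is.null(seed)) set.seed(seed)
  obs <- ic_statistic(pairs$trait1, pairs$trait2)
  pool <- c(pairs$trait1, pairs$trait2)
  m <- length(pool)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(m)
    perm <- ic_statistic(pool[idx[seq_len(n)]], pool[idx[n + seq_len(n)]])
    if (abs(perm) >= abs(obs) - 1e-12) count <- count + 1L
  }
  p <- (1 + count) / (n_perm + 1)
  assoc_result("intraclass_spearman", obs, p, n)
}

#' Age-stratified heritability of XCI skew
#'
#' Assembles complete twin pairs from a cohort table for one tissue (both
#' co-twins informative, zygosity MZ or DZ; singletons and incomplete pairs
#' never enter), splits them into a younger (`age < threshold`) and an
#' older (`age >= threshold`) stratum using the shared pair age, and
#' reports the ACE fit and intraclass Spearman correlations per stratum.
#'
#' @param cohort a cohort table ([cohort_table()]) restricted or
#'   restrictable to `tissue`.
#' @param tissue tissue label to analyse.
#' @param threshold age cut; default 55 years.
#' @param n_perm permutations for the intraclass p-values; default 10000.
#' @param ic if `FALSE`, skip the intraclass correlations (faster).
#' @param seed optional seed for the permutation stream.
#' @return A data frame with one row per age group present: pair counts,
#'   `h2`, `c2`, `e2`, `p_value_A`, and per-zygosity intraclass estimates
#'   and p-values (NA with a note when a component cannot be computed).
#' @export
stratified_heritability <- function(cohort, tissue, threshold = 55,
                                    n_perm = 10000, ic = TRUE, seed = NULL) {
  cc <- cohort[cohort$tissue == tissue, , drop = FALSE]
  if ("time_point" %in% names(cc))
    cc <- cc[cc$time_point == min(cc$time_point), , drop = FALSE]
  cc <- cc[cc$zygosity %in% c("MZ", "DZ"), , drop = FALSE]
  pairs <- build_twin_pairs(cc)
  if (nrow(pairs) == 0L) {
    message("stratified_heritability: no complete twin pairs in tissue '",
            tissue, "'")
    return(empty_heritability_table())
  }
  pairs$age_group <- ifelse(pairs$age >= threshold, "older", "younger")
  out <- list()
  for (grp in intersect(c("younger", "older"), unique(pairs$age_group))) {
    pg <- pairs[pairs$age_group == grp, , drop = FALSE]
    n_mz <- sum(pg$zygosity == "MZ")
    n_dz <- sum(pg$zygosity == "DZ")
    row <- data.frame(tissue = tissue, age_group = grp, n_mz = n_mz,
                      n_dz = n_dz, h2 = NA_real_, c2 = NA_real_,
                      e2 = NA_real_, p_value_A = NA_real_,
                      ic_mz = NA_real_, ic_mz_p = NA_real_,
                      ic_dz = NA_real_, ic_dz_p = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (n_mz >= 2L && n_dz >= 2L) {
      fit <- fit_ace(pg)
      row$h2 <- fit$h2; row$c2 <- fit$c2; row$e2 <- fit$e2
      row$p_value_A <- fit$p_value_A
    } else {
      row$note <- "too few pairs for ACE"
    }
    if (ic) {
      for (zyg in c("MZ", "DZ")) {
        pz <- pg[pg$zygosity == zyg, , drop = FALSE]
        res <- intraclass_spearman(pz, n_perm = n_perm, seed = seed)
        if (zyg == "MZ") {
          row$ic_mz <- res$estimate; row$ic_mz_p <- res$p_value
        } else {
          row$ic_dz <- res$estimate; row$ic_dz_p <- res$p_value
        }
      }
    }
    out[[grp]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_heritability_table <- function() {
  data.frame(tissue = character(), age_group = character(),
             n_mz = integer(), n_dz = integer(), h2 = numeric(),
             c2 = numeric(), e2 = numeric(), p_value_A = numeric(),
             ic_mz = numeric(), ic_mz_p = numeric(), ic_dz = numeric(),
             ic_dz_p = numeric(), note = character(),
             stringsAsFactors = FALSE)
}

# Complete pairs from a single-tissue cohort table: families with exactly
# two informative individuals and a shared age. Co-twins are ordered by
# individual id, which never affects the (order-symmetric) downstream
# statistics.
build_twin_pairs <- function(cc) {
  cc <- cc[order(cc$individual_id), , drop = FALSE]
  fams <- split(cc, cc$family_id)
  rows <- lapply(fams, function(f) {
    if (length(unique(f$individual_id)) != 2L) return(NULL)
    f <- f[!duplicated(f$individual_id), , drop = FALSE]
    if (length(unique(f$age)) != 1L) {
      warning("skipping family ", f$family_id[1],
              ": co-twins do not share an age")
      return(NULL)
    }
    data.frame(family_id = f$family_id[1], trait1 = f$ds[1],
               trait2 = f$ds[2], zygosity = f$zygosity[1], age = f$age[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(family_id = character(), trait1 = numeric(),
                      trait2 = numeric(), zygosity = character(),
                      age = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
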