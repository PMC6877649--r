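#' Configuration for the synthetic twin cohort generator
#'
#' Bundles every generator parameter: cohort structure, latent-skew variance
#' components with optional age gating, tissue structure, per-site read
#' sampling, and the single integer seed from which all randomness flows.
#'
#' The latent trait is `z = logit(p)`, where `p` is the fraction of cells
#' inactivating the haplotype-1 X. `z` is built as
#' `latent_sd * (sqrt(a2) A + sqrt(c2) C + sqrt(e2) E)` with `A` shared
#' within MZ pairs (correlation 1) and correlated 0.5 within DZ pairs, `C`
#' shared within all co-twins and `E` independent; tissues receive
#' correlated `E` draws. In blood-like tissues `|z|` additionally drifts
#' upward by `age_drift` per year of age above `age_threshold`.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort structure.
#' @param tissues named numeric vector: tissue labels mapped to the
#'   correlation of their unique-environment draw with the first
#'   (reference) tissue; the first entry must be 1.
#' @param blood_like character vector of tissue labels subject to the
#'   age drift (and to RA/smoking effects when configured).
#' @param age_range integer years, min and max; ages are drawn uniformly
#'   per family (co-twins share their age).
#' @param variance_components named numeric `(a2, c2, e2)` summing to 1.
#' @param variance_components_older optional override applied to
#'   individuals aged `age_threshold` or above (age-gated genetics).
#' @param latent_sd total standard deviation of the latent trait.
#' @param age_drift latent-scale units per year above `age_threshold`.
#' @param age_threshold years; default 55.
#' @param n_xist_snps,n_nonpar_snps,n_par_snps heterozygous sites per
#'   individual in XIST, in the rest of the non-PAR X, and in PAR1.
#' @param depth_mean,depth_size negative-binomial read-depth distribution
#'   (mean and size/dispersion) per site.
#' @param overdispersion_rho beta-binomial intraclass correlation in
#'   \[0, 1); 0 gives exact binomial sampling.
#' @param escape_prob probability that a non-PAR gene escapes XCI.
#' @param escape_shape1,escape_shape2 Beta parameters for the escape level
#'   `e` of escaping genes (fully silenced genes have `e = 0`; PAR genes
#'   behave as `e = 1`).
#' @param n_time_points RNA-seq time points per sample (counts re-drawn from
#'   the same latent skew, emulating longitudinal sampling).
#' @param ra_pairs number of MZ pairs made discordant for RA.
#' @param ra_effect additive shift of `|z|` in blood-like tissues for the
#'   affected co-twin (0 = null association).
#' @param smoking_prevalence probability an individual is a current smoker.
#' @param smoking_effect additive shift of `|z|` in blood-like tissues for
#'   smokers (0 = null association).
#' @param intervals an [xci_intervals()] object.
#' @param seed integer seed.
#' @return An object of class `xci_sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 100, n_dz_pairs = 100, n_singletons = 50,
                       tissues = c(LCL = 1, blood = 0.8, fat = 0.5,
                                   skin = 0.45),
                       blood_like = c("LCL", "blood"),
                       age_range = c(38, 85),
                       variance_components = c(a2 = 0.34, c2 = 0, e2 = 0.66),
                       variance_components_older = NULL,
                       latent_sd = 1.2,
                       age_drift = 0.015,
                       age_threshold = 55,
                       n_xist_snps = 3, n_nonpar_snps = 30, n_par_snps = 5,
                       depth_mean = 50, depth_size = 5,
                       overdispersion_rho = 0.02,
                       escape_prob = 0.23,
                       escape_shape1 = 1, escape_shape2 = 3,
                       n_time_points = 1,
                       ra_pairs = 0, ra_effect = 0,
                       smoking_prevalence = 0.137, smoking_effect = 0,
                       intervals = xci_intervals(),
                       seed = 1L) {
  check_components <- function(vc, what) {
    if (length(vc) != 3L || any(vc < 0) || abs(sum(vc) - 1) > 1e-8)
      stop(what, " must be three non-negative values summing to 1")
  }
  check_components(variance_components, "variance_components")
  if (!is.null(variance_components_older))
    check_components(variance_components_older, "variance_components_older")
  if (overdispersion_rho < 0 || overdispersion_rho >= 1)
    stop("overdispersion_rho must lie in [0, 1)")
  if (n_mz_pairs + n_dz_pairs + n_singletons < 1)
    stop("cohort must contain at least one individual")
  if (length(tissues) < 1L || is.null(names(tissues)) ||
      abs(tissues[[1]] - 1) > 1e-12)
    stop("tissues must be a named vector whose first (reference) entry is 1")
  if (any(tissues < -1 | tissues > 1))
    stop("tissue correlations must lie in [-1, 1]")
  if (length(age_range) != 2L || age_range[1] > age_range[2] ||
      age_range[1] < 0)
    stop("age_range must be [min, max] with 0 <= min <= max")
  if (ra_pairs > n_mz_pairs)
    stop("ra_pairs cannot exceed n_mz_pairs")
  cfg <- list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_singletons = n_singletons, tissues = tissues,
              blood_like = blood_like, age_range = age_range,
              variance_components = variance_components,
              variance_components_older = variance_components_older,
              latent_sd = latent_sd, age_drift = age_drift,
              age_threshold = age_threshold,
              n_xist_snps = n_xist_snps, n_nonpar_snps = n_nonpar_snps,
              n_par_snps = n_par_snps,
              depth_mean = depth_mean, depth_size = depth_size,
              overdispersion_rho = overdispersion_rho,
              escape_prob = escape_prob, escape_shape1 = escape_shape1,
              escape_shape2 = escape_shape2,
              n_time_points = n_time_points,
              ra_pairs = ra_pairs, ra_effect = ra_effect,
              smoking_prevalence = smoking_prevalence,
              smoking_effect = smoking_effect,
              intervals = intervals, seed = as.integer(seed))
  class(cfg) <- "xci_sim_config"
  cfg
}

# sample() treats a scalar first argument as 1:x; resample never does.
resample <- function(x, k) x[sample.int(length(x), k)]

# Beta-binomial draws parameterised by mean fraction and intraclass rho;
# rho = 0 reduces exactly to binomial sampling.
rbetabinom <- function(n, size, prob, rho) {
  prob <- rep_len(prob, n)
  size <- rep_len(size, n)
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  scale <- (1 - rho) / rho
  p <- prob
  interior <- prob > 0 & prob < 1
  if (any(interior))
    p[interior] <- stats::rbeta(sum(interior), prob[interior] * scale,
                                (1 - prob[interior]) * scale)
  stats::rbinom(n, size, p)
}

# Expected haplotype-1 read fraction at a site. XIST is expressed from the
# inactive X, so its fraction equals p directly; an XCI-subject gene with
# escape level e is expressed at level 1 from the active X and e from the
# inactive X in every cell.
expected_hap1_fraction <- function(p, in_xist, escape) {
  ifelse(in_xist, p, ((1 - p) + p * escape) / (1 + escape))
}

# Cohort skeleton: one row per individual with family structure and shared
# family age. RA discordance and smoking status are assigned here.
sim_individuals <- function(config) {
  n_fam <- config$n_mz_pairs + config$n_dz_pairs + config$n_singletons
  fam_z <- rep(c("MZ", "DZ", "singleton"),
               c(config$n_mz_pairs, config$n_dz_pairs, config$n_singletons))
  fam_id <- sprintf("F%04d", seq_len(n_fam))
  fam_age <- sample(seq(config$age_range[1], config$age_range[2]),
                    n_fam, replace = TRUE)
  twin <- fam_z != "singleton"
  suffix <- c(rep("_T1", sum(twin)), rep("_T2", sum(twin)),
              rep("_S1", sum(!twin)))
  fam_rep <- c(fam_id[twin], fam_id[twin], fam_id[!twin])
  ind <- data.frame(
    individual_id = paste0(fam_rep, suffix),
    family_id = fam_rep,
    zygosity = c(fam_z[twin], fam_z[twin], fam_z[!twin]),
    age = c(fam_age[twin], fam_age[twin], fam_age[!twin]),
    twin_index = c(rep(1L, sum(twin)), rep(2L, sum(twin)),
                   rep(1L, sum(!twin))),
    stringsAsFactors = FALSE)
  ind <- ind[order(ind$family_id, ind$twin_index), , drop = FALSE]
  rownames(ind) <- NULL
  ind$disease <- "none"
  if (config$ra_pairs > 0) {
    mz_fams <- unique(ind$family_id[ind$zygosity == "MZ"])
    ra_fams <- resample(mz_fams, config$ra_pairs)
    for (f in ra_fams) {
      rows <- which(ind$family_id == f)
      ind$disease[resample(rows, 1L)] <- "RA"
    }
  }
  ind$smoking <- ifelse(stats::runif(nrow(ind)) < config$smoking_prevalence,
                        "current", "never")
  ind
}

#' Simulate latent skew fractions for a cohort
#'
#' Draws the per-individual, per-tissue latent skew `z = logit(p)` under the
#' configured ACE covariance structure (see [sim_config()]), applies the
#' age drift and any configured RA/smoking effects in blood-like tissues,
#' and returns the ground truth. Deterministic given `config$seed`.
#'
#' @param config an [sim_config()] object.
#' @param individuals optional pre-built cohort skeleton (internal use; when
#'   supplied, the RNG state is used as-is rather than re-seeded).
#' @return Data frame with one row per individual and tissue: columns
#'   `individual_id`, `family_id`, `zygosity`, `age`, `tissue`, `z`, `p`.
#' @export
simulate_latent_skew <- function(config, individuals = NULL) {
  stopifnot(inherits(config, "xci_sim_config"))
  if (is.null(individuals)) {
    set.seed(config$seed)
    individuals <- sim_individuals(config)
  }
  n <- nrow(individuals)
  fam <- factor(individuals$family_id)
  a_fam <- stats::rnorm(nlevels(fam))[fam]
  a_own <- stats::rnorm(n)
  a <- ifelse(individuals$zygosity == "DZ",
              sqrt(0.5) * a_fam + sqrt(0.5) * a_own,
              ifelse(individuals$zygosity == "MZ", a_fam, a_own))
  c_fam <- stats::rnorm(nlevels(fam))[fam]
  e_ref <- stats::rnorm(n)

  vc <- config$variance_components
  older <- individuals$age >= config$age_threshold
  vc_o <- config$variance_components_older
  sa <- rep(sqrt(vc[[1]]), n); sc <- rep(sqrt(vc[[2]]), n)
  se <- rep(sqrt(vc[[3]]), n)
  if (!is.null(vc_o)) {
    sa[older] <- sqrt(vc_o[[1]]); sc[older] <- sqrt(vc_o[[2]])
    se[older] <- sqrt(vc_o[[3]])
  }

  out <- vector("list", length(config$tissues))
  for (t in seq_along(config$tissues)) {
    tname <- names(config$tissues)[t]
    r <- config$tissues[[t]]
    e_t <- if (t == 1L) e_ref else r * e_ref + sqrt(1 - r^2) * stats::rnorm(n)
    z <- config$latent_sd * (sa * a + sc * c_fam + se * e_t)
    if (tname %in% config$blood_like) {
      shift <- config$age_drift *
        pmax(0, individuals$age - config$age_threshold)
      if (config$ra_effect != 0)
        shift <- shift + config$ra_effect * (individuals$disease == "RA")
      if (config$smoking_effect != 0)
        shift <- shift + config$smoking_effect *
          (individuals$smoking == "current")
      z <- z + sign(z) * shift
    }
    out[[t]] <- data.frame(individuals[c("individual_id", "family_id",
                                         "zygosity", "age")],
                           tissue = tname, z = z, p = stats::plogis(z),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Panel of candidate SNV sites on chromosome X. Non-PAR sites each belong
# to their own gene with a drawn escape level; PAR sites behave as full
# escape; XIST sites follow the XIST rule.
sim_site_panel <- function(config) {
  iv <- config$intervals
  rand_pos <- function(k, lo, hi) sort(sample.int(hi - lo + 1, k) + lo - 1)
  mk <- function(k, lo, hi, region, gene, escape) {
    if (k == 0L) return(NULL)
    pos <- rand_pos(k, lo, hi)
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1))
    data.frame(contig = iv$contig, position = pos, ref_allele = ref,
               alt_allele = alt, region = region, gene = gene,
               escape = escape, stringsAsFactors = FALSE)
  }
  n_x <- max(2L * config$n_xist_snps, if (config$n_xist_snps > 0) 6L else 0L)
  n_np <- 2L * config$n_nonpar_snps
  n_p <- config$n_par_snps
  esc <- numeric(n_np)
  if (n_np > 0) {
    is_escape <- stats::runif(n_np) < config$escape_prob
    esc[is_escape] <- stats::rbeta(sum(is_escape), config$escape_shape1,
                                   config$escape_shape2)
  }
  panel <- rbind(
    mk(n_x, iv$xist[1], iv$xist[2], "xist", "XIST", NA_real_),
    mk(n_np, iv$par1[2] + 1e6, iv$xist[1] - 1e6, "nonpar",
       if (n_np > 0) sprintf("GENE%04d", seq_len(n_np)) else character(),
       esc),
    mk(n_p, iv$par1[1], iv$par1[2], "par",
       if (n_p > 0) sprintf("PAR%02d", seq_len(n_p)) else character(), 1))
  if (is.null(panel)) stop("site panel is empty; increase per-region SNP counts")
  rownames(panel) <- NULL
  panel
}

# Heterozygous-site assignment: each individual is heterozygous at a random
# subset of the panel (exact per-region counts) with random phase.
sim_heterozygous_sites <- function(individuals, panel, config) {
  per_region <- c(xist = config$n_xist_snps, nonpar = config$n_nonpar_snps,
                  par = config$n_par_snps)
  rows_by_region <- split(seq_len(nrow(panel)), panel$region)
  picks <- lapply(seq_len(nrow(individuals)), function(i) {
    unlist(lapply(names(rows_by_region), function(rg) {
      k <- min(per_region[[rg]], length(rows_by_region[[rg]]))
      if (k == 0L) integer() else sort(resample(rows_by_region[[rg]], k))
    }), use.names = FALSE)
  })
  n_per <- lengths(picks)
  idx <- unlist(picks, use.names = FALSE)
  het <- panel[idx, , drop = FALSE]
  het$individual_id <- rep(individuals$individual_id, n_per)
  het$hap1_allele <- ifelse(stats::runif(nrow(het)) < 0.5,
                            het$ref_allele, het$alt_allele)
  rownames(het) <- NULL
  het
}

#' Simulate allelic read counts for one sample
#'
#' Draws per-site read depths from the configured negative-binomial
#' distribution and haplotype-1 read counts from a beta-binomial with the
#' expected fraction implied by the latent skew: `p` at XIST sites (XIST is
#' expressed from the inactive X) and `((1 - p) + p e) / (1 + e)` at
#' XCI-subject sites with escape level `e` (PAR sites behave as `e = 1`).
#' With `overdispersion_rho = 0` sampling is exactly binomial.
#'
#' @param p latent skew fraction of the sample in (0, 1).
#' @param sites data frame of the sample's phased heterozygous sites with
#'   columns `contig`, `position`, `ref_allele`, `alt_allele`,
#'   `hap1_allele`, `region` (`"xist"`, `"nonpar"` or `"par"`) and `escape`.
#' @param config an [sim_config()] object.
#' @param sample_id identifier stamped on the rows.
#' @return Allelic-site data frame in the layout of
#'   [read_allelic_counts()], plus `gene`, `hap1_count` and
#'   `individual_id`/`hap1_allele` columns when present in `sites`.
#' @export
simulate_allelic_counts <- function(p, sites, config,
                                    sample_id = "sample1") {
  stopifnot(inherits(config, "xci_sim_config"))
  if (any(norm_contig(sites$contig) !=
          norm_contig(config$intervals$contig)))
    stop("all sites must lie on chromosome ", config$intervals$contig)
  n <- nrow(sites)
  depth <- stats::rnbinom(n, mu = config$depth_mean, size = config$depth_size)
  esc <- ifelse(sites$region == "par", 1, ifelse(is.na(sites$escape), 0,
                                                 sites$escape))
  frac <- expected_hap1_fraction(p, sites$region == "xist", esc)
  hap1 <- rbetabinom(n, depth, frac, config$overdispersion_rho)
  hap1_is_ref <- sites$hap1_allele == sites$ref_allele
  ref_count <- ifelse(hap1_is_ref, hap1, depth - hap1)
  out <- data.frame(sample_id = sample_id,
                    contig = sites$contig, position = sites$position,
                    ref_allele = sites$ref_allele,
                    alt_allele = sites$alt_allele,
                    ref_count = as.integer(ref_count),
                    alt_count = as.integer(depth - ref_count),
                    total_count = as.integer(depth),
                    in_xist = sites$region == "xist",
                    in_par = sites$region == "par",
                    gene = sites$gene,
                    stringsAsFactors = FALSE)
  if ("individual_id" %in% names(sites))
    out$individual_id <- sites$individual_id
  out
}

#' Simulate a complete twin cohort in memory
#'
#' Generates the cohort skeleton, latent skews, the site panel,
#' per-individual heterozygous sites, per-sample allelic counts at every
#' configured tissue and time point, the sample metadata and the
#' ground-truth table. Everything is deterministic given `config$seed`.
#'
#' @param config an [sim_config()] object.
#' @return A list with elements `genotypes` (phased het sites per
#'   individual), `counts` (allelic counts for all samples), `metadata`,
#'   `truth` (individual, tissue, true `p` and `ds_true = |0.5 - p|`) and
#'   `panel` (the site panel with escape levels).
#' @export
simulate_cohort_data <- function(config) {
  stopifnot(inherits(config, "xci_sim_config"))
  set.seed(config$seed)
  individuals <- sim_individuals(config)
  latent <- simulate_latent_skew(config, individuals = individuals)
  panel <- sim_site_panel(config)
  het <- sim_heterozygous_sites(individuals, panel, config)

  # one sample per individual x tissue x time point
  grid <- merge(latent,
                data.frame(time_point = seq_len(config$n_time_points)),
                by = NULL)
  grid <- grid[order(grid$tissue, grid$individual_id, grid$time_point), ,
               drop = FALSE]
  grid$sample_id <- sprintf("%s_%s_t%d", grid$individual_id, grid$tissue,
                            grid$time_point)

  # expand to the long site table and draw all counts in one pass
  het_by_ind <- split(seq_len(nrow(het)), het$individual_id)
  idx_list <- het_by_ind[grid$individual_id]
  n_sites <- lengths(idx_list)
  rows <- unlist(idx_list, use.names = FALSE)
  long <- het[rows, , drop = FALSE]
  long$sample_id <- rep(grid$sample_id, n_sites)
  long$p <- rep(grid$p, n_sites)
  n <- nrow(long)
  depth <- stats::rnbinom(n, mu = config$depth_mean, size = config$depth_size)
  esc <- ifelse(long$region == "par", 1,
                ifelse(is.na(long$escape), 0, long$escape))
  frac <- expected_hap1_fraction(long$p, long$region == "xist", esc)
  hap1 <- rbetabinom(n, depth, frac, config$overdispersion_rho)
  hap1_is_ref <- long$hap1_allele == long$ref_allele
  ref_count <- ifelse(hap1_is_ref, hap1, depth - hap1)
  counts <- data.frame(sample_id = long$sample_id,
                       contig = long$contig, position = long$position,
                       ref_allele = long$ref_allele,
                       alt_allele = long$alt_allele,
                       ref_count = as.integer(ref_count),
                       alt_count = as.integer(depth - ref_count),
                       total_count = as.integer(depth),
                       in_xist = long$region == "xist",
                       in_par = long$region == "par",
                       gene = long$gene,
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL

  metadata <- data.frame(sample_id = grid$sample_id,
                         individual_id = grid$individual_id,
                         family_id = grid$family_id,
                         zygosity = grid$zygosity,
                         age = grid$age,
                         tissue = grid$tissue,
                         smoking = individuals$smoking[
                           match(grid$individual_id,
                                 individuals$individual_id)],
                         disease = individuals$disease[
                           match(grid$individual_id,
                                 individuals$individual_id)],
                         time_point = grid$time_point,
                         stringsAsFactors = FALSE)
  rownames(metadata) <- NULL

  truth <- latent[c("individual_id", "family_id", "zygosity", "age",
                    "tissue", "p")]
  truth$ds_true <- abs(0.5 - truth$p)
  rownames(truth) <- NULL

  genotypes <- het[c("individual_id", "contig", "position", "ref_allele",
                     "alt_allele", "hap1_allele", "gene", "region")]
  rownames(genotypes) <- NULL

  list(genotypes = genotypes, counts = counts, metadata = metadata,
       truth = truth, panel = panel)
}

#' Simulate a cohort and write all pipeline input files
#'
#' Writes a multi-sample phased VCF of the panel sites, one
#' ASEReadCounter-style count table per sample under `counts/`, the sample
#' metadata table, the ground-truth table and the site panel. Byte-identical
#' outputs are produced for identical seeds.
#'
#' @param config an [sim_config()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the file paths (`vcf`, `counts_dir`,
#'   `metadata`, `truth`, `panel`) plus the in-memory `data`.
#' @export
simulate_cohort <- function(config, dir) {
  data <- simulate_cohort_data(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, showWarnings = FALSE)

  vcf_path <- file.path(dir, "cohort.vcf")
  write_cohort_vcf(data$genotypes, data$panel, vcf_path)

  for (sid in unique(data$counts$sample_id)) {
    rows <- data$counts[data$counts$sample_id == sid, , drop = FALSE]
    tab <- data.frame(contig = rows$contig, position = rows$position,
                      variantID = ".", refAllele = rows$ref_allele,
                      altAllele = rows$alt_allele,
                      refCount = rows$ref_count, altCount = rows$alt_count,
                      totalCount = rows$total_count,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(counts_dir, paste0(sid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  md_path <- file.path(dir, "metadata.tsv")
  utils::write.table(data$metadata, md_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(format_floats(data$truth), truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel_path <- file.path(dir, "panel.tsv")
  utils::write.table(format_floats(data$panel), panel_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf_path, counts_dir = counts_dir,
                 metadata = md_path, truth = truth_path,
                 panel = panel_path, data = data))
}

format_floats <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 17)
  df
}

# Minimal multi-sample VCF writer for the simulator's site panel: phased GT
# at heterozygous sites, 0|0 elsewhere.
write_cohort_vcf <- function(genotypes, panel, path) {
  individuals <- sort(unique(genotypes$individual_id))
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", panel$contig[1], ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individuals), collapse = "\t"))
  key_panel <- paste(panel$contig, panel$position)
  gt <- matrix("0|0", nrow = nrow(panel), ncol = length(individuals),
               dimnames = list(NULL, individuals))
  key_gt <- paste(genotypes$contig, genotypes$position)
  ridx <- match(key_gt, key_panel)
  cidx <- match(genotypes$individual_id, individuals)
  gt[cbind(ridx, cidx)] <- ifelse(
    genotypes$hap1_allele == genotypes$ref_allele, "0|1", "1|0")
  body <- paste(panel$contig, panel$position, ".", panel$ref_allele,
                panel$alt_allele, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate twin pair traits under an ACE model
#'
#' Draws pair trait vectors directly on the (normal) trait scale with the
#' given standardized variance components: MZ pairs share the additive
#' genetic draw, DZ pairs correlate it at 0.5, the common-environment draw
#' is shared within every pair and the unique-environment draw is
#' independent. Used for parameter-recovery studies of [fit_ace()].
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param a2,c2,e2 standardized variance components, summing to 1.
#' @param mean,sd trait mean and total standard deviation.
#' @return A `twin_pairs` data frame (see [twin_pairs()]).
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, a2, c2, e2, mean = 0, sd = 1) {
  if (any(c(a2, c2, e2) < 0) || abs(a2 + c2 + e2 - 1) > 1e-8)
    stop("a2, c2, e2 must be non-negative and sum to 1")
  draw <- function(n, r_a) {
    a_shared <- stats::rnorm(n)
    a1 <- sqrt(r_a) * a_shared + sqrt(1 - r_a) * stats::rnorm(n)
    a2_ <- sqrt(r_a) * a_shared + sqrt(1 - r_a) * stats::rnorm(n)
    cc <- stats::rnorm(n)
    t1 <- sqrt(a2) * a1 + sqrt(c2) * cc + sqrt(e2) * stats::rnorm(n)
    t2 <- sqrt(a2) * a2_ + sqrt(c2) * cc + sqrt(e2) * stats::rnorm(n)
    cbind(t1, t2)
  }
  mz <- if (n_mz > 0) draw(n_mz, 1) else matrix(numeric(), ncol = 2)
  dz <- if (n_dz > 0) draw(n_dz, 0.5) else matrix(numeric(), ncol = 2)
  twin_pairs(trait1 = mean + sd * c(mz[, 1], dz[, 1]),
             trait2 = mean + sd * c(mz[, 2], dz[, 2]),
             zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)))
}
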