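#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the package:
#' minimum site depth 10, DS classification cutoff 0.3, age threshold 55.
#'
#' @param synthetic an [sim_config()] object for synthetic runs, or `NULL`
#'   when real input files are supplied.
#' @param vcf,counts_dir,metadata input paths (ignored in synthetic mode).
#' @param min_depth,ds_threshold,age_threshold quantification and analysis
#'   thresholds.
#' @param intervals an [xci_intervals()] object.
#' @param analyses character vector of analyses to run, any of
#'   `"prevalence"`, `"concordance"`, `"age"`, `"discordant"`, `"smoking"`,
#'   `"longitudinal"`, `"heritability"`.
#' @param heritability_tissues tissues to fit the ACE model in; defaults to
#'   every tissue present.
#' @param n_perm permutations for intraclass p-values.
#' @param seed integer master seed; per-stage substreams are derived from
#'   it so stages can be rerun in isolation.
#' @return A list of class `xci_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, vcf = NULL, counts_dir = NULL,
                            metadata = NULL, min_depth = 10,
                            ds_threshold = 0.3, age_threshold = 55,
                            intervals = xci_intervals(),
                            analyses = c("prevalence", "concordance", "age",
                                         "discordant", "smoking",
                                         "longitudinal", "heritability"),
                            heritability_tissues = NULL,
                            n_perm = 1000, seed = 1L) {
  cfg <- list(synthetic = synthetic, vcf = vcf, counts_dir = counts_dir,
              metadata = metadata, min_depth = min_depth,
              ds_threshold = ds_threshold, age_threshold = age_threshold,
              intervals = intervals, analyses = analyses,
              heritability_tissues = heritability_tissues,
              n_perm = n_perm, seed = as.integer(seed))
  class(cfg) <- "xci_pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' a `synthetic:` mapping is passed to [sim_config()] and `intervals:`
#' (with `xist`, `par1`, `par2`, `contig`) to [xci_intervals()].
#'
#' @param path path to a YAML file.
#' @return A `xci_pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$intervals))
    args$intervals <- do.call(xci_intervals, raw$intervals)
  if (!is.null(raw$synthetic)) {
    sim_args <- raw$synthetic
    if (!is.null(sim_args$tissues)) sim_args$tissues <- unlist(sim_args$tissues)
    if (!is.null(sim_args$variance_components))
      sim_args$variance_components <- unlist(sim_args$variance_components)
    if (!is.null(sim_args$variance_components_older))
      sim_args$variance_components_older <-
        unlist(sim_args$variance_components_older)
    if (!is.null(args$intervals)) sim_args$intervals <- args$intervals
    args$synthetic <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, args)
}

# Derive a per-stage seed from the master seed so stages are independently
# reproducible (kept below 2^31).
stage_seed <- function(seed, stage) {
  (seed * 7919L + match(stage, c("simulate", "quantify", "stats",
                                 "heritability"))) %% .Machine$integer.max
}

#' Run the full XCI-skew pipeline
#'
#' Orchestrates simulate (optional) -> quantify -> cohort statistics ->
#' heritability with a single configuration and a single master seed.
#' Writes one TSV per analysis, a run manifest echoing the configuration,
#' and a log of per-stage sample/site exclusion counts. Outputs are
#' deterministic (byte-identical tables) given the seed.
#'
#' @param config an `xci_pipeline_config` object, or a path to a YAML file
#'   for [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`calls`, `cohort`
#'   and one element per analysis run).
#' @export
run_xci_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "xci_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_lines <- character()
  logf <- function(...) log_lines <<- c(log_lines, paste0(...))

  fail <- function(stage, e) {
    writeLines(c(paste0("stage: ", stage), conditionMessage(e)),
               failed_marker)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  # --- simulate / load inputs -------------------------------------------
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      sim_cfg <- config$synthetic
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      data <- simulate_cohort_data(sim_cfg)
      logf("simulate: ", length(unique(data$metadata$individual_id)),
           " individuals, ", nrow(data$metadata), " samples, ",
           nrow(data$counts), " allelic sites")
      data
    } else {
      if (is.null(config$vcf) || is.null(config$counts_dir) ||
          is.null(config$metadata))
        stop("non-synthetic runs require vcf, counts_dir and metadata paths")
      files <- list.files(config$counts_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      if (length(files) == 0L)
        stop("no count tables (*.tsv) found in ", config$counts_dir)
      counts <- do.call(rbind, lapply(files, read_allelic_counts,
                                      intervals = config$intervals))
      genotypes <- read_phased_vcf(config$vcf)
      metadata <- read_sample_metadata(config$metadata)
      logf("load: ", length(files), " count tables, ",
           nrow(genotypes), " phased genotypes, ",
           nrow(metadata), " metadata rows")
      list(counts = counts, genotypes = genotypes, metadata = metadata)
    }
  }, error = function(e) fail("simulate", e))

  # --- quantify ----------------------------------------------------------
  calls <- tryCatch({
    cl <- quantify_skew(res$counts, res$genotypes, res$metadata,
                        min_depth = config$min_depth,
                        ds_threshold = config$ds_threshold)
    if (nrow(cl) == 0L) stop("no informative samples after filtering")
    excl <- attr(cl, "excluded")
    logf("quantify: ", nrow(cl), " informative samples; ",
         length(attr(cl, "non_informative")), " non-informative; sites ",
         "excluded low_depth=", excl[["low_depth"]],
         " allele_not_detected=", excl[["allele_not_detected"]])
    write_skew_table(cl, file.path(out_dir, "skew_calls.tsv"))
    cl
  }, error = function(e) fail("quantify", e))

  cohort <- cohort_table(calls, res$metadata)
  tissues <- sort(unique(cohort$tissue))
  results <- list(calls = calls, cohort = cohort)
  write_tsv <- function(df, name) {
    utils::write.table(format_floats(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- cohort statistics -------------------------------------------------
  tryCatch({
    base <- cohort[cohort$time_point == min(cohort$time_point), ,
                   drop = FALSE]
    if ("prevalence" %in% config$analyses) {
      results$prevalence <- prevalence_table(base)
      write_tsv(results$prevalence, "prevalence.tsv")
    }
    if ("concordance" %in% config$analyses && length(tissues) > 1L) {
      pairs <- utils::combn(tissues, 2L, simplify = FALSE)
      results$concordance <- do.call(rbind, lapply(pairs, function(pp)
        tissue_concordance(cohort, pp[1], pp[2])))
      write_tsv(results$concordance, "concordance.tsv")
    }
    if ("age" %in% config$analyses) {
      age_rows <- list()
      grp_rows <- list()
      for (tt in tissues) {
        sub <- base[base$tissue == tt, , drop = FALSE]
        ar <- age_regression(sub)
        ar$stratum <- tt
        age_rows[[tt]] <- ar
        if (sum(sub$age < config$age_threshold) >= 2L &&
            sum(sub$age >= config$age_threshold) >= 2L) {
          gt <- age_group_tests(sub, threshold = config$age_threshold)
          gt$t_test$stratum <- tt
          gt$chisq$stratum <- tt
          grp_rows[[tt]] <- rbind(gt$t_test, gt$chisq)
        }
      }
      results$age <- do.call(rbind, c(age_rows, grp_rows))
      write_tsv(results$age, "age_association.tsv")
    }
    if ("discordant" %in% config$analyses) {
      results$discordant <- do.call(rbind, lapply(tissues, function(tt) {
        r <- discordant_pair_test(base[base$tissue == tt, , drop = FALSE])
        r$stratum <- tt
        r
      }))
      write_tsv(results$discordant, "discordant.tsv")
    }
    if ("smoking" %in% config$analyses) {
      results$smoking <- do.call(rbind, lapply(tissues, function(tt) {
        r <- smoking_association(base[base$tissue == tt, , drop = FALSE],
                                 threshold = config$age_threshold)
        if (!is.null(r) && nrow(r)) r$stratum <- paste(tt, r$stratum)
        r
      }))
      write_tsv(results$smoking, "smoking.tsv")
    }
    if ("longitudinal" %in% config$analyses &&
        length(unique(cohort$time_point)) > 1L) {
      results$longitudinal <- do.call(rbind, lapply(tissues, function(tt) {
        r <- longitudinal_concordance(cohort[cohort$tissue == tt, ,
                                             drop = FALSE])
        r$stratum <- paste(tt, r$stratum)
        r
      }))
      write_tsv(results$longitudinal, "longitudinal.tsv")
    }
    logf("stats: analyses run - ",
         paste(intersect(config$analyses,
                         c("prevalence", "concordance", "age", "discordant",
                           "smoking", "longitudinal")), collapse = ", "))
  }, error = function(e) fail("stats", e))

  # --- heritability ------------------------------------------------------
  if ("heritability" %in% config$analyses) {
    tryCatch({
      ht <- config$heritability_tissues
      if (is.null(ht)) ht <- tissues
      set.seed(stage_seed(config$seed, "heritability"))
      results$heritability <- do.call(rbind, lapply(ht, function(tt)
        stratified_heritability(cohort, tt,
                                threshold = config$age_threshold,
                                n_perm = config$n_perm)))
      write_tsv(results$heritability, "heritability.tsv")
      logf("heritability: tissues ", paste(ht, collapse = ", "))
    }, error = function(e) fail("heritability", e))
  }

  manifest <- list(package = "xciskew",
                   version = as.character(utils::packageVersion("xciskew")),
                   seed = config$seed,
                   config = serialise_config(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(results)
}

serialise_config <- function(config) {
  out <- unclass(config)
  out$intervals <- unclass(out$intervals)
  if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$intervals <- unclass(s$intervals)
    s$tissues <- as.list(s$tissues)
    s$variance_components <- as.list(s$variance_components)
    if (!is.null(s$variance_components_older))
      s$variance_components_older <- as.list(s$variance_components_older)
    out$synthetic <- s
  }
  out
}
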