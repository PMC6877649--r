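#' Read phased heterozygous genotypes from a VCF
#'
#' Parses a (possibly multi-sample) VCF and returns one row per phased
#' heterozygous biallelic SNV genotype. Multi-allelic records, indels,
#' homozygous genotypes, unphased genotypes and missing genotypes are
#' skipped; the number skipped for each reason is reported via a message
#' when non-zero. Phase semantics follow the VCF GT field: for `"0|1"` the
#' reference allele lies on haplotype 1, for `"1|0"` the alternate allele
#' does.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param region optional region string `"CHR:START-END"` (1-based,
#'   inclusive); records outside it are dropped. A region containing no
#'   records yields an empty data frame, not an error.
#' @param samples optional character vector restricting to these sample
#'   columns.
#' @return A data frame with columns `individual_id`, `contig`, `position`,
#'   `ref_allele`, `alt_allele`, `hap1_allele` (the base, ref or alt, on
#'   haplotype 1).
#' @export
read_phased_vcf <- function(path, region = NULL, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(fix) || nrow(fix) == 0L) return(empty_genotypes())

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- keep & norm_contig(chrom) == norm_contig(rg$contig) &
      pos >= rg$start & pos <= rg$end
  }
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- nchar(ref) != 1L | (nchar(alt) != 1L & !multi)
  n_nonsnv <- sum(keep & (multi | indel))
  keep <- keep & !multi & !indel
  if (!any(keep)) {
    if (n_nonsnv > 0L)
      message("read_phased_vcf: skipped ", n_nonsnv, " non-SNV/multi-allelic records")
    return(empty_genotypes())
  }

  sample_cols <- setdiff(colnames(gt), "FORMAT")
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, sample_cols)
    if (length(missing_s))
      stop("samples not present in VCF: ", paste(missing_s, collapse = ", "))
    sample_cols <- samples
  }
  if (length(sample_cols) == 0L) stop("VCF '", path, "' has no sample columns")

  out <- vector("list", length(sample_cols))
  n_unphased <- 0L
  n_hom <- 0L
  idx <- which(keep)
  for (k in seq_along(sample_cols)) {
    raw <- gt[idx, sample_cols[k]]
    # GT is the first colon-separated field
    gtf <- sub(":.*$", "", raw)
    gtf[is.na(gtf)] <- "."
    phased <- grepl("|", gtf, fixed = TRUE)
    unphased_het <- !phased & grepl("/", gtf, fixed = TRUE) &
      vapply(strsplit(gtf, "/", fixed = TRUE),
             function(a) length(unique(a)) == 2L && !any(a == "."), logical(1))
    n_unphased <- n_unphased + sum(unphased_het)
    a1 <- sub("\\|.*$", "", gtf)
    a2 <- sub("^.*\\|", "", gtf)
    het <- phased & a1 != a2 & a1 %in% c("0", "1") & a2 %in% c("0", "1")
    n_hom <- n_hom + sum(phased & !het)
    if (!any(het)) next
    i <- idx[het]
    out[[k]] <- data.frame(
      individual_id = sample_cols[k],
      contig = chrom[i],
      position = pos[i],
      ref_allele = ref[i],
      alt_allele = alt[i],
      hap1_allele = ifelse(a1[het] == "0", ref[i], alt[i]),
      stringsAsFactors = FALSE)
  }
  skipped <- c(`non-SNV/multi-allelic` = n_nonsnv, unphased = n_unphased,
               `homozygous/missing` = n_hom)
  if (any(skipped > 0L))
    message("read_phased_vcf: skipped genotypes - ",
            paste(names(skipped), skipped, sep = ": ", collapse = ", "))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_genotypes())
  rownames(res) <- NULL
  res
}

empty_genotypes <- function() {
  data.frame(individual_id = character(), contig = character(),
             position = numeric(), ref_allele = character(),
             alt_allele = character(), hap1_allele = character(),
             stringsAsFactors = FALSE)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("region must have the form 'CHR:START-END', got: ", region)
  list(contig = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Read a table of allelic read counts
#'
#' Reads a tab-separated allelic-count table in the GATK ASEReadCounter
#' output layout (columns `contig`, `position`, `refAllele`, `altAllele`,
#' `refCount`, `altCount`, `totalCount`; `variantID` is carried through when
#' present). Total counts are recomputed as `refCount + altCount` so reads
#' carrying a third base never inflate the depth; rows where the stated
#' total disagreed are counted in a message. Sites are flagged as lying in
#' XIST or a PAR from `intervals`.
#'
#' @param path path to the TSV file.
#' @param intervals an [xci_intervals()] object used to flag sites.
#' @param sample_id sample identifier attached to every row; defaults to the
#'   file name without extension.
#' @return A data frame with columns `sample_id`, `contig`, `position`,
#'   `ref_allele`, `alt_allele`, `ref_count`, `alt_count`, `total_count`,
#'   `in_xist`, `in_par` (plus `variant_id` if present in the input).
#' @export
read_allelic_counts <- function(path, intervals = xci_intervals(),
                                sample_id = NULL) {
  if (!file.exists(path)) stop("allelic count table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("contig", "position", "refAllele", "altAllele",
                "refCount", "altCount", "totalCount")
  absent <- setdiff(required, names(tab))
  if (length(absent))
    stop("allelic count table '", path, "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(tab) == 0L) {
    out <- data.frame(sample_id = character(), contig = character(),
                      position = numeric(), ref_allele = character(),
                      alt_allele = character(), ref_count = integer(),
                      alt_count = integer(), total_count = integer(),
                      in_xist = logical(), in_par = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (any(tab$refCount < 0 | tab$altCount < 0))
    stop("allelic count table '", path, "' contains negative counts")
  total <- tab$refCount + tab$altCount
  n_discrepant <- sum(tab$totalCount != total)
  if (n_discrepant > 0L)
    message("read_allelic_counts: recomputed totalCount as refCount + altCount for ",
            n_discrepant, " row(s) where it disagreed")
  fl <- flag_sites(tab$contig, tab$position, intervals)
  out <- data.frame(sample_id = sample_id,
                    contig = as.character(tab$contig),
                    position = as.numeric(tab$position),
                    ref_allele = as.character(tab$refAllele),
                    alt_allele = as.character(tab$altAllele),
                    ref_count = as.integer(tab$refCount),
                    alt_count = as.integer(tab$altCount),
                    total_count = as.integer(total),
                    in_xist = fl$in_xist,
                    in_par = fl$in_par,
                    stringsAsFactors = FALSE)
  if ("variantID" %in% names(tab)) out$variant_id <- as.character(tab$variantID)
  out
}

#' Read a sample metadata table
#'
#' Tab-separated with header: `sample_id`, `individual_id`, `family_id`,
#' `zygosity` (MZ/DZ/singleton), `age` (years), `tissue`, `smoking`
#' (never/current/unknown), `disease` (none/RA/unknown), `time_point`.
#'
#' @param path path to the TSV file.
#' @return A data frame with the columns above.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "individual_id", "family_id", "zygosity",
                "age", "tissue", "smoking", "disease", "time_point")
  absent <- setdiff(required, names(md))
  if (length(absent))
    stop("metadata table '", path, "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  bad_z <- setdiff(unique(md$zygosity), c("MZ", "DZ", "singleton"))
  if (length(bad_z))
    stop("metadata 'zygosity' must be MZ, DZ or singleton; found: ",
         paste(bad_z, collapse = ", "))
  if (any(md$age < 0)) stop("metadata 'age' must be non-negative")
  md
}

skew_table_columns <- c("sample_id", "tissue", "n_snps", "xist_ase", "ds",
                        "classification")

#' Write per-sample skew calls to a TSV
#'
#' Deterministic column order (`sample_id`, `tissue`, `n_snps`, `xist_ase`,
#' `ds`, `classification`); floats are written with full precision so that
#' [read_skew_table()] round-trips values exactly to at least 1e-10. An empty
#' set of calls yields a header-only file.
#'
#' @param calls a `skew_calls` data frame (see [quantify_skew()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_skew_table <- function(calls, path) {
  cols <- skew_table_columns
  absent <- setdiff(cols, names(calls))
  if (length(absent))
    stop("skew calls are missing column(s): ", paste(absent, collapse = ", "))
  out <- as.data.frame(calls)[, cols, drop = FALSE]
  for (num in c("xist_ase", "ds"))
    out[[num]] <- formatC(out[[num]], format = "g", digits = 17)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write skew table to: ", path)
  invisible(path)
}

#' Read a skew table written by [write_skew_table()]
#'
#' @param path path to the TSV file.
#' @return A `skew_calls` data frame.
#' @export
read_skew_table <- function(path) {
  if (!file.exists(path)) stop("skew table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character",
                                          tissue = "character",
                                          classification = "character"))
  absent <- setdiff(skew_table_columns, names(tab))
  if (length(absent))
    stop("skew table '", path, "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  class(tab) <- c("skew_calls", "data.frame")
  tab
}
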