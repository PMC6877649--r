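#' Filter allelic sites for informativeness
#'
#' Retains sites with a read depth of at least `min_depth` reads and with
#' both alleles detected at least once (the latter guards against genotyping
#' errors masquerading as monoallelic expression). Relative order is
#' preserved. Counts of exclusions by reason are attached as the
#' `"excluded"` attribute.
#'
#' Lowering `min_depth` never removes a previously retained site.
#'
#' @param sites data frame of allelic sites (see [read_allelic_counts()]).
#' @param min_depth minimum total read depth; default 10.
#' @return The retained subset of `sites`, with attribute `excluded`, a
#'   named integer vector with counts for `low_depth` and
#'   `allele_not_detected`.
#' @export
filter_sites <- function(sites, min_depth = 10) {
  if (nrow(sites) == 0L) {
    attr(sites, "excluded") <- c(low_depth = 0L, allele_not_detected = 0L)
    return(sites)
  }
  low <- sites$total_count < min_depth
  mono <- sites$ref_count < 1L | sites$alt_count < 1L
  keep <- !low & !mono
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- c(low_depth = sum(low),
                             allele_not_detected = sum(!low & mono))
  out
}

#' Per-site allele-specific expression, phase-aligned
#'
#' For each site, the reference-allele fraction is the reference read count
#' divided by the site depth; the haplotype-1 fraction re-orients it by
#' phase (`hap1_fraction = ref_fraction` when haplotype 1 carries the
#' reference allele, `1 - ref_fraction` otherwise). Averaging the
#' phase-aligned fractions rather than raw reference fractions is what lets
#' sites with opposite phase reinforce instead of cancel.
#'
#' @param sites data frame of filtered allelic sites carrying an
#'   `individual_id` column (added by [quantify_skew()]; for direct use,
#'   attach it yourself).
#' @param genotypes phased genotypes from [read_phased_vcf()].
#' @return `sites` with columns `hap1_allele`, `ref_fraction`,
#'   `hap1_fraction` appended; sites without a matching phased genotype are
#'   dropped (count in attribute `n_unmatched`).
#' @export
site_ase <- function(sites, genotypes) {
  if (!"individual_id" %in% names(sites))
    stop("'sites' must carry an 'individual_id' column to join with genotypes")
  key_s <- paste(sites$individual_id, norm_contig(sites$contig),
                 sites$position, sep = ":")
  key_g <- paste(genotypes$individual_id, norm_contig(genotypes$contig),
                 genotypes$position, sep = ":")
  m <- match(key_s, key_g)
  matched <- !is.na(m)
  out <- sites[matched, , drop = FALSE]
  g <- genotypes[m[matched], , drop = FALSE]
  mismatch <- out$ref_allele != g$ref_allele | out$alt_allele != g$alt_allele
  if (any(mismatch))
    stop("allele mismatch between count table and VCF at ",
         sum(mismatch), " site(s), e.g. ",
         out$contig[mismatch][1], ":", out$position[mismatch][1])
  if (any(out$total_count <= 0))
    stop("site_ase requires positive total_count; run filter_sites first")
  out$hap1_allele <- g$hap1_allele
  out$ref_fraction <- out$ref_count / out$total_count
  out$hap1_fraction <- ifelse(out$hap1_allele == out$ref_allele,
                              out$ref_fraction, 1 - out$ref_fraction)
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- sum(!matched)
  out
}

#' Sample-level XIST allelic expression
#'
#' The unweighted arithmetic mean of phase-aligned per-site fractions over a
#' sample's informative XIST SNPs. A value of 0.5 indicates equal
#' inactivation of the two parental X chromosomes; 0 or 1 indicates
#' complete inactivation of one of them.
#'
#' @param ase data frame from [site_ase()] restricted to one sample's XIST
#'   sites (rows with `in_xist = FALSE`, if present, are ignored), or a bare
#'   numeric vector of phase-aligned fractions.
#' @param weighted if `TRUE`, weight sites by read depth instead of the
#'   plain mean (off by default).
#' @return The mean fraction in \[0, 1\], or `NA_real_` when the sample has
#'   no informative XIST site (such samples receive no skew call).
#' @export
xist_ase <- function(ase, weighted = FALSE) {
  if (is.numeric(ase)) {
    f <- ase
    w <- rep(1, length(f))
  } else {
    rows <- if ("in_xist" %in% names(ase)) ase$in_xist else rep(TRUE, nrow(ase))
    f <- ase$hap1_fraction[rows]
    w <- if (weighted) ase$total_count[rows] else rep(1, sum(rows))
  }
  if (length(f) == 0L) return(NA_real_)
  if (any(f < 0 | f > 1)) stop("site fractions must lie in [0, 1]")
  sum(w * f) / sum(w)
}

#' Degree of skewing of X inactivation
#'
#' The absolute deviation of the sample-level XIST allelic fraction from
#' 0.5. Ranges from 0 (random XCI, 50:50 mosaic) to 0.5 (completely skewed,
#' 100:0).
#'
#' @param xist_ase numeric vector of sample-level XIST allelic fractions in
#'   \[0, 1\].
#' @return `|0.5 - xist_ase|`, in \[0, 0.5\].
#' @export
degree_of_skewing <- function(xist_ase) {
  if (any(!is.na(xist_ase) & (xist_ase < 0 | xist_ase > 1)))
    stop("xist_ase must lie in [0, 1]")
  abs(0.5 - xist_ase)
}

#' Classify samples as skewed or random XCI
#'
#' Skewed iff the degree of skewing is at least `threshold` (default 0.3,
#' i.e. an 80:20 or more extreme mosaic; boundary inclusive). A 1e-9
#' numerical tolerance is applied at the boundary so values that equal the
#' threshold up to floating-point rounding classify as skewed.
#'
#' @param ds numeric vector of degrees of skewing in \[0, 0.5\].
#' @param threshold classification cutoff; default 0.3.
#' @return Character vector, `"skewed"` or `"random"`.
#' @export
classify_skew <- function(ds, threshold = 0.3) {
  if (any(!is.na(ds) & (ds < -1e-9 | ds > 0.5 + 1e-9)))
    stop("ds must lie in [0, 0.5]")
  ifelse(ds - threshold >= -1e-9, "skewed", "random")
}

#' Quantify XCI skew per sample
#'
#' Runs the full per-sample quantification: site filtering
#' ([filter_sites()]), phase-aligned per-site ASE ([site_ase()]), the
#' sample-level XIST mean ([xist_ase()]), degree of skewing
#' ([degree_of_skewing()]) and classification ([classify_skew()]). Samples
#' with no informative XIST SNP are flagged non-informative and receive no
#' call.
#'
#' @param counts allelic-site data frame (rows for any number of samples),
#'   as from [read_allelic_counts()].
#' @param genotypes phased genotypes from [read_phased_vcf()].
#' @param metadata optional metadata table mapping `sample_id` to
#'   `individual_id` and `tissue`; without it, sample ids are assumed to be
#'   individual ids and tissue is `NA`.
#' @param min_depth minimum site depth; default 10.
#' @param ds_threshold skew classification cutoff; default 0.3.
#' @param weighted depth-weight the XIST mean (off by default).
#' @return A data frame of class `skew_calls` with columns `sample_id`,
#'   `tissue`, `n_snps`, `xist_ase`, `ds`, `classification`. Attributes:
#'   `non_informative` (sample ids with zero informative XIST SNPs),
#'   `excluded` (site-filter counts).
#' @export
quantify_skew <- function(counts, genotypes, metadata = NULL,
                          min_depth = 10, ds_threshold = 0.3,
                          weighted = FALSE) {
  all_samples <- unique(counts$sample_id)
  if (!is.null(metadata)) {
    m <- match(counts$sample_id, metadata$sample_id)
    if (anyNA(m))
      stop("samples missing from metadata: ",
           paste(unique(counts$sample_id[is.na(m)]), collapse = ", "))
    counts$individual_id <- metadata$individual_id[m]
  } else if (!"individual_id" %in% names(counts)) {
    counts$individual_id <- counts$sample_id
  }
  kept <- filter_sites(counts, min_depth = min_depth)
  excluded <- attr(kept, "excluded")
  ase <- site_ase(kept, genotypes)
  xs <- ase[ase$in_xist, , drop = FALSE]
  if (nrow(xs) > 0L) {
    w <- if (weighted) xs$total_count else rep(1, nrow(xs))
    num <- tapply(w * xs$hap1_fraction, xs$sample_id, sum)
    den <- tapply(w, xs$sample_id, sum)
    n_snps <- as.integer(tapply(rep(1L, nrow(xs)), xs$sample_id, sum))
    value <- as.numeric(num / den)
    sample_id <- names(num)
  } else {
    sample_id <- character()
    n_snps <- integer()
    value <- numeric()
  }
  ds <- degree_of_skewing(value)
  tissue <- rep(NA_character_, length(sample_id))
  if (!is.null(metadata))
    tissue <- metadata$tissue[match(sample_id, metadata$sample_id)]
  calls <- data.frame(sample_id = sample_id, tissue = tissue,
                      n_snps = n_snps, xist_ase = value, ds = ds,
                      classification = classify_skew(ds, ds_threshold),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$sample_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("skew_calls", "data.frame")
  attr(calls, "non_informative") <- setdiff(all_samples, sample_id)
  attr(calls, "excluded") <- excluded
  calls
}

#' @exportS3Method base::print
print.skew_calls <- function(x, ...) {
  n <- nrow(x)
  cat("XCI skew calls: ", n, " sample(s)", sep = "")
  if (n > 0L) {
    sk <- sum(x$classification == "skewed")
    cat("; skewed ", sk, " (", round(100 * sk / n), "%)", sep = "")
  }
  cat("\n")
  ni <- attr(x, "non_informative")
  if (length(ni)) cat("non-informative samples:", length(ni), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (n > 10L) cat("... and", n - 10L, "more rows\n")
  invisible(x)
}

#' Alternative skew estimate from non-PAR sites
#'
#' Phase-aligned mean allelic fraction across a sample's informative
#' non-PAR sites outside XIST, after excluding sites in genes known to
#' escape XCI. For fully silenced genes the expected fraction is `1 - p`
#' when a fraction `p` of cells inactivate haplotype 1 (the active-X allele
#' is the one expressed), so its deviation from 0.5 mirrors the
#' XIST-based degree of skewing.
#'
#' @param ase data frame from [site_ase()] (any number of samples).
#' @param escape_genes optional character vector of gene labels to exclude
#'   (requires a `gene` column in `ase`).
#' @param min_sites minimum number of informative non-PAR sites per sample;
#'   default 5. Samples below it are flagged non-informative for this
#'   estimator.
#' @return Data frame with columns `sample_id`, `n_sites`, `nonpar_ase`,
#'   `deviation` (`|0.5 - nonpar_ase|`); attribute `non_informative` lists
#'   samples with too few sites.
#' @export
nonpar_ase <- function(ase, escape_genes = NULL, min_sites = 5) {
  rows <- !ase$in_xist & !ase$in_par
  if (!is.null(escape_genes)) {
    if (!"gene" %in% names(ase))
      stop("escape-gene exclusion requires a 'gene' column")
    rows <- rows & !(ase$gene %in% escape_genes)
  }
  np <- ase[rows, , drop = FALSE]
  if (nrow(np) == 0L) {
    out <- data.frame(sample_id = character(), n_sites = integer(),
                      nonpar_ase = numeric(), deviation = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "non_informative") <- unique(ase$sample_id)
    return(out)
  }
  value <- tapply(np$hap1_fraction, np$sample_id, mean)
  n_sites <- as.integer(tapply(rep(1L, nrow(np)), np$sample_id, sum))
  out <- data.frame(sample_id = names(value), n_sites = n_sites,
                    nonpar_ase = as.numeric(value),
                    deviation = abs(0.5 - as.numeric(value)),
                    stringsAsFactors = FALSE)
  keep <- out$n_sites >= min_sites
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "non_informative") <- c(out$sample_id[!keep],
                                    setdiff(unique(ase$sample_id),
                                            out$sample_id))
  res
}
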