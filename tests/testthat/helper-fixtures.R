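# Shared fixture builders: everything is generated in code at test time.

# Minimal VCF writer for reader tests; `rows` is a data frame with columns
# chrom, pos, ref, alt, gt (one sample unless gt2 given).
write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                           samples = "IND1") {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=X>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_cols <- rows[, grep("^gt", names(rows)), drop = FALSE]
  body <- apply(cbind(rows$chrom, rows$pos, ".", rows$ref, rows$alt, ".",
                      "PASS", ".", "GT", gt_cols), 1L, paste,
                collapse = "\t")
  writeLines(c(header, body), path)
  path
}

# Allelic-site rows in the package's internal layout.
make_sites <- function(ref_count, alt_count, position = NULL,
                       sample_id = "S1", individual_id = sample_id,
                       in_xist = TRUE, in_par = FALSE, contig = "X") {
  n <- length(ref_count)
  if (is.null(position)) position <- 73050000 + seq_len(n)
  data.frame(sample_id = sample_id, individual_id = individual_id,
             contig = contig, position = position,
             ref_allele = rep_len("A", n), alt_allele = rep_len("G", n),
             ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count),
             total_count = as.integer(ref_count + alt_count),
             in_xist = rep_len(in_xist, n), in_par = rep_len(in_par, n),
             stringsAsFactors = FALSE)
}

# Matching phased genotypes; hap1 = "ref" or "alt" per site.
make_genotypes <- function(sites, hap1 = "ref") {
  hap1 <- rep_len(hap1, nrow(sites))
  data.frame(individual_id = sites$individual_id, contig = sites$contig,
             position = sites$position, ref_allele = sites$ref_allele,
             alt_allele = sites$alt_allele,
             hap1_allele = ifelse(hap1 == "ref", sites$ref_allele,
                                  sites$alt_allele),
             stringsAsFactors = FALSE)
}

# Cohort-table rows built directly (bypassing quantification) for the
# statistics tests.
make_cohort <- function(ds, age, tissue = "LCL", individual_id = NULL,
                        family_id = NULL, zygosity = "singleton",
                        smoking = "never", disease = "none",
                        time_point = 1L) {
  n <- length(ds)
  if (is.null(individual_id)) individual_id <- sprintf("I%04d", seq_len(n))
  if (is.null(family_id)) family_id <- individual_id
  out <- data.frame(sample_id = paste0(individual_id, "_", tissue, "_t",
                                       time_point),
                    tissue = rep_len(tissue, n), n_snps = 3L,
                    xist_ase = 0.5 + ds, ds = ds,
                    classification = classify_skew(ds),
                    individual_id = individual_id, family_id = family_id,
                    zygosity = rep_len(zygosity, n), age = age,
                    smoking = rep_len(smoking, n),
                    disease = rep_len(disease, n),
                    time_point = rep_len(time_point, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Folded-normal DS values: a null trait with no age or group structure.
r_null_ds <- function(n, sd = 0.12) pmin(abs(rnorm(n, 0, sd)), 0.5)
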