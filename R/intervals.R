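#' Chromosome X annotation intervals
#'
#' Container for the genomic intervals the pipeline needs on chromosome X:
#' the XIST gene body and the two pseudo-autosomal regions (PARs). Defaults
#' are GRCh37 coordinates (XIST Xq13.2; PAR1/PAR2 as annotated on the GRCh37
#' assembly). All coordinates are 1-based and interval membership is
#' inclusive on both ends, following VCF convention.
#'
#' These are configuration values, not constants: analyses on other
#' assemblies (or with a widened XIST window) pass their own intervals.
#'
#' @param xist length-2 integer vector, start/end of XIST.
#' @param par1 length-2 integer vector, start/end of PAR1.
#' @param par2 length-2 integer vector, start/end of PAR2.
#' @param contig chromosome name; "X" and "chrX" are treated as equal.
#' @return An object of class `xci_intervals`.
#' @examples
#' iv <- xci_intervals()
#' @export
xci_intervals <- function(xist = c(73040486L, 73072588L),
                          par1 = c(60001L, 2699520L),
                          par2 = c(154931044L, 155260560L),
                          contig = "X") {
  for (nm in c("xist", "par1", "par2")) {
    v <- get(nm)
    if (length(v) != 2L || !is.numeric(v) || any(!is.finite(v)) || v[1] > v[2])
      stop("interval '", nm, "' must be a length-2 numeric vector with start <= end")
  }
  structure(list(contig = as.character(contig)[1],
                 xist = as.numeric(xist),
                 par1 = as.numeric(par1),
                 par2 = as.numeric(par2)),
            class = "xci_intervals")
}

# strip any "chr" prefix so "chrX" and "X" compare equal
norm_contig <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

in_interval <- function(pos, interval) {
  pos >= interval[1] & pos <= interval[2]
}

#' Flag positions as lying in XIST or a PAR
#'
#' @param contig character vector of chromosome names.
#' @param position numeric vector of 1-based positions.
#' @param intervals an [xci_intervals()] object.
#' @return A list with logical vectors `in_xist` and `in_par` (inclusive
#'   boundaries; positions on a different contig are `FALSE` for both).
#' @export
flag_sites <- function(contig, position, intervals = xci_intervals()) {
  stopifnot(inherits(intervals, "xci_intervals"))
  on_x <- norm_contig(contig) == norm_contig(intervals$contig)
  list(in_xist = on_x & in_interval(position, intervals$xist),
       in_par = on_x & (in_interval(position, intervals$par1) |
                          in_interval(position, intervals$par2)))
}
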