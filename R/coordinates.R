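#' Genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open. Printed
#' coordinates (e.g. "chrX:66763873-66950461") are 1-based inclusive and are
#' converted at I/O boundaries by [parse_region()] / [format_region()].
#'
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, 0-based half-open; `start < end`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) {
    stop("invalid interval ", chrom, ":[", start, ",", end, "): start must be < end")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
length.genomic_interval <- function(x) x$end - x$start

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
gi_width <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format_region(x), "\n")
  invisible(x)
}

#' Parse a printed region string
#'
#' @param text A string "chrom:start-end" with 1-based inclusive coordinates,
#'   thousands separators allowed.
#' @return A `genomic_interval` (0-based half-open).
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", text)
  s <- as.numeric(gsub(",", "", m[3]))
  e <- as.numeric(gsub(",", "", m[4]))
  genomic_interval(m[2], s - 1, e)
}

#' @rdname parse_region
#' @param x A `genomic_interval`.
#' @export
format_region <- function(x) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start + 1), as.integer(x$end))
}

#' Does a (chrom, pos) point fall inside an interval?
#'
#' @param x A `genomic_interval`.
#' @param chrom,pos Point to test, `pos` 0-based.
#' @export
gi_contains <- function(x, chrom, pos) {
  chrom == x$chrom & pos >= x$start & pos < x$end
}

#' Default AR gene body (hg19, RefSeq NM_000044.3)
#'
#' The locus within which at least one breakend must fall for a structural
#' variant to count as an AR-GSR.
#' @export
ar_gene_body <- function() parse_region("chrX:66763873-66950461")

#' Default copy-number control regions (hg19)
#'
#' Five off-target control regions of the capture panel used to normalize
#' mean read coverage before computing the locus copy-number ratio.
#' @return Named list of `genomic_interval`s C1..C5.
#' @export
control_regions <- function() {
  list(
    C1 = parse_region("chr9:98258995-98264381"),
    C2 = parse_region("chrX:16153017-16159789"),
    C3 = parse_region("chr14:105249980-105255049"),
    C4 = parse_region("chr15:40514992-40520036"),
    C5 = parse_region("chr15:67390102-67395049")
  )
}
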