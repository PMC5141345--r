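#' Reference sequence store helpers
#'
#' References are plain named [Biostrings::DNAStringSet] objects, one entry
#' per chromosome. Fetches use the package-internal 0-based half-open
#' convention.
#'
#' @param ref A named `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @param strand "+" returns the forward sequence, "-" its reverse complement.
#' @return A character scalar.
#' @export
ref_fetch <- function(ref, chrom, start, end, strand = "+") {
  if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
  L <- length(ref[[chrom]])
  if (start < 0 || end > L || start >= end) {
    stop("coordinates out of reference bounds: ", chrom, ":[", start, ",", end,
         ") on length-", L, " sequence")
  }
  s <- Biostrings::subseq(ref[[chrom]], start + 1, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

ref_base <- function(ref, chrom, pos) ref_fetch(ref, chrom, pos, pos + 1)

#' Read/write FASTA references
#' @param path File path.
#' @export
read_reference <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_reference
#' @param ref Named `DNAStringSet`.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, filepath = path)
  invisible(path)
}
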