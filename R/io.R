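#' Interchange formats: BEDPE, VCF breakends, BED, bundled tables
#'
#' BEDPE records carry one junction per line (0-based half-open breakend
#' intervals, orientation in the strand columns, inserted sequence in an
#' extra column). VCF output uses breakend (BND) notation with two mated
#' records per junction; the reader reconstructs junctions from the
#' first-mate records.
#'
#' @name io
NULL

#' @rdname io
#' @param junctions List of [bfj()]s.
#' @param path File path.
#' @export
write_bedpe <- function(junctions, path) {
  lines <- vapply(seq_along(junctions), function(i) {
    j <- junctions[[i]]
    paste(j$left$chrom, j$left$pos, j$left$pos + 1,
          j$right$chrom, j$right$pos, j$right$pos + 1,
          paste0("bfj_", i), 100, j$left$orient, j$right$orient,
          j$svclass,
          if (nchar(j$inserted_seq)) j$inserted_seq else ".",
          sep = "\t")
  }, character(1))
  writeLines(c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\tstrand1\tstrand2\tsvclass\tinserted_seq",
               lines), path)
  invisible(path)
}

#' @rdname io
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ins <- if (ncol(df) >= 12 && df[i, 12] != ".") df[i, 12] else ""
    bfj(breakend(df[i, 1], df[i, 2], df[i, 9]),
        breakend(df[i, 4], df[i, 5], df[i, 10]),
        inserted_seq = ins)
  })
}

bnd_alt <- function(self_orient, partner, ins) {
  p <- paste0(partner$chrom, ":", partner$pos + 1)
  bracket <- if (partner$orient == "+") paste0("[", p, "[") else
    paste0("]", p, "]")
  if (self_orient == "+") paste0("N", ins, bracket)
  else paste0(bracket, ins, "N")
}

#' @rdname io
#' @export
write_vcf_bnd <- function(junctions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##ALT=<ID=BND,Description=\"Breakend\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate record\">",
               "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"Junction class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_along(junctions)) {
    j <- junctions[[i]]
    id1 <- sprintf("bnd_%d_1", i); id2 <- sprintf("bnd_%d_2", i)
    alt1 <- bnd_alt(j$left$orient, j$right, j$inserted_seq)
    # mate record: the same adjacency seen from the right breakend
    mate_partner <- list(chrom = j$left$chrom, pos = j$left$pos,
                         orient = if (j$left$orient == "+") "-" else "+")
    self2 <- if (j$right$orient == "+") "-" else "+"
    alt2 <- bnd_alt(self2, mate_partner, j$inserted_seq)
    writeLines(sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;SVCLASS=%s",
                       c(j$left$chrom, j$right$chrom),
                       c(j$left$pos + 1, j$right$pos + 1),
                       c(id1, id2), c(alt1, alt2), c(id2, id1),
                       j$svclass), con)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_vcf_bnd <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- grep("SVTYPE=BND", lines, value = TRUE)
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!grepl("_1$", f[3])) next
    alt <- f[5]
    m <- regmatches(alt, regexec(
      "^([ACGTN]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([ACGTN]*)$", alt))[[1]]
    if (length(m) != 7) stop("unparseable BND ALT: ", alt)
    t_prefix <- m[2] != ""
    self_orient <- if (t_prefix) "+" else "-"
    partner_orient <- if (m[3] == "[") "+" else "-"
    ins <- if (t_prefix) substr(m[2], 2, nchar(m[2])) else
      substr(m[7], 1, nchar(m[7]) - 1)
    out[[length(out) + 1]] <- bfj(
      breakend(f[1], as.numeric(f[2]) - 1, self_orient),
      breakend(m[4], as.numeric(m[5]) - 1, partner_orient),
      inserted_seq = ins)
  }
  out
}

#' @rdname io
#' @param exons Exon annotation data.frame (`chrom`, `start`, `end`,
#'   `name`, optional `kind`).
#' @export
write_bed <- function(exons, path) {
  score <- rep(0L, nrow(exons))
  lines <- paste(exons$chrom, exons$start, exons$end, exons$name, score,
                 "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[, 1], start = df[, 2], end = df[, 3],
             name = if (ncol(df) >= 4) df[, 4] else
               paste0("region_", seq_len(nrow(df))),
             stringsAsFactors = FALSE)
}

#' Bundled break-fusion-junction table (hg19)
#'
#' The published per-tumour junction coordinates, classes and variant
#' allele fractions for the CRPC cohort, as printed (one row per
#' junction; the VAF of one imprecise call is NA).
#'
#' @return data.frame with `patient`, `tumour`, `tumour_type`, `gsr`,
#'   `junction` (printed notation), `vaf_pct`.
#' @export
ar_gsr_table <- function() {
  path <- system.file("extdata", "ar_gsr_junctions.tsv", package = "argsr",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled cohort alteration counts
#'
#' Sample counts by alteration status used for the cohort 2x2 tables
#' (GSR status versus amplification, missense mutation, and disease
#' stage).
#'
#' @return Named integer vector.
#' @export
cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.tsv", package = "argsr",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$count), df$group)
}

#' Cohort 2x2 contingency tables
#'
#' Builds the three tables fed to [fisher_exact_two_tailed()]:
#' GSR status by amplification status (metastases), GSR status by
#' missense-mutation status (metastases), and GSR status by disease
#' stage (CRPC versus hormone-naive).
#'
#' @return Named list of 2x2 matrices.
#' @export
cohort_tables <- function() {
  ct <- cohort_counts()
  list(
    amplification = matrix(c(ct[["amplified_gsr_pos"]],
                             ct[["amplified_gsr_neg"]],
                             ct[["neutral_gsr_pos"]],
                             ct[["neutral_gsr_neg"]]),
                           2, 2, byrow = TRUE,
                           dimnames = list(c("amplified", "copy-neutral"),
                                           c("GSR+", "GSR-"))),
    mutation = matrix(c(ct[["mutant_gsr_pos"]], ct[["mutant_gsr_neg"]],
                        ct[["wildtype_gsr_pos"]], ct[["wildtype_gsr_neg"]]),
                      2, 2, byrow = TRUE,
                      dimnames = list(c("missense+", "missense-"),
                                      c("GSR+", "GSR-"))),
    stage = matrix(c(ct[["crpc_gsr_pos"]], ct[["crpc_gsr_neg"]],
                     ct[["naive_gsr_pos"]], ct[["naive_gsr_neg"]]),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("CRPC", "hormone-naive"),
                                   c("GSR+", "GSR-")))
  )
}
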