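#' Aligned-read records
#'
#' Alignments travel through the pipeline as a data.frame mirroring SAM
#' columns: `qname`, `flag`, `rname`, `pos` (1-based leftmost aligned
#' position, SAM convention), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#' `seq` and `sa` (the SA tag body for split reads, NA otherwise). Flag
#' bits follow SAM: 0x1 paired, 0x2 proper pair, 0x10 reverse, 0x20 mate
#' reverse, 0x40/0x80 first/last in pair, 0x400 duplicate, 0x800
#' supplementary. [write_sam()] / [read_sam()] convert to and from the
#' plain-text format.
#'
#' @name alignments
NULL

FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L; FLAG_FIRST <- 0x40L; FLAG_LAST <- 0x80L
FLAG_DUP <- 0x400L; FLAG_SUPP <- 0x800L

aln_frame <- function(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      sa = character(0)) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
             seq = seq, sa = sa, stringsAsFactors = FALSE)
}

has_flag <- function(flag, bit) bitwAnd(flag, bit) > 0L

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Reference bases consumed by an alignment (vectorized; fast path for the
# ubiquitous clip/M/clip cigars).
cigar_ref_width <- function(cigar) {
  out <- numeric(length(cigar))
  simple <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cigar)
  out[simple] <- as.numeric(sub("^(?:[0-9]+S)?([0-9]+)M(?:[0-9]+S)?$", "\\1",
                                cigar[simple]))
  for (i in which(!simple)) {
    co <- cigar_ops(cigar[i])
    out[i] <- sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
  }
  out
}

# 1-based inclusive reference end position.
aln_end <- function(aln) aln$pos + cigar_ref_width(aln$cigar) - 1

#' Mean read coverage over an interval
#'
#' Sum of aligned (M) bases overlapping the interval divided by its width,
#' after the standard hygiene filters.
#'
#' @param aln Alignment data.frame.
#' @param interval A [genomic_interval()].
#' @param min_mapq Minimum mapping quality (reads below are discarded).
#' @param drop_dup Exclude duplicate-flagged reads.
#' @return Mean per-base coverage (numeric).
#' @export
mean_coverage <- function(aln, interval, min_mapq = 20L, drop_dup = TRUE) {
  keep <- aln$rname == interval$chrom & aln$mapq >= min_mapq
  if (drop_dup) keep <- keep & !has_flag(aln$flag, FLAG_DUP)
  a <- aln[keep, , drop = FALSE]
  if (!nrow(a)) return(0)
  total <- 0
  # Fast path: single-M cigars with optional soft clips (the common case).
  simple <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", a$cigar)
  if (any(simple)) {
    mlen <- as.numeric(sub("^(?:[0-9]+S)?([0-9]+)M(?:[0-9]+S)?$", "\\1",
                           a$cigar[simple]))
    lo <- pmax(a$pos[simple] - 1, interval$start)
    hi <- pmin(a$pos[simple] - 1 + mlen, interval$end)
    total <- total + sum(pmax(0, hi - lo))
  }
  for (i in which(!simple)) {
    co <- cigar_ops(a$cigar[i])
    rpos <- a$pos[i] - 1  # 0-based
    for (k in seq_len(nrow(co))) {
      if (co$op[k] %in% c("M", "=", "X")) {
        lo <- max(rpos, interval$start); hi <- min(rpos + co$len[k], interval$end)
        if (hi > lo) total <- total + (hi - lo)
      }
      if (co$op[k] %in% c("M", "D", "N", "=", "X")) rpos <- rpos + co$len[k]
    }
  }
  total / gi_width(interval)
}

#' Base pileup over an interval
#'
#' Per-position counts of A/C/G/T/N from aligned (M) bases. Intended for
#' locus-scale intervals (the targeted gene body and hotspot windows), not
#' whole genomes.
#'
#' @param aln Alignment data.frame.
#' @param interval A [genomic_interval()].
#' @param min_mapq Minimum mapping quality.
#' @param drop_dup Exclude duplicate-flagged reads.
#' @return data.frame with `chrom`, `pos` (0-based), `A`, `C`, `G`, `T`,
#'   `N`, `depth`.
#' @export
pileup <- function(aln, interval, min_mapq = 0L, drop_dup = TRUE) {
  w <- gi_width(interval)
  counts <- matrix(0L, nrow = w, ncol = 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  keep <- aln$rname == interval$chrom & aln$mapq >= min_mapq &
    !has_flag(aln$flag, FLAG_SUPP)
  if (drop_dup) keep <- keep & !has_flag(aln$flag, FLAG_DUP)
  a <- aln[keep, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    co <- cigar_ops(a$cigar[i])
    rpos <- a$pos[i] - 1; qpos <- 0L
    for (k in seq_len(nrow(co))) {
      op <- co$op[k]; len <- co$len[k]
      if (op %in% c("M", "=", "X")) {
        lo <- max(rpos, interval$start); hi <- min(rpos + len, interval$end)
        if (hi > lo) {
          offs <- (lo:(hi - 1)) - rpos
          bases <- strsplit(substr(a$seq[i], qpos + min(offs) + 1,
                                   qpos + max(offs) + 1), "")[[1]]
          rows <- (lo:(hi - 1)) - interval$start + 1
          for (m in seq_along(rows)) {
            b <- bases[m]
            if (b %in% colnames(counts)) {
              counts[rows[m], b] <- counts[rows[m], b] + 1L
            }
          }
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      }
    }
  }
  data.frame(chrom = interval$chrom,
             pos = interval$start + seq_len(w) - 1,
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], N = counts[, "N"],
             depth = rowSums(counts),
             stringsAsFactors = FALSE)
}

#' Write / read plain-text SAM
#'
#' @param aln Alignment data.frame (see [alignments]).
#' @param path Output path.
#' @param seqinfo Named vector of chromosome lengths for the `@SQ` header
#'   (optional on write).
#' @export
write_sam <- function(aln, path, seqinfo = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  if (!is.null(seqinfo)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                       as.integer(seqinfo)), con)
  }
  ord <- order(aln$rname, aln$pos)
  a <- aln[ord, , drop = FALSE]
  qual <- vapply(nchar(a$seq), function(n) strrep("I", n), character(1))
  lines <- paste(a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar,
                 a$rnext, a$pnext, a$tlen, a$seq, qual, sep = "\t")
  sa <- !is.na(a$sa) & a$sa != ""
  lines[sa] <- paste0(lines[sa], "\tSA:Z:", a$sa[sa])
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(aln_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  sa <- vapply(fields, function(f) {
    hit <- grep("^SA:Z:", f[-(1:11)], value = TRUE)
    if (length(hit)) sub("^SA:Z:", "", hit[1]) else NA_character_
  }, character(1))
  aln_frame(qname = get(1), flag = as.integer(get(2)), rname = get(3),
            pos = as.integer(get(4)), mapq = as.integer(get(5)),
            cigar = get(6), rnext = get(7), pnext = as.integer(get(8)),
            tlen = as.integer(get(9)), seq = get(10), sa = sa)
}
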