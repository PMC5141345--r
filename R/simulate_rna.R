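#' Simulate spliced RNA-seq alignments against a derivative assembly
#'
#' Transcripts are exon chains on a (possibly rearranged) genome assembly;
#' reads are drawn from the mRNA and emitted as spliced alignments whose
#' N-gaps fall exactly at the transcript's exon boundaries on that
#' assembly. Junction read counts are multinomial in the expression
#' weights. Deterministic in `seed`.
#'
#' @name simulate_rna
NULL

# Derivative-coordinate instances of a source exon (forward-strand pieces).
exon_instances <- function(d, interval) {
  L <- der_length(d)
  pieces <- der_lift_interval(d, 0, L)
  out <- list()
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    if (is.na(p$chrom) || p$chrom != interval$chrom || p$strand != "+") next
    lo <- max(p$start, interval$start); hi <- min(p$end, interval$end)
    if (lo >= hi) next
    out[[length(out) + 1]] <- data.frame(
      dstart = p$dstart + (lo - p$start), dend = p$dstart + (hi - p$start),
      complete = lo == interval$start && hi == interval$end)
  }
  if (!length(out)) {
    return(data.frame(dstart = numeric(0), dend = numeric(0),
                      complete = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$dstart), , drop = FALSE]
}

#' Build a transcript model on a derivative genome
#'
#' @param d A `derivative_chromosome` (or identity derivative for an
#'   unrearranged genome).
#' @param ref Reference `DNAStringSet`.
#' @param exons Exon annotation data.frame (`chrom`, `start`, `end`, `name`).
#' @param chain Character vector of exon names, in transcription order.
#' @param copies Integer vector selecting which derivative copy of each
#'   exon to use (default 1 = lowest coordinate; relevant inside
#'   duplications).
#' @param name Transcript name.
#' @param weight Expression weight.
#' @return list of class `transcript_spec` with `exons` (derivative
#'   coordinates), `mrna`, `chrom`, `weight`.
#' @export
make_transcript <- function(d, ref, exons, chain, copies = NULL,
                            name = "tx", weight = 1) {
  if (is.null(copies)) copies <- rep(1L, length(chain))
  stopifnot(length(copies) == length(chain))
  gseq <- der_sequence(d, ref)
  rows <- list()
  for (i in seq_along(chain)) {
    e <- exons[exons$name == chain[i], , drop = FALSE]
    if (nrow(e) != 1) stop("exon not found in annotation: ", chain[i])
    inst <- exon_instances(d, genomic_interval(e$chrom, e$start, e$end))
    inst <- inst[inst$complete, , drop = FALSE]
    if (nrow(inst) < copies[i]) {
      stop("exon chain not on this genome: ", chain[i],
           " (copy ", copies[i], " absent)")
    }
    rows[[i]] <- data.frame(label = chain[i],
                            dstart = inst$dstart[copies[i]],
                            dend = inst$dend[copies[i]])
  }
  ex <- do.call(rbind, rows)
  if (is.unsorted(ex$dstart)) {
    stop("exon chain is not colinear on the target genome; pick copies ",
         "that follow transcription order")
  }
  mrna <- paste0(substring(gseq, ex$dstart + 1, ex$dend), collapse = "")
  structure(list(name = name, chrom = d$name, exons = ex, mrna = mrna,
                 weight = weight),
            class = "transcript_spec")
}

#' @rdname simulate_rna
#' @param transcripts List of `transcript_spec`s (same target genome).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sample Sample label used in read names.
#' @return Alignment data.frame on the transcripts' genome, coordinate
#'   sorted.
#' @export
simulate_rna_reads <- function(transcripts, config = sim_config(), seed = 1L,
                               sample = "s") {
  rl <- config$read_len_rna
  weights <- vapply(transcripts, function(t) t$weight, numeric(1))
  rows <- list()
  with_seed(seed, {
    npairs <- as.vector(stats::rmultinom(1, config$rna_pairs,
                                         weights / sum(weights)))
    for (ti in seq_along(transcripts)) {
      tx <- transcripts[[ti]]
      n <- npairs[ti]
      if (n < 1) next
      Lm <- nchar(tx$mrna)
      if (Lm < rl) stop("transcript shorter than the read length: ", tx$name)
      flen <- round(stats::rnorm(n, config$rna_insert_mean,
                                 config$rna_insert_sd))
      flen <- pmax(pmin(flen, min(Lm, 400)), rl)
      start <- floor(stats::runif(n, 0, Lm - flen + 1))
      qn <- sprintf("%s_%s_r%06d", sample, tx$name, seq_len(n))
      r1 <- spliced_records(tx, start, start + rl, tx$mrna, FALSE, qn,
                            FLAG_FIRST)
      r2 <- spliced_records(tx, start + flen - rl, start + flen, tx$mrna,
                            TRUE, qn, FLAG_LAST)
      r1$rnext <- r2$rname; r1$pnext <- r2$pos
      r2$rnext <- r1$rname; r2$pnext <- r1$pos
      rows[[length(rows) + 1]] <- rbind(r1, r2)
    }
  })
  aln <- do.call(rbind, rows)
  if (is.null(aln)) return(aln_frame())
  aln$tlen <- 0L
  aln <- aln[order(aln$rname, aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

# Map mRNA-interval reads to spliced alignment rows (M/N cigars).
spliced_records <- function(tx, a, b, mrna, is_mate2, qname, matebit) {
  cum <- c(0, cumsum(tx$exons$dend - tx$exons$dstart))
  n <- length(a)
  e1 <- findInterval(a, cum, rightmost.closed = FALSE)
  e2 <- findInterval(b - 1, cum, rightmost.closed = FALSE)
  rl <- b - a
  flag <- FLAG_PAIRED + FLAG_PROPER + matebit +
    (if (is_mate2) FLAG_REVERSE else FLAG_MREVERSE)
  seqs <- substring(mrna, a + 1, b)

  pos <- integer(n); cig <- character(n)
  simple <- e1 == e2
  pos[simple] <- tx$exons$dstart[e1[simple]] + (a[simple] - cum[e1[simple]]) + 1
  cig[simple] <- paste0(rl[simple], "M")
  for (k in which(!simple)) {
    parts <- character(0)
    for (e in e1[k]:e2[k]) {
      lo <- max(a[k], cum[e]); hi <- min(b[k], cum[e + 1])
      parts <- c(parts, paste0(hi - lo, "M"))
      if (e < e2[k]) {
        gap <- tx$exons$dstart[e + 1] - tx$exons$dend[e]
        parts <- c(parts, paste0(gap, "N"))
      }
    }
    cig[k] <- paste(parts, collapse = "")
    pos[k] <- tx$exons$dstart[e1[k]] + (a[k] - cum[e1[k]]) + 1
  }
  data.frame(qname = qname, flag = flag, rname = tx$chrom,
             pos = as.integer(pos), mapq = 60L, cigar = cig,
             rnext = tx$chrom, pnext = 0L, tlen = 0L, seq = seqs,
             sa = NA_character_, stringsAsFactors = FALSE)
}
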