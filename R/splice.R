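#' Splice-junction bin matrices and rearrangement-dependent junction calls
#'
#' Spliced reads aligned to a derivative assembly are summarized as counts
#' of junctions between ordered exon/intron bins (the heatmap readout),
#' and unique junctions are called against a matched control sample from
#' the same subject: a junction is rearrangement-dependent when it is
#' absent from the control and either crosses a rearrangement seam of the
#' derivative or reaches a minimum read count.
#'
#' @name splice_matrix
NULL

#' Extract splice junctions from spliced alignments
#'
#' A junction observation is retained iff the read maps at least
#' `min_overhang` bases on each side of the N-gap. Positions are 0-based:
#' `donor` is the last aligned base before the gap, `acceptor` the first
#' aligned base after it.
#'
#' @param aln Alignment data.frame with spliced (M/N) cigars.
#' @param min_overhang Minimum aligned bases on each side (default 5,
#'   boundary inclusive).
#' @return list with `junctions` (data.frame chrom, donor, acceptor,
#'   count), `retained_reads`, `discarded_short_overhang`.
#' @export
extract_junctions <- function(aln, min_overhang = 5L) {
  spliced <- grepl("N", aln$cigar, fixed = TRUE)
  if (any(grepl("^\\*$", aln$cigar))) stop("alignments without CIGAR encoding")
  obs <- list(); retained <- 0L; discarded <- 0L
  for (i in which(spliced)) {
    co <- cigar_ops(aln$cigar[i])
    rpos <- aln$pos[i] - 1
    msum <- ifelse(co$op %in% c("M", "=", "X"), co$len, 0L)
    consumes_ref <- co$op %in% c("M", "D", "N", "=", "X")
    for (k in which(co$op == "N")) {
      left <- sum(msum[seq_len(k - 1)])
      right <- sum(msum[seq(k + 1, nrow(co))])
      gap_start <- rpos + sum(co$len[seq_len(k - 1)][consumes_ref[seq_len(k - 1)]])
      if (left >= min_overhang && right >= min_overhang) {
        retained <- retained + 1L
        obs[[length(obs) + 1]] <- data.frame(
          chrom = aln$rname[i], donor = gap_start - 1,
          acceptor = gap_start + co$len[k], stringsAsFactors = FALSE)
      } else discarded <- discarded + 1L
    }
  }
  if (!length(obs)) {
    j <- data.frame(chrom = character(0), donor = numeric(0),
                    acceptor = numeric(0), count = integer(0))
  } else {
    all_obs <- do.call(rbind, obs)
    j <- stats::aggregate(list(count = rep(1L, nrow(all_obs))),
                          by = all_obs[c("chrom", "donor", "acceptor")],
                          FUN = sum)
    j <- j[order(j$chrom, j$donor, j$acceptor), , drop = FALSE]
    rownames(j) <- NULL
  }
  list(junctions = j, retained_reads = retained,
       discarded_short_overhang = discarded)
}

#' Exon/intron bins of a derivative architecture
#'
#' Creates one bin per annotated exon instance on the derivative (exons
#' inside duplicated regions yield one bin per copy, suffixed
#' `" (copy k)"`), with intron bins filling the gaps and flank bins at the
#' ends, so the bins tile the derivative without overlap.
#'
#' @param d A `derivative_chromosome`.
#' @param exons Exon annotation data.frame (`chrom`, `start`, `end`,
#'   `name`) in source coordinates.
#' @return data.frame with `label`, `dstart`, `dend`, `kind`
#'   ("exon"/"intron"/"flank").
#' @export
make_bins <- function(d, exons) {
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    inst <- exon_instances(d, genomic_interval(exons$chrom[i],
                                               exons$start[i],
                                               exons$end[i]))
    for (k in seq_len(nrow(inst))) {
      lab <- exons$name[i]
      if (nrow(inst) > 1 && k > 1) lab <- sprintf("%s (copy %d)", lab, k)
      rows[[length(rows) + 1]] <- data.frame(label = lab,
                                             dstart = inst$dstart[k],
                                             dend = inst$dend[k],
                                             kind = "exon",
                                             stringsAsFactors = FALSE)
    }
  }
  ex <- do.call(rbind, rows)
  ex <- ex[order(ex$dstart), , drop = FALSE]
  if (any(ex$dstart[-1] < ex$dend[-nrow(ex)])) {
    stop("overlapping exon instances; bins must tile without overlap")
  }
  out <- list()
  L <- der_length(d)
  cursor <- 0; intron_i <- 0L
  for (i in seq_len(nrow(ex))) {
    if (ex$dstart[i] > cursor) {
      lab <- if (cursor == 0) "5'-flank" else {
        intron_i <- intron_i + 1L
        sprintf("intron %d", intron_i)
      }
      out[[length(out) + 1]] <- data.frame(label = lab, dstart = cursor,
                                           dend = ex$dstart[i],
                                           kind = ifelse(cursor == 0, "flank",
                                                         "intron"),
                                           stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- ex[i, ]
    cursor <- ex$dend[i]
  }
  if (cursor < L) {
    out[[length(out) + 1]] <- data.frame(label = "3'-flank", dstart = cursor,
                                         dend = L, kind = "flank",
                                         stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  if (anyDuplicated(bins$label)) stop("bin labels are not unique")
  rownames(bins) <- NULL
  bins
}

#' Splice-junction bin matrix (the heatmap computation)
#'
#' Each retained junction observation increments the cell
#' (bin of donor, bin of acceptor); counts are order-sensitive (donor ->
#' acceptor, transcription on the derivative forward strand). Observations
#' on other chromosomes or outside the bins are tallied separately.
#'
#' @param junction_set Output of [extract_junctions()].
#' @param bins Bin data.frame from [make_bins()].
#' @param chrom Derivative chromosome name the bins refer to.
#' @return list of class `splice_junction_matrix`: `counts` (labelled
#'   square matrix), `bins`, `retained_reads`,
#'   `discarded_short_overhang`, `out_of_bin`.
#' @export
junction_matrix <- function(junction_set, bins, chrom) {
  j <- junction_set$junctions
  n <- nrow(bins)
  counts <- matrix(0L, n, n, dimnames = list(donor = bins$label,
                                             acceptor = bins$label))
  out_of_bin <- 0L
  assign_bin <- function(pos) {
    i <- findInterval(pos, bins$dstart)
    ifelse(i >= 1 & pos < bins$dend[pmax(i, 1)], i, NA_integer_)
  }
  for (i in seq_len(nrow(j))) {
    if (j$chrom[i] != chrom) { out_of_bin <- out_of_bin + j$count[i]; next }
    bi <- assign_bin(j$donor[i]); bj <- assign_bin(j$acceptor[i])
    if (is.na(bi) || is.na(bj)) { out_of_bin <- out_of_bin + j$count[i]; next }
    counts[bi, bj] <- counts[bi, bj] + j$count[i]
  }
  structure(list(counts = counts, bins = bins,
                 retained_reads = junction_set$retained_reads,
                 discarded_short_overhang = junction_set$discarded_short_overhang,
                 out_of_bin = out_of_bin),
            class = "splice_junction_matrix")
}

#' @export
print.splice_junction_matrix <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("splice junction matrix:", nrow(x$counts), "bins,", sum(x$counts),
      "binned observations in", nz, "cells;", x$out_of_bin, "out-of-bin\n")
  invisible(x)
}

#' Write the matrix as labelled TSV
#' @param m A `splice_junction_matrix`.
#' @param path Output path.
#' @export
write_junction_matrix <- function(m, path) {
  utils::write.table(m$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Call rearrangement-dependent splice junctions against a matched control
#'
#' @param case,control Outputs of [extract_junctions()] for the tumour and
#'   its matched control mapped to the same derivative assembly.
#' @param d The `derivative_chromosome`.
#' @param min_reads Minimum case read count for a non-seam-crossing novel
#'   junction to be called rearrangement-dependent.
#' @return data.frame of junction calls: `donor`, `acceptor`,
#'   `count_case`, `count_control`, `crosses_seam`, `status` in
#'   {canonical, novel, rearrangement_dependent}.
#' @export
call_rearrangement_dependent <- function(case, control, d, min_reads = 3L) {
  cj <- case$junctions[case$junctions$chrom == d$name, , drop = FALSE]
  kj <- control$junctions[control$junctions$chrom == d$name, , drop = FALSE]
  seam_pos <- der_seams(d)$dpos
  key <- function(df) paste(df$donor, df$acceptor)
  ctrl_count <- stats::setNames(kj$count, key(kj))
  out <- cj
  out$count_case <- cj$count
  out$count_control <- as.integer(ifelse(is.na(ctrl_count[key(cj)]), 0L,
                                         ctrl_count[key(cj)]))
  out$crosses_seam <- vapply(seq_len(nrow(cj)), function(i) {
    any(seam_pos > cj$donor[i] & seam_pos <= cj$acceptor[i])
  }, logical(1))
  out$status <- ifelse(out$count_control > 0, "canonical",
                ifelse(out$crosses_seam | out$count_case >= min_reads,
                       "rearrangement_dependent", "novel"))
  out$count <- NULL; out$chrom <- NULL
  rownames(out) <- NULL
  out
}
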