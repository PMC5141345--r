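#' Simulate aligned paired-end DNA reads for a sample
#'
#' Reads are emitted pre-aligned: fragments are drawn from each clone's
#' rearranged genome (built with [build_derivative()] from the clone's
#' junctions) and mapped back to source coordinates through the
#' derivative's own coordinate map. Read pairs straddling an implanted
#' junction therefore appear as discordant pairs, and reads crossing it as
#' split alignments with correct soft clips and SA tags. Per-base coverage
#' scales with `coverage * fraction * copy_number / 2` over the amplifiable
#' locus region and `coverage * fraction` elsewhere. Deterministic in
#' `seed`.
#'
#' @param sample A [sample_spec()].
#' @param ref A reference bundle from [make_reference()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return list with `aln` (alignment data.frame, coordinate-sorted) and
#'   `truth` (expected junction VAFs, SNV VAFs, mean locus copy number,
#'   fragment counts).
#' @export
simulate_dna <- function(sample, ref, config = sim_config(), seed = 1L) {
  stopifnot(inherits(sample, "sample_spec"))
  rl <- config$read_len_dna
  chrlens <- stats::setNames(Biostrings::width(ref$seqs), names(ref$seqs))
  windows <- lapply(names(chrlens), function(ch) {
    genomic_interval(ch, 0, chrlens[[ch]])
  })
  names(windows) <- names(chrlens)

  rows <- list()
  with_seed(seed, {
    for (ci in seq_along(sample$clones)) {
      cl <- sample$clones[[ci]]
      if (cl$fraction <= 0) next
      derA <- build_derivative(cl$junctions, windows,
                               name = paste0("cl", ci, "_A"))
      derB <- derivative_new(windows["chrB"], name = paste0("cl", ci, "_B"),
                             primary = "chrB")
      for (g in list(derA, derB)) {
        gseq <- der_sequence(g, ref$seqs)
        gseq <- mutate_hom_snvs(g, gseq, cl)
        wp <- weight_profile(g, ref$gene, cl$locus_cn)
        weff <- sum((wp$dend - wp$dstart) * wp$w)
        nfrag <- round(weff * config$coverage * cl$fraction / (2 * rl))
        if (nfrag < 1) next
        rows[[length(rows) + 1]] <- simulate_clone_reads(
          g, gseq, wp, nfrag, cl, config,
          qprefix = paste0(sample$name, "_c", ci, "_", g$name))
      }
    }
  })
  aln <- do.call(rbind, rows)
  aln <- aln[order(aln$rname, aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  list(aln = aln, truth = dna_truth(sample))
}

# Expected downstream quantities implied by the clone mixture.
dna_truth <- function(sample) {
  fr <- vapply(sample$clones, function(cl) cl$fraction, numeric(1))
  cn <- vapply(sample$clones, function(cl) cl$locus_cn, numeric(1))
  total_cn <- sum(fr * cn)
  jkeys <- unique(unlist(lapply(sample$clones, function(cl) {
    vapply(cl$junctions, format_bfj, character(1))
  })))
  jvaf <- vapply(jkeys, function(k) {
    carrier <- vapply(sample$clones, function(cl) {
      k %in% vapply(cl$junctions, format_bfj, character(1))
    }, logical(1))
    sum(fr[carrier] * cn[carrier]) / total_cn
  }, numeric(1))
  snvs <- list()
  for (cl in sample$clones) {
    if (is.null(cl$snvs)) next
    for (i in seq_len(nrow(cl$snvs))) snvs[[length(snvs) + 1]] <- cl$snvs[i, ]
  }
  snv_vaf <- NULL
  if (length(snvs)) {
    snv_df <- unique(do.call(rbind, snvs)[, c("pos", "ref", "alt")])
    snv_vaf <- vapply(seq_len(nrow(snv_df)), function(i) {
      num <- 0
      for (k in seq_along(sample$clones)) {
        cl <- sample$clones[[k]]
        if (is.null(cl$snvs)) next
        hit <- cl$snvs$pos == snv_df$pos[i] & cl$snvs$alt == snv_df$alt[i]
        if (any(hit)) {
          af <- ifelse(cl$snvs$zygosity[hit][1] == "hom", 1, 0.5)
          num <- num + fr[k] * cn[k] * af
        }
      }
      num / total_cn
    }, numeric(1))
    snv_df$expected_vaf <- snv_vaf
    snv_vaf <- snv_df
  }
  list(mean_locus_cn = total_cn,
       junction_vaf = stats::setNames(jvaf, jkeys),
       snv_vaf = snv_vaf)
}

mutate_hom_snvs <- function(d, gseq, cl) {
  if (is.null(cl$snvs)) return(gseq)
  hom <- cl$snvs[cl$snvs$zygosity == "hom", , drop = FALSE]
  for (i in seq_len(nrow(hom))) {
    for (p in der_lift_back(d, "chrA", hom$pos[i])) {
      src <- der_lift(d, p)
      b <- if (src$strand == "+") hom$alt[i] else comp_base(hom$alt[i])
      substr(gseq, p + 1, p + 1) <- b
    }
  }
  gseq
}

# Piecewise-constant sampling weight along the derivative: copy-number
# scaling cn/2 over derivative bases lifting into the amplifiable region.
weight_profile <- function(d, amp, cn) {
  L <- der_length(d)
  pieces <- der_lift_interval(d, 0, L)
  cuts <- c(0, L)
  amp_ranges <- list()
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    if (is.na(p$chrom) || p$chrom != amp$chrom) next
    lo <- max(p$start, amp$start); hi <- min(p$end, amp$end)
    if (lo >= hi) next
    dr <- if (p$strand == "+") {
      c(p$dstart + (lo - p$start), p$dstart + (hi - p$start))
    } else {
      c(p$dstart + (p$end - hi), p$dstart + (p$end - lo))
    }
    cuts <- c(cuts, dr)
    amp_ranges[[length(amp_ranges) + 1]] <- dr
  }
  cuts <- sort(unique(cuts))
  out <- data.frame(dstart = cuts[-length(cuts)], dend = cuts[-1])
  out$w <- 1
  for (r in amp_ranges) {
    sel <- out$dstart >= r[1] & out$dend <= r[2]
    out$w[sel] <- cn / 2
  }
  out[out$dend > out$dstart, , drop = FALSE]
}

simulate_clone_reads <- function(d, gseq, wp, nfrag, cl, config, qprefix) {
  rl <- config$read_len_dna
  L <- der_length(d)
  idx <- sample.int(nrow(wp), nfrag, replace = TRUE,
                    prob = wp$w * (wp$dend - wp$dstart))
  start <- floor(stats::runif(nfrag, min = wp$dstart[idx],
                              max = wp$dend[idx]))
  # truncate the fragment distribution at mean + 4 sd, the same bound the
  # pairing logic uses for insert-size concordance, so an unrearranged
  # genome yields no discordant pairs by chance
  flen <- round(stats::rnorm(nfrag, config$insert_mean, config$insert_sd))
  flen <- pmax(pmin(flen, config$insert_mean + 4 * config$insert_sd),
               rl + 20)
  flen <- pmin(flen, L - start)
  keep <- flen >= rl + 1
  start <- start[keep]; flen <- flen[keep]
  n <- length(start)
  if (!n) return(NULL)
  qname <- sprintf("%s_f%06d", qprefix, seq_len(n))

  a1 <- start; b1 <- start + rl
  a2 <- start + flen - rl; b2 <- start + flen
  fw1 <- substring(gseq, a1 + 1, b1)
  fw2 <- substring(gseq, a2 + 1, b2)

  # Heterozygous SNVs: allele drawn per fragment; substitution applied on
  # the derivative-forward read strings before orientation transforms.
  if (!is.null(cl$snvs)) {
    het <- cl$snvs[cl$snvs$zygosity == "het", , drop = FALSE]
    for (i in seq_len(nrow(het))) {
      for (p in der_lift_back(d, "chrA", het$pos[i])) {
        src <- der_lift(d, p)
        b <- if (src$strand == "+") het$alt[i] else comp_base(het$alt[i])
        carrier <- stats::runif(n) < 0.5
        in1 <- carrier & p >= a1 & p < b1
        substr(fw1[in1], p - a1[in1] + 1, p - a1[in1] + 1) <- b
        in2 <- carrier & p >= a2 & p < b2
        substr(fw2[in2], p - a2[in2] + 1, p - a2[in2] + 1) <- b
      }
    }
  }
  if (config$error_rate > 0) {
    fw1 <- sprinkle_errors(fw1, config$error_rate)
    fw2 <- sprinkle_errors(fw2, config$error_rate)
  }

  r1 <- map_reads(d, a1, b1, fw1, ro = "+", qname = qname,
                  matebit = FLAG_FIRST)
  r2 <- map_reads(d, a2, b2, fw2, ro = "-", qname = qname,
                  matebit = FLAG_LAST)
  pair_up(r1, r2, config)
}

sprinkle_errors <- function(seqs, rate) {
  nc <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), nc, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(nc[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Map reads (derivative intervals) to source alignment records. Returns a
# data.frame of alignment rows plus a `frag` column (fragment index) and
# `primary` flag column for pairing.
map_reads <- function(d, a, b, fw, ro, qname, matebit) {
  segs <- d$segments
  off <- der_offsets(segs)
  i1 <- findInterval(a, off)
  i2 <- findInterval(b - 1, off)
  n <- length(a)
  simple <- i1 == i2 & is.na(segs$ins[i1])
  rl <- b - a

  out <- list()
  if (any(simple)) {
    i <- i1[simple]
    ps <- segs$strand[i]
    src_start <- ifelse(ps == "+", segs$start[i] + (a[simple] - off[i]),
                        segs$end[i] - (b[simple] - off[i]))
    strand <- ifelse(ps == "+", ro, flip_strand(ro))
    seqv <- fw[simple]
    neg <- ps == "-"
    if (any(neg)) seqv[neg] <- revcomp_vec(seqv[neg])
    out[[1]] <- data.frame(
      qname = qname[simple], frag = which(simple), primary = TRUE,
      flag = FLAG_PAIRED + matebit +
        ifelse(strand == "-", FLAG_REVERSE, 0L),
      rname = segs$chrom[i], pos = as.integer(src_start + 1), mapq = 60L,
      cigar = paste0(rl[simple], "M"), seq = seqv, sa = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (k in which(!simple)) {
    pieces <- der_lift_interval(d, a[k], b[k])
    aligned <- pieces[is.na(pieces$ins), , drop = FALSE]
    if (!nrow(aligned)) next
    recs <- lapply(seq_len(nrow(aligned)), function(j) {
      p <- aligned[j, ]
      lclip <- if (p$strand == "+") p$dstart - a[k] else b[k] - p$dend
      M <- p$dend - p$dstart
      rclip <- rl[k] - M - lclip
      cig <- paste0(if (lclip > 0) paste0(lclip, "S"), M, "M",
                    if (rclip > 0) paste0(rclip, "S"))
      strand <- if (p$strand == "+") ro else flip_strand(ro)
      seqv <- if (p$strand == "+") fw[k] else revcomp_chr(fw[k])
      data.frame(qname = qname[k], frag = k, primary = FALSE,
                 flag = FLAG_PAIRED + matebit +
                   if (strand == "-") FLAG_REVERSE else 0L,
                 rname = p$chrom, pos = as.integer(p$start + 1), mapq = 60L,
                 cigar = cig, seq = seqv, sa = NA_character_,
                 stringsAsFactors = FALSE)
    })
    widths <- aligned$dend - aligned$dstart
    pri <- which.max(widths)
    satag <- vapply(seq_along(recs), function(j) {
      others <- setdiff(seq_along(recs), j)
      paste0(vapply(others, function(o) {
        r <- recs[[o]]
        paste(r$rname, r$pos, if (has_flag(r$flag, FLAG_REVERSE)) "-" else "+",
              r$cigar, r$mapq, 0, sep = ",")
      }, character(1)), ";", collapse = "")
    }, character(1))
    for (j in seq_along(recs)) {
      recs[[j]]$sa <- satag[j]
      recs[[j]]$primary <- j == pri
      if (j != pri) recs[[j]]$flag <- recs[[j]]$flag + FLAG_SUPP
    }
    out[[length(out) + 1]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fill in mate fields, template length and proper-pair flags from the two
# primary alignments of each fragment.
pair_up <- function(r1, r2, config) {
  both <- rbind(r1, r2)
  p1 <- r1[r1$primary, ]; p1 <- p1[order(p1$frag), ]
  p2 <- r2[r2$primary, ]; p2 <- p2[order(p2$frag), ]
  stopifnot(identical(p1$frag, p2$frag))
  mate_of <- function(df, mate) {
    i <- match(df$frag, mate$frag)
    list(rname = mate$rname[i], pos = mate$pos[i],
         rev = has_flag(mate$flag[i], FLAG_REVERSE),
         end = mate$pos[i] + cigar_ref_width(mate$cigar[i]) - 1)
  }
  m_for_1 <- mate_of(p1, p2)  # mate info indexed like p1
  maxins <- config$insert_mean + 4 * config$insert_sd
  same <- p1$rname == m_for_1$rname
  span <- pmax(m_for_1$end, p1$pos + cigar_ref_width(p1$cigar) - 1) -
    pmin(p1$pos, m_for_1$pos) + 1
  fr <- xor(has_flag(p1$flag, FLAG_REVERSE), m_for_1$rev)
  proper <- same & fr & span <= maxins
  proper_frag <- p1$frag[proper]

  fill <- function(df, mate_pri) {
    i <- match(df$frag, mate_pri$frag)
    df$rnext <- mate_pri$rname[i]
    df$pnext <- mate_pri$pos[i]
    mrev <- has_flag(mate_pri$flag[i], FLAG_REVERSE)
    df$flag <- df$flag + ifelse(mrev, FLAG_MREVERSE, 0L) +
      ifelse(df$frag %in% proper_frag, FLAG_PROPER, 0L)
    df
  }
  r1 <- fill(r1, p2); r2 <- fill(r2, p1)
  both <- rbind(r1, r2)
  tl <- ifelse(both$rnext == both$rname,
               abs(both$pnext - both$pos) + config$read_len_dna, 0L)
  both$tlen <- as.integer(tl)
  both$frag <- NULL; both$primary <- NULL
  both[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
           "pnext", "tlen", "seq", "sa")]
}

#' Write reads as FASTQ
#'
#' Emits the sequenced (instrument-orientation) reads of the primary
#' alignments as a two-file pair.
#'
#' @param aln Alignment data.frame.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq <- function(aln, prefix) {
  for (mate in 1:2) {
    bit <- if (mate == 1) FLAG_FIRST else FLAG_LAST
    sel <- has_flag(aln$flag, bit) & !has_flag(aln$flag, FLAG_SUPP)
    a <- aln[sel, , drop = FALSE]
    a <- a[order(a$qname), , drop = FALSE]
    seqs <- a$seq
    rev <- has_flag(a$flag, FLAG_REVERSE)
    if (any(rev)) seqs[rev] <- revcomp_vec(seqs[rev])
    lines <- as.vector(rbind(paste0("@", a$qname, "/", mate), seqs, "+",
                             vapply(nchar(seqs), strrep, character(1),
                                    x = "I")))
    writeLines(lines, sprintf("%s_%d.fastq", prefix, mate))
  }
  invisible(prefix)
}
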