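#' AR-GSR detection from dual call sets and alignment evidence
#'
#' A genomic structural rearrangement of the locus (GSR) is defined as a
#' structural variant supported by both configured callers, with at least
#' one breakend inside the gene body and at least `min_pe` supporting
#' discordant read pairs and `min_sr` supporting split reads. A
#' sample-level cDNA-contamination rule demotes samples whose candidate
#' set consists exclusively of deletions coinciding with annotated splice
#' donor/acceptor pairs.
#'
#' Call sets are data.frames with columns `caller`, `chrom1`, `pos1`,
#' `orient1`, `chrom2`, `pos2`, `orient2`, `svclass` and optionally `qual`
#' and `precise` (0-based positions).
#'
#' @name gsr_detection
NULL

#' Build a caller-style call-set data.frame from junctions
#'
#' @param junctions List of [bfj()]s.
#' @param caller Caller label.
#' @param precise Are positions split-read precise?
#' @export
callset_from_junctions <- function(junctions, caller, precise = TRUE) {
  if (!length(junctions)) {
    return(data.frame(caller = character(0), chrom1 = character(0),
                      pos1 = numeric(0), orient1 = character(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      orient2 = character(0), svclass = character(0),
                      qual = numeric(0), precise = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(junctions, function(j) {
    data.frame(caller = caller, chrom1 = j$left$chrom, pos1 = j$left$pos,
               orient1 = j$left$orient, chrom2 = j$right$chrom,
               pos2 = j$right$pos, orient2 = j$right$orient,
               svclass = j$svclass, qual = 100, precise = precise,
               stringsAsFactors = FALSE)
  }))
}

row_junction <- function(row, inserted_seq = "") {
  bfj(breakend(row$chrom1, row$pos1, row$orient1),
      breakend(row$chrom2, row$pos2, row$orient2),
      inserted_seq = inserted_seq)
}

check_sorted <- function(aln) {
  if (any(is.na(aln$mapq))) stop("mapping-quality field missing from alignments")
  ok <- all(tapply(aln$pos, aln$rname, function(p) !is.unsorted(p)))
  if (!ok) stop("alignment stream is not coordinate-sorted")
  invisible(TRUE)
}

#' Count read-pair and split-read support for a junction
#'
#' Paired-end support counts read pairs whose primary alignments flank the
#' two breakends in orientations consistent with the junction and whose
#' pairing is discordant; split-read support counts reads with a
#' primary/supplementary split placing the breakpoint within `tol` bp of
#' both breakends. Reads with mapping quality below `min_mapq` and
#' duplicate-flagged reads are excluded.
#'
#' @param junction A [bfj()].
#' @param aln Coordinate-sorted alignment data.frame.
#' @param tol Breakpoint tolerance (bp) for split-read matching.
#' @param flank_window Maximum distance (bp) from a breakend at which a
#'   flanking mate may start.
#' @param min_mapq Mapping-quality cutoff.
#' @return Named integer vector `c(pe = ..., sr = ...)`.
#' @export
extract_support <- function(junction, aln, tol = 10L, flank_window = 500L,
                            min_mapq = 20L) {
  s <- support_sets(junction, aln, tol = tol, flank_window = flank_window,
                    min_mapq = min_mapq)
  c(pe = length(s$pe_qnames), sr = length(s$sr_keys))
}

# Internal workhorse: returns the supporting read-pair and split-read
# identifier sets so that VAF estimation can deduplicate fragments.
support_sets <- function(junction, aln, tol = 10L, flank_window = 500L,
                         min_mapq = 20L) {
  check_sorted(aln)
  keep <- aln$mapq >= min_mapq & !has_flag(aln$flag, FLAG_DUP)
  a <- aln[keep, , drop = FALSE]
  if (!nrow(a)) {
    return(list(pe_qnames = character(0), sr_keys = character(0),
                sr_qnames = character(0)))
  }
  L <- junction$left; R <- junction$right
  pos0 <- a$pos - 1
  end0 <- pos0 + cigar_ref_width(a$cigar) - 1
  rev <- has_flag(a$flag, FLAG_REVERSE)

  # split reads: any two alignment pieces of the same read matching the two
  # breakend sides at clip precision
  split <- !is.na(a$sa) & a$sa != ""
  # donor side: the piece's aligned span terminates at the breakend (at its
  # high end for "+", low end for "-"); acceptor side: the span begins there
  left_side <- if (L$orient == "+") abs(end0 - L$pos) <= tol else
    abs(pos0 - L$pos) <= tol
  right_side <- if (R$orient == "+") abs(pos0 - R$pos) <= tol else
    abs(end0 - R$pos) <= tol
  lm <- split & a$rname == L$chrom & left_side
  rm_ <- split & a$rname == R$chrom & right_side
  key <- paste(a$qname, has_flag(a$flag, FLAG_FIRST))
  sr_keys <- intersect(unique(key[lm]), unique(key[rm_]))

  # discordant flanking pairs (primary alignments only)
  pri <- !has_flag(a$flag, FLAG_SUPP)
  left_flank <- pri & a$rname == L$chrom &
    (if (L$orient == "+") {
      !rev & end0 >= L$pos - flank_window & end0 <= L$pos + tol
    } else {
      rev & pos0 >= L$pos - tol & pos0 <= L$pos + flank_window
    })
  right_flank <- pri & a$rname == R$chrom &
    (if (R$orient == "+") {
      rev & pos0 >= R$pos - tol & pos0 <= R$pos + flank_window
    } else {
      !rev & end0 >= R$pos - flank_window & end0 <= R$pos + tol
    })
  discordant <- !has_flag(a$flag, FLAG_PROPER)
  pe_q <- intersect(unique(a$qname[left_flank & discordant]),
                    unique(a$qname[right_flank & discordant]))
  list(pe_qnames = pe_q, sr_keys = sr_keys,
       sr_qnames = unique(a$qname[key %in% sr_keys]))
}

#' Merge two structural-variant call sets into consensus candidates
#'
#' A pair of calls merges iff they come from the two different callers,
#' share the chromosome pair and class, and both breakend distances are at
#' most `max_dist` (inclusive). Matching is one-to-one, greedy by smallest
#' summed breakend distance with deterministic tie-breaking by coordinate;
#' consensus coordinates come from the split-read-precise call if exactly
#' one is flagged precise, else from `set_a`. Unmatched calls are dropped.
#'
#' @param set_a,set_b Call-set data.frames (see [gsr_detection]).
#' @param max_dist Breakend merge distance in bp (default 1 kb).
#' @return data.frame of consensus candidates with support columns
#'   initialized to NA and `status = "candidate"`.
#' @export
merge_callsets <- function(set_a, set_b, max_dist = 1000L) {
  callers <- unique(c(set_a$caller, set_b$caller))
  if (length(callers) > 2L) {
    stop("more than two caller labels present: ", paste(callers, collapse = ", "))
  }
  empty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                      orient1 = character(0), chrom2 = character(0),
                      pos2 = numeric(0), orient2 = character(0),
                      svclass = character(0), pe_support = integer(0),
                      sr_support = integer(0), in_gene_body = logical(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (!nrow(set_a) || !nrow(set_b)) return(empty)
  pairs <- list()
  for (i in seq_len(nrow(set_a))) for (j in seq_len(nrow(set_b))) {
    if (set_a$chrom1[i] != set_b$chrom1[j] ||
        set_a$chrom2[i] != set_b$chrom2[j] ||
        set_a$svclass[i] != set_b$svclass[j]) next
    d1 <- abs(set_a$pos1[i] - set_b$pos1[j])
    d2 <- abs(set_a$pos2[i] - set_b$pos2[j])
    if (d1 > max_dist || d2 > max_dist) next
    pairs[[length(pairs) + 1]] <- data.frame(i = i, j = j, total = d1 + d2)
  }
  if (!length(pairs)) return(empty)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$total, set_a$pos1[pairs$i], set_b$pos1[pairs$j]), ,
                 drop = FALSE]
  used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pa <- isTRUE(set_a$precise[i]); pb <- isTRUE(set_b$precise[j])
    src <- if (pb && !pa) set_b[j, ] else set_a[i, ]
    out[[length(out) + 1]] <- data.frame(
      chrom1 = src$chrom1, pos1 = src$pos1, orient1 = src$orient1,
      chrom2 = src$chrom2, pos2 = src$pos2, orient2 = src$orient2,
      svclass = src$svclass, pe_support = NA_integer_,
      sr_support = NA_integer_, in_gene_body = NA,
      status = "candidate", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom1, res$pos1, res$chrom2, res$pos2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Attach read support to candidates
#'
#' @param candidates Candidate data.frame from [merge_callsets()].
#' @param aln Alignment data.frame.
#' @param ... Passed to [extract_support()].
#' @export
add_support <- function(candidates, aln, ...) {
  for (i in seq_len(nrow(candidates))) {
    s <- extract_support(row_junction(candidates[i, ]), aln, ...)
    candidates$pe_support[i] <- s[["pe"]]
    candidates$sr_support[i] <- s[["sr"]]
  }
  candidates
}

#' Validate candidates by gene body and support thresholds
#'
#' @param candidates Candidate data.frame with support columns filled.
#' @param gene_body A [genomic_interval()]; defaults to the AR gene body
#'   when the bundled hg19 annotation is intended.
#' @param min_pe,min_sr Support thresholds ("at least ten" each).
#' @return The data.frame with `in_gene_body` set and `status` updated to
#'   "validated" or "filtered".
#' @export
filter_candidates <- function(candidates, gene_body = ar_gene_body(),
                              min_pe = 10L, min_sr = 10L) {
  if (!nrow(candidates)) return(candidates)
  ingb <- gi_contains(gene_body, candidates$chrom1, candidates$pos1) |
    gi_contains(gene_body, candidates$chrom2, candidates$pos2)
  candidates$in_gene_body <- ingb
  pass <- ingb & candidates$pe_support >= min_pe &
    candidates$sr_support >= min_sr
  candidates$status <- ifelse(pass, "validated", "filtered")
  candidates
}

#' Flag samples contaminated with spliced cDNA
#'
#' A candidate is splice-coincident iff it is a deletion whose left
#' breakend lies within `tol` bp of an annotated exon end (splice donor)
#' and whose right breakend lies within `tol` bp of an annotated exon
#' start (acceptor) — the footprint a reverse-transcribed mRNA leaves when
#' sequenced as DNA. The sample is flagged contaminated iff it has at
#' least one candidate and every candidate is splice-coincident; flagged
#' samples are reported GSR-negative.
#'
#' @param candidates Candidate data.frame for one sample.
#' @param exons Exon annotation data.frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param tol Splice-site coincidence tolerance (bp).
#' @return list with `contaminated` flag and the data.frame gaining a
#'   `splice_coincident` column.
#' @export
flag_cdna_contamination <- function(candidates, exons, tol = 5L) {
  if (!nrow(candidates)) {
    candidates$splice_coincident <- logical(0)
    return(list(contaminated = FALSE, candidates = candidates))
  }
  sc <- vapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    if (r$svclass != "deletion") return(FALSE)
    donor <- any(exons$chrom == r$chrom1 & abs((exons$end - 1) - r$pos1) <= tol)
    acceptor <- any(exons$chrom == r$chrom2 & abs(exons$start - r$pos2) <= tol)
    donor && acceptor
  }, logical(1))
  candidates$splice_coincident <- sc
  list(contaminated = all(sc), candidates = candidates)
}

#' Full per-sample GSR detection
#'
#' Consensus merge, support extraction, gene-body and support filtering,
#' and the contamination rule, in one call.
#'
#' @param set_a,set_b Caller call sets.
#' @param aln Alignments for the sample.
#' @param gene_body Gene-body interval.
#' @param exons Exon annotation (for the contamination rule); NULL skips it.
#' @param sample Sample label attached to the output.
#' @param min_pe,min_sr,max_dist,tol See the stage functions.
#' @return list(events, contaminated, gsr_positive).
#' @export
detect_gsrs <- function(set_a, set_b, aln, gene_body = ar_gene_body(),
                        exons = NULL, sample = NA_character_,
                        min_pe = 10L, min_sr = 10L, max_dist = 1000L,
                        tol = 10L) {
  cand <- merge_callsets(set_a, set_b, max_dist = max_dist)
  cand <- add_support(cand, aln, tol = tol)
  cand <- filter_candidates(cand, gene_body, min_pe = min_pe, min_sr = min_sr)
  contaminated <- FALSE
  if (!is.null(exons) && nrow(cand)) {
    flagged <- flag_cdna_contamination(cand[cand$status == "validated", ,
                                            drop = FALSE], exons)
    contaminated <- flagged$contaminated && nrow(flagged$candidates) > 0
  }
  cand$sample <- rep(sample, nrow(cand))
  n_valid <- sum(cand$status == "validated")
  list(events = cand, contaminated = contaminated,
       gsr_positive = !contaminated && n_valid > 0)
}
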