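#' Derivative chromosomes
#'
#' A derivative chromosome is an ordered list of oriented reference segments
#' (plus any non-templated inserted sequences at seams) representing a
#' rearranged allele. It carries a bidirectional coordinate map between
#' derivative and source coordinates, and a masking list of the source
#' windows it was built from, so that reads can be forced to map to the
#' derivative in a combined reference.
#'
#' Segments are rows of a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open source coordinates), `strand` ("+"/"-"; "-" segments
#' are reverse-complemented on assembly) and `ins` (NA, or the inserted
#' sequence for insertion rows, which have `chrom = NA`).
#'
#' @name derivative
NULL

seg_row <- function(chrom, start, end, strand = "+", ins = NA_character_) {
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             strand = strand, ins = ins, stringsAsFactors = FALSE)
}

ins_row <- function(seq) seg_row(NA_character_, 0, nchar(seq), "+", seq)

seg_widths <- function(segs) segs$end - segs$start

#' Create an empty derivative over source windows
#'
#' @param windows Named list of [genomic_interval()]s, one per source
#'   chromosome that may contribute segments. The derivative starts as the
#'   `primary` window; further windows are drawn in by translocations.
#' @param name Derivative chromosome name.
#' @param primary Chromosome whose window seeds the derivative (default: the
#'   first window).
#' @return A `derivative_chromosome`.
#' @export
derivative_new <- function(windows, name = "der1", primary = NULL) {
  if (inherits(windows, "genomic_interval")) {
    windows <- stats::setNames(list(windows), windows$chrom)
  }
  stopifnot(length(windows) >= 1, !is.null(names(windows)))
  if (is.null(primary)) primary <- names(windows)[1]
  w <- windows[[primary]]
  structure(list(name = name,
                 segments = seg_row(w$chrom, w$start, w$end),
                 windows = windows,
                 mask = list(w)),
            class = "derivative_chromosome")
}

#' @export
print.derivative_chromosome <- function(x, ...) {
  cat("derivative chromosome '", x$name, "': ", nrow(x$segments),
      " segment(s), length ", der_length(x), " bp\n", sep = "")
  invisible(x)
}

#' @rdname derivative
#' @param d A `derivative_chromosome`.
#' @export
der_length <- function(d) sum(seg_widths(d$segments))

der_offsets <- function(segs) c(0, cumsum(seg_widths(segs)))

# Extract derivative interval [a, b) as a segment data.frame.
der_slice <- function(d, a, b) {
  segs <- d$segments
  off <- der_offsets(segs)
  stopifnot(a >= 0, b <= off[length(off)], a <= b)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s0 <- off[i]; s1 <- off[i + 1]
    lo <- max(a, s0); hi <- min(b, s1)
    if (lo >= hi) next
    r <- segs[i, , drop = FALSE]
    if (r$strand == "+" || !is.na(r$ins)) {
      r$start <- segs$start[i] + (lo - s0)
      r$end <- segs$start[i] + (hi - s0)
      if (!is.na(r$ins)) r$ins <- substr(segs$ins[i], r$start + 1, r$end)
      if (!is.na(r$ins)) { r$end <- r$end - r$start; r$start <- 0 }
    } else {
      r$end <- segs$end[i] - (lo - s0)
      r$start <- segs$end[i] - (hi - s0)
    }
    out[[length(out) + 1]] <- r
  }
  if (!length(out)) return(seg_row("x", 0, 1)[0, ])
  do.call(rbind, out)
}

rev_segs <- function(segs) {
  if (!nrow(segs)) return(segs)
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  flip <- is.na(segs$ins)
  segs$strand[flip] <- ifelse(segs$strand[flip] == "+", "-", "+")
  segs$ins[!flip] <- vapply(segs$ins[!flip], revcomp_chr, character(1))
  rownames(segs) <- NULL
  segs
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Merge boundaries that are reference-adjacent (pure cut points).
der_normalize <- function(d) {
  segs <- d$segments
  if (nrow(segs) < 2) return(d)
  keep <- list(segs[1, , drop = FALSE])
  for (i in 2:nrow(segs)) {
    last <- keep[[length(keep)]]
    cur <- segs[i, , drop = FALSE]
    mergeable <- is.na(last$ins) && is.na(cur$ins) &&
      !is.na(last$chrom) && identical(last$chrom, cur$chrom) &&
      identical(last$strand, cur$strand) &&
      ((last$strand == "+" && last$end == cur$start) ||
       (last$strand == "-" && last$start == cur$end))
    if (mergeable) {
      if (last$strand == "+") last$end <- cur$end else last$start <- cur$start
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1]] <- cur
  }
  d$segments <- do.call(rbind, keep)
  rownames(d$segments) <- NULL
  d
}

#' Lift derivative positions to source coordinates
#'
#' @param d A `derivative_chromosome`.
#' @param dpos Vector of derivative positions (0-based).
#' @return data.frame with `chrom`, `pos`, `strand`, `inserted` (TRUE for
#'   bases inside non-templated insertions, where `chrom`/`pos` are NA and
#'   `ins_offset` gives the offset within the insertion).
#' @export
der_lift <- function(d, dpos) {
  segs <- d$segments
  off <- der_offsets(segs)
  if (any(dpos < 0 | dpos >= off[length(off)])) {
    stop("derivative position out of range")
  }
  i <- findInterval(dpos, off, rightmost.closed = FALSE)
  within <- dpos - off[i]
  inserted <- !is.na(segs$ins[i])
  pos <- ifelse(segs$strand[i] == "+", segs$start[i] + within,
                segs$end[i] - 1 - within)
  data.frame(chrom = ifelse(inserted, NA_character_, segs$chrom[i]),
             pos = ifelse(inserted, NA_real_, pos),
             strand = segs$strand[i],
             inserted = inserted,
             ins_offset = ifelse(inserted, within, NA_real_),
             stringsAsFactors = FALSE)
}

#' Lift a source position to all its derivative copies
#'
#' @param d A `derivative_chromosome`.
#' @param chrom,pos Source coordinate (0-based).
#' @param strand Restrict to segments of this strand (NULL = any).
#' @return Sorted numeric vector of derivative positions (possibly empty;
#'   length >= 2 inside duplicated regions).
#' @export
der_lift_back <- function(d, chrom, pos, strand = NULL) {
  segs <- d$segments
  off <- der_offsets(segs)
  hit <- which(!is.na(segs$chrom) & segs$chrom == chrom &
                 pos >= segs$start & pos < segs$end &
                 (if (is.null(strand)) TRUE else segs$strand == strand))
  if (!length(hit)) return(numeric(0))
  dpos <- ifelse(segs$strand[hit] == "+",
                 off[hit] + (pos - segs$start[hit]),
                 off[hit] + (segs$end[hit] - 1 - pos))
  sort(dpos)
}

#' Lift a derivative interval to source pieces
#'
#' Intervals crossing a seam are split; each piece maps contiguously.
#'
#' @param d A `derivative_chromosome`.
#' @param a,b Derivative interval, 0-based half-open.
#' @return data.frame of pieces with source `chrom`, `start`, `end`,
#'   `strand`, `ins`, and derivative offsets `dstart`, `dend`.
#' @export
der_lift_interval <- function(d, a, b) {
  segs <- d$segments
  off <- der_offsets(segs)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    lo <- max(a, off[i]); hi <- min(b, off[i + 1])
    if (lo >= hi) next
    piece <- der_slice(d, lo, hi)
    piece$dstart <- lo; piece$dend <- hi
    out[[length(out) + 1]] <- piece
  }
  if (!length(out)) {
    z <- seg_row("x", 0, 1)[0, ]
    z$dstart <- numeric(0); z$dend <- numeric(0)
    return(z)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the derivative sequence
#'
#' @param d A `derivative_chromosome`.
#' @param reference Named `DNAStringSet` covering all source segments.
#' @return Character scalar, the assembled sequence.
#' @export
der_sequence <- function(d, reference) {
  pieces <- vapply(seq_len(nrow(d$segments)), function(i) {
    r <- d$segments[i, ]
    if (!is.na(r$ins)) return(r$ins)
    ref_fetch(reference, r$chrom, r$start, r$end, r$strand)
  }, character(1))
  paste0(pieces, collapse = "")
}

# --- junction application ----------------------------------------------------

# Enumerate candidate (dL, dR) placements for a junction on the current
# derivative. Breakend bases must live on forward-strand segments (the
# supported application regime); placements violating the class geometry are
# dropped.
junction_placements <- function(d, j) {
  cls <- j$svclass
  dLs <- der_lift_back(d, j$left$chrom, j$left$pos, strand = "+")
  if (cls == "translocation") {
    if (j$left$orient != "+") {
      stop("translocation application requires a forward left breakend")
    }
    if (!length(dLs)) return(list())
    return(lapply(dLs, function(dl) list(dL = dl, dR = NA_real_)))
  }
  dRs <- der_lift_back(d, j$right$chrom, j$right$pos, strand = "+")
  out <- list()
  for (dl in dLs) for (dr in dRs) {
    ok <- switch(cls,
      deletion = dl < dr,
      duplication = dr <= dl,
      inversion = if (j$left$orient == "+") dl < dr else dl <= dr,
      FALSE)
    if (ok) out[[length(out) + 1]] <- list(dL = dl, dR = dr)
  }
  out
}

#' Apply one break fusion junction to a derivative
#'
#' Deletions remove the open interval between the breakends; tandem
#' duplications append a second copy of the bracketed segment; inversions
#' reverse the bracketed segment; translocations splice in the partner
#' window from the right breakend onward, with any inserted sequence at the
#' seam. Breakends are given in source coordinates; when a breakend base
#' occurs in several derivative copies (inside duplications), `placement`
#' selects among candidate placements enumerated in increasing derivative
#' coordinate.
#'
#' @param d A `derivative_chromosome`.
#' @param j A [bfj()].
#' @param placement Index into the candidate placement list.
#' @return The updated `derivative_chromosome`.
#' @export
apply_junction <- function(d, j, placement = 1L) {
  pl <- junction_placements(d, j)
  if (!length(pl)) {
    stop("junction not applicable (breakend absent from derivative, ",
         "e.g. removed by a prior deletion): ", format_bfj(j))
  }
  if (placement > length(pl)) stop("placement index out of range")
  p <- pl[[placement]]
  L <- der_length(d)
  ins <- if (nchar(j$inserted_seq) > 0) ins_row(j$inserted_seq) else NULL
  segs <- switch(j$svclass,
    deletion = ,
    duplication = rbind(der_slice(d, 0, p$dL + 1), ins, der_slice(d, p$dR, L)),
    inversion = {
      if (j$left$orient == "+") {
        rbind(der_slice(d, 0, p$dL + 1),
              rev_segs(der_slice(d, p$dL + 1, p$dR + 1)),
              der_slice(d, p$dR + 1, L))
      } else {
        rbind(der_slice(d, 0, p$dL),
              rev_segs(der_slice(d, p$dL, p$dR)),
              der_slice(d, p$dR, L))
      }
    },
    translocation = {
      w <- d$windows[[j$right$chrom]]
      if (is.null(w)) {
        stop("no window configured for partner chromosome ", j$right$chrom,
             " (junction ", format_bfj(j), ")")
      }
      if (!gi_contains(w, j$right$chrom, j$right$pos)) {
        stop("right breakend outside its window: ", format_bfj(j))
      }
      partner <- if (j$right$orient == "+") {
        seg_row(j$right$chrom, j$right$pos, w$end, "+")
      } else {
        seg_row(j$right$chrom, w$start, j$right$pos + 1, "-")
      }
      d$mask <- c(d$mask, list(w))
      rbind(der_slice(d, 0, p$dL + 1), ins, partner)
    },
    stop("unsupported junction class: ", j$svclass))
  rownames(segs) <- NULL
  d$segments <- segs
  der_normalize(d)
}

#' Build a derivative chromosome from an ordered junction list
#'
#' @param junctions List of [bfj()]s, applied in order (order matters when
#'   later junctions fall inside regions duplicated or removed by earlier
#'   ones). An empty list returns the window itself.
#' @param windows Named list of [genomic_interval()]s (or a single interval);
#'   see [derivative_new()].
#' @param name Derivative name.
#' @return A `derivative_chromosome` with all source windows recorded for
#'   masking.
#' @export
build_derivative <- function(junctions, windows, name = "der1") {
  d <- derivative_new(windows, name = name)
  for (j in junctions) d <- apply_junction(d, j)
  d
}

# --- seams -------------------------------------------------------------------

#' Rearrangement seams of a derivative
#'
#' A seam is a boundary between consecutive segments (possibly spanning one
#' inserted-sequence row) that is not reference-adjacent. Each seam is
#' reported as the oriented source coordinates of its two flanking bases,
#' in [bfj()] breakend semantics, plus the derivative coordinate of the
#' first base after the seam.
#'
#' @param d A `derivative_chromosome`.
#' @return data.frame with columns `left_chrom`, `left_pos`, `left_orient`,
#'   `right_chrom`, `right_pos`, `right_orient`, `inserted_seq`, `dpos`.
#' @export
der_seams <- function(d) {
  segs <- d$segments
  off <- der_offsets(segs)
  out <- list()
  i <- 1L
  while (i < nrow(segs)) {
    k <- i + 1L
    ins <- ""
    if (!is.na(segs$ins[k])) {
      ins <- segs$ins[k]
      k <- k + 1L
      if (k > nrow(segs)) break
    }
    li <- segs[i, ]; ri <- segs[k, ]
    ref_adj <- ins == "" && !is.na(li$chrom) && !is.na(ri$chrom) &&
      li$chrom == ri$chrom && li$strand == ri$strand &&
      ((li$strand == "+" && li$end == ri$start) ||
       (li$strand == "-" && li$start == ri$end))
    if (!ref_adj) {
      out[[length(out) + 1]] <- data.frame(
        left_chrom = li$chrom,
        left_pos = if (li$strand == "+") li$end - 1 else li$start,
        left_orient = li$strand,
        right_chrom = ri$chrom,
        right_pos = if (ri$strand == "+") ri$start else ri$end - 1,
        right_orient = ri$strand,
        inserted_seq = ins,
        dpos = off[k],
        stringsAsFactors = FALSE)
    }
    i <- k
  }
  if (!length(out)) {
    return(data.frame(left_chrom = character(0), left_pos = numeric(0),
                      left_orient = character(0), right_chrom = character(0),
                      right_pos = numeric(0), right_orient = character(0),
                      inserted_seq = character(0), dpos = numeric(0)))
  }
  do.call(rbind, out)
}

# Does the derivative contain this junction's seam signature?
junction_in_derivative <- function(d, j) {
  s <- der_seams(d)
  any(s$left_chrom == j$left$chrom & s$left_pos == j$left$pos &
      s$left_orient == j$left$orient &
      s$right_chrom == j$right$chrom & s$right_pos == j$right$pos &
      s$right_orient == j$right$orient &
      s$inserted_seq == j$inserted_seq)
}

# Derivative coordinate of a junction's seam, NA if absent.
junction_seam_dpos <- function(d, j) {
  s <- der_seams(d)
  hit <- s$left_chrom == j$left$chrom & s$left_pos == j$left$pos &
    s$left_orient == j$left$orient &
    s$right_chrom == j$right$chrom & s$right_pos == j$right$pos &
    s$right_orient == j$right$orient & s$inserted_seq == j$inserted_seq
  if (!any(hit)) NA_real_ else s$dpos[which(hit)[1]]
}

# --- allele reconstruction ---------------------------------------------------

permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Search for a single-allele architecture explaining multiple junctions
#'
#' Explores application orders and, inside duplicated regions, breakend
#' placements, for a derivative chromosome on which every input junction's
#' seam signature co-occurs. Orders are tried starting from a deterministic
#' canonical ordering (duplications before deletions, then remaining
#' classes, each by left-breakend coordinate); the first consistent
#' reconstruction is returned.
#'
#' @param junctions List of [bfj()]s (1 to `max_ops`).
#' @param windows As for [build_derivative()].
#' @param max_ops Combinatorial search cap.
#' @return List of class `allele_reconstruction`: `junctions`, `consistent`,
#'   `operation_order` (junctions in applied order; NULL if inconsistent),
#'   `derivative`, `junction_spans` (pairwise seam distances, bp).
#' @export
reconstruct_allele <- function(junctions, windows, max_ops = 5L) {
  n <- length(junctions)
  if (n < 1L || n > max_ops) {
    stop("reconstruct_allele requires 1..max_ops junctions (got ", n, ")")
  }
  prio <- c(duplication = 1, deletion = 2, inversion = 3, translocation = 4)
  cls <- vapply(junctions, function(j) j$svclass, character(1))
  lpos <- vapply(junctions, function(j) j$left$pos, numeric(1))
  canon <- order(prio[cls], lpos)
  junctions <- junctions[canon]

  try_apply <- function(d, idx) {
    if (!length(idx)) {
      ok <- all(vapply(junctions, function(j) junction_in_derivative(d, j),
                       logical(1)))
      return(if (ok) d else NULL)
    }
    j <- junctions[[idx[1]]]
    pl <- junction_placements(d, j)
    for (k in seq_along(pl)) {
      d2 <- tryCatch(apply_junction(d, j, placement = k),
                     error = function(e) NULL)
      if (is.null(d2)) next
      res <- try_apply(d2, idx[-1])
      if (!is.null(res)) return(res)
    }
    NULL
  }

  for (perm in permutations(n)) {
    d0 <- derivative_new(windows)
    res <- try_apply(d0, perm)
    if (!is.null(res)) {
      dps <- vapply(junctions, function(j) junction_seam_dpos(res, j),
                    numeric(1))
      spans <- abs(outer(dps, dps, "-"))
      dimnames(spans) <- NULL
      return(structure(list(junctions = junctions, consistent = TRUE,
                            operation_order = junctions[perm],
                            derivative = res, junction_spans = spans),
                       class = "allele_reconstruction"))
    }
  }
  structure(list(junctions = junctions, consistent = FALSE,
                 operation_order = NULL, derivative = NULL,
                 junction_spans = NULL),
            class = "allele_reconstruction")
}

# --- export ------------------------------------------------------------------

#' Segment table of a derivative
#'
#' @param d A `derivative_chromosome`.
#' @return data.frame with derivative and source coordinates per segment.
#' @export
der_segment_table <- function(d) {
  off <- der_offsets(d$segments)
  n <- nrow(d$segments)
  data.frame(derivative = d$name,
             derivative_start = off[-(n + 1)],
             derivative_end = off[-1],
             source_chrom = d$segments$chrom,
             source_start = d$segments$start,
             source_end = d$segments$end,
             orientation = d$segments$strand,
             inserted_seq = ifelse(is.na(d$segments$ins), "", d$segments$ins),
             stringsAsFactors = FALSE)
}

#' Combined masked reference plus derivative
#'
#' Hard-masks (N-fills) every source window contributing segments and
#' appends the assembled derivative, mirroring a mapping scheme where reads
#' from the rearranged allele are forced onto the derivative contig.
#'
#' @param d A `derivative_chromosome`.
#' @param reference Named `DNAStringSet`.
#' @return A `DNAStringSet` with the masked source chromosomes plus the
#'   derivative.
#' @export
combined_reference <- function(d, reference) {
  out <- reference
  for (w in d$mask) {
    if (!w$chrom %in% names(out)) next
    s <- out[[w$chrom]]
    mask_width <- min(w$end, length(s)) - max(w$start, 0)
    Biostrings::subseq(s, max(w$start, 0) + 1,
                       min(w$end, length(s))) <-
      Biostrings::DNAString(paste(rep("N", mask_width), collapse = ""))
    out[[w$chrom]] <- s
  }
  der <- Biostrings::DNAStringSet(der_sequence(d, reference))
  names(der) <- d$name
  c(out, der)
}
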