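#' Annotate the end-joining signature of a junction
#'
#' Classifies the sequence context of a break fusion junction:
#' non-templated insertion length, microhomology between the two breakend
#' flanks, and overlap with annotated repeat elements. Microhomology is the
#' number of bases over which the junction placement is ambiguous, i.e. the
#' junction can be shifted without changing the assembled derivative
#' sequence; it is computed from the reference flanks and reported with the
#' junction shifted to its left-aligned (lowest-coordinate) placement.
#' Under this convention a junction with a non-empty inserted sequence has
#' zero microhomology and vice versa; both being positive is impossible.
#'
#' @param junction A [bfj()].
#' @param reference Named `DNAStringSet` containing both breakend chromosomes.
#' @param repeats Optional repeat annotation `data.frame(chrom, start, end,
#'   label)` (0-based half-open).
#' @param max_scan Cap on the homology scan length.
#' @return A list of class `junction_signature` with fields `junction`
#'   (left-aligned), `microhomology_len`, `nontemplated_len`,
#'   `repeat_context`.
#' @export
annotate_signature <- function(junction, reference, repeats = NULL,
                               max_scan = 1000L) {
  stopifnot(inherits(junction, "bfj"))
  L <- junction$left; R <- junction$right
  for (b in list(L, R)) {
    if (!b$chrom %in% names(reference)) {
      stop("breakend chromosome not in reference: ", b$chrom)
    }
    if (b$pos < 0 || b$pos >= length(reference[[b$chrom]])) {
      stop("breakend outside reference bounds: ", b$chrom, ":", b$pos + 1)
    }
  }
  nontemplated <- nchar(junction$inserted_seq)

  # Oriented base accessors around the seam. Offsets k >= 1.
  donor_next <- function(k) {            # donor-chromosome continuation past the seam
    if (L$orient == "+") safe_base(reference, L$chrom, L$pos + k)
    else comp_base(safe_base(reference, L$chrom, L$pos - k))
  }
  donor_last <- function(k) {            # k-th base counting back from the seam (k=1 at pos)
    if (L$orient == "+") safe_base(reference, L$chrom, L$pos - k + 1)
    else comp_base(safe_base(reference, L$chrom, L$pos + k - 1))
  }
  acceptor_first <- function(k) {        # k-th acceptor base after the seam (k=1 at pos)
    if (R$orient == "+") safe_base(reference, R$chrom, R$pos + k - 1)
    else comp_base(safe_base(reference, R$chrom, R$pos - k + 1))
  }
  acceptor_prev <- function(k) {         # acceptor-chromosome sequence preceding the seam
    if (R$orient == "+") safe_base(reference, R$chrom, R$pos - k)
    else comp_base(safe_base(reference, R$chrom, R$pos + k))
  }

  mh <- 0L; shift_back <- 0L
  if (nontemplated == 0L) {
    fwd <- 0L
    while (fwd < max_scan) {
      a <- donor_next(fwd + 1L); b <- acceptor_first(fwd + 1L)
      if (is.na(a) || is.na(b) || a != b) break
      fwd <- fwd + 1L
    }
    bwd <- 0L
    while (bwd < max_scan) {
      a <- donor_last(bwd + 1L); b <- acceptor_prev(bwd + 1L)
      if (is.na(a) || is.na(b) || a != b) break
      bwd <- bwd + 1L
    }
    mh <- fwd + bwd
    shift_back <- bwd
  }

  aligned <- junction
  if (shift_back > 0L) {
    lshift <- if (L$orient == "+") -shift_back else shift_back
    rshift <- if (R$orient == "+") -shift_back else shift_back
    aligned <- bfj(breakend(L$chrom, L$pos + lshift, L$orient),
                   breakend(R$chrom, R$pos + rshift, R$orient),
                   inserted_seq = junction$inserted_seq)
  }

  ctx <- "none"
  if (!is.null(repeats) && nrow(repeats) > 0) {
    hit <- (repeats$chrom == L$chrom & L$pos >= repeats$start & L$pos < repeats$end) |
           (repeats$chrom == R$chrom & R$pos >= repeats$start & R$pos < repeats$end)
    if (any(hit)) ctx <- paste(unique(repeats$label[hit]), collapse = ",")
  }

  structure(list(junction = aligned,
                 microhomology_len = as.integer(mh),
                 nontemplated_len = as.integer(nontemplated),
                 repeat_context = ctx),
            class = "junction_signature")
}

safe_base <- function(ref, chrom, pos) {
  if (pos < 0 || pos >= length(ref[[chrom]])) return(NA_character_)
  ref_base(ref, chrom, pos)
}

comp_base <- function(b) {
  if (is.na(b)) return(NA_character_)
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}
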