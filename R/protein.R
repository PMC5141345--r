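#' Translation and annotation of truncated receptor variants
#'
#' Variant transcripts are translated with the standard code from the
#' canonical start codon, the frame carried across splice junctions; the
#' product is compared against the canonical receptor translation to
#' delimit the C-terminal extension, which is scanned for an NLS-like
#' basic motif, and an average-mass molecular weight is computed.
#'
#' @name arv_assembly
NULL

#' Translate a transcript from its start codon
#'
#' @param model A transcript model (from [assemble_transcripts()] or
#'   [make_transcript()]), or an mRNA character string.
#' @param start_offset 0-based offset of the ATG within the mRNA (for a
#'   transcript beginning at canonical exon 1, this is the start-codon
#'   offset within exon 1).
#' @param canonical_protein Canonical receptor protein sequence used to
#'   delimit the shared N-terminal prefix (optional).
#' @param nls_window,nls_min_basic Passed to [scan_nls_like()].
#' @return list of class `protein_product`: `sequence` (ends at the first
#'   stop), `non_stop` (TRUE if no in-frame stop before the transcript
#'   end), `canonical_prefix_len`, `cterm_extension`, `nls_like`,
#'   `nls_motif`, `mol_weight`.
#' @export
translate_orf <- function(model, start_offset, canonical_protein = NULL,
                          nls_window = 15L, nls_min_basic = 2L) {
  mrna <- if (is.character(model)) model else model$mrna
  if (toupper(substr(mrna, start_offset + 1, start_offset + 3)) != "ATG") {
    stop("no ATG start codon at offset ", start_offset)
  }
  cds <- substr(mrna, start_offset + 1, nchar(mrna))
  cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  non_stop <- stop_at < 0
  seqaa <- if (non_stop) aa else substr(aa, 1, stop_at - 1)

  prefix_len <- NA_integer_; ext <- NA_character_
  if (!is.null(canonical_protein)) {
    prefix_len <- common_prefix_len(seqaa, canonical_protein)
    ext <- substr(seqaa, prefix_len + 1, nchar(seqaa))
  }
  nls <- if (!is.null(canonical_protein) && !is.na(ext) && nchar(ext) > 0) {
    scan_nls_like(ext, window = nls_window, min_basic = nls_min_basic)
  } else list(flag = FALSE, motif = NA_character_)

  structure(list(sequence = seqaa, non_stop = non_stop,
                 canonical_prefix_len = prefix_len,
                 cterm_extension = ext,
                 nls_like = nls$flag, nls_motif = nls$motif,
                 mol_weight = if (nchar(seqaa) > 0)
                   molecular_weight(seqaa) else NA_real_),
            class = "protein_product")
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  mism <- which(av != bv)
  if (!length(mism)) n else mism[1] - 1L
}

#' Scan a C-terminal extension for an NLS-like basic motif
#'
#' Flags the extension when any 5-residue window within the first
#' `window` residues contains at least `min_basic` basic residues (K/R),
#' reporting the maximal-scoring window. This captures motifs resembling
#' the second half of a bipartite nuclear localization signal (e.g.
#' VRRGR, VGKTK).
#'
#' @param extension Amino-acid string (the C-terminal extension).
#' @param window Scan region length in residues from the extension start.
#' @param k Motif window size.
#' @param min_basic Minimum K/R count within a window.
#' @return list(`flag`, `motif`, `score`).
#' @export
scan_nls_like <- function(extension, window = 15L, k = 5L, min_basic = 2L) {
  region <- substr(extension, 1, min(window, nchar(extension)))
  n <- nchar(region)
  if (n == 0) return(list(flag = FALSE, motif = NA_character_, score = 0L))
  kk <- min(k, n)
  best <- -1L; best_motif <- NA_character_
  for (i in seq_len(n - kk + 1)) {
    w <- substr(region, i, i + kk - 1)
    score <- nchar(gsub("[^KR]", "", w))
    if (score > best) { best <- score; best_motif <- w }
  }
  list(flag = best >= min_basic, motif = best_motif, score = best)
}

AA_AVG_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                 V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                 I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                 K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                 F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_AVG_MASS <- 18.0153

#' Average-mass molecular weight of a peptide
#'
#' Sum of average residue masses plus one water; average (not
#' monoisotopic) masses match gel-mobility comparisons.
#'
#' @param sequence Amino-acid string (standard 20 residues).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(sequence) {
  if (!nchar(sequence)) stop("empty peptide sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(AA_AVG_MASS))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS
}
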