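#' Breakends and break fusion junctions
#'
#' A break fusion junction (BFJ) is the novel adjacency created by a genomic
#' rearrangement: two oriented breakends plus an optional non-templated
#' inserted sequence. Orientation semantics: a forward ("+") left breakend
#' means the derivative retains reference sequence approaching `pos` from
#' lower coordinates (through `pos` itself); a forward right breakend means
#' the derivative continues from `pos` toward higher coordinates. Reverse
#' ("-") flips the respective direction. Positions are 0-based internally;
#' the printed notation ("chrX:66,934,778 (+)") is 1-based.
#'
#' @param chrom Chromosome name.
#' @param pos 0-based position of the breakend base.
#' @param orient "+" (forward) or "-" (reverse).
#' @return A `breakend` object.
#' @export
breakend <- function(chrom, pos, orient = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  if (!orient %in% c("+", "-")) stop("orient must be \"+\" or \"-\"")
  structure(list(chrom = chrom, pos = as.numeric(pos), orient = orient),
            class = "breakend")
}

#' @export
print.breakend <- function(x, ...) {
  cat(format_breakend(x), "\n")
  invisible(x)
}

format_breakend <- function(x, with_chrom = TRUE, with_orient = TRUE) {
  pos <- formatC(x$pos + 1, big.mark = ",", format = "d")
  out <- if (with_chrom) paste0(x$chrom, ":", pos) else pos
  if (with_orient) out <- paste0(out, " (", x$orient, ")")
  out
}

#' Classify a junction by its breakend geometry
#'
#' @param left,right `breakend` objects.
#' @return One of "deletion", "duplication", "inversion", "translocation".
#'   Tandem duplications are the same-chromosome forward/forward case with
#'   `left$pos > right$pos`; equal forward/forward positions are degenerate
#'   and raise an error.
#' @export
classify_junction <- function(left, right) {
  stopifnot(inherits(left, "breakend"), inherits(right, "breakend"))
  if (left$chrom != right$chrom) return("translocation")
  n_rev <- sum(c(left$orient, right$orient) == "-")
  if (n_rev >= 1L) return("inversion")
  if (left$pos < right$pos) return("deletion")
  if (left$pos > right$pos) return("duplication")
  stop("degenerate junction: identical forward breakends at ",
       left$chrom, ":", left$pos + 1)
}

#' Construct a break fusion junction
#'
#' @param left,right `breakend`s (or printed breakend strings).
#' @param inserted_seq Non-templated bases at the seam (A/C/G/T/N), "" if none.
#' @param pe_support,sr_support Supporting read-pair / split-read counts.
#' @param svclass Optional class label; must agree with [classify_junction()].
#' @export
bfj <- function(left, right, inserted_seq = "", pe_support = NA_integer_,
                sr_support = NA_integer_, svclass = NULL) {
  if (is.character(left)) left <- parse_breakend_token(left)$bnd
  if (is.character(right)) right <- parse_breakend_token(right)$bnd
  inserted_seq <- toupper(inserted_seq)
  if (nchar(inserted_seq) > 0 &&
      grepl("[^ACGTN]", inserted_seq)) {
    stop("inserted_seq may contain only A/C/G/T/N: ", inserted_seq)
  }
  cls <- classify_junction(left, right)
  if (!is.null(svclass) && !identical(tolower(svclass), cls)) {
    stop("declared svclass '", svclass, "' disagrees with breakend geometry ('",
         cls, "')")
  }
  structure(list(left = left, right = right, inserted_seq = inserted_seq,
                 svclass = cls,
                 pe_support = as.integer(pe_support),
                 sr_support = as.integer(sr_support)),
            class = "bfj")
}

#' @export
print.bfj <- function(x, ...) {
  cat(format_bfj(x), " [", x$svclass, "]\n", sep = "")
  invisible(x)
}

parse_breakend_token <- function(token) {
  token <- gsub("−", "-", trimws(token))  # printed minus sign
  m <- regmatches(token,
    regexec("^(?:([A-Za-z0-9_.]+):)?([0-9,]+)(?:\\s*\\(([+-])\\))?$", token))[[1]]
  if (length(m) != 4L || m[3] == "") {
    stop("malformed breakend token: '", token, "'")
  }
  chrom <- m[2]
  pos <- as.numeric(gsub(",", "", m[3])) - 1
  orient <- m[4]
  orient_missing <- orient == ""
  if (orient_missing) orient <- "+"
  list(bnd = if (chrom == "") NULL else breakend(chrom, pos, orient),
       chrom_missing = chrom == "", pos = pos, orient = orient,
       orient_missing = orient_missing)
}

#' Parse printed break-fusion-junction notation
#'
#' Grammar: `chrom:pos (+)[/INS]/[chrom:]pos [(+)]` with optional thousands
#' separators. The right breakend may omit the chromosome (inherited from the
#' left) and, in one published row, the orientation token; a missing
#' orientation defaults to forward and is recorded in the
#' `right_orient_missing` attribute (with a warning unless `quiet = TRUE`).
#' `format_bfj(parse_bfj(x))` is the identity on well-formed strings.
#'
#' @param text The printed junction string.
#' @param quiet Suppress the missing-orientation warning.
#' @return A `bfj`.
#' @export
parse_bfj <- function(text, quiet = FALSE) {
  parts <- strsplit(gsub("−", "-", text), "/", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(2L, 3L)) {
    stop("malformed junction string (expected 2 breakends, optional insert): '",
         text, "'")
  }
  ins <- ""
  if (length(parts) == 3L) {
    ins <- toupper(trimws(parts[2]))
    if (nchar(ins) == 0 || grepl("[^ACGTN]", ins)) {
      stop("malformed inserted-sequence token: '", parts[2], "'")
    }
    parts <- parts[c(1, 3)]
  }
  lt <- parse_breakend_token(parts[1])
  if (lt$chrom_missing) stop("left breakend lacks a chromosome: '", parts[1], "'")
  rt <- parse_breakend_token(parts[2])
  right <- if (rt$chrom_missing) {
    breakend(lt$bnd$chrom, rt$pos, rt$orient)
  } else rt$bnd
  if (rt$orient_missing && !quiet) {
    warning("right breakend orientation missing in '", text,
            "'; defaulting to forward (+)")
  }
  out <- bfj(lt$bnd, right, inserted_seq = ins)
  attr(out, "right_chrom_implicit") <- rt$chrom_missing
  attr(out, "right_orient_missing") <- rt$orient_missing
  out
}

#' @rdname parse_bfj
#' @param x A `bfj`.
#' @export
format_bfj <- function(x) {
  left <- format_breakend(x$left)
  right <- format_breakend(
    x$right,
    with_chrom = !isTRUE(attr(x, "right_chrom_implicit")),
    with_orient = !isTRUE(attr(x, "right_orient_missing")))
  mid <- if (nchar(x$inserted_seq) > 0) paste0(x$inserted_seq, "/") else ""
  paste0(left, "/", mid, right)
}
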