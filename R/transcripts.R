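#' Assembly of variant transcripts from observed splice junctions
#'
#' Builds a junction graph over exon instances on the derivative and
#' enumerates transcript models starting from a 5' exon: at each branch
#' point, outgoing junctions are followed in order of decreasing read
#' count (ties by lower acceptor coordinate), and one transcript is
#' emitted per terminal branch. A path ends at an exon with no outgoing
#' junction; a terminal exon keeps its annotated 3' end, while a novel
#' acceptor (no annotated exon starting there) defines a terminal exon of
#' `terminal_ext` bp past the acceptor.
#'
#' @param calls Junction data.frame with `donor`, `acceptor` (derivative
#'   coordinates, 0-based) and a count column (`count_case` or `count`).
#' @param bins Exon bins from [make_bins()] (rows with kind "exon"), or
#'   any data.frame with `label`, `dstart`, `dend`.
#' @param d The `derivative_chromosome`.
#' @param reference Reference `DNAStringSet` (for mRNA assembly).
#' @param start_exon Label of the 5' exon to start from (all derivative
#'   copies are used as starting points, ordered by coordinate).
#' @param tol Donor/acceptor matching tolerance (bp).
#' @param terminal_ext Terminal-extension length for unannotated 3' exons.
#' @return list of transcript models (`name`, `chrom`, `exons`, `mrna`).
#' @export
assemble_transcripts <- function(calls, bins, d, reference,
                                 start_exon = "exon 1", tol = 5L,
                                 terminal_ext = 300L) {
  cnt <- if ("count_case" %in% names(calls)) calls$count_case else calls$count
  ex <- if ("kind" %in% names(bins)) {
    bins[bins$kind == "exon", , drop = FALSE]
  } else bins
  nodes <- data.frame(label = ex$label, dstart = ex$dstart, dend = ex$dend,
                      stringsAsFactors = FALSE)

  # attach each junction: donor inside an exon node; acceptor at an exon
  # start (within tol) or a novel terminal node
  edges <- list()
  for (i in seq_len(nrow(calls))) {
    don <- calls$donor[i]; acc <- calls$acceptor[i]
    from <- which(nodes$dstart <= don & don < nodes$dend)
    if (!length(from)) next
    to <- which(abs(nodes$dstart - acc) <= tol)
    if (!length(to)) {
      nodes <- rbind(nodes, data.frame(label = sprintf("novel@%d", acc),
                                       dstart = acc,
                                       dend = acc + terminal_ext))
      to <- nrow(nodes)
    }
    edges[[length(edges) + 1]] <- data.frame(
      from = from[1], to = to[1], donor_end = don + 1,
      acceptor_start = nodes$dstart[to[1]], count = cnt[i])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), donor_end = numeric(0),
               acceptor_start = numeric(0), count = numeric(0))

  gseq <- der_sequence(d, reference)
  starts <- which(nodes$label == start_exon |
                    startsWith(nodes$label, paste0(start_exon, " (copy")))
  starts <- starts[order(nodes$dstart[starts])]
  if (!length(starts)) stop("start exon not found: ", start_exon)

  out <- list()
  walk <- function(node, path_nodes, pieces) {
    eo <- edges[edges$from == node, , drop = FALSE]
    if (!nrow(eo)) {
      # terminal exon: from its (possibly spliced-into) start to its end
      pieces[[length(pieces) + 1]] <- c(nodes$dstart[node], nodes$dend[node],
                                        node)
      exdf <- do.call(rbind, lapply(pieces, function(p) {
        data.frame(label = nodes$label[p[3]], dstart = p[1], dend = p[2],
                   stringsAsFactors = FALSE)
      }))
      mrna <- paste0(substring(gseq, exdf$dstart + 1, exdf$dend),
                     collapse = "")
      out[[length(out) + 1]] <<- structure(
        list(name = sprintf("tx%d", length(out) + 1), chrom = d$name,
             exons = exdf, mrna = mrna),
        class = "transcript_model")
      return(invisible(NULL))
    }
    eo <- eo[order(-eo$count, eo$acceptor_start), , drop = FALSE]
    for (k in seq_len(nrow(eo))) {
      nxt <- eo$to[k]
      if (nxt %in% path_nodes) {
        stop("cyclic junction graph: ",
             paste(nodes$label[c(path_nodes, nxt)], collapse = " -> "))
      }
      p2 <- pieces
      p2[[length(p2) + 1]] <- c(nodes$dstart[node], eo$donor_end[k], node)
      walk(nxt, c(path_nodes, nxt), p2)
    }
    invisible(NULL)
  }
  for (s in starts) walk(s, s, list())
  out
}
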