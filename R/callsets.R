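#' Emulate two independent structural-variant callers
#'
#' Each implanted junction appears in each call set with probability
#' `1 - fn_rate`, with breakend positions jittered uniformly within
#' `jitter_bp`; `fp_count` caller-unique decoy calls are added per set,
#' drawn so that decoys of the two sets stay far apart (they must never
#' merge under the consensus rule). Deterministic in `seed`.
#'
#' @param junctions List of true [bfj()]s.
#' @param seed Integer seed.
#' @param jitter_bp Maximum absolute per-breakend jitter (bp).
#' @param fn_rate Per-caller false-negative rate.
#' @param fp_count Decoy calls per set.
#' @param decoy_region Interval decoys are placed in.
#' @param callers Two caller labels.
#' @return list(`A`, `B`) of call-set data.frames.
#' @export
emit_caller_callsets <- function(junctions, seed = 1L, jitter_bp = 0L,
                                 fn_rate = 0, fp_count = 0L,
                                 decoy_region = NULL,
                                 callers = c("lumpy", "delly")) {
  stopifnot(length(callers) == 2)
  with_seed(seed, {
    sets <- lapply(seq_along(callers), function(ci) {
      rows <- list()
      for (j in junctions) {
        if (stats::runif(1) < fn_rate) next
        jit <- function(p) {
          if (jitter_bp > 0) p + sample(-jitter_bp:jitter_bp, 1) else p
        }
        rows[[length(rows) + 1]] <- data.frame(
          caller = callers[ci], chrom1 = j$left$chrom, pos1 = jit(j$left$pos),
          orient1 = j$left$orient, chrom2 = j$right$chrom,
          pos2 = jit(j$right$pos), orient2 = j$right$orient,
          svclass = j$svclass, qual = 100,
          precise = ci == 1, stringsAsFactors = FALSE)
      }
      if (fp_count > 0) {
        stopifnot(!is.null(decoy_region))
        # decoys of set A on an even grid, set B on an odd grid, so that
        # cross-set breakend distances always exceed the merge window
        base <- decoy_region$start + (ci - 1) * 2500
        for (k in seq_len(fp_count)) {
          p <- base + (k - 1) * 6000
          rows[[length(rows) + 1]] <- data.frame(
            caller = callers[ci], chrom1 = decoy_region$chrom, pos1 = p,
            orient1 = "+", chrom2 = decoy_region$chrom, pos2 = p + 500 + k,
            orient2 = "+", svclass = "deletion", qual = 10,
            precise = FALSE, stringsAsFactors = FALSE)
        }
      }
      if (!length(rows)) callset_from_junctions(list(), callers[ci])
      else do.call(rbind, rows)
    })
    names(sets) <- c("A", "B")
    sets
  })
}
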