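#' Synthetic cohort generation
#'
#' The generator builds a fully truth-annotated stand-in for a targeted
#' DNA/RNA sequencing study of a receptor locus: a ~200 kb locus chromosome
#' carrying an 8-exon gene with cryptic and upstream exons, a partner
#' chromosome for translocations, clones carrying structural rearrangements
#' at stated cell fractions, integer locus copy-number states, hotspot
#' missense SNVs, pre-aligned paired-end DNA reads (insert 300 +/- 50,
#' 2 x 150 bp), spliced RNA reads (2 x 50 bp) and caller-style structural
#' variant call sets. Every output is a pure function of (configuration,
#' seed).
#'
#' @name synthetic_cohort
NULL

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Codons that never terminate translation; used for engineered coding spans.
codons_nostop <- function(n) {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  ok <- setdiff(all3, c("TAA", "TAG", "TGA"))
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

peptide_codons <- function(aa) {
  tab <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
           H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
           P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTG",
           W = "TGG", Y = "TAT")
  paste(tab[strsplit(aa, "")[[1]]], collapse = "")
}

#' Build a synthetic reference with an AR-like locus
#'
#' Two chromosomes: `chrA` carries the gene body (8 canonical exons, an
#' intron-3 cryptic exon `CE3`, and four exons upstream of the gene named
#' `4-ups`/`5a-ups`/`5b-ups`/`5c-ups` after their splicing order in variant
#' mRNAs), `chrB` is a translocation partner carrying a cassette exon
#' (`B-term`) and the five copy-number control regions. The canonical open
#' reading frame is stop-free from its ATG through exon 8 (stop planted at
#' the exon-8 end); the cryptic/upstream/partner exons carry engineered
#' in-frame C-terminal extensions with basic (K/R-rich) motifs so that
#' rearrangement-dependent transcripts translate to truncated receptor
#' variants with known protein sequences.
#'
#' @param seed Integer seed; same seed, same bytes.
#' @param locus_len Length of the locus chromosome (>= 150 kb recommended
#'   for realistic intron/upstream spans).
#' @param partner_len Length of the partner chromosome.
#' @param n_exons Number of canonical exons (fixed layout supports 8).
#' @return A list: `seqs` (DNAStringSet), `exons` (data.frame chrom, start,
#'   end, name, kind), `gene` (gene-body interval), `controls` (list C1..C5),
#'   `hotspots` (data.frame), `cds_start` (0-based position of the ATG),
#'   `locus_chrom`, `partner_chrom`.
#' @export
make_reference <- function(seed = 1L, locus_len = 200000L,
                           partner_len = 50000L, n_exons = 8L) {
  if (locus_len < 150000L) stop("locus_len too short for the exon layout")
  if (n_exons != 8L) stop("the bundled exon layout uses 8 canonical exons")
  gene_start <- round(locus_len * 0.45)
  if (gene_start < 35000L || gene_start + 62000L > locus_len) {
    stop("exon layout infeasible for requested locus length")
  }
  exon_off <- c(0, 24000, 28000, 40000, 46000, 50000, 54000, 58000)
  exon_len <- c(1587, 152, 117, 288, 145, 131, 158, 558)
  cds_off <- 10L  # ATG offset within exon 1

  with_seed(seed, {
    chrA <- strsplit(random_dna(locus_len), "")[[1]]
    chrB <- strsplit(random_dna(partner_len), "")[[1]]

    put <- function(v, pos0, s) {
      v[(pos0 + 1):(pos0 + nchar(s))] <- strsplit(s, "")[[1]]
      v
    }

    # Canonical coding sequence: ATG + stop-free codons + terminal TAA,
    # distributed across the exons in genomic order.
    n_cds <- sum(exon_len) - cds_off
    stopifnot(n_cds %% 3 == 0)
    cds <- paste0("ATG", codons_nostop(n_cds / 3 - 2), "TAA")
    exon_seq <- character(8)
    cursor <- 1L
    for (i in 1:8) {
      lead <- if (i == 1) random_dna(cds_off) else ""
      take <- exon_len[i] - nchar(lead)
      exon_seq[i] <- paste0(lead, substr(cds, cursor, cursor + take - 1))
      cursor <- cursor + take
    }
    for (i in 1:8) chrA <- put(chrA, gene_start + exon_off[i], exon_seq[i])

    # Phase bookkeeping: coding bases through the exon-3 donor.
    thru_e3 <- sum(exon_len[1:3]) - cds_off
    pad3 <- (3 - thru_e3 %% 3) %% 3              # bases completing the codon
    phase_pad <- substr("TG", 1, pad3)           # X+TG is never a stop

    cassette <- function(pad, peptide, terminal, fill_to) {
      body <- paste0(pad, peptide_codons(peptide), if (terminal) "TAA" else "")
      stopifnot(nchar(body) <= fill_to)
      extra <- fill_to - nchar(body)
      if (!terminal) {
        # internal exon: keep the tail stop-free on the exon's codon grid
        rem <- (nchar(body) - nchar(pad)) %% 3
        tail_codons <- codons_nostop(ceiling((extra + rem) / 3) + 1)
        tail <- substr(tail_codons, rem + 1, rem + extra)
        paste0(body, tail)
      } else paste0(body, random_dna(extra))
    }

    ce3_len <- 150L
    ups_specs <- list(
      `4-ups`  = list(off = -30000, len = 180L, pep = "VRRGRSSAEL",
                      terminal = FALSE),
      `5a-ups` = list(off = -26000, len = 150L, pep = "VRRGRAEQL",
                      terminal = TRUE),
      `5b-ups` = list(off = -22000, len = 141L, pep = "VRRGRGDS",
                      terminal = TRUE),
      `5c-ups` = list(off = -18000, len = 162L, pep = "VRRGREDAAKV",
                      terminal = TRUE))
    # CE3-like cryptic exon in intron 3 (terminal in the canonical-variant
    # sense, with its own short extension and stop).
    ce3_seq <- cassette(phase_pad, "ARESPKDLQ", TRUE, ce3_len)
    chrA <- put(chrA, gene_start + 33000, ce3_seq)
    exons <- data.frame(chrom = "chrA",
                        start = gene_start + exon_off,
                        end = gene_start + exon_off + exon_len,
                        name = paste("exon", 1:8),
                        kind = "canonical", stringsAsFactors = FALSE)
    exons <- rbind(exons, data.frame(chrom = "chrA",
                                     start = gene_start + 33000,
                                     end = gene_start + 33000 + ce3_len,
                                     name = "CE3", kind = "cryptic"))
    # 4-ups is internal to the variant mRNAs, so its frame continues; the
    # pad for the 5x-ups exons completes the codon left open after 4-ups.
    after_4ups <- (thru_e3 + ups_specs[["4-ups"]]$len) %% 3
    pad5 <- substr("TG", 1, (3 - after_4ups) %% 3)
    for (nm in names(ups_specs)) {
      sp <- ups_specs[[nm]]
      pad <- if (nm == "4-ups") phase_pad else pad5
      s <- cassette(pad, sp$pep, sp$terminal, sp$len)
      chrA <- put(chrA, gene_start + sp$off, s)
      exons <- rbind(exons, data.frame(chrom = "chrA",
                                       start = gene_start + sp$off,
                                       end = gene_start + sp$off + sp$len,
                                       name = nm, kind = "upstream"))
    }

    # Partner-chromosome terminal cassette: 1 bridge residue + 12 planted
    # residues = a 13-aa C-terminal extension with a VGKTK NLS-like motif.
    bterm_len <- 300L
    bterm <- cassette(phase_pad, "VGKTKSGVEDNL", TRUE, bterm_len)
    bterm_start <- 42000L
    chrB <- put(chrB, bterm_start, bterm)
    exons <- rbind(exons, data.frame(chrom = "chrB", start = bterm_start,
                                     end = bterm_start + bterm_len,
                                     name = "B-term", kind = "partner"))

    controls <- lapply(0:4, function(i) {
      genomic_interval("chrB", 2000 + i * 8000, 7000 + i * 8000)
    })
    names(controls) <- paste0("C", 1:5)

    # Hotspot missense positions in the exon-8 (ligand-binding-domain
    # analogue) coding sequence.
    e8 <- gene_start + exon_off[8]
    hs_pos <- c(e8 + 101, e8 + 222)
    transversion <- c(A = "C", C = "A", G = "T", T = "G")
    hotspots <- data.frame(chrom = "chrA", pos = hs_pos,
                           ref = chrA[hs_pos + 1],
                           alt = unname(transversion[chrA[hs_pos + 1]]),
                           name = c("H1", "H2"), stringsAsFactors = FALSE)
    rownames(hotspots) <- NULL

    seqs <- Biostrings::DNAStringSet(c(chrA = paste(chrA, collapse = ""),
                                       chrB = paste(chrB, collapse = "")))
    rownames(exons) <- NULL
    list(seqs = seqs, exons = exons,
         gene = genomic_interval("chrA", gene_start, gene_start + 60000),
         controls = controls, hotspots = hotspots,
         cds_start = gene_start + cds_off,
         locus_chrom = "chrA", partner_chrom = "chrB")
  })
}

#' Simulation configuration
#'
#' @param coverage Mean fold coverage of the DNA reads over copy-neutral
#'   sequence.
#' @param read_len_dna,read_len_rna Read lengths (bp).
#' @param insert_mean,insert_sd DNA fragment size model (bp).
#' @param rna_insert_mean,rna_insert_sd RNA fragment size model (bp).
#' @param rna_pairs Total RNA read pairs per sample.
#' @param error_rate Per-base substitution error rate (off by default; error
#'   modelling is noise for the logic under test).
#' @export
sim_config <- function(coverage = 100, read_len_dna = 150L,
                       insert_mean = 300, insert_sd = 50,
                       read_len_rna = 50L, rna_insert_mean = 170,
                       rna_insert_sd = 30, rna_pairs = 20000L,
                       error_rate = 0) {
  stopifnot(coverage > 0, read_len_dna > 0, read_len_rna > 0,
            insert_mean > 0, insert_sd >= 0)
  structure(list(coverage = coverage, read_len_dna = as.integer(read_len_dna),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len_rna = as.integer(read_len_rna),
                 rna_insert_mean = rna_insert_mean,
                 rna_insert_sd = rna_insert_sd,
                 rna_pairs = as.integer(rna_pairs),
                 error_rate = error_rate),
            class = "sim_config")
}

#' Clone and sample specifications
#'
#' A clone is a cell population at a given fraction of the sample, carrying
#' an ordered list of break fusion junctions, an integer locus copy number,
#' and SNVs (`data.frame(pos, ref, alt, zygosity)` with zygosity "het" or
#' "hom"). Clone fractions within a sample must sum to 1.
#'
#' @param fraction Cell fraction in [0, 1].
#' @param junctions List of [bfj()]s applied in order.
#' @param locus_cn Integer locus copy number (reference baseline is 2 for
#'   autosome-like normalization; a hemizygous locus is `locus_cn = 1`).
#' @param snvs SNV data.frame or NULL.
#' @export
clone_spec <- function(fraction, junctions = list(), locus_cn = 2L,
                       snvs = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, locus_cn >= 0)
  structure(list(fraction = fraction, junctions = junctions,
                 locus_cn = as.integer(locus_cn), snvs = snvs),
            class = "clone_spec")
}

#' @rdname clone_spec
#' @param name Sample label.
#' @param clones List of `clone_spec`s.
#' @param type Free-text sample type label.
#' @export
sample_spec <- function(name, clones, type = "CRPC met") {
  fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("clone fractions must sum to 1 (got ", sum(fr), ")")
  }
  structure(list(name = name, clones = clones, type = type),
            class = "sample_spec")
}
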