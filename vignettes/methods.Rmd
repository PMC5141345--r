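---
title: "Detecting and reconstructing AR structural rearrangements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and reconstructing AR structural rearrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argsr)
```

## The problem

Castration-resistant prostate cancer (CRPC) frequently sustains androgen
receptor (AR) signalling through structural alterations of the *AR* locus.
Beyond amplification and hotspot missense mutations, genomic structural
rearrangements with a breakpoint inside the *AR* gene body (AR-GSRs) can
rewire the gene's architecture so that splicing recruits cryptic 3'-terminal
exons, producing truncated receptor variants (AR-Vs) that lack the
ligand-binding domain and are constitutively active. `argsr` implements the
computational pipeline for this biology end to end: consensus detection of
break fusion junctions from targeted paired-end DNA-seq, copy-number and
sub-clonal allele-fraction quantification, derivative-chromosome
reconstruction with coordinate liftover, splice-junction binning of RNA-seq
against the rearranged assembly, and assembly, translation and annotation of
the resulting variant proteins — together with a seeded synthetic-cohort
generator so every stage is testable without access to controlled patient
data.

## Coordinates, breakends and junction classes

All internal coordinates are 0-based, half-open; printed coordinates
(`chrX:66,934,778 (+)`) are 1-based and converted only at I/O boundaries.
A break fusion junction is two oriented breakends plus an optional
non-templated insert. The orientation semantics are fixed by the requirement
that the four printed rearrangement classes fall out of pure geometry: a
forward left breakend retains reference sequence approaching the position
from below, a forward right breakend continues from the position upward.
Then different chromosomes give a translocation; one reversed orientation an
inversion; forward/forward with the left position below the right a
deletion, above it a tandem duplication. Equal forward/forward positions are
degenerate and rejected. One published duplication row omits its second
orientation token; the parser defaults it to forward (the only orientation
consistent with the printed class) and records the omission.

Microhomology at a junction is defined operationally as the number of
alternative placements that assemble to the identical derivative sequence,
scanned in both directions from the declared placement; ambiguous junctions
are reported left-aligned (lowest coordinates) so placements are
deterministic. A junction with a non-templated insert has zero microhomology
by construction. The unit tests pin this definition to a brute-force oracle
that enumerates every placement on toy sequences.

## Consensus detection and filters

Two caller-style call sets are merged one-to-one: a pair of calls merges iff
it shares the chromosome pair and class and **both** breakend distances are
at most 1 kb (inclusive). The published rule does not state whether one or
both breakends are constrained; we chose the stricter both-breakend reading,
configurable via `max_dist`. Multiplicity is resolved greedily by smallest
summed breakend distance with coordinate tie-breaks — one-to-one matching
prevents a single call from validating two candidates. Consensus coordinates
come from the split-read-precise call when exactly one set flags precision,
else from the first set.

Support extraction mirrors standard discordant/split evidence: split reads
must place both clip boundaries within ±10 bp of the breakends (a small
tolerance absorbing microhomology-driven clip ambiguity); discordant pairs
must flank both breakends in junction-consistent orientations within a
500 bp window. Reads below mapping quality 20 and duplicate-flagged reads
are discarded. Validation requires at least one breakend inside the gene
body (`chrX:66763873-66950461` for the real locus) and at least ten
supporting pairs **and** ten split reads.

The cDNA-contamination rule addresses a failure mode of targeted DNA-seq:
reverse-transcribed mRNA in the library masquerades as genomic deletions
whose breakpoints coincide with splice donor/acceptor sites. A sample is
flagged (and reported GSR-negative) iff it has at least one candidate and
*every* candidate is such a splice-coincident deletion; the coincidence
tolerance defaults to ±5 bp.

## Copy number and allele fraction

Locus copy number is mean locus coverage normalized by the mean of the mean
coverages of five control regions on the capture panel, expressed as a ratio
against the same quantity in a copy-number-neutral sample. The published
normalization formula is referenced but not reproduced in the text we worked
from; dividing by the across-region mean of per-region means is the unique
reading consistent with the prose, and whether the original averaged
per-region means or pooled bases is unstated — per-region means were chosen.
Amplification is called at ratio > 1 by the stated definition; at realistic
coverage noise a margin (e.g. 1.2) is advisable and the threshold is an
argument.

Junction allele fraction is supporting evidence over supporting plus
reference-spanning depth: supporting counts each fragment once (union of
pair- and split-read identifiers), spanning is the mean count of concordant,
unsplit, non-duplicate reads crossing each breakend with ≥5 aligned bases on
both sides, and a Clopper–Pearson 95% interval is attached. This is a
deliberate re-derivation rather than a port of any specific caller's VAF
machinery: it captures "fraction of evidence supporting the variant" at the
level the downstream analysis consumes, and its accuracy is established by
parameter recovery on synthetic mixtures (absolute bias below 0.05 at 200×
across cell fractions 0.05–1). A small upward bias is intrinsic — supporting
evidence is fragment-level while spanning depth is read-level — and stays
well inside that bound at the tested depths.

SNV calling replaces the two callers' genotype-likelihood machinery with
their published decision thresholds on pileups: rule-set A requires ≥3
alternate reads, ≥10% allele fraction and depth ≥20; rule-set B filters to
mapping quality ≥5 and requires ≥1% fraction. Only the intersection (keyed
by chrom/pos/ref/alt, one record per alternate allele) is reported, with
rule-set A's counts. At the clinically observed VAF floor (~38%) and 100×,
the consensus recovers essentially every site (checked over 200 binomial
replicates).

## Derivative chromosomes, liftover and allele reconstruction

A derivative chromosome is an ordered list of oriented source segments plus
inserted sequences, which makes the coordinate map bidirectional and total:
every derivative base lifts to exactly one source base (or an insert
offset), and a source base inside a duplication lifts back to every copy.
Junction application is defined on the evolving derivative: forward/forward
junctions are "retain through the left breakend, continue from the right"
(which uniformly produces deletions and tandem duplications), a single
inversion junction reverses the bracketed segment, and a translocation
splices the partner window from the right breakend on, with the insert at
the seam. Applying a junction whose breakend no longer exists (e.g. removed
by a prior deletion) is an explicit error rather than a silent fix-up, and
events are applied in the declared order because order demonstrably matters.
The supported application regime is breakends on forward-oriented segments;
stacking events inside already-inverted segments is out of scope.

`reconstruct_allele` exists for the case where no order is declared: it
searches application orders (and breakend placements among duplicated
copies) for a derivative on which *every* input junction's seam signature
survives, returning the first success under a deterministic enumeration that
tries duplications before deletions, each by coordinate. For the published
three-junction allele this recovers the duplication-first model; for
mutually erasing deletions it correctly reports inconsistency. Masking for
read-mapping is hard-masking (N-fill) of every source window that
contributed a segment — the published description does not enumerate which
endogenous sequences were masked, so the implementation masks all
contributing windows.

## Splice-junction matrices and variant transcripts

RNA evidence is consumed as spliced alignments against the tumour-specific
derivative assembly. A junction observation is kept iff the read aligns at
least 5 bp on each side of the gap (boundary inclusive). Exon and intron
bins tile the derivative — exons inside duplications contribute one bin per
copy — and the matrix counts ordered (donor bin, acceptor bin) observations,
with transcription taken on the derivative's forward strand (the simulated
libraries are stranded). Junction calling against the matched control from
the same subject is deliberately conservative: a case junction is
rearrangement-dependent iff the control lacks it entirely and it either
crosses a rearrangement seam of the derivative or reaches `min_reads`
(default 3; the source analysis states no count threshold, so it is exposed
as an argument).

Transcript assembly builds a junction graph over exon instances, walks it
from the configured 5' exon following observed junctions (branches in
decreasing count order, ties by lower acceptor), and emits one model per
terminal branch — so three alternative 3'-terminal exons yield three
transcript models sharing their 5' exons. Novel acceptors with no annotated
exon define terminal exons of a configurable extension length (default
300 bp), standing in for the coverage-extent inference used on real data.
Translation runs from the canonical ATG with the frame carried across
junctions to the first in-frame stop (a missing stop is flagged, not
fatal); the canonical prefix is delimited by comparison with the canonical
translation, and the C-terminal extension is scanned for an NLS-like basic
motif: any 5-residue window within the first 15 extension residues
containing at least two K/R residues (this threshold admits both VRRGR-type
and VGKTK-type motifs reported for such variants; requiring three would
reject VGKTK). Molecular weights use average residue masses, matching
gel-mobility comparisons.

## Statistics

The two-tailed Fisher exact test sums hypergeometric point probabilities not
exceeding the observed table's (relative tolerance 1e-12) — the convention
that uniquely reproduces all three published cohort p-values (0.0450,
0.0741, 0.0021) from their printed counts, and the implementation is checked
exhaustively against a log-binomial enumeration oracle for all tables with
n ≤ 40. The one-sided Mann–Whitney U test delegates to R's rank-sum
machinery (exact for small untied samples, normal approximation with tie
correction otherwise), with the direction a per-call argument since the
source analyses state only which group was expected higher. Relative
expression uses the differential-Ct transform
$2^{-(\Delta Ct_{sample} - \Delta Ct_{calibrator})}$ with
$\Delta Ct = Ct_{target} - Ct_{housekeeping}$. Normality pre-testing
(used upstream only to justify the rank test) is intentionally not
implemented.

## What the synthetic cohort does and does not emulate

`make_reference` builds a 200 kb locus chromosome carrying an 8-exon gene
(~3.1 kb coding, a 1,041-residue product — AR-like proportions at reduced
intron scale), an intron-3 cryptic exon, four upstream exons named
`4-ups`/`5a-ups`/`5b-ups`/`5c-ups` after their splicing order in variant
mRNAs, and a 50 kb partner chromosome carrying the five copy-number control
regions and a cassette exon whose recruitment yields a 13-residue VGKTK
extension. Coding spans are stop-free by construction with planted basic
motifs in the cryptic/upstream cassettes, so every rearrangement-dependent
transcript has a known protein truth. Clones carry ordered junction lists,
integer locus copy numbers and hotspot SNVs at stated fractions; fragment
lengths are Normal(300, 50) truncated at mean + 4 sd (the same bound the
concordance test uses, so an unrearranged genome yields no discordant pairs
by chance), reads are 2 × 150 bp DNA and 2 × 50 bp spliced RNA, and reads
are emitted pre-aligned through the derivative's own coordinate map, so
junction-crossing reads appear as correctly clipped split alignments and
straddling pairs as discordant pairs.

Deliberate simplifications: no sequencing-error or base-quality model by
default (a substitution rate is configurable; no stage consumes qualities
beyond depth), no GC or capture-efficiency bias, no repeat-driven
multi-mapping — on real data the locus's high repeat content is precisely
what makes detection hard, so passing tests here demonstrate the logic of
the pipeline, not its sensitivity on repeat-rich alignments. Caller
emulation jitters breakend positions uniformly and adds caller-unique
decoys; it does not model correlated caller errors.

Default problem sizes were chosen as the smallest at which the statistical
properties under test are comfortably identified: 100× DNA coverage for
detection examples (the ten/ten support rule needs deep targeted coverage,
as on the real capture panel), 200× for VAF-recovery properties, 60× for
copy-number ratios, and 20–30k RNA read pairs per sample. The bundled
analysis scripts use 150× for the six-sample cohort so that sub-clonal
junctions at ~30% cell fraction clear the support thresholds.

## Known limitations

* Junction application assumes breakends on forward-oriented segments;
  nested inversions are not supported.
* `reconstruct_allele` is exhaustive and limited to five operations; its
  complexity grows factorially.
* The pileup is intended for locus-scale intervals, not genome-wide
  scans.
* VCF breakend records are written in standard BND notation, but the reader
  reconstructs junctions from the first-mate records of the package's own
  writer dialect.
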