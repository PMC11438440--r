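---
title: "Methods: mitogenome recovery and species identification from nanopore genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome recovery and species identification from nanopore genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A genome skim is shallow whole-genome shotgun sequencing: far too little
coverage to assemble a nuclear genome, but enough to recover high-copy
fractions such as the mitochondrial genome. On a low-output nanopore flow
cell a single small-mammal sample yields on the order of 100-900 Mbp of
long reads at roughly 5% per-base error (R9-class chemistry), of which only
about 0.01-0.4% of bases are mitochondrial. `mitoskim` implements the full
desk workflow over such data:

1. quality filtering (reads with mean Q-score >= 7);
2. mitochondrial read recruitment, by a strict blastn-style search against
   a broad mitogenome panel or by permissive mapping against the closest
   available reference;
3. mitogenome reconstruction under six routines - three data types (whole
   run, panel-filtered, reference-filtered) crossed with two assemblers
   (reference-guided consensus, minimal de novo overlap assembly) - with
   optional consensus polishing;
4. gene-level quality control by annotation projection and open-reading-frame
   checks under the vertebrate mitochondrial genetic code;
5. species identification from raw recruited reads against taxonomically
   scoped databases with explicit hit ranking.

A simulator generates annotated mitogenomes and ONT-like skim runs with
known per-read truth, so every stage is testable without downloads.

## Per-read quality

A read's Q-score is the ONT convention: per-base Phred scores are converted
to error probabilities, averaged, and converted back
(`-10 log10(mean 10^(-q/10))`). This matches how MinKNOW/NanoFilt-style
tools aggregate read quality; the inclusive `>= 7` cutoff is the routine
filter for this data class. FASTQ input is fixed to Phred+33; other
encodings are rejected rather than guessed.

## The aligner

All recruitment, assembly and identification steps run on one seeded,
gapped local aligner written for the blastn cost model used in this
workflow: reward +1, mismatch -4, and a gap of length L costing
`1 + 2L` (gapopen 1, gapextend 2, kept exactly as practitioners pass them
to blastn, including the unusually cheap open cost). Exact 11-mer seeds are
found on both strands through a hashed word index; seeds sharing a diagonal
band are clustered, and each cluster is extended by banded affine-gap
Smith-Waterman (default half-width 50). A band covering the whole matrix
turns the extension into exact local alignment; the test suite verifies
that mode against a brute-force dynamic-programming oracle and against an
independent aligner with the same gap model. One best HSP is kept per
read/subject pair. No X-drop early termination is implemented: at the
problem sizes this toolkit targets (16.5 kb references, kilobase reads)
banding alone bounds the work, and the exact full-band mode doubles as the
oracle reference.

Circular references are searched through a doubled sequence; hits are
re-mapped modulo the length and duplicate diagonals (offset by exactly one
genome length) are skipped.

E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)`.
`lambda` is solved from the score-generating equation
`sum p_i p_j exp(lambda s_ij) = 1` (for +1/-4 under uniform composition,
lambda ~ 1.383; for +1/-1 it is exactly ln 3). `K` is a documented constant
0.46 rather than the series computation: within this toolkit the E-value
serves as a monotone ranking statistic at fixed database size, every
consumer orders hits by (E-value, identity), and no absolute NCBI-calibrated
expectation is claimed. Ungapped parameters are applied to gapped scores
without edge-effect correction, the same deliberate approximation.

A 100-column minimum alignment length accompanies the 90% identity gate in
recruitment and identification searches. The identity cutoff itself is
derived, not assumed: a 95% nucleotide-homology threshold minus the ~5%
sequencing error gives 90%; with ~1%-error chemistry the same rule gives
98-99%.

## Recruitment routes

The panel route recruits a read iff it aligns to any member of a broad
mitogenome panel at >= 90% identity over >= 100 columns. The reference
route emulates long-read mapping against the closest relative and uses a
permissive 80% identity floor (mapping tolerates more divergence than the
strict blast cutoff; the floor is a configurable default, not a claim about
any mapper's internals). Reports carry the mitochondrial fraction both as a
base fraction (matching how yields are discussed) and as a read fraction.
Nuclear copies of mitochondrial segments (NUMTs) are recruited like any
other high-identity match; the simulator can embed one so the resulting
precision loss is measured rather than hidden.

## Assembly

**Reference-guided.** Reads are aligned to the doubled circular reference
and a per-column consensus is taken over the pileup: majority vote over
substitutions and deletions, with insertions accepted when supported by
more than half of the covering reads. Columns with zero coverage retain the
reference base and are flagged - deliberately reproducing the
reference-bias failure mode of guided assembly (it succeeds even at very
low yield, but uncovered regions are the reference, not the sample). The
assembly succeeds whenever at least one read aligns.

**De novo.** A minimal overlap-layout-consensus stand-in, not a
reimplementation of any production assembler: candidate mitochondrial reads
are recruited by canonical k-mer multiplicity (k = 16; a read qualifies
when the upper quartile of its k-mer multiplicities is >= 3 - the upper
quartile, because at 5% error most k-mers of even a high-copy read are
unique), laid out by greedy end extension along best overlaps (>= 300
columns at >= 80% identity, about what two 5%-error reads share), and
polished by pileup consensus. Circularity is declared when the contig start
re-occurs near the end with >= 1 kb overlap at >= 90% identity, trimming
the duplication. The contract mirrors observed de novo behaviour on skims:
assembles at adequate depth, and *declares* `not_assembled` when no contig
reaches 80% of the expected ~16.5 kb or mean depth falls below 3 - low-yield
failure is an explicit category, never an exception.

**Polishing** is consensus re-estimation: re-align the reads to the current
contig, recompute the consensus, repeat to a fixed point or a round budget.
Signal-level polishing is out of scope (raw signal is not an input), and
the null result it produced in practice is mirrored here as a property: at
adequate depth the consensus converges within a few rounds and further
rounds change nothing.

Canonical rotation aligns a probe from the reference origin to the doubled
contig, reverse-complementing and rotating so position 0 matches reference
position 0; the applied offset is recorded.

## Gene-level QC

The reference annotation is projected through a circular-aware banded
alignment of the (rotated) assembly to the reference; each gene's endpoints
map through the alignment, with unmappable or collapsed spans (mapped span
below 30% of the gene) reported unlocated. Projection refuses references
below 70% overall identity. Each gene is then classified:

- `complete` - CDS: a valid start codon at the mapped gene start (accepted
  starts ATG, ATA, ATT, GTG under the vertebrate mitochondrial code) and a
  first stop codon (TAA, TAG, AGA, AGG) that is terminal - falling within
  `endpoint_slack` (6 bp) of the mapped end and no earlier than 90% of the
  reference gene length. The frame is anchored at the mapped start and
  never re-anchored at alternative starts, so a frameshifted gene cannot
  classify as complete through a chance compensating ORF; rRNA/tRNA:
  located span within 95% of the reference length.
- `stop_codon` - an internal stop in the annotated frame (frameshifts
  almost always land here: a shifted frame hits a stop every ~16 codons).
- `incomplete` - located but short (< 90% of the reference CDS length) or
  missing start/stop.
- `null` - not located in the contig.

`not_assembled` remains a genome-level category that suppresses gene
tallies. The 90%/95% completeness fractions are this package's choices
(they keep single-indel consensus noise from flipping a complete gene to
incomplete) and are exposed in `qc_config()`. Annotation is projection
from an annotated relative, not ab initio gene finding; the QC categories
only require located genes plus reading-frame checks, so covariance-model
tRNA detection is deliberately out of scope. Markers (COI, CYTB) are
extracted only when their assessment is `complete`; rejections carry the
failing status.

## Identification

Reads (typically panel-recruited) are searched against a taxonomically
scoped database: the full collection, one order, or one family - scoping
is an in-process filter over a lineage table rather than any external
partitioning. Each read keeps its best hit; the per-read best hits are
pooled and ranked by e-value ascending, then percent identity descending
(with score and subject id as deterministic tie-breaks, which the source
rule leaves unspecified), and the first-ranked hit's lineage is the
identification. "Pooling per-read best hits for the sample, then ranking
globally" is this package's reading of ranking "the hits for each
individual"; both the per-read table and the pooled ranking are exposed so
either convention can be inspected. Agreement percentages use reads-with-
hits as the denominator (the hit counts published alongside such
percentages pair naturally with that choice); zero reads with hits yields
an explicit undefined outcome, never 0%.

## The simulator and what it does (not) show

`build_mitogenome()` lays out the canonical vertebrate complement - 13 CDS
(valid ORFs under translation table 2, including TGA-Trp codons that betray
the genome under the standard code), 2 rRNAs, 22 tRNAs, a control region -
around a 16.5 kb circle, deterministically per seed. `mutate_genome()`
derives relatives at a chosen substitution divergence while redrawing any
substitution that would break an ORF (congeners have intact genes), so a
2% divergence yields ~98% identity exactly. `simulate_run()` draws
log-normal read lengths (sigma 0.70, putting the 99th percentile near 4x
the mean - published runs report only means), uniform circular start
positions, uniform strands, a 55/25/20 substitution/insertion/deletion
error split (a typical R9-class profile; the total ~5% figure is the
stated chemistry rate), and per-read qualities tuned so the expected
Q >= 7 pass fraction is 0.82.

Desk scaling: test fixtures use 1-10 Mbp yields with mitochondrial
fractions roughly ten-fold the field values so that recruited read counts
land in a workable range; full-scale configurations remain expressible.
Yield-class boundaries in the benchmark aggregation scale proportionally
(coverage, which the boundary proxies, scales with yield). The simulator
does not model squiggle-level error motifs, homopolymer-specific errors, or
quality/error correlation; passing tests therefore demonstrate the
pipeline's correctness under a realistic error *rate* and length regime,
not robustness to every base-caller artifact of real flow cells. Real-run
yield thresholds (such as a particular Mbp boundary for de novo success)
are empirical properties of real data that a scaled synthetic cannot
reproduce; the stand-in exposes analogous thresholds instead.

The default fixture bundle builds a hierarchical synthetic taxonomy -
backbones derived along the tree (ancestor, then order, family, genus,
species), so congeners sit a few percent apart, confamilial genera ~5-8%,
and orders >15% - a 60-record identification database over 3 orders x 2
families, a 10-genome filter panel anchored near the family backbones
(its nearest member ~4-6% from any sample, the regime the 90% cutoff was
derived for), and one sample whose species is deliberately absent from the
database - the scenario where the correct outcome is the nearest congener:
genus right, species wrong. The default mitochondrial fraction (0.04 at
1-2 Mbp yields) is roughly ten-fold the field values, chosen once so
recruited read counts per sample land in the tens.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open on the stored + strand everywhere
  internally; GFF3 I/O converts from 1-based inclusive.
- One master seed drives every stage; per-stage seeds derive from it by a
  fixed documented arithmetic, so partial reruns reproduce bit-exactly.
- Consensus ties prefer the template base, then alphabetical order.
- Empty inputs are contracts, not crashes: an empty FASTQ is an empty read
  set; a run with no mitochondrial reads filters to an empty set, assembles
  to `not_assembled`, and identifies to an explicit no-identification.
- `lambda` is solved to residual < 1e-9 by root bracketing; the bracket's
  upper end is where the match term alone reaches 1, which always bounds
  the root.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on simulated data at
desk scale, chosen as sizes a laptop analysis of one skim would touch:
16.5 kb genomes; read sets of 5-30X mitochondrial depth (tens to a few
hundred reads); whole-run simulations of 1-9 Mbp; a 60-record database;
1,000 alignment-oracle pairs up to 60 bp; 10-20 seeded replicates for
stochastic recovery properties.

## Known limitations

- The de novo arm is a stand-in with the contract of a skim assembler, not
  a repeat-aware production assembler; tandem duplications or heteroplasmy
  are out of scope.
- E-values are internally consistent ranking statistics, not calibrated
  expectations; comparing them across databases of different sizes is
  meaningful only through the explicit `m`/`n` dependence.
- Annotation quality is bounded by the projection reference: a gene absent
  or mislabelled in the reference is invisible to QC.
- The identification database is whatever the user supplies; the usual
  caveats about mislabelled public records apply unchanged.
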