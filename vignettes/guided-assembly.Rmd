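---
title: "Transcriptome-guided assembly: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-guided assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txguide)
```

## The problem and the model

For a species without a reference genome, transcriptome inference must start
from either de novo assembly or from alignment against the transcriptome of
a related species. `txguide` implements the guided route at the *gene*
level: each read is assigned to the gene whose reference transcript it best
matches under a local aligner, the assigned reads are assembled per gene,
and each resulting contig is validated by re-annotation against the same
reference. The unit of inference is deliberately the gene, not the
transcript: isoform resolution is out of scope, and each gene is represented
by its longest reference transcript, which also serves as the yardstick for
all coverage metrics.

The central empirical question the package is built to answer is how read
assignment behaves as the focal species diverges from the reference. The
simulator therefore folds sequencing error, polymorphism and species
divergence into a single per-base substitution probability, applied
independently to each read position. This is a deliberate simplification:
real divergence is autocorrelated along genes (conserved domains, codon
structure) and real sequencing error is position- and platform-dependent.
What the simulation isolates is the aligner-and-threshold behaviour under a
controlled mismatch load.

## Pipeline stages and their parameters

**Quality control.** Ends are trimmed until a base of Phred ≥ 13
(error < 0.05) is met; a trimmed read is rejected if any base is below
Phred 5, more than 10% of bases are below 13, the mean is below 20, or
fewer than 30 bases remain. All four boundaries are strict, so a read that
sits exactly on a boundary survives; the rules are applied to the trimmed
read, in that order. In paired mode a rejected mate is replaced by a 50-base
all-N placeholder so R1/R2 files keep record parity; placeholders cannot
seed an alignment and pairs where both mates are placeholders are dropped
before assignment. Pair merging accepts the longest suffix–prefix
read-through overlap of at least 8 bases at ≥ 90% identity — a
deterministic criterion chosen over a statistical merge test so that results
carry no dependency on an external merger; the merged base at a
disagreeing column is the higher-quality one and merged qualities take the
per-position maximum. The over-representation filter (identical-sequence
cap) ships off by default: no principled threshold generalises across
library types, so capping is left as an explicit analyst decision.

**Alignment.** The seed-and-extend aligner indexes every exact 9-mer of the
reference (words containing N are skipped; only the plus strand is indexed,
the minus strand being searched by reverse-complementing the query). Seed
hits are grouped by diagonal, extended ungapped under an x-drop of 20, and
refined by a banded affine-gap local DP (half-band 5 diagonals around the
seed cluster) with full traceback, so every HSP carries exact column,
identity and score counts. Scoring is the classic nucleotide-BLAST scheme —
match +2, mismatch −3, gap open 5, gap extend 2 — the least surprising
completion given that only the word size is dictated by the assignment
protocol. Word size 9 makes seeding sensitive enough for 30% divergence on
100-base reads (the chance that an 80–100-base read retains no intact
9-mer is negligible below ~30% divergence, and failures at 30% are exactly
the degradation the method measures). E-values are not computed; ranking
uses the raw score, so no subject-length "attractor" effect is introduced.
Coordinates are 0-based half-open throughout, with subject intervals always
on the subject plus strand.

**Assignment.** An HSP supports assignment only when it covers more than
70% of the read and exceeds 70% identity over its columns (both strict).
Among passing HSPs, each gene is represented by its best HSP (multiple HSPs
of one read on one gene never sum) and the maximal score defines the hit
set. Ties across gene ids set `hit_multigene`; a tie on one gene id across
reference sources sets `hit_multispecies`. Under the default `ties =
"exclude"` policy, tied reads count toward no individual gene — ambiguity
on paralogs is information to report, not noise to resolve — and a
`--ties=duplicate` style option (`ties = "duplicate"`) exists for
sensitivity analysis, counting a tied read once per tied gene and as
correct when its true gene is among the tie. Whether tied reads should
count toward recovery was genuinely open; exclusion was chosen as the
default because it makes rr and sr conservative and keeps the two policies
ordered (duplicate ≥ exclude for every gene).

**Assembly and validation.** The built-in assembler is a greedy
overlap-layout-consensus procedure: repeatedly merge the contig pair with
the longest suffix–prefix overlap (both orientations) of at least 30 bases
— the QC minimum read length — at ≥ 95% identity, with a per-column
majority vote carried through merges, so a consensus base is always
supported by at least one member read at that column. Ties in overlap
length break by lexicographic read id, making assembly deterministic.
Validation re-annotates every contig with the same aligner and thresholds;
the best HSP is authoritative: it fixes the gene (re-binning contigs whose
bin and annotation disagree), orients the contig to the reference plus
strand, and discards contigs with no passing hit. Adapters reproduce the
documented invocations of Trinity (`--normalize_reads`, stranded), Spades
(`--careful`, `--cov-cutoff auto`) and CAP3 (defaults) when those binaries
are present, and fail loudly when they are not.

**Metrics.** Completeness and contiguity are computed from each validated
contig's best-HSP subject interval on the gene's longest reference
transcript: completeness is the covered fraction under the union of all
contig intervals, contiguity the covered fraction under the longest contig
alone (length ties break lexicographically). Using pairwise HSP coordinates
instead of a multiple alignment of contigs onto the reference is a design
choice: it is deterministic, dependency-free, and measures the same
covered-base cardinality. Interval arithmetic is delegated to `IRanges`.

## The synthetic catalog

`synthesize_catalog()` generates gene sets in which no two genes share any
9-mer on either strand, by building each sequence as a random walk in the
order-9 De Bruijn graph that avoids every word already claimed by another
gene (plain rejection sampling cannot reach the word densities involved: 50
genes of 1 kb occupy roughly 40% of the 9-mer space). Word-disjointness
guarantees that at zero divergence every read seeds only on its own gene,
making the ideal outcome — all genes *perfect*, completeness and contiguity
1 — exactly attainable and testable. Planted paralog pairs (mutated copies
of existing genes, exempt from the screen against their template) produce
controlled multigene ties.

What this emulates, and what it does not: real transcriptomes contain gene
families with graded homology, shared domains, repeats and length
heterogeneity spanning two orders of magnitude. A word-disjoint catalog is
the opposite extreme — maximally separable — so passing the ideal-case
tests demonstrates correctness of the machinery, not performance on real
paralog-rich transcriptomes; the planted-paralog mode probes the ambiguity
machinery specifically. Simulated reads also carry uniform Phred 40
qualities so the QC stage is a no-op on them, isolating assignment
behaviour from filtering.

Tiling is even-spaced by default — `n = ceiling(coverage * L / r_eff)`
reads with starts spanning `[0, L − r_eff]` — which realises the stated
coverage exactly and keeps every test deterministic; a random-start mode is
available behind the `tiling` flag. Each gene draws from its own RNG
sub-stream derived by a stable hash of its id, so simulations are
order-independent and gene sets can be extended without disturbing
existing reads.

## Numerical conventions and degenerate inputs

Strict inequalities at every QC and assignment boundary; 0-based half-open
intervals; deterministic tie-breaks everywhere (lexicographic transcript id
for equal-length transcripts, lexicographic read id in assembly, sorted
gene ids in tie sets, lexicographic contig id for equal-length contigs).
Empty inputs error early (`build_gene_catalog`, `greedy_assemble`,
`seed_index`) rather than propagating empty results; queries shorter than
the word size and all-N placeholders yield empty HSP lists by construction.
A gene with reads but no passing assignment gets rr = 0 and sr = NA
(written as "NA" in TSV output) and the *undetectable* category; rr = 0
with a defined positive sr is rejected as an impossible state. The
specificity of a gene that only captured foreign reads (rr = 0, sr = 0)
falls in the *mixed* category, the only consistent reading of the typology.

The exact Smith–Waterman cross-check (`sw_oracle`) delegates to
`Biostrings::pairwiseAlignment` under the identical scoring scheme and is
used in tests as an upper bound on HSP scores and as the best-hit oracle;
it guards against sequences over 2,000 bases because of its quadratic cost,
and clips scores at zero (the empty local alignment).

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path while staying comfortably reproducible on a
laptop: catalogs of 3–50 genes of 0.3–1 kb, 10X coverage, the four
divergence levels 0/5/15/30%, and 200 random instances for the
heuristic-vs-exact best-hit comparison. The architecture streams reads and
indexes subjects once, so full-transcriptome catalogs (tens of thousands of
genes) differ only in wall time, not in code path.

## Known limitations

- The internal assembler's 95% overlap identity is calibrated for reads
  that agree with each other. Reads carrying independent substitutions at
  divergence *d* agree pairwise at only about `(1−d)² + d²/3` (90% at
  *d* = 0.05, 73% at *d* = 0.15), so at high divergence bins assemble into
  single-read contigs: completeness stays high but contiguity collapses.
  Dedicated assemblers with error correction are the right tool there — the
  adapters exist precisely for that.
- Substitution-only divergence: no indels are simulated, and the banded
  extension (half-band 5) only tolerates small indel offsets in real data.
- No e-value statistics, no low-complexity masking; raw-score ranking can
  differ from BLAST-ranked output on borderline hits.
- Expression heterogeneity, insert-size models and platform error profiles
  are not simulated; the uniform-coverage design measures assignment, not
  quantification.
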