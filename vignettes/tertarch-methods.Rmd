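---
title: "Methods: comparative TERT gene-architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative TERT gene-architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tertarch)
```

`tertarch` implements a comparative analysis of the exon–intron
architecture of TERT (telomerase reverse transcriptase) genes:
projecting intron positions into protein coordinates and classifying
them against a reference species, transferring reference motif
annotations through alignments, mining lineage-restricted conserved
blocks, and classifying alternative-splice (AS) variants structurally.
This vignette documents the models and procedures, the tunable
parameters, the numerical choices, and what the simulator-based
validation does and does not establish.

## Coordinate model

All transcript and protein offsets are 0-based half-open; ordinal ranks
(exon 8, intron 4, alignment column 12) are 1-based. GFF3 input
(1-based inclusive) is converted on read. An exon boundary is stored as
a single integer: the transcript offset of the first nucleotide of the
downstream exon, i.e. the cumulative length of the exons 5′ of the
intron. This one integer determines the intron's position in every
coordinate system:

* hosting residue: `residue_index = ⌊(b − cds_start)/3⌋` (0-based),
* codon phase: `phase = (b − cds_start) mod 3`, the number of
  nucleotides of the interrupted codon lying 5′ of the intron.

For a phase-0 boundary the hosting residue is the residue immediately
after the boundary, which keeps the formula uniform across phases.
Boundaries in untranslated regions carry no protein position; they are
excluded from conservation counts and reported separately. Minus-strand
genes are reverse-complemented on transcript construction and yield the
same transcript model as their plus-strand mirror (property-tested).
A CDS whose joined length is not a multiple of three — common in
fragmentary TERT models — is flagged and its trailing 1–2 nt dropped at
translation rather than rejected.

## Pairwise alignment

Cross-species comparisons run on pairwise global protein alignments
(affine Needleman–Wunsch; BLOSUM62, gap open 11, extend 1, a gap of
length L costing `open + L·extend`). Multiple alignments are imported
from aligned FASTA, not computed: building MSAs is a job for dedicated
aligners, and the intron projection only needs pairwise maps to the
reference. The aligner is the standard dynamic-programming engine from
Biostrings behind the package's interface; the test suite checks its
optimality against an independent brute-force enumeration over all
alignments of short sequences, and checks that the emitted alignment
itself achieves the reported score. Nucleotide mode (match 2, mismatch
−3, gap open 10, extend 0.5 — configurable defaults) serves the
variant-mapping step.

Percent identity is not uniquely defined in the literature, so the
denominator is a mode flag: `"aligned"` (default) counts all columns
between the first and last position where both rows have residues
(terminal gaps excluded, internal gaps penalised); `"ungapped"` counts
only columns where both rows have residues. Multi-row alignments return
the mean over all pairs.

## Intron conservation

Each query intron's hosting residue is mapped to its alignment column;
it is *conserved* when some reference intron's column lies within
`tolerance` columns (default 0: exact shared column, the strict reading
of "equivalent position"; the flag exists for sensitivity analysis).
Codon phase is recorded but not required to match by default, since
cross-phyla comparisons are made on protein position; `require_phase`
tightens this. Each reference intron can match at most one query
intron; assignment is greedy by column distance with ties to the
5′-most intron, which resolves the rare case of two query introns
competing for one reference column deterministically.

Invariants: `n_conserved + n_specific = n_introns`;
`n_conserved ≤ min(n_query, n_reference)`; `n_conserved` is
non-decreasing in the tolerance. These hold structurally and are
property-tested over randomized models.

## Motif transfer and conserved blocks

Reference motif intervals — for TERT the canonical series GQ (with the
DAT sub-region), CP, QFP, T, the RT motifs 1, 2, A, B′, C, D, E, plus
the derived N-terminal linker (between GQ and CP) and CTE (after E) —
are given as residue intervals on a named reference row. For each
target row, coverage is the fraction of reference motif columns aligned
to target residues. Status thresholds (present ≥ 0.70, partial ≥ 0.20)
are package inventions: published analyses make qualitative
present/absent calls by eye, so the cut-offs are configuration keys,
logged in every output header. Two packaged coordinate sets (hTERT,
C. elegans TERT) are approximate, literature-based fixtures intended to
be overridden with exact annotations.

Conservation profiles report, per column, the modal non-gap residue and
its frequency. The denominator is a flag (`"nongap"` default, `"all"`
alternative) because the treatment of gap rows in such profiles is
rarely stated; modal ties break alphabetically for determinism; all-gap
columns are dropped.

The conserved-block scanner formalises manual lineage-specific motif
calls such as `(I/V)QQRVxLQF`: maximal column runs where at most
`max_states` (2) residues cover at least `f_within` (0.8) of the clade
members while the outside-clade modal frequency stays below
`f_background_max` (0.5); single failing columns flanked by two passing
columns on each side render as `x`; runs shorter than
`min_block_length` (4) are dropped. These parameters approximate, not
replicate, judgements that were originally made by hand; the scanner's
value is that its calls are explicit and reproducible.

## Splice-variant classification

Variants are mapped onto the full-length isoform 1 by global nucleotide
alignment; alignments whose non-gap identity falls below 80% are
rejected as "not a variant of this reference" (such records go to a
rejects table; runs continue). Maximal gap runs become deletion or
insertion segments in reference coordinates. Because an indel bordered
by repeated sequence can slide without changing the spliced product,
classification scans each segment's sliding equivalence class for a
placement whose ends sit at exon boundaries — the same normalisation
logic used for indel representation in variant calling — before giving
up on a boundary interpretation.

Event classes: a deletion with both ends within `tol_nt` (3) of exon
boundaries is exon skipping (reporting 1-based skipped exon ranks, e.g.
"8-10"); an insertion at a boundary whose sequence matches the adjacent
genomic intron at ≥ 90% identity is intron retention; everything else
is a splice-site mutation, with insertions at boundaries lacking
genomic sequence flagged "possible retention". `tol_nt = 3` absorbs
residual junction ambiguity without bridging distinct exons.

Variants are translated in the reference reading frame from the image
of the reference start codon; a stop before the final codon is a
premature termination codon and the ORF is called lost. Motif presence
is recomputed on the variant protein via alignment to the reference
protein, and domain status derives purely from motif status: TRBD from
{CP, QFP, T} and RT from {1, 2, A, B′, C, D, E} (each restricted to
motifs the reference actually carries — planarian-style references
lacking CP use {QFP, T}); *intact* iff all present, *missing* iff all
absent, *truncated* otherwise. This derivation is property-tested over
all 3^9 motif-status combinations. Variants supplied only as protein
skip nucleotide-level event typing and receive motif/domain calls only.
Boundaries for species without genomes can be projected from a related
donor species through a protein alignment (donor intron residue →
target residue → cDNA offset using the donor phase), with unplaceable
boundaries flagged and the projection rejected when more than half are
unplaced.

## The simulator and what it shows

`simulate_family()` builds a stop-free, codon-structured ancestral gene
(default 16 exons — the exon count of planarian TERT, matching hTERT's
15 introns — exon lengths uniform on 60–240 nt, intron sequences with
canonical GT..AG ends) and evolves it depth-first along a user tree.
Defaults emulate a metazoan-scale family: substitution rate 0.5 per
codon site per unit branch length on a tree with branch lengths 0.1–0.6,
indel rate 0.01 per codon site, geometric indel lengths (mean 2
codons), intron loss probability 0.1 and motif loss probability 0.05
per branch, Poisson intron gains (mean 0.5 per branch) landing at
uniform CDS positions never within 3 nt of an existing boundary (keeps
the ground truth unambiguous). Substitutions pick a uniform alternative
residue, then a uniform codon for it — divergence, not realism, is what
the downstream tests need, so no empirical exchangeability matrix is
used. Stop-creating substitutions are excluded by construction unless
`allow_stops = TRUE` (used to test PTC logic separately from frame
logic). Splice variants per leaf mix exon skipping (1–3 interior
exons), intron retention and boundary-jittered deletion (±1–2 nt), with
a configurable frame-preserving fraction enforced by resampling;
simulated intron bodies avoid T outside the donor GT so that a retained
intron cannot introduce a stop in any frame, keeping frame-preserving
retentions constructible.

Every event is logged, and replaying the log against the recorded
ancestor must reproduce each leaf byte-for-byte (checked through a JSON
round trip). Two bookkeeping choices to know about: indels operate at
codon granularity (what matters downstream is protein-coordinate
stability; nucleotide-level frameshifts are exercised through the
variant generator instead), and an intron whose hosting codon is
deleted is removed from that lineage and from the truth.

Validation on simulated families establishes: aligner optimality on
short sequences; 100% conserved-intron recall and precision under
substitution-only evolution; ≥ 95% recall at tolerance 0 with indels at
0.01/site; 100% splice-event classification at exact boundaries and
≥ 95% under ±2 nt jitter at `tol_nt = 3`; binomial intron survival on a
50-leaf star tree (mean within 2 SE of n·(1−p)). Problem sizes (20
replicates of 4-taxon families, 200 variants, 1000 random gene models)
were chosen as the smallest that give the statistics meaningful
resolution. What passing does **not** show: the simulator draws
uniform substitutions without rate heterogeneity, evolves introns
neutrally and independently, and does not model alignment-unfriendly
low-complexity regions — real TERTs (extreme length variation,
lineage-specific insertions, fragmentary models) will stress the
alignment step harder than any simulated family, so published per-taxon
counts can only be reproduced by running the pipeline on the real
sequence sets themselves.

## Degenerate inputs and determinism

Empty FASTA files, duplicate ids, out-of-range intervals, CDS < 3 nt,
clades with fewer than 3 members, motif intervals beyond the reference,
and projections with > 50% unplaced boundaries all error with specific
messages; empty variant files yield header-only reports. Every
stochastic routine flows from a single integer seed; reruns are
byte-identical, and each pipeline output TSV begins with comment
headers recording the package version, a configuration hash and input
checksums. Outputs are written atomically so failed runs leave no
partial files.
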