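---
title: "Building and validating multi-marker supermatrices with genecat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating multi-marker supermatrices with genecat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecat)
```

## The problem

Multi-gene phylogenetic analyses need a *supermatrix*: per-marker alignments
joined side by side over a shared taxon set, together with partition
information recording which columns belong to which marker. Assembling one by
hand is error-prone in exactly the ways that are hard to see afterwards —
sample names that differ by an underscore silently become two taxa, a marker
pasted at the wrong offset corrupts every downstream model, and a misspelled
voucher can leave two groups of samples that share no data at all yet sit in
one matrix. genecat is a headless toolkit for this workflow: readers and
writers for the formats the community actually exchanges (FASTA, relaxed
Phylip, Nexus with SETS blocks, tab-delimited specimen tables), a
concatenation/de-concatenation engine, partition-file export for IQ-TREE and
RAxML, and validators that look for the two classic failure modes.

## Data model

Everything flows through three small types:

* a **marker block** — one locus with the sequences of the samples that carry
  it (residues are IUPAC nucleotide codes plus `-` for alignment gaps and `?`
  for missing data; everything is upper-cased on ingestion);
* a **data matrix** — an ordered list of marker blocks over a sparse sample
  universe (a sample need not occur in every marker), plus an optional
  metadata table;
* a **concatenated alignment** — equal-length sequences with whole-marker
  charsets (1-based inclusive column ranges) that tile the columns exactly,
  and optional step-3 codon charsets.

Sample matching is **exact and case-sensitive** throughout. Fuzzy matching
would occasionally rescue a typo, but it would also merge names that users
keep deliberately distinct, and it makes results depend on a similarity
threshold nobody can audit; the validators below are the intended remedy for
typos. Marker and sample names are restricted to the token alphabet
`[A-Za-z0-9_.-]` so they survive Phylip and Nexus round trips unquoted.

## Concatenation

```{r concat}
m <- make_matrix(list(
  marker_block("M1", c(A = "ACGTA", B = "ACCTA")),
  marker_block("M2", c(B = "TGC", C = "TGA"))))
aln <- concatenate(m)
aln$sequences
```

Samples are joined in first-appearance order across markers; where a sample
lacks a marker, the fill character is substituted over that marker's columns.
The fill defaults to `?` (the Nexus missing symbol) rather than `N`, because a
padded cell means "never sequenced", which is different information from a
sequenced-but-ambiguous base; `N` or `-` can be chosen instead. Markers must
already be aligned — a ragged marker is a hard error pointing to the align
step, never silently padded.

`deconcatenate()` inverts this using the charsets. By default records that
are entirely `?`/`N` within a marker's columns are dropped, so the padding
introduced above does not fabricate data rows when a supermatrix is split
back into per-gene files. Note that for sparse matrices the *within-marker
record order* after a round trip follows the concatenated sample order, not
the original file order; tests therefore compare records by name.

Codon subsetting splits a protein-coding marker's charset into three step-3
sets (`M1_pos1 = 1-6\3` and so on). The reading-frame offset says which codon
position the marker's first column carries; all three sets always partition
the marker's columns exactly, whatever the offset or length. For a marker
shorter than three columns some subsets are empty; they are representable
(start past end) but omitted by all writers, since downstream programs
reject empty ranges.

In partition files, codon triplets *replace* their marker's whole-range set —
IQ-TREE and RAxML require non-overlapping partitions. The Nexus SETS block of
an exported alignment, by contrast, keeps both the whole-marker and the codon
sets, which is legal there and preserves the full structure for re-import.

## Formats and dialects

* **FASTA** — the header token up to the first whitespace is the sample name;
  description text is dropped because concatenation matches exact tokens.
* **Phylip** — the *relaxed* dialect (names of any length, whitespace
  terminated); strict 10-character Phylip would truncate exactly the names
  matching depends on. Sequential and interleaved layouts are auto-detected
  on read; sequential is the write default.
* **Nexus** — DATA/CHARACTERS block with case-insensitive keywords;
  MISSING/GAP symbols from the FORMAT line are honored and canonicalized to
  `?`/`-`. Whole-marker charsets must tile the columns (overlaps and gaps
  raise an error; uncovered runs can optionally be kept as
  `unassigned_<i>` markers).
* **TSV** — one row per sample; columns named `sequence_<marker>` carry
  sequences, everything else is metadata. An empty cell means the sample
  lacks that marker. `build_sequence_names()` joins chosen metadata columns
  (voucher, species, locality, ...) into display names for the concatenated
  output, sanitized and checked for collisions.

All writers emit `\n` line endings and a trailing newline, so outputs are
byte-stable and can be compared against golden files.

## Validation

Two validators target the two classic assembly failures.

**Outlier sequences per marker.** For every alignment column the Shannon
entropy $H = -\sum_c p_c \log_2 p_c$ is computed over the counted states A,
C, G, T and gap; `?`, `N` and the other ambiguity codes are excluded as
absence of signal, while gaps are kept as a fifth state because indel
structure is alignment signal. The cost of a sequence pair is the sum of
entropies over columns where both carry counted states that differ; a
sequence's score is the **median** of its pairwise costs against all other
sequences (full pairwise analysis, no sampling). A sequence is flagged when
its score exceeds $Q_3 + k \cdot (Q_3 - Q_1)$ over the per-sequence score
distribution, with quartiles by linear interpolation (type 7) for
determinism across implementations. The coefficient $k$ defaults to 20,
suitable for conserved protein-coding barcoding markers; highly variable
alignments (e.g. rRNA across divergent taxa) may need values down to 1.
Because the threshold is quantile-based, small $k$ on clean data will flag
the tail of a perfectly ordinary score distribution — outlier calls are
advisory, sequences are never removed automatically, and the method assumes
outliers are rare (it fails when a large fraction of the alignment is
misaligned).

**Non-overlapping sample blocks.** Two samples are connected when some marker
contains both with at least one shared column where both carry a counted
state — co-occurring in a marker is *not* enough, since two records can cover
disjoint column ranges. More than one connected component means subsets of
samples share no sequence evidence whatsoever, the typical footprint of a
misspelled sample name, and a tree inferred from such a matrix would be
unsupported at the join. Components are computed over the sample graph and
reported largest first.

## The synthetic-data generator

`generate_matrix(fixture_spec(...))` produces deterministic datasets used by
the whole test suite: per marker a uniform-random ancestral sequence, per
sample independent per-site substitutions (to a different base) with
probability `divergence`, absent cells with probability `missing_fraction`,
planted outliers drawn uniformly at random instead of mutated, and planted
disjoint blocks made by renaming a fraction of samples (suffix `_2`) in the
second half of the markers while keeping only those renamed samples there —
emulating a second input file whose names were misspelled wholesale. Every
planted defect is returned as a truth label. Each (marker, sample) cell
draws from its own sub-stream seeded by a stable string hash, so enlarging a
dataset never reshuffles existing cells.

Defaults mirror a typical DNA-barcoding project: 300 bp fragments and 2%
per-site divergence. The generator is a star phylogeny — no tree structure,
no rate variation among sites, no indels — so passing tests demonstrate
correctness of the machinery (formats, algebra, detection thresholds) on
clean, exchangeable sequences, not robustness to phylogenetic structure or
alignment error in real data.

A note on what the planted-outlier conditions can and cannot guarantee: at
2% divergence each sequence's median cost inherits the spread of its own
mutation count, and a quantile threshold at $k = 1$ sits near the
$\mu + 2\sigma$ point of a 20-value sample, so one or two ordinary sequences
exceed it in a sizable fraction of replicates. The planted sequence is
recovered (flagged, and with the largest cost) in every replicate; being the
*only* flagged sequence every time would require near-zero divergence. The
acceptance suite reports both rates.

## Problem sizes and numerical choices

The test and acceptance suites run 200 round-trip matrices across all
dialects, 1 000 random codon partitions checked by column enumeration, 50
outlier blocks checked against an independent brute-force double loop, 20
planted-outlier replicates (20 sequences x 300 bp), and one scaled
many-marker run (1 000 markers x 50 samples, 100 bp each, L = 100 000) that
concatenates, exports Nexus plus partition file, and splits back — sizes
chosen so the whole suite completes in about a minute on a single core while
still exercising sparse matrices up to 90% missing cells.

Other fixed choices: quartiles are type 7; an all-excluded entropy column
contributes 0 bits; `concatenate` output order is first-appearance (a
lexicographic flag exists) so golden files are byte-stable; empty markers
(no records) are dropped rather than contributing zero-width charsets.

## Limitations

Protein sequences, morphological matrices and nucleotide-to-protein
translation are out of scope, as are alignment and tree inference themselves:
`align_markers()` is a thin adapter that shells out to an externally
installed MAFFT (fast = FFT-NS-1, thorough = G-INS-i) and fails plainly when
it is absent. Reverse-complement auto-correction is not provided. The whole
dataset is held in memory; inputs must fit in RAM.
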