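---
title: "Mapping protein domains onto transcript structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein domains onto transcript structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainmapr)
```

## The problem and the model

A profile search (rpsblast against Pfam-, SMART- or CDD-formatted
position-specific scoring matrices) reports domain hits in protein-residue
coordinates on each transcript's translation product. Gene annotation
reports transcript structure — exons, CDS segments, UTRs — in genomic
coordinates. `domainmapr` joins the two by lifting every hit through the
splice structure.

The lift rests on one assumption: the annotated protein is the
translation of the concatenated CDS segments taken in **translation
order** — ascending genomic coordinates on the `+` strand, descending on
`-` — starting at the first segment's phase. Under that assumption the
map is exact arithmetic, with no alignment involved:

1. residue interval `[s, e]` occupies CDS nucleotides
   `[3(s−1)+1, 3e]` (`protein_to_cds()`);
2. walking CDS segments in translation order with cumulative offsets,
   that CDS interval is intersected with each segment and translated to
   genomic coordinates, splitting at every splice junction it crosses
   (`cds_to_genomic()`);
3. adding the 5′-leader length (exonic nucleotides preceding CDS
   position 1 in transcription order) gives the cDNA interval
   (`cds_to_cdna()`).

Every projection therefore satisfies three invariants that the test suite
asserts exhaustively: summed genomic segment length equals `3 ×` the
residue count; every genomic segment lies inside a CDS segment; and CDS
and cDNA intervals have equal length.

All public coordinates follow the GFF3 convention — 1-based, inclusive at
both ends — everywhere. No half-open coordinates appear in any interface;
a single convention removes the classic family of off-by-one bugs at the
cost of `+1`s in length arithmetic.

## The independent oracle

Interval arithmetic is easy to get subtly wrong (phase handling, strand
reflection, junction splitting), so the package carries a second, shared-
code-free implementation: `oracle_project()` builds the explicit per-base
array mapping each CDS position to its genomic position by walking
segments one nucleotide at a time, slices the hit's positions out, and
merges adjacent positions back into intervals. It is deliberately naive —
its only virtue is that it is obviously correct. The central acceptance
property of the package is exact agreement between the two routes on every
generated transcript/hit pair, both strands, 1–8 exons (the suite checks
the 500-transcript fixture plus 1,000 random probes; the acceptance
script recomputes the same quantity from a user-supplied seed).

## Numerical and edge-case choices

* **Phase.** CDS phases are read from GFF column 8 (`.` → 0). If the
  translationally first segment carries a nonzero phase, CDS position 1
  starts after skipping `phase` nucleotides, with a warning — ignoring
  phase silently shifts every downstream coordinate by 1–2 nt.
  `protein_capacity()` is `floor((cds_length − phase) / 3)`.
* **Stop codon.** Both GFF conventions (CDS with and without the stop
  codon) exist in the wild, so capacity is permissive by one codon: a hit
  ending exactly at capacity is legal even when the CDS includes the
  stop.
* **Over-long hits.** A hit whose `prot_end` exceeds capacity usually
  signals mismatched annotation versions. It is attached but flagged
  invalid and excluded from projection, with a warning — fail soft,
  loudly, and conserve the hit count (`attached + unmatched = parsed`).
* **UTRs.** Derived as exon − CDS, never read from explicit UTR rows
  (which are consistency-checked, then ignored): many GFF releases omit
  them, and deriving them guarantees presence.
* **Degenerate GFFs.** Transcripts with no exons are dropped with a
  warning; CDS-only transcripts get exons synthesized from their CDS
  (common in minimal plant-genome releases). Exons are stored sorted by
  ascending genomic start on both strands; orientation is handled by the
  projection and rendering code, never by list order.
* **Accepted feature types.** `mRNA` and `transcript` rows define
  transcripts, resolved through `Parent` attributes only (no ID-prefix
  inference), with `ID` values URL-decoded. This is a deliberate
  narrowing for deterministic behavior across GFF dialects.

## Query semantics

The three modes are set predicates over the multiset of a record's domain
labels (each domain matchable through accession or short name,
case-insensitively): **ANY** — some pattern matches some domain; **ALL** —
every pattern matches some domain; **EXACT** — ALL holds and every domain
matches some pattern. Two readings were genuinely open and were fixed as
follows:

* "all entered domains" is per-pattern satisfiability, not per-copy
  counting: `P = [A, A]` does not demand two copies of A;
* duplicate copies of a queried domain are never background, so tandem
  repeats (ubiquitous in plant resistance genes) do not make EXACT
  useless.

Regular-expression patterns are anchored full matches — `pfam087..`
matches `pfam08774` but `pfam08` does not — because substring semantics
would let `pfam1` silently match every `pfam1xxxx` family. Containment is
spelled explicitly (`.*DUF.*`). These choices make
`EXACT ⊆ ALL ⊆ ANY` a theorem, which the suite verifies over randomized
pattern sets, and tightening an e-value ceiling provably never grows a
result set.

## The merged-database dialect

One row per feature (`exon`, `cds`, `utr5`, `utr3`, `domain_segment`),
19 tab-separated columns, versioned header `#vpd-db/1`. The schema
includes a `phase` column (filled only on `cds` rows) because the format
contract is a lossless round trip and phase is not reconstructible for a
translationally first segment once dropped. E-values and bit scores are
serialized at 17 significant digits so doubles round-trip bit-exactly.
Query output uses the same dialect, so any subset can be re-queried or
re-plotted from its file alone.

## Rendering

The testable intermediate between query results and pixels is the
`track_layout`: rows ordered by `(genome, seqid, span start, transcript
id)`, per-feature display intervals, a first-appearance color map over
the palette, and the resolved font size. Layout is a pure function of its
inputs; `serialize_layout()` exists so determinism can be asserted as
string equality.

Display choices, all of them this package's own where the visual grammar
was open: each row is x-scaled independently to its own extent (rows may
come from different chromosomes and genomes, so a shared axis is
meaningless); minus-strand transcripts are flipped so transcription runs
rightward; domains draw over CDS boxes at full feature height with a
black outline while UTRs draw at half height; introns are connector
lines. The auto-sizing formulas — label size `clamp(round(180/n), 4, 12)`
pt and canvas height `max(1.5, 0.28 n)` inches — are linear rules chosen
to be monotone and testable, not fitted to anything.

PNG export computes pixel dimensions as `round(width × dpi)` exactly.
SVG is produced by the package's own writer emitting plain
`rect`/`line`/`text` nodes with no timestamps or session state, so two
exports of one layout are byte-identical and each transcript label is a
single `<text>` node — properties the suite checks literally.

## What the synthetic generator emulates — and what it does not

`make_toy_genome(n, seed)` draws, per transcript: 1–8 exons, strand `-`
with probability 0.5, non-coding status with probability 0.1, CDS lengths
of 20–200 codons split arbitrarily across exons (so internal phases 0/1/2
all occur), UTRs of 0–150 nt, introns of 50–500 nt, and 0–3 hits of
10–60 residues placed within capacity, with e-values spread
log-uniformly over 10⁻³–10⁻³⁰. A controlled 2% of transcripts per
architecture is planted with `{A}`, `{A,B}` and `{A, background}` label
sets (accessions `pfam08774`, `pfam00931`, `smart00220`) and their IDs
recorded, giving query tests an exact expected answer. Expected
projections are computed by the per-base oracle at generation time, never
by the code under test. All randomness flows from one seed through an
isolated RNG scope, so regeneration is byte-identical and the session RNG
is untouched.

The generator emulates coordinates only. It produces no nucleotide or
protein sequence, no overlapping genes, no alternative isoforms sharing
exons, no trans-splicing, and its first CDS segments always carry phase 0
(nonzero first phases are exercised by dedicated unit tests instead).
Passing on fixtures therefore demonstrates coordinate correctness and
query/format semantics — not robustness to the annotation pathologies of
real genome releases, which enter only through the parser's validation
rules and warnings.

## Problem sizes

The default suite runs the 500-transcript fixture (seed 7, ~700 hits)
for oracle equivalence, conservation and round trips; 1,000 random
probes for the dual-route check; 200 reflected transcripts for strand
symmetry; 50 random pattern sets for query nesting; and smaller seeded
genomes (30–120 transcripts) in per-module tests. The acceptance script
reuses exactly these sizes from a caller-supplied seed.

## Known limitations

* One transcript, one protein: no fuzzy coordinates, trans-splicing,
  circular replicons, or cross-assembly liftover.
* GTF and other GFF dialects are out of scope; so are domain clan
  hierarchies and domain-order (architecture-string) queries.
* Transcript rows are not ordered by phylogenetic relationship; ordering
  is purely positional.
* The figure output is static; no interactivity.
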