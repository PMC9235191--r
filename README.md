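# domainmapr

Protein domains live in protein-residue coordinates; gene structure lives
in genomic coordinates. To see a Pfam/SMART/CDD domain on top of the
exon–intron architecture of the transcript that encodes it — across a
whole genome, or several genomes at once — the two coordinate systems must
be merged. `domainmapr` does that merge and everything downstream of it:

* **Merge** — parse a GFF3 genome annotation into per-transcript gene
  models and an rpsblast-style tabular hit file (BLAST outfmt 6, 12 or 13
  columns) into domain hits, attach hits to transcripts, and project every
  hit through the splice structure.
* **Project** — residue `i` of a protein corresponds to coding-sequence
  nucleotides `3(i−1)+1 .. 3i`, counted along the concatenated CDS in
  translation order (ascending genomic coordinates on `+`, descending on
  `−`, honoring the first segment's phase). The CDS interval is then split
  at every splice junction it crosses to give genomic segments, and
  shifted by the 5′-leader length to give cDNA coordinates. Each hit ends
  up with all three representations; summed genomic length always equals
  `3 × residues`.
* **Store** — the merged result is a flat, greppable, versioned TSV
  (`#vpd-db/1` header; one row per exon/CDS/UTR/domain segment) that
  round-trips losslessly and can be re-queried or re-plotted later.
* **Query** — genome-wide screens by domain pattern under three modes:
  **ANY** (at least one entered domain, background ignored), **ALL**
  (every entered domain, background ignored), **EXACT** (every entered
  domain and nothing else). Patterns are case-insensitive literals or
  anchored regular expressions (`pfam087..`), matched against accession
  and short name; transcript-name screens are also supported, and several
  genome databases can be screened at once.
* **Draw** — deterministic multi-track figures in three views (genomic
  with introns, cDNA, CDS-only), minus-strand transcripts flipped so
  transcription runs left-to-right, domain boxes colored by accession,
  label font size auto-scaled to the number of transcripts
  (`clamp(round(180/n), 4, 12)` pt), exported to PNG (exact pixel
  geometry), PDF, or byte-reproducible SVG.

The package also ships a seeded synthetic toy-genome generator
(`make_toy_genome()`) whose expected projections are computed by an
independent per-base oracle — the test substrate for everything above —
and a three-subcommand CLI (`build`, `query`, `plot`).

## Worked example

A two-exon transcript on `chr1:101-400 (+)` with CDS segments `131–220`
and `301–390` encodes 60 residues. A domain hit on residues 21–40
straddles the intron:

```r
library(domainmapr)
t1 <- transcript_model("T1", "G1", "chr1", "+",
  exons = data.frame(start = c(101, 301), end = c(220, 400)),
  cds   = data.frame(start = c(131, 301), end = c(220, 390), phase = c(0, 0)))
t1
#> <transcript_model> T1 (gene G1) chr1:101-400 (+) [genome]
#>   2 exon(s), 2 CDS segment(s); cDNA 220 nt, CDS 180 nt, capacity 60 aa

hit <- domain_hit("T1", "pfam08774", 21, 40, evalue = 1e-8, bitscore = 55.2,
                  domain_name = "DUF1985")
project_hit(t1, hit)
#> <projected_domain> pfam08774 21-40 aa -> genomic [191-220, 301-330], cds 61-120, cdna 91-150
```

Residues 21–40 are CDS nucleotides 61–120; the first 30 of them exhaust
the first CDS segment (genomic `191–220`), the rest continue after the
intron (`301–330`); with a 30-nt 5′ UTR the cDNA interval is `91–150`.

The same pipeline genome-wide, on a 500-transcript synthetic genome:

```r
truth <- make_toy_genome(500, seed = 7)
paths <- write_fixture(truth, "demo")
models <- parse_gff(paths["gff"], genome_label = "toy-7")
att    <- attach_hits(transcript_index(models), parse_hits(paths["hits"]))
db     <- build_database(models, att)
db
#> <merged_db> 500 transcript(s), 702 projected domain(s), genome(s): toy-7

res <- query_databases(db, query_spec("pfam087..", mode = "EXACT", regex = TRUE))
res
#> <merged_db> 10 transcript(s), 10 projected domain(s), genome(s): toy-7

spec <- figure_spec(view = "cds", width = 6, dpi = 300, format = "png")
lay  <- build_layout(res, spec)
lay
#> <track_layout> 10 row(s), view cds, 1 domain color(s), fontsize 12 pt
export_figure(lay, spec, "demo/fig.png")   # exactly 1800 px wide
```

The EXACT query returns precisely the 10 transcripts the generator
planted with a `{pfam08774}`-only architecture; records carrying it next
to other domains are excluded as background.

Or from a shell, via the installed launcher:

```sh
domainmapr build --gff demo/toy-7.gff3 --hits demo/toy-7.hits.tsv \
    --genome-label toy-7 --out demo/toy.db.tsv
domainmapr query --db demo/toy.db.tsv --domains 'pfam087..' --regex \
    --mode exact --out demo/subset.tsv
domainmapr plot --db demo/subset.tsv --view cds --format png \
    --width 6 --dpi 300 --out demo/fig.png
```

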