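Package: domainmapr
Title: Project Protein Domains onto Transcript Structures and Draw Them
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges GFF3 genome annotations with tabular protein-domain
    search hits (rpsblast/BLAST outfmt 6 against Pfam, SMART or CDD
    profiles), projects domain hits from protein-residue coordinates
    through the spliced CDS structure onto genomic, cDNA and CDS
    coordinates, stores the merged result as a versioned flat-text
    database, supports genome-wide domain-architecture queries under
    ANY/ALL/EXACT semantics with optional regular expressions, and
    renders deterministic multi-track transcript+domain figures to
    PNG, PDF or SVG.  Includes a seeded synthetic toy-genome generator
    with an independent per-base projection oracle, and a command-line
    interface with build, query and plot subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    png,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
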