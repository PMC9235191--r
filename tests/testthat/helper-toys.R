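# Hand-checkable two-transcript toy used throughout the suite.
#
# T1 ("+"): exons 101-220 and 301-400, CDS 131-220 and 301-390
#   -> cDNA 220 nt, CDS 180 nt, capacity 60 aa, 5' leader 30 nt
# T2 ("-"): exons 81-200 and 281-400, CDS 121-200 and 281-380
#   (translation order: 281-380 then 121-200) -> 5' leader 20 nt

toy_T1 <- function() {
  transcript_model("T1", "G1", "chr1", "+",
                   exons = data.frame(start = c(101L, 301L), end = c(220L, 400L)),
                   cds = data.frame(start = c(131L, 301L), end = c(220L, 390L),
                                    phase = c(0L, 0L)),
                   genome_label = "toy")
}

toy_T2 <- function() {
  transcript_model("T2", "G2", "chr1", "-",
                   exons = data.frame(start = c(81L, 281L), end = c(200L, 400L)),
                   cds = data.frame(start = c(121L, 281L), end = c(200L, 380L),
                                    phase = c(2L, 0L)),
                   genome_label = "toy")
}

toy_T1_gff <- function() {
  c("##gff-version 3",
    "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=G1",
    "chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\ttoy\texon\t101\t220\t.\t+\t.\tParent=T1",
    "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=T1",
    "chr1\ttoy\tCDS\t131\t220\t.\t+\t0\tParent=T1",
    "chr1\ttoy\tCDS\t301\t390\t.\t+\t0\tParent=T1")
}

# small merged database: T1 carries one pfam08774 hit, T2 none
toy_db <- function() {
  models <- list(toy_T1(), toy_T2())
  h <- domain_hit("T1", "pfam08774", 21, 40, evalue = 1e-8, bitscore = 55.2,
                  domain_name = "DUF1985")
  att <- attach_hits(transcript_index(models), list(h))
  build_database(models, att, genome_label = "toy")
}

# database of records with set architectures, for query-mode tests:
# R1 = {A, B}, R2 = {A}, R3 = {A, A, C}
architecture_db <- function() {
  mk <- function(id, start, accs) {
    t <- transcript_model(id, paste0("g", id), "chr1", "+",
                          exons = data.frame(start = start, end = start + 599L),
                          cds = data.frame(start = start, end = start + 599L,
                                           phase = 0L),
                          genome_label = "arch")
    hits <- lapply(seq_along(accs), function(i)
      domain_hit(id, accs[i], 10L * i, 10L * i + 9L, evalue = 10^(-3 - i)))
    att <- attach_hits(transcript_index(list(t)), hits)
    build_database(list(t), att, genome_label = "arch")[[1]]
  }
  structure(list(mk("R1", 1000L, c("A", "B")),
                 mk("R2", 3000L, "A"),
                 mk("R3", 5000L, c("A", "A", "C"))),
            class = "merged_db")
}

record_ids <- function(db)
  vapply(db, function(r) r$transcript$transcript_id, character(1))
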