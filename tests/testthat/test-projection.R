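test_that("protein_to_cds is the closed-form codon map", {
  expect_identical(protein_to_cds(1, 1), c(1L, 3L))
  expect_identical(protein_to_cds(21, 40), c(61L, 120L))
  expect_identical(protein_to_cds(31, 35), c(91L, 105L))
  expect_error(protein_to_cds(5, 4))
  expect_error(protein_to_cds(0, 1))
})

test_that("cds_to_genomic splits intervals across splice junctions on both strands", {
  T1 <- toy_T1()
  expect_identical(cds_to_genomic(T1, c(61, 120)),
                   data.frame(start = c(191L, 301L), end = c(220L, 330L)))
  expect_identical(cds_to_genomic(T1, c(1, 90)),
                   data.frame(start = 131L, end = 220L))
  T2 <- toy_T2()
  expect_identical(cds_to_genomic(T2, c(91, 105)),
                   data.frame(start = c(196L, 281L), end = c(200L, 290L)))
  expect_error(cds_to_genomic(T1, c(1, 181)), "capacity")
  expect_error(cds_to_genomic(T1, c(0, 10)))
  nc <- transcript_model("NC", "g", "chr1", "+",
                         exons = data.frame(start = 1L, end = 300L))
  expect_error(cds_to_genomic(nc, c(1, 3)), "non-coding")
})

test_that("cds_to_cdna shifts by the 5'-leader length", {
  expect_identical(cds_to_cdna(toy_T1(), c(61, 120)), c(91L, 150L))
  expect_identical(cds_to_cdna(toy_T2(), c(1, 3)), c(21L, 23L))
  leaderless <- transcript_model("L", "g", "chr1", "+",
                                 exons = data.frame(start = 1L, end = 300L),
                                 cds = data.frame(start = 1L, end = 300L,
                                                  phase = 0L))
  expect_identical(cds_to_cdna(leaderless, c(1, 30)), c(1L, 30L))
})

test_that("a nonzero first-segment phase shifts CDS space with a warning", {
  t <- transcript_model("PH", "g", "chr1", "+",
                        exons = data.frame(start = 1L, end = 100L),
                        cds = data.frame(start = 10L, end = 30L, phase = 2L))
  # 21 raw nt, 2 skipped -> capacity floor(19/3) = 6 aa
  expect_identical(protein_capacity(t), 6L)
  expect_warning(got <- cds_to_genomic(t, c(1, 3)), "phase 2")
  expect_identical(got, data.frame(start = 12L, end = 14L))
  expect_identical(suppressWarnings(oracle_project(t, domain_hit("PH", "x", 1, 1))),
                   data.frame(start = 12L, end = 14L))
})

test_that("project_hit fills all three coordinate systems consistently", {
  p <- project_hit(toy_T1(), domain_hit("T1", "pfam08774", 21, 40, 1e-8, 55.2))
  expect_identical(p$genomic_segments,
                   data.frame(start = c(191L, 301L), end = c(220L, 330L)))
  expect_identical(p$cds_interval, c(61L, 120L))
  expect_identical(p$cdna_interval, c(91L, 150L))
  p2 <- project_hit(toy_T2(), domain_hit("T2", "x", 31, 35))
  expect_identical(p2$genomic_segments,
                   data.frame(start = c(196L, 281L), end = c(200L, 290L)))
  # full-CDS hit spans the whole CDS
  p3 <- project_hit(toy_T1(), domain_hit("T1", "x", 1, 60))
  expect_identical(p3$genomic_segments,
                   data.frame(start = c(131L, 301L), end = c(220L, 390L)))
})

test_that("projection equals the per-base oracle on the fixture genome", {
  tr <- shared_fixture()
  idx <- transcript_index(tr$transcripts)
  for (e in tr$expected_projections) {
    p <- project_hit(idx[[e$transcript_id]], e$hit)
    expect_identical(p$genomic_segments, e$genomic_segments)
    expect_identical(p$cds_interval, as.integer(e$cds_interval))
    expect_identical(p$cdna_interval, as.integer(e$cdna_interval))
    # conservation: summed genomic length == 3 * residues
    expect_identical(sum(p$genomic_segments$end - p$genomic_segments$start + 1L),
                     3L * (e$hit$prot_end - e$hit$prot_start + 1L))
  }
})

test_that("genomic segments invert back to the CDS interval through the oracle map", {
  tr <- shared_fixture(n = 80, seed = 3)
  idx <- transcript_index(tr$transcripts)
  for (e in tr$expected_projections[seq_len(min(60, length(tr$expected_projections)))]) {
    t <- idx[[e$transcript_id]]
    p <- project_hit(t, e$hit)
    # per-base translation-order position map, built independently here
    ord <- if (t$strand == "+") seq_len(nrow(t$cds)) else rev(seq_len(nrow(t$cds)))
    pos <- unlist(lapply(ord, function(i)
      if (t$strand == "+") t$cds$start[i]:t$cds$end[i] else t$cds$end[i]:t$cds$start[i]))
    covered <- unlist(lapply(seq_len(nrow(p$genomic_segments)), function(i)
      p$genomic_segments$start[i]:p$genomic_segments$end[i]))
    cds_positions <- sort(match(covered, pos))
    expect_identical(range(cds_positions), c(p$cds_interval[1], p$cds_interval[2]))
    expect_identical(diff(range(cds_positions)) + 1L, length(cds_positions))
  }
})

test_that("projections of non-overlapping hits keep transcription order", {
  for (t in list(toy_T1(), toy_T2())) {
    h1 <- project_hit(t, domain_hit(t$transcript_id, "x", 2, 10))
    h2 <- project_hit(t, domain_hit(t$transcript_id, "y", 21, 40))
    if (t$strand == "+") {
      expect_lt(max(h1$genomic_segments$end), min(h2$genomic_segments$start))
    } else {
      expect_gt(min(h1$genomic_segments$start), max(h2$genomic_segments$end))
    }
  }
})

test_that("build_database keeps every transcript and orders records deterministically", {
  db <- toy_db()
  expect_s3_class(db, "merged_db")
  expect_length(db, 2L)
  # records are ordered by (seqid, span start): T2 spans 81-400, T1 101-400
  expect_identical(record_ids(db), c("T2", "T1"))
  db_sorted <- build_database(list(toy_T1(), toy_T2()), list())
  expect_identical(record_ids(db_sorted), c("T2", "T1"))
  expect_length(db[[which(record_ids(db) == "T1")]]$domains, 1L)
  expect_length(db[[which(record_ids(db) == "T2")]]$domains, 0L)
  # empty hit list -> all-empty domain lists
  expect_true(all(vapply(db_sorted, function(r) length(r$domains) == 0L,
                         logical(1))))
})

test_that("the database TSV round-trips field-exactly", {
  db <- shared_fixture_db()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_database(db, f)
  expect_equal(read_database(f), db)
  # toy database too
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_database(toy_db(), f2)
  expect_equal(read_database(f2), toy_db())
})

test_that("the database reader rejects unknown versions and truncated rows", {
  f <- withr::local_tempfile()
  writeLines("#vpd-db/99", f)
  expect_error(read_database(f), "version")
  writeLines("just text", f)
  expect_error(read_database(f), "vpd-db")

  good <- withr::local_tempfile()
  write_database(toy_db(), good)
  lines <- readLines(good)
  lines[length(lines)] <- substr(lines[length(lines)], 1, 20)
  trunc <- withr::local_tempfile()
  writeLines(lines, trunc)
  expect_error(read_database(trunc), "truncated")
})
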