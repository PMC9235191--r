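test_that("auto_fontsize follows the clamp formula and is non-increasing", {
  expect_identical(auto_fontsize(1), 12)
  expect_identical(auto_fontsize(30), 6)
  expect_identical(auto_fontsize(500), 4)
  sizes <- vapply(1:600, auto_fontsize, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(sizes >= 4 & sizes <= 12))
})

test_that("display coordinates match projection in cds and cdna views", {
  db <- toy_db()
  r1 <- db[[which(record_ids(db) == "T1")]]
  cds <- to_display_coords(r1, "cds")
  expect_identical(cds$x_domain, c(1L, 180L))
  dom <- cds$features[cds$features$type == "domain", ]
  expect_identical(c(dom$start, dom$end), c(61L, 120L))
  cdna <- to_display_coords(r1, "cdna")
  expect_identical(cdna$x_domain, c(1L, 220L))
  dom2 <- cdna$features[cdna$features$type == "domain", ]
  expect_identical(c(dom2$start, dom2$end), c(91L, 150L))
  # UTR boxes flank the CDS in cdna view
  expect_identical(cdna$features$type[1:3], c("utr5", "cds", "utr3"))
  expect_identical(cdna$features$end[1], 30L)
})

test_that("the genomic view flips minus-strand transcripts so 5' is left", {
  t2 <- toy_T2()
  h <- domain_hit("T2", "x", 1, 5)
  att <- attach_hits(transcript_index(list(t2)), list(h))
  r <- build_database(list(t2), att)[[1]]
  disp <- to_display_coords(r, "genomic")
  f <- disp$features
  # genomic 400 (5' end of transcription) must display at x = 1
  utr5 <- f[f$type == "utr5", ]
  expect_identical(utr5$start, 1L)
  expect_identical(utr5$end, 20L)
  # first codons sit just after the 5' UTR on the display axis
  dom <- f[f$type == "domain", ]
  expect_identical(min(dom$start), 21L)
  # all features inside the x_domain
  expect_true(all(f$start >= disp$x_domain[1] & f$end <= disp$x_domain[2]))
})

test_that("domain box lengths conserve projected lengths in every view", {
  db <- shared_fixture_db(n = 120, seed = 13)
  res <- query_databases(db, query_spec(".*", "ANY", regex = TRUE))
  for (r in res[seq_len(min(30, length(res)))]) {
    for (view in c("genomic", "cdna", "cds")) {
      f <- to_display_coords(r, view)$features
      dom_len <- sum(f$end[f$type == "domain"] - f$start[f$type == "domain"] + 1L)
      expected <- sum(vapply(r$domains, function(d)
        3L * (d$hit$prot_end - d$hit$prot_start + 1L), integer(1)))
      if (view == "cds" || view == "genomic") {
        expect_identical(dom_len, expected)
      } else {
        expect_identical(dom_len, expected)  # cdna intervals are contiguous
      }
    }
  }
})

test_that("cds and cdna views reject non-coding transcripts", {
  nc <- transcript_model("NC1", "g", "chr1", "+",
                         exons = data.frame(start = 1L, end = 300L))
  r <- build_database(list(nc), list())[[1]]
  expect_error(to_display_coords(r, "cds"), "NC1")
  expect_error(to_display_coords(r, "cdna"), "non-coding")
  expect_silent(to_display_coords(r, "genomic"))
})

test_that("layout is deterministic, ordered, and cycles palette colors", {
  db <- shared_fixture_db(n = 120, seed = 13)
  res <- query_databases(db, query_spec(".*", "ANY", regex = TRUE))
  spec <- figure_spec(view = "genomic", palette = c("#111111", "#222222"))
  lay <- build_layout(res, spec)
  expect_identical(lay$n_rows, length(res))
  expect_identical(vapply(lay$rows, function(r) r$row_index, integer(1)),
                   seq_len(lay$n_rows) - 1L)
  # rows ordered by (genome, seqid, span start, id)
  keys <- lapply(lay$rows, function(r)
    c(r$record$genome_label, r$record$transcript$seqid,
      sprintf("%012d", r$record$transcript$span$start),
      r$record$transcript$transcript_id))
  expect_false(is.unsorted(vapply(keys, paste, character(1), collapse = "|")))
  # palette cycling by first appearance
  expect_true(all(unname(lay$colors) %in% c("#111111", "#222222")))
  expect_identical(unname(lay$colors[1:2]), c("#111111", "#222222"))
  if (length(lay$colors) >= 3)
    expect_identical(unname(lay$colors[3]), "#111111")
  # identical inputs -> identical serialized layout
  expect_identical(serialize_layout(lay),
                   serialize_layout(build_layout(res, spec)))
  expect_error(build_layout(structure(list(), class = "merged_db"), spec),
               "nothing to plot")
})

test_that("explicit label_fontsize overrides the auto formula", {
  db <- toy_db()
  lay <- build_layout(db, figure_spec(label_fontsize = 9))
  expect_identical(lay$fontsize_used, 9)
  expect_identical(build_layout(db, figure_spec())$fontsize_used, 12)
})

test_that("png export honors width and dpi exactly", {
  skip_if_not_installed("png")
  db <- toy_db()
  spec <- figure_spec(view = "cds", width = 6, dpi = 300, format = "png")
  lay <- build_layout(query_databases(db, query_spec(".*", "ANY", regex = TRUE)),
                      spec)
  out <- file.path(withr::local_tempdir(), "toy.png")
  export_figure(lay, spec, out)
  d <- dim(png::readPNG(out))
  expect_identical(d[2], 1800L)
  expect_identical(d[1], as.integer(round(
    max(1.5, 0.28 * lay$n_rows + 0.4) * 300)))
})

test_that("pdf export writes a pdf and unknown formats are rejected", {
  db <- toy_db()
  spec <- figure_spec(view = "genomic", format = "pdf", width = 5, height = 3)
  lay <- build_layout(db, spec)
  out <- file.path(withr::local_tempdir(), "toy.pdf")
  export_figure(lay, spec, out)
  expect_identical(readBin(out, "raw", 4), charToRaw("%PDF"))
  expect_error(figure_spec(format = "tiff"), "unknown figure format")
  expect_error(export_figure(lay, spec, file.path(tempfile("nodir"), "x.pdf")),
               "directory")
})

test_that("svg export is byte-reproducible with one text node per label", {
  db <- shared_fixture_db(n = 120, seed = 13)
  res <- query_databases(db, query_spec("pfam08774", "ANY"))
  spec <- figure_spec(view = "genomic", format = "svg")
  lay <- build_layout(res, spec)
  dir <- withr::local_tempdir()
  export_figure(lay, spec, file.path(dir, "a.svg"))
  export_figure(lay, spec, file.path(dir, "b.svg"))
  a <- readLines(file.path(dir, "a.svg"))
  expect_identical(a, readLines(file.path(dir, "b.svg")))
  expect_identical(sum(grepl("class=\"transcript-label\"", a)), lay$n_rows)
  # legend maps every accession
  for (acc in names(lay$colors))
    expect_true(any(grepl(acc, a, fixed = TRUE)))
})
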