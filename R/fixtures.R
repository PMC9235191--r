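#' Independent per-base projection oracle
#'
#' Projects a protein-domain hit onto the genome by brute force: it walks
#' the CDS segments in translation order one nucleotide at a time to build
#' the explicit array mapping CDS position to genomic position, slices
#' residues `prot_start..prot_end` out of it, and merges adjacent
#' positions back into intervals.  It shares no interval arithmetic with
#' [cds_to_genomic]; the two implementations agreeing exactly on random
#' transcripts is the package's central correctness property.
#'
#' @param t a coding [transcript_model].
#' @param h a [domain_hit] within the transcript's [protein_capacity].
#' @return data.frame of genomic intervals (`start`, `end`), ascending.
#' @export
oracle_project <- function(t, h) {
  if (!t$coding) stop("oracle_project needs a coding transcript")
  # translation order: ascending genomic on "+", descending on "-"
  idx <- if (t$strand == "+") seq_len(nrow(t$cds)) else rev(seq_len(nrow(t$cds)))
  pos <- integer(0)
  for (i in idx) {
    if (t$strand == "+") {
      pos <- c(pos, seq.int(t$cds$start[i], t$cds$end[i]))
    } else {
      pos <- c(pos, seq.int(t$cds$end[i], t$cds$start[i]))
    }
  }
  ph <- if (t$strand == "+") t$cds$phase[1L] else t$cds$phase[nrow(t$cds)]
  if (ph > 0L) pos <- pos[-seq_len(ph)]
  lo <- 3L * (h$prot_start - 1L) + 1L
  hi <- 3L * h$prot_end
  if (hi > length(pos))
    stop("hit beyond CDS capacity of transcript ", t$transcript_id)
  picked <- sort(pos[lo:hi])
  breaks <- which(diff(picked) != 1L)
  starts <- picked[c(1L, breaks + 1L)]
  ends <- picked[c(breaks, length(picked))]
  data.frame(start = starts, end = ends)
}

# per-base cDNA interval of a hit: walk exons in transcription order to
# index every exonic nucleotide, then locate the hit's first and last CDS
# nucleotide in that indexing (independent of leader_length arithmetic)
oracle_cdna_interval <- function(t, h) {
  eidx <- if (t$strand == "+") seq_len(nrow(t$exons)) else rev(seq_len(nrow(t$exons)))
  cdna_pos <- integer(0)
  for (i in eidx) {
    if (t$strand == "+") {
      cdna_pos <- c(cdna_pos, seq.int(t$exons$start[i], t$exons$end[i]))
    } else {
      cdna_pos <- c(cdna_pos, seq.int(t$exons$end[i], t$exons$start[i]))
    }
  }
  idx <- if (t$strand == "+") seq_len(nrow(t$cds)) else rev(seq_len(nrow(t$cds)))
  cds_pos <- integer(0)
  for (i in idx) {
    if (t$strand == "+") {
      cds_pos <- c(cds_pos, seq.int(t$cds$start[i], t$cds$end[i]))
    } else {
      cds_pos <- c(cds_pos, seq.int(t$cds$end[i], t$cds$start[i]))
    }
  }
  ph <- if (t$strand == "+") t$cds$phase[1L] else t$cds$phase[nrow(t$cds)]
  if (ph > 0L) cds_pos <- cds_pos[-seq_len(ph)]
  lo <- 3L * (h$prot_start - 1L) + 1L
  hi <- 3L * h$prot_end
  c(match(cds_pos[lo], cdna_pos), match(cds_pos[hi], cdna_pos))
}

# domain label pools for the generator; the planted trio carries the
# architectures the query tests rely on
PLANTED_A <- "pfam08774"
PLANTED_B <- "pfam00931"
PLANTED_C <- "smart00220"
FIXTURE_NAMES <- c(pfam08774 = "DUF1985", pfam00931 = "NB-ARC",
                   smart00220 = "TyrKc", pfam03106 = "WRKY")
NOISE_ACCESSIONS <- c("pfam01535", "cd00180", "CDD:284797", "pfam03106",
                      "smart00112", "CDD:197705")

#' Generate a deterministic synthetic toy genome with known answers
#'
#' Emits a coordinate-only toy genome (no sequence): `n_transcripts`
#' transcripts over 5 chromosomes with 1..`max_exons` exons, random UTR
#' and intron lengths, CDS lengths of 20–200 codons split arbitrarily
#' across exons (so internal CDS phases are exercised), and 0–3 domain
#' hits per coding transcript placed within protein capacity.  A
#' controlled subset of coding transcripts is planted with the canonical
#' architectures `{A}`, `{A,B}` and `{A, background}` (accessions
#' `pfam08774`, `pfam00931`, `smart00220`) and their IDs recorded, so
#' query semantics can be checked against ground truth.  Expected
#' projections for every hit are computed by the independent per-base
#' oracle, never by the projection module under test.
#'
#' All randomness comes from one seeded generator; the same seed
#' reproduces byte-identical GFF3 and hits text.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param seed integer seed.
#' @param max_exons maximum exons per transcript.
#' @param p_minus probability of the minus strand.
#' @param p_noncoding probability a transcript carries no CDS.
#' @return an object of class `fixture_truth`: list with `seed`,
#'   `transcripts` (models), `hits` (emission order),
#'   `expected_projections` (per transcript: hit, genomic segments,
#'   cds/cdna intervals), `planted` (lists `A_only`, `A_B`, `A_bg` of
#'   transcript IDs), `gff_lines` and `hits_lines` (the file texts).
#' @export
make_toy_genome <- function(n_transcripts, seed, max_exons = 8,
                            p_minus = 0.5, p_noncoding = 0.1) {
  stopifnot(n_transcripts >= 1, max_exons >= 1)
  withr::with_seed(seed, make_toy_genome_impl(
    n_transcripts, seed, max_exons, p_minus, p_noncoding))
}

make_toy_genome_impl <- function(n_transcripts, seed, max_exons, p_minus,
                                 p_noncoding) {
  cursor <- stats::setNames(rep(1000L, 5), paste0("chr", 1:5))
  models <- vector("list", n_transcripts)
  coding_ids <- character(0)

  for (i in seq_len(n_transcripts)) {
    tid <- sprintf("TX%04d", i)
    gid <- sprintf("G%04d", i)
    seqid <- paste0("chr", 1L + (i - 1L) %% 5L)
    strand <- if (stats::runif(1) < p_minus) "-" else "+"
    coding <- stats::runif(1) >= p_noncoding
    n_ex <- sample.int(max_exons, 1L)

    if (coding) {
      k <- sample(20:200, 1L)           # residues
      total <- 3L * k                   # CDS nt
      # split total across n_ex segments, each >= 3 nt, arbitrary remainder
      extra <- total - 3L * n_ex
      alloc <- if (extra > 0L)
        tabulate(sample.int(n_ex, extra, replace = TRUE), n_ex) else
        rep(0L, n_ex)
      cds_lens <- 3L + alloc            # translation order
      utr5 <- sample(0:150, 1L)
      utr3 <- sample(0:150, 1L)
      ex_lens <- cds_lens
      ex_lens[1L] <- ex_lens[1L] + utr5
      ex_lens[n_ex] <- ex_lens[n_ex] + utr3
    } else {
      ex_lens <- sample(100:400, n_ex, replace = TRUE)
      cds_lens <- integer(0)
      utr5 <- 0L
    }
    introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer(0)

    # lay out in transcription order on a plus-strand template ...
    s <- cursor[[seqid]]
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    cur <- s
    for (j in seq_len(n_ex)) {
      ex_start[j] <- cur
      ex_end[j] <- cur + ex_lens[j] - 1L
      cur <- ex_end[j] + 1L + if (j < n_ex) introns[j] else 0L
    }
    span_end <- ex_end[n_ex]
    if (coding) {
      cds_start <- integer(n_ex); cds_end <- integer(n_ex)
      for (j in seq_len(n_ex)) {
        off <- if (j == 1L) utr5 else 0L
        cds_start[j] <- ex_start[j] + off
        cds_end[j] <- cds_start[j] + cds_lens[j] - 1L
      }
      cum <- cumsum(c(0L, cds_lens[-n_ex]))
      phases <- (3L - cum %% 3L) %% 3L  # translation order, first = 0
    }
    # ... then reflect for the minus strand so transcription runs high->low
    if (strand == "-") {
      refl <- function(p) s + span_end - p
      tmp <- refl(ex_end); ex_end <- refl(ex_start); ex_start <- tmp
      if (coding) {
        tmp <- refl(cds_end); cds_end <- refl(cds_start); cds_start <- tmp
      }
    }
    exons <- data.frame(start = ex_start, end = ex_end)
    cds <- if (coding)
      data.frame(start = cds_start, end = cds_end, phase = phases) else empty_cds()
    models[[i]] <- transcript_model(tid, gid, seqid, strand,
                                    exons = exons, cds = cds,
                                    genome_label = sprintf("toy-%d", seed))
    if (coding) coding_ids <- c(coding_ids, tid)
    cursor[[seqid]] <- span_end + 5000L
  }
  index <- transcript_index(models)

  # planted architectures among coding transcripts
  k_each <- max(1L, round(n_transcripts * 0.02))
  planted <- list(A_only = character(0), A_B = character(0), A_bg = character(0))
  pool <- coding_ids
  if (length(pool) >= 3L * k_each) {
    picks <- sample(pool, 3L * k_each)
    planted$A_only <- sort(picks[seq_len(k_each)])
    planted$A_B <- sort(picks[k_each + seq_len(k_each)])
    planted$A_bg <- sort(picks[2L * k_each + seq_len(k_each)])
  }
  planted_all <- unlist(planted)

  # hits per coding transcript
  hits <- list()
  for (tid in coding_ids) {
    t <- index[[tid]]
    cap <- protein_capacity(t)
    accs <- if (tid %in% planted$A_only) {
      PLANTED_A
    } else if (tid %in% planted$A_B) {
      c(PLANTED_A, PLANTED_B)
    } else if (tid %in% planted$A_bg) {
      c(PLANTED_A, PLANTED_C)
    } else {
      n_h <- sample(0:3, 1L)
      if (n_h == 0L) character(0) else
        sample(NOISE_ACCESSIONS, n_h, replace = TRUE)
    }
    for (acc in accs) {
      len <- min(sample(10:60, 1L), cap)
      start <- if (cap > len) sample.int(cap - len + 1L, 1L) else 1L
      nm <- if (acc %in% names(FIXTURE_NAMES)) FIXTURE_NAMES[[acc]] else acc
      hits[[length(hits) + 1L]] <- domain_hit(
        tid, acc, start, start + len - 1L,
        evalue = 10^(-stats::runif(1, 3, 30)),
        bitscore = round(stats::runif(1, 30, 300), 1),
        domain_name = nm)
    }
  }

  # expected projections from the per-base oracle
  expected <- list()
  for (h in hits) {
    t <- index[[h$query_id]]
    expected[[length(expected) + 1L]] <- list(
      transcript_id = h$query_id,
      hit = h,
      genomic_segments = oracle_project(t, h),
      cds_interval = c(3L * (h$prot_start - 1L) + 1L, 3L * h$prot_end),
      cdna_interval = oracle_cdna_interval(t, h))
  }

  gff_path <- tempfile(fileext = ".gff3")
  serialize_gff(models, gff_path)
  gff_lines <- readLines(gff_path)
  unlink(gff_path)

  structure(list(
    seed = seed,
    transcripts = models,
    hits = hits,
    expected_projections = expected,
    planted = planted,
    gff_lines = gff_lines,
    hits_lines = hits_tsv_lines(hits)
  ), class = "fixture_truth")
}

# emit outfmt-6-style rows; the dialect is a pure function of the
# accession so names stay consistent across rows
hits_tsv_lines <- function(hits) {
  lines <- "# synthetic rpsblast tabular hits (outfmt 6, 12/13 columns)"
  for (h in hits) {
    len <- h$prot_end - h$prot_start + 1L
    common <- c(h$query_id, NA, "90.0", len, "0", "0",
                h$prot_start, h$prot_end, "1", len,
                sprintf("%.17g", h$evalue), sprintf("%.17g", h$bitscore))
    if (startsWith(h$domain_accession, "CDD:")) {
      common[2] <- paste0("gnl|CDD|", sub("^CDD:", "", h$domain_accession))
      lines <- c(lines, paste(common, collapse = "\t"))
    } else if (h$domain_name != h$domain_accession) {
      common[2] <- h$domain_accession
      title <- paste0(h$domain_accession, ", ", h$domain_name,
                      ", synthetic toy profile")
      lines <- c(lines, paste(c(common, title), collapse = "\t"))
    } else {
      common[2] <- h$domain_accession
      lines <- c(lines, paste(common, collapse = "\t"))
    }
  }
  lines
}

#' Write a fixture's GFF3 and hits files to disk
#'
#' @param truth a [make_toy_genome] result.
#' @param dir output directory (created if missing).
#' @return named character vector with elements `gff` and `hits`.
#' @export
write_fixture <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gff <- file.path(dir, sprintf("toy-%d.gff3", truth$seed))
  hits <- file.path(dir, sprintf("toy-%d.hits.tsv", truth$seed))
  writeLines(truth$gff_lines, gff)
  writeLines(truth$hits_lines, hits)
  c(gff = gff, hits = hits)
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf("<fixture_truth> seed %d: %d transcript(s), %d hit(s), planted %d+%d+%d\n",
              x$seed, length(x$transcripts), length(x$hits),
              length(x$planted$A_only), length(x$planted$A_B),
              length(x$planted$A_bg)))
  invisible(x)
}
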