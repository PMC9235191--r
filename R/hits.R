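#' Domain hits from rpsblast-style tabular output
#'
#' A `domain_hit` records one profile match on a protein query, in 1-based
#' residue coordinates.  The reader accepts BLAST outfmt-6-style files of
#' 12 columns (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`) or 13 columns with a trailing
#' subject-title column, as produced by rpsblast against CDD-formatted
#' profile databases.
#'
#' @name domain_hit
NULL

#' Construct a domain hit record
#'
#' @param query_id protein/transcript identifier the hit was found on.
#' @param domain_accession profile accession (e.g. `"pfam08774"`,
#'   `"CDD:284797"`).
#' @param prot_start,prot_end 1-based residue coordinates,
#'   `prot_start <= prot_end`.
#' @param evalue non-negative expectation value.
#' @param bitscore bit score.
#' @param domain_name short domain name; defaults to the accession.
#' @return an object of class `domain_hit`.
#' @export
domain_hit <- function(query_id, domain_accession, prot_start, prot_end,
                       evalue = 0, bitscore = 0, domain_name = domain_accession) {
  prot_start <- as.integer(prot_start)
  prot_end <- as.integer(prot_end)
  stopifnot(prot_start >= 1L, prot_end >= prot_start, evalue >= 0)
  structure(list(
    query_id = query_id,
    domain_accession = domain_accession,
    domain_name = domain_name,
    prot_start = prot_start,
    prot_end = prot_end,
    evalue = as.numeric(evalue),
    bitscore = as.numeric(bitscore)
  ), class = "domain_hit")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("<domain_hit> %s [%s] %d-%d aa (e=%g, bits=%g) on %s\n",
              x$domain_accession, x$domain_name, x$prot_start, x$prot_end,
              x$evalue, x$bitscore, x$query_id))
  invisible(x)
}

#' Parse an rpsblast/BLAST tabular hits file
#'
#' Lines beginning with `#` are skipped.  `qstart`/`qend` are normalized so
#' `prot_start <= prot_end`.  Subject-ID dialects: `gnl|CDD|<digits>`
#' becomes accession `CDD:<digits>`; bare `pfamNNNNN`/`smartNNNNN`/`cdNNNNN`
#' tokens are kept verbatim.  When a 13th title column exists and starts
#' `"<accession>, <shortname>, ..."` the short name is used as
#' `domain_name`; otherwise `domain_name` equals the accession.
#'
#' @param path path to a tab-separated 12- or 13-column hits file.
#' @return list of [domain_hit] records, in file order.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("cannot read hits file: ", path)
  lines <- readLines(path, warn = FALSE)
  hits <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(12L, 13L))
      stop("hits parse error at line ", ln,
           ": expected 12 or 13 tab-separated columns, got ", length(f))
    qstart <- suppressWarnings(as.integer(f[7]))
    qend <- suppressWarnings(as.integer(f[8]))
    evalue <- suppressWarnings(as.numeric(f[11]))
    bitscore <- suppressWarnings(as.numeric(f[12]))
    if (is.na(qstart) || is.na(qend) || is.na(evalue) || is.na(bitscore))
      stop("hits parse error at line ", ln, ": non-numeric coordinates or scores")
    acc <- normalize_subject_id(f[2])
    name <- acc
    if (length(f) == 13L) {
      parsed <- parse_subject_title(f[13])
      if (!is.null(parsed)) {
        acc <- parsed$accession
        name <- parsed$name
      }
    }
    hits[[length(hits) + 1L]] <- domain_hit(
      query_id = f[1], domain_accession = acc, domain_name = name,
      prot_start = min(qstart, qend), prot_end = max(qstart, qend),
      evalue = evalue, bitscore = bitscore)
  }
  hits
}

normalize_subject_id <- function(sseqid) {
  m <- regmatches(sseqid, regexec("^gnl\\|CDD\\|([0-9]+)$", sseqid))[[1]]
  if (length(m) == 2L) return(paste0("CDD:", m[2]))
  sseqid
}

# "pfam08774, DUF1985, ..." -> accession + short name
parse_subject_title <- function(title) {
  parts <- strsplit(title, ",", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  acc <- trimws(parts[1])
  if (!grepl("^(pfam|PFAM|Pfam|smart|cd|CDD:)[0-9]+$", acc)) return(NULL)
  list(accession = acc, name = trimws(parts[2]))
}

#' Attach domain hits to their transcripts
#'
#' A hit is attached to the transcript whose `transcript_id` equals the
#' hit's `query_id` after optional normalization (`id_normalizer` is a
#' regular expression removed from query IDs, e.g. `"\\.[0-9]+$"` to strip
#' protein-isoform suffixes).  Unmatched hits are returned, never silently
#' dropped.  Hits whose `prot_end` exceeds the transcript's
#' [protein_capacity] are attached but flagged invalid (excluded from
#' projection) with a warning.  Within a transcript, hits are sorted by
#' `(prot_start, evalue)` ascending.
#'
#' @param index named transcript index from [transcript_index].
#' @param hits list of [domain_hit] records.
#' @param id_normalizer optional regex stripped from query IDs before
#'   matching.
#' @return a list with elements `attached` (named list:
#'   `transcript_id -> list of hits`, each hit carrying a logical `valid`
#'   field) and `unmatched` (list of hits with no matching transcript).
#' @export
attach_hits <- function(index, hits, id_normalizer = NULL) {
  attached <- list()
  unmatched <- list()
  for (h in hits) {
    qid <- h$query_id
    if (!is.null(id_normalizer)) qid <- sub(id_normalizer, "", qid)
    t <- index[[qid]]
    if (is.null(t)) {
      unmatched[[length(unmatched) + 1L]] <- h
      next
    }
    h$valid <- TRUE
    if (!t$coding || h$prot_end > protein_capacity(t)) {
      warning("hit ", h$domain_accession, " at ", h$prot_start, "-", h$prot_end,
              " aa exceeds capacity of transcript ", qid,
              " (", if (t$coding) protein_capacity(t) else 0L,
              " aa); flagged invalid, excluded from projection")
      h$valid <- FALSE
    }
    attached[[qid]] <- c(attached[[qid]], list(h))
  }
  if (length(hits) > 0L && length(unmatched) == length(hits))
    warning("no hits matched any transcript; consider an id_normalizer ",
            "(e.g. \"\\\\.[0-9]+$\" to strip isoform suffixes)")
  for (id in names(attached)) {
    hs <- attached[[id]]
    o <- order(vapply(hs, function(h) h$prot_start, integer(1)),
               vapply(hs, function(h) h$evalue, numeric(1)))
    attached[[id]] <- hs[o]
  }
  list(attached = attached, unmatched = unmatched)
}
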