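#' Flat-text merged-database format
#'
#' The merged database is serialized as a tab-separated file, one row per
#' structural feature, with the versioned header line `#vpd-db/1`.
#' Columns: `genome_label, seqid, strand, gene_id, transcript_id,
#' row_type, start, end, phase, domain_accession, domain_name, prot_start,
#' prot_end, cds_start, cds_end, cdna_start, cdna_end, evalue, bitscore`.
#' `row_type` is one of `exon`, `cds`, `utr5`, `utr3`, `domain_segment`;
#' domain columns are empty on structural rows and `phase` is set only on
#' `cds` rows.  A projected domain occupies one `domain_segment` row per
#' genomic segment, each repeating the hit's protein/CDS/cDNA coordinates
#' and scores.  The round trip `read_database(write_database(db))` is
#' field-exact; a hit's `query_id` is recorded as the transcript it was
#' attached to.
#'
#' @name vpd_db_format
NULL

DB_VERSION <- "#vpd-db/1"
DB_COLUMNS <- c("genome_label", "seqid", "strand", "gene_id", "transcript_id",
                "row_type", "start", "end", "phase", "domain_accession",
                "domain_name", "prot_start", "prot_end", "cds_start",
                "cds_end", "cdna_start", "cdna_end", "evalue", "bitscore")

#' Write a merged database to a TSV file
#'
#' @param records a `merged_db` (list of merged records) from
#'   [build_database] or [query_databases].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [vpd_db_format] for the on-disk dialect.
#' @export
write_database <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(DB_VERSION, con)
  writeLines(paste0("#", paste(DB_COLUMNS, collapse = "\t")), con)
  blank <- rep("", length(DB_COLUMNS))
  names(blank) <- DB_COLUMNS
  for (r in records) {
    t <- r$transcript
    base <- blank
    base["genome_label"] <- r$genome_label
    base["seqid"] <- t$seqid
    base["strand"] <- t$strand
    base["gene_id"] <- t$gene_id
    base["transcript_id"] <- t$transcript_id
    rows <- character(0)
    for (i in seq_len(nrow(t$exons)))
      rows <- c(rows, db_row(base, "exon", t$exons$start[i], t$exons$end[i]))
    for (i in seq_len(nrow(t$cds))) {
      row <- base
      row["phase"] <- t$cds$phase[i]
      rows <- c(rows, db_row(row, "cds", t$cds$start[i], t$cds$end[i]))
    }
    utrs <- derive_utrs(t)
    for (i in seq_len(nrow(utrs)))
      rows <- c(rows, db_row(base, utrs$side[i], utrs$start[i], utrs$end[i]))
    for (d in r$domains) {
      row <- base
      h <- d$hit
      row["domain_accession"] <- h$domain_accession
      row["domain_name"] <- h$domain_name
      row["prot_start"] <- h$prot_start
      row["prot_end"] <- h$prot_end
      row["cds_start"] <- d$cds_interval[1]
      row["cds_end"] <- d$cds_interval[2]
      row["cdna_start"] <- d$cdna_interval[1]
      row["cdna_end"] <- d$cdna_interval[2]
      row["evalue"] <- sprintf("%.17g", h$evalue)
      row["bitscore"] <- sprintf("%.17g", h$bitscore)
      for (i in seq_len(nrow(d$genomic_segments)))
        rows <- c(rows, db_row(row, "domain_segment",
                               d$genomic_segments$start[i],
                               d$genomic_segments$end[i]))
    }
    writeLines(rows, con)
  }
  invisible(path)
}

db_row <- function(fields, row_type, start, end) {
  fields["row_type"] <- row_type
  fields["start"] <- start
  fields["end"] <- end
  paste(fields, collapse = "\t")
}

#' Read a merged database from a TSV file
#'
#' @param path path to a file written by [write_database] (or a subset
#'   exported by the query tools; same dialect).
#' @return a `merged_db` list of merged records, in file order.
#' @section Errors:
#' A missing or unknown version header is an error; a row with the wrong
#' column count is reported as truncation, naming the last good line.
#' @export
read_database <- function(path) {
  if (!file.exists(path)) stop("cannot read database file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#vpd-db/"))
    stop("not a vpd-db file (missing #vpd-db header): ", path)
  if (lines[1] != DB_VERSION)
    stop("unknown database format version '", sub("^#", "", lines[1]),
         "' (this build reads ", sub("^#", "", DB_VERSION), ")")

  # per transcript accumulation, preserving first-appearance order
  tx_rows <- list()
  tx_order <- character(0)
  last_good <- 1L
  for (ln in seq_along(lines)[-1]) {
    line <- lines[[ln]]
    if (line == "" || startsWith(line, "#")) { last_good <- ln; next }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; pad from the tab count
    ntabs <- nchar(line) - nchar(gsub("\t", "", line, fixed = TRUE))
    if (ntabs != length(DB_COLUMNS) - 1L)
      stop("truncated or corrupt database at line ", ln,
           " (last good line: ", last_good, ")")
    if (length(f) < length(DB_COLUMNS))
      f <- c(f, rep("", length(DB_COLUMNS) - length(f)))
    names(f) <- DB_COLUMNS
    key <- paste(f["genome_label"], f["transcript_id"], sep = "\r")
    if (is.null(tx_rows[[key]])) tx_order <- c(tx_order, key)
    tx_rows[[key]] <- c(tx_rows[[key]], list(f))
    last_good <- ln
  }

  records <- lapply(tx_order, function(key) rebuild_record(tx_rows[[key]]))
  structure(records, class = "merged_db")
}

rebuild_record <- function(rows) {
  first <- rows[[1]]
  types <- vapply(rows, function(f) f[["row_type"]], character(1))
  ex <- rows[types == "exon"]
  cd <- rows[types == "cds"]
  exons <- data.frame(
    start = vapply(ex, function(f) as.integer(f[["start"]]), integer(1)),
    end = vapply(ex, function(f) as.integer(f[["end"]]), integer(1)))
  cds <- if (length(cd) == 0L) empty_cds() else data.frame(
    start = vapply(cd, function(f) as.integer(f[["start"]]), integer(1)),
    end = vapply(cd, function(f) as.integer(f[["end"]]), integer(1)),
    phase = vapply(cd, function(f) as.integer(f[["phase"]]), integer(1)))
  t <- transcript_model(first[["transcript_id"]], first[["gene_id"]],
                        first[["seqid"]], first[["strand"]],
                        exons = exons, cds = cds,
                        genome_label = first[["genome_label"]])
  # domain_segment rows: consecutive rows sharing one hit tuple form one domain
  domains <- list()
  cur_key <- NULL
  cur_segs <- NULL
  cur_row <- NULL
  flush <- function() {
    if (is.null(cur_row)) return()
    h <- domain_hit(first[["transcript_id"]], cur_row[["domain_accession"]],
                    as.integer(cur_row[["prot_start"]]),
                    as.integer(cur_row[["prot_end"]]),
                    evalue = as.numeric(cur_row[["evalue"]]),
                    bitscore = as.numeric(cur_row[["bitscore"]]),
                    domain_name = cur_row[["domain_name"]])
    h$valid <- TRUE
    segs <- do.call(rbind, cur_segs)
    domains[[length(domains) + 1L]] <<- structure(list(
      hit = h,
      genomic_segments = data.frame(start = segs[, 1], end = segs[, 2]),
      cds_interval = c(as.integer(cur_row[["cds_start"]]),
                       as.integer(cur_row[["cds_end"]])),
      cdna_interval = c(as.integer(cur_row[["cdna_start"]]),
                        as.integer(cur_row[["cdna_end"]]))
    ), class = "projected_domain")
  }
  for (f in rows[types == "domain_segment"]) {
    key <- paste(f[["domain_accession"]], f[["prot_start"]], f[["prot_end"]],
                 f[["evalue"]], f[["bitscore"]], sep = "\r")
    if (!identical(key, cur_key)) {
      flush()
      cur_key <- key
      cur_row <- f
      cur_segs <- list()
    }
    cur_segs[[length(cur_segs) + 1L]] <- c(as.integer(f[["start"]]),
                                           as.integer(f[["end"]]))
  }
  flush()
  structure(list(genome_label = first[["genome_label"]], transcript = t,
                 domains = domains), class = "merged_record")
}
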