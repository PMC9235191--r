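#' Read a GFF3 genome annotation into transcript models
#'
#' Assembles one [transcript_model] per `mRNA`/`transcript` feature from a
#' 9-column GFF3 file.  Parent/child links are resolved through the
#' `Parent` attribute only; `ID` values are URL-decoded.  Exon lists are
#' sorted by ascending genomic start; CDS phases are taken from column 8
#' (`.` means 0).  Transcripts without CDS rows are retained and flagged
#' non-coding.  Explicit UTR rows are checked for consistency against the
#' exon structure and then ignored: UTRs are always re-derived as exon
#' minus CDS (see [derive_utrs]), so they are present even for GFFs that
#' omit them.
#'
#' @param path path to a GFF3 file (`##gff-version 3` directive optional).
#' @param genome_label label attached to every returned model.
#' @return list of [transcript_model] objects, in file order of their
#'   mRNA/transcript rows.
#' @section Errors and warnings:
#' A line with the wrong column count is a parse error naming the line
#' number.  An exon/CDS whose `Parent` matches no transcript is dropped
#' with a warning.  A CDS segment outside all exons of its parent is a
#' validation error naming the transcript.  A transcript with neither
#' exons nor CDS is dropped with a warning; one with CDS but no exons has
#' exons synthesized from the CDS, with a warning.
#' @export
parse_gff <- function(path, genome_label = "genome") {
  if (!file.exists(path)) stop("cannot read GFF file: ", path)
  lines <- readLines(path, warn = FALSE)

  tx <- list()         # transcript_id -> list(gene_id, seqid, strand)
  tx_order <- character(0)
  exon_rows <- list()  # per parent id
  cds_rows <- list()
  utr_rows <- list()
  orphans <- character(0)

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("GFF parse error at line ", ln, ": expected 9 tab-separated columns, got ",
           length(f))
    type <- f[3]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("GFF parse error at line ", ln, ": non-numeric coordinates")
    attrs <- parse_gff_attributes(f[9])

    if (type %in% c("mRNA", "transcript")) {
      id <- attrs[["ID"]]
      if (is.null(id)) {
        warning("GFF line ", ln, ": ", type, " feature without ID attribute, dropped")
        next
      }
      if (!f[7] %in% c("+", "-"))
        stop("GFF parse error at line ", ln, ": transcript ", id,
             " has strand '", f[7], "' (must be + or -)")
      parent <- attrs[["Parent"]]
      tx[[id]] <- list(gene_id = if (is.null(parent)) id else parent,
                       seqid = f[1], strand = f[7])
      tx_order <- c(tx_order, id)
    } else if (type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")) {
      parent <- attrs[["Parent"]]
      if (is.null(parent)) {
        warning("GFF line ", ln, ": ", type, " feature without Parent attribute, dropped")
        next
      }
      # GFF3 allows multi-parent features (shared exons)
      for (p in strsplit(parent, ",", fixed = TRUE)[[1]]) {
        row <- data.frame(start = start, end = end)
        if (type == "exon") {
          exon_rows[[p]] <- c(exon_rows[[p]], list(row))
        } else if (type == "CDS") {
          row$phase <- if (f[8] %in% c("0", "1", "2")) as.integer(f[8]) else 0L
          cds_rows[[p]] <- c(cds_rows[[p]], list(row))
        } else {
          utr_rows[[p]] <- c(utr_rows[[p]], list(row))
        }
      }
    }
    # gene rows and other feature types carry no per-transcript structure
  }

  # orphaned structural features: Parent never declared as mRNA/transcript
  for (nm in union(names(exon_rows), names(cds_rows))) {
    if (is.null(tx[[nm]])) orphans <- c(orphans, nm)
  }
  if (length(orphans) > 0L)
    warning("dropped exon/CDS features with unknown Parent(s): ",
            paste(unique(orphans), collapse = ", "))

  models <- list()
  for (id in tx_order) {
    info <- tx[[id]]
    ex <- if (is.null(exon_rows[[id]])) empty_cds()[, c("start", "end")] else
      do.call(rbind, exon_rows[[id]])
    cd <- if (is.null(cds_rows[[id]])) empty_cds() else
      do.call(rbind, cds_rows[[id]])
    if (nrow(ex) == 0L && nrow(cd) == 0L) {
      warning("transcript ", id, " has no exons and no CDS, dropped")
      next
    }
    m <- transcript_model(id, info$gene_id, info$seqid, info$strand,
                          exons = ex, cds = cd, genome_label = genome_label)
    # consistency check for explicit UTR rows, then ignore them
    if (!is.null(utr_rows[[id]])) {
      ur <- do.call(rbind, utr_rows[[id]])
      for (i in seq_len(nrow(ur))) {
        inside <- any(ur$start[i] >= m$exons$start & ur$end[i] <= m$exons$end)
        if (!inside)
          warning("explicit UTR ", ur$start[i], "-", ur$end[i],
                  " of transcript ", id,
                  " lies outside its exons; UTRs are re-derived from exon/CDS")
      }
    }
    models[[length(models) + 1L]] <- m
  }
  models
}

parse_gff_attributes <- function(text) {
  out <- list()
  for (kv in strsplit(text, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    if (key %in% c("ID", "Parent")) val <- utils::URLdecode(val)
    out[[key]] <- val
  }
  out
}

#' Serialize transcript models back to GFF3
#'
#' Writes gene, mRNA, exon and CDS rows (UTRs are derived, never written).
#' Parsing the output with [parse_gff] reproduces the input models
#' field-for-field.
#'
#' @param models list of [transcript_model] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_gff <- function(models, path) {
  lines <- "##gff-version 3"
  genes_seen <- character(0)
  for (m in models) {
    if (!m$gene_id %in% genes_seen) {
      lines <- c(lines, gff_row(m$seqid, "gene", m$span$start, m$span$end,
                                m$strand, ".", paste0("ID=", m$gene_id)))
      genes_seen <- c(genes_seen, m$gene_id)
    }
    lines <- c(lines, gff_row(m$seqid, "mRNA", m$span$start, m$span$end,
                              m$strand, ".",
                              paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, gff_row(m$seqid, "exon", m$exons$start[i], m$exons$end[i],
                                m$strand, ".", paste0("Parent=", m$transcript_id)))
    for (i in seq_len(nrow(m$cds)))
      lines <- c(lines, gff_row(m$seqid, "CDS", m$cds$start[i], m$cds$end[i],
                                m$strand, m$cds$phase[i],
                                paste0("Parent=", m$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

gff_row <- function(seqid, type, start, end, strand, phase, attrs) {
  paste(seqid, "annotation", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}
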