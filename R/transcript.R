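#' Transcript gene models
#'
#' A `transcript_model` is the coordinate substrate for domain projection:
#' one transcript's exon/CDS structure on a chromosome, in GFF3 convention
#' (1-based, inclusive at both ends).  Exons and CDS segments are stored as
#' data frames with integer `start`/`end` columns (CDS additionally carries
#' `phase`), always sorted by ascending genomic start regardless of strand;
#' transcription orientation is handled downstream, never by list order.
#'
#' @name transcript_model
NULL

#' Construct a transcript model
#'
#' @param transcript_id transcript identifier (unique within a genome).
#' @param gene_id parent gene identifier.
#' @param seqid chromosome/scaffold identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (1-based,
#'   inclusive), one row per exon.
#' @param cds data.frame with integer columns `start`, `end`, `phase`
#'   (0/1/2); zero rows for a non-coding transcript.
#' @param genome_label label of the genome this transcript belongs to.
#'
#' @return an object of class `transcript_model`: a list with the fields
#'   above plus `span` (the enclosing interval) and `coding` (logical).
#' @export
transcript_model <- function(transcript_id, gene_id, seqid, strand,
                             exons, cds = empty_cds(), genome_label = "genome") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  exons <- normalize_intervals(exons, transcript_id, "exon")
  cds <- normalize_intervals(cds, transcript_id, "CDS", phase = TRUE)

  if (nrow(exons) == 0L && nrow(cds) > 0L) {
    warning("transcript ", transcript_id,
            " has CDS but no exons; synthesizing exons from CDS segments")
    exons <- cds[, c("start", "end")]
  }
  if (nrow(exons) == 0L)
    stop("transcript ", transcript_id, " has no exons")

  # exons must not overlap each other
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)

  # every CDS segment must lie within exactly one exon
  if (nrow(cds) > 0L) {
    for (i in seq_len(nrow(cds))) {
      inside <- cds$start[i] >= exons$start & cds$end[i] <= exons$end
      if (sum(inside) != 1L)
        stop("CDS segment ", cds$start[i], "-", cds$end[i],
             " not contained in exactly one exon of transcript ", transcript_id)
    }
  }

  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    seqid = seqid,
    strand = strand,
    exons = exons,
    cds = cds,
    span = list(start = min(exons$start), end = max(exons$end)),
    coding = nrow(cds) > 0L,
    genome_label = genome_label
  ), class = "transcript_model")
}

empty_cds <- function() {
  data.frame(start = integer(0), end = integer(0), phase = integer(0))
}

normalize_intervals <- function(df, transcript_id, what, phase = FALSE) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0))
    if (phase) out$phase <- integer(0)
    return(out)
  }
  start <- as.integer(df$start)
  end <- as.integer(df$end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric ", what, " coordinates in transcript ", transcript_id)
  if (any(start < 1L) || any(end < start))
    stop("invalid ", what, " interval (start < 1 or end < start) in transcript ",
         transcript_id)
  out <- data.frame(start = start, end = end)
  if (phase) {
    ph <- df$phase
    if (is.null(ph)) ph <- rep(0L, nrow(df))
    ph <- as.integer(ph)
    ph[is.na(ph)] <- 0L
    if (any(!ph %in% 0:2))
      stop("CDS phase outside {0,1,2} in transcript ", transcript_id)
    out$phase <- ph
  }
  o <- order(out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcript length accessors
#'
#' `cds_length()` is the summed length of all CDS segments, `cdna_length()`
#' the summed length of all exons, and `protein_capacity()` the number of
#' whole codons the CDS can encode, `floor(cds_length / 3)`.  The capacity
#' is deliberately permissive by one codon: when the GFF includes the stop
#' codon in the CDS, capacity exceeds the true protein length by one, and
#' hits ending at the capacity are still accepted.
#'
#' @param t a [transcript_model].
#' @return an integer length (nucleotides, or residues for
#'   `protein_capacity`).
#' @export
cds_length <- function(t) sum(t$cds$end - t$cds$start + 1L)

#' @rdname cds_length
#' @export
cdna_length <- function(t) sum(t$exons$end - t$exons$start + 1L)

#' @rdname cds_length
#' @export
protein_capacity <- function(t) (cds_length(t) - first_phase(t)) %/% 3L

# phase of the translationally first CDS segment (nt to skip before codon 1)
first_phase <- function(t) {
  if (!t$coding) return(0L)
  if (t$strand == "+") t$cds$phase[1L] else t$cds$phase[nrow(t$cds)]
}

#' Derive UTR intervals from exon and CDS structure
#'
#' UTRs are computed as exon minus CDS (explicit UTR rows in a GFF are
#' ignored), then split into 5' and 3' sides relative to the strand.
#'
#' @param t a [transcript_model].
#' @return a data.frame with columns `start`, `end`, `side`
#'   (`"utr5"`/`"utr3"`); zero rows for non-coding transcripts.
#' @export
derive_utrs <- function(t) {
  none <- data.frame(start = integer(0), end = integer(0), side = character(0))
  if (!t$coding) return(none)
  cds_lo <- min(t$cds$start)
  cds_hi <- max(t$cds$end)
  rows <- list()
  for (i in seq_len(nrow(t$exons))) {
    es <- t$exons$start[i]; ee <- t$exons$end[i]
    # part of the exon left of the CDS span
    if (es < cds_lo) {
      lo_end <- min(ee, cds_lo - 1L)
      side <- if (t$strand == "+") "utr5" else "utr3"
      rows[[length(rows) + 1L]] <- data.frame(start = es, end = lo_end, side = side)
    }
    # part of the exon right of the CDS span
    if (ee > cds_hi) {
      hi_start <- max(es, cds_hi + 1L)
      side <- if (t$strand == "+") "utr3" else "utr5"
      rows[[length(rows) + 1L]] <- data.frame(start = hi_start, end = ee, side = side)
    }
  }
  if (length(rows) == 0L) return(none)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d (%s) [%s]\n",
              x$transcript_id, x$gene_id, x$seqid,
              x$span$start, x$span$end, x$strand, x$genome_label))
  cat(sprintf("  %d exon(s), %d CDS segment(s)%s; cDNA %d nt",
              nrow(x$exons), nrow(x$cds),
              if (x$coding) "" else " (non-coding)", cdna_length(x)))
  if (x$coding)
    cat(sprintf(", CDS %d nt, capacity %d aa", cds_length(x), protein_capacity(x)))
  cat("\n")
  invisible(x)
}

#' Index transcript models by identifier
#'
#' @param models list of [transcript_model] objects.
#' @return a named list (environment-free) keyed by `transcript_id`.
#'   Duplicate IDs within one genome label are a hard error.
#' @export
transcript_index <- function(models) {
  if (length(models) == 0L) return(structure(list(), names = character(0)))
  ids <- vapply(models, function(m) m$transcript_id, character(1))
  labs <- vapply(models, function(m) m$genome_label, character(1))
  key <- paste(labs, ids, sep = "\r")
  dup <- unique(ids[duplicated(key)])
  if (length(dup) > 0L)
    stop("duplicate transcript_id within one genome: ",
         paste(dup, collapse = ", "))
  stats::setNames(models, ids)
}
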