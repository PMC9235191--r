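#' Protein-to-CDS codon arithmetic
#'
#' Residue `i` of a protein corresponds to coding-sequence nucleotides
#' `3*(i-1)+1 .. 3*i`, counting along the concatenated CDS in translation
#' order (5' to 3' of the mRNA).
#'
#' @param prot_start,prot_end 1-based residue coordinates,
#'   `1 <= prot_start <= prot_end`.
#' @return integer vector `c(start, end)` of 1-based CDS nucleotide
#'   positions.
#' @examples
#' protein_to_cds(1, 1)    # c(1, 3)
#' protein_to_cds(21, 40)  # c(61, 120)
#' @export
protein_to_cds <- function(prot_start, prot_end) {
  prot_start <- as.integer(prot_start)
  prot_end <- as.integer(prot_end)
  stopifnot(prot_start >= 1L, prot_end >= prot_start)
  c(3L * (prot_start - 1L) + 1L, 3L * prot_end)
}

# CDS segments in translation order: ascending genomic coordinates on "+",
# descending on "-".
translation_order_cds <- function(t) {
  if (t$strand == "+") t$cds else t$cds[rev(seq_len(nrow(t$cds))), , drop = FALSE]
}

# effective CDS length after skipping the first segment's phase
effective_cds_length <- function(t) cds_length(t) - first_phase(t)

#' Lift a CDS-space interval onto the genome
#'
#' CDS-space position 1 is the first translated nucleotide of the
#' translationally first CDS segment: the lowest-coordinate segment on
#' `"+"`, the highest-coordinate one on `"-"`.  When that segment carries a
#' nonzero phase, translation starts after skipping `phase` nucleotides
#' (with a warning).  The interval is split at every CDS-segment boundary
#' it crosses; the returned pieces are sorted by ascending genomic start.
#'
#' The lift is pure interval arithmetic over segment offsets; the per-base
#' enumeration in [oracle_project] is an independent implementation of the
#' same map used to cross-check this one.
#'
#' @param t a coding [transcript_model].
#' @param cds_interval integer `c(start, end)` in CDS space, within
#'   `[1, cds_length(t)]`.
#' @return data.frame of genomic intervals (`start`, `end`), ascending.
#' @export
cds_to_genomic <- function(t, cds_interval) {
  if (!t$coding) stop("transcript ", t$transcript_id, " is non-coding")
  s <- as.integer(cds_interval[1]); e <- as.integer(cds_interval[2])
  cap <- effective_cds_length(t)
  if (s < 1L || e < s || e > cap)
    stop("CDS interval ", s, "-", e, " out of range for transcript ",
         t$transcript_id, " (CDS capacity ", cap, " nt)")
  ph <- first_phase(t)
  if (ph > 0L)
    warning("first CDS segment of ", t$transcript_id, " has phase ", ph,
            "; CDS position 1 starts after skipping ", ph, " nt")

  segs <- translation_order_cds(t)
  out <- list()
  offset <- 0L  # CDS-space nt consumed by previous segments
  for (i in seq_len(nrow(segs))) {
    g_lo <- segs$start[i]; g_hi <- segs$end[i]
    len <- g_hi - g_lo + 1L
    if (i == 1L && ph > 0L) len <- len - ph  # skipped nt are not CDS space
    lo <- max(s, offset + 1L)
    hi <- min(e, offset + len)
    if (lo <= hi) {
      if (t$strand == "+") {
        base <- g_lo + (if (i == 1L) ph else 0L)
        out[[length(out) + 1L]] <- c(base + (lo - offset - 1L),
                                     base + (hi - offset - 1L))
      } else {
        base <- g_hi - (if (i == 1L) ph else 0L)
        out[[length(out) + 1L]] <- c(base - (hi - offset - 1L),
                                     base - (lo - offset - 1L))
      }
    }
    offset <- offset + len
    if (offset >= e) break
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# number of exonic nt preceding CDS position 1 in transcription order
leader_length <- function(t) {
  ph <- first_phase(t)
  if (t$strand == "+") {
    g0 <- min(t$cds$start) + ph  # genomic position of CDS nt 1
    lo <- pmin(t$exons$end, g0 - 1L)
    sum(pmax(0L, lo - t$exons$start + 1L))
  } else {
    g0 <- max(t$cds$end) - ph
    hi <- pmax(t$exons$start, g0 + 1L)
    sum(pmax(0L, t$exons$end - hi + 1L))
  }
}

#' Shift a CDS-space interval into cDNA space
#'
#' cDNA coordinates run along the spliced transcript (exons concatenated,
#' introns removed, UTRs included).  The shift is the 5'-leader length:
#' the number of exonic nucleotides preceding CDS position 1 in
#' transcription order.
#'
#' @inheritParams cds_to_genomic
#' @return integer `c(start, end)` in cDNA space.
#' @export
cds_to_cdna <- function(t, cds_interval) {
  if (!t$coding) stop("transcript ", t$transcript_id, " is non-coding")
  s <- as.integer(cds_interval[1]); e <- as.integer(cds_interval[2])
  cap <- effective_cds_length(t)
  if (s < 1L || e < s || e > cap)
    stop("CDS interval ", s, "-", e, " out of range for transcript ",
         t$transcript_id, " (CDS capacity ", cap, " nt)")
  leader <- leader_length(t)
  c(s + leader, e + leader)
}

#' Project a protein-domain hit through the splice structure
#'
#' Composes [protein_to_cds], [cds_to_genomic] and [cds_to_cdna] to lift
#' one hit into all three coordinate systems.  The summed length of the
#' genomic segments always equals `3 * (prot_end - prot_start + 1)`.
#'
#' @param t a coding [transcript_model].
#' @param h a [domain_hit] attached to `t`.
#' @return an object of class `projected_domain`: list with fields `hit`,
#'   `genomic_segments` (data.frame `start`/`end`, ascending),
#'   `cds_interval` and `cdna_interval` (integer pairs).
#' @export
project_hit <- function(t, h) {
  cds_iv <- protein_to_cds(h$prot_start, h$prot_end)
  structure(list(
    hit = h,
    genomic_segments = cds_to_genomic(t, cds_iv),
    cds_interval = cds_iv,
    cdna_interval = cds_to_cdna(t, cds_iv)
  ), class = "projected_domain")
}

#' @export
print.projected_domain <- function(x, ...) {
  segs <- paste(sprintf("%d-%d", x$genomic_segments$start,
                        x$genomic_segments$end), collapse = ", ")
  cat(sprintf("<projected_domain> %s %d-%d aa -> genomic [%s], cds %d-%d, cdna %d-%d\n",
              x$hit$domain_accession, x$hit$prot_start, x$hit$prot_end, segs,
              x$cds_interval[1], x$cds_interval[2],
              x$cdna_interval[1], x$cdna_interval[2]))
  invisible(x)
}

#' Build the merged transcript + domain database
#'
#' Creates one `merged_record` per transcript — including coding
#' transcripts with zero hits and non-coding transcripts, whose domain
#' lists are empty — with every valid attached hit projected into genomic,
#' cDNA and CDS coordinates.  Records are ordered deterministically by
#' `(seqid, span start, transcript_id)`.
#'
#' @param models list of [transcript_model] objects (one genome).
#' @param attachment result of [attach_hits] (or its `attached` element).
#' @param genome_label label stored on every record; defaults to the label
#'   of the first model.
#' @return list of `merged_record` objects, class `merged_db`.
#' @export
build_database <- function(models, attachment = list(),
                           genome_label = NULL) {
  attached <- if (!is.null(attachment$attached)) attachment$attached else attachment
  if (is.null(genome_label))
    genome_label <- if (length(models) > 0L) models[[1]]$genome_label else "genome"
  o <- order(vapply(models, function(m) m$seqid, character(1)),
             vapply(models, function(m) m$span$start, integer(1)),
             vapply(models, function(m) m$transcript_id, character(1)))
  records <- lapply(models[o], function(m) {
    hs <- attached[[m$transcript_id]]
    domains <- list()
    for (h in hs) {
      if (!is.null(h$valid) && !h$valid) next
      domains[[length(domains) + 1L]] <- project_hit(m, h)
    }
    structure(list(genome_label = genome_label, transcript = m,
                   domains = domains), class = "merged_record")
  })
  structure(records, class = "merged_db")
}

#' @export
print.merged_db <- function(x, ...) {
  n_dom <- sum(vapply(x, function(r) length(r$domains), integer(1)))
  labs <- unique(vapply(x, function(r) r$genome_label, character(1)))
  cat(sprintf("<merged_db> %d transcript(s), %d projected domain(s), genome(s): %s\n",
              length(x), n_dom, paste(labs, collapse = ", ")))
  invisible(x)
}
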