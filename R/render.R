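#' Figure specification
#'
#' Controls the coordinate view, canvas geometry, export format and
#' styling of a transcript+domain figure.  Height and label font size
#' default to auto modes scaled by the number of transcripts drawn:
#' `height = max(1.5, 0.28 * n_rows)` inches and
#' [auto_fontsize]`(n_rows)` points.  These auto-sizing formulas are this
#' package's own.
#'
#' @param view `"genomic"` (transcript feature with introns), `"cdna"`
#'   (exons concatenated) or `"cds"` (coding sequence only, UTRs absent).
#' @param width canvas width in inches.
#' @param height canvas height in inches, or `NULL` for auto.
#' @param dpi raster resolution in dots per inch (>= 36); PNG pixel
#'   dimensions are exactly `round(width * dpi)` by `round(height * dpi)`.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @param label_fontsize transcript-label size in points, or `NULL` for
#'   auto.
#' @param feature_height fraction of a track row occupied by feature
#'   boxes, in (0, 1].
#' @param palette ordered character vector of color hex codes; domain
#'   accessions are assigned colors by first appearance, cycling.
#' @param show_legend draw a color-to-accession legend?
#' @return an object of class `figure_spec`.
#' @export
figure_spec <- function(view = "genomic", width = 8, height = NULL,
                        dpi = 150, format = "png", label_fontsize = NULL,
                        feature_height = 0.55,
                        palette = c("#E64B35", "#4DBBD5", "#00A087",
                                    "#3C5488", "#F39B7F", "#8491B4",
                                    "#91D1C2", "#DC0000"),
                        show_legend = TRUE) {
  if (!view %in% c("genomic", "cdna", "cds"))
    stop("view must be one of genomic, cdna, cds")
  if (!format %in% c("png", "pdf", "svg"))
    stop("unknown figure format '", format, "' (png, pdf or svg)")
  stopifnot(width > 0, dpi >= 36, length(palette) > 0,
            feature_height > 0, feature_height <= 1)
  if (!is.null(height)) stopifnot(height > 0)
  if (!is.null(label_fontsize)) stopifnot(label_fontsize > 0)
  structure(list(view = view, width = width, height = height, dpi = dpi,
                 format = format, label_fontsize = label_fontsize,
                 feature_height = feature_height, palette = palette,
                 show_legend = show_legend),
            class = "figure_spec")
}

#' Auto-scaled transcript-label font size
#'
#' `clamp(round(180 / n), 4, 12)` points: monotone non-increasing in the
#' number of transcripts, so hundreds of rows remain labelled without
#' overlap.
#'
#' @param n_transcripts number of transcript rows (>= 1).
#' @return font size in points.
#' @export
auto_fontsize <- function(n_transcripts) {
  stopifnot(n_transcripts >= 1)
  min(12, max(4, round(180 / n_transcripts)))
}

#' Display coordinates of one record in a chosen view
#'
#' Converts a merged record's features into 1-based display intervals
#' along the view axis, 5' to 3' left-to-right (minus-strand transcripts
#' are flipped in the genomic view so transcription runs rightward).
#'
#' @param r a merged record.
#' @param view `"genomic"`, `"cdna"` or `"cds"`.
#' @return a list with `x_domain` (`c(1, axis_length)`) and `features`, a
#'   data.frame with columns `type` (`utr5`/`utr3`/`cds`/`exon`/`intron`/
#'   `domain`), `start`, `end`, `accession`, `name`.  Non-coding
#'   transcripts are only drawable in the genomic view.
#' @export
to_display_coords <- function(r, view = "genomic") {
  t <- r$transcript
  if (view %in% c("cdna", "cds") && !t$coding)
    stop("transcript ", t$transcript_id, " is non-coding; ", view,
         " view requires a coding transcript")
  feat <- function(type, start, end, accession = NA_character_,
                   name = NA_character_) {
    data.frame(type = type, start = start, end = end,
               accession = accession, name = name)
  }
  rows <- list()
  if (view == "genomic") {
    flip <- function(g) if (t$strand == "+") g - t$span$start + 1L else
      t$span$end - g + 1L
    box <- function(type, gs, ge, acc = NA_character_, nm = NA_character_) {
      a <- flip(gs); b <- flip(ge)
      feat(type, min(a, b), max(a, b), acc, nm)
    }
    if (t$coding) {
      utrs <- derive_utrs(t)
      for (i in seq_len(nrow(utrs)))
        rows[[length(rows) + 1L]] <- box(utrs$side[i], utrs$start[i], utrs$end[i])
      for (i in seq_len(nrow(t$cds)))
        rows[[length(rows) + 1L]] <- box("cds", t$cds$start[i], t$cds$end[i])
    } else {
      for (i in seq_len(nrow(t$exons)))
        rows[[length(rows) + 1L]] <- box("exon", t$exons$start[i], t$exons$end[i])
    }
    if (nrow(t$exons) > 1L) {
      for (i in seq_len(nrow(t$exons) - 1L))
        rows[[length(rows) + 1L]] <- box("intron", t$exons$end[i] + 1L,
                                         t$exons$start[i + 1L] - 1L)
    }
    for (d in r$domains) {
      for (i in seq_len(nrow(d$genomic_segments)))
        rows[[length(rows) + 1L]] <- box("domain", d$genomic_segments$start[i],
                                         d$genomic_segments$end[i],
                                         d$hit$domain_accession,
                                         d$hit$domain_name)
    }
    axis_len <- t$span$end - t$span$start + 1L
  } else if (view == "cdna") {
    leader <- leader_length(t)
    eff <- effective_cds_length(t)
    n <- cdna_length(t)
    if (leader > 0L) rows[[length(rows) + 1L]] <- feat("utr5", 1L, leader)
    rows[[length(rows) + 1L]] <- feat("cds", leader + 1L, leader + eff)
    if (leader + eff < n)
      rows[[length(rows) + 1L]] <- feat("utr3", leader + eff + 1L, n)
    for (d in r$domains)
      rows[[length(rows) + 1L]] <- feat("domain", d$cdna_interval[1],
                                        d$cdna_interval[2],
                                        d$hit$domain_accession,
                                        d$hit$domain_name)
    axis_len <- n
  } else {
    eff <- effective_cds_length(t)
    # translation-order segment boundaries, so splice junctions stay visible
    segs <- translation_order_cds(t)
    lens <- segs$end - segs$start + 1L
    lens[1] <- lens[1] - first_phase(t)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    for (i in seq_along(lens))
      rows[[length(rows) + 1L]] <- feat("cds", offs[i] + 1L, offs[i] + lens[i])
    for (d in r$domains)
      rows[[length(rows) + 1L]] <- feat("domain", d$cds_interval[1],
                                        d$cds_interval[2],
                                        d$hit$domain_accession,
                                        d$hit$domain_name)
    axis_len <- eff
  }
  features <- if (length(rows) == 0L)
    feat(character(0), integer(0), integer(0))[0, ] else do.call(rbind, rows)
  rownames(features) <- NULL
  list(x_domain = c(1L, as.integer(axis_len)), features = features)
}

#' Compute a deterministic track layout
#'
#' Orders records by `(genome_label, seqid, span start, transcript_id)`,
#' converts each to display coordinates in the requested view, assigns
#' domain colors by first appearance of their accession over the palette
#' (cycling), and resolves the label font size.  Identical inputs always
#' produce identical layouts (see [serialize_layout]).
#'
#' @param records a `merged_db` of records to draw (non-empty).
#' @param spec a [figure_spec].
#' @return an object of class `track_layout` with fields `rows` (each:
#'   `record`, `row_index`, `x_domain`, `features`, `label`), `colors`
#'   (named accession-to-hex map), `fontsize_used`, `view`, `n_rows`.
#' @export
build_layout <- function(records, spec = figure_spec()) {
  if (length(records) == 0L) stop("nothing to plot: no records supplied")
  o <- order(vapply(records, function(r) r$genome_label, character(1)),
             vapply(records, function(r) r$transcript$seqid, character(1)),
             vapply(records, function(r) r$transcript$span$start, integer(1)),
             vapply(records, function(r) r$transcript$transcript_id, character(1)))
  records <- records[o]
  colors <- character(0)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    disp <- to_display_coords(r, spec$view)
    for (acc in disp$features$accession[disp$features$type == "domain"]) {
      if (!acc %in% names(colors)) {
        colors[acc] <- spec$palette[(length(colors) %% length(spec$palette)) + 1L]
      }
    }
    rows[[i]] <- list(record = r, row_index = i - 1L,
                      x_domain = disp$x_domain, features = disp$features,
                      label = r$transcript$transcript_id)
  }
  fontsize <- if (!is.null(spec$label_fontsize)) spec$label_fontsize else
    auto_fontsize(length(rows))
  structure(list(rows = rows, colors = colors, fontsize_used = fontsize,
                 view = spec$view, n_rows = length(rows)),
            class = "track_layout")
}

#' @export
print.track_layout <- function(x, ...) {
  cat(sprintf("<track_layout> %d row(s), view %s, %d domain color(s), fontsize %g pt\n",
              x$n_rows, x$view, length(x$colors), x$fontsize_used))
  invisible(x)
}

#' Serialize a track layout to canonical JSON text
#'
#' A stable text form of the layout geometry (rows, display intervals,
#' colors, font size) used to assert layout determinism in tests.
#'
#' @param layout a [build_layout] result.
#' @return a single JSON string.
#' @export
serialize_layout <- function(layout) {
  x <- list(
    view = layout$view,
    n_rows = layout$n_rows,
    fontsize_used = layout$fontsize_used,
    colors = as.list(layout$colors),
    rows = lapply(layout$rows, function(row) list(
      label = row$label,
      row_index = row$row_index,
      x_domain = row$x_domain,
      features = row$features
    ))
  )
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                na = "null", dataframe = "columns"))
}

resolved_height <- function(spec, n_rows) {
  if (!is.null(spec$height)) spec$height else
    max(1.5, 0.28 * n_rows + if (spec$show_legend) 0.4 else 0)
}

#' Export a layout to a figure file
#'
#' PNG output honors the requested resolution exactly: pixel dimensions
#' are `round(width * dpi)` by `round(height * dpi)`.  PDF and SVG embed
#' physical width/height in inches.  SVG is written by the package's own
#' deterministic writer (no timestamps; transcript labels are `<text>`
#' nodes), so repeated exports of one layout are byte-identical.
#'
#' @param layout a [build_layout] result.
#' @param spec the [figure_spec] (format, geometry, styling).
#' @param path output file path; its parent directory must exist.
#' @return `path`, invisibly.
#' @export
export_figure <- function(layout, spec, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write figure: directory does not exist: ", dirname(path))
  height <- resolved_height(spec, layout$n_rows)
  if (spec$format == "png") {
    grDevices::png(path, width = round(spec$width * spec$dpi),
                   height = round(height * spec$dpi), res = spec$dpi,
                   units = "px", type = "cairo")
    on.exit(grDevices::dev.off())
    draw_layout(layout, spec)
  } else if (spec$format == "pdf") {
    grDevices::pdf(path, width = spec$width, height = height)
    on.exit(grDevices::dev.off())
    draw_layout(layout, spec)
  } else if (spec$format == "svg") {
    writeLines(layout_svg(layout, spec, height), path)
  } else {
    stop("unknown figure format '", spec$format, "'")
  }
  invisible(path)
}

# ---- shared geometry -------------------------------------------------------
# Normalized canvas: labels in [0, label_w), tracks in [track_x0, 0.99].
# Each row is x-scaled independently to its own extent (records may span
# different chromosomes and genomes, so there is no shared axis).
LABEL_W <- 0.16
TRACK_X0 <- 0.18
TRACK_X1 <- 0.99

row_geometry <- function(layout, spec, legend_frac) {
  n <- layout$n_rows
  y_top <- 1 - legend_frac
  list(
    n = n,
    y_center = function(i) y_top * (1 - (i + 0.5) / n),
    row_h = y_top / n
  )
}

scale_x <- function(x, x_domain) {
  span <- x_domain[2] - x_domain[1] + 1
  TRACK_X0 + (x - x_domain[1]) / span * (TRACK_X1 - TRACK_X0)
}

# half-height factors per feature type (fraction of feature_height)
feature_half <- function(type) {
  switch(type, utr5 = 0.5, utr3 = 0.5, 0.999) # cds/exon/domain full
}

feature_fill <- function(type, acc, colors) {
  switch(type,
         domain = unname(colors[acc]),
         cds = "#B8B8B8", exon = "#B8B8B8",
         utr5 = "#D9D9D9", utr3 = "#D9D9D9",
         NA_character_)
}

draw_layout <- function(layout, spec) {
  legend_frac <- if (spec$show_legend && length(layout$colors) > 0) 0.08 else 0
  geo <- row_geometry(layout, spec, legend_frac)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), xaxs = "i", yaxs = "i")
  cex <- layout$fontsize_used / 12
  for (row in layout$rows) {
    yc <- geo$y_center(row$row_index)
    hh <- spec$feature_height * geo$row_h / 2
    f <- row$features
    for (pass in list(c("intron"), c("exon", "cds", "utr5", "utr3"), c("domain"))) {
      idx <- which(f$type %in% pass)
      for (i in idx) {
        x0 <- scale_x(f$start[i], row$x_domain)
        x1 <- scale_x(f$end[i] + 1L, row$x_domain)
        if (f$type[i] == "intron") {
          graphics::segments(x0, yc, x1, yc, col = "#555555", lwd = 0.8)
        } else {
          h <- hh * feature_half(f$type[i])
          graphics::rect(x0, yc - h, x1, yc + h,
                         col = feature_fill(f$type[i], f$accession[i],
                                            layout$colors),
                         border = if (f$type[i] == "domain") "black" else NA,
                         lwd = 0.6)
        }
      }
    }
    graphics::text(LABEL_W, yc, labels = row$label, adj = c(1, 0.5), cex = cex)
  }
  if (legend_frac > 0) {
    accs <- names(layout$colors)
    k <- length(accs)
    for (j in seq_len(k)) {
      x0 <- TRACK_X0 + (j - 1) / k * (TRACK_X1 - TRACK_X0)
      y0 <- 1 - legend_frac / 2
      graphics::rect(x0, y0 - 0.015, x0 + 0.02, y0 + 0.015,
                     col = layout$colors[[j]], border = "black", lwd = 0.5)
      graphics::text(x0 + 0.025, y0, labels = accs[j], adj = c(0, 0.5),
                     cex = 0.7)
    }
  }
}

# ---- hand-written SVG back end --------------------------------------------
# 100 user units per inch; emits plain rect/line/text nodes with no
# timestamps or session state, so output is byte-deterministic.
layout_svg <- function(layout, spec, height) {
  W <- spec$width * 100
  H <- height * 100
  legend_frac <- if (spec$show_legend && length(layout$colors) > 0) 0.08 else 0
  geo <- row_geometry(layout, spec, legend_frac)
  # y normalized (0 bottom) -> svg pixels (0 top)
  ypix <- function(y) (1 - y) * H
  xpix <- function(x) x * W
  fontsize_px <- layout$fontsize_used / 72 * 100
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  num <- function(x) sprintf("%.2f", x)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%gin\"",
                   " height=\"%gin\" viewBox=\"0 0 %s %s\">"),
            spec$width, height, num(W), num(H)),
    sprintf("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"white\"/>",
            num(W), num(H)))
  rect_node <- function(x0, y0, x1, y1, fill, stroke = NA) {
    sprintf(paste0("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\"",
                   " fill=\"%s\"%s/>"),
            num(min(x0, x1)), num(min(y0, y1)), num(abs(x1 - x0)),
            num(abs(y1 - y0)), fill,
            if (is.na(stroke)) "" else
              sprintf(" stroke=\"%s\" stroke-width=\"0.6\"", stroke))
  }
  for (row in layout$rows) {
    yc <- geo$y_center(row$row_index)
    hh <- spec$feature_height * geo$row_h / 2
    f <- row$features
    for (pass in list(c("intron"), c("exon", "cds", "utr5", "utr3"), c("domain"))) {
      for (i in which(f$type %in% pass)) {
        x0 <- xpix(scale_x(f$start[i], row$x_domain))
        x1 <- xpix(scale_x(f$end[i] + 1L, row$x_domain))
        if (f$type[i] == "intron") {
          out <- c(out, sprintf(paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\"",
                                       " y2=\"%s\" stroke=\"#555555\"",
                                       " stroke-width=\"0.8\"/>"),
                                num(x0), num(ypix(yc)), num(x1), num(ypix(yc))))
        } else {
          h <- hh * feature_half(f$type[i])
          out <- c(out, rect_node(x0, ypix(yc - h), x1, ypix(yc + h),
                                  feature_fill(f$type[i], f$accession[i],
                                               layout$colors),
                                  if (f$type[i] == "domain") "black" else NA))
        }
      }
    }
    out <- c(out, sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"%s\"",
                                 " font-family=\"sans-serif\"",
                                 " text-anchor=\"end\"",
                                 " dominant-baseline=\"middle\"",
                                 " class=\"transcript-label\">%s</text>"),
                          num(xpix(LABEL_W)), num(ypix(yc)),
                          num(fontsize_px), esc(row$label)))
  }
  if (legend_frac > 0) {
    accs <- names(layout$colors)
    k <- length(accs)
    for (j in seq_len(k)) {
      x0 <- xpix(TRACK_X0 + (j - 1) / k * (TRACK_X1 - TRACK_X0))
      y0 <- ypix(1 - legend_frac / 2)
      out <- c(out, rect_node(x0, y0 - 3, x0 + 6, y0 + 3,
                              layout$colors[[j]], "black"),
               sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"8\"",
                              " font-family=\"sans-serif\"",
                              " dominant-baseline=\"middle\">%s</text>"),
                       num(x0 + 9), num(y0), esc(accs[j])))
    }
  }
  c(out, "</svg>")
}
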