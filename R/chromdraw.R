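#' Ideogram rendering configuration
#'
#' Controls the banded-chromosome drawing and the per-window log2 bar track
#' drawn alongside it. The stain palette follows the conventional Giemsa
#' grayscale (gneg white through gpos100 black, acen red); every stain value
#' must be covered.
#'
#' @param bp_per_pixel Genomic bp per pixel of ideogram length (default
#'   5000).
#' @param track_max_abs_log2 Clip value: |log2| at or beyond this draws a
#'   full-length bar (default 2).
#' @param loss_color,gain_color,undefined_color Colors for loss bars, gain
#'   bars and undefined-window markers.
#' @param stain_palette Named character vector mapping every stain to a fill
#'   color.
#' @param orientation `"vertical"` (default) or `"horizontal"`.
#' @param label_bands Draw band-name labels (default TRUE).
#' @return A list of class `render_config`.
#' @export
render_config <- function(bp_per_pixel = 5000,
                          track_max_abs_log2 = 2,
                          loss_color = "#c0392b",
                          gain_color = "#2471a3",
                          undefined_color = "#bdbdbd",
                          stain_palette = c(gneg = "#ffffff",
                                            gpos25 = "#c8c8c8",
                                            gpos50 = "#969696",
                                            gpos75 = "#646464",
                                            gpos100 = "#000000",
                                            acen = "#b03a2e",
                                            gvar = "#d9d9f3",
                                            stalk = "#7f7f7f"),
                          orientation = c("vertical", "horizontal"),
                          label_bands = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(bp_per_pixel > 0, track_max_abs_log2 > 0)
  missing <- setdiff(.known_stains, names(stain_palette))
  if (length(missing) > 0L) {
    stop("stain_palette must cover all stains; missing: ",
         paste(missing, collapse = ", "))
  }
  structure(list(bp_per_pixel = bp_per_pixel,
                 track_max_abs_log2 = track_max_abs_log2,
                 loss_color = loss_color, gain_color = gain_color,
                 undefined_color = undefined_color,
                 stain_palette = stain_palette,
                 orientation = orientation, label_bands = label_bands),
            class = "render_config")
}

fmt_px <- function(x) sprintf("%.2f", x)

svg_el <- function(tag, ..., close = TRUE) {
  attrs <- c(...)
  body <- paste(sprintf('%s="%s"', names(attrs), attrs), collapse = " ")
  if (close) sprintf("<%s %s/>", tag, body) else sprintf("<%s %s>", tag, body)
}

# layout constants (px)
.ly <- list(top = 20, left = 10, rod_w = 22, gap = 14, track_halfw = 44,
            label_w = 56, seg_w = 56, bottom = 16, cap = 8)

chrom_panel_width <- function(config) {
  lab <- if (config$label_bands) .ly$label_w else 0
  .ly$left + lab + .ly$rod_w + .ly$gap + 2 * .ly$track_halfw + .ly$seg_w
}

# SVG fragment for one chromosome panel, translated by (x0, 0).
# bands: GRanges subset for this chromosome (may be empty);
# vals: per-window log2 (may be NULL); wdf: window coords for this chromosome.
chromosome_panel <- function(chrom, length_bp, bands, wdf, vals, segments,
                             config, x0) {
  pp <- config$bp_per_pixel
  lab <- if (config$label_bands) .ly$label_w else 0
  rod_x <- x0 + .ly$left + lab
  trk_c <- rod_x + .ly$rod_w + .ly$gap + .ly$track_halfw
  rod_h <- length_bp / pp
  out <- character(0)
  clip_id <- sprintf("clip-%s", chrom)
  out <- c(out, sprintf('<clipPath id="%s">', clip_id),
           svg_el("rect", x = fmt_px(rod_x), y = fmt_px(.ly$top),
                  width = fmt_px(.ly$rod_w), height = fmt_px(rod_h),
                  rx = fmt_px(.ly$cap), ry = fmt_px(.ly$cap)),
           "</clipPath>")
  out <- c(out, svg_el("text", x = fmt_px(rod_x + .ly$rod_w / 2),
                       y = fmt_px(.ly$top - 6),
                       `text-anchor` = "middle", `font-size` = "11",
                       `font-family` = "sans-serif",
                       id = sprintf("label:%s", chrom), close = FALSE))
  out[length(out)] <- paste0(out[length(out)], chrom, "</text>")
  # band rects (clipped to the rounded rod); acen bands as pinch triangles
  if (length(bands) > 0L) {
    bs <- GenomicRanges::start(bands) - 1
    be <- GenomicRanges::end(bands)
    for (i in seq_along(bands)) {
      y <- .ly$top + bs[i] / pp
      h <- (be[i] - bs[i]) / pp
      fill <- unname(config$stain_palette[bands$stain[i]])
      id <- sprintf("band:%s:%s", chrom, bands$band[i])
      if (bands$stain[i] == "acen") {
        xc <- rod_x + .ly$rod_w / 2
        pts <- if (startsWith(bands$band[i], "p")) {
          # p-side acen narrows downward
          sprintf("%s,%s %s,%s %s,%s", fmt_px(rod_x), fmt_px(y),
                  fmt_px(rod_x + .ly$rod_w), fmt_px(y), fmt_px(xc),
                  fmt_px(y + h))
        } else {
          sprintf("%s,%s %s,%s %s,%s", fmt_px(xc), fmt_px(y),
                  fmt_px(rod_x + .ly$rod_w), fmt_px(y + h), fmt_px(rod_x),
                  fmt_px(y + h))
        }
        out <- c(out, svg_el("polygon", points = pts, fill = fill,
                             stroke = "#303030", `stroke-width` = "0.5",
                             id = id))
      } else {
        out <- c(out, svg_el("rect", x = fmt_px(rod_x), y = fmt_px(y),
                             width = fmt_px(.ly$rod_w), height = fmt_px(h),
                             fill = fill, `clip-path` = sprintf("url(#%s)", clip_id),
                             id = id))
      }
      if (config$label_bands) {
        out <- c(out, svg_el("text", x = fmt_px(rod_x - 4),
                             y = fmt_px(y + h / 2 + 3),
                             `text-anchor` = "end", `font-size` = "8",
                             `font-family` = "sans-serif",
                             id = sprintf("bandlabel:%s:%s", chrom, bands$band[i]),
                             close = FALSE))
        out[length(out)] <- paste0(out[length(out)], bands$band[i], "</text>")
      }
    }
  }
  # rod outline on top of the fills
  out <- c(out, svg_el("rect", x = fmt_px(rod_x), y = fmt_px(.ly$top),
                       width = fmt_px(.ly$rod_w), height = fmt_px(rod_h),
                       rx = fmt_px(.ly$cap), ry = fmt_px(.ly$cap),
                       fill = "none", stroke = "#303030",
                       `stroke-width` = "1",
                       id = sprintf("rod:%s", chrom)))
  # log2 bar track: losses extend left of the center line, gains right
  if (!is.null(vals)) {
    out <- c(out, svg_el("line", x1 = fmt_px(trk_c), y1 = fmt_px(.ly$top),
                         x2 = fmt_px(trk_c), y2 = fmt_px(.ly$top + rod_h),
                         stroke = "#909090", `stroke-width` = "0.5",
                         id = sprintf("axis:%s", chrom)))
    clip <- config$track_max_abs_log2
    for (j in seq_len(nrow(wdf))) {
      y <- .ly$top + wdf$start[j] / pp
      h <- (wdf$end[j] - wdf$start[j]) / pp
      v <- vals[j]
      id <- sprintf("win:%s:%d", chrom, wdf$window[j])
      if (is.na(v)) {
        out <- c(out, svg_el("rect", x = fmt_px(trk_c - 2), y = fmt_px(y),
                             width = fmt_px(4), height = fmt_px(h),
                             fill = config$undefined_color, id = id))
      } else {
        w <- min(abs(v), clip) / clip * .ly$track_halfw
        x <- if (v < 0) trk_c - w else trk_c
        fill <- if (v < 0) config$loss_color else config$gain_color
        out <- c(out, svg_el("rect", x = fmt_px(x), y = fmt_px(y),
                             width = fmt_px(w), height = fmt_px(h),
                             fill = fill, id = id))
      }
    }
  }
  # segment brackets right of the track
  if (!is.null(segments) && length(segments) > 0L) {
    xb <- trk_c + .ly$track_halfw + 4
    for (k in seq_along(segments)) {
      y1 <- .ly$top + (GenomicRanges::start(segments)[k] - 1) / pp
      y2 <- .ly$top + GenomicRanges::end(segments)[k] / pp
      col <- if (segments$direction[k] == "loss") config$loss_color else config$gain_color
      out <- c(out,
               svg_el("path",
                      d = sprintf("M %s %s h 4 V %s h -4", fmt_px(xb),
                                  fmt_px(y1), fmt_px(y2)),
                      fill = "none", stroke = col, `stroke-width` = "1.5",
                      id = sprintf("seg:%s:%d", chrom, k)))
      lab <- paste(unlist(segments$bands[k]), collapse = " ")
      if (nzchar(lab)) {
        out <- c(out, svg_el("text", x = fmt_px(xb + 7),
                             y = fmt_px((y1 + y2) / 2 + 3),
                             `font-size` = "8", `font-family` = "sans-serif",
                             id = sprintf("seglabel:%s:%d", chrom, k),
                             close = FALSE))
        out[length(out)] <- paste0(out[length(out)], lab, "</text>")
      }
    }
  }
  out
}

svg_document <- function(lines, width, height) {
  doc <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   fmt_px(width), fmt_px(height), fmt_px(width),
                   fmt_px(height)),
           lines, "</svg>")
  structure(doc, class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("svg_document: %d lines\n", length(x)))
  invisible(x)
}

#' Write an SVG document to file
#'
#' Output is byte-deterministic for identical inputs (all coordinates are
#' fixed-format, LF line endings).
#'
#' @param doc An `svg_document` from [render_chromosome()] or
#'   [render_genome_panorama()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "svg_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unclass(doc), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Render one chromosome as a banded ideogram with its log2 track
#'
#' Draws the chromosome rod with stain-colored cytobands (rounded telomere
#' caps, pinched acen centromere), a per-window bar track (losses left of
#' the axis in `loss_color`, gains right in `gain_color`, undefined windows
#' as small `undefined_color` markers, lengths proportional to |log2|
#' clipped at `track_max_abs_log2`) and optional segment brackets labelled
#' with their bands. Every element carries a machine-readable `id`
#' (`band:<chrom>:<name>`, `win:<chrom>:<window>`, `seg:<chrom>:<k>`), so
#' the document can be queried structurally.
#'
#' @param chrom Chromosome name.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param bands Cytoband `GRanges` (may be empty: a band-less rod is drawn).
#' @param track A `ratio_track` covering the chromosome, or NULL for no
#'   track.
#' @param segments Optional segment `GRanges`.
#' @param config A [render_config()].
#' @return An `svg_document` (character vector of SVG lines).
#' @export
render_chromosome <- function(chrom, genome, bands = NULL, track = NULL,
                              segments = NULL, config = render_config()) {
  stopifnot(methods::is(genome, "Seqinfo"))
  if (!(chrom %in% GenomeInfoDb::seqnames(genome))) {
    stop("chromosome not in genome index: ", chrom)
  }
  len <- as.numeric(GenomeInfoDb::seqlengths(genome)[chrom])
  bands_c <- subset_chrom(bands, chrom, "band")
  wdf <- NULL; vals <- NULL
  if (!is.null(track)) {
    if (!(chrom %in% track$grid$chrom)) {
      stop("track does not cover chromosome ", chrom)
    }
    wdf <- windows_df(track$grid, chrom)
    i <- match(chrom, track$grid$chrom)
    vals <- track$log2_ratio[track$grid$offset[i] + seq_len(track$grid$n_windows[i])]
  }
  segs_c <- subset_chrom(segments, chrom, "segment")
  lines <- chromosome_panel(chrom, len, bands_c, wdf, vals, segs_c, config,
                            x0 = 0)
  svg_document(lines, width = chrom_panel_width(config),
               height = .ly$top + len / config$bp_per_pixel + .ly$bottom)
}

subset_chrom <- function(gr, chrom, what) {
  if (is.null(gr) || length(gr) == 0L) return(gr)
  gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
}

#' Render the whole-genome panorama
#'
#' One panel per chromosome, side by side in genome-index order, sharing a
#' common bp scale so panel heights are proportional to chromosome lengths
#' — the gain/loss overview map. Chromosomes absent from the track (or with
#' `track = NULL`) are drawn as bare ideograms with a warning.
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param bands Cytoband `GRanges` (may be NULL/empty).
#' @param track A genome-wide `ratio_track`, or NULL.
#' @param segments Optional segment `GRanges`.
#' @param config A [render_config()].
#' @return An `svg_document`.
#' @export
render_genome_panorama <- function(genome, bands = NULL, track = NULL,
                                   segments = NULL,
                                   config = render_config()) {
  stopifnot(methods::is(genome, "Seqinfo"))
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  panel_w <- chrom_panel_width(config)
  lines <- character(0)
  for (i in seq_along(chroms)) {
    wdf <- NULL; vals <- NULL
    if (!is.null(track) && chroms[i] %in% track$grid$chrom) {
      wdf <- windows_df(track$grid, chroms[i])
      gi <- match(chroms[i], track$grid$chrom)
      vals <- track$log2_ratio[track$grid$offset[gi] +
                               seq_len(track$grid$n_windows[gi])]
    } else if (!is.null(track)) {
      warning("no track windows for chromosome ", chroms[i],
              "; drawing bare ideogram")
    }
    lines <- c(lines, chromosome_panel(
      chroms[i], lens[i], subset_chrom(bands, chroms[i], "band"), wdf, vals,
      subset_chrom(segments, chroms[i], "segment"), config,
      x0 = (i - 1) * panel_w))
  }
  svg_document(lines, width = panel_w * length(chroms),
               height = .ly$top + max(lens) / config$bp_per_pixel + .ly$bottom)
}
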