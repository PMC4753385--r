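#' Segment-calling configuration
#'
#' Thresholded-window calling: a run of consecutive windows beyond a log2
#' threshold becomes a segment. Neutral or undefined windows inside a run
#' are bridged up to `max_gap_windows`; a run needs at least
#' `min_consecutive_windows` qualifying windows to be reported. Defaults
#' (−0.5/+0.5, min 3, gap 1) are toolkit choices — a hemizygous loss in all
#' pool members sits at −1, so −0.5 is its half-way point — exposed for
#' tuning.
#'
#' @param loss_threshold Log2 value at or below which a window is "lost"
#'   (must be < 0; default −0.5).
#' @param gain_threshold Log2 value at or above which a window is "gained"
#'   (must be > 0; default +0.5).
#' @param min_consecutive_windows Minimum qualifying windows per segment
#'   (default 3).
#' @param max_gap_windows Maximum run of non-qualifying (neutral or
#'   undefined) windows bridged inside a segment (default 1).
#' @return A list of class `call_config`.
#' @export
call_config <- function(loss_threshold = -0.5, gain_threshold = 0.5,
                        min_consecutive_windows = 3L, max_gap_windows = 1L) {
  stopifnot(loss_threshold < 0, gain_threshold > 0,
            min_consecutive_windows >= 1, max_gap_windows >= 0)
  structure(list(loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 min_consecutive_windows = as.integer(min_consecutive_windows),
                 max_gap_windows = as.integer(max_gap_windows)),
            class = "call_config")
}

#' Call loss/gain segments from a ratio track
#'
#' Scans each chromosome for maximal runs of windows at or beyond the loss
#' or gain threshold. Runs separated by at most `max_gap_windows`
#' non-qualifying windows are merged; undefined (`NA`) windows neither
#' qualify nor hard-break a run — they count toward the gap like any other
#' non-qualifying window. `mean_log2` is the mean over the defined windows
#' spanned by the segment. Segments never cross chromosome boundaries, never
#' overlap, and come out sorted.
#'
#' @param track A `ratio_track`.
#' @param config A [call_config()].
#' @return A [GenomicRanges::GRanges] of segments with metadata columns
#'   `direction` ("loss"/"gain"), `n_windows` (windows spanned), `mean_log2`
#'   and `bands` (empty until [annotate_bands()]).
#' @examples
#' gi <- genome_index("chr1", 400000)
#' g <- window_grid(gi, 40000)
#' s <- window_counts(c(50, 50, 25, 25, 25, 25, 50, 50, 50, 50), g)
#' r <- window_counts(rep(50, 10), g)
#' call_segments(log2_ratio_track(s, r, normalize = FALSE))
#' @export
call_segments <- function(track, config = call_config()) {
  stopifnot(inherits(track, "ratio_track"), inherits(config, "call_config"))
  grid <- track$grid
  segs <- list()
  for (i in seq_along(grid$chrom)) {
    idx <- grid$offset[i] + seq_len(grid$n_windows[i])
    vals <- track$log2_ratio[idx]
    for (dir in c("loss", "gain")) {
      qual <- if (dir == "loss") {
        !is.na(vals) & vals <= config$loss_threshold
      } else {
        !is.na(vals) & vals >= config$gain_threshold
      }
      runs <- qualifying_runs(qual, config$max_gap_windows,
                              config$min_consecutive_windows)
      for (r in runs) {
        first <- r[1L]; last <- r[2L]
        span <- vals[first:last]
        start0 <- (first - 1L) * as.numeric(grid$window_bp)
        end0 <- min(last * as.numeric(grid$window_bp), grid$length[i])
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = grid$chrom[i], start0 = start0, end0 = end0,
          direction = dir, n_windows = last - first + 1L,
          mean_log2 = mean(span, na.rm = TRUE))
      }
    }
  }
  segments_granges(segs, grid$genome)
}

# maximal runs of TRUE, merging across gaps of <= max_gap FALSE/NA windows,
# keeping runs with >= min_qual qualifying windows; returns list of
# c(first, last) window indices (1-based, ends always qualifying)
qualifying_runs <- function(qual, max_gap, min_qual) {
  idx <- which(qual)
  if (length(idx) == 0L) return(list())
  breaks <- which(diff(idx) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  out <- list()
  for (k in seq_along(starts)) {
    members <- idx[starts[k]:ends[k]]
    if (length(members) >= min_qual) {
      out[[length(out) + 1L]] <- c(members[1L], members[length(members)])
    }
  }
  out
}

segments_granges <- function(segs, genome) {
  if (length(segs) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = genome)
    gr$direction <- character(0)
    gr$n_windows <- integer(0)
    gr$mean_log2 <- numeric(0)
    gr$bands <- IRanges::CharacterList()
    return(gr)
  }
  df <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = GenomeInfoDb::seqnames(genome)),
    ranges = IRanges::IRanges(start = df$start0 + 1, end = df$end0),
    seqinfo = genome)
  gr$direction <- df$direction
  gr$n_windows <- as.integer(df$n_windows)
  gr$mean_log2 <- df$mean_log2
  gr$bands <- IRanges::CharacterList(rep(list(character(0)), length(gr)))
  BiocGenerics::sort(gr)
}

#' Intersect same-direction segments across pools
#'
#' The "shared loss" operation: the genomic intersection of segments of one
#' direction that are present in every input list. With two pools each
#' carrying a private deletion plus one shared deletion, only the shared
#' interval survives, trimmed to the coordinates common to all pools. The
#' operation is commutative and associative in its inputs.
#'
#' @param per_pool_segments List (length >= 2) of segment `GRanges` as
#'   returned by [call_segments()], one per pool, on the same genome.
#' @param direction "loss" or "gain".
#' @param min_pools Number of pools a region must be called in (default: all
#'   of them).
#' @return A segment `GRanges`; `mean_log2` is the across-pool mean of the
#'   overlapping source segments' means, `n_windows` is `NA` (the window
#'   grid is a property of the source tracks).
#' @export
intersect_segments <- function(per_pool_segments,
                               direction = c("loss", "gain"),
                               min_pools = length(per_pool_segments)) {
  direction <- match.arg(direction)
  stopifnot(is.list(per_pool_segments), length(per_pool_segments) >= 2L,
            min_pools >= 1L, min_pools <= length(per_pool_segments))
  sel <- lapply(per_pool_segments, function(gr) {
    GenomicRanges::reduce(gr[gr$direction == direction])
  })
  genome <- GenomeInfoDb::seqinfo(per_pool_segments[[1L]])
  cov <- GenomicRanges::coverage(do.call(c, unname(sel)))
  shared <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_pools,
                                                  rangesOnly = TRUE),
                                   seqinfo = genome)
  if (length(shared) == 0L) return(segments_granges(list(), genome))
  means <- vapply(seq_along(shared), function(i) {
    per_pool <- vapply(per_pool_segments, function(gr) {
      hit <- gr[gr$direction == direction &
                IRanges::overlapsAny(gr, shared[i])]
      if (length(hit) == 0L) return(NA_real_)
      mean(hit$mean_log2)
    }, numeric(1))
    mean(per_pool, na.rm = TRUE)
  }, numeric(1))
  shared$direction <- direction
  shared$n_windows <- NA_integer_
  shared$mean_log2 <- means
  shared$bands <- IRanges::CharacterList(rep(list(character(0)), length(shared)))
  BiocGenerics::sort(shared)
}

#' Annotate segments with overlapping cytogenetic bands
#'
#' Fills the `bands` column with the names of every cytoband overlapping
#' each segment by at least 1 bp, in genomic order — the translation from
#' window coordinates to the cytogenetic vocabulary used to report losses.
#'
#' @param segments Segment `GRanges` (from [call_segments()] or
#'   [intersect_segments()]).
#' @param bands Cytoband `GRanges` (from [load_cytobands()]).
#' @return The segments with `bands` filled; segments on chromosomes without
#'   any band get an empty list with a warning.
#' @examples
#' gi <- genome_index("chr5", 180e6)
#' bands <- cytobands(data.frame(chrom = "chr5", start = 68e6, end = 72e6,
#'                               band = "q13.2", stain = "gneg"), gi)
#' seg <- GenomicRanges::GRanges("chr5", IRanges::IRanges(68500001, 71000000),
#'                               seqinfo = gi)
#' seg$direction <- "loss"; seg$n_windows <- NA_integer_
#' seg$mean_log2 <- -1; seg$bands <- IRanges::CharacterList(list(character(0)))
#' annotate_bands(seg, bands)$bands  # q13.2
#' @export
annotate_bands <- function(segments, bands) {
  stopifnot(methods::is(segments, "GRanges"), methods::is(bands, "GRanges"))
  hits <- GenomicRanges::findOverlaps(segments, bands, minoverlap = 1L)
  lst <- rep(list(character(0)), length(segments))
  for (i in seq_along(segments)) {
    b <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    lst[[i]] <- bands$band[sort(b)]
  }
  no_band_chrom <- setdiff(
    unique(as.character(GenomicRanges::seqnames(segments))),
    unique(as.character(GenomicRanges::seqnames(bands))))
  if (length(no_band_chrom) > 0L) {
    warning("no cytobands available for chromosome(s): ",
            paste(no_band_chrom, collapse = ", "))
  }
  segments$bands <- IRanges::CharacterList(lst)
  segments
}

#' Segment span in megabases
#'
#' @param segments Segment `GRanges`.
#' @return Numeric vector: `(end - start) / 1e6` in the 0-based half-open
#'   sense, i.e. the genomic extent in Mb.
#' @examples
#' gi <- genome_index("chr5", 180e6)
#' seg <- GenomicRanges::GRanges("chr5", IRanges::IRanges(68500001, 71000000),
#'                               seqinfo = gi)
#' segment_span_mb(seg)  # 2.5
#' @export
segment_span_mb <- function(segments) {
  stopifnot(methods::is(segments, "GRanges"))
  w <- GenomicRanges::width(segments)
  if (any(w < 1)) stop("zero-length segment")
  as.numeric(w) / 1e6
}

#' Count annotated genes per segment
#'
#' Optional helper: given a gene annotation as a `GRanges` (e.g. read from a
#' BED or GFF of gene spans), counts genes overlapping each segment by at
#' least 1 bp. No annotation ships with the package — gene counts depend
#' entirely on the annotation version supplied.
#'
#' @param segments Segment `GRanges`.
#' @param genes Gene `GRanges`.
#' @return Integer vector of gene counts per segment.
#' @export
count_genes <- function(segments, genes) {
  GenomicRanges::countOverlaps(segments, genes, minoverlap = 1L)
}

#' Segments as a report table
#'
#' Human-readable summary with 1-based inclusive printed coordinates, the
#' band list, the "start M – end M" location string, and the span in Mb.
#'
#' @param segments Segment `GRanges` (band-annotated or not).
#' @return Data frame: `chrom`, `bands`, `location`, `span_mb`, `direction`,
#'   `mean_log2`, `n_windows`.
#' @export
segments_table <- function(segments) {
  n <- length(segments)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(segments)),
    bands = vapply(as.list(segments$bands), paste, "", collapse = " "),
    location = sprintf("%.1f M-%.1f M",
                       (GenomicRanges::start(segments) - 1) / 1e6,
                       GenomicRanges::end(segments) / 1e6),
    span_mb = segment_span_mb(segments),
    direction = segments$direction,
    mean_log2 = segments$mean_log2,
    n_windows = segments$n_windows,
    row.names = NULL)
}

#' Write segments as BED6
#'
#' Name = space-joined band list (or "."), score = `1000 * |mean_log2|`
#' clipped to 1000, strand = ".". Coordinates are BED-native 0-based
#' half-open.
#'
#' @param segments Segment `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  if (length(segments) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- vapply(as.list(segments$bands), function(b) {
    if (length(b) == 0L) "." else paste(b, collapse = " ")
  }, "")
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(segments)),
               start = format(GenomicRanges::start(segments) - 1,
                              scientific = FALSE, trim = TRUE),
               end = format(GenomicRanges::end(segments),
                            scientific = FALSE, trim = TRUE),
               name = name,
               score = pmin(round(1000 * abs(segments$mean_log2)), 1000),
               strand = "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
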