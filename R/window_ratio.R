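#' Fixed-length window grid over a genome
#'
#' Partitions every chromosome into non-overlapping windows of `window_bp`
#' (default 40 kb), tiling it exactly: chromosome `c` of length `L` gets
#' `ceiling(L / window_bp)` windows, window `i` (0-based) spanning
#' `[i * window_bp, min((i + 1) * window_bp, L))`. The last window may be
#' short; it is kept and flagged rather than length-rescaled, since sample
#' and reference share the same short window and their ratio stays fair.
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param window_bp Window length in bp (default 40000).
#' @return An object of class `window_grid`.
#' @export
window_grid <- function(genome, window_bp = 40000L) {
  stopifnot(methods::is(genome, "Seqinfo"), window_bp >= 1)
  window_bp <- as.integer(window_bp)
  chrom <- GenomeInfoDb::seqnames(genome)
  len <- as.numeric(GenomeInfoDb::seqlengths(genome))
  n_win <- as.integer(ceiling(len / window_bp))
  structure(list(window_bp = window_bp, chrom = chrom, length = len,
                 n_windows = n_win,
                 offset = c(0L, cumsum(n_win))[seq_along(n_win)],
                 genome = genome),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d chromosome(s), %d bp windows, %d windows total\n",
              length(x$chrom), x$window_bp, sum(x$n_windows)))
  invisible(x)
}

total_windows <- function(grid) sum(grid$n_windows)

grids_identical <- function(a, b) {
  a$window_bp == b$window_bp && identical(a$chrom, b$chrom) &&
    identical(a$length, b$length)
}

#' Window coordinate table for a grid
#'
#' @param grid A [window_grid()].
#' @param chrom Optional chromosome name(s) to restrict to.
#' @return Data frame with `chrom`, `window` (0-based index within the
#'   chromosome), `start`, `end` (0-based half-open) and `short` (TRUE for a
#'   truncated terminal window).
#' @export
windows_df <- function(grid, chrom = NULL) {
  sel <- if (is.null(chrom)) seq_along(grid$chrom) else match(chrom, grid$chrom)
  if (anyNA(sel)) stop("chromosome(s) not in grid: ",
                       paste(chrom[is.na(sel)], collapse = ", "))
  out <- do.call(rbind, lapply(sel, function(i) {
    w <- seq_len(grid$n_windows[i]) - 1L
    start <- w * as.numeric(grid$window_bp)
    end <- pmin(start + grid$window_bp, grid$length[i])
    data.frame(chrom = grid$chrom[i], window = w, start = start, end = end,
               short = (end - start) < grid$window_bp)
  }))
  rownames(out) <- NULL
  out
}

#' Count mapped reads in windows
#'
#' Each read is assigned to exactly one window — the window containing its
#' 0-based start position. Counts are exact integers and sum to the number
#' of reads assigned.
#'
#' @param reads Mapped-read data frame (see [mapped_reads()]).
#' @param grid A [window_grid()] built from the same genome index.
#' @return An object of class `window_counts`: list with `grid`, `counts`
#'   (integer vector over all windows, chromosome-major) and `total_reads`.
#' @examples
#' gi <- genome_index("chr1", 80000)
#' grid <- window_grid(gi, 40000)
#' reads <- mapped_reads("chr1", c(0, 39999, 40000), genome = gi)
#' count_reads_in_windows(reads, grid)$counts  # 2 1
#' @export
count_reads_in_windows <- function(reads, grid) {
  stopifnot(inherits(grid, "window_grid"))
  ci <- match(reads$chrom, grid$chrom)
  if (anyNA(ci)) {
    stop("read(s) on chromosome(s) absent from the grid: ",
         paste(unique(reads$chrom[is.na(ci)]), collapse = ", "))
  }
  if (nrow(reads) > 0L && any(reads$start < 0L | reads$start >= grid$length[ci])) {
    stop("read start beyond chromosome end (upstream invariant breach)")
  }
  idx <- grid$offset[ci] + reads$start %/% grid$window_bp + 1L
  counts <- tabulate(idx, nbins = total_windows(grid))
  structure(list(grid = grid, counts = as.integer(counts),
                 total_reads = nrow(reads)),
            class = "window_counts")
}

#' Build window counts directly from a count vector
#'
#' @param counts Integer vector, one count per grid window (chromosome-major).
#' @param grid A [window_grid()].
#' @return A `window_counts` object.
#' @export
window_counts <- function(counts, grid) {
  stopifnot(inherits(grid, "window_grid"),
            length(counts) == total_windows(grid), all(counts >= 0))
  structure(list(grid = grid, counts = as.integer(counts),
                 total_reads = sum(counts)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d reads over %d windows (%d bp)\n",
              x$total_reads, total_windows(x$grid), x$grid$window_bp))
  invisible(x)
}

#' Per-window log2 sample/reference ratio track
#'
#' The core statistic: per window,
#' `log2((s + pseudocount) / (r' + pseudocount))` where `s` and `r'` are the
#' sample and (optionally library-size-scaled) reference counts. The log2
#' ratio is symmetric — +2 and −2 correspond to 4:1 and 1:4 relations, both
#' a fold change of 4 — which is what makes reciprocal dosage changes
#' directly comparable.
#'
#' With `normalize` (the default) reference counts are first scaled by
#' `sample$total_reads / reference$total_reads`, so unequal library sizes do
#' not masquerade as dosage. With `pseudocount = 0`, windows where either
#' count is zero get `NA` (an explicit undefined marker, rendered as a gap)
#' rather than an infinite ratio; a positive pseudocount is opt-in because
#' it shrinks exactly the extreme losses this analysis looks for.
#'
#' @param sample,reference `window_counts` on identical grids.
#' @param pseudocount Non-negative real added to both counts (default 0).
#' @param normalize Scale reference to the sample's library size (default
#'   TRUE).
#' @return An object of class `ratio_track`: list with `grid`, `log2_ratio`
#'   (numeric, `NA` = undefined), `pseudocount`, `normalized`.
#' @examples
#' gi <- genome_index("chr1", 80000)
#' g <- window_grid(gi, 40000)
#' s <- window_counts(c(4, 1), g)
#' r <- window_counts(c(1, 4), g)
#' log2_ratio_track(s, r)$log2_ratio  # +2 -2
#' @export
log2_ratio_track <- function(sample, reference, pseudocount = 0,
                             normalize = TRUE) {
  stopifnot(inherits(sample, "window_counts"),
            inherits(reference, "window_counts"), pseudocount >= 0)
  if (!grids_identical(sample$grid, reference$grid)) {
    stop("sample and reference window grids differ")
  }
  s <- as.numeric(sample$counts)
  r <- as.numeric(reference$counts)
  if (normalize) {
    if (reference$total_reads == 0L) stop("reference has no reads to scale")
    r <- r * (sample$total_reads / reference$total_reads)
  }
  ratio <- log2((s + pseudocount) / (r + pseudocount))
  if (pseudocount == 0) ratio[s == 0 | r == 0] <- NA_real_
  structure(list(grid = sample$grid, log2_ratio = ratio,
                 pseudocount = pseudocount, normalized = normalize),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  def <- sum(!is.na(x$log2_ratio))
  cat(sprintf(
    "ratio_track: %d windows (%d defined), pseudocount %g, normalized %s\n",
    length(x$log2_ratio), def, x$pseudocount, x$normalized))
  invisible(x)
}

#' Fold change of a log2 ratio
#'
#' `2^|x|`: the magnitude of the dosage relation regardless of direction
#' (both +2 and −2 give 4). Undefined (`NA`) in, undefined out.
#'
#' @param log2_value Numeric vector of log2 ratios.
#' @return Positive numeric vector.
#' @export
fold_change <- function(log2_value) 2^abs(log2_value)

#' Ratio track as a data frame
#'
#' One row per window with 0-based half-open coordinates, suitable for TSV
#' export; band annotation can be joined downstream.
#'
#' @param x A `ratio_track`.
#' @param ... Unused.
#' @return Data frame: `chrom`, `window`, `start`, `end`, `short`,
#'   `log2_ratio`.
#' @export
as.data.frame.ratio_track <- function(x, ...) {
  out <- windows_df(x$grid)
  out$log2_ratio <- x$log2_ratio
  out
}

#' @export
as.data.frame.window_counts <- function(x, ...) {
  out <- windows_df(x$grid)
  out$count <- x$counts
  out
}

#' Write a per-window track as bedGraph
#'
#' Four columns (chrom, 0-based start, end, value); undefined windows are
#' omitted, leaving visible gaps in a browser.
#'
#' @param x A `ratio_track` or `window_counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  df <- as.data.frame(x)
  value <- if (!is.null(df$log2_ratio)) df$log2_ratio else df$count
  keep <- !is.na(value)
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE),
               value)[keep, ],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sum window counts per chromosome
#'
#' @param x A `window_counts`.
#' @return Named numeric vector of read counts, one per chromosome, in
#'   genome-index order.
#' @export
chrom_read_counts <- function(x) {
  stopifnot(inherits(x, "window_counts"))
  grp <- rep(seq_along(x$grid$chrom), x$grid$n_windows)
  counts <- vapply(seq_along(x$grid$chrom),
                   function(i) sum(x$counts[grp == i]), numeric(1))
  stats::setNames(counts, x$grid$chrom)
}
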