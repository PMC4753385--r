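#' Sample an in-silico reference read set from the genome
#'
#' Low-coverage tumor pools are compared against a simulated normal: reads
#' drawn uniformly at random from the reference sequence, with replacement.
#' Each read start is uniform over all valid start positions genome-wide —
#' a chromosome is chosen with probability proportional to its number of
#' valid starts (length − read_length + 1), and the position uniformly
#' within it — so expected per-window counts are flat and per-chromosome
#' counts are proportional to chromosome length.
#'
#' With `exclude_ambiguous`, reads whose `read_length` window overlaps a run
#' of `N` bases are rejected and redrawn.
#'
#' @param seqs A [Biostrings::DNAStringSet] of genome sequences (see
#'   [load_genome_sequences()]).
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in bp (default 75, typical of the short-read
#'   instruments this pipeline targets). Must not exceed the shortest
#'   chromosome.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param exclude_ambiguous Reject reads overlapping `N` runs (default TRUE).
#' @return A mapped-read data frame (see [mapped_reads()]), with attribute
#'   `read_length`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 250), collapse = "")))
#' ref <- sample_reference_reads(seqs, n_reads = 5, read_length = 100, seed = 1)
#' range(ref$start)  # all starts in [0, 900]
#' @export
sample_reference_reads <- function(seqs, n_reads, read_length = 75L,
                                   seed = NULL, exclude_ambiguous = TRUE) {
  stopifnot(methods::is(seqs, "DNAStringSet"), n_reads >= 1, read_length >= 1)
  genome <- genome_index(names(seqs), Biostrings::width(seqs))
  valid <- Biostrings::width(seqs) - as.integer(read_length) + 1L
  if (all(valid <= 0L)) {
    stop("no valid start positions: read_length ", read_length,
         " exceeds every chromosome length")
  }
  if (any(valid <= 0L)) {
    stop("read_length ", read_length, " exceeds chromosome(s): ",
         paste(names(seqs)[valid <= 0L], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_runs <- find_n_runs(seqs)
  draw <- function(k) {
    ci <- sample.int(length(seqs), k, replace = TRUE, prob = valid)
    pos <- floor(stats::runif(k) * valid[ci])  # 0-based, in [0, valid-1]
    data.frame(ci = ci, pos = as.integer(pos))
  }
  out <- draw(n_reads)
  if (exclude_ambiguous && any(lengths(n_runs) > 0L)) {
    for (iter in seq_len(1000L)) {
      bad <- overlaps_n_run(out, n_runs, read_length)
      if (!any(bad)) break
      if (iter == 1000L) {
        stop("unable to draw N-free reads after 1000 rounds of rejection; ",
             "is the genome mostly ambiguous bases?")
      }
      out[bad, ] <- draw(sum(bad))
    }
  }
  reads <- mapped_reads(names(seqs)[out$ci], out$pos,
                        read_id = sprintf("ref_%07d", seq_len(n_reads)),
                        genome = genome)
  attr(reads, "read_length") <- as.integer(read_length)
  reads
}

# per-chromosome IRanges of N runs (1-based)
find_n_runs <- function(seqs) {
  lapply(seq_along(seqs), function(i) {
    IRanges::reduce(as(Biostrings::matchPattern("N", seqs[[i]]), "IRanges"))
  })
}

overlaps_n_run <- function(draws, n_runs, read_length) {
  bad <- logical(nrow(draws))
  for (i in unique(draws$ci)) {
    runs <- n_runs[[i]]
    if (length(runs) == 0L) next
    sel <- draws$ci == i
    q <- IRanges::IRanges(start = draws$pos[sel] + 1L, width = read_length)
    bad[sel] <- IRanges::overlapsAny(q, runs)
  }
  bad
}

#' Write reads as FASTQ with their genomic sequence
#'
#' Emits each read's sequence (taken from the genome at its sampled
#' position) with a constant quality string of `I` (Phred 40), suitable for
#' feeding to an external mapper when one wants mappability losses to apply
#' to the in-silico reference as well.
#'
#' @param reads Mapped-read data frame carrying a `read_length` attribute
#'   (or pass `read_length` explicitly).
#' @param seqs The genome [Biostrings::DNAStringSet] the reads were drawn from.
#' @param path Output FASTQ path.
#' @param read_length Read length in bp; defaults to the reads' attribute.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, seqs, path,
                              read_length = attr(reads, "read_length")) {
  if (is.null(read_length)) stop("read_length is required")
  idx <- match(reads$chrom, names(seqs))
  views <- Biostrings::DNAStringSet(lapply(seq_len(nrow(reads)), function(i) {
    Biostrings::subseq(seqs[[idx[i]]], start = reads$start[i] + 1L,
                       width = read_length)
  }))
  names(views) <- reads$read_id
  qual <- Biostrings::PhredQuality(rep(strrep("I", read_length), length(views)))
  Biostrings::writeXStringSet(views, path, format = "fastq", qualities = qual)
  invisible(path)
}
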