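# Shared fixture builders and independent brute-force oracles.

toy_seqinfo <- function(lengths, names = paste0("chr", seq_along(lengths))) {
  genome_index(names, lengths)
}

# a ratio_track built directly from a vector of log2 values (internal repr)
manual_track <- function(vals, grid) {
  stopifnot(length(vals) == sum(grid$n_windows))
  structure(list(grid = grid, log2_ratio = as.numeric(vals),
                 pseudocount = 0, normalized = FALSE),
            class = "ratio_track")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_fastq <- function(path, seqs, quals) {
  stopifnot(length(seqs) == length(quals))
  lines <- as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", quals))
  writeLines(lines, path)
  path
}

# minimal SAM writer: records = data.frame(qname, flag, chrom, pos1, mapq, nh)
# nh = NA omits the NH tag
write_sam <- function(path, genome, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", GenomeInfoDb::seqnames(genome),
                   GenomeInfoDb::seqlengths(genome)))
  seq10 <- strrep("A", 10)
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    line <- sprintf("%s\t%d\t%s\t%d\t%d\t10M\t*\t0\t0\t%s\t%s",
                    r$qname, r$flag, r$chrom, r$pos1, r$mapq, seq10,
                    strrep("I", 10))
    if (!is.na(r$nh)) line <- paste0(line, sprintf("\tNH:i:%d", r$nh))
    line
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# ---- independent oracles -------------------------------------------------

# brute-force window counting: one read at a time
oracle_window_counts <- function(reads, grid) {
  counts <- integer(sum(grid$n_windows))
  for (i in seq_len(nrow(reads))) {
    ci <- match(reads$chrom[i], grid$chrom)
    w <- reads$start[i] %/% grid$window_bp
    counts[grid$offset[ci] + w + 1L] <- counts[grid$offset[ci] + w + 1L] + 1L
  }
  counts
}

# brute-force Shannon entropy via table()
oracle_entropy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# brute-force DUST: enumerate every overlapping triplet with substring()
oracle_dust <- function(seq) {
  L <- nchar(seq)
  if (L < 3) return(0)
  tri <- vapply(seq_len(L - 2), function(i) substring(seq, i, i + 2), "")
  tri <- tri[!grepl("N", tri, fixed = TRUE)]
  m <- length(tri)
  if (m < 2) return(0)
  ct <- table(tri)
  100 * sum(ct * (ct - 1) / 2) / (m * (m - 1) / 2)
}

# per-base membership intersection on one chromosome of length L:
# seg_lists = list of data.frames with start0/end0 (one direction already)
oracle_intersect_base <- function(seg_lists, L, min_pools = length(seg_lists)) {
  hit <- integer(L)
  for (segs in seg_lists) {
    mem <- logical(L)
    for (i in seq_len(nrow(segs))) {
      s <- segs$start0[i]; e <- segs$end0[i]
      if (e > s) mem[(s + 1):e] <- TRUE
    }
    hit <- hit + mem
  }
  shared <- hit >= min_pools
  if (!any(shared)) {
    return(data.frame(start0 = numeric(0), end0 = numeric(0)))
  }
  r <- rle(shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start0 = starts[r$values], end0 = ends[r$values])
}

# wrap plain intervals as a segment GRanges for intersect_segments()
as_segments <- function(df, genome, chrom = "chr1", direction = "loss") {
  if (nrow(df) == 0) {
    gr <- GenomicRanges::GRanges(seqinfo = genome)
    gr$direction <- character(0)
    gr$n_windows <- integer(0)
    gr$mean_log2 <- numeric(0)
    gr$bands <- IRanges::CharacterList()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(df$start0 + 1, df$end0),
                               seqinfo = genome)
  gr$direction <- direction
  gr$n_windows <- NA_integer_
  gr$mean_log2 <- if (direction == "loss") -1 else 1
  gr$bands <- IRanges::CharacterList(rep(list(character(0)), nrow(df)))
  gr
}

segments_to_df <- function(gr) {
  data.frame(start0 = GenomicRanges::start(gr) - 1,
             end0 = GenomicRanges::end(gr))
}
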