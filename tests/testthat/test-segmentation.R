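test_that("a flat track calls nothing; a clean run calls one segment", {
  gi <- toy_seqinfo(400000, "chr1")
  grid <- window_grid(gi, 40000)
  expect_length(call_segments(manual_track(rep(0, 10), grid)), 0L)
  segs <- call_segments(manual_track(rep(-1.2, 10), grid),
                        call_config(min_consecutive_windows = 3))
  expect_length(segs, 1L)
  expect_equal(segs$direction, "loss")
  expect_equal(segs$n_windows, 10L)
  expect_equal(GenomicRanges::start(segs), 1L)
  expect_equal(GenomicRanges::end(segs), 400000L)
  expect_equal(segs$mean_log2, -1.2)
})

test_that("gap bridging merges runs up to max_gap_windows only", {
  gi <- toy_seqinfo(200000, "chr1")
  grid <- window_grid(gi, 40000)
  vals <- c(-1, -1, 0, -1, -1)
  merged <- call_segments(manual_track(vals, grid),
                          call_config(min_consecutive_windows = 2,
                                      max_gap_windows = 1))
  expect_length(merged, 1L)
  expect_equal(merged$n_windows, 5L)
  expect_equal(merged$mean_log2, mean(vals))
  split <- call_segments(manual_track(vals, grid),
                         call_config(min_consecutive_windows = 2,
                                     max_gap_windows = 0))
  expect_length(split, 2L)
  expect_equal(GenomicRanges::start(split), c(1L, 120001L))
  # exhaustive check of the same 5-window vector against run enumeration:
  # qualifying indices 1,2,4,5; gap of one window sits between them
  expect_equal(split$n_windows, c(2L, 2L))
})

test_that("undefined windows neither qualify nor hard-break a bridged run", {
  gi <- toy_seqinfo(280000, "chr1")
  grid <- window_grid(gi, 40000)
  vals <- c(-1, NA, -1, -1, NA, NA, -1)
  cfg <- call_config(min_consecutive_windows = 3, max_gap_windows = 1)
  segs <- call_segments(manual_track(vals, grid), cfg)
  # NA at 2 bridges; the double-NA at 5-6 exceeds max_gap 1 and splits,
  # leaving a 4-window left run and an unreportable single right window
  expect_length(segs, 1L)
  expect_equal(segs$n_windows, 4L)
  expect_equal(segs$mean_log2, -1)
})

test_that("gains and losses are called independently with correct signs", {
  gi <- toy_seqinfo(480000, "chr1")
  grid <- window_grid(gi, 40000)
  vals <- c(-1, -1, -1, 0, 0, 0.8, 0.8, 0.8, 0, 0, 0, 0)
  segs <- call_segments(manual_track(vals, grid))
  expect_equal(segs$direction, c("loss", "gain"))
  expect_true(all(sign(segs$mean_log2) == ifelse(segs$direction == "loss",
                                                 -1, 1)))
  # segments from one track never overlap and come out sorted
  expect_false(any(IRanges::overlapsAny(segs, drop.self = TRUE)))
  expect_equal(segs, BiocGenerics::sort(segs))
})

test_that("min_consecutive_windows suppresses short runs", {
  gi <- toy_seqinfo(400000, "chr1")
  grid <- window_grid(gi, 40000)
  vals <- c(-1, -1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_length(call_segments(manual_track(vals, grid),
                              call_config(min_consecutive_windows = 3)), 0L)
  expect_length(call_segments(manual_track(vals, grid),
                              call_config(min_consecutive_windows = 2)), 1L)
})

test_that("intersection of identical lists is idempotent; overlap is trimmed", {
  gi <- toy_seqinfo(1e6, "chr1")
  a <- as_segments(data.frame(start0 = 0, end0 = 100000), gi)
  same <- intersect_segments(list(a, a), "loss")
  expect_equal(segments_to_df(same), data.frame(start0 = 0, end0 = 100000))
  b <- as_segments(data.frame(start0 = 40000, end0 = 200000), gi)
  trimmed <- intersect_segments(list(a, b), "loss")
  expect_equal(segments_to_df(trimmed),
               data.frame(start0 = 40000, end0 = 100000))
})

test_that("intersection agrees with per-base membership on random fixtures", {
  gi <- toy_seqinfo(1e6, "chr1")
  set.seed(50)
  for (i in 1:100) {
    n_pools <- sample(2:3, 1)
    lists <- lapply(seq_len(n_pools), function(p) {
      k <- sample(0:4, 1)
      if (k == 0) return(data.frame(start0 = numeric(0), end0 = numeric(0)))
      s <- sort(sample(seq(0, 9.5e5, by = 1000), k))
      w <- sample(seq(1000, 50000, by = 1000), k, replace = TRUE)
      # keep them disjoint the way call_segments guarantees
      e <- pmin(s + w, c(s[-1], 1e6))
      keep <- e > s
      data.frame(start0 = s[keep], end0 = e[keep])
    })
    got <- segments_to_df(intersect_segments(
      lapply(lists, as_segments, genome = gi), "loss"))
    want <- oracle_intersect_base(lists, 1e6)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("intersection is commutative and associative over its inputs", {
  gi <- toy_seqinfo(1e6, "chr1")
  set.seed(51)
  mk <- function() {
    s <- sort(sample(seq(0, 9e5, by = 5000), 3))
    as_segments(data.frame(start0 = s, end0 = s + 40000), gi)
  }
  x <- mk(); y <- mk(); z <- mk()
  perms <- list(list(x, y, z), list(z, x, y), list(y, z, x))
  results <- lapply(perms, function(p) segments_to_df(
    intersect_segments(p, "loss")))
  expect_equal(results[[1]], results[[2]])
  expect_equal(results[[1]], results[[3]])
  # fold-left pairwise equals the 3-way intersection
  xy <- intersect_segments(list(x, y), "loss")
  expect_equal(segments_to_df(intersect_segments(list(xy, z), "loss")),
               results[[1]])
})

test_that("only the direction asked for is intersected", {
  gi <- toy_seqinfo(1e6, "chr1")
  loss <- as_segments(data.frame(start0 = 0, end0 = 100000), gi, direction = "loss")
  gain <- as_segments(data.frame(start0 = 0, end0 = 100000), gi, direction = "gain")
  expect_length(intersect_segments(list(loss, gain), "loss"), 0L)
  expect_length(intersect_segments(list(gain, gain), "gain"), 1L)
})

test_that("band annotation lists overlapping bands in genomic order", {
  gi <- toy_seqinfo(200e6, "chr5")
  bands <- cytobands(data.frame(
    chrom = "chr5",
    start = c(0, 68e6, 72e6, 80e6),
    end = c(68e6, 72e6, 80e6, 200e6),
    band = c("q13.1", "q13.2", "q13.3", "q14"),
    stain = c("gneg", "gpos50", "gneg", "gpos25")), gi)
  seg <- as_segments(data.frame(start0 = 68.5e6, end0 = 71e6), gi,
                     chrom = "chr5")
  ann <- annotate_bands(seg, bands)
  expect_equal(unlist(ann$bands), "q13.2")
  wide <- as_segments(data.frame(start0 = 67.9e6, end0 = 81e6), gi,
                      chrom = "chr5")
  expect_equal(unlist(annotate_bands(wide, bands)$bands),
               c("q13.1", "q13.2", "q13.3", "q14"))
})

test_that("a 1-bp touch at a band's last base still annotates (overlap >= 1)", {
  gi <- toy_seqinfo(1e6, "chr1")
  bands <- cytobands(data.frame(chrom = "chr1", start = c(0, 500000),
                                end = c(500000, 1e6),
                                band = c("p11", "q11"),
                                stain = c("acen", "acen")), gi)
  # segment [499999, 600000): overlaps p11 only at its final base
  seg <- as_segments(data.frame(start0 = 499999, end0 = 600000), gi)
  expect_equal(unlist(annotate_bands(seg, bands)$bands), c("p11", "q11"))
})

test_that("segments on band-less chromosomes warn and stay empty", {
  gi <- toy_seqinfo(c(1e6, 1e6), c("chr1", "chr2"))
  bands <- cytobands(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                band = "p11", stain = "gneg"), gi)
  seg <- as_segments(data.frame(start0 = 0, end0 = 1000), gi, chrom = "chr2")
  expect_warning(ann <- annotate_bands(seg, bands), "chr2")
  expect_equal(lengths(ann$bands), 0L, ignore_attr = TRUE)
})

test_that("segment spans in Mb reproduce reported interval arithmetic", {
  gi <- toy_seqinfo(250e6, "chr0")
  segs <- as_segments(data.frame(start0 = c(68.5e6, 20e6, 28.4e6),
                                 end0 = c(71e6, 22.5e6, 33.4e6)), gi,
                      chrom = "chr0")
  expect_equal(segment_span_mb(segs), c(2.5, 2.5, 5))
})

test_that("segment table and BED export carry bands, spans and clipped scores", {
  gi <- toy_seqinfo(1e6, "chr1")
  seg <- as_segments(data.frame(start0 = 100000, end0 = 300000), gi)
  seg$mean_log2 <- -2.4
  seg$bands <- IRanges::CharacterList(list(c("p12", "p11")))
  tab <- segments_table(seg)
  expect_equal(tab$bands, "p12 p11")
  expect_equal(tab$span_mb, 0.2)
  expect_equal(tab$location, "0.1 M-0.3 M")
  bed <- tempfile(fileext = ".bed")
  write_segments_bed(seg, bed)
  row <- read.delim(bed, header = FALSE)
  expect_equal(row$V2, 100000L)            # BED stays 0-based
  expect_equal(row$V5, 1000)               # 1000*|mean_log2| clipped
})

test_that("gene counting is a plain overlap count against a supplied annotation", {
  gi <- toy_seqinfo(1e6, "chr1")
  seg <- as_segments(data.frame(start0 = c(0, 500000),
                                end0 = c(100000, 600000)), gi)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10, 50000, 99999, 700000),
                     width = c(100, 1000, 5000, 100)), seqinfo = gi)
  expect_equal(count_genes(seg, genes), c(3L, 0L))
})
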