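test_that("toy genome bands tile every chromosome exactly", {
  toy <- make_toy_genome(c(400000, 250000), seed = 60)
  for (ch in c("chr1", "chr2")) {
    b <- toy$bands[GenomicRanges::seqnames(toy$bands) == ch]
    expect_gte(length(b), 3L)
    expect_lte(length(b), 8L)
    expect_equal(GenomicRanges::start(b)[1], 1L)
    expect_equal(GenomicRanges::end(b)[length(b)],
                 unname(GenomeInfoDb::seqlengths(toy$genome)[ch]))
    # contiguous: each band starts where the previous one ended
    if (length(b) > 1) {
      expect_equal(GenomicRanges::start(b)[-1],
                   GenomicRanges::end(b)[-length(b)] + 1L)
    }
    expect_equal(sum(b$stain == "acen"), 2L)
    expect_setequal(b$band[b$stain == "acen"], c("p11", "q11"))
  }
})

test_that("same seed reproduces identical FASTA bytes and band tables", {
  d1 <- file.path(tempdir(), "toyA"); d2 <- file.path(tempdir(), "toyB")
  t1 <- make_toy_genome(c(60000, 40000), seed = 61, dir = d1)
  t2 <- make_toy_genome(c(60000, 40000), seed = 61, dir = d2)
  expect_identical(readBin(t1$fasta, "raw", file.size(t1$fasta)),
                   readBin(t2$fasta, "raw", file.size(t2$fasta)))
  expect_identical(readLines(t1$cytoband_path), readLines(t2$cytoband_path))
})

test_that("generated band tables always pass the cytoband validator", {
  for (seed in 1:100) {
    toy <- make_toy_genome(c(50000), seed = seed)
    tsv <- tempfile()
    write_cytobands(toy$bands, tsv)
    reloaded <- load_cytobands(tsv, toy$genome)  # validator; errors would fail
    expect_equal(length(reloaded), length(toy$bands))
    expect_equal(reloaded$band, toy$bands$band)
  }
})

test_that("a neutral pool is indistinguishable from uniform sampling", {
  toy <- make_toy_genome(4e6, seed = 62)
  pool <- simulate_pool_reads(toy$seqs, pool_size = 4,
                              per_member_reads = 50000, seed = 63)
  expect_equal(nrow(pool), 200000L)
  grid <- window_grid(toy$genome, 40000)
  counts <- count_reads_in_windows(pool, grid)$counts
  v <- c(rep(40000, 99), 40000 - 74)       # valid-start support per window
  expect_gt(stats::chisq.test(counts, p = v / sum(v))$p.value, 0.001)
})

test_that("every simulated read satisfies the coordinate invariants", {
  toy <- make_toy_genome(c(120000, 80000), seed = 64)
  pool <- simulate_pool_reads(toy$seqs, 3, per_member_reads = 2000, seed = 65,
                              cnvs = list(cnv_spec("chr2", 0, 40000, 0, 1:3)))
  lens <- GenomeInfoDb::seqlengths(toy$genome)[pool$chrom]
  expect_true(all(pool$start >= 0 & pool$start < lens))
  # homozygous deletion: no member samples a start inside it
  expect_false(any(pool$chrom == "chr2" & pool$start < 40000))
})

test_that("carrier fraction sets the pooled dosage of an engineered deletion", {
  toy <- make_toy_genome(c(4800000, 3200000), seed = 66)
  grid <- window_grid(toy$genome, 40000)
  ref <- sample_reference_reads(toy$seqs, 40000, seed = 67)
  rc <- count_reads_in_windows(ref, grid)
  del_sel <- {
    df <- windows_df(grid)
    df$chrom == "chr1" & df$start >= 1600000 & df$end <= 2000000
  }
  # 2 of 4 carriers: expected dosage 0.75, log2 ~ -0.415
  pool <- simulate_pool_reads(toy$seqs, 4, per_member_reads = 10000,
                              seed = 68,
                              cnvs = list(cnv_spec("chr1", 1600000, 2000000,
                                                   1, c(1, 3))))
  tr <- log2_ratio_track(count_reads_in_windows(pool, grid), rc)
  expect_equal(mean(tr$log2_ratio[del_sel]), log2(0.75), tolerance = 0.15)
})

test_that("expected window counts scale linearly with summed pool copy number", {
  toy <- make_toy_genome(800000, seed = 69)
  # dosage steps 0.5x, 1x, 1.5x, 2x across distinct window blocks
  cnvs <- list(cnv_spec("chr1", 0, 160000, 1, 1:4),
               cnv_spec("chr1", 320000, 480000, 3, 1:4),
               cnv_spec("chr1", 640000, 800000, 4, 1:4))
  pool <- simulate_pool_reads(toy$seqs, 4, per_member_reads = 50000,
                              seed = 70, cnvs = cnvs)
  grid <- window_grid(toy$genome, 40000)
  counts <- count_reads_in_windows(pool, grid)$counts
  dosage <- rep(2, 20)
  dosage[1:4] <- 1; dosage[9:12] <- 3; dosage[17:20] <- 4
  fit <- stats::lm(counts ~ dosage)
  # slope within 5% of theory: total_reads / sum(dosage) per dosage unit
  theory <- 200000 / sum(dosage)
  expect_lt(abs(unname(coef(fit)[2]) - theory) / theory, 0.05)
  expect_lt(abs(unname(coef(fit)[1])), 0.05 * theory * 2)
})

test_that("overlapping CNVs for one carrier are a hard error", {
  toy <- make_toy_genome(200000, seed = 71)
  cnvs <- list(cnv_spec("chr1", 0, 100000, 1, 1:2),
               cnv_spec("chr1", 50000, 150000, 3, 2))
  expect_error(simulate_pool_reads(toy$seqs, 2, 100, seed = 72, cnvs = cnvs),
               "overlapping CNV")
  # disjoint carriers are fine even with overlapping intervals
  ok <- list(cnv_spec("chr1", 0, 100000, 1, 1),
             cnv_spec("chr1", 50000, 150000, 3, 2))
  expect_silent(simulate_pool_reads(toy$seqs, 2, 100, seed = 73, cnvs = ok))
})

test_that("cnv_spec validates its interval and carriers", {
  expect_error(cnv_spec("chr1", 100, 100, 1, 1))
  expect_error(cnv_spec("chr1", 0, 100, 9, 1))
  expect_error(cnv_spec("chr1", 0, 100, 1, integer(0)))
  toy <- make_toy_genome(50000, seed = 74)
  expect_error(simulate_pool_reads(toy$seqs, 2, 10,
                                   cnvs = list(cnv_spec("chr1", 0, 60000, 1, 1))),
               "beyond chromosome end")
  expect_error(simulate_pool_reads(toy$seqs, 2, 10,
                                   cnvs = list(cnv_spec("chr1", 0, 100, 1, 3))),
               "pool_size")
})
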