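# Fixed rendering fixtures shared by the chromdraw tests and the script
# that (re)generates the frozen golden files (scratch use only).

golden_chrom_fixture <- function() {
  genome <- genome_index("chr1", 400000)
  bands <- cytobands(data.frame(
    chrom = "chr1",
    start = c(0, 160000, 200000, 240000),
    end = c(160000, 200000, 240000, 400000),
    band = c("p12", "p11", "q11", "q12"),
    stain = c("gpos50", "acen", "acen", "gneg")), genome)
  grid <- window_grid(genome, 40000)
  track <- manual_track(c(0.25, -1, -2, NA, 0, 1, 2.5, -0.4, 0.8, -1.6),
                        grid)
  segments <- as_segments(data.frame(start0 = 40000, end0 = 120000), genome)
  segments$bands <- IRanges::CharacterList(list("p12"))
  config <- render_config(bp_per_pixel = 2000)
  list(genome = genome, bands = bands, track = track, segments = segments,
       config = config)
}

golden_panorama_fixture <- function() {
  genome <- genome_index(c("chr1", "chr2"), c(400000, 240000))
  bands <- cytobands(data.frame(
    chrom = c(rep("chr1", 4), rep("chr2", 3)),
    start = c(0, 160000, 200000, 240000, 0, 100000, 140000),
    end = c(160000, 200000, 240000, 400000, 100000, 140000, 240000),
    band = c("p12", "p11", "q11", "q12", "p11", "q11", "q12"),
    stain = c("gpos50", "acen", "acen", "gneg", "acen", "acen", "gpos25")),
    genome)
  grid <- window_grid(genome, 40000)
  track <- manual_track(round(seq(-2, 2, length.out = 16), 3), grid)
  config <- render_config(bp_per_pixel = 2000)
  list(genome = genome, bands = bands, track = track, config = config)
}
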