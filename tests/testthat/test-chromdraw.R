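# structural queries work on the SVG via xml2; every element carries a
# machine-readable id (band:<chrom>:<name>, win:<chrom>:<index>, ...)
svg_xml <- function(doc) {
  path <- tempfile(fileext = ".svg")
  write_svg(doc, path)
  xml2::read_xml(path)
}

ids_with_prefix <- function(x, prefix) {
  nodes <- xml2::xml_find_all(x, sprintf("//*[starts-with(@id, '%s')]", prefix))
  xml2::xml_attr(nodes, "id")
}

attr_by_id <- function(x, id, attr) {
  node <- xml2::xml_find_first(x, sprintf("//*[@id='%s']", id))
  as.numeric(xml2::xml_attr(node, attr))
}

test_that("chromosome rendering matches the frozen golden file byte for byte", {
  fx <- golden_chrom_fixture()
  doc <- render_chromosome("chr1", fx$genome, fx$bands, fx$track,
                           fx$segments, fx$config)
  out <- tempfile(fileext = ".svg")
  write_svg(doc, out)
  golden <- test_path("golden", "chromosome.svg")
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(golden, "raw", file.size(golden)))
})

test_that("panorama rendering matches its frozen golden file", {
  fx <- golden_panorama_fixture()
  doc <- render_genome_panorama(fx$genome, fx$bands, fx$track,
                                config = fx$config)
  out <- tempfile(fileext = ".svg")
  write_svg(doc, out)
  golden <- test_path("golden", "panorama.svg")
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(golden, "raw", file.size(golden)))
})

test_that("document contains one identified element per band and per window", {
  fx <- golden_chrom_fixture()
  x <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands, fx$track,
                                 fx$segments, fx$config))
  expect_length(ids_with_prefix(x, "band:chr1:"), length(fx$bands))
  expect_length(ids_with_prefix(x, "win:chr1:"), 10L)
  expect_length(ids_with_prefix(x, "seg:chr1:"), 1L)
  # a zero track still draws one (flat) bar element per window
  zero <- manual_track(rep(0, 10), fx$track$grid)
  x0 <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands, zero,
                                  config = fx$config))
  expect_length(ids_with_prefix(x0, "win:chr1:"), 10L)
  expect_equal(attr_by_id(x0, "win:chr1:0", "width"), 0)
})

test_that("a window at the clip value draws exactly one maximal loss bar", {
  fx <- golden_chrom_fixture()
  vals <- rep(0, 10); vals[3] <- -2
  x <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands,
                                 manual_track(vals, fx$track$grid),
                                 config = fx$config))
  widths <- vapply(0:9, function(i)
    attr_by_id(x, sprintf("win:chr1:%d", i), "width"), numeric(1))
  expect_equal(sum(widths > 0), 1L)
  expect_equal(widths[3], 44)              # full track half-width
  node <- xml2::xml_find_first(x, "//*[@id='win:chr1:2']")
  expect_equal(xml2::xml_attr(node, "fill"), fx$config$loss_color)
})

test_that("band pixel extents track genomic extents within half a pixel", {
  fx <- golden_chrom_fixture()
  x <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands, fx$track,
                                 fx$segments, fx$config))
  # non-acen bands are rects with height = (end-start)/bp_per_pixel
  for (nm in c("p12", "q12")) {
    b <- fx$bands[fx$bands$band == nm]
    want <- (GenomicRanges::end(b) - GenomicRanges::start(b) + 1) /
      fx$config$bp_per_pixel
    expect_lt(abs(attr_by_id(x, paste0("band:chr1:", nm), "height") - want),
              0.5)
  }
})

test_that("bar length is monotone in |log2| and clipped beyond the maximum", {
  fx <- golden_chrom_fixture()
  vals <- c(-3, -2, -1, -0.5, 0, 0.25, 1, 1.5, 2, 3)
  x <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands,
                                 manual_track(vals, fx$track$grid),
                                 config = fx$config))
  widths <- vapply(0:9, function(i)
    attr_by_id(x, sprintf("win:chr1:%d", i), "width"), numeric(1))
  ord <- order(abs(vals))
  expect_true(all(diff(widths[ord]) >= 0))
  expect_equal(widths[1], widths[9])       # both at/beyond the clip
})

test_that("undefined windows draw in the undefined color, not as bars", {
  fx <- golden_chrom_fixture()
  x <- svg_xml(render_chromosome("chr1", fx$genome, fx$bands, fx$track,
                                 config = fx$config))
  node <- xml2::xml_find_first(x, "//*[@id='win:chr1:3']")  # NA window
  expect_equal(xml2::xml_attr(node, "fill"), fx$config$undefined_color)
})

test_that("panorama lays out one panel per chromosome at a common scale", {
  fx <- golden_panorama_fixture()
  x <- svg_xml(render_genome_panorama(fx$genome, fx$bands, fx$track,
                                      config = fx$config))
  expect_length(ids_with_prefix(x, "rod:"), 2L)
  h1 <- attr_by_id(x, "rod:chr1", "height")
  h2 <- attr_by_id(x, "rod:chr2", "height")
  expect_equal(h1 / h2, 400000 / 240000, tolerance = 0.01)
  expect_length(ids_with_prefix(x, "win:chr1:"), 10L)
  expect_length(ids_with_prefix(x, "win:chr2:"), 6L)
})

test_that("a chromosome missing from the track renders bare with a warning", {
  fx <- golden_panorama_fixture()
  part_genome <- genome_index("chr1", 400000)
  part_grid <- window_grid(part_genome, 40000)
  part_track <- manual_track(rep(0.5, 10), part_grid)
  expect_warning(
    doc <- render_genome_panorama(fx$genome, fx$bands, part_track,
                                  config = fx$config),
    "chr2")
  x <- svg_xml(doc)
  expect_length(ids_with_prefix(x, "win:chr2:"), 0L)
  expect_length(ids_with_prefix(x, "rod:chr2"), 1L)
})

test_that("rendering rejects mismatched inputs and incomplete palettes", {
  fx <- golden_chrom_fixture()
  expect_error(render_chromosome("chr9", fx$genome, fx$bands, fx$track,
                                 config = fx$config), "chr9")
  other <- genome_index("chrZ", 100000)
  zt <- manual_track(rep(0, 3), window_grid(other, 40000))
  expect_error(render_chromosome("chr1", fx$genome, fx$bands, zt,
                                 config = fx$config), "does not cover")
  expect_error(render_config(stain_palette = c(gneg = "#fff")), "missing")
})
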