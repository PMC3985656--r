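test_that("Tel23 sequence has the four canonical G-tracts", {
  tr <- gTracts(tel23)
  expect_equal(nrow(tr), 4)
  expect_equal(tr$start, c(3, 9, 15, 21))
  expect_equal(tr$end, c(5, 11, 17, 23))
  expect_true(all(tr$length == 3))
  expect_equal(loopResidues(tel23), c(6, 7, 8, 12, 13, 14, 18, 19, 20))
  expect_error(G4Sequence("TAGXG"), "only A, C, G, T")
})

test_that("peak list lines parse to the expected fields", {
  tmp <- withr::local_tempfile(fileext = ".list")
  writeLines(c("# comment", "G3H1-G21H8 200 1.35e5 na", "",
               "G9H1'-G9H8 100 2e4 k"), tmp)
  pt <- readPeakList(tmp)
  pk <- peaks(pt)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$res1[1], 3)
  expect_equal(pk$atom1[1], "H1")
  expect_equal(pk$res2[1], 21)
  expect_equal(pk$atom2[1], "H8")
  expect_equal(pk$mixing_time[1], 200)
  expect_equal(pk$intensity[1], 1.35e5)
  expect_equal(pk$condition[1], "na")
  expect_equal(pk$atom1[2], "H1'")  # H1' disambiguated from H1
})

test_that("malformed lines are reported with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".list")
  writeLines(c("G3H1-G21H8 200 1e5 na", "G3Q1-G21H8 200 1e5 na"), tmp)
  expect_error(readPeakList(tmp), "line 2.*G3Q1")
  writeLines("G3H1-G21H8 200 -5 na", tmp)
  expect_error(readPeakList(tmp), "negative intensity")
})

test_that("empty peak list warns and yields an empty table", {
  tmp <- withr::local_tempfile(fileext = ".list")
  writeLines(character(), tmp)
  expect_warning(pt <- readPeakList(tmp), "empty")
  expect_equal(length(pt), 0)
})

test_that("pair storage is canonical regardless of read order", {
  tmp <- withr::local_tempfile(fileext = ".list")
  writeLines("G21H8-G3H1 200 1e5 na", tmp)
  a <- peaks(readPeakList(tmp))
  writeLines("G3H1-G21H8 200 1e5 na", tmp)
  b <- peaks(readPeakList(tmp))
  expect_equal(a, b)
})

test_that("write/read round trip is lossless", {
  pt <- genNoesyPeaks(topology = "hybrid-I", seed = 11, noise_sd = 0.02)
  tmp <- withr::local_tempfile(fileext = ".list")
  writePeakList(pt, tmp)
  back <- readPeakList(tmp)
  a <- peaks(pt); b <- peaks(back)
  ord <- function(d) {
    d <- d[order(d$res1, d$atom1, d$res2, d$atom2, d$mixing_time), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(b), ord(a), tolerance = 1e-9)
})

test_that("duplicate peak rows are rejected", {
  pk <- data.frame(res1 = c(3, 3), base1 = "G", atom1 = "H1",
                   res2 = 21, base2 = "G", atom2 = "H8",
                   mixing_time = 200, intensity = 1, condition = "na")
  expect_error(NOESYPeakTable(pk), "duplicate")
})

test_that("normalization anchors endpoints to the fractional scale", {
  ts <- suppressWarnings(
    normalizeSeries(TitrationSeries(c(0, 150), c(200, 0), form = "na_form")))
  expect_equal(ts@intensity, c(1, 0))
  k <- suppressWarnings(
    normalizeSeries(TitrationSeries(c(0, 50, 100, 150), c(10, 40, 70, 100),
                                    form = "k_form")))
  expect_equal(k@intensity[1], 0)
  expect_equal(k@intensity[4], 1)
})

test_that("normalization is idempotent and rejects degenerate series", {
  raw <- TitrationSeries(seq(0, 150, 25), c(180, 120, 70, 40, 25, 20, 20),
                         form = "na_form")
  once <- normalizeSeries(raw)
  twice <- normalizeSeries(once)
  expect_equal(twice@intensity, once@intensity, tolerance = 1e-12)
  expect_error(
    normalizeSeries(TitrationSeries(c(0, 50, 100, 150), rep(7, 4),
                                    form = "na_form")),
    "degenerate")
  expect_error(
    normalizeSeries(TitrationSeries(c(0, 50, 100, 150), rep(0, 4),
                                    form = "na_form")),
    "degenerate")
})

test_that("normalized noisy series track the generating fractions", {
  sd <- 0.02
  # a grid long enough for the Na+-form signal to reach its plateau, so the
  # endpoint anchors coincide with the true fraction limits
  sim <- genTitration(noise_sd = sd, seed = 42, conc = seq(0, 1000, 50))
  fr <- speciesFractions(59.7, 2.7, concMolar(sim$na))
  # generator emits fractional data; renormalizing a raw-scaled copy of the
  # same curve recovers the fractions within the noise envelope
  raw <- TitrationSeries(sim$na@conc, 150 * sim$na@intensity + 12,
                         form = "na_form")
  norm <- suppressWarnings(normalizeSeries(raw))
  expect_lt(max(abs(norm@intensity - fr$fa)), 4 * sd)
})
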