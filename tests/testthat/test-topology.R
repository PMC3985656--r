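test_that("glycosidic calls recover the published syn set", {
  pt <- fig3cPeakTable()
  calls <- classifyGlycosidic(pt, tel23)
  syn <- calls$residue[calls$conformation %in% "syn"]
  expect_setequal(syn, c(3, 9, 21, 15, 16))
  expect_true(all(calls$called))
  # threshold sweep within the syn/anti gap never changes the calls
  for (thr in seq(2.6, 3.6, 0.2)) {
    calls_t <- classifyGlycosidic(pt, tel23, threshold = thr)
    expect_setequal(calls_t$residue[calls_t$conformation %in% "syn"], syn)
  }
})

test_that("all-weak H1'-H8 peaks give zero syn calls", {
  pt <- genNoesyPeaks(topology = "propeller")
  calls <- classifyGlycosidic(pt, tel23)
  expect_equal(sum(calls$conformation == "syn"), 0)
})

test_that("missing glycosidic evidence yields uncalled entries", {
  pt <- fig3cPeakTable()
  pk <- peaks(pt)
  drop <- pk$res1 == 3 & pk$res2 == 3
  pt2 <- NOESYPeakTable(pk[!drop, ])
  calls <- classifyGlycosidic(pt2, tel23)
  expect_false(calls$called[calls$residue == 3])
  expect_true(all(calls$called[calls$residue != 3]))
})

test_that("tetrad detection recovers the published cycles and layers", {
  td <- detectTetrads(fig3cPeakTable(), tel23)
  expect_equal(nrow(td), 3)
  expect_equal(td$layer, c("top", "central", "bottom"))
  expect_equal(unlist(td[td$layer == "top", c("g1", "g2", "g3", "g4")],
                      use.names = FALSE), c(3, 21, 17, 9))
  expect_equal(unlist(td[td$layer == "central", c("g1", "g2", "g3", "g4")],
                      use.names = FALSE), c(4, 10, 16, 22))
  expect_equal(unlist(td[td$layer == "bottom", c("g1", "g2", "g3", "g4")],
                      use.names = FALSE), c(5, 11, 15, 23))
  expect_equal(td$sense,
               c("anticlockwise", "clockwise", "clockwise"))
})

test_that("empty and cycle-free peak tables give zero tetrads", {
  td <- detectTetrads(NOESYPeakTable(), tel23)
  expect_equal(nrow(td), 0)
  expect_match(attr(td, "diagnostic"), "no directed 4-cycle")
})

test_that("detection is invariant to peak order and stored pair orientation", {
  pt <- fig3cPeakTable()
  pk <- peaks(pt)
  set.seed(31)
  shuffled <- NOESYPeakTable(pk[sample(nrow(pk)), ])
  td1 <- detectTetrads(pt, tel23)
  td2 <- detectTetrads(shuffled, tel23)
  expect_equal(td2, td1, ignore_attr = TRUE)
})

test_that("minor-conformation peaks below the floor are ignored", {
  pt <- genNoesyPeaks(topology = "hybrid-I", minor_peaks = TRUE)
  td <- detectTetrads(pt, tel23)
  expect_equal(nrow(td), 3)
  topo <- inferTopology(pt, tel23)
  expect_equal(topologyLabel(topo), "hybrid-I (3+1)")
})

test_that("cycle search agrees with brute-force enumeration", {
  seq16 <- ggggSequence()
  tract_of <- rep(NA_integer_, length(seq16))
  tr <- gTracts(seq16)
  for (i in seq_len(nrow(tr))) tract_of[tr$start[i]:tr$end[i]] <- i
  g_pos <- which(!is.na(tract_of))
  set.seed(97)
  for (rep in 1:20) {
    n_edge <- sample(8:30, 1)
    from <- sample(g_pos, n_edge, replace = TRUE)
    to <- sample(g_pos, n_edge, replace = TRUE)
    keep <- from != to & !duplicated(paste(from, to))
    from <- from[keep]; to <- to[keep]
    if (!length(from)) next
    pk <- data.frame(res1 = from, base1 = "G", atom1 = "H1",
                     res2 = to, base2 = "G", atom2 = "H8",
                     mixing_time = 200, intensity = 1000, condition = "na")
    # keep rows whose canonical form is unique (H1/H8 swap collisions)
    key <- paste(pmin(from, to), pmax(from, to),
                 ifelse(from < to, "H1H8", "H8H1"))
    pk <- pk[!duplicated(paste(pmin(from, to), pmax(from, to),
                               ifelse(from < to, "H1-H8", "H8-H1"))), ]
    pt <- tryCatch(NOESYPeakTable(pk), error = function(e) NULL)
    if (is.null(pt)) next
    td <- suppressWarnings(detectTetrads(pt, seq16, minor_floor = 0))
    got <- if (nrow(td))
      sort(apply(td[, c("g1", "g2", "g3", "g4")], 1, cycleKey))
    else character()
    edges <- data.frame(from = pk$res1, to = pk$res2)
    want <- sort(unique(vapply(bruteForceFourCycles(edges, tract_of),
                               cycleKey, character(1))))
    expect_equal(got, want)
  }
})

test_that("orientations: published calls give exactly one antiparallel tract", {
  pt <- fig3cPeakTable()
  td <- detectTetrads(pt, tel23)
  calls <- classifyGlycosidic(pt, tel23)
  orient <- inferOrientations(td, calls, tel23)
  expect_equal(sum(orient == "down"), 1)
  expect_equal(unname(orient["tract3"]), "down")
})

test_that("all-anti calls with same-sense cycles give four parallel tracts", {
  pt <- genNoesyPeaks(topology = "propeller")
  td <- detectTetrads(pt, tel23)
  calls <- classifyGlycosidic(pt, tel23)
  orient <- inferOrientations(td, calls, tel23)
  expect_true(all(orient == "up"))
  loops <- classifyLoops(orient, attr(td, "ring"))
  expect_equal(loops, rep("double-chain-reversal", 3))
})

test_that("contradictory glycosidic patterns raise an inference error", {
  pt <- fig3cPeakTable()
  td <- detectTetrads(pt, tel23)
  calls <- classifyGlycosidic(pt, tel23)
  # flip one call so the flipped-tract partition differs across tetrads
  calls$conformation[calls$residue == 16] <- "anti"
  calls$conformation[calls$residue == 22] <- "syn"
  expect_error(inferOrientations(td, calls, tel23), "inconsistent")
})

test_that("loop taxonomy follows the orientation/ring rule table", {
  # Tel23 hybrid-I: reversal loop first, then two laterals
  orient <- c(tract1 = "up", tract2 = "up", tract3 = "down", tract4 = "up")
  expect_equal(classifyLoops(orient, 1:4),
               c("double-chain-reversal", "lateral", "lateral"))
  # basket: alternating strands on a crossed ring
  orient_b <- c(tract1 = "up", tract2 = "down", tract3 = "up",
                tract4 = "down")
  expect_equal(classifyLoops(orient_b, c(1L, 2L, 4L, 3L)),
               c("lateral", "diagonal", "lateral"))
  # chair: alternating strands on the sequential ring
  expect_equal(classifyLoops(orient_b, 1:4), rep("lateral", 3))
})

test_that("the full Tel23 evidence classifies as hybrid-I", {
  topo <- inferTopology(fig3cPeakTable(), tel23)
  expect_equal(topologyLabel(topo), "hybrid-I (3+1)")
  expect_equal(topo@loops, c("double-chain-reversal", "lateral", "lateral"))
  expect_equal(sum(topo@orientations == "down"), 1)
  layers <- tetradLayers(topo)
  expect_equal(unname(layers[c("3", "4", "5")]),
               c("top", "central", "bottom"))
})

test_that("a mirrored loop order classifies as hybrid-II", {
  pt <- genNoesyPeaks(topology = "hybrid-II")
  topo <- inferTopology(pt, tel23)
  expect_equal(topologyLabel(topo), "hybrid-II (3+1)")
  expect_equal(topo@loops, c("lateral", "lateral", "double-chain-reversal"))
})

test_that("all five canonical folds round-trip through the classifier", {
  expected <- c("hybrid-I" = "hybrid-I (3+1)",
                "hybrid-II" = "hybrid-II (3+1)",
                "propeller" = "parallel propeller",
                "basket" = "antiparallel basket",
                "chair" = "antiparallel chair")
  labels <- vapply(names(expected), function(fold) {
    pt <- genNoesyPeaks(topology = fold)
    topologyLabel(inferTopology(pt, tel23))
  }, character(1))
  expect_equal(unname(labels), unname(expected))
  # distinct folds map to distinct labels
  expect_equal(anyDuplicated(labels), 0L)
  expect_error(genNoesyPeaks(topology = "zigzag"), "available")
})

test_that("every classified model has n_tracts - 1 loops", {
  for (fold in canonicalTopologies()) {
    topo <- inferTopology(genNoesyPeaks(topology = fold), tel23)
    expect_length(topo@loops, length(topo@orientations) - 1)
  }
})
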