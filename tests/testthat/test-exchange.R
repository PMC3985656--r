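test_that("species fractions conserve mass and hit the limits", {
  fr0 <- speciesFractions(59.7, 2.7, 0)
  expect_equal(unlist(fr0[c("fa", "fb", "fc")]), c(fa = 1, fb = 0, fc = 0))
  fr_big <- speciesFractions(59.7, 2.7, 1e6)
  expect_gt(fr_big$fc, 0.999)
  set.seed(7)
  for (i in 1:25) {
    k1 <- 10^runif(1, -2, 3); k2 <- 10^runif(1, -2, 3)
    x <- sort(c(0, 10^runif(20, -4, 1)))
    fr <- speciesFractions(k1, k2, x)
    expect_true(all(abs(fr$fa + fr$fb + fr$fc - 1) < 1e-12))
    expect_true(all(fr$fa >= 0 & fr$fa <= 1 & fr$fc >= 0 & fr$fc <= 1))
    expect_true(all(diff(fr$fa) <= 0))   # fa strictly decreasing
    expect_true(all(diff(fr$fc) >= 0))   # fc strictly increasing
  }
  expect_error(speciesFractions(59.7, 2.7, -1), "must be >= 0")
  expect_error(speciesFractions(-1, 2.7, 1), "must be > 0")
})

test_that("intermediate fraction is unimodal with argmax 1/sqrt(K1 K2)", {
  k1 <- 59.7; k2 <- 2.7
  x <- seq(1e-4, 1, length.out = 20000)
  fb <- speciesFractions(k1, k2, x)$fb
  x_star <- x[which.max(fb)]
  expect_equal(x_star, 1 / sqrt(k1 * k2), tolerance = 1e-3)
  expect_equal(x_star, 0.0788, tolerance = 0.005)
  # unimodal: increasing then decreasing
  d <- diff(fb)
  expect_equal(sum(diff(sign(d)) != 0), 1)
})

test_that("fractions are invariant under concentration rescaling", {
  set.seed(11)
  for (i in 1:10) {
    k1 <- 10^runif(1, -1, 2); k2 <- 10^runif(1, -1, 2)
    s <- 10^runif(1, -2, 2)
    x <- 10^runif(10, -3, 0)
    a <- speciesFractions(k1, k2, x)
    b <- speciesFractions(k1 / s, k2 / s, x * s)
    expect_equal(a[c("fa", "fb", "fc")], b[c("fa", "fb", "fc")],
                 tolerance = 1e-12)
  }
})

test_that("joint fit recovers the generating constants from noiseless data", {
  sim <- genTitration(noise_sd = 0)
  fit <- fitExchange(sim$na, sim$k)
  k <- exchangeConstants(fit)
  expect_equal(unname(k["K1"]), 59.7, tolerance = 1e-4)
  expect_equal(unname(k["K2"]), 2.7, tolerance = 1e-4)
  expect_lt(fit@rss, 1e-10)
  expect_length(fit@flags, 0)
  # sequential mode agrees on noiseless data
  fit2 <- fitExchange(sim$na, sim$k, mode = "sequential")
  expect_equal(fit2@K1, 59.7, tolerance = 1e-3)
  expect_equal(fit2@K2, 2.7, tolerance = 1e-3)
})

test_that("fit matches an exhaustive log-grid search on a small instance", {
  sim <- genTitration(noise_sd = 0.05, seed = 5,
                      conc = c(0, 10, 30, 75, 150, 400))
  x <- concMolar(sim$na)
  y_na <- sim$na@intensity; y_k <- sim$k@intensity
  ks <- 10^seq(-3, 4, length.out = 200)
  rss <- outer(seq_along(ks), seq_along(ks), Vectorize(function(i, j) {
    fr <- speciesFractions(ks[i], ks[j], x)
    sum((fr$fa - y_na)^2) + sum((fr$fc - y_k)^2)
  }))
  best <- arrayInd(which.min(rss), dim(rss))
  fit <- fitExchange(sim$na, sim$k)
  step <- log(ks[2] / ks[1])
  expect_lt(abs(log(fit@K1 / ks[best[1]])), 1.5 * step)
  expect_lt(abs(log(fit@K2 / ks[best[2]])), 1.5 * step)
  expect_lte(fit@rss, min(rss) + 1e-10)
})

test_that("flat series pin the first constant at its bound and are flagged", {
  conc <- seq(0, 150, 25)
  na <- TitrationSeries(conc, rep(1, 7), form = "na_form", normalized = TRUE)
  k <- TitrationSeries(conc, rep(0, 7), form = "k_form", normalized = TRUE)
  fit <- fitExchange(na, k)
  expect_true("boundary_K1" %in% fit@flags)
})

test_that("parameters are recovered within 10% under 2% noise", {
  # grid spanning both transitions (midpoints ~17 mM and ~370 mM)
  conc <- c(seq(0, 150, 10), 200, 300, 500, 750, 1000)
  n_rep <- 200
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- genTitration(noise_sd = 0.02, seed = 6000 + r, conc = conc)
    fit <- fitExchange(sim$na, sim$k)
    ok[r] <- abs(fit@K1 / 59.7 - 1) <= 0.1 && abs(fit@K2 / 2.7 - 1) <= 0.1
  }
  expect_gte(mean(ok), 0.95)
})

test_that("observed intermediate population follows mass balance", {
  sim <- genTitration(noise_sd = 0)
  fit <- fitExchange(sim$na, sim$k)
  fb <- intermediatePopulation(sim$na, sim$k)
  expect_equal(fb$fb_obs[1], 0)
  model <- speciesFractions(fit@K1, fit@K2, fb$x)
  expect_lt(max(abs(fb$fb_obs - model$fb)), 1e-8)
  expect_equal(attr(fb, "n_clipped"), 0)
  # noisy case: mean deviation bounded by the noise level
  sigma <- 0.03
  simn <- genTitration(noise_sd = sigma, seed = 9)
  fbn <- intermediatePopulation(simn$na, simn$k)
  truth <- speciesFractions(59.7, 2.7, fbn$x)$fb
  expect_lte(mean(abs(fbn$fb_obs - truth)), 2 * sigma)
  # mismatched grids error unless interpolation is requested
  short <- TitrationSeries(seq(0, 140, 20), rep(0.1, 8), form = "k_form",
                           normalized = TRUE)
  expect_error(intermediatePopulation(sim$na, short), "grids differ")
  expect_silent(intermediatePopulation(sim$na, short, interpolate = TRUE))
})

test_that("per-layer summary reports the bottom-tetrad lag", {
  mkfit <- function(res, k1) new("ExchangeFit", residue = as.integer(res),
                                 atom = "H1", K1 = k1, K2 = 2.7,
                                 stderr_K1 = NA_real_, stderr_K2 = NA_real_,
                                 rss = 0, n_points = 10L, mode = "joint",
                                 flags = character())
  map <- c(`3` = "top", `9` = "top", `4` = "central", `10` = "central",
           `5` = "bottom", `11` = "bottom")
  fits <- list(mkfit(3, 50), mkfit(9, 50), mkfit(4, 50), mkfit(10, 50),
               mkfit(5, 10), mkfit(11, 10))
  s <- perResidueSummary(fits, map)
  expect_equal(s$ratio_k1, 5)
  expect_false(any(s$residues$flag_outlier))
  # single fit: one row, no ratio
  s1 <- suppressWarnings(perResidueSummary(fits[1], map))
  expect_equal(nrow(s1$residues), 1)
  expect_true(is.na(s1$ratio_k1))
  expect_error(perResidueSummary(fits, map[-1]), "absent from tetrad_map")
})

test_that("fitting bottom-lag synthetic data recovers a 2- to 5-fold ratio", {
  conc <- c(seq(0, 150, 10), 250, 500, 1000)
  fit_one <- function(res, mult, seed) {
    sim <- genTitration(residue = res, k1_multiplier = mult, conc = conc,
                        noise_sd = 0.01, seed = seed)
    fitExchange(sim$na, sim$k)
  }
  others <- Map(fit_one, c(3, 9, 17, 4, 10, 16, 21, 22),
                1, 300 + seq_len(8))
  bottom <- Map(fit_one, c(5, 11, 15), 1 / 3, 400 + seq_len(3))
  map <- c(`3` = "top", `9` = "top", `17` = "top", `21` = "top",
           `4` = "central", `10` = "central", `16` = "central",
           `22` = "central", `5` = "bottom", `11` = "bottom",
           `15` = "bottom")
  s <- perResidueSummary(c(others, bottom), map)
  expect_gte(s$ratio_k1, 2)
  expect_lte(s$ratio_k1, 5)
})
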