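test_that("mono-exponential fit recovers a noiseless HDX decay", {
  tr <- genKineticTrace("tel23_hdx_na")
  fit <- fitMonoexp(tr)
  expect_equal(timeConstants(fit), 14, tolerance = 1e-3)
  expect_equal(fit@offset, 0, tolerance = 1e-6)
  expect_equal(fit@amp_total, 1, tolerance = 1e-6)
  expect_gt(fit@r2, 0.9999)
  # half-life identity on the fitted curve: S(tau ln2) - offset = A/2
  s_at <- fit@offset + fit@amp_total * exp(-(fit@taus * log(2)) / fit@taus)
  expect_equal(s_at - fit@offset, fit@amp_total / 2, tolerance = 1e-12)
})

test_that("constant traces are flagged as no decay", {
  tr <- KineticTrace(seq(0, 100, 10), rep(3.2, 11), kind = "hdx",
                     time_unit = "min")
  fit <- fitMonoexp(tr)
  expect_true("no_decay" %in% fit@flags)
})

test_that("dead-time points are excluded from mono fits", {
  t <- seq(0, 120, 5)
  y <- exp(-t / 14)
  y[t < 20] <- 5  # corrupt the pre-dead-time points
  tr <- KineticTrace(t, y, kind = "hdx", time_unit = "min", dead_time = 20)
  fit <- fitMonoexp(tr)
  expect_equal(timeConstants(fit), 14, tolerance = 1e-3)
})

test_that("bi-exponential fit recovers the CD conversion parameters", {
  tr <- genKineticTrace("tel23_cd_conversion")
  fit <- fitBiexp(tr)
  expect_equal(timeConstants(fit), c(80, 930), tolerance = 0.01)
  expect_equal(ampPercent(fit), c(89, 11), tolerance = 0.01)
  expect_gt(fit@r2, 0.9999)
  expect_lt(fit@offset - 1, 1e-6)      # rise plateau
  expect_lt(fit@amp_total, 0)          # rising signal: negative amplitude
})

test_that("pure mono input triggers the bi-exponential degeneracy flag", {
  tr <- genKineticTrace("tel23_hdx_na")
  fit <- fitBiexp(tr)
  expect_true("degenerate_taus" %in% fit@flags)
})

test_that("bi-exponential fit matches the variable-projection grid oracle", {
  set.seed(21)
  t <- seq(0, 3600, 30)
  y <- 1 - (0.89 * exp(-t / 80) + 0.11 * exp(-t / 930)) +
    rnorm(length(t), 0, 0.01)
  tr <- KineticTrace(t, y, kind = "cd_conversion", time_unit = "s")
  fit <- fitBiexp(tr)
  # oracle: 100x100 log grid over the taus, amplitudes solved linearly
  taus <- exp(seq(log(5), log(10000), length.out = 100))
  best <- list(rss = Inf)
  for (i in 1:99) for (j in (i + 1):100) {
    X <- cbind(1, exp(-t / taus[i]), exp(-t / taus[j]))
    r <- stats::lm.fit(X, y)
    rss <- sum(r$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, t1 = taus[i], t2 = taus[j])
  }
  step <- log(taus[2] / taus[1])
  expect_lt(abs(log(fit@taus[1] / best$t1)), 1.5 * step)
  expect_lt(abs(log(fit@taus[2] / best$t2)), 1.5 * step)
  fitted_y <- fit@offset + fit@amp_total *
    (fit@amp_fracs[1] * exp(-t / fit@taus[1]) +
     fit@amp_fracs[2] * exp(-t / fit@taus[2]))
  expect_lte(sum((fitted_y - y)^2), best$rss + 1e-10)
})

test_that("fitted taus rescale exactly with the time unit", {
  base <- genKineticTrace("tel23_hdx_nak", noise_sd = 0.01, seed = 3)
  fit_min <- fitMonoexp(base)
  scaled <- KineticTrace(base@times * 60, base@signal, kind = "hdx",
                         time_unit = "s")
  fit_s <- fitMonoexp(scaled)
  expect_equal(fit_s@taus, fit_min@taus * 60, tolerance = 1e-6)
})

test_that("mono tau recovery under 2% noise is within 5% in >=95% of runs", {
  n_rep <- 200
  # two-phase sampling: dense over the first 1.5 time constants, then the
  # plateau (the standard design for exponential time constants)
  t <- c(seq(0, 21, length.out = 30), seq(24, 120, length.out = 20))
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    y <- exp(-t / 14) + rnorm(length(t), 0, 0.02)
    fit <- fitMonoexp(KineticTrace(t, y, kind = "hdx", time_unit = "min"))
    ok[r] <- abs(fit@taus / 14 - 1) <= 0.05
  }
  expect_gte(mean(ok), 0.95)
})

test_that("condition summaries give means and sample SDs", {
  mk <- function(tau) new("KineticFit", model = "mono", taus = tau,
                          amp_fracs = 1, amp_total = 1, offset = 0,
                          r2 = 0.99, stderr_taus = NA_real_,
                          time_unit = "min", flags = character())
  s <- summarizeCondition(lapply(c(14, 14, 14, 14), mk), "na")
  expect_equal(s$mean_tau, 14)
  expect_equal(s$sd_tau, 0)
  s2 <- summarizeCondition(lapply(c(9, 14, 14, 19), mk), "na")
  expect_equal(s2$mean_tau, 14)
  expect_equal(s2$sd_tau, 4.0824829, tolerance = 1e-6)
  expect_error(summarizeCondition(list(), "na"), "no fits")
})

test_that("fold difference propagates uncertainty like Monte Carlo", {
  a <- data.frame(condition = "na", mean_tau = 14, sd_tau = 5,
                  n_residues = 4, time_unit = "min")
  b <- data.frame(condition = "na_k_simultaneous", mean_tau = 136,
                  sd_tau = 28, n_residues = 4, time_unit = "min")
  fd <- foldDifference(a, b)
  expect_equal(unname(fd["ratio"]), 136 / 14, tolerance = 1e-12)
  expect_equal(round(fd[["ratio"]]), 10)
  # first-order propagation vs Monte Carlo on moderate spreads
  a2 <- data.frame(condition = "x", mean_tau = 20, sd_tau = 2,
                   n_residues = 4, time_unit = "min")
  b2 <- data.frame(condition = "y", mean_tau = 100, sd_tau = 8,
                   n_residues = 4, time_unit = "min")
  fd2 <- foldDifference(a2, b2)
  set.seed(13)
  mc <- stats::sd(rnorm(1e4, 100, 8) / rnorm(1e4, 20, 2))
  expect_equal(unname(fd2["se"]), mc, tolerance = 0.1)
  expect_error(foldDifference(a2, transform(b2, mean_tau = 0)), "> 0")
})

test_that("hybridization decay and rise share one time constant", {
  pair <- genKineticTrace("tel23_hybridization", noise_sd = 0)
  fd <- fitMonoexp(pair$decay)
  fr <- fitMonoexp(pair$rise)
  expect_equal(fd@taus, 127, tolerance = 1e-4)
  expect_equal(fr@taus, fd@taus, tolerance = 1e-4)
  expect_lt(fr@amp_total, 0)  # rise fitted with negative amplitude
})
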