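#' Extract the melting temperature from a CD melting curve
#'
#' Folded and unfolded linear baselines are fitted to the terminal 10
#' percent windows of the temperature range and the curve is converted to a
#' folded fraction `alpha(T) = (theta - b_u(T)) / (b_f(T) - b_u(T))`, which
#' makes the result invariant under affine transforms of the ellipticity
#' axis. The first derivative of `alpha` is computed with a
#' Savitzky-Golay filter (polynomial order 2, window `smooth_window`), and
#' the melting temperature is the temperature of the derivative's extremum,
#' refined by parabolic interpolation through the three points around the
#' peak. A curve without a resolvable transition (baseline separation below
#' three times the baseline noise, or a derivative extremum within three
#' times the derivative noise) raises a "no transition" error.
#'
#' @param curve a [MeltingCurve-class] with >= 20 points.
#' @param smooth_window smoothing window in degrees Celsius (default 5).
#' @param baseline_frac terminal fraction of the temperature range used for
#'   each baseline fit (default 0.1).
#' @return a [MeltingResult-class] (`method = "derivative"`).
#' @examples
#' mc <- genMeltingCurve("tel23_melting_k")
#' extractTm(mc)
#' @export
extractTm <- function(curve, smooth_window = 5, baseline_frac = 0.1) {
  stopifnot(is(curve, "MeltingCurve"))
  Tm_ <- curve@temperature; y <- curve@ellipticity
  if (length(Tm_) < 20L) stop("need at least 20 points")
  # resample onto a regular grid if needed
  dt <- diff(Tm_)
  if (max(dt) - min(dt) > 1e-8 * stats::median(dt)) {
    step <- stats::median(dt)
    grid <- seq(min(Tm_), max(Tm_), by = step)
    y <- stats::approx(Tm_, y, xout = grid)$y
    Tm_ <- grid
  }
  step <- Tm_[2] - Tm_[1]
  n <- length(Tm_)
  span <- Tm_[n] - Tm_[1]
  k <- max(3L, ceiling(baseline_frac * n))
  low <- seq_len(k); high <- seq(n - k + 1L, n)
  fit_f <- stats::lm(y[low] ~ Tm_[low])    # folded baseline (low T)
  fit_u <- stats::lm(y[high] ~ Tm_[high])  # unfolded baseline (high T)
  bf <- stats::coef(fit_f)[1] + stats::coef(fit_f)[2] * Tm_
  bu <- stats::coef(fit_u)[1] + stats::coef(fit_u)[2] * Tm_
  t_mid <- (Tm_[1] + Tm_[n]) / 2
  amp <- (stats::coef(fit_f)[1] + stats::coef(fit_f)[2] * t_mid) -
    (stats::coef(fit_u)[1] + stats::coef(fit_u)[2] * t_mid)
  noise <- stats::sd(c(stats::residuals(fit_f), stats::residuals(fit_u)))
  if (abs(amp) < max(3 * noise, 0.05 * stats::sd(y), 1e-12))
    stop("no transition: baselines are not separated")
  alpha <- (y - bu) / (bf - bu)
  win <- round(smooth_window / step)
  win <- max(5L, win + (1L - win %% 2L))  # odd, >= 5
  if (win >= n) win <- n - (1L - n %% 2L)
  d <- signal::sgolayfilt(alpha, p = 2, n = win, m = 1, ts = step)
  half <- (win - 1L) %/% 2L
  interior <- (half + 1L):(n - half)
  i_pk <- interior[which.max(abs(d[interior]))]
  d_noise <- stats::mad(c(d[low], d[high]))
  if (abs(d[i_pk]) < max(3 * d_noise, 1e-12))
    stop("no transition: derivative extremum within noise")
  # parabolic refinement of the extremum
  tm <- Tm_[i_pk]
  if (i_pk > 1L && i_pk < n) {
    y3 <- abs(d[(i_pk - 1L):(i_pk + 1L)])
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (abs(denom) > 1e-15) {
      delta <- 0.5 * (y3[1] - y3[3]) / denom
      if (abs(delta) <= 1) tm <- Tm_[i_pk] + delta * step
    }
  }
  if (tm < Tm_[1] || tm > Tm_[n]) stop("melting temperature outside range")
  new("MeltingResult", tm = unname(tm), dheight = abs(d[i_pk]),
      width = NA_real_, method = "derivative")
}

#' Two-state sigmoid fit of a melting curve
#'
#' Cross-check for [extractTm()]: fits a two-state transition with linear
#' folded/unfolded baselines,
#' `theta(T) = b_u(T) + (b_f(T) - b_u(T)) / (1 + exp((T - Tm)/w))`,
#' and returns the midpoint and width parameter.
#'
#' @param curve a [MeltingCurve-class] with >= 20 points.
#' @return a [MeltingResult-class] (`method = "two_state_fit"`, `width`
#'   filled in).
#' @export
fitTwoState <- function(curve) {
  stopifnot(is(curve, "MeltingCurve"))
  Tm_ <- curve@temperature; y <- curve@ellipticity
  if (length(Tm_) < 20L) stop("need at least 20 points")
  n <- length(Tm_)
  k <- max(3L, ceiling(0.1 * n))
  low <- seq_len(k); high <- seq(n - k + 1L, n)
  cf_f <- stats::coef(stats::lm(y[low] ~ Tm_[low]))
  cf_u <- stats::coef(stats::lm(y[high] ~ Tm_[high]))
  tm0 <- tryCatch(extractTm(curve)@tm, error = function(e) mean(range(Tm_)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (au + bu * Tm_) + ((af + bf * Tm_) - (au + bu * Tm_)) /
        (1 + exp((Tm_ - tm) / w)),
      start = list(af = unname(cf_f[1]), bf = unname(cf_f[2]),
                   au = unname(cf_u[1]), bu = unname(cf_u[2]),
                   tm = tm0, w = 2),
      lower = c(-Inf, -Inf, -Inf, -Inf, min(Tm_), 0.05),
      upper = c(Inf, Inf, Inf, Inf, max(Tm_), diff(range(Tm_))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("two-state melting fit failed to converge")
  cf <- stats::coef(fit)
  new("MeltingResult", tm = unname(cf[["tm"]]), dheight = NA_real_,
      width = unname(cf[["w"]]), method = "two_state_fit")
}

#' Melting temperature of a result
#' @param x a [MeltingResult-class].
#' @return numeric Tm in degrees Celsius.
#' @export
meltingTm <- function(x) {
  stopifnot(is(x, "MeltingResult"))
  x@tm
}

setMethod("show", "MeltingResult", function(object) {
  cat(sprintf("MeltingResult (%s): Tm = %.2f degC", object@method,
              object@tm))
  if (!is.na(object@dheight))
    cat(sprintf(", derivative peak %.3g /degC", object@dheight))
  if (!is.na(object@width))
    cat(sprintf(", width %.2f degC", object@width))
  cat("\n")
})
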