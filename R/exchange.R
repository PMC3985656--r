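#' Species fractions of the stepwise di-cation exchange model
#'
#' Three-state stepwise replacement of the two channel cations of a
#' three-tetrad G-quadruplex: pure Na+ form (a) -> mixed Na+/K+ form (b) ->
#' pure K+ form (c), governed by two stepwise equilibrium constants. At
#' added-cation concentration `x` the folded population partitions as
#' \deqn{f_a = 1/D, \quad f_b = K_1 x / D, \quad f_c = K_1 K_2 x^2 / D,}
#' with \eqn{D = 1 + K_1 x + K_1 K_2 x^2}, so the three fractions always sum
#' to one. The mixed form peaks at \eqn{x = 1/\sqrt{K_1 K_2}}.
#'
#' @param k1,k2 stepwise equilibrium constants (> 0), in inverse units of
#'   `x` (conventionally 1/M).
#' @param x non-negative cation concentration(s), conventionally molar.
#' @return data.frame with columns `x`, `fa`, `fb`, `fc`.
#' @examples
#' speciesFractions(59.7, 2.7, c(0, 0.017, 0.15))
#' @export
speciesFractions <- function(k1, k2, x) {
  if (k1 <= 0 || k2 <= 0) stop("equilibrium constants must be > 0")
  if (any(x < 0)) stop("concentrations must be >= 0")
  d <- 1 + k1 * x + k1 * k2 * x^2
  data.frame(x = x, fa = 1 / d, fb = k1 * x / d, fc = k1 * k2 * x^2 / d)
}

# residuals of the joint isotherm fit at log-parameters th = (logK1, logK2)
.exchResid <- function(th, x_na, y_na, x_k, y_k) {
  k1 <- exp(th[1]); k2 <- exp(th[2])
  d_na <- 1 + k1 * x_na + k1 * k2 * x_na^2
  d_k <- 1 + k1 * x_k + k1 * k2 * x_k^2
  c(1 / d_na - y_na, (k1 * k2 * x_k^2) / d_k - y_k)
}

.LOGK_LOWER <- log(1e-4)
.LOGK_UPPER <- log(1e6)

# numerical jacobian of a residual function
.numJacobian <- function(fn, th, eps = 1e-6) {
  r0 <- fn(th)
  J <- matrix(NA_real_, length(r0), length(th))
  for (j in seq_along(th)) {
    h <- eps * max(1, abs(th[j]))
    thp <- th; thp[j] <- th[j] + h
    J[, j] <- (fn(thp) - r0) / h
  }
  J
}

.lmFit <- function(resid_fn, start, lower, upper) {
  minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                     fn = resid_fn,
                     control = minpack.lm::nls.lm.control(maxiter = 200))
}

#' Fit the stepwise exchange constants to a pair of titration series
#'
#' Estimates the two stepwise equilibrium constants by nonlinear least
#' squares on the species-fraction curves: the Na+-form series is fitted by
#' \eqn{f_a(x)} and the K+-form series by \eqn{f_c(x)} (see
#' [speciesFractions()]). The default joint mode minimizes the concatenated
#' residuals of both curves; the sequential mode mirrors fitting the
#' disappearance and appearance curves one after the other (constants from
#' the Na+-form curve first, then the second constant refined on the K+-form
#' curve with the first held fixed). Optimization is multi-start on a log
#' grid of both constants (the surface is bilinear in log space and
#' single-start fits stall), with box bounds; estimates pinned at a bound
#' are flagged rather than silently returned.
#'
#' @param na_series,k_series normalized [TitrationSeries-class] objects
#'   (fractional scale) for the same residue.
#' @param mode `"joint"` (default) or `"sequential"`.
#' @param starts numeric vector of start values for each constant (1/M) used
#'   to build the multi-start grid.
#' @return an [ExchangeFit-class]; constants and standard errors are per
#'   molar. Standard errors come from the Gauss-Newton covariance at the
#'   optimum via the delta method (fits run in log space).
#' @examples
#' sim <- genTitration(noise_sd = 0)
#' fitExchange(sim$na, sim$k)
#' @export
fitExchange <- function(na_series, k_series, mode = c("joint", "sequential"),
                        starts = c(0.1, 1, 10, 100, 1000)) {
  mode <- match.arg(mode)
  stopifnot(is(na_series, "TitrationSeries"), is(k_series, "TitrationSeries"))
  if (na_series@form != "na_form" || k_series@form != "k_form")
    stop("expected a na_form and a k_form series, in that order")
  if (length(na_series) < 5L || length(k_series) < 5L)
    stop("need at least 5 points in each series")
  if (!na_series@normalized || !k_series@normalized)
    warning("series are not flagged as normalized; ",
            "fitting assumes fractional scale")
  if (!is.na(na_series@residue) && !is.na(k_series@residue) &&
      na_series@residue != k_series@residue)
    warning("series belong to different residues (",
            na_series@residue, " vs ", k_series@residue, ")")
  x_na <- concMolar(na_series); y_na <- na_series@intensity
  x_k <- concMolar(k_series); y_k <- k_series@intensity

  resid_fn <- function(th) .exchResid(th, x_na, y_na, x_k, y_k)
  grid <- as.matrix(expand.grid(log(starts), log(starts)))
  rss0 <- apply(grid, 1L, function(th) sum(resid_fn(th)^2))
  top <- grid[order(rss0)[seq_len(min(3L, nrow(grid)))], , drop = FALSE]

  runStarts <- function(fn, start_mat, lower, upper) {
    best <- NULL
    errors <- character()
    for (i in seq_len(nrow(start_mat))) {
      res <- tryCatch(.lmFit(fn, start_mat[i, ], lower, upper),
                      error = function(e) e)
      if (inherits(res, "error")) { errors <- c(errors, conditionMessage(res)); next }
      if (is.null(best) || res$deviance < best$deviance) best <- res
    }
    if (is.null(best))
      stop("exchange fit failed to converge from all starts: ",
           paste(unique(errors), collapse = "; "))
    best
  }

  if (mode == "joint") {
    best <- runStarts(resid_fn, top, rep(.LOGK_LOWER, 2), rep(.LOGK_UPPER, 2))
    th <- best$par
  } else {
    fn_na <- function(th) .exchResid(th, x_na, y_na, numeric(), numeric())
    b1 <- runStarts(fn_na, top, rep(.LOGK_LOWER, 2), rep(.LOGK_UPPER, 2))
    lk1 <- b1$par[1]
    fn_k <- function(th2) .exchResid(c(lk1, th2), numeric(), numeric(),
                                     x_k, y_k)
    st2 <- matrix(log(starts), ncol = 1)
    b2 <- runStarts(fn_k, st2, .LOGK_LOWER, .LOGK_UPPER)
    th <- c(lk1, b2$par[1])
    best <- list(deviance = sum(resid_fn(th)^2))
  }

  flags <- character()
  tol <- 1e-6
  if (th[1] < .LOGK_LOWER + tol) flags <- c(flags, "boundary_K1")
  if (th[1] > .LOGK_UPPER - tol) flags <- c(flags, "boundary_K1_upper")
  if (th[2] < .LOGK_LOWER + tol) flags <- c(flags, "boundary_K2")
  if (th[2] > .LOGK_UPPER - tol) flags <- c(flags, "boundary_K2_upper")

  rss <- sum(resid_fn(th)^2)
  n <- length(y_na) + length(y_k)
  se_log <- rep(NA_real_, 2)
  if (n > 2L && !length(flags)) {
    J <- .numJacobian(resid_fn, th)
    jtj <- crossprod(J)
    cv <- tryCatch(solve(jtj) * rss / (n - 2L), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se_log <- sqrt(diag(cv))
  }
  k <- unname(exp(th))
  new("ExchangeFit",
      residue = na_series@residue, atom = na_series@atom,
      K1 = k[1], K2 = k[2],
      stderr_K1 = k[1] * se_log[1], stderr_K2 = k[2] * se_log[2],
      rss = rss, n_points = as.integer(n), mode = mode, flags = flags)
}

#' @rdname exchangeConstants
#' @export
setGeneric("exchangeConstants", function(x) standardGeneric("exchangeConstants"))

#' Stepwise equilibrium constants of a fit
#'
#' @param x an [ExchangeFit-class].
#' @return named numeric `c(K1 = , K2 = )`, per molar.
#' @export
setMethod("exchangeConstants", "ExchangeFit", function(x) {
  c(K1 = x@K1, K2 = x@K2)
})

setMethod("show", "ExchangeFit", function(object) {
  cat(sprintf("ExchangeFit (residue %s, %s mode):\n", object@residue,
              object@mode))
  cat(sprintf("  K1 = %.4g +/- %.3g /M, K2 = %.4g +/- %.3g /M (ratio %.3g)\n",
              object@K1, object@stderr_K1, object@K2, object@stderr_K2,
              object@K1 / object@K2))
  cat(sprintf("  rss = %.4g over %d points\n", object@rss, object@n_points))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Observed intermediate (mixed di-cation) population
#'
#' The mixed-form fraction is not observed directly; it is recovered by mass
#' balance, subtracting the observed Na+-form and K+-form fractions from the
#' total folded population: `fb_obs(x) = 1 - fa_obs(x) - fc_obs(x)`. Values
#' are clipped to \[0, 1\] and the number of clipped points is reported.
#'
#' @param na_series,k_series normalized [TitrationSeries-class] objects.
#' @param interpolate logical; if the two concentration grids differ,
#'   linearly interpolate the K+-form series onto the Na+-form grid instead
#'   of erroring.
#' @return data.frame with columns `x` (molar), `fb_obs`; attribute
#'   `n_clipped` counts points clipped into \[0, 1\].
#' @export
intermediatePopulation <- function(na_series, k_series, interpolate = FALSE) {
  stopifnot(is(na_series, "TitrationSeries"), is(k_series, "TitrationSeries"))
  x_na <- concMolar(na_series); x_k <- concMolar(k_series)
  fa <- na_series@intensity
  if (length(x_na) == length(x_k) && all(abs(x_na - x_k) < 1e-12)) {
    fc <- k_series@intensity
  } else if (interpolate) {
    fc <- stats::approx(x_k, k_series@intensity, xout = x_na, rule = 2)$y
  } else {
    stop("concentration grids differ; set interpolate = TRUE to resample")
  }
  fb <- 1 - fa - fc
  n_clip <- sum(fb < 0 | fb > 1)
  fb <- pmin(pmax(fb, 0), 1)
  out <- data.frame(x = x_na, fb_obs = fb)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Per-layer summary of exchange fits
#'
#' Aggregates per-residue stepwise constants by tetrad layer and reports the
#' lag of the bottom tetrad: the ratio of the mean first-step constant of the
#' non-bottom layers to that of the bottom layer. Residues whose first-step
#' constant deviates more than 3-fold from their layer mean are flagged.
#'
#' @param fits list of [ExchangeFit-class] objects.
#' @param tetrad_map named character vector mapping residue index (as names)
#'   to layer (`"top"`, `"central"`, `"bottom"`); see [tetradLayers()].
#' @return list with `residues` (per-residue data.frame with layer and
#'   outlier flag), `layers` (per-layer means and n), and `ratio_k1`
#'   (non-bottom / bottom mean K1; NA when either side is missing).
#' @export
perResidueSummary <- function(fits, tetrad_map) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, logical(1), "ExchangeFit")))
  res <- vapply(fits, slot, integer(1), "residue")
  missing <- setdiff(as.character(res), names(tetrad_map))
  if (length(missing))
    stop("residue(s) absent from tetrad_map: ",
         paste(missing, collapse = ", "))
  df <- data.frame(residue = res,
                   K1 = vapply(fits, slot, numeric(1), "K1"),
                   K2 = vapply(fits, slot, numeric(1), "K2"),
                   layer = unname(tetrad_map[as.character(res)]))
  layers <- c("top", "central", "bottom")
  present <- layers[layers %in% df$layer]
  if (length(setdiff(layers, present)))
    warning("empty layer(s) omitted: ",
            paste(setdiff(layers, present), collapse = ", "))
  lay <- do.call(rbind, lapply(present, function(l) {
    d <- df[df$layer == l, ]
    data.frame(layer = l, mean_K1 = mean(d$K1), mean_K2 = mean(d$K2),
               n = nrow(d))
  }))
  df$flag_outlier <- FALSE
  for (l in present) {
    m <- lay$mean_K1[lay$layer == l]
    i <- df$layer == l
    df$flag_outlier[i] <- df$K1[i] > 3 * m | df$K1[i] < m / 3
  }
  ratio <- NA_real_
  if ("bottom" %in% present && length(setdiff(present, "bottom"))) {
    non_bottom <- df$K1[df$layer != "bottom"]
    ratio <- mean(non_bottom) / mean(df$K1[df$layer == "bottom"])
  }
  list(residues = df, layers = lay, ratio_k1 = ratio)
}
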