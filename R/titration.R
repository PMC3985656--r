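#' Construct a TitrationSeries
#'
#' @param conc numeric cation concentrations, non-negative, strictly
#'   increasing.
#' @param intensity numeric intensities (raw or already fractional).
#' @param form `"na_form"` (disappearing Na+-form signal) or `"k_form"`
#'   (appearing K+-form signal).
#' @param residue integer residue index the imino proton belongs to.
#' @param atom observed proton label (default `"H1"`).
#' @param conc_unit `"mM"` (default) or `"M"`.
#' @param normalized logical; set TRUE when `intensity` is already on the
#'   fractional 0-1 scale (e.g. model-generated species fractions).
#' @return a [TitrationSeries-class].
#' @export
TitrationSeries <- function(conc, intensity, form = c("na_form", "k_form"),
                            residue = NA_integer_, atom = "H1",
                            conc_unit = "mM", normalized = FALSE) {
  form <- match.arg(form)
  new("TitrationSeries", residue = as.integer(residue), atom = atom,
      form = form, conc = as.numeric(conc), intensity = as.numeric(intensity),
      conc_unit = conc_unit, normalized = normalized,
      norm_anchors = if (normalized) c(zero = NA_real_, plateau = NA_real_)
                     else numeric())
}

#' @export
setMethod("length", "TitrationSeries", function(x) length(x@conc))

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries (%s, residue %s, %s): %d point(s), 0-%g %s%s\n",
              object@form, object@residue, object@atom, length(object),
              if (length(object)) max(object@conc) else NA, object@conc_unit,
              if (object@normalized) ", normalized" else ""))
})

#' Concentrations of a titration series, in molar
#'
#' @param x a [TitrationSeries-class].
#' @return numeric concentrations converted to molar.
#' @export
concMolar <- function(x) {
  stopifnot(is(x, "TitrationSeries"))
  if (x@conc_unit == "mM") x@conc / 1000 else x@conc
}

#' Normalize a titration series to the fractional scale
#'
#' Anchors a raw intensity series so that it reads as a species fraction:
#' for a Na+-form series the zero-titrant intensity maps to 1 and the
#' end plateau (mean of the trailing 10 percent of points) to 0; for a
#' K+-form series the zero-titrant intensity maps to 0 and the end plateau
#' to 1. The anchoring is idempotent: normalizing twice is a no-op.
#'
#' @param x a [TitrationSeries-class].
#' @param tail_frac fraction of trailing points used to estimate the plateau
#'   (default 0.1, at least one point).
#' @return a normalized [TitrationSeries-class] with `norm_anchors` recording
#'   the zero-titrant and plateau intensities used.
#' @examples
#' ts <- TitrationSeries(c(0, 150), c(200, 0), form = "na_form")
#' normalizeSeries(ts)@intensity   # 1, 0
#' @export
normalizeSeries <- function(x, tail_frac = 0.1) {
  stopifnot(is(x, "TitrationSeries"))
  n <- length(x)
  if (n < 2L) stop("need at least 2 points to normalize")
  if (n < 4L) warning("fewer than 4 points; normalization anchors are crude")
  if (all(abs(x@intensity) < .Machine$double.eps))
    stop("degenerate series: all intensities are zero")
  if (min(x@conc) > 0) {
    warning("no zero-titrant point; using the first point as the zero anchor")
    i0 <- x@intensity[1L]
  } else {
    i0 <- mean(x@intensity[x@conc == 0])
  }
  k <- max(1L, ceiling(tail_frac * n))
  plateau <- mean(x@intensity[(n - k + 1L):n])
  span <- i0 - plateau
  if (abs(span) < 1e-12 * max(abs(x@intensity), 1))
    stop("degenerate series: zero-titrant and plateau intensities coincide")
  norm <- if (x@form == "na_form") (x@intensity - plateau) / span
          else (x@intensity - i0) / -span
  if (any(norm < -0.05 | norm > 1.05))
    warning("normalized intensities outside [-0.05, 1.05]; ",
            "check anchors or noise level")
  out <- x
  out@intensity <- norm
  out@normalized <- TRUE
  out@norm_anchors <- c(zero = i0, plateau = plateau)
  out
}
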