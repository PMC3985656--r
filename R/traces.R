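#' Construct a KineticTrace
#'
#' @param times numeric, strictly increasing.
#' @param signal numeric, same length.
#' @param kind `"hdx"`, `"hybridization"` or `"cd_conversion"`.
#' @param time_unit `"s"` or `"min"`.
#' @param dead_time numeric scalar in the same unit as `times` (points
#'   earlier than this are excluded from fits); default 0.
#' @return a [KineticTrace-class].
#' @export
KineticTrace <- function(times, signal,
                         kind = c("hdx", "hybridization", "cd_conversion"),
                         time_unit = c("s", "min"), dead_time = 0) {
  kind <- match.arg(kind)
  time_unit <- match.arg(time_unit)
  new("KineticTrace", times = as.numeric(times), signal = as.numeric(signal),
      kind = kind, time_unit = time_unit, dead_time = dead_time)
}

#' @export
setMethod("length", "KineticTrace", function(x) length(x@times))

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace (%s): %d point(s), %g-%g %s, dead time %g %s\n",
              object@kind, length(object),
              if (length(object)) min(object@times) else NA,
              if (length(object)) max(object@times) else NA,
              object@time_unit, object@dead_time, object@time_unit))
})

#' Construct a MeltingCurve
#'
#' @param temperature numeric degrees Celsius, strictly increasing.
#' @param ellipticity numeric millidegrees.
#' @param wavelength monitored wavelength in nm (metadata; default 295).
#' @return a [MeltingCurve-class].
#' @export
MeltingCurve <- function(temperature, ellipticity, wavelength = 295) {
  new("MeltingCurve", temperature = as.numeric(temperature),
      ellipticity = as.numeric(ellipticity), wavelength = wavelength)
}

#' @export
setMethod("length", "MeltingCurve", function(x) length(x@temperature))

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve: %d point(s), %g-%g degC at %g nm\n",
              length(object),
              if (length(object)) min(object@temperature) else NA,
              if (length(object)) max(object@temperature) else NA,
              object@wavelength))
})
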