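#' @import methods
NULL

# Atom vocabulary shared by parsers, generators and the topology engine.
# H1 = guanine imino, H8 = purine aromatic, H1' = sugar, H6/CH3 = thymine.
.VALID_ATOMS <- c("H1", "H8", "H1'", "CH3", "H6")
.VALID_CONDITIONS <- c("na", "k", "na_k_mixed")
.STANDARD_MIXING_TIMES <- c(50, 100, 150, 200)

.PEAK_COLS <- c("res1", "base1", "atom1", "res2", "base2", "atom2",
                "mixing_time", "intensity", "condition")

#' G-quadruplex-forming DNA sequence
#'
#' Holds a DNA sequence together with its G-tracts (runs of two or more
#' consecutive guanines), the scaffold on which tetrads and loops are defined.
#'
#' @slot seq a [Biostrings::DNAString] with the 5'-3' sequence.
#' @slot tracts data.frame with columns `tract`, `start`, `end`, `length`
#'   (1-based, inclusive).
#' @seealso [G4Sequence()], [tel23Sequence()], [gTracts()]
#' @exportClass G4Sequence
setClass("G4Sequence",
         representation(seq = "DNAString", tracts = "data.frame"))

setValidity("G4Sequence", function(object) {
  msg <- character()
  tr <- object@tracts
  need <- c("tract", "start", "end", "length")
  if (!all(need %in% names(tr)))
    return(paste("tracts must have columns", paste(need, collapse = ", ")))
  if (nrow(tr)) {
    s <- as.character(object@seq)
    for (i in seq_len(nrow(tr))) {
      run <- substring(s, tr$start[i], tr$end[i])
      if (gsub("G", "", run) != "")
        msg <- c(msg, sprintf("tract %d positions %d-%d contain non-G bases",
                              tr$tract[i], tr$start[i], tr$end[i]))
    }
    if (any(tr$length < 2)) msg <- c(msg, "G-tracts must have length >= 2")
    if (is.unsorted(tr$start, strictly = TRUE))
      msg <- c(msg, "tracts must be in ascending order")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Assigned NOESY cross-peak table
#'
#' Canonical container for assigned NOESY cross-peak intensities: one row per
#' (atom pair, mixing time, condition). Pairs are stored canonically (lower
#' (residue, atom) first); the physically meaningful direction of
#' imino-to-aromatic connectivities is carried by the atom types themselves.
#'
#' @slot peaks data.frame with columns `res1`, `base1`, `atom1`, `res2`,
#'   `base2`, `atom2`, `mixing_time` (ms), `intensity` (arbitrary units,
#'   non-negative), `condition` (one of `"na"`, `"k"`, `"na_k_mixed"`).
#' @slot source character scalar: file path or `"synthetic"`.
#' @seealso [readPeakList()], [writePeakList()], [genNoesyPeaks()]
#' @exportClass NOESYPeakTable
setClass("NOESYPeakTable",
         representation(peaks = "data.frame", source = "character"))

setValidity("NOESYPeakTable", function(object) {
  pk <- object@peaks
  if (!all(.PEAK_COLS %in% names(pk)))
    return(paste("peaks must have columns", paste(.PEAK_COLS, collapse = ", ")))
  msg <- character()
  if (nrow(pk)) {
    if (any(pk$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
    if (!all(pk$atom1 %in% .VALID_ATOMS) || !all(pk$atom2 %in% .VALID_ATOMS))
      msg <- c(msg, paste("atoms must be one of",
                          paste(.VALID_ATOMS, collapse = ", ")))
    if (!all(pk$condition %in% .VALID_CONDITIONS))
      msg <- c(msg, paste("condition must be one of",
                          paste(.VALID_CONDITIONS, collapse = ", ")))
    key <- paste(pk$res1, pk$atom1, pk$res2, pk$atom2,
                 pk$mixing_time, pk$condition)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (pair, mixing_time, condition) rows")
    swapped <- pk$res1 > pk$res2 |
      (pk$res1 == pk$res2 & pk$atom1 > pk$atom2)
    if (any(swapped))
      msg <- c(msg, "pairs are not stored canonically")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-residue imino-proton titration series
#'
#' Normalized (or raw) imino-proton intensity of one residue as a function of
#' added cation concentration, tracking either the disappearing Na+-form
#' signal or the appearing K+-form signal.
#'
#' @slot residue integer residue index (1-based).
#' @slot atom character, the observed proton (imino `"H1"`).
#' @slot form `"na_form"` or `"k_form"`.
#' @slot conc numeric, non-negative, strictly increasing concentrations.
#' @slot intensity numeric, same length as `conc`.
#' @slot conc_unit `"mM"` (default) or `"M"`.
#' @slot normalized logical; TRUE once [normalizeSeries()] has anchored the
#'   series to the fractional 0-1 scale.
#' @slot norm_anchors numeric; the zero-titrant and plateau intensities used
#'   for normalization (empty until normalized).
#' @seealso [TitrationSeries()], [normalizeSeries()], [fitExchange()]
#' @exportClass TitrationSeries
setClass("TitrationSeries",
         representation(residue = "integer", atom = "character",
                        form = "character", conc = "numeric",
                        intensity = "numeric", conc_unit = "character",
                        normalized = "logical", norm_anchors = "numeric"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@conc) != length(object@intensity))
    msg <- c(msg, "conc and intensity lengths differ")
  if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (is.unsorted(object@conc, strictly = TRUE))
    msg <- c(msg, "concentrations must be strictly increasing")
  if (!object@form %in% c("na_form", "k_form"))
    msg <- c(msg, "form must be 'na_form' or 'k_form'")
  if (!object@conc_unit %in% c("mM", "M"))
    msg <- c(msg, "conc_unit must be 'mM' or 'M'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Time-resolved kinetic trace
#'
#' A single kinetic observable versus time: an HDX imino decay, a
#' hybridization-trap decay/rise, or a real-time CD conversion signal.
#'
#' @slot times numeric, strictly increasing.
#' @slot signal numeric, same length as `times`.
#' @slot kind `"hdx"`, `"hybridization"` or `"cd_conversion"`.
#' @slot time_unit `"s"` or `"min"`.
#' @slot dead_time numeric scalar, same unit as `times`; points earlier than
#'   this are excluded from fitting (default 0).
#' @seealso [KineticTrace()], [fitMonoexp()], [fitBiexp()]
#' @exportClass KineticTrace
setClass("KineticTrace",
         representation(times = "numeric", signal = "numeric",
                        kind = "character", time_unit = "character",
                        dead_time = "numeric"))

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@signal))
    msg <- c(msg, "times and signal lengths differ")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (!object@kind %in% c("hdx", "hybridization", "cd_conversion"))
    msg <- c(msg, "kind must be hdx, hybridization or cd_conversion")
  if (!object@time_unit %in% c("s", "min"))
    msg <- c(msg, "time_unit must be 's' or 'min'")
  if (object@dead_time < 0) msg <- c(msg, "dead_time must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' CD melting curve
#'
#' Ellipticity versus temperature at a fixed monitoring wavelength
#' (295 nm for G-quadruplexes).
#'
#' @slot temperature numeric degrees Celsius, strictly increasing, in
#'   \[0, 110\].
#' @slot ellipticity numeric millidegrees, same length.
#' @slot wavelength numeric nm (metadata; default 295).
#' @seealso [MeltingCurve()], [extractTm()], [fitTwoState()]
#' @exportClass MeltingCurve
setClass("MeltingCurve",
         representation(temperature = "numeric", ellipticity = "numeric",
                        wavelength = "numeric"))

setValidity("MeltingCurve", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@ellipticity))
    msg <- c(msg, "temperature and ellipticity lengths differ")
  if (is.unsorted(object@temperature, strictly = TRUE))
    msg <- c(msg, "temperatures must be strictly increasing")
  if (length(object@temperature) &&
      (min(object@temperature) < 0 || max(object@temperature) > 110))
    msg <- c(msg, "temperatures must lie within [0, 110] degC")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Fitted stepwise exchange constants for one residue
#'
#' Result of fitting the three-state stepwise cation-exchange isotherm to a
#' pair of titration series (Na+-form disappearance, K+-form appearance).
#' Equilibrium constants are reported per molar.
#'
#' @slot residue integer residue index.
#' @slot atom character observed proton.
#' @slot K1,K2 numeric stepwise equilibrium constants (1/M).
#' @slot stderr_K1,stderr_K2 numeric standard errors (1/M; NA if the
#'   covariance was singular).
#' @slot rss numeric residual sum of squares of the joint fit.
#' @slot n_points integer number of fitted points (both series).
#' @slot mode `"joint"` or `"sequential"`.
#' @slot flags character; e.g. `"boundary_K1"` when an estimate is pinned at
#'   a box bound.
#' @seealso [fitExchange()], [speciesFractions()]
#' @exportClass ExchangeFit
setClass("ExchangeFit",
         representation(residue = "integer", atom = "character",
                        K1 = "numeric", K2 = "numeric",
                        stderr_K1 = "numeric", stderr_K2 = "numeric",
                        rss = "numeric", n_points = "integer",
                        mode = "character", flags = "character"))

setValidity("ExchangeFit", function(object) {
  msg <- character()
  if (!is.na(object@K1) && object@K1 <= 0) msg <- c(msg, "K1 must be > 0")
  if (!is.na(object@K2) && object@K2 <= 0) msg <- c(msg, "K2 must be > 0")
  if (!is.na(object@rss) && object@rss < 0) msg <- c(msg, "rss must be >= 0")
  ok <- function(s) is.na(s) || s >= 0
  if (!ok(object@stderr_K1) || !ok(object@stderr_K2))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Mono- or bi-exponential kinetic fit
#'
#' Fit of `S(t) = offset + A * sum_i f_i * exp(-t / tau_i)` with `sum f_i = 1`
#' and `A` signed (negative for rising signals, so `offset` is the plateau).
#'
#' @slot model `"mono"` or `"bi"`.
#' @slot taus numeric time constants, ascending, in `time_unit`.
#' @slot amp_fracs numeric amplitude fractions matching `taus` (length 1 for
#'   mono; sums to 1).
#' @slot amp_total numeric signed total amplitude `A` in signal units.
#' @slot offset numeric baseline/plateau in signal units.
#' @slot r2 numeric coefficient of determination over the fitted range.
#' @slot stderr_taus numeric standard errors of `taus` (NA if unavailable).
#' @slot time_unit `"s"` or `"min"`.
#' @slot flags character; e.g. `"no_decay"`, `"degenerate_taus"`.
#' @seealso [fitMonoexp()], [fitBiexp()], [timeConstants()]
#' @exportClass KineticFit
setClass("KineticFit",
         representation(model = "character", taus = "numeric",
                        amp_fracs = "numeric", amp_total = "numeric",
                        offset = "numeric", r2 = "numeric",
                        stderr_taus = "numeric", time_unit = "character",
                        flags = "character"))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (!object@model %in% c("mono", "bi"))
    msg <- c(msg, "model must be 'mono' or 'bi'")
  tt <- object@taus[!is.na(object@taus)]
  if (any(tt <= 0)) msg <- c(msg, "taus must be > 0")
  if (is.unsorted(object@taus, na.rm = TRUE))
    msg <- c(msg, "taus must be ascending")
  f <- object@amp_fracs
  if (length(f) && !anyNA(f) && abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "amplitude fractions must sum to 1")
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must be <= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Melting-temperature result
#'
#' @slot tm numeric melting temperature, degrees Celsius.
#' @slot dheight numeric absolute height of the derivative extremum of the
#'   folded fraction (1/degC; NA for the two-state fit).
#' @slot width numeric transition width parameter of the two-state fit
#'   (degC; NA for the derivative method).
#' @slot method `"derivative"` or `"two_state_fit"`.
#' @seealso [extractTm()], [fitTwoState()]
#' @exportClass MeltingResult
setClass("MeltingResult",
         representation(tm = "numeric", dheight = "numeric",
                        width = "numeric", method = "character"))

#' Inferred G-quadruplex topology
#'
#' @slot tetrads data.frame with one row per tetrad: columns `layer`
#'   (`top`/`central`/`bottom`), `sense` (`clockwise`/`anticlockwise`) and
#'   `g1`..`g4`, the guanine residues in imino-to-aromatic (H1 -> H8)
#'   connectivity order starting from the first G-tract's member.
#' @slot orientations named character, per-tract `"up"`/`"down"` strand
#'   direction (first tract anchored `"up"`).
#' @slot loops character loop taxonomy in sequence order:
#'   `"double-chain-reversal"`, `"lateral"`, `"diagonal"` (or
#'   `"unclassified"`).
#' @slot glycosidic data.frame of per-residue syn/anti calls (see
#'   [classifyGlycosidic()]).
#' @slot ring integer cyclic order of tracts around the tetrad core.
#' @slot label fold label: `"parallel propeller"`, `"antiparallel basket"`,
#'   `"antiparallel chair"`, `"hybrid-I (3+1)"`, `"hybrid-II (3+1)"`,
#'   `"(2+2)"` or `"unclassified"`.
#' @seealso [inferTopology()], [classifyTopology()]
#' @exportClass TopologyModel
setClass("TopologyModel",
         representation(tetrads = "data.frame", orientations = "character",
                        loops = "character", glycosidic = "data.frame",
                        ring = "integer", label = "character"))

setValidity("TopologyModel", function(object) {
  msg <- character()
  n_tracts <- length(object@orientations)
  if (n_tracts && length(object@loops) != n_tracts - 1)
    msg <- c(msg, "a model with n tracts must have n - 1 loops")
  if (length(object@orientations) &&
      !all(object@orientations %in% c("up", "down")))
    msg <- c(msg, "orientations must be 'up' or 'down'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
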