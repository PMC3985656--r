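# Run code under a temporary RNG seed, restoring global RNG state after.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Canonical fold definitions on a four-tract, three-tetrad scaffold.
# orient: per-tract strand direction; ring: cyclic spatial order of tracts
# around the tetrad core; senses: rotational sense of each layer's
# imino->aromatic connectivity cycle; maj: majority glycosidic state per
# layer (the antiparallel minority tract takes the opposite state).
.CANONICAL_FOLDS <- list(
  "hybrid-I" = list(
    orient = c("up", "up", "down", "up"), ring = c(1L, 2L, 3L, 4L),
    senses = c(top = "anticlockwise", central = "clockwise",
               bottom = "clockwise"),
    maj = c(top = "syn", central = "anti", bottom = "anti")),
  "hybrid-II" = list(
    orient = c("up", "down", "up", "up"), ring = c(1L, 2L, 3L, 4L),
    senses = c(top = "clockwise", central = "clockwise",
               bottom = "clockwise"),
    maj = c(top = "anti", central = "anti", bottom = "anti")),
  "propeller" = list(
    orient = c("up", "up", "up", "up"), ring = c(1L, 2L, 3L, 4L),
    senses = c(top = "clockwise", central = "clockwise",
               bottom = "clockwise"),
    maj = c(top = "anti", central = "anti", bottom = "anti")),
  "basket" = list(
    orient = c("up", "down", "up", "down"), ring = c(1L, 2L, 4L, 3L),
    senses = c(top = "clockwise", central = "clockwise",
               bottom = "clockwise"),
    maj = c(top = "anti", central = "anti", bottom = "anti")),
  "chair" = list(
    orient = c("up", "down", "up", "down"), ring = c(1L, 2L, 3L, 4L),
    senses = c(top = "clockwise", central = "clockwise",
               bottom = "clockwise"),
    maj = c(top = "anti", central = "anti", bottom = "anti")))

#' Names of the canonical topology presets
#' @return character vector of fold labels accepted by [genNoesyPeaks()].
#' @export
canonicalTopologies <- function() names(.CANONICAL_FOLDS)

# residue occupying layer l (1=top, 2=central, 3=bottom) of tract t
.layerMember <- function(tracts, t, l, orient) {
  if (orient[t] == "up") tracts$start[t] + (l - 1L)
  else tracts$end[t] - (l - 1L)
}

# build the structural model (tetrad cycles, members, glycosidic states)
# for a canonical fold on a given sequence
.canonicalModel <- function(fold, seq) {
  spec <- .CANONICAL_FOLDS[[fold]]
  if (is.null(spec))
    stop("unknown topology '", fold, "'; available: ",
         paste(canonicalTopologies(), collapse = ", "))
  tracts <- gTracts(seq)
  if (nrow(tracts) != 4L || any(tracts$length < 3L))
    stop("canonical folds need 4 G-tracts of length >= 3")
  layers <- c("top", "central", "bottom")
  members <- sapply(1:3, function(l)
    vapply(1:4, function(t) .layerMember(tracts, t, l, spec$orient),
           integer(1)))  # 4 tracts x 3 layers
  cycles <- lapply(1:3, function(l) {
    tr_seq <- if (spec$senses[[layers[l]]] == "clockwise") spec$ring
              else spec$ring[c(1, 4, 3, 2)]
    members[tr_seq, l]
  })
  glyco <- list()
  flipped <- which(spec$orient == "down")
  for (l in 1:3) {
    st <- rep(spec$maj[[layers[l]]], 4)
    st[flipped] <- setdiff(c("syn", "anti"), spec$maj[[layers[l]]])
    glyco[[layers[l]]] <- stats::setNames(st, members[, l])
  }
  list(spec = spec, members = members, cycles = cycles, glyco = glyco,
       layers = layers)
}

# distance moments (mean, sd) per pair class and condition, matching the
# reported tetrad stacking statistics
.DIST_MOMENTS <- list(
  na = list(h8h1 = c(5.1, 0.2), h1h1 = c(4.9, 0.6)),
  k = list(h8h1 = c(4.6, 0.4), h1h1 = c(4.3, 0.3)),
  na_k_mixed = list(h8h1 = c(4.3, 0.4), h1h1 = c(4.0, 0.3)))

#' Generate a synthetic assigned NOESY peak table
#'
#' Emits the cross-peak pattern of a canonical G-quadruplex fold: directed
#' inter-guanine imino-aromatic (H1 -> H8) peaks tracing each tetrad cycle,
#' intra-tetrad and inter-tetrad imino-imino (H1-H1) peaks, intra-residue
#' H1'-H8 peaks encoding the syn/anti glycosidic pattern (2.5 vs 3.7
#' Angstrom), a few loop-residue contacts, and the thymine H6-CH3 reference
#' pair at 2.99 Angstrom. Intensities follow the r^-6 law with linear
#' buildup across the mixing times, so inverting the calibration recovers
#' the generating distances exactly in the noiseless case.
#'
#' The Tel23 scenarios draw tetrad distances from the per-class moments of
#' the corresponding cation condition (Na+ form: 5.1 +/- 0.2 Angstrom
#' H8-H1, 4.9 +/- 0.6 H1-H1; K+ form: 4.6 +/- 0.4, 4.3 +/- 0.3; mixed form
#' 4.3 +/- 0.4, 4.0 +/- 0.3); canonical-topology mode uses the fixed class
#' means (no structural jitter).
#'
#' @param scenario `"tel23_noesy_na"`, `"tel23_noesy_k"`,
#'   `"tel23_noesy_mixed"`, or NULL when `topology` or `distances` is given.
#' @param topology canonical fold label (see [canonicalTopologies()]).
#' @param seq the [G4Sequence-class] scaffold (default [tel23Sequence()]).
#' @param distances optional data.frame (`res1`, `atom1`, `res2`, `atom2`,
#'   `r`) to emit directly instead of a fold pattern.
#' @param seed integer seed recorded in the output metadata.
#' @param noise_sd multiplicative intensity noise (fraction; default 0).
#' @param mixing_times numeric mixing times in ms.
#' @param condition condition label (defaults to the scenario's).
#' @param minor_peaks logical; add weak spurious imino-aromatic peaks at 3
#'   percent of the median intensity, emulating a minor conformation.
#' @return a [NOESYPeakTable-class]; attributes `seed` and `config` record
#'   provenance.
#' @export
genNoesyPeaks <- function(scenario = NULL, topology = NULL,
                          seq = tel23Sequence(), distances = NULL,
                          seed = NULL, noise_sd = 0,
                          mixing_times = c(50, 100, 150, 200),
                          condition = NULL, minor_peaks = FALSE) {
  jitter <- FALSE
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("tel23_noesy_na", "tel23_noesy_k",
                                      "tel23_noesy_mixed"))
    topology <- "hybrid-I"
    condition <- switch(scenario, tel23_noesy_na = "na", tel23_noesy_k = "k",
                        tel23_noesy_mixed = "na_k_mixed")
    jitter <- TRUE
  }
  if (is.null(condition)) condition <- "na"
  moments <- .DIST_MOMENTS[[condition]]

  .withSeed(seed, {
    if (is.null(distances)) {
      if (is.null(topology))
        stop("supply one of scenario, topology or distances")
      model <- .canonicalModel(topology, seq)
      draw <- function(n, m)
        if (jitter) stats::rnorm(n, m[1], m[2]) else rep(m[1], n)
      rows <- list()
      add <- function(r1, a1, r2, a2, r)
        rows[[length(rows) + 1L]] <<- data.frame(res1 = r1, atom1 = a1,
                                                 res2 = r2, atom2 = a2, r = r)
      for (l in 1:3) {
        cy <- model$cycles[[l]]
        d_hh <- draw(4, moments$h8h1)
        d_ii <- draw(4, moments$h1h1)
        for (i in 1:4) {
          j <- i %% 4L + 1L
          add(cy[i], "H1", cy[j], "H8", d_hh[i])   # directed tetrad cycle
          add(cy[i], "H1", cy[j], "H1", d_ii[i])   # intra-tetrad imino-imino
        }
      }
      for (l in 1:2) for (t in 1:4)                 # inter-tetrad stacking
        add(model$members[t, l], "H1", model$members[t, l + 1L], "H1",
            draw(1, moments$h1h1))
      for (l in 1:3) {                              # glycosidic evidence
        g <- model$glyco[[l]]
        for (res in as.integer(names(g)))
          add(res, "H1'", res, "H8",
              if (g[[as.character(res)]] == "syn") 2.5 else 3.7)
      }
      # a few loop thymine-thymine contacts
      lr <- loopResidues(seq)
      tt <- lr[residueBase(seq, lr) == "T" &
                 residueBase(seq, pmin(lr + 1L, length(seq))) == "T" &
                 (lr + 1L) %in% lr]
      for (res in utils::head(tt, 2L))
        add(res, "H6", res + 1L, "H6", 4.5)
      distances <- do.call(rbind, rows)
    }
    ref_res <- which(residueBase(seq) == "T")[1]
    if (is.na(ref_res)) stop("sequence has no thymine for the reference pair")
    distances <- rbind(distances,
                       data.frame(res1 = ref_res, atom1 = "H6",
                                  res2 = ref_res, atom2 = "CH3", r = 2.99))
    base1 <- residueBase(seq, distances$res1)
    base2 <- residueBase(seq, distances$res2)
    ref_slope <- 40  # intensity units per ms for the 2.99 A reference
    slope <- ref_slope * (2.99 / distances$r)^6
    pk <- do.call(rbind, lapply(seq_along(mixing_times), function(i) {
      I <- slope * mixing_times[i]
      if (noise_sd > 0) I <- pmax(I * (1 + stats::rnorm(length(I), 0, noise_sd)), 0)
      data.frame(res1 = distances$res1, base1 = base1, atom1 = distances$atom1,
                 res2 = distances$res2, base2 = base2, atom2 = distances$atom2,
                 mixing_time = mixing_times[i], intensity = I,
                 condition = condition)
    }))
    if (minor_peaks && !is.null(topology)) {
      model <- .canonicalModel(topology, seq)
      weak <- 0.03 * stats::median(pk$intensity[pk$atom1 %in% c("H1", "H8") &
                                                  pk$atom2 %in% c("H1", "H8")])
      extra <- data.frame(
        res1 = c(model$members[1, 1], model$members[2, 1]), base1 = "G",
        atom1 = "H1",
        res2 = c(model$members[2, 2], model$members[3, 3]), base2 = "G",
        atom2 = "H8",
        mixing_time = mixing_times[1], intensity = weak,
        condition = condition)
      pk <- rbind(pk, extra)
    }
    out <- NOESYPeakTable(pk, source = "synthetic")
    attr(out, "seed") <- seed
    attr(out, "config") <- list(scenario = scenario, topology = topology,
                                condition = condition, noise_sd = noise_sd)
    out
  })
}

#' Generate a synthetic cation titration for one residue
#'
#' Produces the paired observables of an imino-proton NMR titration: the
#' disappearing Na+-form fraction `fa(x)` and the appearing K+-form fraction
#' `fc(x)` of the stepwise exchange model (see [speciesFractions()]), on a
#' concentration grid, plus Gaussian noise. The defaults are the constants
#' fitted for residue G22 of Tel23 (K1 = 59.7, K2 = 2.7 per molar) on a
#' 0-150 mM grid. A per-residue first-step multiplier emulates the
#' bottom-tetrad lag (bottom-layer residues exchange their lower cation
#' site 2- to 5-fold more reluctantly).
#'
#' @param residue residue index (default 22).
#' @param k1,k2 generating stepwise constants, per molar.
#' @param k1_multiplier multiplier applied to `k1` (default 1).
#' @param conc concentration grid in `conc_unit` (default 0-150 mM, 5 mM
#'   step).
#' @param conc_unit `"mM"` (default) or `"M"`.
#' @param noise_sd Gaussian noise SD on the fractional scale (default 0).
#' @param seed integer seed.
#' @return list with elements `na` and `k` ([TitrationSeries-class],
#'   normalized scale); attributes `seed` and `config`.
#' @examples
#' sim <- genTitration(noise_sd = 0)
#' exchangeConstants(fitExchange(sim$na, sim$k))
#' @export
genTitration <- function(residue = 22, k1 = 59.7, k2 = 2.7,
                         k1_multiplier = 1, conc = seq(0, 150, by = 5),
                         conc_unit = "mM", noise_sd = 0, seed = NULL) {
  stopifnot(k1 > 0, k2 > 0, k1_multiplier > 0, noise_sd >= 0)
  .withSeed(seed, {
    x <- if (conc_unit == "mM") conc / 1000 else conc
    fr <- speciesFractions(k1 * k1_multiplier, k2, x)
    y_na <- fr$fa + stats::rnorm(length(x), 0, noise_sd)
    y_k <- fr$fc + stats::rnorm(length(x), 0, noise_sd)
    out <- list(
      na = TitrationSeries(conc, y_na, form = "na_form", residue = residue,
                           conc_unit = conc_unit, normalized = TRUE),
      k = TitrationSeries(conc, y_k, form = "k_form", residue = residue,
                          conc_unit = conc_unit, normalized = TRUE))
    attr(out, "seed") <- seed
    attr(out, "config") <- list(k1 = k1 * k1_multiplier, k2 = k2,
                                conc_unit = conc_unit, noise_sd = noise_sd)
    out
  })
}

.KINETIC_PRESETS <- list(
  tel23_hdx_na = list(kind = "hdx", model = "mono", taus = 14,
                      times = seq(0, 120, by = 5), unit = "min",
                      direction = "decay"),
  tel23_hdx_nak = list(kind = "hdx", model = "mono", taus = 136,
                       times = seq(0, 600, by = 10), unit = "min",
                       direction = "decay"),
  tel23_cd_conversion = list(kind = "cd_conversion", model = "bi",
                             taus = c(80, 930), fracs = c(0.89, 0.11),
                             times = seq(0, 3600, by = 5), unit = "s",
                             direction = "rise"))

.HYBRIDIZATION_TAUS <- c(na = 17, na_k_simultaneous = 127,
                         na_k_pretreat = 130)

#' Generate synthetic kinetic traces
#'
#' Scenario presets reproduce the study conditions: `tel23_hdx_na`
#' (mono-exponential HDX imino decay, time constant 14 min, sampled every
#' 5 min to 120 min), `tel23_hdx_nak` (simultaneous Na+/K+ HDX, 136 min,
#' every 10 min to 600 min), `tel23_cd_conversion` (bi-exponential 265 nm
#' CD rise, 80 s at 89 percent amplitude plus 930 s at 11 percent, every
#' 5 s to 3600 s) and `tel23_hybridization` (paired traces: the G4 imino
#' decay and the Watson-Crick imino rise sharing one time constant; 17,
#' 127 or 130 min depending on `condition`).
#'
#' @param scenario one of `"tel23_hdx_na"`, `"tel23_hdx_nak"`,
#'   `"tel23_cd_conversion"`, `"tel23_hybridization"`.
#' @param condition for the hybridization scenario: `"na"`,
#'   `"na_k_simultaneous"` (default) or `"na_k_pretreat"`.
#' @param n_traces number of replicate traces (e.g. one per monitored
#'   residue).
#' @param noise_sd Gaussian noise SD as a fraction of the amplitude.
#' @param seed integer seed.
#' @param times,taus,fracs,dead_time optional overrides of the preset grid
#'   and parameters.
#' @return with `n_traces = 1` a single [KineticTrace-class] (for
#'   hybridization, a list with `decay` and `rise`); otherwise a list of
#'   `n_traces` such elements. Attributes `seed` and `config` record
#'   provenance.
#' @examples
#' tr <- genKineticTrace("tel23_cd_conversion")
#' timeConstants(fitBiexp(tr))
#' @export
genKineticTrace <- function(scenario, condition = "na_k_simultaneous",
                            n_traces = 1, noise_sd = 0, seed = NULL,
                            times = NULL, taus = NULL, fracs = NULL,
                            dead_time = 0) {
  scenario <- match.arg(scenario, c(names(.KINETIC_PRESETS),
                                    "tel23_hybridization"))
  .withSeed(seed, {
    if (scenario == "tel23_hybridization") {
      condition <- match.arg(condition, names(.HYBRIDIZATION_TAUS))
      tau <- if (is.null(taus)) .HYBRIDIZATION_TAUS[[condition]] else taus[1]
      tt <- if (is.null(times)) seq(0, 600, by = 10) else times
      one <- function() {
        eps <- function() stats::rnorm(length(tt), 0, noise_sd)
        list(decay = KineticTrace(tt, exp(-tt / tau) + eps(),
                                  kind = "hybridization", time_unit = "min",
                                  dead_time = dead_time),
             rise = KineticTrace(tt, 1 - exp(-tt / tau) + eps(),
                                 kind = "hybridization", time_unit = "min",
                                 dead_time = dead_time))
      }
      out <- if (n_traces == 1L) one() else replicate(n_traces, one(),
                                                      simplify = FALSE)
      attr(out, "seed") <- seed
      attr(out, "config") <- list(scenario = scenario, condition = condition,
                                  tau = tau, noise_sd = noise_sd)
      return(out)
    }
    preset <- .KINETIC_PRESETS[[scenario]]
    if (is.null(times)) times <- preset$times
    if (is.null(taus)) taus <- preset$taus
    if (is.null(fracs)) fracs <- if (is.null(preset$fracs)) 1 else preset$fracs
    decay_part <- function()
      rowSums(vapply(seq_along(taus),
                     function(i) fracs[i] * exp(-times / taus[i]),
                     numeric(length(times))))
    one <- function() {
      core <- decay_part()
      y <- if (preset$direction == "decay") core else 1 - core
      if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
      KineticTrace(times, y, kind = preset$kind, time_unit = preset$unit,
                   dead_time = dead_time)
    }
    out <- if (n_traces == 1L) one() else replicate(n_traces, one(),
                                                    simplify = FALSE)
    attr(out, "seed") <- seed
    attr(out, "config") <- list(scenario = scenario, taus = taus,
                                fracs = fracs, noise_sd = noise_sd)
    out
  })
}

#' Generate a synthetic CD melting curve
#'
#' Two-state sigmoid with linear folded/unfolded baselines on the standard
#' 25-95 degC grid at 295 nm. Presets set the midpoint to the measured Tm
#' of the Tel23 K+ form (68.9 degC) or Na+ form (59.3 degC); the transition
#' width defaults to 2.5 degC (a van't Hoff enthalpy of roughly 50
#' kcal/mol at these midpoints).
#'
#' @param scenario `"tel23_melting_k"` or `"tel23_melting_na"` (ignored
#'   when `tm` is given).
#' @param tm optional midpoint override, degC.
#' @param width transition width parameter, degC (default 2.5).
#' @param temps temperature grid, degC.
#' @param baseline_f,baseline_u intercept/slope of the folded and unfolded
#'   ellipticity baselines (millidegrees).
#' @param noise_sd Gaussian noise SD as a fraction of the transition
#'   amplitude at the midpoint.
#' @param seed integer seed.
#' @return a [MeltingCurve-class]; attributes `seed` and `config`.
#' @examples
#' meltingTm(extractTm(genMeltingCurve("tel23_melting_k")))
#' @export
genMeltingCurve <- function(scenario = c("tel23_melting_k",
                                         "tel23_melting_na"),
                            tm = NULL, width = 2.5,
                            temps = seq(25, 95, by = 0.5),
                            baseline_f = c(8, -0.02),
                            baseline_u = c(0.5, -0.005),
                            noise_sd = 0, seed = NULL) {
  if (is.null(tm)) {
    scenario <- match.arg(scenario)
    tm <- switch(scenario, tel23_melting_k = 68.9, tel23_melting_na = 59.3)
  }
  if (tm < min(temps) || tm > max(temps))
    warning("midpoint ", tm, " degC lies outside the temperature grid")
  .withSeed(seed, {
    bf <- baseline_f[1] + baseline_f[2] * temps
    bu <- baseline_u[1] + baseline_u[2] * temps
    frac <- 1 / (1 + exp((temps - tm) / width))
    y <- bu + (bf - bu) * frac
    if (noise_sd > 0) {
      amp <- (baseline_f[1] + baseline_f[2] * tm) -
        (baseline_u[1] + baseline_u[2] * tm)
      y <- y + stats::rnorm(length(temps), 0, noise_sd * abs(amp))
    }
    out <- MeltingCurve(temps, y)
    attr(out, "seed") <- seed
    attr(out, "config") <- list(tm = tm, width = width, noise_sd = noise_sd)
    out
  })
}
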