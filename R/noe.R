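#' Initial slope of an NOE buildup series
#'
#' In the initial-rate regime the NOESY cross-peak intensity grows linearly
#' with mixing time, so the initial slope is estimated by an
#' origin-constrained least-squares line through the (mixing time,
#' intensity) points. A curvature guard protects against spin-diffusion
#' flattening at long mixing times: while any retained point deviates from
#' the origin line by more than `curvature_tol` of its own intensity, the
#' longest mixing time is dropped (never below 2 points). A single-point
#' series falls back to `intensity / mixing_time` with a `"single_point"`
#' flag (the non-exchangeable-proton NOESY recorded at one 200 ms mixing
#' time takes this path).
#'
#' @param mixing_times numeric mixing times (ms).
#' @param intensities numeric intensities (>= 0), same length.
#' @param curvature_tol maximum tolerated relative residual per point
#'   (default 0.05).
#' @return list with `slope` (intensity per ms), `n_used`, and `flags`
#'   (`"single_point"`, `"zero_slope"`, `"curvature_dropped"`).
#' @examples
#' buildupSlope(c(50, 100, 150, 200), 3 * c(50, 100, 150, 200))$slope  # 3
#' @export
buildupSlope <- function(mixing_times, intensities, curvature_tol = 0.05) {
  stopifnot(length(mixing_times) == length(intensities),
            length(mixing_times) >= 1L)
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (any(mixing_times <= 0)) stop("mixing times must be > 0")
  ord <- order(mixing_times)
  tm <- mixing_times[ord]; I <- intensities[ord]
  if (all(I == 0))
    return(list(slope = 0, n_used = length(tm), flags = "zero_slope"))
  if (length(tm) == 1L)
    return(list(slope = I / tm, n_used = 1L, flags = "single_point"))
  flags <- character()
  repeat {
    slope <- sum(tm * I) / sum(tm^2)
    rel <- abs(slope * tm - I) / pmax(I, 1e-12 * max(I))
    if (length(tm) <= 2L || max(rel) <= curvature_tol) break
    tm <- tm[-length(tm)]; I <- I[-length(I)]
    flags <- union(flags, "curvature_dropped")
  }
  list(slope = slope, n_used = length(tm), flags = flags)
}

#' Calibrate an inter-proton distance from NOE buildup slopes
#'
#' Under the isolated spin-pair approximation the NOE buildup rate scales as
#' the inverse sixth power of the inter-proton distance, so a distance
#' follows from a single reference pair of known geometry:
#' \deqn{r = r_{ref} \, (s_{ref} / s)^{1/6}.}
#' The conventional reference is the thymine H6-CH3 pair at 2.99 Angstrom.
#'
#' @param slope buildup initial slope of the query pair (> 0).
#' @param ref_slope buildup initial slope of the reference pair (> 0).
#' @param ref_distance reference distance in Angstrom (default 2.99).
#' @return distance in Angstrom.
#' @examples
#' calibrateDistance(1, 1)        # 2.99
#' calibrateDistance(1 / 64, 1)   # 5.98: 64-fold weaker NOE = twice as far
#' @export
calibrateDistance <- function(slope, ref_slope, ref_distance = 2.99) {
  if (any(slope <= 0) || any(ref_slope <= 0))
    stop("slopes must be > 0 for distance calibration")
  ref_distance * (ref_slope / slope)^(1 / 6)
}

# classify an atom pair given sequence context and an optional layer map
.pairClass <- function(res1, atom1, res2, atom2, seq, layer_of = NULL) {
  base1 <- residueBase(seq, res1); base2 <- residueBase(seq, res2)
  atoms <- c(atom1, atom2)
  in_loop <- any(c(res1, res2) %in% loopResidues(seq))
  if (setequal(atoms, c("H1", "H8")) && base1 == "G" && base2 == "G" &&
      res1 != res2) {
    if (!is.null(layer_of)) {
      l1 <- layer_of[as.character(res1)]; l2 <- layer_of[as.character(res2)]
      if (!is.na(l1) && !is.na(l2) && l1 == l2) return("H8-H1 intra-tetrad")
    } else {
      return("H8-H1 intra-tetrad")
    }
    return("other")
  }
  if (all(atoms == "H1")) return("H1-H1")
  if (setequal(atoms, c("H1'", "H8"))) return("H1'-H8")
  if (in_loop) return("loop")
  "other"
}

#' Estimate calibrated distances for every pair in a peak table
#'
#' Groups the peak table by (pair, condition), estimates each pair's buildup
#' initial slope ([buildupSlope()]), and calibrates distances against the
#' reference pair's slope in the same condition ([calibrateDistance()]).
#' Pairs are classified as `"H8-H1 intra-tetrad"` (guanine imino-aromatic
#' within one tetrad layer when a layer map is supplied), `"H1-H1"`,
#' `"H1'-H8"`, `"loop"` or `"other"`.
#'
#' @param x a [NOESYPeakTable-class].
#' @param seq the [G4Sequence-class] the assignments refer to.
#' @param ref_pair list with `res`, `atom1`, `atom2` identifying the
#'   reference pair (default thymine 1 H6-CH3).
#' @param ref_distance reference distance in Angstrom (default 2.99).
#' @param tetrad_map optional named character vector residue -> layer used to
#'   restrict the intra-tetrad class; without it any inter-guanine H1/H8
#'   pair counts as intra-tetrad.
#' @return data.frame with columns `res1`, `atom1`, `res2`, `atom2`,
#'   `condition`, `slope`, `r` (Angstrom), `class`, `flags`.
#' @export
estimateDistances <- function(x, seq,
                              ref_pair = list(res = 1, atom1 = "H6",
                                              atom2 = "CH3"),
                              ref_distance = 2.99, tetrad_map = NULL) {
  stopifnot(is(x, "NOESYPeakTable"), is(seq, "G4Sequence"))
  pk <- peaks(x)
  if (!nrow(pk)) stop("empty peak table")
  pk$pair_id <- paste(pk$res1, pk$atom1, pk$res2, pk$atom2, pk$condition,
                      sep = "|")
  is_ref <- pk$res1 == ref_pair$res & pk$res2 == ref_pair$res &
    ((pk$atom1 == ref_pair$atom1 & pk$atom2 == ref_pair$atom2) |
     (pk$atom1 == ref_pair$atom2 & pk$atom2 == ref_pair$atom1))
  if (!any(is_ref))
    stop("reference pair not found in peak table")
  ref_slopes <- new.env()
  for (cond in unique(pk$condition[is_ref])) {
    sub <- pk[is_ref & pk$condition == cond, ]
    assign(cond, buildupSlope(sub$mixing_time, sub$intensity)$slope,
           envir = ref_slopes)
  }
  out <- lapply(split(pk[!is_ref, ], pk$pair_id[!is_ref]), function(sub) {
    cond <- sub$condition[1]
    rs <- if (exists(cond, envir = ref_slopes)) get(cond, envir = ref_slopes)
          else get(ls(ref_slopes)[1], envir = ref_slopes)
    bs <- buildupSlope(sub$mixing_time, sub$intensity)
    r <- if (bs$slope > 0) calibrateDistance(bs$slope, rs, ref_distance)
         else NA_real_
    data.frame(res1 = sub$res1[1], atom1 = sub$atom1[1],
               res2 = sub$res2[1], atom2 = sub$atom2[1],
               condition = cond, slope = bs$slope, r = r,
               class = .pairClass(sub$res1[1], sub$atom1[1], sub$res2[1],
                                  sub$atom2[1], seq, tetrad_map),
               flags = paste(bs$flags, collapse = ";"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Grouped distance statistics
#'
#' Arithmetic mean and sample standard deviation of calibrated distances per
#' (pair class, condition) group; groups with fewer than two estimates are
#' dropped with a warning.
#'
#' @param estimates data.frame from [estimateDistances()] (needs columns
#'   `class`, `condition`, `r`).
#' @return data.frame with `class`, `condition`, `mean_r`, `sd_r`, `n`.
#' @export
distanceStats <- function(estimates) {
  stopifnot(all(c("class", "condition", "r") %in% names(estimates)))
  est <- estimates[!is.na(estimates$r), ]
  if (!nrow(est)) stop("no distance estimates to summarize")
  grp <- split(est, paste(est$class, est$condition, sep = "|"))
  small <- vapply(grp, nrow, integer(1)) < 2L
  if (any(small))
    warning("group(s) with < 2 estimates dropped: ",
            paste(names(grp)[small], collapse = ", "))
  out <- do.call(rbind, lapply(grp[!small], function(d) {
    data.frame(class = d$class[1], condition = d$condition[1],
               mean_r = mean(d$r), sd_r = stats::sd(d$r), n = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Welch comparison of two distance groups
#'
#' Two-sided Welch two-sample t-test of group means, used to ask whether the
#' tetrad stacking distances differ between cation conditions. Degenerate
#' inputs with zero variance in both groups are handled explicitly: equal
#' means give p = 1, unequal means p = 0.
#'
#' @param g1,g2 numeric vectors of distances (each n >= 3).
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `t`, `df`, `p`, `significant`.
#' @export
compareConditions <- function(g1, g2, alpha = 0.05) {
  if (length(g1) < 3L || length(g2) < 3L)
    stop("need at least 3 estimates per group")
  s1 <- stats::sd(g1); s2 <- stats::sd(g2)
  eps <- 1e-12 * max(abs(c(g1, g2)), 1)
  if (s1 < eps && s2 < eps) {
    same <- abs(mean(g1) - mean(g2)) < eps
    return(list(t = if (same) 0 else Inf,
                df = length(g1) + length(g2) - 2,
                p = if (same) 1 else 0, significant = !same))
  }
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha)
}
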