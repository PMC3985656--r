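#' Classify glycosidic conformations from intra-residue H1'-H8 NOEs
#'
#' A syn guanine places its aromatic H8 close to its own sugar H1'
#' (about 2.5 Angstrom) while an anti guanine holds it far (about 3.7
#' Angstrom), so a strong intra-residue H1'-H8 NOE marks a syn glycosidic
#' bond. Intensities are converted to distances by r^-6 calibration against
#' the reference pair and thresholded (default 3.3 Angstrom, the midpoint of
#' the syn/anti range). Tetrad guanines without an intra-residue H1'-H8 peak
#' are listed uncalled; classification proceeds for the others.
#'
#' @param x a [NOESYPeakTable-class].
#' @param seq the [G4Sequence-class].
#' @param threshold syn/anti distance threshold in Angstrom (default 3.3).
#' @param ref_pair,ref_distance reference pair spec as in
#'   [estimateDistances()].
#' @return data.frame with columns `residue`, `r` (Angstrom, NA if
#'   uncalled), `conformation` (`"syn"`/`"anti"`/NA), `called`.
#' @export
classifyGlycosidic <- function(x, seq, threshold = 3.3,
                               ref_pair = list(res = 1, atom1 = "H6",
                                               atom2 = "CH3"),
                               ref_distance = 2.99) {
  stopifnot(is(x, "NOESYPeakTable"), is(seq, "G4Sequence"))
  pk <- peaks(x)
  tract_res <- which(!is.na(.tractOf(seq)))
  is_ref <- pk$res1 == ref_pair$res & pk$res2 == ref_pair$res &
    ((pk$atom1 == ref_pair$atom1 & pk$atom2 == ref_pair$atom2) |
     (pk$atom1 == ref_pair$atom2 & pk$atom2 == ref_pair$atom1))
  if (!any(is_ref)) stop("reference pair not found in peak table")
  ref_sub <- pk[is_ref, ]
  ref_slope <- buildupSlope(ref_sub$mixing_time, ref_sub$intensity)$slope
  out <- lapply(tract_res, function(res) {
    sub <- pk[pk$res1 == res & pk$res2 == res &
                ((pk$atom1 == "H1'" & pk$atom2 == "H8") |
                 (pk$atom1 == "H8" & pk$atom2 == "H1'")), ]
    if (!nrow(sub))
      return(data.frame(residue = res, r = NA_real_,
                        conformation = NA_character_, called = FALSE))
    bs <- buildupSlope(sub$mixing_time, sub$intensity)
    if (bs$slope <= 0)
      return(data.frame(residue = res, r = NA_real_,
                        conformation = NA_character_, called = FALSE))
    r <- calibrateDistance(bs$slope, ref_slope, ref_distance)
    data.frame(residue = res, r = r,
               conformation = if (r < threshold) "syn" else "anti",
               called = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# directed G-G imino(H1) -> aromatic(H8) edges from a peak table,
# with the minor-conformation intensity floor applied
.iminoAromaticEdges <- function(pk, minor_floor) {
  gg <- pk[pk$base1 == "G" & pk$base2 == "G" & pk$res1 != pk$res2 &
             ((pk$atom1 == "H1" & pk$atom2 == "H8") |
              (pk$atom1 == "H8" & pk$atom2 == "H1")), , drop = FALSE]
  if (!nrow(gg)) return(data.frame(from = integer(), to = integer()))
  from <- ifelse(gg$atom1 == "H1", gg$res1, gg$res2)
  to <- ifelse(gg$atom1 == "H1", gg$res2, gg$res1)
  key <- paste(from, to)
  peak_int <- tapply(gg$intensity, key, max)
  keep_key <- names(peak_int)[peak_int >= minor_floor * stats::median(peak_int)]
  uniq <- !duplicated(key) & key %in% keep_key
  data.frame(from = from[uniq], to = to[uniq])
}

# all directed 4-cycles with distinct nodes; each reported once, rotated so
# the smallest node leads; direction preserved
.directedFourCycles <- function(edges) {
  if (!nrow(edges)) return(list())
  adj <- split(edges$to, edges$from)
  nodes <- sort(unique(c(edges$from, edges$to)))
  cycles <- list()
  for (s in nodes) {
    for (a in adj[[as.character(s)]]) {
      if (is.null(a) || a <= s) next
      for (b in adj[[as.character(a)]]) {
        if (is.null(b) || b <= s || b == a) next
        for (cc in adj[[as.character(b)]]) {
          if (is.null(cc) || cc <= s || cc == a || cc == b) next
          if (s %in% adj[[as.character(cc)]])
            cycles[[length(cycles) + 1L]] <- c(s, a, b, cc)
        }
      }
    }
  }
  cycles
}

# canonical undirected ring through tract indices: start at the smallest
# tract and walk toward its smaller neighbour
.canonicalRing <- function(tracts) {
  i <- which.min(tracts)
  ring <- tracts[((i - 1L + 0:3) %% 4L) + 1L]
  if (ring[4] < ring[2]) ring <- ring[c(1, 4, 3, 2)]
  ring
}

#' Detect G-tetrads from imino-aromatic NOE connectivity
#'
#' Within a G-tetrad each guanine's Hoogsteen-bonded imino proton (H1) sits
#' next to the aromatic H8 of its ring neighbour, so the tetrad appears as a
#' directed 4-cycle of inter-guanine H1 -> H8 NOEs. All directed 4-cycles
#' whose members come from four distinct G-tracts are accepted as tetrads.
#' Weak peaks below `minor_floor` of the median imino-aromatic peak
#' intensity are excluded first (minor-conformation suppression).
#'
#' Layers are ordered by the within-tract position of each tetrad's
#' first-tract guanine (first = top, by the convention that tract 1 runs
#' upward); when inter-tetrad imino-imino NOEs are present they must agree
#' (the central tetrad is the one NOE-connected to both others), otherwise
#' an error is raised rather than guessing. Each tetrad's rotational sense
#' is `"clockwise"` when its cycle follows the canonical tract ring forward
#' and `"anticlockwise"` when it runs backward.
#'
#' @param x a [NOESYPeakTable-class].
#' @param seq the [G4Sequence-class].
#' @param minor_floor intensity floor as a fraction of the median
#'   imino-aromatic peak intensity (default 0.1).
#' @return data.frame with one row per tetrad: `layer`, `sense`,
#'   `g1`..`g4` (cycle order, starting from the lowest-numbered tract's
#'   member, following H1 -> H8 direction); attribute `ring` holds the
#'   cyclic tract order. Zero rows (with a diagnostic message attribute
#'   `diagnostic`) when no 4-cycle exists.
#' @export
detectTetrads <- function(x, seq, minor_floor = 0.1) {
  stopifnot(is(x, "NOESYPeakTable"), is(seq, "G4Sequence"))
  pk <- peaks(x)
  tract_of <- .tractOf(seq)
  rank_of <- .tractRank(seq)
  edges <- .iminoAromaticEdges(pk, minor_floor)
  cycles <- .directedFourCycles(edges)
  # keep cycles spanning 4 distinct tracts
  cycles <- Filter(function(cy) {
    tr <- tract_of[cy]
    !anyNA(tr) && length(unique(tr)) == 4L
  }, cycles)
  if (!length(cycles)) {
    out <- data.frame(layer = character(), sense = character(),
                      g1 = integer(), g2 = integer(), g3 = integer(),
                      g4 = integer())
    attr(out, "ring") <- integer()
    attr(out, "diagnostic") <- sprintf(
      "no directed 4-cycle across 4 tracts among %d imino-aromatic edge(s) on %d guanine(s)",
      nrow(edges), length(unique(c(edges$from, edges$to))))
    return(out)
  }
  # rotate each cycle to start at the lowest-numbered tract's member
  cycles <- lapply(cycles, function(cy) {
    i <- which.min(tract_of[cy])
    cy[((i - 1L + 0:3) %% 4L) + 1L]
  })
  rings <- lapply(cycles, function(cy) .canonicalRing(tract_of[cy]))
  ring <- rings[[1]]
  if (!all(vapply(rings, function(r) all(r == ring), logical(1))))
    warning("tetrads imply different tract rings; using the first")
  sense <- vapply(cycles, function(cy) {
    tr <- tract_of[cy]
    if (tr[2] == ring[2]) "clockwise" else "anticlockwise"
  }, character(1))
  rank1 <- vapply(cycles, function(cy) rank_of[cy[1]], integer(1))
  layer <- rep(NA_character_, length(cycles))
  if (length(cycles) <= 3L && !anyDuplicated(rank1)) {
    layer <- c("top", "central", "bottom")[rank1]
  } else {
    warning("could not order tetrad layers by tract position (",
            length(cycles), " tetrad(s), ranks ",
            paste(rank1, collapse = ","), "); layers set to NA")
  }
  out <- data.frame(layer = layer, sense = sense,
                    g1 = vapply(cycles, `[`, integer(1), 1L),
                    g2 = vapply(cycles, `[`, integer(1), 2L),
                    g3 = vapply(cycles, `[`, integer(1), 3L),
                    g4 = vapply(cycles, `[`, integer(1), 4L))
  ord <- order(match(out$layer, c("top", "central", "bottom")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  # cross-check with inter-tetrad imino-imino NOEs when present
  hh <- pk[pk$atom1 == "H1" & pk$atom2 == "H1" & pk$res1 != pk$res2, ]
  if (nrow(hh) && !anyNA(out$layer) && nrow(out) == 3L) {
    members <- lapply(seq_len(nrow(out)),
                      function(i) unlist(out[i, c("g1", "g2", "g3", "g4")]))
    link <- matrix(FALSE, 3, 3)
    for (i in 1:2) for (j in (i + 1):3) {
      link[i, j] <- any(hh$res1 %in% members[[i]] & hh$res2 %in% members[[j]] |
                        hh$res1 %in% members[[j]] & hh$res2 %in% members[[i]])
    }
    n_links <- rowSums(link | t(link))
    if (any(n_links == 2) && which.max(n_links) != 2L &&
        sum(n_links == 2) == 1L)
      stop("inter-tetrad NOEs contradict tract-position layer ordering")
  }
  attr(out, "ring") <- ring
  out
}

#' Infer strand orientations from glycosidic patterns
#'
#' Within a tetrad, strands running in the same direction share their
#' glycosidic state, while a strand running against the others flips it.
#' For each tetrad the per-tract conformation pattern is therefore reduced
#' to a partition: all-equal (all four tracts parallel), three-against-one
#' (the minority tract is antiparallel), or two-against-two (a (2+2)
#' arrangement; the group not containing tract 1 is called antiparallel,
#' anchoring tract 1 "up"). The partitions must agree across tetrads;
#' conflicting evidence raises an error listing the per-tetrad patterns.
#'
#' @param tetrads tetrad table from [detectTetrads()].
#' @param glycosidic calls from [classifyGlycosidic()].
#' @param seq the [G4Sequence-class].
#' @return named character vector, per tract, `"up"` or `"down"`.
#' @export
inferOrientations <- function(tetrads, glycosidic, seq) {
  stopifnot(is(seq, "G4Sequence"), nrow(tetrads) >= 1L)
  tract_of <- .tractOf(seq)
  n_tracts <- nrow(gTracts(seq))
  conf <- stats::setNames(glycosidic$conformation,
                          as.character(glycosidic$residue))
  flipped <- vector("list", nrow(tetrads))
  patterns <- character(nrow(tetrads))
  for (i in seq_len(nrow(tetrads))) {
    members <- unlist(tetrads[i, c("g1", "g2", "g3", "g4")])
    st <- conf[as.character(members)]
    if (anyNA(st))
      stop("glycosidic conformation missing for residue(s): ",
           paste(members[is.na(st)], collapse = ", "))
    tr <- tract_of[members]
    st_by_tract <- st[order(tr)]
    patterns[i] <- paste(st_by_tract, collapse = "-")
    n_syn <- sum(st_by_tract == "syn")
    flipped[[i]] <- if (n_syn %in% c(0L, 4L)) integer()
      else if (n_syn == 1L) sort(tr)[st_by_tract == "syn"]
      else if (n_syn == 3L) sort(tr)[st_by_tract == "anti"]
      else {  # 2-2 split: the group not containing tract 1 is antiparallel
        ref_state <- st_by_tract[1]
        sort(tr)[st_by_tract != ref_state]
      }
  }
  same <- vapply(flipped, function(f) identical(f, flipped[[1]]), logical(1))
  if (!all(same))
    stop("glycosidic patterns are inconsistent across tetrads ",
         "(no orientation assignment satisfies all): ",
         paste(sprintf("tetrad %d: %s", seq_along(patterns), patterns),
               collapse = "; "))
  orient <- rep("up", n_tracts)
  orient[flipped[[1]]] <- "down"
  stats::setNames(orient, paste0("tract", seq_len(n_tracts)))
}

#' Classify connecting loops
#'
#' Loop taxonomy from strand orientations and the spatial tract ring: a loop
#' joining two parallel ring-adjacent tracts runs along the groove exterior
#' (double-chain-reversal); joining antiparallel ring-adjacent tracts it
#' crosses a tetrad face edge-wise (lateral); joining antiparallel
#' diagonally opposed tracts it crosses the face corner-to-corner
#' (diagonal).
#'
#' @param orientations named per-tract `"up"`/`"down"` vector from
#'   [inferOrientations()].
#' @param ring integer cyclic tract order (attribute `ring` of
#'   [detectTetrads()] output).
#' @return character vector of n_tracts - 1 loop labels.
#' @export
classifyLoops <- function(orientations, ring) {
  n <- length(orientations)
  stopifnot(n >= 2L, length(ring) == n)
  vapply(seq_len(n - 1L), function(i) {
    parallel <- orientations[i] == orientations[i + 1L]
    pos <- c(match(i, ring), match(i + 1L, ring))
    adjacent <- (abs(diff(pos)) %% n) %in% c(1L, n - 1L)
    if (parallel && adjacent) "double-chain-reversal"
    else if (!parallel && adjacent) "lateral"
    else if (!parallel) "diagonal"
    else "unclassified"
  }, character(1))
}

#' Assign a named fold label
#'
#' Decision table over the orientation multiset and loop sequence:
#' all-parallel with three double-chain-reversal loops is the parallel
#' propeller; one antiparallel tract is a (3+1) hybrid, hybrid-I when the
#' double-chain-reversal loop comes first and hybrid-II when it comes last;
#' two antiparallel tracts give the antiparallel basket
#' (lateral-diagonal-lateral), the antiparallel chair (all lateral) or a
#' generic (2+2) fold. Patterns outside the table are labelled
#' `"unclassified"`.
#'
#' @param tetrads tetrad table from [detectTetrads()].
#' @param orientations from [inferOrientations()].
#' @param loops from [classifyLoops()].
#' @param glycosidic calls from [classifyGlycosidic()].
#' @param ring integer cyclic tract order.
#' @return a [TopologyModel-class].
#' @export
classifyTopology <- function(tetrads, orientations, loops, glycosidic,
                             ring = attr(tetrads, "ring")) {
  n_down <- sum(orientations == "down")
  dcr <- loops == "double-chain-reversal"
  label <- "unclassified"
  if (n_down == 0L && all(dcr)) {
    label <- "parallel propeller"
  } else if (n_down == 1L && length(loops) == 3L) {
    if (dcr[1] && !dcr[2] && !dcr[3]) label <- "hybrid-I (3+1)"
    else if (!dcr[1] && !dcr[2] && dcr[3]) label <- "hybrid-II (3+1)"
  } else if (n_down == 2L && length(loops) == 3L) {
    if (identical(loops, c("lateral", "diagonal", "lateral")))
      label <- "antiparallel basket"
    else if (all(loops == "lateral"))
      label <- "antiparallel chair"
    else if (any(dcr))
      label <- "(2+2)"
  }
  new("TopologyModel", tetrads = as.data.frame(tetrads),
      orientations = orientations, loops = loops,
      glycosidic = as.data.frame(glycosidic),
      ring = as.integer(ring), label = label)
}

#' Infer a G-quadruplex topology from an assigned peak table
#'
#' End-to-end wrapper: glycosidic syn/anti calls
#' ([classifyGlycosidic()]), tetrad detection ([detectTetrads()]), strand
#' orientations ([inferOrientations()]), loop taxonomy ([classifyLoops()])
#' and the fold label ([classifyTopology()]).
#'
#' @param x a [NOESYPeakTable-class].
#' @param seq the [G4Sequence-class].
#' @param threshold syn/anti distance threshold in Angstrom (default 3.3).
#' @param minor_floor minor-conformation intensity floor (default 0.1).
#' @param ref_pair,ref_distance reference pair spec as in
#'   [estimateDistances()].
#' @return a [TopologyModel-class].
#' @examples
#' pt <- genNoesyPeaks(topology = "hybrid-I")
#' topologyLabel(inferTopology(pt, tel23Sequence()))
#' @export
inferTopology <- function(x, seq, threshold = 3.3, minor_floor = 0.1,
                          ref_pair = list(res = 1, atom1 = "H6",
                                          atom2 = "CH3"),
                          ref_distance = 2.99) {
  glyco <- classifyGlycosidic(x, seq, threshold, ref_pair, ref_distance)
  tetrads <- detectTetrads(x, seq, minor_floor)
  if (!nrow(tetrads))
    stop("no tetrads detected: ", attr(tetrads, "diagnostic"))
  orient <- inferOrientations(tetrads, glyco, seq)
  loops <- classifyLoops(orient, attr(tetrads, "ring"))
  classifyTopology(tetrads, orient, loops, glyco)
}

#' @rdname topologyLabel
#' @export
setGeneric("topologyLabel", function(x) standardGeneric("topologyLabel"))

#' Fold label of a topology model
#' @param x a [TopologyModel-class].
#' @return character fold label.
#' @export
setMethod("topologyLabel", "TopologyModel", function(x) x@label)

#' Tetrad layer of each guanine
#'
#' @param x a [TopologyModel-class].
#' @return named character vector mapping residue index (names) to layer,
#'   for use as the `tetrad_map` of [perResidueSummary()] and
#'   [estimateDistances()].
#' @export
tetradLayers <- function(x) {
  stopifnot(is(x, "TopologyModel"))
  td <- x@tetrads
  out <- character()
  for (i in seq_len(nrow(td))) {
    members <- unlist(td[i, c("g1", "g2", "g3", "g4")])
    out[as.character(members)] <- td$layer[i]
  }
  out
}

setMethod("show", "TopologyModel", function(object) {
  cat("TopologyModel:", object@label, "\n")
  td <- object@tetrads
  for (i in seq_len(nrow(td)))
    cat(sprintf("  %s tetrad (%s): G%d->G%d->G%d->G%d\n",
                td$layer[i], td$sense[i],
                td$g1[i], td$g2[i], td$g3[i], td$g4[i]))
  cat("  orientations:",
      paste(sprintf("%s=%s", names(object@orientations),
                    object@orientations), collapse = ", "), "\n")
  cat("  loops:", paste(object@loops, collapse = ", "), "\n")
})
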