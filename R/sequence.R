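#' Construct a G4Sequence
#'
#' Parses a DNA sequence and locates its G-tracts (maximal runs of >= 2
#' consecutive guanines), the building blocks of a G-quadruplex core.
#'
#' @param x character scalar or [Biostrings::DNAString] (A/C/G/T only).
#' @return a [G4Sequence-class] object.
#' @examples
#' seq <- G4Sequence("TAGGGTTAGGGTTAGGGTTAGGG")
#' gTracts(seq)
#' @export
G4Sequence <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("'x' must be a single character string or DNAString")
  x <- toupper(x)
  if (grepl("[^ACGT]", x))
    stop("sequence may contain only A, C, G, T")
  r <- rle(strsplit(x, "")[[1]] == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  tracts <- data.frame(tract = seq_len(sum(keep)),
                       start = starts[keep], end = ends[keep],
                       length = r$lengths[keep])
  new("G4Sequence", seq = Biostrings::DNAString(x), tracts = tracts)
}

#' The Tel23 human telomeric sequence
#'
#' Tel23, d\[TAGGG(TTAGGG)3\]: 23 nt, four G-tracts of three guanines at
#' positions 3-5, 9-11, 15-17 and 21-23.
#'
#' @return a [G4Sequence-class] object.
#' @export
tel23Sequence <- function() G4Sequence("TAGGGTTAGGGTTAGGGTTAGGG")

#' @rdname gTracts
#' @export
setGeneric("gTracts", function(x) standardGeneric("gTracts"))

#' G-tracts of a sequence
#'
#' @param x a [G4Sequence-class].
#' @return data.frame with columns `tract`, `start`, `end`, `length`.
#' @export
setMethod("gTracts", "G4Sequence", function(x) x@tracts)

#' Number of residues in a G4Sequence
#' @param x a [G4Sequence-class].
#' @export
setMethod("length", "G4Sequence", function(x) length(x@seq))

#' Base at each position
#'
#' @param x a [G4Sequence-class].
#' @param i integer positions (default: all).
#' @return character vector of bases.
#' @export
residueBase <- function(x, i = seq_len(length(x))) {
  stopifnot(is(x, "G4Sequence"))
  if (any(i < 1L | i > length(x)))
    stop("residue index out of range")
  strsplit(as.character(x@seq), "")[[1]][i]
}

# tract index of each residue (NA outside tracts)
.tractOf <- function(seq) {
  out <- rep(NA_integer_, length(seq))
  tr <- gTracts(seq)
  for (i in seq_len(nrow(tr))) out[tr$start[i]:tr$end[i]] <- tr$tract[i]
  out
}

# within-tract rank (1 = 5'-most G of the tract)
.tractRank <- function(seq) {
  out <- rep(NA_integer_, length(seq))
  tr <- gTracts(seq)
  for (i in seq_len(nrow(tr)))
    out[tr$start[i]:tr$end[i]] <- seq_len(tr$length[i])
  out
}

#' Loop residues of a G4 sequence
#'
#' Residues lying between consecutive G-tracts (the loop segments of the
#' folded quadruplex).
#'
#' @param x a [G4Sequence-class].
#' @return integer vector of residue indices.
#' @export
loopResidues <- function(x) {
  tr <- gTracts(x)
  if (nrow(tr) < 2) return(integer())
  unlist(lapply(seq_len(nrow(tr) - 1L),
                function(i) seq(tr$end[i] + 1L, tr$start[i + 1L] - 1L)),
         use.names = FALSE)
}

setMethod("show", "G4Sequence", function(object) {
  cat("G4Sequence of", length(object), "nt:",
      as.character(object@seq), "\n")
  tr <- object@tracts
  cat(sprintf("  %d G-tract(s): %s\n", nrow(tr),
              paste(sprintf("%d-%d", tr$start, tr$end), collapse = ", ")))
})
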