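# Sparky-like assignment token, e.g. "G3H1", "T13CH3", "G9H1'".
# H1' must be tried before H1.
.ATOM_ALT <- "H1'|CH3|H1|H8|H6"
.TOKEN_RE <- sprintf("^([ACGT])([0-9]+)(%s)$", .ATOM_ALT)

# "G3H1-G21H8" -> list(res=, base=, atom=) x2, or NULL if malformed
.parseAssignment <- function(token) {
  halves <- strsplit(token, "-", fixed = TRUE)[[1]]
  if (length(halves) != 2L) return(NULL)
  out <- vector("list", 2L)
  for (i in 1:2) {
    m <- regmatches(halves[i], regexec(.TOKEN_RE, halves[i]))[[1]]
    if (length(m) != 4L) return(NULL)
    out[[i]] <- list(res = as.integer(m[3]), base = m[2], atom = m[4])
  }
  out
}

.formatAtom <- function(base, res, atom) sprintf("%s%d%s", base, res, atom)

# canonical order: lower (res, atom) first
.canonicalizePeaks <- function(pk) {
  if (!nrow(pk)) return(pk)
  swap <- pk$res1 > pk$res2 | (pk$res1 == pk$res2 & pk$atom1 > pk$atom2)
  if (any(swap)) {
    tmp <- pk[swap, c("res1", "base1", "atom1")]
    pk[swap, c("res1", "base1", "atom1")] <-
      pk[swap, c("res2", "base2", "atom2")]
    pk[swap, c("res2", "base2", "atom2")] <- tmp
  }
  rownames(pk) <- NULL
  pk
}

#' Construct a NOESYPeakTable
#'
#' @param peaks data.frame with columns `res1`, `base1`, `atom1`, `res2`,
#'   `base2`, `atom2`, `mixing_time`, `intensity`, `condition`. Pairs are
#'   canonicalized on construction.
#' @param source character scalar provenance label.
#' @return a [NOESYPeakTable-class].
#' @export
NOESYPeakTable <- function(peaks = data.frame(), source = "synthetic") {
  if (!nrow(peaks)) {
    peaks <- data.frame(res1 = integer(), base1 = character(),
                        atom1 = character(), res2 = integer(),
                        base2 = character(), atom2 = character(),
                        mixing_time = numeric(), intensity = numeric(),
                        condition = character())
  }
  peaks <- as.data.frame(peaks)[, .PEAK_COLS]
  peaks$res1 <- as.integer(peaks$res1)
  peaks$res2 <- as.integer(peaks$res2)
  for (cl in c("base1", "atom1", "base2", "atom2", "condition"))
    peaks[[cl]] <- as.character(peaks[[cl]])
  peaks$mixing_time <- as.numeric(peaks$mixing_time)
  peaks$intensity <- as.numeric(peaks$intensity)
  peaks <- .canonicalizePeaks(peaks)
  new("NOESYPeakTable", peaks = peaks, source = source)
}

#' @rdname peaks
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' Peak rows of a NOESYPeakTable
#'
#' @param x a [NOESYPeakTable-class].
#' @return the underlying data.frame (one row per peak).
#' @export
setMethod("peaks", "NOESYPeakTable", function(x) x@peaks)

#' @export
setMethod("length", "NOESYPeakTable", function(x) nrow(x@peaks))

setMethod("show", "NOESYPeakTable", function(object) {
  pk <- object@peaks
  cat("NOESYPeakTable:", nrow(pk), "peak(s) from", object@source, "\n")
  if (nrow(pk)) {
    cat("  conditions:", paste(unique(pk$condition), collapse = ", "), "\n")
    cat("  mixing times (ms):",
        paste(sort(unique(pk$mixing_time)), collapse = ", "), "\n")
  }
})

#' Read a Sparky-style assigned peak list
#'
#' Reads whitespace-delimited peak lists of the form
#' `G3H1-G21H8 200 1.35e5 na`: assignment pair, mixing time (ms), intensity,
#' condition. Lines starting with `#` and blank lines are skipped. All
#' malformed lines are collected and reported with their line numbers.
#'
#' @param path file path.
#' @return a [NOESYPeakTable-class] with `source = path`.
#' @examples
#' tmp <- tempfile(fileext = ".list")
#' writeLines("G3H1-G21H8 200 1.35e5 na", tmp)
#' peaks(readPeakList(tmp))
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) {
    warning("empty peak list: ", path)
    return(NOESYPeakTable(source = path))
  }
  rows <- vector("list", length(keep))
  bad <- character()
  for (j in seq_along(keep)) {
    ln <- keep[j]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != 4L) {
      bad <- c(bad, sprintf("line %d: expected 4 fields, got %d",
                            ln, length(fields)))
      next
    }
    asgn <- .parseAssignment(fields[1])
    if (is.null(asgn)) {
      bad <- c(bad, sprintf("line %d: unparseable assignment token '%s'",
                            ln, fields[1]))
      next
    }
    tmix <- suppressWarnings(as.numeric(fields[2]))
    inten <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(tmix) || is.na(inten)) {
      bad <- c(bad, sprintf("line %d: non-numeric mixing time or intensity",
                            ln))
      next
    }
    if (inten < 0) {
      bad <- c(bad, sprintf("line %d: negative intensity %g", ln, inten))
      next
    }
    if (!fields[4] %in% .VALID_CONDITIONS) {
      bad <- c(bad, sprintf("line %d: unknown condition '%s'", ln, fields[4]))
      next
    }
    rows[[j]] <- data.frame(
      res1 = asgn[[1]]$res, base1 = asgn[[1]]$base, atom1 = asgn[[1]]$atom,
      res2 = asgn[[2]]$res, base2 = asgn[[2]]$base, atom2 = asgn[[2]]$atom,
      mixing_time = tmix, intensity = inten, condition = fields[4])
  }
  if (length(bad))
    stop("malformed peak list ", path, ":\n  ",
         paste(bad, collapse = "\n  "))
  pk <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  odd <- setdiff(unique(pk$mixing_time), .STANDARD_MIXING_TIMES)
  if (length(odd))
    warning("non-standard mixing time(s): ", paste(odd, collapse = ", "),
            " ms (buildup series normally use 50/100/150/200 ms)")
  NOESYPeakTable(pk, source = path)
}

#' Write a NOESYPeakTable as a Sparky-style peak list
#'
#' Inverse of [readPeakList()]: the written file re-reads to an identical
#' table (lossless round trip).
#'
#' @param x a [NOESYPeakTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(x, path) {
  stopifnot(is(x, "NOESYPeakTable"))
  pk <- peaks(x)
  lines <- sprintf("%s-%s %.10g %.10g %s",
                   .formatAtom(pk$base1, pk$res1, pk$atom1),
                   .formatAtom(pk$base2, pk$res2, pk$atom2),
                   pk$mixing_time, pk$intensity, pk$condition)
  writeLines(lines, path)
  invisible(path)
}
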