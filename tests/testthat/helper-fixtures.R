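# Shared fixtures built in code.

tel23 <- tel23Sequence()

# The three published tetrad cycles of the Tel23 Na+ form, as directed
# imino -> aromatic connectivities, plus glycosidic and reference peaks,
# assembled by hand (independent of the generator).
fig3cPeakTable <- function() {
  cycles <- list(c(3, 21, 17, 9), c(4, 10, 16, 22), c(5, 11, 15, 23))
  syn <- c(3, 9, 21, 15, 16)
  rows <- list()
  add <- function(r1, a1, r2, a2, inten) {
    rows[[length(rows) + 1L]] <<- data.frame(
      res1 = r1, base1 = residueBase(tel23, r1), atom1 = a1,
      res2 = r2, base2 = residueBase(tel23, r2), atom2 = a2,
      mixing_time = 200, intensity = inten, condition = "na")
  }
  for (cy in cycles) for (i in 1:4)
    add(cy[i], "H1", cy[i %% 4 + 1], "H8", 1000)
  # inter-tetrad imino-imino contacts down each tract
  for (t in c(3, 9, 15, 21)) {
    add(t, "H1", t + 1, "H1", 800)
    add(t + 1, "H1", t + 2, "H1", 800)
  }
  ref_int <- 5e4
  for (g in c(3:5, 9:11, 15:17, 21:23)) {
    r <- if (g %in% syn) 2.5 else 3.7
    add(g, "H1'", g, "H8", ref_int * (2.99 / r)^6)
  }
  add(1, "H6", 1, "CH3", ref_int)
  NOESYPeakTable(do.call(rbind, rows))
}

# Brute-force oracle: all directed 4-cycles (distinct nodes, each from a
# distinct tract), enumerated over ordered 4-subsets; cycles are rotated to
# start at their smallest node. Independent of the package's DFS search.
bruteForceFourCycles <- function(edges, tract_of) {
  has <- function(a, b) any(edges$from == a & edges$to == b)
  nodes <- sort(unique(c(edges$from, edges$to)))
  found <- list()
  if (length(nodes) < 4) return(found)
  for (sub in utils::combn(nodes, 4, simplify = FALSE)) {
    if (length(unique(tract_of[sub])) != 4) next
    perms <- list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4),
                  c(1,3,4,2), c(1,4,2,3), c(1,4,3,2))
    for (p in perms) {
      cy <- sub[p]
      ok <- all(vapply(1:4, function(i) has(cy[i], cy[i %% 4 + 1]),
                       logical(1)))
      if (ok) found[[length(found) + 1L]] <- cy
    }
  }
  found
}

cycleKey <- function(cy) {
  i <- which.min(cy)
  paste(cy[((i - 1 + 0:3) %% 4) + 1], collapse = "-")
}

# a 19-nt scaffold with four G-tracts of four guanines, for graph tests
ggggSequence <- function() G4Sequence("GGGGTGGGGTGGGGTGGGG")
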