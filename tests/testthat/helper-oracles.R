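# Independent oracles: exhaustive enumeration under the baseline model
# (pair weights GC=3, AU=2, GU=1; +2 per stacked pair; min hairpin loop 3)
# and a literal reference implementation of the constraint-dominance
# comparator.  These recompute expected values from the model definition by
# brute force, independently of the package's dynamic programming and
# sorting code.

.oW <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
.oW["G", "C"] <- .oW["C", "G"] <- 3
.oW["A", "U"] <- .oW["U", "A"] <- 2
.oW["G", "U"] <- .oW["U", "G"] <- 1
.oStack <- 2
.oMinLoop <- 3

# all pseudoknot-free pair sets over positions i..j (as lists of c(i, j)),
# honoring the minimum hairpin loop; memoized by interval length (the
# structure catalogue depends only on the length, positions are shifted)
.enumCache <- new.env(parent = emptyenv())

.enumByLen <- function(L) {
  key <- as.character(L)
  if (!is.null(.enumCache[[key]])) return(.enumCache[[key]])
  res <- if (L <= 1) list(list()) else {
    out <- list()
    for (s in .enumByLen(L - 1))          # position 1 unpaired, shift +1
      out[[length(out) + 1]] <- lapply(s, function(p) p + 1)
    for (k in (.oMinLoop + 2):L) {        # position 1 paired with k
      if (k > L) break
      inner <- .enumByLen(k - 2)
      rest <- .enumByLen(L - k)
      for (a in inner) for (b in rest)
        out[[length(out) + 1]] <- c(list(c(1, k)),
                                    lapply(a, function(p) p + 1),
                                    lapply(b, function(p) p + k))
    }
    out
  }
  .enumCache[[key]] <- res
  res
}

enumStructures <- function(i, j) {
  L <- j - i + 1
  if (L <= 0) return(list(list()))
  lapply(.enumByLen(L), function(s) lapply(s, function(p) p + i - 1))
}

# score of a fixed structure for a sequence (character vector)
oracleScore <- function(chars, pairs) {
  if (length(pairs) == 0) return(0)
  sc <- sum(vapply(pairs, function(p) .oW[chars[p[1]], chars[p[2]]],
                   numeric(1)))
  key <- vapply(pairs, function(p) paste(p, collapse = ","), character(1))
  stacked <- sum(vapply(pairs, function(p)
    paste(p[1] + 1, p[2] - 1, sep = ",") %in% key, logical(1)))
  sc + .oStack * stacked
}

# does a structure satisfy a structureConstraint-style spec?
oracleValid <- function(pairs, codes, partner) {
  pos <- unlist(lapply(pairs, identity))
  pairedAt <- rep(NA_integer_, length(codes))
  for (p in pairs) { pairedAt[p[1]] <- p[2]; pairedAt[p[2]] <- p[1] }
  for (i in seq_along(codes)) {
    code <- codes[i]
    if (code == "pair" && (is.na(pairedAt[i]) || pairedAt[i] != partner[i]))
      return(FALSE)
    if (code %in% c("nopair", "nointra") && !is.na(pairedAt[i]))
      return(FALSE)
  }
  TRUE
}

# brute-force optimal single-strand fold: max score over all constraint-valid
# structures (pairable pairs only); returns the score (energy = -score)
oracleFoldScore <- function(x, codes = NULL, partner = NULL) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  if (is.null(codes)) codes <- rep("free", n)
  if (is.null(partner)) partner <- rep(NA_integer_, n)
  best <- -Inf
  for (pairs in enumStructures(1, n)) {
    if (length(pairs) > 0 &&
        any(vapply(pairs, function(p) .oW[chars[p[1]], chars[p[2]]] == 0,
                   logical(1)))) next
    if (!oracleValid(pairs, codes, partner)) next
    sc <- oracleScore(chars, pairs)
    if (sc > best) best <- sc
  }
  best
}

# brute-force minimum duplex energy over all (window1, window2, alignment)
# contiguous antiparallel duplexes of length <= w lying wholly inside the
# candidate position sets of the two strands
oracleBestDuplex <- function(x1, x2, cand1, cand2, w) {
  c1 <- strsplit(x1, "")[[1]]
  c2 <- strsplit(x2, "")[[1]]
  best <- 0
  for (a in seq_along(c1)) {
    for (b in seq_along(c2)) {
      sc <- 0
      for (L in 1:w) {
        i <- a + L - 1
        j <- b - L + 1
        if (i > length(c1) || j < 1) break
        if (!(i %in% cand1) || !(j %in% cand2)) break
        wgt <- .oW[c1[i], c2[j]]
        if (wgt == 0) break
        sc <- sc + wgt + if (L > 1) .oStack else 0
        if (sc > best) best <- sc
      }
    }
  }
  -best
}

# literal reference implementation of the constraint-dominance comparison
refComparator <- function(fa, va, fb, vb) {
  feasA <- va == 0
  feasB <- vb == 0
  if (feasA && !feasB) return("a")
  if (!feasA && feasB) return("b")
  if (!feasA && !feasB) {
    if (va < vb) return("a")
    if (vb < va) return("b")
    return("neither")
  }
  if (all(fa <= fb) && any(fa != fb)) return("a")
  if (all(fb <= fa) && any(fa != fb)) return("b")
  "neither"
}

# brute-force non-dominated fronts by repeated peeling
bruteFronts <- function(objs, v) {
  remaining <- seq_len(nrow(objs))
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && refComparator(objs[j, ], v[j], objs[i, ], v[i]) == "a"
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = "")

# IUPAC nucleotide classes, written out for constraint-satisfaction checks
.IUPAC_RNA_TEST <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))
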