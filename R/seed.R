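# Interaction-seed prediction: candidate construction, the constrained
# single-accessible-region procedure, and the sliding-window scan.

.emptySeed <- function() {
  new("Seed", pairs = matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("i", "j"))),
      energy = 0)
}

#' Seed-candidate positions
#'
#' Seed candidates are the nucleotide positions eligible to carry the
#' interaction seed: the endpoints of intermolecular base pairs of the
#' predicted joint structure whose positions are loop (unpaired) in the
#' respective independently folded strand.  A pair contributes its
#' endpoints only when both are loop nucleotides in the isolated
#' structures.
#'
#' @param joint two-strand [PredictedStructure-class] of the complex.
#' @param iso1,iso2 single-strand [PredictedStructure-class] of the
#'   independently folded strands.
#' @return sorted integer vector of global candidate positions (possibly
#'   empty).
#' @export
seedCandidates <- function(joint, iso1, iso2) {
  sl <- joint@strandLengths
  if (length(sl) != 2L) stop("'joint' must be a two-strand prediction")
  n1 <- sl[1L]
  if (iso1@strandLengths[1L] != n1 || iso2@strandLengths[1L] != sl[2L])
    stop("isolated structures do not match the joint prediction's lengths")
  cand <- integer(0)
  for (i in seq_len(n1)) {
    j <- joint@partner[i]
    if (is.na(j) || j <= n1) next   # unpaired or intramolecular
    if (is.na(iso1@partner[i]) && is.na(iso2@partner[j - n1]))
      cand <- c(cand, i, j)
  }
  sort(cand)
}

# hybridization energy of a fixed duplex under the baseline model: pair
# weights plus the stacking credit for every helix-elongating pair
.duplexEnergy <- function(pair, pairs) {
  if (nrow(pairs) == 0L) return(0)
  chars <- strsplit(.concatSeq(pair), "")[[1]]
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  score <- sum(vapply(seq_len(nrow(pairs)), function(k)
    .PAIR_SCORE[chars[pairs[k, 1L]], chars[pairs[k, 2L]]], numeric(1)))
  if (nrow(pairs) > 1L) {
    stacked <- sum(diff(pairs[, 1L]) == 1L & diff(pairs[, 2L]) == -1L)
    score <- score + .STACK_BONUS * stacked
  }
  -score
}

.seedFromJoint <- function(pair, pred, backend) {
  n1 <- pred@strandLengths[1L]
  inter <- which(!is.na(pred@partner[seq_len(n1)]) &
                 pred@partner[seq_len(n1)] > n1)
  if (length(inter) == 0L) return(.emptySeed())
  pairs <- cbind(i = inter, j = pred@partner[inter])
  if (is(backend, "BaselinePredictor")) {
    en <- .duplexEnergy(pair, pairs)
  } else {
    # fold the seed windows duplex-only with the backend to price the helix
    r1 <- range(pairs[, 1L]); r2 <- range(pairs[, 2L]) - n1
    s1 <- substr(pair@x1, r1[1L], r1[2L])
    s2 <- substr(pair@x2, r2[1L], r2[2L])
    nc <- function(n) structureConstraint(rep("nointra", n))
    sub <- foldJoint(backend, s1, s2, nc(nchar(s1)), nc(nchar(s2)),
                     maxRegions = 1L, maxRegionLength = max(nchar(s1), nchar(s2)))
    en <- sub@energy
  }
  new("Seed", pairs = pairs, energy = en)
}

#' Predict the interaction seed (constrained-prediction procedure)
#'
#' Implements the constrained single-accessible-region procedure: every
#' non-candidate position is pinned to its independently folded state
#' (intramolecular pairs enforced, loop positions prohibited from pairing),
#' candidate positions are prohibited from intramolecular pairing, and the
#' complex is re-folded with at most one accessible region of at most
#' \code{w} nt.  The resulting single intermolecular duplex is the
#' interaction seed; its energy is the hybridization energy of that helix.
#' An empty candidate set yields an empty seed with energy 0.
#'
#' @param pair a [SequencePair-class].
#' @param iso1,iso2 independently folded strand structures.
#' @param candidates global candidate positions from [seedCandidates()].
#' @param w maximum seed length in base pairs (default 6).
#' @param backend a [Predictor-class].
#' @return a [Seed-class].
#' @export
findSeedConstrained <- function(pair, iso1, iso2, candidates, w = 6L,
                                backend = baselinePredictor()) {
  if (length(candidates) == 0L) return(.emptySeed())
  n1 <- nchar(pair@x1); n2 <- nchar(pair@x2)
  if (is(backend, "BaselinePredictor")) {
    raw <- .rawSeedConstrained(.seqToInt(pair@x1), .seqToInt(pair@x2),
                               list(partner = iso1@partner),
                               list(partner = iso2@partner),
                               candidates, w)
    return(new("Seed", pairs = raw$pairs, energy = raw$energy))
  }
  mkCons <- function(iso, n, offset) {
    codes <- character(n)
    partner <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if ((i + offset) %in% candidates) {
        codes[i] <- "nointra"
      } else if (!is.na(iso@partner[i])) {
        codes[i] <- "pair"
        partner[i] <- iso@partner[i]
      } else {
        codes[i] <- "nopair"
      }
    }
    structureConstraint(codes, partner)
  }
  c1 <- mkCons(iso1, n1, 0L)
  c2 <- mkCons(iso2, n2, n1)
  pred <- foldJoint(backend, pair@x1, pair@x2, c1, c2,
                    maxRegions = 1L, maxRegionLength = as.integer(w))
  .seedFromJoint(pair, pred, backend)
}

# raw-layer constrained seed prediction: non-candidates pinned to their
# isolated state, candidates prohibited from intramolecular pairing, one
# accessible region of at most w nt; the selected duplex region is the seed
.rawSeedConstrained <- function(v1, v2, iso1, iso2, cand, w) {
  empty <- list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))),
                energy = 0)
  if (length(cand) == 0L) return(empty)
  n1 <- length(v1)
  code1 <- ifelse(is.na(iso1$partner), 2L, 1L)
  code1[cand[cand <= n1]] <- 3L
  code2 <- ifelse(is.na(iso2$partner), 2L, 1L)
  code2[cand[cand > n1] - n1] <- 3L
  reg <- cpp_best_windows(v1, v2, code1, code2, 1L, as.integer(w))
  if (nrow(reg) == 0L) return(empty)
  len <- reg[1L, 3L]
  pairs <- cbind(i = reg[1L, 1L] + 0:(len - 1L),
                 j = n1 + reg[1L, 2L] - 0:(len - 1L))
  list(pairs = pairs, energy = -reg[1L, 4L])
}

# maximal runs of consecutive candidate positions on one strand
.candidateRuns <- function(candidates, from, to) {
  pos <- candidates[candidates >= from & candidates <= to]
  if (length(pos) == 0L) return(list())
  breaks <- c(0L, which(diff(pos) != 1L), length(pos))
  lapply(seq_len(length(breaks) - 1L), function(k)
    pos[(breaks[k] + 1L):breaks[k + 1L]])
}

#' Predict the interaction seed (sliding-window scan)
#'
#' Slides a window of up to \code{w} nt along each strand; for every pair of
#' windows lying fully inside continuous candidate runs the two
#' subsequences are folded as a duplex-only complex and the lowest-energy
#' result over the scan is returned, with deterministic leftmost
#' tie-breaking.  Agrees with [findSeedConstrained()] whenever a single
#' duplex dominates.
#'
#' @inheritParams findSeedConstrained
#' @param joint the predicted joint structure (unused by the scan itself
#'   but kept for interface symmetry with candidate construction).
#' @return a [Seed-class].
#' @export
findSeedScan <- function(pair, joint, iso1, iso2, candidates, w = 6L,
                         backend = baselinePredictor()) {
  if (length(candidates) == 0L) return(.emptySeed())
  n1 <- nchar(pair@x1); n2 <- nchar(pair@x2)
  runs1 <- .candidateRuns(candidates, 1L, n1)
  runs2 <- .candidateRuns(candidates, n1 + 1L, n1 + n2)
  if (length(runs1) == 0L || length(runs2) == 0L) return(.emptySeed())
  best <- NULL
  nc <- function(n) structureConstraint(rep("nointra", n))
  for (r1 in runs1) {
    w1 <- min(w, length(r1))
    for (a in seq(r1[1L], r1[length(r1)] - w1 + 1L)) {
      win1 <- a:(a + w1 - 1L)
      s1 <- substr(pair@x1, win1[1L], win1[w1])
      for (r2 in runs2) {
        w2 <- min(w, length(r2))
        for (b in seq(r2[1L], r2[length(r2)] - w2 + 1L)) {
          win2 <- b:(b + w2 - 1L)
          s2 <- substr(pair@x2, win2[1L] - n1, win2[w2] - n1)
          sub <- foldJoint(backend, s1, s2, nc(w1), nc(w2),
                           maxRegions = 1L, maxRegionLength = as.integer(w))
          if (is.null(best) || sub@energy < best$energy) {
            # map window-local pairs back to global coordinates
            lp <- basePairs(sub)
            lp <- lp[lp[, 2L] > w1, , drop = FALSE]
            pairs <- cbind(i = win1[lp[, 1L]],
                           j = win2[lp[, 2L] - w1] )
            best <- list(energy = sub@energy, pairs = pairs)
          }
        }
      }
    }
  }
  if (is.null(best) || nrow(best$pairs) == 0L) return(.emptySeed())
  if (is(backend, "BaselinePredictor"))
    best$energy <- .duplexEnergy(pair, best$pairs)
  new("Seed", pairs = best$pairs, energy = best$energy)
}
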