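# Objective functions, GC-content constraints, overall violation and the
# constraint-dominance comparator.

.objectiveVector <- function(fdist, fint, fE, g1, g2) {
  v <- max(g1, 0) + max(g2, 0)
  new("ObjectiveVector", fdist = fdist, fint = fint, fE = fE,
      g1 = g1, g2 = g2, v = v, feasible = v == 0)
}

#' Assemble the target list for a design
#'
#' @param iso1,iso2 single-strand [TargetStructure-class] objects for the
#'   isolated strands (omitted in the single-target preset).
#' @param hyb two-strand [TargetStructure-class] for the hybridized complex.
#' @return a named list understood by [evaluateObjectives()] and
#'   [runDesign()].
#' @export
targetSet <- function(hyb, iso1 = NULL, iso2 = NULL) {
  stopifnot(is(hyb, "TargetStructure"), length(hyb@strandLengths) == 2L)
  if (!is.null(iso1)) {
    stopifnot(is(iso1, "TargetStructure"), length(iso1@strandLengths) == 1L,
              iso1@strandLengths == hyb@strandLengths[1L])
  }
  if (!is.null(iso2)) {
    stopifnot(is(iso2, "TargetStructure"), length(iso2@strandLengths) == 1L,
              iso2@strandLengths == hyb@strandLengths[2L])
  }
  list(iso1 = iso1, iso2 = iso2, hyb = hyb)
}

#' Evaluate a sequence pair against the design objectives
#'
#' Folds the two isolated strands (intermolecular pairing prohibited), the
#' hybridized complex, and the interaction seed, then computes
#' \itemize{
#'   \item \code{fdist = d_hyb + d_iso1 + d_iso2}, the summed structure
#'     distances against the three targets,
#'   \item \code{fint = E_seed + E_hyb - (E_iso1 + E_iso2)}, which rewards a
#'     stable seed and a large energy gain upon hybridization,
#'   \item \code{fE = E_hyb}, the complex energy,
#'   \item \code{g1 = gcMin - gc}, \code{g2 = gc - gcMax} and the overall
#'     violation \code{v = max(g1,0) + max(g2,0)}.
#' }
#' In the single-target preset only the hybridized target is used:
#' \code{fdist = d_hyb}, \code{fE = E_hyb} and \code{fint} is \code{NA}.
#'
#' @param s a [SequencePair-class], compatible with the targets.
#' @param targets a list from [targetSet()].
#' @param config a [DesignConfig-class] (GC bounds, seed window, preset,
#'   accessible-region model).
#' @param backend a [Predictor-class].
#' @return a list with elements \code{objectives}
#'   (an [ObjectiveVector-class]) and \code{predictions} (list of
#'   \code{iso1}, \code{iso2}, \code{hyb}, \code{seed}).
#' @export
evaluateObjectives <- function(s, targets, config = designConfig(),
                               backend = baselinePredictor()) {
  stopifnot(is(s, "SequencePair"))
  raw <- .evaluateRaw(s, targets, config, backend)
  obj <- .objectiveVector(fdist = raw$fdist, fint = raw$fint, fE = raw$fE,
                          g1 = raw$g1, g2 = raw$g2)
  n1 <- nchar(s@x1); n2 <- nchar(s@x2)
  pr <- raw$predictions
  wrapP <- function(p, sl) {
    if (is.null(p)) return(NULL)
    new("PredictedStructure", strandLengths = as.integer(sl),
        partner = p$partner, energy = p$energy)
  }
  seed <- if (is.null(pr$seed)) NULL else
    new("Seed", pairs = pr$seed$pairs, energy = pr$seed$energy)
  list(objectives = obj,
       predictions = list(iso1 = wrapP(pr$iso1, n1), iso2 = wrapP(pr$iso2, n2),
                          hyb = wrapP(pr$hyb, c(n1, n2)), seed = seed))
}

# Raw evaluation: plain lists throughout; the GA calls this per child.
.evaluateRaw <- function(s, targets, config, backend) {
  n1 <- nchar(s@x1); n2 <- nchar(s@x2)
  chars <- strsplit(.concatSeq(s), "")[[1]]
  gc <- 100 * sum(chars %in% c("G", "C")) / (n1 + n2)
  g1 <- config@gcMin - gc
  g2 <- gc - config@gcMax
  maxLen <- if (config@maxRegionLength <= 0L) min(n1, n2) else
    config@maxRegionLength
  baseline <- is(backend, "BaselinePredictor")

  if (baseline) {
    v1 <- .seqToInt(s@x1); v2 <- .seqToInt(s@x2)
    z1 <- integer(n1); z2 <- integer(n2)
    na1 <- rep(NA_integer_, n1); na2 <- rep(NA_integer_, n2)
    hyb <- .rawFoldJoint(v1, v2, z1, na1, z2, na2, config@maxRegions, maxLen)
  } else {
    h <- foldJoint(backend, s@x1, s@x2, maxRegions = config@maxRegions,
                   maxRegionLength = maxLen)
    hyb <- list(partner = h@partner, energy = h@energy,
                regions = attr(h, "regions"))
  }
  dhyb <- .distCore(hyb$partner, c(n1, n2), targets$hyb)

  if (config@preset == "single") {
    v <- max(g1, 0) + max(g2, 0)
    return(list(fdist = dhyb, fint = NA_real_, fE = hyb$energy,
                g1 = g1, g2 = g2, v = v,
                predictions = list(iso1 = NULL, iso2 = NULL, hyb = hyb,
                                   seed = NULL)))
  }

  if (baseline) {
    iso1 <- .rawFoldSingle(v1)
    iso2 <- .rawFoldSingle(v2)
  } else {
    i1 <- foldSingle(backend, s@x1)
    i2 <- foldSingle(backend, s@x2)
    iso1 <- list(partner = i1@partner, energy = i1@energy)
    iso2 <- list(partner = i2@partner, energy = i2@energy)
  }
  # seed candidates: intermolecular pairs whose endpoints are loop
  # nucleotides in both independently folded strands
  hp1 <- hyb$partner[seq_len(n1)]
  inter <- which(!is.na(hp1) & hp1 > n1)
  okc <- is.na(iso1$partner[inter]) & is.na(iso2$partner[hp1[inter] - n1])
  cand1 <- inter[okc]
  cand <- sort(c(cand1, hp1[cand1]))

  seed <- if (baseline) {
    .rawSeedConstrained(v1, v2, iso1, iso2, cand, config@seedWindow)
  } else {
    i1 <- new("PredictedStructure", strandLengths = n1,
              partner = iso1$partner, energy = iso1$energy)
    i2 <- new("PredictedStructure", strandLengths = n2,
              partner = iso2$partner, energy = iso2$energy)
    sd <- findSeedConstrained(s, i1, i2, cand, w = config@seedWindow,
                              backend = backend)
    list(pairs = sd@pairs, energy = sd@energy)
  }

  d1 <- .distCore(iso1$partner, n1, targets$iso1)
  d2 <- .distCore(iso2$partner, n2, targets$iso2)
  fint <- seed$energy + hyb$energy - (iso1$energy + iso2$energy)
  v <- max(g1, 0) + max(g2, 0)
  list(fdist = dhyb + d1 + d2, fint = fint, fE = hyb$energy,
       g1 = g1, g2 = g2, v = v,
       predictions = list(iso1 = iso1, iso2 = iso2, hyb = hyb, seed = seed))
}

#' Constraint-dominance comparison of two objective vectors
#'
#' Extended Pareto dominance with constraint handling: a feasible solution
#' dominates an infeasible one; two feasible solutions are compared by
#' standard Pareto dominance on the minimized objectives, requiring strict
#' improvement in at least one; two infeasible solutions are ordered by
#' their overall violation, with ties non-dominating.
#'
#' @param a,b [ObjectiveVector-class] objects from the same configuration.
#' @return \code{"a"}, \code{"b"} or \code{"neither"}.
#' @export
dominates <- function(a, b) {
  stopifnot(is(a, "ObjectiveVector"), is(b, "ObjectiveVector"))
  if (a@feasible && !b@feasible) return("a")
  if (!a@feasible && b@feasible) return("b")
  if (!a@feasible && !b@feasible) {
    if (a@v < b@v) return("a")
    if (b@v < a@v) return("b")
    return("neither")
  }
  fa <- c(a@fdist, a@fint, a@fE)
  fb <- c(b@fdist, b@fint, b@fE)
  keep <- !is.na(fa) & !is.na(fb)
  fa <- fa[keep]; fb <- fb[keep]
  if (all(fa <= fb) && any(fa != fb)) return("a")
  if (all(fb <= fa) && any(fa != fb)) return("b")
  "neither"
}
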