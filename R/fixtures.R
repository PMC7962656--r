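# Designable-target fixture generation and the benchmark harness.

#' Convert a predicted structure into a target structure
#'
#' Every predicted pair becomes an explicit target pair; all other
#' positions become \code{"."} (unpaired).  Used to turn the fold of a
#' known sequence into a design target that is attainable by construction.
#'
#' @param p a [PredictedStructure-class].
#' @return a [TargetStructure-class].
#' @export
asTargetStructure <- function(p) {
  stopifnot(is(p, "PredictedStructure"))
  codes <- ifelse(is.na(p@partner), ".", "P")
  new("TargetStructure", strandLengths = p@strandLengths,
      codes = codes, partner = p@partner)
}

# a random RNA string of length n with the given number of G+C nucleotides
.randomSeqGC <- function(n, gcCount) {
  strong <- sample(c("G", "C"), gcCount, replace = TRUE)
  weak <- sample(c("A", "U"), n - gcCount, replace = TRUE)
  paste(sample(c(strong, weak)), collapse = "")
}

#' Generate a designable target triple
#'
#' Emulates the predicted-dataset protocol: a random sequence pair is drawn
#' (with joint GC content inside \code{gcRange}, so the generating pair is
#' itself a feasible design), the two strands are folded independently and
#' as a complex with the backend, and the three predicted structures become
#' the targets.  By construction the generating pair attains structure
#' distance 0 on this target set, so a perfect solution exists.
#'
#' @param n1,n2 strand lengths (>= 10).
#' @param backend a [Predictor-class].
#' @param gcRange joint GC-content range (per cent) for the generating
#'   sequences; defaults to the design bounds 45--55.
#' @param maxRegions,maxRegionLength accessible-region model used for the
#'   complex fold (must match the design configuration for the fixture to
#'   be exactly attainable).
#' @return list with \code{pair} (the generating [SequencePair-class]) and
#'   \code{targets} (a [targetSet()] list).
#' @export
generateFixture <- function(n1 = 30L, n2 = 30L,
                            backend = baselinePredictor(),
                            gcRange = c(45, 55),
                            maxRegions = 1L, maxRegionLength = NULL) {
  stopifnot(n1 >= 10L, n2 >= 10L)
  n <- n1 + n2
  lo <- ceiling(gcRange[1L] * n / 100)
  hi <- floor(gcRange[2L] * n / 100)
  if (lo > hi) stop("gcRange admits no integer GC count at this length")
  gcCount <- sample(lo:hi, 1L)
  chars <- strsplit(.randomSeqGC(n, gcCount), "")[[1]]
  pair <- .pairFromChars(chars, n1)
  iso1 <- foldSingle(backend, pair@x1)
  iso2 <- foldSingle(backend, pair@x2)
  hyb <- foldJoint(backend, pair@x1, pair@x2, maxRegions = maxRegions,
                   maxRegionLength = maxRegionLength)
  list(pair = pair,
       targets = targetSet(hyb = asTargetStructure(hyb),
                           iso1 = asTargetStructure(iso1),
                           iso2 = asTargetStructure(iso2)))
}

#' Benchmark the design engine on a set of target triples
#'
#' Runs \code{runsPerTarget} independently seeded designs for every target
#' set and population size, and reports the per-run best structure distance
#' and whether the run attained a perfect design (best distance 0).  The
#' summary statistics mirror the benchmark protocol: the mean over targets
#' of the per-target best distance, and the count of perfect runs.
#'
#' @param targetSets list of [targetSet()] lists (e.g. the \code{targets}
#'   component of [generateFixture()] results).
#' @param popSizes integer vector of population sizes to compare.
#' @param runsPerTarget independent runs per target and population size.
#' @param config a [DesignConfig-class] template; its population size is
#'   overridden per grid point.  Runs stop early once a perfect design is
#'   found unless the template says otherwise.
#' @param backend a [Predictor-class].
#' @param seed base random seed; run r of target t uses a seed derived
#'   deterministically from it.
#' @return data.frame with columns \code{target}, \code{popSize},
#'   \code{run}, \code{bestDist}, \code{perfect}, \code{generations}.
#' @export
benchmarkDesigns <- function(targetSets, popSizes = c(20L, 50L),
                             runsPerTarget = 5L,
                             config = designConfig(generations = 100L,
                                                   earlyStopDistance = 0),
                             backend = baselinePredictor(), seed = 1L) {
  if (length(targetSets) == 0L) stop("no target sets supplied")
  rows <- list()
  counter <- 0L
  for (t in seq_along(targetSets)) {
    for (p in popSizes) {
      cfg <- config
      cfg@popSize <- as.integer(p)
      for (r in seq_len(runsPerTarget)) {
        counter <- counter + 1L
        runSeed <- (as.integer(seed) * 10007L + counter * 271L) %% 2147483647L
        res <- runDesign(targetSets[[t]], cfg, backend = backend,
                         seed = runSeed)
        rows[[counter]] <- data.frame(
          target = t, popSize = p, run = r, bestDist = res@bestDistance,
          perfect = res@bestDistance == 0,
          generations = res@generationsRun)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark table
#'
#' @param bench the data.frame from [benchmarkDesigns()].
#' @return data.frame with one row per population size: the mean over
#'   targets of the per-target best distance (lowest distance across that
#'   target's runs) and the total number of perfect runs.
#' @export
summarizeBenchmark <- function(bench) {
  out <- list()
  for (p in sort(unique(bench$popSize))) {
    sub <- bench[bench$popSize == p, ]
    perTarget <- tapply(sub$bestDist, sub$target, min)
    out[[length(out) + 1L]] <- data.frame(
      popSize = p, meanBestDist = mean(perTarget),
      perfectRuns = sum(sub$perfect), totalRuns = nrow(sub))
  }
  do.call(rbind, out)
}
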