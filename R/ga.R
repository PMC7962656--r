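# NSGA-II design engine: dependency-graph-aware compatible sampling, the
# four GA operators, non-dominated sorting, crowding distance, tournament
# selection, prohibited-motif mutation, and the generational loop.

#' Design run configuration
#'
#' @param popSize population size (N_p).
#' @param generations generation budget.
#' @param mutationProb per-position point-mutation probability.
#' @param gcMin,gcMax allowed GC-content range in per cent.
#' @param seedWindow maximum interaction-seed length w in base pairs.
#' @param prohibitedMotifs IUPAC motifs to eliminate (default: homopolymer
#'   tracts of four or more nucleotides).
#' @param tournamentSize tournament size for parent selection.
#' @param preset \code{"switch"} or \code{"single"} (hybridized target only).
#' @param maxRegions,maxRegionLength accessible-region model for the
#'   complex prediction (\code{maxRegionLength = 0} means unrestricted).
#' @param earlyStopDistance stop once the best structure distance reaches
#'   this value (\code{NA} = always run the full budget).
#' @return a [DesignConfig-class].
#' @export
designConfig <- function(popSize = 100L, generations = 150L,
                         mutationProb = 0.03, gcMin = 45, gcMax = 55,
                         seedWindow = 6L,
                         prohibitedMotifs = c("AAAA", "CCCC", "GGGG", "UUUU"),
                         tournamentSize = 2L, preset = c("switch", "single"),
                         maxRegions = 1L, maxRegionLength = 0L,
                         earlyStopDistance = NA_real_) {
  preset <- match.arg(preset)
  new("DesignConfig", popSize = as.integer(popSize),
      generations = as.integer(generations),
      mutationProb = mutationProb, gcMin = gcMin, gcMax = gcMax,
      seedWindow = as.integer(seedWindow),
      prohibitedMotifs = as.character(prohibitedMotifs),
      tournamentSize = as.integer(tournamentSize), preset = preset,
      maxRegions = as.integer(maxRegions),
      maxRegionLength = as.integer(maxRegionLength),
      earlyStopDistance = as.numeric(earlyStopDistance))
}

# --- dependency graph ------------------------------------------------------

# Map the explicit pairs of a target to global positions over the pair.
.globalPairs <- function(t, n1, which = c("hyb", "iso1", "iso2")) {
  which <- match.arg(which)
  pairs <- basePairs(t)
  if (which == "iso2" && nrow(pairs) > 0L) pairs <- pairs + n1
  pairs
}

#' Dependency components of the target positions
#'
#' Builds a graph over the global sequence positions whose edges are the
#' explicit base pairs of all targets; nucleotides in one connected
#' component must be assigned jointly (a position paired differently in
#' different targets links all of its partners into one component).
#'
#' @param targets a list from [targetSet()].
#' @return a list with \code{n} (total length), \code{edges} (two-column
#'   matrix of global positions), \code{membership} (component id per
#'   position), \code{components} (list of position vectors) and \code{adj}
#'   (adjacency list).
#' @export
dependencyComponents <- function(targets) {
  n1 <- targets$hyb@strandLengths[1L]
  n <- sum(targets$hyb@strandLengths)
  edges <- .globalPairs(targets$hyb, n1, "hyb")
  if (!is.null(targets$iso1))
    edges <- rbind(edges, .globalPairs(targets$iso1, n1, "iso1"))
  if (!is.null(targets$iso2))
    edges <- rbind(edges, .globalPairs(targets$iso2, n1, "iso2"))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  comps <- unname(split(seq_len(n), memb))
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # precomputed BFS order and local adjacency for larger components
  compData <- lapply(comps, function(comp) {
    m <- length(comp)
    if (m <= 2L) return(NULL)
    local <- match(seq_len(n), comp)
    adjLocal <- lapply(comp, function(p) {
      q <- local[adj[[p]]]
      q[!is.na(q)]
    })
    ord <- integer(0)
    seen <- logical(m)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      ord <- c(ord, p)
      for (q in adjLocal[[p]]) {
        if (!seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    list(adjLocal = adjLocal, ord = ord)
  })
  list(n = n, edges = edges, membership = memb,
       components = comps, adj = adj, compData = compData)
}

# --- compatible sampling ---------------------------------------------------

# Assign nucleotides to the positions of one component by randomized
# propagation with backtracking.  chars: current assignment (modified copy
# returned); pin: named character vector of fixed assignments (global
# position -> nucleotide).  Returns the component's characters or NULL when
# unsatisfiable.
.sampleComponent <- function(comp, deps, domains, pin = NULL, data = NULL) {
  m <- length(comp)
  doms <- domains[comp]
  if (!is.null(pin)) {
    pidx <- match(as.integer(names(pin)), comp)
    for (q in which(!is.na(pidx)))
      doms[[pidx[q]]] <- intersect(doms[[pidx[q]]], pin[[q]])
    if (any(lengths(doms) == 0L)) return(NULL)
  }
  # fast paths: singletons and single pairs dominate in practice
  if (m == 1L) {
    d <- doms[[1L]]
    if (length(d) == 0L) return(NULL)
    return(if (length(d) == 1L) d else sample(d, 1L))
  }
  if (m == 2L) {
    ok <- .PAIRTAB[.PAIRTAB[, 1L] %in% doms[[1L]] &
                   .PAIRTAB[, 2L] %in% doms[[2L]], , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
    k <- if (nrow(ok) == 1L) 1L else sample(nrow(ok), 1L)
    return(ok[k, ])
  }
  # general case: BFS order + randomized backtracking
  if (is.null(data)) {
    local <- match(seq_len(deps$n), comp)
    adjLocal <- lapply(comp, function(p) {
      q <- local[deps$adj[[p]]]
      q[!is.na(q)]
    })
    ord <- integer(0)
    seen <- logical(m)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      ord <- c(ord, p)
      for (q in adjLocal[[p]]) {
        if (!seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  } else {
    adjLocal <- data$adjLocal
    ord <- data$ord
  }
  assign <- rep(NA_character_, m)
  recurse <- function(k) {
    if (k > m) return(TRUE)
    pos <- ord[k]
    dom <- doms[[pos]]
    for (q in adjLocal[[pos]]) {
      if (is.na(assign[q])) next
      dom <- dom[dom %in% .PAIRABLE[[assign[q]]]]
      if (length(dom) == 0L) return(FALSE)
    }
    for (a in (if (length(dom) == 1L) dom else sample(dom, length(dom)))) {
      assign[pos] <<- a
      if (recurse(k + 1L)) return(TRUE)
      assign[pos] <<- NA_character_
    }
    FALSE
  }
  if (!recurse(1L)) return(NULL)
  assign
}

.domainsFromConstraint <- function(constraint, n) {
  if (is.null(constraint)) return(rep(list(.NTS), n))
  stopifnot(is(constraint, "SequenceConstraint"))
  if (length(constraint@codes) != n)
    stop("sequence constraint length does not match the targets")
  lapply(constraint@codes, function(code) .IUPAC_RNA[[code]])
}

#' Sample a sequence pair compatible with the targets
#'
#' Assigns nucleotides component by component along the dependency graph:
#' each explicit target pair forces its endpoints into the pairable set
#' (AU, GC, GU in either orientation) intersected with the IUPAC
#' constraints, with backtracking on cycles.  The output always passes
#' [isCompatible()] and the sequence constraints.
#'
#' @param targets a list from [targetSet()].
#' @param constraint optional [SequenceConstraint-class].
#' @param deps precomputed [dependencyComponents()] (recomputed if omitted).
#' @return a [SequencePair-class].
#' @export
sampleCompatible <- function(targets, constraint = NULL, deps = NULL) {
  if (is.null(deps)) deps <- dependencyComponents(targets)
  n <- deps$n
  domains <- .domainsFromConstraint(constraint, n)
  chars <- character(n)
  for (id in seq_along(deps$components)) {
    comp <- deps$components[[id]]
    got <- .sampleComponent(comp, deps, domains,
                            data = deps$compData[[id]])
    if (is.null(got))
      stop("unsatisfiable target/constraint combination at position(s) ",
           paste(comp, collapse = ", "))
    chars[comp] <- got
  }
  n1 <- targets$hyb@strandLengths[1L]
  sequencePair(paste(chars[seq_len(n1)], collapse = ""),
               paste(chars[(n1 + 1L):n], collapse = ""))
}

# trusted internal constructor: chars come from controlled resampling, so
# slot assignment skips validation (50x cheaper than new())
.protoCache <- new.env(parent = emptyenv())
.pairFromChars <- function(chars, n1) {
  p <- .protoCache$pair
  if (is.null(p)) {
    p <- new("SequencePair", x1 = "A", x2 = "A")
    .protoCache$pair <- p
  }
  methods::slot(p, "x1", check = FALSE) <-
    paste(chars[seq_len(n1)], collapse = "")
  methods::slot(p, "x2", check = FALSE) <-
    paste(chars[-seq_len(n1)], collapse = "")
  p
}

# resample the components listed in compIds on top of chars; returns chars
.resampleComponents <- function(chars, compIds, deps, domains, pin = NULL) {
  for (id in unique(compIds)) {
    comp <- deps$components[[id]]
    got <- .sampleComponent(comp, deps, domains, pin = pin,
                            data = deps$compData[[id]])
    if (is.null(got)) return(NULL)
    chars[comp] <- got
  }
  chars
}

# --- GA operators ----------------------------------------------------------

#' GA variation operators
#'
#' The four reproduction operators.  All of them preserve the hard
#' invariant that every produced sequence pair is compatible with the
#' targets and satisfies the IUPAC constraints; where a specific
#' reassignment is impossible they fall back to point mutation.
#'
#' \describe{
#'   \item{\code{pointMutation}}{selects each position independently with
#'     probability \code{pM} and jointly resamples the dependency
#'     components containing selected positions.}
#'   \item{\code{negativeDesign}}{picks a predicted base pair inconsistent
#'     with the targets and reassigns its endpoints to a non-pairable
#'     nucleotide combination.}
#'   \item{\code{positiveDesign}}{picks a target base pair missing from the
#'     prediction and assigns G and C to its endpoints.}
#'   \item{\code{crossoverPairs}}{concatenates the 5' part of one parent
#'     with the 3' part of another at a random cut, repairing any
#'     dependency component whose mixed assignment breaks pairability.}
#' }
#'
#' @param parent,parentA,parentB [SequencePair-class] parents.
#' @param targets a list from [targetSet()].
#' @param constraint optional [SequenceConstraint-class].
#' @param deps precomputed [dependencyComponents()].
#' @param pM per-position mutation probability.
#' @param predictions cached predictions of the parent (list with
#'   \code{iso1}, \code{iso2}, \code{hyb}) as returned by
#'   [evaluateObjectives()].
#' @return a [SequencePair-class].
#' @name gaOperators
NULL

.depsDomains <- function(targets, constraint, deps) {
  if (is.null(deps)) deps <- dependencyComponents(targets)
  if (!is.null(deps$domains))
    return(list(deps = deps, domains = deps$domains))
  domains <- .domainsFromConstraint(constraint, deps$n)
  list(deps = deps, domains = domains)
}

#' @rdname gaOperators
#' @export
pointMutation <- function(parent, targets, constraint = NULL, pM = 0.03,
                          deps = NULL) {
  dd <- .depsDomains(targets, constraint, deps)
  n <- dd$deps$n
  chars <- strsplit(.concatSeq(parent), "")[[1]]
  hit <- which(stats::runif(n) < pM)
  if (length(hit) == 0L) return(parent)
  new <- .resampleComponents(chars, dd$deps$membership[hit], dd$deps,
                             dd$domains)
  if (is.null(new)) return(parent)
  .pairFromChars(new, targets$hyb@strandLengths[1L])
}

# base pairs of a prediction, accepting either the S4 class or the raw list
.bpOf <- function(p) {
  if (is.list(p)) .partnerToPairs(p$partner) else basePairs(p)
}

# predicted pairs (global coordinates) of all cached predictions, with the
# target each is judged against
.predictedPairs <- function(predictions, targets) {
  n1 <- targets$hyb@strandLengths[1L]
  out <- list()
  if (!is.null(predictions$iso1) && !is.null(targets$iso1))
    out$iso1 <- list(pairs = .bpOf(predictions$iso1), target = targets$iso1,
                     offset = 0L)
  if (!is.null(predictions$iso2) && !is.null(targets$iso2))
    out$iso2 <- list(pairs = .bpOf(predictions$iso2) + n1,
                     target = targets$iso2, offset = n1)
  out$hyb <- list(pairs = .bpOf(predictions$hyb), target = targets$hyb,
                  offset = 0L)
  out
}

#' @rdname gaOperators
#' @export
negativeDesign <- function(parent, predictions, targets, constraint = NULL,
                           deps = NULL, pM = 0.03) {
  dd <- .depsDomains(targets, constraint, deps)
  n1 <- targets$hyb@strandLengths[1L]
  undesired <- NULL
  for (pp in .predictedPairs(predictions, targets)) {
    if (nrow(pp$pairs) == 0L) next
    sl <- pp$target@strandLengths
    li <- pp$pairs[, 1L] - pp$offset
    lj <- pp$pairs[, 2L] - pp$offset
    same <- if (length(sl) == 1L) rep(TRUE, length(li)) else
      .strandOf(li, sl) == .strandOf(lj, sl)
    okEnd <- function(pos, partner) {
      code <- pp$target@codes[pos]
      out <- logical(length(pos))
      out[code == "*" | code == "+"] <- TRUE
      out[code == "@"] <- same[code == "@"]
      out[code == "^"] <- !same[code == "^"]
      isP <- code == "P"
      out[isP] <- pp$target@partner[pos[isP]] == partner[isP]
      out
    }
    bad <- !(okEnd(li, lj) & okEnd(lj, li))
    if (any(bad))
      undesired <- rbind(undesired, pp$pairs[bad, , drop = FALSE])
  }
  if (is.null(undesired))
    return(pointMutation(parent, targets, constraint, pM, dd$deps))
  pick <- undesired[sample(nrow(undesired), 1L), ]
  i <- pick[1L]; j <- pick[2L]
  chars <- strsplit(.concatSeq(parent), "")[[1]]
  combos <- .NONPAIRTAB[.NONPAIRTAB[, 1L] %in% dd$domains[[i]] &
                        .NONPAIRTAB[, 2L] %in% dd$domains[[j]], , drop = FALSE]
  if (nrow(combos) > 0L) {
    for (k in sample(nrow(combos), nrow(combos))) {
      pin <- stats::setNames(c(combos[k, 1L], combos[k, 2L]),
                             as.character(c(i, j)))
      new <- .resampleComponents(chars, dd$deps$membership[c(i, j)],
                                 dd$deps, dd$domains, pin = pin)
      if (!is.null(new) && !.pairable(new[i], new[j]))
        return(.pairFromChars(new, n1))
    }
  }
  pointMutation(parent, targets, constraint, pM, dd$deps)
}

#' @rdname gaOperators
#' @export
positiveDesign <- function(parent, predictions, targets, constraint = NULL,
                           deps = NULL, pM = 0.03) {
  dd <- .depsDomains(targets, constraint, deps)
  n1 <- targets$hyb@strandLengths[1L]
  missing <- NULL
  for (pp in .predictedPairs(predictions, targets)) {
    tp <- basePairs(pp$target)
    if (nrow(tp) == 0L) next
    predPartner <- rep(NA_integer_, sum(pp$target@strandLengths))
    if (nrow(pp$pairs) > 0L) {
      li <- pp$pairs[, 1L] - pp$offset
      lj <- pp$pairs[, 2L] - pp$offset
      predPartner[li] <- lj
      predPartner[lj] <- li
    }
    miss <- is.na(predPartner[tp[, 1L]]) | predPartner[tp[, 1L]] != tp[, 2L]
    if (any(miss))
      missing <- rbind(missing, tp[miss, , drop = FALSE] + pp$offset)
  }
  if (is.null(missing))
    return(pointMutation(parent, targets, constraint, pM, dd$deps))
  pick <- missing[sample(nrow(missing), 1L), ]
  i <- pick[1L]; j <- pick[2L]
  chars <- strsplit(.concatSeq(parent), "")[[1]]
  orientations <- list(c("G", "C"), c("C", "G"))
  for (ori in sample(orientations, 2L)) {
    if (!(ori[1L] %in% dd$domains[[i]]) || !(ori[2L] %in% dd$domains[[j]]))
      next
    pin <- stats::setNames(ori, as.character(c(i, j)))
    new <- .resampleComponents(chars, dd$deps$membership[c(i, j)],
                               dd$deps, dd$domains, pin = pin)
    if (!is.null(new)) return(.pairFromChars(new, n1))
  }
  pointMutation(parent, targets, constraint, pM, dd$deps)
}

#' @rdname gaOperators
#' @export
crossoverPairs <- function(parentA, parentB, targets, constraint = NULL,
                           deps = NULL) {
  dd <- .depsDomains(targets, constraint, deps)
  n <- dd$deps$n
  n1 <- targets$hyb@strandLengths[1L]
  cut <- sample(n - 1L, 1L)
  ca <- strsplit(.concatSeq(parentA), "")[[1]]
  cb <- strsplit(.concatSeq(parentB), "")[[1]]
  chars <- c(ca[seq_len(cut)], cb[(cut + 1L):n])
  # repair components whose mixed assignment breaks pairability
  broken <- integer(0)
  if (nrow(dd$deps$edges) > 0L) {
    for (k in seq_len(nrow(dd$deps$edges))) {
      i <- dd$deps$edges[k, 1L]; j <- dd$deps$edges[k, 2L]
      if (!.pairable(chars[i], chars[j]))
        broken <- c(broken, dd$deps$membership[i])
    }
  }
  if (length(broken) > 0L) {
    new <- .resampleComponents(chars, broken, dd$deps, dd$domains)
    if (is.null(new)) return(parentA)
    chars <- new
  }
  .pairFromChars(chars, n1)
}

#' Eliminate prohibited sequence motifs
#'
#' Scans both strands for matches of the IUPAC motifs and resamples the
#' dependency components overlapping each match, retrying up to
#' \code{maxTries} times.  This is a soft constraint: if a motif cannot be
#' eliminated (e.g. it is forced by the sequence constraints) the sequence
#' is kept and flagged via the \code{"motifFlagged"} attribute.
#'
#' @param s a [SequencePair-class].
#' @param motifs character vector of IUPAC motifs.
#' @param targets a list from [targetSet()].
#' @param constraint optional [SequenceConstraint-class].
#' @param deps precomputed [dependencyComponents()].
#' @param maxTries resampling attempts before giving up.
#' @return a [SequencePair-class]; attribute \code{motifFlagged} is TRUE
#'   when a motif persists.
#' @export
mutateProhibitedMotifs <- function(s, motifs, targets, constraint = NULL,
                                   deps = NULL, maxTries = 10L) {
  if (length(motifs) == 0L) return(s)
  dd <- .depsDomains(targets, constraint, deps)
  n1 <- targets$hyb@strandLengths[1L]
  pattern <- .iupacToRegex(motifs)
  findHits <- function(chars) {
    hits <- integer(0)
    strands <- list(seq_len(n1), (n1 + 1L):dd$deps$n)
    for (idx in strands) {
      str <- paste(chars[idx], collapse = "")
      m <- gregexpr(pattern, str, perl = TRUE)[[1L]]
      if (m[1L] != -1L) {
        len <- attr(m, "capture.length")[, 1L]
        for (q in seq_along(m))
          hits <- c(hits, idx[m[q]:(m[q] + len[q] - 1L)])
      }
    }
    unique(hits)
  }
  chars <- strsplit(.concatSeq(s), "")[[1]]
  for (try in seq_len(maxTries)) {
    hits <- findHits(chars)
    if (length(hits) == 0L) {
      out <- .pairFromChars(chars, n1)
      attr(out, "motifFlagged") <- FALSE
      return(out)
    }
    new <- .resampleComponents(chars, dd$deps$membership[hits], dd$deps,
                               dd$domains)
    if (!is.null(new)) chars <- new
  }
  out <- if (length(findHits(chars)) == 0L) {
    res <- .pairFromChars(chars, n1)
    attr(res, "motifFlagged") <- FALSE
    res
  } else {
    res <- s
    attr(res, "motifFlagged") <- TRUE
    res
  }
  out
}

# IUPAC motifs -> one overlapping-match regex (lookahead, one capture group)
.iupacToRegex <- function(motifs) {
  one <- function(motif) {
    chars <- strsplit(toupper(motif), "")[[1]]
    cls <- vapply(chars, function(ch) {
      set <- .IUPAC_RNA[[ch]]
      if (is.null(set)) stop("invalid IUPAC code '", ch, "' in motif")
      if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
    }, character(1))
    paste(cls, collapse = "")
  }
  paste0("(?=(", paste(vapply(motifs, one, character(1)), collapse = "|"), "))")
}

# --- non-dominated sorting and crowding ------------------------------------

.objectiveMatrix <- function(objectives) {
  fdist <- vapply(objectives, function(o) o@fdist, numeric(1))
  fint <- vapply(objectives, function(o) o@fint, numeric(1))
  fE <- vapply(objectives, function(o) o@fE, numeric(1))
  v <- vapply(objectives, function(o) o@v, numeric(1))
  m <- cbind(fdist = fdist, fint = fint, fE = fE)
  m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  list(objs = m, v = v)
}

#' Non-dominated sorting under constraint dominance
#'
#' @param objectives list of [ObjectiveVector-class] (or of
#'   [Solution-class], whose objectives are extracted).
#' @return list of fronts, each an integer vector of indices into
#'   \code{objectives}; front 1 contains the solutions dominated by none.
#' @export
nondominatedSort <- function(objectives) {
  if (length(objectives) == 0L) return(list())
  if (is(objectives[[1L]], "Solution"))
    objectives <- lapply(objectives, function(s) s@objectives)
  om <- .objectiveMatrix(objectives)
  ranks <- cpp_pareto_ranks(om$objs, om$v)
  lapply(seq_len(max(ranks)), function(r) which(ranks == r))
}

#' NSGA-II crowding distance within one front
#'
#' Per objective the front is sorted; boundary solutions receive infinite
#' distance and interior solutions accumulate the normalized gap between
#' their neighbours.  Objectives with zero range contribute nothing.
#'
#' @param objectives list of [ObjectiveVector-class] (or [Solution-class])
#'   forming one front.
#' @return numeric vector of crowding distances aligned with the input.
#' @export
crowdingDistance <- function(objectives) {
  if (length(objectives) == 0L) return(numeric(0))
  if (is(objectives[[1L]], "Solution"))
    objectives <- lapply(objectives, function(s) s@objectives)
  .crowdMatrix(.objectiveMatrix(objectives)$objs)
}

.crowdMatrix <- function(m) {
  nsol <- nrow(m)
  if (nsol <= 2L) return(rep(Inf, nsol))
  d <- rep(0, nsol)
  for (j in seq_len(ncol(m))) {
    ord <- order(m[, j])
    rng <- m[ord[nsol], j] - m[ord[1L], j]
    d[ord[c(1L, nsol)]] <- Inf
    if (rng > 0) {
      vals <- m[ord, j]
      d[ord[2L:(nsol - 1L)]] <- d[ord[2L:(nsol - 1L)]] +
        (vals[3L:nsol] - vals[1L:(nsol - 2L)]) / rng
    }
  }
  d
}

# --- generational loop -----------------------------------------------------

.tournament <- function(ranks, crowding, size) {
  cand <- sample(length(ranks), size, replace = length(ranks) < size)
  best <- cand[1L]
  for (c in cand[-1L]) {
    if (ranks[c] < ranks[best] ||
        (ranks[c] == ranks[best] && crowding[c] > crowding[best]))
      best <- c
  }
  best
}

#' Run a full multi-objective design
#'
#' Initializes a population of target-compatible sequence pairs, then
#' iterates NSGA-II generations: the parent and child sets are pooled,
#' non-dominated sorting under constraint dominance ranks them, the best
#' \code{popSize} survive (ties broken by larger crowding distance), and
#' new children are bred by binary tournament selection followed by one of
#' the four variation operators (chosen uniformly at random) and
#' prohibited-motif elimination.  Fully reproducible given \code{seed}.
#'
#' @param targets a list from [targetSet()] (for the \code{"single"}
#'   preset only \code{hyb} is consulted).
#' @param config a [DesignConfig-class].
#' @param constraint optional [SequenceConstraint-class].
#' @param backend a [Predictor-class].
#' @param seed integer random seed (\code{NULL} = leave the RNG state).
#' @return a [DesignResult-class]: the final non-dominated archive, the
#'   per-generation log, and the best structure distance attained.
#' @export
runDesign <- function(targets, config = designConfig(), constraint = NULL,
                      backend = baselinePredictor(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config@preset == "switch" &&
      (is.null(targets$iso1) || is.null(targets$iso2)))
    stop("the switch preset needs iso1, iso2 and hyb targets")
  deps <- dependencyComponents(targets)
  deps$domains <- .domainsFromConstraint(constraint, deps$n)
  motifLog <- 0L

  breed <- function(pop, ranks, crowding) {
    op <- sample(4L, 1L)
    a <- pop[[.tournament(ranks, crowding, config@tournamentSize)]]
    child <- switch(op,
      pointMutation(a$pair, targets, constraint, config@mutationProb, deps),
      negativeDesign(a$pair, a$predictions, targets, constraint, deps,
                     config@mutationProb),
      positiveDesign(a$pair, a$predictions, targets, constraint, deps,
                     config@mutationProb),
      {
        b <- pop[[.tournament(ranks, crowding, config@tournamentSize)]]
        crossoverPairs(a$pair, b$pair, targets, constraint, deps)
      })
    child <- mutateProhibitedMotifs(child, config@prohibitedMotifs, targets,
                                    constraint, deps)
    if (isTRUE(attr(child, "motifFlagged"))) motifLog <<- motifLog + 1L
    child
  }

  # evaluation cache: prediction is deterministic, so duplicate genotypes
  # (common near convergence) are priced once
  evalCache <- new.env(parent = emptyenv())
  evalPair <- function(pair) {
    key <- paste0(pair@x1, "&", pair@x2)
    hit <- evalCache[[key]]
    if (!is.null(hit)) {
      hit$pair <- pair
      return(hit)
    }
    ev <- .evaluateRaw(pair, targets, config, backend)
    ev$pair <- pair
    evalCache[[key]] <- ev
    ev
  }

  # initialization: popSize compatible solutions, motifs eliminated
  P <- vector("list", config@popSize)
  for (k in seq_len(config@popSize)) {
    pair <- sampleCompatible(targets, constraint, deps)
    pair <- mutateProhibitedMotifs(pair, config@prohibitedMotifs, targets,
                                   constraint, deps)
    if (isTRUE(attr(pair, "motifFlagged"))) motifLog <- motifLog + 1L
    P[[k]] <- evalPair(pair)
  }
  bestDist <- min(vapply(P, `[[`, numeric(1), "fdist"))

  rankCrowd <- function(pop) {
    fd <- vapply(pop, `[[`, numeric(1), "fdist")
    fi <- vapply(pop, `[[`, numeric(1), "fint")
    fe <- vapply(pop, `[[`, numeric(1), "fE")
    vv <- vapply(pop, `[[`, numeric(1), "v")
    m <- cbind(fd, fi, fe)
    m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
    ranks <- cpp_pareto_ranks(m, vv)
    crowd <- numeric(length(pop))
    fronts <- lapply(seq_len(max(ranks)), function(r) which(ranks == r))
    for (idx in fronts)
      crowd[idx] <- .crowdMatrix(m[idx, , drop = FALSE])
    list(fronts = fronts, ranks = ranks, crowding = crowd,
         fd = fd, fi = fi, fe = fe, vv = vv)
  }
  rc <- rankCrowd(P)

  logRows <- list()
  gen <- 0L
  logRow <- function(rc, gen) {
    data.frame(generation = gen, front1 = sum(rc$ranks == min(rc$ranks)),
               fronts = length(unique(rc$ranks)), best_fdist = min(rc$fd),
               best_fint = if (all(is.na(rc$fi))) NA_real_ else
                 min(rc$fi, na.rm = TRUE),
               best_fE = min(rc$fe), mean_violation = mean(rc$vv),
               feasible = sum(rc$vv == 0), motif_persist = motifLog)
  }
  logRows[[1L]] <- logRow(rc, 0L)

  stopEarly <- function() !is.na(config@earlyStopDistance) &&
    bestDist <= config@earlyStopDistance
  while (gen < config@generations && !stopEarly()) {
    gen <- gen + 1L
    C <- vector("list", config@popSize)
    for (k in seq_len(config@popSize)) {
      child <- breed(P, rc$ranks, rc$crowding)
      C[[k]] <- evalPair(child)
    }
    bestDist <- min(bestDist, vapply(C, `[[`, numeric(1), "fdist"))
    pool <- c(P, C)
    rcPool <- rankCrowd(pool)
    keep <- integer(0)
    for (r in seq_along(rcPool$fronts)) {
      idx <- rcPool$fronts[[r]]
      room <- config@popSize - length(keep)
      if (room <= 0L) break
      if (length(idx) <= room) {
        keep <- c(keep, idx)
      } else {
        ord <- idx[order(rcPool$crowding[idx], decreasing = TRUE)]
        keep <- c(keep, ord[seq_len(room)])
      }
    }
    P <- pool[keep]
    # the survivors inherit rank and crowding from the pool-level sort
    rc <- list(fronts = list(which(rcPool$ranks[keep] ==
                                     min(rcPool$ranks[keep]))),
               ranks = rcPool$ranks[keep],
               crowding = rcPool$crowding[keep],
               fd = rcPool$fd[keep], fi = rcPool$fi[keep],
               fe = rcPool$fe[keep], vv = rcPool$vv[keep])
    logRows[[length(logRows) + 1L]] <- logRow(rc, gen)
  }

  n1 <- targets$hyb@strandLengths[1L]
  n2 <- targets$hyb@strandLengths[2L]
  wrapP <- function(p, sl) {
    if (is.null(p)) return(NULL)
    new("PredictedStructure", strandLengths = as.integer(sl),
        partner = p$partner, energy = p$energy)
  }
  front1 <- rc$fronts[[1L]]
  archive <- lapply(front1, function(k) {
    s <- P[[k]]
    obj <- .objectiveVector(s$fdist, s$fint, s$fE, s$g1, s$g2)
    preds <- list(iso1 = wrapP(s$predictions$iso1, n1),
                  iso2 = wrapP(s$predictions$iso2, n2),
                  hyb = wrapP(s$predictions$hyb, c(n1, n2)),
                  seed = if (is.null(s$predictions$seed)) NULL else
                    new("Seed", pairs = s$predictions$seed$pairs,
                        energy = s$predictions$seed$energy))
    new("Solution", pair = s$pair, objectives = obj,
        rank = 1, crowding = rc$crowding[k], predictions = preds)
  })
  new("DesignResult", archive = archive,
      log = do.call(rbind, logRows), bestDistance = bestDist,
      config = config, generationsRun = gen)
}
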