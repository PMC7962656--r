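.seqToInt <- function(x) {
  v <- match(strsplit(x, "")[[1]], .NTS) - 1L
  if (anyNA(v)) stop("sequence contains characters outside A/C/G/U")
  v
}

.intToSeq <- function(v) paste(.NTS[v + 1L], collapse = "")

.pairable <- function(a, b) b %in% .PAIRABLE[[a]]

.checkRNA <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x) ||
      !grepl("^[ACGU]+$", x))
    stop(what, " must be a non-empty string over A, C, G, U")
  invisible(x)
}

#' Construct a sequence pair
#'
#' @param x1,x2 RNA sequences (strings over A, C, G, U); lowercase and T are
#'   normalized.
#' @return A [SequencePair-class].
#' @examples
#' sequencePair("GGGAAACCC", "AAAAUUUU")
#' @export
sequencePair <- function(x1, x2) {
  norm <- function(x) chartr("acgutT", "ACGUUU", x)
  x1 <- norm(x1); x2 <- norm(x2)
  .checkRNA(x1, "x1"); .checkRNA(x2, "x2")
  new("SequencePair", x1 = x1, x2 = x2)
}

#' Strand lengths of a structure or pair
#' @param x a TargetStructure, PredictedStructure or SequencePair.
#' @return integer vector of strand lengths.
#' @export
setGeneric("strandLengths", function(x) standardGeneric("strandLengths"))

#' @rdname strandLengths
#' @export
setMethod("strandLengths", "TargetStructure", function(x) x@strandLengths)
#' @rdname strandLengths
#' @export
setMethod("strandLengths", "PredictedStructure", function(x) x@strandLengths)
#' @rdname strandLengths
#' @export
setMethod("strandLengths", "SequencePair",
          function(x) c(nchar(x@x1), nchar(x@x2)))

#' Base pairs of a structure
#'
#' @param x a TargetStructure, PredictedStructure or Seed.
#' @return two-column integer matrix of global positions (i < j for
#'   intramolecular pairs; strand-1 then strand-2 position for seeds).
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

.partnerToPairs <- function(partner) {
  i <- which(!is.na(partner) & seq_along(partner) < partner)
  cbind(i = i, j = partner[i], deparse.level = 0)
}

#' @rdname basePairs
#' @export
setMethod("basePairs", "TargetStructure",
          function(x) .partnerToPairs(x@partner))
#' @rdname basePairs
#' @export
setMethod("basePairs", "PredictedStructure",
          function(x) .partnerToPairs(x@partner))
#' @rdname basePairs
#' @export
setMethod("basePairs", "Seed", function(x) x@pairs)

#' Backend energy of a prediction or seed
#' @param x a PredictedStructure or Seed.
#' @return numeric(1) in backend units.
#' @export
setGeneric("energy", function(x) standardGeneric("energy"))
#' @rdname energy
#' @export
setMethod("energy", "PredictedStructure", function(x) x@energy)
#' @rdname energy
#' @export
setMethod("energy", "Seed", function(x) x@energy)

#' Sequences of a pair
#' @param x a SequencePair.
#' @return named character vector \code{c(strand1 = ..., strand2 = ...)}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname sequences
#' @export
setMethod("sequences", "SequencePair",
          function(x) c(strand1 = x@x1, strand2 = x@x2))

#' Objective values as a named numeric vector
#' @param x an ObjectiveVector or Solution.
#' @return named numeric vector with fdist, fint, fE, g1, g2, v.
#' @export
setGeneric("objectiveValues", function(x) standardGeneric("objectiveValues"))
#' @rdname objectiveValues
#' @export
setMethod("objectiveValues", "ObjectiveVector", function(x)
  c(fdist = x@fdist, fint = x@fint, fE = x@fE, g1 = x@g1, g2 = x@g2, v = x@v))
#' @rdname objectiveValues
#' @export
setMethod("objectiveValues", "Solution",
          function(x) objectiveValues(x@objectives))

setMethod("show", "SequencePair", function(object) {
  cat("SequencePair (", nchar(object@x1), "+", nchar(object@x2), " nt)\n",
      "  strand1: ", object@x1, "\n  strand2: ", object@x2, "\n", sep = "")
})

setMethod("show", "TargetStructure", function(object) {
  cat("TargetStructure (", paste(object@strandLengths, collapse = " + "),
      " nt, ", nrow(basePairs(object)), " explicit pairs)\n  ",
      renderDotBracket(object), "\n", sep = "")
})

setMethod("show", "PredictedStructure", function(object) {
  np <- nrow(basePairs(object))
  cat("PredictedStructure (", paste(object@strandLengths, collapse = " + "),
      " nt, ", np, " pairs, energy ", object@energy, ")\n", sep = "")
})

setMethod("show", "Seed", function(object) {
  if (nrow(object@pairs) == 0L) {
    cat("Seed: empty (energy 0)\n")
  } else {
    cat("Seed: ", nrow(object@pairs), " intermolecular pairs, energy ",
        object@energy, "\n", sep = "")
  }
})

setMethod("show", "ObjectiveVector", function(object) {
  cat(sprintf(
    "ObjectiveVector: fdist=%g fint=%g fE=%g  g1=%.2f g2=%.2f v=%.2f (%s)\n",
    object@fdist, object@fint, object@fE, object@g1, object@g2, object@v,
    if (object@feasible) "feasible" else "infeasible"))
})

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult: ", length(object@archive), " archived solutions, ",
      object@generationsRun, " generations, best structure distance ",
      object@bestDistance, "\n", sep = "")
})

# strand index (1 or 2) of a global position
.strandOf <- function(pos, strandLengths) {
  ifelse(pos <= strandLengths[1L], 1L, 2L)
}

# global concatenated sequence of a pair
.concatSeq <- function(pair) paste0(pair@x1, pair@x2)

#' Free structure constraint of a given length
#' @param n number of positions.
#' @return a [StructureConstraint-class] with all positions free.
#' @export
freeConstraint <- function(n) {
  new("StructureConstraint", codes = rep("free", n),
      partner = rep(NA_integer_, n))
}

#' Build a structure constraint
#'
#' @param codes character vector over \code{free}, \code{pair},
#'   \code{nopair}, \code{nointra}, \code{nointer}.
#' @param partner integer vector of enforced partners (strand-local,
#'   symmetric) for positions coded \code{pair}; \code{NA} elsewhere.
#' @return a [StructureConstraint-class].
#' @export
structureConstraint <- function(codes, partner = rep(NA_integer_, length(codes))) {
  new("StructureConstraint", codes = codes, partner = as.integer(partner))
}
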