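# Structure-prediction backends: the deterministic built-in baseline and an
# adapter for external command-line folding programs.

.CONS_CODE <- c(free = 0L, pair = 1L, nopair = 2L, nointra = 3L, nointer = 4L)

.consToInt <- function(constraint, n) {
  if (is.null(constraint)) constraint <- freeConstraint(n)
  stopifnot(is(constraint, "StructureConstraint"))
  if (length(constraint@codes) != n)
    stop("constraint length (", length(constraint@codes),
         ") does not match sequence length (", n, ")")
  list(code = unname(.CONS_CODE[constraint@codes]),
       partner = constraint@partner)
}

#' Construct the built-in baseline predictor
#' @return a [BaselinePredictor-class].
#' @export
baselinePredictor <- function() new("BaselinePredictor")

# Raw folding layer: plain lists over the C++ engine, shared by the S4
# methods and the GA hot loop (which avoids S4 construction per child).
.rawFoldSingle <- function(v, code = integer(length(v)),
                           partner = rep(NA_integer_, length(v))) {
  res <- cpp_fold_single(v, code, partner)
  if (!isTRUE(res$ok))
    stop("contradictory structure constraints: no valid structure exists")
  list(partner = as.integer(res$partner), energy = -as.numeric(res$score))
}

.rawFoldJoint <- function(v1, v2, code1, partner1, code2, partner2,
                          maxRegions, maxLen) {
  res <- cpp_fold_joint(v1, v2, code1, partner1, code2, partner2,
                        as.integer(maxRegions), as.integer(maxLen))
  if (!isTRUE(res$ok))
    stop("contradictory structure constraints: no valid structure exists")
  list(partner = as.integer(res$partner), energy = -as.numeric(res$score),
       regions = res$regions)
}

#' Fold a single RNA strand
#'
#' @param backend a [Predictor-class] backend.
#' @param x RNA sequence string.
#' @param constraint optional [StructureConstraint-class] (strand-local
#'   enforced partners).
#' @return a [PredictedStructure-class].
#' @details The baseline backend computes the maximum-score pseudoknot-free
#'   intramolecular structure by dynamic programming with pair weights
#'   GC/CG = 3, AU/UA = 2, GU/UG = 1 and a minimum hairpin loop of 3 nt,
#'   honoring the constraints; the energy is the negated total pair score.
#'   Tie-breaks are deterministic (the unpaired option is preferred, then
#'   the leftmost partner), so identical inputs give identical outputs.
#' @examples
#' foldSingle(baselinePredictor(), "GGGAAACCC")
#' @export
setGeneric("foldSingle", function(backend, x, constraint = NULL)
  standardGeneric("foldSingle"))

#' Fold a two-strand complex
#'
#' @param backend a [Predictor-class] backend.
#' @param x1,x2 RNA sequence strings.
#' @param c1,c2 optional per-strand [StructureConstraint-class] objects.
#' @param maxRegions maximum number of accessible (intermolecular duplex)
#'   regions; the complex model uses one region.
#' @param maxRegionLength maximum duplex-region length in nucleotides per
#'   strand (\code{NULL} = unrestricted).
#' @return a [PredictedStructure-class] over both strands with a
#'   \code{regions} attribute (matrix: strand-1 start, strand-2 start
#'   partner, length, score).
#' @details The baseline backend enumerates all contiguous antiparallel
#'   intermolecular duplex windows respecting constraints, greedily selects
#'   up to \code{maxRegions} best-scoring non-overlapping windows
#'   (ties: leftmost on strand 1, then strand 2), then folds the remaining
#'   positions of each strand intramolecularly.  Because a duplex window may
#'   connect two hairpin loops, kissing-hairpin (external pseudoknot)
#'   topologies are representable.  With \code{maxRegions = 0} the result
#'   equals two independent single-strand folds.
#' @examples
#' foldJoint(baselinePredictor(), "AAAA", "UUUU")
#' @export
setGeneric("foldJoint", function(backend, x1, x2, c1 = NULL, c2 = NULL,
                                 maxRegions = 1L, maxRegionLength = NULL)
  standardGeneric("foldJoint"))

#' @rdname foldSingle
#' @export
setMethod("foldSingle", "BaselinePredictor", function(backend, x, constraint = NULL) {
  .checkRNA(x)
  v <- .seqToInt(x)
  cc <- .consToInt(constraint, length(v))
  res <- .rawFoldSingle(v, cc$code, cc$partner)
  new("PredictedStructure", strandLengths = length(v),
      partner = res$partner, energy = res$energy)
})

#' @rdname foldJoint
#' @export
setMethod("foldJoint", "BaselinePredictor",
          function(backend, x1, x2, c1 = NULL, c2 = NULL,
                   maxRegions = 1L, maxRegionLength = NULL) {
  .checkRNA(x1, "x1"); .checkRNA(x2, "x2")
  v1 <- .seqToInt(x1); v2 <- .seqToInt(x2)
  cc1 <- .consToInt(c1, length(v1))
  cc2 <- .consToInt(c2, length(v2))
  if (is.null(maxRegionLength)) maxRegionLength <- min(length(v1), length(v2))
  res <- .rawFoldJoint(v1, v2, cc1$code, cc1$partner, cc2$code, cc2$partner,
                       maxRegions, maxRegionLength)
  out <- new("PredictedStructure",
             strandLengths = c(length(v1), length(v2)),
             partner = res$partner, energy = res$energy)
  attr(out, "regions") <- res$regions
  out
})

# --- external backend adapter ---------------------------------------------

#' Construct an adapter around an external folding program
#'
#' The program must accept the sequence on stdin (two strands joined by
#' \code{"&"} for complexes, the RNAfold/RNAcofold convention), optionally
#' followed by a one-character-per-position constraint line, and print a
#' dot-bracket line ending in the energy in parentheses.  The constraint
#' dialect emitted is: \code{.} free, \code{x} all pairs prohibited,
#' \code{i} intramolecular pairs prohibited, \code{e} intermolecular pairs
#' prohibited, and \code{(}/\code{)} for an enforced pair.
#'
#' @param command executable name or path; resolved at construction and a
#'   missing executable is a configuration error.
#' @param args character vector of arguments always passed.
#' @param constraintArgs arguments appended when a non-trivial constraint is
#'   supplied (e.g. \code{"-C"}).
#' @param name label used for the backend's energy units.
#' @return an [ExternalPredictor-class].
#' @export
externalPredictor <- function(command, args = character(0),
                              constraintArgs = character(0),
                              name = basename(command)) {
  resolved <- Sys.which(command)
  if (!nzchar(resolved) && !file.exists(command))
    stop("external predictor executable not found: ", command)
  new("ExternalPredictor", command = command, args = args,
      constraintArgs = constraintArgs, name = name)
}

.constraintDialect <- function(constraint, n) {
  if (is.null(constraint)) return(NULL)
  ch <- character(n)
  map <- c(free = ".", nopair = "x", nointra = "i", nointer = "e")
  for (i in seq_len(n)) {
    code <- constraint@codes[i]
    if (code == "pair") {
      ch[i] <- if (constraint@partner[i] > i) "(" else ")"
    } else ch[i] <- map[[code]]
  }
  s <- paste(ch, collapse = "")
  if (grepl("^\\.*$", s)) NULL else s
}

.runExternal <- function(backend, input) {
  out <- tryCatch(
    suppressWarnings(system2(backend@command, args = c(backend@args),
                             input = input, stdout = TRUE, stderr = FALSE)),
    error = function(e) stop("external predictor '", backend@name,
                             "' failed to run: ", conditionMessage(e)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("external predictor '", backend@name, "' exited with status ", status)
  out
}

.parseExternalOutput <- function(lines, n, backendName) {
  pat <- "^([.()\\[\\]{}<>&]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$"
  hit <- grep(pat, lines, value = TRUE, perl = TRUE)
  if (length(hit) == 0L)
    stop("unparseable output from external predictor '", backendName, "'")
  m <- regmatches(hit[1L], regexec(pat, hit[1L], perl = TRUE))[[1L]]
  struct <- m[2]; en <- as.numeric(m[3])
  t <- parseDotBracket(struct)
  if (sum(t@strandLengths) != n)
    stop("external predictor '", backendName,
         "' returned a structure of the wrong length")
  new("PredictedStructure", strandLengths = t@strandLengths,
      partner = t@partner, energy = en)
}

#' @rdname foldSingle
#' @export
setMethod("foldSingle", "ExternalPredictor", function(backend, x, constraint = NULL) {
  .checkRNA(x)
  cons <- .constraintDialect(constraint, nchar(x))
  input <- c(x, cons)
  bk <- backend
  if (!is.null(cons)) bk@args <- c(bk@args, bk@constraintArgs)
  out <- .runExternal(bk, input)
  res <- .parseExternalOutput(out, nchar(x), backend@name)
  if (length(res@strandLengths) != 1L)
    stop("external predictor returned a complex structure for a single strand")
  res
})

#' @rdname foldJoint
#' @export
setMethod("foldJoint", "ExternalPredictor",
          function(backend, x1, x2, c1 = NULL, c2 = NULL,
                   maxRegions = 1L, maxRegionLength = NULL) {
  .checkRNA(x1, "x1"); .checkRNA(x2, "x2")
  n1 <- nchar(x1); n2 <- nchar(x2)
  cons1 <- .constraintDialect(c1, n1)
  cons2 <- .constraintDialect(c2, n2)
  cons <- if (is.null(cons1) && is.null(cons2)) NULL else
    paste0(if (is.null(cons1)) strrep(".", n1) else cons1, "&",
           if (is.null(cons2)) strrep(".", n2) else cons2)
  bk <- backend
  if (!is.null(cons)) bk@args <- c(bk@args, bk@constraintArgs)
  out <- .runExternal(bk, c(paste0(x1, "&", x2), cons))
  res <- .parseExternalOutput(out, n1 + n2, backend@name)
  if (length(res@strandLengths) == 1L) {
    # backend printed the concatenation without '&'; re-split
    res@strandLengths <- c(n1, n2)
  }
  res
})
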