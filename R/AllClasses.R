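#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib RNASwitchDesign, .registration = TRUE
NULL

.STRUCT_CODES <- c(".", "*", "+", "@", "^", "P")

# Nucleotide encoding shared with the C++ engine: A=0, C=1, G=2, U=3.
.NTS <- c("A", "C", "G", "U")

# IUPAC nucleotide classes, RNA alphabet (T of the DNA map read as U).
.IUPAC_RNA <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(lapply(m, function(s) {
    unique(chartr("T", "U", strsplit(s, "")[[1]]))
  }), chartr("T", "U", names(m)))
})

# nucleotide combinations that can base-pair (AU, GC, GU in either order)
.PAIRABLE <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))

# the six pairable ordered combinations, and the ten non-pairable ones
.PAIRTAB <- cbind(a = c("A", "U", "C", "G", "G", "U"),
                  b = c("U", "A", "G", "C", "U", "G"))
.NONPAIRTAB <- local({
  all <- expand.grid(a = .NTS, b = .NTS, stringsAsFactors = FALSE)
  ok <- paste(all$a, all$b) %in% paste(.PAIRTAB[, 1], .PAIRTAB[, 2])
  as.matrix(all[!ok, ])
})

# baseline pair weights (GC=3, AU=2, GU=1) and helix-stacking credit
.STACK_BONUS <- 2
.PAIR_SCORE <- matrix(0, 4, 4, dimnames = list(.NTS, .NTS))
.PAIR_SCORE["G", "C"] <- .PAIR_SCORE["C", "G"] <- 3
.PAIR_SCORE["A", "U"] <- .PAIR_SCORE["U", "A"] <- 2
.PAIR_SCORE["G", "U"] <- .PAIR_SCORE["U", "G"] <- 1

#' Extended target secondary structure
#'
#' A per-position description of a target secondary structure for one strand
#' or for a two-strand complex.  Each position carries one extended structure
#' code: \code{"."} (unpaired), \code{"P"} (explicitly paired, with the
#' partner position resolved in \code{partner}), \code{"*"} (any structure
#' allowed), \code{"+"} (paired, either kind), \code{"@"} (intramolecularly
#' paired) or \code{"^"} (intermolecularly paired).  Positions are indexed
#' 1-based over the concatenation of the strands; explicit pairs may cross
#' (pseudoknots and kissing-hairpin topologies are representable).
#'
#' @slot strandLengths integer vector of one or two strand lengths.
#' @slot codes character vector, one extended code per position.
#' @slot partner integer vector, global partner position for \code{"P"}
#'   positions, \code{NA} elsewhere.
#' @seealso [parseDotBracket()], [parseSPlus()], [renderDotBracket()]
#' @export
setClass("TargetStructure",
  representation(strandLengths = "integer", codes = "character",
                 partner = "integer"))

setValidity("TargetStructure", function(object) {
  n <- sum(object@strandLengths)
  if (length(object@codes) != n) return("codes length != total length")
  if (length(object@partner) != n) return("partner length != total length")
  if (!all(object@codes %in% .STRUCT_CODES)) return("invalid structure code")
  paired <- which(!is.na(object@partner))
  if (!all(object@codes[paired] == "P")) return("partner set on non-pair code")
  if (any(is.na(object@partner[object@codes == "P"])))
    return("pair code without partner")
  j <- object@partner[paired]
  if (any(j < 1 | j > n)) return("partner out of range")
  if (any(j == paired)) return("self pairing")
  back <- object@partner[j]
  if (any(is.na(back)) || any(back != paired))
    return("asymmetric partner references")
  TRUE
})

#' Per-position IUPAC sequence constraint
#'
#' One IUPAC nucleotide class per position (concatenated over strands).
#' \code{"N"} places no restriction.
#'
#' @slot strandLengths integer vector of strand lengths.
#' @slot codes character vector of IUPAC codes.
#' @export
setClass("SequenceConstraint",
  representation(strandLengths = "integer", codes = "character"))

setValidity("SequenceConstraint", function(object) {
  if (length(object@codes) != sum(object@strandLengths))
    return("codes length != total length")
  if (!all(object@codes %in% names(.IUPAC_RNA)))
    return("invalid IUPAC code")
  TRUE
})

#' A pair of designed RNA strands
#'
#' @slot x1,x2 character(1), RNA sequences over A, C, G, U.
#' @export
setClass("SequencePair", representation(x1 = "character", x2 = "character"))

setValidity("SequencePair", function(object) {
  for (x in c(object@x1, object@x2))
    if (!grepl("^[ACGU]*$", x)) return("sequence contains non-ACGU characters")
  TRUE
})

#' Predicted secondary structure
#'
#' Partner-array representation of a predicted structure for one strand or a
#' two-strand complex, with the backend energy.  \code{partner[i]} is the
#' global 1-based partner of position \code{i}, or \code{NA} when unpaired.
#'
#' @slot strandLengths integer vector of strand lengths.
#' @slot partner integer vector of partners (\code{NA} = loop nucleotide).
#' @slot energy numeric(1), backend energy units.
#' @export
setClass("PredictedStructure",
  representation(strandLengths = "integer", partner = "integer",
                 energy = "numeric"))

setValidity("PredictedStructure", function(object) {
  n <- sum(object@strandLengths)
  if (length(object@partner) != n) return("partner length != total length")
  paired <- which(!is.na(object@partner))
  j <- object@partner[paired]
  if (any(j < 1 | j > n) || any(j == paired)) return("partner out of range")
  back <- object@partner[j]
  if (any(is.na(back)) || any(back != paired)) return("asymmetric partners")
  TRUE
})

#' Interaction seed
#'
#' A short helix of continuous intermolecular base pairs modelling the
#' nucleation step of complex formation, with its hybridization energy.
#' An empty seed (no pairs) has energy 0.
#'
#' @slot pairs two-column integer matrix of global positions
#'   (strand-1 position, strand-2 global position), one row per pair.
#' @slot energy numeric(1).
#' @export
setClass("Seed", representation(pairs = "matrix", energy = "numeric"))

#' Per-position structure constraints for prediction
#'
#' Codes: \code{"free"}, \code{"pair"} (enforce the pair given in
#' \code{partner}, strand-local 1-based), \code{"nopair"} (prohibit all
#' pairs), \code{"nointra"}, \code{"nointer"}.
#'
#' @slot codes character vector of constraint codes.
#' @slot partner integer vector, strand-local enforced partner or \code{NA}.
#' @export
setClass("StructureConstraint",
  representation(codes = "character", partner = "integer"))

setValidity("StructureConstraint", function(object) {
  ok <- c("free", "pair", "nopair", "nointra", "nointer")
  if (!all(object@codes %in% ok)) return("invalid constraint code")
  if (length(object@partner) != length(object@codes))
    return("partner length != codes length")
  for (i in which(object@codes == "pair")) {
    j <- object@partner[i]
    if (is.na(j)) return("enforced pair without partner")
    if (j < 1 || j > length(object@codes)) return("enforced partner out of range")
    if (object@codes[j] != "pair" || object@partner[j] != i)
      return("enforced pairs must be symmetric")
  }
  TRUE
})

#' Objective vector of a candidate design
#'
#' Objectives (all minimized): \code{fdist} the summed structure distance of
#' the isolated and hybridized states; \code{fint} the interaction term
#' E_seed + E_hyb - (E_iso1 + E_iso2); \code{fE} the energy of the hybridized
#' state.  GC-content constraints enter through \code{g1 = gcMin - gc} and
#' \code{g2 = gc - gcMax}; the overall violation is
#' \code{v = max(g1, 0) + max(g2, 0)} and a solution is feasible iff
#' \code{v == 0}.  In the single-target preset \code{fint} is \code{NA} and
#' dominance is decided on \code{(fdist, fE)} only.
#'
#' @slot fdist,fint,fE,g1,g2,v numeric(1).
#' @slot feasible logical(1).
#' @export
setClass("ObjectiveVector",
  representation(fdist = "numeric", fint = "numeric", fE = "numeric",
                 g1 = "numeric", g2 = "numeric", v = "numeric",
                 feasible = "logical"))

#' One GA solution
#'
#' @slot pair a [SequencePair-class].
#' @slot objectives an [ObjectiveVector-class].
#' @slot rank Pareto front index (1 = non-dominated).
#' @slot crowding NSGA-II crowding distance (may be \code{Inf}).
#' @slot predictions list of cached predictions (\code{iso1}, \code{iso2},
#'   \code{hyb} [PredictedStructure-class] and \code{seed} [Seed-class]).
#' @export
setClass("Solution",
  representation(pair = "SequencePair", objectives = "ObjectiveVector",
                 rank = "numeric", crowding = "numeric",
                 predictions = "list"))

#' Virtual base class of structure-prediction backends
#' @export
setClass("Predictor", representation("VIRTUAL"))

#' Built-in deterministic structure predictor
#'
#' Maximum-score folding with pair weights GC/CG = 3, AU/UA = 2, GU/UG = 1,
#' a minimum hairpin loop of 3 nt, and greedy selection of intermolecular
#' duplex regions for two-strand complexes.  Energies are the negated total
#' pair score (dimensionless units internal to this backend).  Fully
#' deterministic: identical inputs give identical outputs.
#' @export
setClass("BaselinePredictor", contains = "Predictor")

#' Adapter for an external folding program
#'
#' Wraps a command-line predictor following the text protocol: sequence(s)
#' on stdin (two strands joined by \code{"&"}), a dot-bracket line plus an
#' energy in parentheses on stdout, e.g. the RNAfold/RNAcofold convention.
#' Constraints are passed as a second input line in the backend's
#' one-character-per-position dialect.  Failures (missing executable,
#' unparseable output, non-zero exit) surface as errors, never as silent
#' defaults.
#'
#' @slot command character(1), the executable.
#' @slot args character vector of fixed arguments.
#' @slot constraintArgs character vector of arguments enabling constrained
#'   folding (appended when constraints are non-trivial).
#' @slot name character(1) label used to tag energies.
#' @export
setClass("ExternalPredictor", contains = "Predictor",
  representation(command = "character", args = "character",
                 constraintArgs = "character", name = "character"))

#' Design run configuration
#'
#' Defaults follow the benchmark settings of the underlying algorithm:
#' population 100, 150 generations, point-mutation probability 0.03,
#' GC content within 45--55 per cent, interaction-seed window w = 6 base
#' pairs, homopolymer tracts of four or more nucleotides prohibited.
#'
#' @slot popSize,generations,tournamentSize integer(1).
#' @slot mutationProb numeric(1) per-position mutation probability.
#' @slot gcMin,gcMax numeric(1) GC-content bounds in per cent.
#' @slot seedWindow integer(1) maximum seed length w in base pairs.
#' @slot prohibitedMotifs character vector of IUPAC motifs.
#' @slot preset \code{"switch"} (three objectives over three targets) or
#'   \code{"single"} (hybridized target only; objectives d_hyb and E_hyb).
#' @slot maxRegions,maxRegionLength integer(1) accessible-region model of
#'   the complex prediction.
#' @slot earlyStopDistance numeric(1); stop once the best structure distance
#'   reaches this value (\code{NA} = run the full generation budget).
#' @export
setClass("DesignConfig",
  representation(popSize = "integer", generations = "integer",
                 mutationProb = "numeric", gcMin = "numeric",
                 gcMax = "numeric", seedWindow = "integer",
                 prohibitedMotifs = "character", tournamentSize = "integer",
                 preset = "character", maxRegions = "integer",
                 maxRegionLength = "integer", earlyStopDistance = "numeric"))

setValidity("DesignConfig", function(object) {
  if (object@popSize < 2) return("popSize must be >= 2")
  if (object@mutationProb < 0 || object@mutationProb > 1)
    return("mutationProb must lie in [0, 1]")
  if (object@gcMin > object@gcMax) return("gcMin > gcMax")
  if (!object@preset %in% c("switch", "single"))
    return("preset must be 'switch' or 'single'")
  TRUE
})

#' Result of a design run
#'
#' @slot archive list of front-1 [Solution-class] objects at the final
#'   generation.
#' @slot log data.frame with one row per generation (front sizes, best
#'   objectives, violation statistics).
#' @slot bestDistance numeric(1), lowest structure distance attained by any
#'   solution evaluated during the run.
#' @slot config the [DesignConfig-class] used.
#' @slot generationsRun integer(1).
#' @export
setClass("DesignResult",
  representation(archive = "list", log = "data.frame",
                 bestDistance = "numeric", config = "DesignConfig",
                 generationsRun = "integer"))
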