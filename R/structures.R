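# Sequence/target compatibility, structure distance and GC content.

#' Is a sequence pair compatible with the target structures?
#'
#' A sequence assignment is compatible with a target structure when every
#' explicit base pair of the target carries a pairable nucleotide
#' combination (AU, GC or GU, in either orientation).  Wildcard positions
#' impose no sequence condition.  Compatibility extends to several targets
#' by requiring it for each.
#'
#' @param s a [SequencePair-class] (or a single sequence string for
#'   single-strand targets).
#' @param targets a [TargetStructure-class] or a list of them.  Targets over
#'   one strand are checked against the matching strand (first single-strand
#'   target against strand 1, second against strand 2) when \code{s} is a
#'   pair; two-strand targets are checked against the concatenation.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' isCompatible("GAAAC", parseDotBracket("(...)"))
#' isCompatible(sequencePair("GGGG", "CCCC"), parseDotBracket("((((&))))"))
#' @export
isCompatible <- function(s, targets) {
  if (is(targets, "TargetStructure")) targets <- list(targets)
  seqs <- if (is(s, "SequencePair")) c(s@x1, s@x2) else s
  singleSeen <- 0L
  for (t in targets) {
    if (length(t@strandLengths) == 2L) {
      x <- paste(seqs, collapse = "")
    } else {
      singleSeen <- singleSeen + 1L
      if (singleSeen > length(seqs))
        stop("more single-strand targets than strands")
      x <- seqs[singleSeen]
    }
    if (nchar(x) != sum(t@strandLengths))
      stop("sequence length (", nchar(x), ") does not match target length (",
           sum(t@strandLengths), ")")
    chars <- strsplit(x, "")[[1]]
    pairs <- basePairs(t)
    if (nrow(pairs) > 0L) {
      ok <- vapply(seq_len(nrow(pairs)), function(k)
        .pairable(chars[pairs[k, 1L]], chars[pairs[k, 2L]]), logical(1))
      if (!all(ok)) return(FALSE)
    }
  }
  TRUE
}

# Consistency of a single predicted position with one extended target code.
# predPartner: global predicted partner or NA; sameStrand: logical, whether
# the predicted partner lies on the same strand (ignored when unpaired).
.consistentPos <- function(code, targetPartner, predPartner, sameStrand) {
  switch(code,
    "." = is.na(predPartner),
    "*" = TRUE,
    "+" = !is.na(predPartner),
    "@" = !is.na(predPartner) && sameStrand,
    "^" = !is.na(predPartner) && !sameStrand,
    "P" = !is.na(predPartner) && predPartner == targetPartner,
    stop("unknown structure code ", code))
}

#' Structure distance between a prediction and a target
#'
#' The number of positions whose predicted state is inconsistent with the
#' extended target code: \code{"."} requires unpaired, an explicit pair
#' requires exactly the specified partner, \code{"*"} is always consistent,
#' \code{"+"} requires any pair, \code{"@"} an intramolecular and
#' \code{"^"} an intermolecular pair.  For a two-strand target the distance
#' is summed over both strands.
#'
#' @param p a [PredictedStructure-class] (or dot-bracket string, parsed with
#'   [parseDotBracket()] for convenience).
#' @param t a [TargetStructure-class] (or dot-bracket string).
#' @return non-negative integer between 0 and the total length.
#' @examples
#' structureDistance("......", "((..))")  # 4
#' @export
structureDistance <- function(p, t) {
  if (is.character(t)) t <- parseDotBracket(t)
  if (is.character(p)) {
    ps <- parseDotBracket(p)
    p <- new("PredictedStructure", strandLengths = ps@strandLengths,
             partner = ps@partner, energy = NA_real_)
  }
  n <- sum(t@strandLengths)
  if (sum(p@strandLengths) != n)
    stop("prediction and target lengths differ")
  .distCore(p@partner, p@strandLengths, t)
}

# vectorized distance core shared with the GA hot loop
.distCore <- function(pp, sl, t) {
  n <- sum(sl)
  strand <- rep(seq_along(sl), sl)
  paired <- !is.na(pp)
  same <- rep(FALSE, n)
  same[paired] <- strand[pp[paired]] == strand[paired]
  bad <- logical(n)
  code <- t@codes
  bad[code == "."] <- paired[code == "."]
  bad[code == "+"] <- !paired[code == "+"]
  bad[code == "@"] <- !(paired & same)[code == "@"]
  bad[code == "^"] <- !(paired & !same)[code == "^"]
  isP <- code == "P"
  bad[isP] <- !paired[isP] | pp[isP] != t@partner[isP]
  sum(bad, na.rm = TRUE) + sum(is.na(bad))
}

#' Joint GC content of a sequence pair
#'
#' @param s a [SequencePair-class].
#' @return percentage of G+C nucleotides over both strands jointly.
#' @examples
#' gcContent(sequencePair("GGCC", "AUAU"))  # 50
#' @export
gcContent <- function(s) {
  stopifnot(is(s, "SequencePair"))
  x <- .concatSeq(s)
  if (nchar(x) == 0L) stop("empty sequence pair")
  chars <- strsplit(x, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Read or write a sequence pair as FASTA
#'
#' Two records with IDs \code{strand1} and \code{strand2}.
#'
#' @param file path to a FASTA file.
#' @return [readSequencePair()] returns a [SequencePair-class];
#'   [writeSequencePair()] returns \code{file} invisibly.
#' @export
readSequencePair <- function(file) {
  set <- Biostrings::readRNAStringSet(file)
  if (length(set) != 2L)
    stop("expected exactly two FASTA records, found ", length(set))
  sequencePair(as.character(set[[1L]]), as.character(set[[2L]]))
}

#' @rdname readSequencePair
#' @param s a [SequencePair-class] to write.
#' @export
writeSequencePair <- function(s, file) {
  set <- Biostrings::RNAStringSet(c(strand1 = s@x1, strand2 = s@x2))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
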