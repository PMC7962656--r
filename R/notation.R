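# Target-structure notation: extended dot-bracket and S+ shape notation.

.BRACKET_OPEN  <- c("(", "[", "{", "<")
.BRACKET_CLOSE <- c(")", "]", "}", ">")
.WILDCARDS <- c("*", "+", "@", "^")

#' Parse an extended dot-bracket string
#'
#' Parses a secondary-structure string over the extended alphabet
#' \code{. ( ) [ ] \{ \} < > * + @ ^} with an optional strand separator
#' \code{&}.  The four bracket families are matched independently by stack
#' matching over the concatenated string, so pairs from different families
#' may cross (pseudoknots).  Pairs whose endpoints lie on opposite sides of
#' \code{&} are intermolecular.  The wildcard codes mean: \code{*} any
#' structure, \code{+} paired (either kind), \code{@} intramolecularly
#' paired, \code{^} intermolecularly paired.
#'
#' @param text a single structure string, e.g. \code{"((..[[..))..]]"} or
#'   \code{"((((&))))"}.
#' @return A [TargetStructure-class].
#' @examples
#' parseDotBracket("((..))")
#' basePairs(parseDotBracket("((((&))))"))
#' @export
parseDotBracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  amp <- which(chars == "&")
  if (length(amp) > 1L) stop("at most one strand separator '&' is allowed")
  body <- chars[chars != "&"]
  n <- length(body)
  if (n == 0L) stop("empty structure string")
  strandLengths <- if (length(amp) == 1L)
    c(amp - 1L, n - (amp - 1L)) else n
  if (any(strandLengths == 0L)) stop("empty strand on one side of '&'")

  legal <- c(".", .WILDCARDS, .BRACKET_OPEN, .BRACKET_CLOSE)
  bad <- setdiff(unique(body), legal)
  if (length(bad) > 0L)
    stop("illegal structure character(s): ", paste(bad, collapse = " "))

  codes <- ifelse(body %in% .WILDCARDS, body, ".")
  partner <- rep(NA_integer_, n)
  for (f in seq_along(.BRACKET_OPEN)) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (body[i] == .BRACKET_OPEN[f]) {
        stack <- c(stack, i)
      } else if (body[i] == .BRACKET_CLOSE[f]) {
        if (length(stack) == 0L)
          stop("unbalanced '", .BRACKET_CLOSE[f], "' at position ", i)
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[j] <- i
        partner[i] <- j
        codes[c(i, j)] <- "P"
      }
    }
    if (length(stack) > 0L)
      stop("unbalanced '", .BRACKET_OPEN[f], "' (", length(stack),
           " unclosed)")
  }
  new("TargetStructure", strandLengths = as.integer(strandLengths),
      codes = codes, partner = partner)
}

#' Render a target structure as extended dot-bracket
#'
#' Inverse of [parseDotBracket()]: explicit pairs are written with bracket
#' families assigned greedily so that crossing stems receive distinct
#' families; wildcard codes are emitted verbatim and \code{&} separates two
#' strands.
#'
#' @param t a [TargetStructure-class].
#' @return a character string; parsing it back reproduces \code{t}'s pairs
#'   and codes.
#' @export
renderDotBracket <- function(t) {
  stopifnot(is(t, "TargetStructure"))
  n <- sum(t@strandLengths)
  out <- ifelse(t@codes %in% .WILDCARDS, t@codes, ".")
  pairs <- basePairs(t)
  if (nrow(pairs) > 0L) {
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    fam <- integer(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      placed <- FALSE
      for (f in seq_along(.BRACKET_OPEN)) {
        prev <- which(fam[seq_len(k - 1L)] == f)
        crossing <- FALSE
        for (q in prev) {
          a <- pairs[q, 1L]; b <- pairs[q, 2L]
          if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
            crossing <- TRUE; break
          }
        }
        if (!crossing) { fam[k] <- f; placed <- TRUE; break }
      }
      if (!placed)
        stop("structure has more than four mutually crossing stem families",
             " and cannot be rendered in dot-bracket notation")
      out[i] <- .BRACKET_OPEN[fam[k]]
      out[j] <- .BRACKET_CLOSE[fam[k]]
    }
  }
  if (length(t@strandLengths) == 2L) {
    n1 <- t@strandLengths[1L]
    paste0(paste(out[seq_len(n1)], collapse = ""), "&",
           paste(out[(n1 + 1L):n], collapse = ""))
  } else {
    paste(out, collapse = "")
  }
}

# --- S+ notation -----------------------------------------------------------

# Tokenize the top-level S+ string.  Tokens:
#   list(type = "loop",  len = int or NA (the 'x' wildcard))
#   list(type = "open",  len = int)
#   list(type = "close")
#   list(type = "amp")
#   list(type = "motif", letter = chr)
#   list(type = "raw",   char = chr)        # literal extended dot-bracket char
.tokenizeSPlus <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- list()
  i <- 1L
  readInt <- function() {
    start <- i
    while (i <= length(chars) && grepl("[0-9]", chars[i])) i <<- i + 1L
    if (i == start) return(NA_integer_)
    as.integer(paste(chars[start:(i - 1L)], collapse = ""))
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("U", "u", "_")) {
      i <- i + 1L
      if (i <= length(chars) && chars[i] %in% c("x", "X")) {
        i <- i + 1L
        toks[[length(toks) + 1L]] <- list(type = "loop", len = NA_integer_)
      } else {
        len <- readInt()
        if (is.na(len)) len <- 1L
        toks[[length(toks) + 1L]] <- list(type = "loop", len = len)
      }
    } else if (ch == "[") {
      i <- i + 1L
      if (i <= length(chars) && chars[i] %in% c("x", "X"))
        stop("the integer wildcard 'x' cannot be attached to a bracket")
      len <- readInt()
      if (is.na(len)) len <- 1L
      toks[[length(toks) + 1L]] <- list(type = "open", len = len)
    } else if (ch == "]") {
      i <- i + 1L
      toks[[length(toks) + 1L]] <- list(type = "close")
    } else if (ch == "&") {
      i <- i + 1L
      toks[[length(toks) + 1L]] <- list(type = "amp")
    } else if (ch %in% c(".", "(", ")", "{", "}", "<", ">", "*", "+", "@", "^")) {
      i <- i + 1L
      toks[[length(toks) + 1L]] <- list(type = "raw", char = ch)
    } else if (grepl("[A-Za-z]", ch)) {
      if (ch %in% c("x", "X"))
        stop("'x' is only valid as a loop-length wildcard (after U or _)")
      i <- i + 1L
      toks[[length(toks) + 1L]] <- list(type = "motif", letter = ch)
    } else if (grepl("[0-9]", ch)) {
      stop("unexpected integer at position ", i,
           " (lengths must follow 'U', '_' or '[')")
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      stop("illegal S+ character '", ch, "'")
    }
  }
  toks
}

# Parse motif definition lines into list(letter -> list(structure, sequence)).
# Each motif is one or two lines of the form "A = ......"; the structure line
# is mandatory and comes first, an optional sequence line (IUPAC) follows.
.parseMotifLines <- function(lines) {
  motifs <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z])\\s*=\\s*\"?([^\"]*?)\"?\\s*$", ln))[[1]]
    if (length(m) == 0L)
      stop("cannot parse motif definition line: ", ln)
    letter <- m[2]; value <- m[3]
    if (letter %in% c("u", "U", "x", "X"))
      stop("'", letter, "' cannot be used as a motif letter")
    if (is.null(motifs[[letter]])) {
      # structure line: extended dot-bracket only
      if (!grepl("^[].()<>{}[*+@^]*$", value))
        stop("motif '", letter, "' structure line contains illegal characters")
      motifs[[letter]] <- list(structure = value, sequence = NULL)
    } else if (is.null(motifs[[letter]]$sequence)) {
      seqv <- toupper(value)
      if (!all(strsplit(seqv, "")[[1]] %in% names(.IUPAC_RNA)) &&
          nzchar(seqv))
        stop("motif '", letter, "' sequence line is not valid IUPAC")
      if (nchar(seqv) != nchar(motifs[[letter]]$structure))
        stop("motif '", letter, "' sequence and structure lines differ in length")
      motifs[[letter]]$sequence <- seqv
    } else {
      stop("motif '", letter, "' is defined more than once")
    }
  }
  motifs
}

#' Parse an S+ target specification
#'
#' S+ (shape-plus) notation describes a target secondary structure
#' compactly: \code{U}/\code{_} runs are loop nucleotides (\code{U5} = five
#' unpaired positions), \code{[n} opens a duplex of n base pairs whose
#' closing half is the matching \code{]}, \code{&} separates the two
#' strands, \code{Ux} is a loop run whose length is resolved from the
#' declared strand length, and any other letter (except \code{u}, \code{U},
#' \code{x}, \code{X}) splices in a named motif.  A motif is declared on
#' subsequent lines as \code{A = <structure>} (extended dot-bracket,
#' mandatory) optionally followed by \code{A = <IUPAC sequence>} of the same
#' length; without a sequence line the motif is unconstrained (all N).
#' Bracket runs whose halves lie on opposite sides of \code{&} encode
#' intermolecular duplexes.
#'
#' @param lines character vector: the S+ string first, then motif
#'   definition lines; empty and \code{#}-comment lines are ignored.
#' @param strandLengths optional declared strand lengths, required to
#'   resolve \code{x} wildcards (one \code{x} per strand at most).
#' @return A list with components \code{structure}
#'   (a [TargetStructure-class]) and \code{constraint}
#'   (a [SequenceConstraint-class]).
#' @examples
#' parseSPlus("U2[3U4]U2")$structure
#' parseSPlus(c("U2A U4]U2", "A = [[[[[[", "A = aggagg"))$constraint
#' @export
parseSPlus <- function(lines, strandLengths = NULL) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty S+ specification")
  toks <- .tokenizeSPlus(lines[1L])
  motifs <- .parseMotifLines(lines[-1L])

  # expansion pass: structure characters + IUPAC characters per token
  expandTok <- function(tok) {
    switch(tok$type,
      loop  = list(struct = strrep(".", tok$len), iupac = strrep("N", tok$len)),
      open  = list(struct = strrep("[", tok$len), iupac = strrep("N", tok$len),
                   open = tok$len),
      close = list(struct = NULL, iupac = NULL),  # resolved via stack
      amp   = list(struct = "&", iupac = ""),
      raw   = list(struct = tok$char, iupac = if (tok$char == "&") "" else "N"),
      motif = {
        mt <- motifs[[tok$letter]]
        if (is.null(mt))
          stop("motif letter '", tok$letter, "' used without a definition")
        sq <- if (is.null(mt$sequence)) strrep("N", nchar(mt$structure))
              else mt$sequence
        list(struct = mt$structure, iupac = sq)
      })
  }

  # resolve 'x' loop lengths: at most one per strand, from declared lengths
  strandIdx <- 1L
  fixedLen <- c(0L, 0L)
  xCount <- c(0L, 0L)
  openStack <- integer(0)  # lengths of open duplexes (for close tokens)
  tokLens <- integer(length(toks))
  tokStrand <- integer(length(toks))
  for (k in seq_along(toks)) {
    tok <- toks[[k]]
    tokStrand[k] <- strandIdx
    if (tok$type == "amp") {
      strandIdx <- strandIdx + 1L
      if (strandIdx > 2L) stop("at most one strand separator '&' is allowed")
      tokLens[k] <- 0L
    } else if (tok$type == "loop" && is.na(tok$len)) {
      xCount[strandIdx] <- xCount[strandIdx] + 1L
      if (xCount[strandIdx] > 1L)
        stop("at most one 'x' loop-length wildcard per strand")
      tokLens[k] <- NA_integer_
    } else if (tok$type == "open") {
      openStack <- c(openStack, tok$len)
      tokLens[k] <- tok$len
      fixedLen[strandIdx] <- fixedLen[strandIdx] + tok$len
    } else if (tok$type == "close") {
      if (length(openStack) == 0L) {
        # no top-level '[n' to match: the upstream half lives inside a motif
        # fragment; emit a literal ']' and let the dot-bracket parser pair it
        tokLens[k] <- 1L
        fixedLen[strandIdx] <- fixedLen[strandIdx] + 1L
      } else {
        len <- openStack[length(openStack)]
        openStack <- openStack[-length(openStack)]
        tokLens[k] <- len
        fixedLen[strandIdx] <- fixedLen[strandIdx] + len
      }
    } else if (tok$type == "loop") {
      tokLens[k] <- tok$len
      fixedLen[strandIdx] <- fixedLen[strandIdx] + tok$len
    } else if (tok$type == "motif") {
      mt <- motifs[[tok$letter]]
      if (is.null(mt))
        stop("motif letter '", tok$letter, "' used without a definition")
      tokLens[k] <- nchar(mt$structure)
      fixedLen[strandIdx] <- fixedLen[strandIdx] + tokLens[k]
    } else { # raw
      tokLens[k] <- 1L
      fixedLen[strandIdx] <- fixedLen[strandIdx] + 1L
    }
  }
  if (length(openStack) > 0L) stop("unbalanced '[' in S+ string")
  nStrands <- strandIdx
  if (any(xCount > 0L)) {
    if (is.null(strandLengths))
      stop("the S+ string contains 'x' but no strand lengths were declared")
    if (length(strandLengths) < nStrands)
      stop("declared strand lengths do not cover every strand")
    for (s in seq_len(nStrands)) {
      if (xCount[s] == 1L) {
        xl <- strandLengths[s] - fixedLen[s]
        if (xl < 0L)
          stop("'x' on strand ", s, " is unresolvable: fixed lengths exceed ",
               "the declared strand length")
        k <- which(is.na(tokLens) & tokStrand == s)
        tokLens[k] <- xl
        toks[[k]]$len <- xl
      }
    }
  }

  # emission pass with a stack for close tokens
  structParts <- character(0)
  iupacParts <- character(0)
  closeStack <- integer(0)
  for (k in seq_along(toks)) {
    tok <- toks[[k]]
    if (tok$type == "open") closeStack <- c(closeStack, tok$len)
    if (tok$type == "close") {
      if (length(closeStack) == 0L) {
        len <- 1L
      } else {
        len <- closeStack[length(closeStack)]
        closeStack <- closeStack[-length(closeStack)]
      }
      structParts <- c(structParts, strrep("]", len))
      iupacParts <- c(iupacParts, strrep("N", len))
    } else {
      e <- expandTok(tok)
      structParts <- c(structParts, e$struct)
      iupacParts <- c(iupacParts, e$iupac)
    }
  }
  structStr <- paste(structParts, collapse = "")
  target <- parseDotBracket(structStr)
  iupac <- strsplit(paste(iupacParts, collapse = ""), "")[[1]]
  if (length(iupac) != sum(target@strandLengths))
    stop("internal S+ expansion length mismatch")
  if (!is.null(strandLengths) &&
      !identical(as.integer(strandLengths[seq_len(nStrands)]),
                 target@strandLengths))
    stop("S+ expansion length (",
         paste(target@strandLengths, collapse = "+"),
         ") does not match the declared strand lengths (",
         paste(strandLengths[seq_len(nStrands)], collapse = "+"), ")")
  constraint <- new("SequenceConstraint",
                    strandLengths = target@strandLengths, codes = iupac)
  list(structure = target, constraint = constraint)
}
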