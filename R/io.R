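# Target-file reading, configuration files, and result serialization.

# intersect two IUPAC codes; error when the intersection is empty
.iupacIntersect <- function(a, b) {
  set <- intersect(.IUPAC_RNA[[a]], .IUPAC_RNA[[b]])
  if (length(set) == 0L)
    stop("contradictory sequence constraints: '", a, "' vs '", b, "'")
  hit <- names(.IUPAC_RNA)[vapply(.IUPAC_RNA, function(s)
    setequal(s, set), logical(1))]
  hit[1L]
}

#' Read one target-structure file
#'
#' A plain-text file holding one target: either a single extended
#' dot-bracket line or an S+ specification (the S+ string followed by
#' motif definition lines).  Lines starting with \code{#} and blank lines
#' are ignored.
#'
#' @param path file path.
#' @param strandLengths optional declared strand lengths (needed to resolve
#'   \code{x} wildcards in S+ strings).
#' @return list with \code{structure} (a [TargetStructure-class]) and
#'   \code{constraint} (a [SequenceConstraint-class], all-N when the file
#'   does not constrain the sequence).
#' @export
readTargetFile <- function(path, strandLengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no target specification in ", path)
  first <- gsub("\\s", "", lines[1L])
  if (length(lines) == 1L && grepl("^[.()\\[\\]{}<>*+@^&]+$", first,
                                   perl = TRUE)) {
    t <- parseDotBracket(first)
    list(structure = t,
         constraint = new("SequenceConstraint",
                          strandLengths = t@strandLengths,
                          codes = rep("N", sum(t@strandLengths))))
  } else {
    parseSPlus(lines, strandLengths = strandLengths)
  }
}

#' Read a target triple from three files
#'
#' Reads the hybridized-complex target first (its strand lengths resolve
#' any \code{x} wildcards in the isolated-strand specifications), checks
#' that the lengths agree, and merges the per-file IUPAC constraints by
#' intersection.
#'
#' @param iso1,iso2,hyb file paths; \code{iso1}/\code{iso2} may be
#'   \code{NULL} for the single-target preset.
#' @return list with \code{targets} (a [targetSet()] list) and
#'   \code{constraint} (merged [SequenceConstraint-class]).
#' @export
readTargets <- function(hyb, iso1 = NULL, iso2 = NULL) {
  h <- readTargetFile(hyb)
  if (length(h$structure@strandLengths) != 2L)
    stop("the hybridized target must contain the strand separator '&'")
  n1 <- h$structure@strandLengths[1L]
  n2 <- h$structure@strandLengths[2L]
  codes <- h$constraint@codes
  t1 <- NULL; t2 <- NULL
  if (!is.null(iso1)) {
    r <- readTargetFile(iso1, strandLengths = n1)
    if (!identical(r$structure@strandLengths, n1))
      stop("iso1 target length (", sum(r$structure@strandLengths),
           ") does not match the complex (", n1, ")")
    t1 <- r$structure
    codes[seq_len(n1)] <- mapply(.iupacIntersect, codes[seq_len(n1)],
                                 r$constraint@codes)
  }
  if (!is.null(iso2)) {
    r <- readTargetFile(iso2, strandLengths = n2)
    if (!identical(r$structure@strandLengths, n2))
      stop("iso2 target length (", sum(r$structure@strandLengths),
           ") does not match the complex (", n2, ")")
    t2 <- r$structure
    codes[n1 + seq_len(n2)] <- mapply(.iupacIntersect, codes[n1 + seq_len(n2)],
                                      r$constraint@codes)
  }
  list(targets = targetSet(hyb = h$structure, iso1 = t1, iso2 = t2),
       constraint = new("SequenceConstraint",
                        strandLengths = c(n1, n2), codes = codes))
}

#' Read a design configuration from a YAML key-value file
#'
#' Recognized keys match the arguments of [designConfig()]; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return a [DesignConfig-class].
#' @export
readDesignConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(designConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(designConfig, vals)
}

#' Write the results of a design run
#'
#' Creates \code{dir} and writes: \code{sequences.fasta} (the archived
#' sequence pairs), \code{structures.db} (their predicted structures in
#' extended dot-bracket, complexes with \code{&}), \code{pareto.tsv} (the
#' objective table), \code{seed.txt} (the predicted interaction seed of
#' the first archived solution and the motif-elimination report) and
#' \code{log.tsv} (the per-generation log).
#'
#' @param result a [DesignResult-class].
#' @param dir output directory.
#' @param backendName label for the energy units in the outputs.
#' @return \code{dir}, invisibly.
#' @export
writeDesignResult <- function(result, dir, backendName = "baseline") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  archive <- result@archive

  seqs <- character(0)
  for (k in seq_along(archive)) {
    s <- archive[[k]]@pair
    seqs <- c(seqs,
              stats::setNames(c(s@x1, s@x2),
                              paste0("solution", k, "_strand", 1:2)))
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs),
                              file.path(dir, "sequences.fasta"))

  db <- character(0)
  for (k in seq_along(archive)) {
    pr <- archive[[k]]@predictions
    db <- c(db, paste0("# solution", k, " (energies: ", backendName, ")"))
    if (!is.null(pr$iso1))
      db <- c(db, paste0(renderDotBracket(asTargetStructure(pr$iso1)),
                         "  iso1 (", pr$iso1@energy, ")"))
    if (!is.null(pr$iso2))
      db <- c(db, paste0(renderDotBracket(asTargetStructure(pr$iso2)),
                         "  iso2 (", pr$iso2@energy, ")"))
    db <- c(db, paste0(renderDotBracket(asTargetStructure(pr$hyb)),
                       "  hybrid (", pr$hyb@energy, ")"))
  }
  writeLines(db, file.path(dir, "structures.db"))

  tab <- do.call(rbind, lapply(seq_along(archive), function(k) {
    o <- archive[[k]]@objectives
    data.frame(solution = k, fdist = o@fdist, fint = o@fint, fE = o@fE,
               gc = gcContent(archive[[k]]@pair), g1 = o@g1, g2 = o@g2,
               violation = o@v, feasible = o@feasible,
               crowding = archive[[k]]@crowding)
  }))
  utils::write.table(tab, file.path(dir, "pareto.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  seedLines <- c(paste0("# interaction seed of solution1 (energies: ",
                        backendName, ")"))
  if (length(archive) > 0L && !is.null(archive[[1L]]@predictions$seed)) {
    sd <- archive[[1L]]@predictions$seed
    if (nrow(sd@pairs) == 0L) {
      seedLines <- c(seedLines, "empty seed (energy 0)")
    } else {
      seedLines <- c(seedLines, paste0("energy\t", sd@energy),
                     apply(sd@pairs, 1L, function(p)
                       paste0(p[1L], "\t", p[2L])))
    }
  } else {
    seedLines <- c(seedLines, "not computed (single-target preset)")
  }
  persist <- utils::tail(result@log$motif_persist, 1L)
  seedLines <- c(seedLines,
                 paste0("# prohibited-motif persistence events: ",
                        if (length(persist)) persist else 0L))
  writeLines(seedLines, file.path(dir, "seed.txt"))

  utils::write.table(result@log, file.path(dir, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run a design from target files
#'
#' High-level entry point mirroring the command-line interface: read the
#' targets (and merged IUPAC constraints), run the design, write the
#' result files.
#'
#' @param hyb,iso1,iso2 target file paths ([readTargets()]).
#' @param outDir output directory for [writeDesignResult()].
#' @param config a [DesignConfig-class].
#' @param backend a [Predictor-class].
#' @param seed integer random seed.
#' @return the [DesignResult-class], invisibly.
#' @export
designFromFiles <- function(hyb, iso1 = NULL, iso2 = NULL, outDir,
                            config = designConfig(),
                            backend = baselinePredictor(), seed = NULL) {
  rd <- readTargets(hyb, iso1, iso2)
  if (is.null(iso1) || is.null(iso2)) config@preset <- "single"
  res <- runDesign(rd$targets, config, constraint = rd$constraint,
                   backend = backend, seed = seed)
  writeDesignResult(res, outDir,
                    backendName = if (is(backend, "ExternalPredictor"))
                      backend@name else "baseline")
  invisible(res)
}
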