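# A stub prediction backend with fixed energies, used to check the
# objective arithmetic on constructed energy fixtures.  The joint fold
# returns a four-pair intermolecular duplex with energy `hybEnergy`; when
# called with non-trivial constraints (the seed procedure) it returns the
# same duplex with energy `seedEnergy`; single-strand folds are fully
# unpaired with energies `isoEnergy1` / `isoEnergy2` (matched by sequence).

setClass("StubPredictor", contains = "Predictor",
         representation(x1 = "character", isoEnergy1 = "numeric",
                        isoEnergy2 = "numeric", hybEnergy = "numeric",
                        seedEnergy = "numeric"))

stubPredictor <- function(x1, isoEnergy1 = -3, isoEnergy2 = -4,
                          hybEnergy = -20, seedEnergy = -5) {
  new("StubPredictor", x1 = x1, isoEnergy1 = isoEnergy1,
      isoEnergy2 = isoEnergy2, hybEnergy = hybEnergy,
      seedEnergy = seedEnergy)
}

setMethod("foldSingle", "StubPredictor", function(backend, x, constraint = NULL) {
  en <- if (identical(x, backend@x1)) backend@isoEnergy1 else backend@isoEnergy2
  new("PredictedStructure", strandLengths = nchar(x),
      partner = rep(NA_integer_, nchar(x)), energy = en)
})

setMethod("foldJoint", "StubPredictor",
          function(backend, x1, x2, c1 = NULL, c2 = NULL,
                   maxRegions = 1L, maxRegionLength = NULL) {
  n1 <- nchar(x1); n2 <- nchar(x2)
  partner <- rep(NA_integer_, n1 + n2)
  for (k in 0:3) {                       # duplex: (1..4) with (n2..n2-3)
    i <- 1L + k; j <- n1 + n2 - k
    partner[i] <- j; partner[j] <- i
  }
  constrained <- !is.null(c1) && any(c1@codes != "free")
  en <- if (constrained) backend@seedEnergy else backend@hybEnergy
  new("PredictedStructure", strandLengths = c(n1, n2),
      partner = as.integer(partner), energy = en)
})
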