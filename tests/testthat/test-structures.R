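test_that("compatibility requires pairable nucleotides at every target pair", {
  expect_true(isCompatible("GAAAC", parseDotBracket("(...)")))
  expect_false(isCompatible("AAAAC", parseDotBracket("(...)")))
  expect_true(isCompatible(sequencePair("GGGG", "CCCC"),
                           parseDotBracket("((((&))))")))
  expect_false(isCompatible(sequencePair("GGGG", "AAAA"),
                            parseDotBracket("((((&))))")))
  expect_error(isCompatible("GAAAC", parseDotBracket("(....)")),
               "does not match")
})

test_that("compatibility is monotone under removing explicit pairs", {
  set.seed(7)
  for (r in 1:20) {
    fx <- generateFixture(15, 15)
    t <- fx$targets$hyb
    expect_true(isCompatible(fx$pair, t))
    # drop one pair: still compatible
    bp <- basePairs(t)
    if (nrow(bp) == 0) next
    k <- sample(nrow(bp), 1)
    t2 <- t
    t2@codes[bp[k, ]] <- "."
    t2@partner[bp[k, ]] <- NA_integer_
    expect_true(isCompatible(fx$pair, t2))
  }
})

test_that("structure distance counts positions inconsistent with the target", {
  expect_equal(structureDistance("((..))", "((..))"), 0L)
  expect_equal(structureDistance("......", "((..))"), 4L)
  expect_equal(structureDistance("((..))", "******"), 0L)
  expect_equal(structureDistance("......", "******"), 0L)
})

test_that("wildcard codes distinguish pair kinds", {
  # '+' requires any pair, '@' intramolecular, '^' intermolecular
  pred <- parseDotBracket("((((&))))")        # four intermolecular pairs
  p <- new("PredictedStructure", strandLengths = pred@strandLengths,
           partner = pred@partner, energy = 0)
  expect_equal(structureDistance(p, "++++&++++"), 0L)
  expect_equal(structureDistance(p, "^^^^&^^^^"), 0L)
  expect_equal(structureDistance(p, "@@@@&@@@@"), 8L)
  expect_equal(structureDistance(p, "....&...."), 8L)

  intra <- parseDotBracket("((...))..&..")    # intramolecular pairs, strand 1
  pi <- new("PredictedStructure", strandLengths = intra@strandLengths,
            partner = intra@partner, energy = 0)
  expect_equal(structureDistance(pi, "@@...@@..&.."), 0L)
  expect_equal(structureDistance(pi, "^^...^^..&.."), 4L)

  # explicit pair requires the exact partner (positions 4 and 8 agree)
  shifted <- parseDotBracket(".((..)).")
  ps <- new("PredictedStructure", strandLengths = shifted@strandLengths,
            partner = shifted@partner, energy = 0)
  expect_equal(structureDistance(ps, "((..)).."), 6L)
})

test_that("distance is bounded by the total length", {
  set.seed(11)
  for (r in 1:20) {
    fx <- generateFixture(12, 12)
    p <- foldJoint(baselinePredictor(), randomRNA(12), randomRNA(12))
    d <- structureDistance(p, fx$targets$hyb)
    expect_gte(d, 0)
    expect_lte(d, 24)
  }
})

test_that("GC content is a joint percentage over both strands", {
  expect_equal(gcContent(sequencePair("GGCC", "AUAU")), 50)
  expect_equal(gcContent(sequencePair("GCGC", "GCGC")), 100)
  expect_equal(gcContent(sequencePair("AUAU", "AUAU")), 0)
})

test_that("sequence pairs round-trip through FASTA", {
  s <- sequencePair("GGGAAACCC", "AAAAUUUU")
  f <- tempfile(fileext = ".fasta")
  writeSequencePair(s, f)
  s2 <- readSequencePair(f)
  expect_equal(sequences(s2), sequences(s))
  unlink(f)
})
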