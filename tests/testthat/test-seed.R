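# build a PredictedStructure from a dot-bracket string (energy irrelevant)
predFromDb <- function(db) {
  t <- parseDotBracket(db)
  new("PredictedStructure", strandLengths = t@strandLengths,
      partner = t@partner, energy = 0)
}

test_that("seed candidates intersect intermolecular pairs with loop regions", {
  joint <- predFromDb("((((((((((..&..))))))))))")
  n1 <- 12
  # strand 1 isolated fold pairs positions 1 and 6 (an intramolecular stem
  # with 2 and 5 would also do); use explicit partner arrays
  p1 <- rep(NA_integer_, 12); p1[1] <- 6L; p1[6] <- 1L
  iso1 <- new("PredictedStructure", strandLengths = 12L, partner = p1,
              energy = 0)
  iso2 <- new("PredictedStructure", strandLengths = 12L,
              partner = rep(NA_integer_, 12), energy = 0)
  cand <- seedCandidates(joint, iso1, iso2)
  expect_equal(length(cand), 16L)   # 8 of the 10 intermolecular pairs
  expect_false(any(c(1L, 6L) %in% cand))
  expect_false(any((joint@partner[c(1L, 6L)]) %in% cand))

  # fully unpaired isolated structures keep every endpoint
  iso1b <- new("PredictedStructure", strandLengths = 12L,
               partner = rep(NA_integer_, 12), energy = 0)
  expect_equal(length(seedCandidates(joint, iso1b, iso2)), 20L)

  # no intermolecular pairs -> empty candidate set
  j2 <- predFromDb("((..))......&............")
  expect_equal(length(seedCandidates(j2, iso1b, iso2)), 0L)
})

test_that("both seed procedures find the optimal duplex window", {
  b <- baselinePredictor()
  pair <- sequencePair("AAAA", "UUUU")
  iso <- function(n) new("PredictedStructure", strandLengths = as.integer(n),
                         partner = rep(NA_integer_, n), energy = 0)
  joint <- foldJoint(b, "AAAA", "UUUU")
  cand <- seedCandidates(joint, iso(4), iso(4))
  s1 <- findSeedConstrained(pair, iso(4), iso(4), cand, w = 6L)
  expect_equal(s1@energy, oracleBestDuplex("AAAA", "UUUU", 1:4, 1:4, 6))
  s2 <- findSeedScan(pair, joint, iso(4), iso(4), cand, w = 6L)
  expect_equal(s2@energy, s1@energy)
  expect_equal(s2@pairs, s1@pairs)

  # a shorter window cap limits the seed
  s3 <- findSeedConstrained(pair, iso(4), iso(4), cand, w = 2L)
  expect_equal(s3@energy, oracleBestDuplex("AAAA", "UUUU", 1:4, 1:4, 2))
  expect_equal(nrow(s3@pairs), 2L)

  # empty candidate set -> empty seed with energy 0
  s4 <- findSeedConstrained(pair, iso(4), iso(4), integer(0))
  expect_equal(nrow(s4@pairs), 0L)
  expect_equal(s4@energy, 0)
})

test_that("seed energies equal the brute-force duplex minimum", {
  b <- baselinePredictor()
  set.seed(17)
  for (r in 1:25) {
    n1 <- sample(8:15, 1); n2 <- sample(8:15, 1)
    x1 <- randomRNA(n1); x2 <- randomRNA(n2)
    pair <- sequencePair(x1, x2)
    iso1 <- foldSingle(b, x1)
    iso2 <- foldSingle(b, x2)
    joint <- foldJoint(b, x1, x2)
    cand <- seedCandidates(joint, iso1, iso2)
    w <- 6L
    cand1 <- cand[cand <= n1]
    cand2 <- cand[cand > n1] - n1
    oracle <- oracleBestDuplex(x1, x2, cand1, cand2, w)
    sc <- findSeedConstrained(pair, iso1, iso2, cand, w = w)
    ss <- findSeedScan(pair, joint, iso1, iso2, cand, w = w)
    expect_equal(sc@energy, oracle, info = paste(x1, x2))
    expect_equal(ss@energy, oracle, info = paste(x1, x2))
    # seed pairs lie inside the candidate set and within the window cap
    if (nrow(sc@pairs) > 0) {
      expect_true(all(sc@pairs[, 1] %in% cand))
      expect_true(all(sc@pairs[, 2] %in% cand))
      expect_lte(nrow(sc@pairs), w)
    }
  }
})
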