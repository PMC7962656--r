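test_that("single-strand folding matches hand-checked cases", {
  b <- baselinePredictor()
  p <- foldSingle(b, "GGGAAACCC")
  expect_equal(renderDotBracket(asTargetStructure(p)), "(((...)))")
  expect_equal(p@energy, -oracleFoldScore("GGGAAACCC"))

  # no pairable partners at hairpin-loop distance
  p2 <- foldSingle(b, "AAAAAA")
  expect_equal(nrow(basePairs(p2)), 0L)
  expect_equal(p2@energy, 0)

  # prohibiting all pairs forces the open chain
  cons <- structureConstraint(rep("nopair", 9))
  p3 <- foldSingle(b, "GGGAAACCC", cons)
  expect_equal(nrow(basePairs(p3)), 0L)
  expect_equal(p3@energy, 0)

  # an enforced pair between unpairable nucleotides is contradictory
  codes <- rep("free", 9); codes[c(1, 9)] <- "pair"
  partner <- rep(NA_integer_, 9); partner[1] <- 9L; partner[9] <- 1L
  bad <- structureConstraint(codes, partner)
  expect_error(foldSingle(b, "AGGAAACCC", bad), "contradictory")
})

test_that("single-strand folding equals exhaustive enumeration", {
  b <- baselinePredictor()
  set.seed(5)
  for (r in 1:30) {
    n <- sample(5:12, 1)
    x <- randomRNA(n)
    p <- foldSingle(b, x)
    expect_equal(p@energy, -oracleFoldScore(x), info = x)
    # the returned structure must itself attain the optimal score
    chars <- strsplit(x, "")[[1]]
    bp <- basePairs(p)
    pairs <- lapply(seq_len(nrow(bp)), function(k) bp[k, ])
    expect_equal(oracleScore(chars, pairs), oracleFoldScore(x), info = x)
  }
})

test_that("constrained folds honor enforced and prohibited positions", {
  b <- baselinePredictor()
  set.seed(13)
  for (r in 1:10) {
    x <- randomRNA(10)
    codes <- rep("free", 10)
    codes[sample(10, 3)] <- "nopair"
    cons <- structureConstraint(codes)
    p <- foldSingle(b, x, cons)
    expect_equal(p@energy, -oracleFoldScore(x, codes), info = x)
    banned <- which(codes == "nopair")
    expect_true(all(is.na(p@partner[banned])))
  }
})

test_that("joint folding selects the best intermolecular duplex region", {
  b <- baselinePredictor()
  j <- foldJoint(b, "AAAA", "UUUU")
  bp <- basePairs(j)
  expect_equal(nrow(bp), 4L)
  expect_true(all(bp[, 1] <= 4 & bp[, 2] > 4))
  expect_equal(j@energy, oracleBestDuplex("AAAA", "UUUU", 1:4, 1:4, 6))

  # with intermolecular pairing prohibited the strands fold independently
  nc <- structureConstraint(rep("nointer", 9))
  nc2 <- structureConstraint(rep("nointer", 9))
  j2 <- foldJoint(b, "GGGAAACCC", "AAAAAAAAA", nc, nc2)
  expect_equal(j2@energy, foldSingle(b, "GGGAAACCC")@energy)
  bp2 <- basePairs(j2)
  expect_true(all(bp2[, 2] <= 9))

  # zero regions reduce exactly to independent single-strand folds
  set.seed(23)
  for (r in 1:5) {
    x1 <- randomRNA(15); x2 <- randomRNA(15)
    j3 <- foldJoint(b, x1, x2, maxRegions = 0L)
    expect_equal(j3@energy,
                 foldSingle(b, x1)@energy + foldSingle(b, x2)@energy)
  }
})

test_that("identical inputs give identical predictions", {
  b <- baselinePredictor()
  set.seed(31)
  x1 <- randomRNA(30); x2 <- randomRNA(30)
  a <- foldJoint(b, x1, x2)
  bb <- foldJoint(b, x1, x2)
  expect_identical(a@partner, bb@partner)
  expect_identical(a@energy, bb@energy)
})

test_that("the external-backend adapter enforces its text protocol", {
  expect_error(externalPredictor("no-such-folding-program-xyz"), "not found")

  # a mock backend that logs its stdin and echoes a fixed prediction
  log <- tempfile()
  mock <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", paste0("cat > ", log),
               "echo '((((....)))) (-4.50)'"), mock)
  Sys.chmod(mock, "0755")
  ext <- externalPredictor(mock, constraintArgs = "-C", name = "mock")
  p <- foldSingle(ext, "GGGGAAAACCCC")
  expect_equal(p@energy, -4.5)
  expect_equal(nrow(basePairs(p)), 4L)

  # the constraint line uses the one-character-per-position dialect
  cons <- structureConstraint(rep("nointer", 12))
  p2 <- foldSingle(ext, "GGGGAAAACCCC", cons)
  sent <- readLines(log)
  expect_equal(sent[1], "GGGGAAAACCCC")
  expect_equal(sent[2], strrep("e", 12))

  # joint protocol: strands joined by '&'
  mock2 <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo '((((&)))) (-7.25)'"), mock2)
  Sys.chmod(mock2, "0755")
  ext2 <- externalPredictor(mock2, name = "mock2")
  j <- foldJoint(ext2, "GGGG", "CCCC")
  expect_equal(j@strandLengths, c(4L, 4L))
  expect_equal(j@energy, -7.25)
  expect_equal(nrow(basePairs(j)), 4L)

  # unparseable output surfaces as an error, never a silent default
  mock3 <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'garbage'"), mock3)
  Sys.chmod(mock3, "0755")
  expect_error(foldSingle(externalPredictor(mock3), "GGGG"), "unparseable")
})
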