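test_that("extended dot-bracket parsing resolves pairs by per-family stacks", {
  t <- parseDotBracket("((..))")
  expect_equal(t@strandLengths, 6L)
  expect_equal(basePairs(t), cbind(i = c(1L, 2L), j = c(6L, 5L)))
  expect_equal(t@codes[3:4], c(".", "."))

  # crossing families encode a pseudoknot
  pk <- parseDotBracket("((..[[..))..]]")
  expect_equal(basePairs(pk),
               cbind(i = c(1L, 2L, 5L, 6L), j = c(10L, 9L, 14L, 13L)))

  # pairs spanning '&' are intermolecular
  h <- parseDotBracket("((((&))))")
  expect_equal(h@strandLengths, c(4L, 4L))
  expect_equal(basePairs(h), cbind(i = 1:4, j = 8:5))

  # wildcards carry no partner
  w <- parseDotBracket("**.^")
  expect_equal(w@codes, c("*", "*", ".", "^"))
  expect_equal(nrow(basePairs(w)), 0L)
})

test_that("malformed dot-bracket input is rejected", {
  expect_error(parseDotBracket("(()"), "unbalanced")
  expect_error(parseDotBracket("((]]"), "unbalanced")
  expect_error(parseDotBracket("((z))"), "illegal")
  expect_error(parseDotBracket("(&)&("), "at most one")
})

test_that("rendering inverts parsing on pairs and wildcard codes", {
  cases <- c("((..))", "((..[[..))..]]", "((((&))))", "**.^", "...",
             "((..)).(((...)))", "(((..[[[..)))..]]].**")
  for (s in cases) {
    t <- parseDotBracket(s)
    r <- renderDotBracket(t)
    t2 <- parseDotBracket(r)
    expect_equal(basePairs(t2), basePairs(t), info = s)
    expect_equal(t2@codes, t@codes, info = s)
    expect_equal(t2@strandLengths, t@strandLengths, info = s)
  }
})

test_that("round-trip holds for predicted structures of random sequences", {
  set.seed(41)
  b <- baselinePredictor()
  for (r in 1:10) {
    p <- foldJoint(b, randomRNA(25), randomRNA(25))
    t <- asTargetStructure(p)
    t2 <- parseDotBracket(renderDotBracket(t))
    expect_equal(basePairs(t2), basePairs(t))
  }
})

test_that("S+ runs expand into dot-bracket with declared lengths", {
  r <- parseSPlus("U2[3U4]U2")
  expect_equal(renderDotBracket(r$structure),
               renderDotBracket(parseDotBracket("..(((....)))..")))
  expect_equal(sum(r$structure@strandLengths), 14L)
  expect_equal(r$constraint@codes, rep("N", 14))

  # 'x' resolves against the declared strand length
  r2 <- parseSPlus("UxU3", strandLengths = 8L)
  expect_equal(sum(r2$structure@strandLengths), 8L)
  expect_equal(nrow(basePairs(r2$structure)), 0L)

  # '_' is a loop of length one unless followed by an integer
  r3 <- parseSPlus("_[3_3]_")
  expect_equal(sum(r3$structure@strandLengths), 11L)
  expect_equal(nrow(basePairs(r3$structure)), 3L)

  # intermolecular duplex: halves on opposite sides of '&'
  r4 <- parseSPlus("U2[4&]U2")
  expect_equal(r4$structure@strandLengths, c(6L, 6L))
  bp <- basePairs(r4$structure)
  expect_equal(nrow(bp), 4L)
  expect_true(all(bp[, 1] <= 6 & bp[, 2] > 6))
})

test_that("S+ motifs splice structure and IUPAC sequence constraints", {
  r <- parseSPlus(c("U3A U4 B U3", "A = [[[[[[", "A = aggagg",
                    "B = ]]]]]]"))
  expect_equal(sum(r$structure@strandLengths), 22L)
  bp <- basePairs(r$structure)
  expect_equal(nrow(bp), 6L)
  expect_equal(bp[, 1], 4:9)       # upstream duplex positions
  expect_equal(r$constraint@codes[4:9], c("A", "G", "G", "A", "G", "G"))
  expect_equal(r$constraint@codes[1:3], c("N", "N", "N"))
})

test_that("S+ errors are informative", {
  expect_error(parseSPlus("U2Q"), "without a definition")
  expect_error(parseSPlus("[x"), "cannot be attached")
  expect_error(parseSPlus("Ux"), "no strand lengths")
  expect_error(parseSPlus(c("A", "A = ((", "A = aggagg")),
               "differ in length")
  expect_error(parseSPlus(c("AA", "A = ..", "A = nn", "A = ..")),
               "more than once")
  expect_error(parseSPlus("U2[3U4]U2", strandLengths = 10L),
               "does not match")
})
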