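tinyTargets <- function(iso1, iso2, hyb) {
  targetSet(hyb = parseDotBracket(hyb),
            iso1 = parseDotBracket(iso1),
            iso2 = parseDotBracket(iso2))
}

test_that("dependency components union the pairs of all targets", {
  t <- tinyTargets("(...)", ".....", ".....&.....")
  d <- dependencyComponents(t)
  comps <- d$components[order(vapply(d$components, min, numeric(1)))]
  expect_true(list(c(1L, 5L)) %in% comps ||
                any(vapply(comps, function(cc) setequal(cc, c(1, 5)),
                           logical(1))))
  expect_equal(length(comps), 9L)   # {1,5} + 8 singletons

  # a position paired differently in different targets chains the partners
  # into one component: iso1 pairs (1,6), the complex pairs 6 with the
  # first position of strand 2 (global 7)
  t2 <- tinyTargets("(....)", "......", ".....(&).....")
  d2 <- dependencyComponents(t2)
  big <- d2$components[[which(vapply(d2$components, function(cc) 1 %in% cc,
                                     logical(1)))]]
  expect_true(setequal(big, c(1, 6, 7)))

  # no pairs anywhere -> all singletons
  t3 <- tinyTargets("....", "....", "....&....")
  expect_equal(length(dependencyComponents(t3)$components), 8L)
})

test_that("compatible sampling respects pairs and IUPAC constraints", {
  t <- tinyTargets("(...)", ".....", ".....&.....")
  set.seed(2)
  for (r in 1:20) {
    s <- sampleCompatible(t)
    expect_true(isCompatible(s, Filter(Negate(is.null), t)))
  }
  # 'GNNNC' forces G at 1; the partner at 5 must pair with G
  cons <- new("SequenceConstraint", strandLengths = c(5L, 5L),
              codes = c("G", "N", "N", "N", "N", rep("N", 5)))
  cons@codes[5] <- "N"
  consG <- new("SequenceConstraint", strandLengths = c(5L, 5L),
               codes = c("G", rep("N", 9)))
  set.seed(3)
  for (r in 1:10) {
    s <- sampleCompatible(t, consG)
    ch <- strsplit(sequences(s)[1], "")[[1]]
    expect_equal(ch[1], "G")
    expect_true(ch[5] %in% c("C", "U"))
  }
  # A at 1 and C at 5 with pair (1,5) is unsatisfiable
  bad <- new("SequenceConstraint", strandLengths = c(5L, 5L),
             codes = c("A", "N", "N", "N", "C", rep("N", 5)))
  expect_error(sampleCompatible(t, bad), "unsatisfiable")
})

test_that("point mutation preserves compatibility at any rate", {
  set.seed(5)
  fx <- generateFixture(15, 15)
  deps <- dependencyComponents(fx$targets)
  parent <- fx$pair
  # pM = 0 leaves the parent untouched
  expect_equal(sequences(pointMutation(parent, fx$targets, pM = 0,
                                       deps = deps)),
               sequences(parent))
  ts <- Filter(Negate(is.null), fx$targets)
  for (pM in c(0.05, 0.5, 1)) {
    for (r in 1:30) {
      child <- pointMutation(parent, fx$targets, pM = pM, deps = deps)
      expect_true(isCompatible(child, ts))
    }
  }
})

test_that("negative design breaks an undesired predicted pair", {
  # target: all unpaired; a self-complementary strand will fold -> every
  # predicted pair is undesired
  t <- tinyTargets(strrep(".", 12), strrep(".", 12),
                   paste0(strrep(".", 12), "&", strrep(".", 12)))
  parent <- sequencePair("GGGGAAAACCCC", "AAAAAAAAAAAA")
  ev <- evaluateObjectives(parent, t)
  expect_gt(ev$objectives@fdist, 0)
  set.seed(11)
  improvedOnce <- FALSE
  for (r in 1:20) {
    child <- negativeDesign(parent, ev$predictions, t)
    expect_true(isCompatible(child, Filter(Negate(is.null), t)))
    if (!identical(sequences(child), sequences(parent))) improvedOnce <- TRUE
  }
  expect_true(improvedOnce)

  # nothing undesired -> falls back to point mutation without error
  set.seed(12)
  fx <- generateFixture(15, 15)
  ev2 <- evaluateObjectives(fx$pair, fx$targets)
  expect_equal(ev2$objectives@fdist, 0)
  child2 <- negativeDesign(fx$pair, ev2$predictions, fx$targets)
  expect_true(isCompatible(child2, Filter(Negate(is.null), fx$targets)))
})

test_that("positive design installs G/C at a missing target pair", {
  set.seed(13)
  fx <- generateFixture(15, 15)
  deps <- dependencyComponents(fx$targets)
  # a random compatible pair whose prediction misses some target pairs
  repeat {
    parent <- sampleCompatible(fx$targets, deps = deps)
    ev <- evaluateObjectives(parent, fx$targets)
    if (ev$objectives@fdist > 0) break
  }
  # the missing target pairs (global coordinates) over all three targets
  missingOf <- function(t, pred, offset) {
    tp <- basePairs(t)
    pp <- pred@partner
    tp[is.na(pp[tp[, 1]]) | pp[tp[, 1]] != tp[, 2], , drop = FALSE] + offset
  }
  missing <- rbind(
    missingOf(fx$targets$iso1, ev$predictions$iso1, 0L),
    missingOf(fx$targets$iso2, ev$predictions$iso2, 15L),
    missingOf(fx$targets$hyb, ev$predictions$hyb, 0L))
  sawGC <- FALSE
  ts <- Filter(Negate(is.null), fx$targets)
  for (r in 1:30) {
    child <- positiveDesign(parent, ev$predictions, fx$targets, deps = deps)
    expect_true(isCompatible(child, ts))
    ch <- strsplit(paste(sequences(child), collapse = ""), "")[[1]]
    if (nrow(missing) > 0) {
      for (k in seq_len(nrow(missing))) {
        pairNts <- sort(ch[missing[k, ]])
        if (identical(pairNts, c("C", "G"))) sawGC <- TRUE
      }
    }
  }
  expect_true(sawGC)
})

test_that("crossover concatenates parents and repairs broken components", {
  set.seed(17)
  fx <- generateFixture(15, 15)
  deps <- dependencyComponents(fx$targets)
  a <- sampleCompatible(fx$targets, deps = deps)
  b <- sampleCompatible(fx$targets, deps = deps)
  ts <- Filter(Negate(is.null), fx$targets)
  for (r in 1:30) {
    child <- crossoverPairs(a, b, fx$targets, deps = deps)
    expect_true(isCompatible(child, ts))
  }
  # identical parents reproduce themselves whatever the cut
  for (r in 1:10) {
    child <- crossoverPairs(a, a, fx$targets, deps = deps)
    expect_equal(sequences(child), sequences(a))
  }
})

test_that("prohibited motifs are eliminated where the constraints permit", {
  t <- tinyTargets(strrep(".", 10), strrep(".", 10),
                   paste0(strrep(".", 10), "&", strrep(".", 10)))
  s <- sequencePair("GGGGAUUUUC", "ACGUACGUAC")
  set.seed(19)
  out <- mutateProhibitedMotifs(s, c("GGGG", "UUUU"), t)
  expect_false(grepl("GGGG|UUUU", sequences(out)[1]))
  expect_false(isTRUE(attr(out, "motifFlagged")))

  # no match -> identity
  s2 <- sequencePair("ACGUACGUAC", "ACGUACGUAC")
  out2 <- mutateProhibitedMotifs(s2, c("GGGG"), t)
  expect_equal(sequences(out2), sequences(s2))

  # a motif forced by the IUPAC constraints persists and is flagged
  consG <- new("SequenceConstraint", strandLengths = c(10L, 10L),
               codes = c(rep("G", 4), rep("N", 16)))
  s3 <- sampleCompatible(t, consG)
  out3 <- mutateProhibitedMotifs(s3, c("GGGG"), t, constraint = consG)
  expect_true(isTRUE(attr(out3, "motifFlagged")))
  expect_equal(unname(substr(sequences(out3)[1], 1, 4)), "GGGG")
})

test_that("non-dominated sorting matches brute-force fronts", {
  mkov <- function(f, v) {
    new("ObjectiveVector", fdist = f[1], fint = f[2], fE = f[3],
        g1 = v, g2 = -1, v = v, feasible = v == 0)
  }
  # printed-style example in two objectives (third held constant)
  objs <- list(mkov(c(1, 1, 0), 0), mkov(c(1, 2, 0), 0),
               mkov(c(2, 1, 0), 0), mkov(c(2, 2, 0), 0))
  fronts <- nondominatedSort(objs)
  expect_equal(fronts, list(1L, c(2L, 3L), 4L))

  # identical vectors are mutually non-dominating
  same <- replicate(4, mkov(c(1, 1, 1), 0))
  expect_equal(nondominatedSort(same), list(1:4))

  # one feasible + three infeasible with distinct violations
  mix <- list(mkov(c(9, 9, 9), 0), mkov(c(0, 0, 0), 1),
              mkov(c(0, 0, 0), 2), mkov(c(0, 0, 0), 3))
  expect_equal(nondominatedSort(mix), list(1L, 2L, 3L, 4L))

  set.seed(23)
  for (r in 1:10) {
    n <- sample(5:30, 1)
    objs <- matrix(sample(0:4, n * 3, TRUE), ncol = 3)
    v <- sample(c(0, 0, 1, 2), n, TRUE)
    ovs <- lapply(seq_len(n), function(i) mkov(objs[i, ], v[i]))
    fronts <- nondominatedSort(ovs)
    ref <- bruteFronts(objs, v)
    expect_equal(lapply(fronts, sort), lapply(ref, sort))
  }
})

test_that("crowding distance accumulates normalized neighbour gaps", {
  mkov <- function(f1, f2) {
    new("ObjectiveVector", fdist = f1, fint = f2, fE = 0,
        g1 = -1, g2 = -1, v = 0, feasible = TRUE)
  }
  front <- list(mkov(1, 3), mkov(2, 2), mkov(3, 1))
  expect_equal(crowdingDistance(front), c(Inf, 2, Inf))
  expect_equal(crowdingDistance(front[1]), Inf)
  expect_equal(crowdingDistance(front[1:2]), c(Inf, Inf))
})

test_that("design runs are reproducible and elitist", {
  set.seed(31)
  fx <- generateFixture(16, 16)
  # wide GC bounds keep every solution feasible, so the population minimum
  # of f_dist is protected by elitism (boundary solutions have infinite
  # crowding distance)
  cfg <- designConfig(popSize = 10L, generations = 8L, gcMin = 0, gcMax = 100)
  r1 <- runDesign(fx$targets, cfg, seed = 99)
  r2 <- runDesign(fx$targets, cfg, seed = 99)
  expect_identical(lapply(r1@archive, function(s) sequences(s@pair)),
                   lapply(r2@archive, function(s) sequences(s@pair)))
  expect_identical(r1@log, r2@log)
  # the kept population's best distance never increases (elitism)
  expect_true(all(diff(r1@log$best_fdist) <= 0))
  # archived solutions are front-1 and mutually non-dominating
  objs <- lapply(r1@archive, function(s) s@objectives)
  expect_equal(length(nondominatedSort(objs)), 1L)
})

test_that("unsatisfiable targets are reported before the loop", {
  t <- tinyTargets("(...)", ".....", ".....&.....")
  bad <- new("SequenceConstraint", strandLengths = c(5L, 5L),
             codes = c("A", "N", "N", "N", "C", rep("N", 5)))
  expect_error(runDesign(t, designConfig(popSize = 4L, generations = 1L),
                         constraint = bad), "unsatisfiable")
})
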