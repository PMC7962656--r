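test_that("objective arithmetic reproduces the energy-fixture identities", {
  # constructed energies: E_iso = -3, -4; E_hyb = -20; E_seed = -5
  x1 <- "GGGGGAAAAA"; x2 <- "AAAAACCCCC"
  stub <- stubPredictor(x1)
  fx <- targetSet(hyb = parseDotBracket(paste0(strrep("*", 10), "&",
                                               strrep("*", 10))),
                  iso1 = parseDotBracket(strrep("*", 10)),
                  iso2 = parseDotBracket(strrep("*", 10)))
  ev <- evaluateObjectives(sequencePair(x1, x2), fx, designConfig(),
                           backend = stub)
  o <- ev$objectives
  expect_equal(o@fint, -5 + (-20) - (-3 + -4))   # = -18
  expect_equal(o@fE, -20)
  expect_equal(o@fdist, 0)                       # all-wildcard targets
  expect_equal(o@g1, 45 - 50)
  expect_equal(o@g2, 50 - 55)
  expect_equal(o@v, 0)
  expect_true(o@feasible)
})

test_that("fint, fE and the GC constraints are internally consistent", {
  set.seed(3)
  cfg <- designConfig()
  for (r in 1:10) {
    fx <- generateFixture(18, 18)
    s <- sampleCompatible(fx$targets)
    ev <- evaluateObjectives(s, fx$targets, cfg)
    o <- ev$objectives
    pr <- ev$predictions
    expect_equal(o@fint,
                 pr$seed@energy + pr$hyb@energy -
                   (pr$iso1@energy + pr$iso2@energy))
    expect_equal(o@fE, pr$hyb@energy)
    gc <- gcContent(s)
    expect_equal(o@g1, cfg@gcMin - gc)
    expect_equal(o@g2, gc - cfg@gcMax)
    expect_equal(o@v, max(o@g1, 0) + max(o@g2, 0))
    expect_equal(o@feasible, o@v == 0)
    d <- structureDistance(pr$hyb, fx$targets$hyb) +
      structureDistance(pr$iso1, fx$targets$iso1) +
      structureDistance(pr$iso2, fx$targets$iso2)
    expect_equal(o@fdist, d)
  }
})

test_that("a prediction identical to the targets has distance zero", {
  set.seed(9)
  for (r in 1:5) {
    fx <- generateFixture(20, 20)
    ev <- evaluateObjectives(fx$pair, fx$targets)
    expect_equal(ev$objectives@fdist, 0)
  }
})

test_that("constraint dominance follows the three comparison branches", {
  ov <- function(fd, fi, fe, g1 = -1, g2 = -1) {
    v <- max(g1, 0) + max(g2, 0)
    new("ObjectiveVector", fdist = fd, fint = fi, fE = fe, g1 = g1, g2 = g2,
        v = v, feasible = v == 0)
  }
  # feasible beats infeasible regardless of objectives
  expect_equal(dominates(ov(10, 10, 10), ov(0, 0, 0, g1 = 3)), "a")
  expect_equal(dominates(ov(0, 0, 0, g1 = 3), ov(10, 10, 10)), "b")
  # two feasible: Pareto with strict improvement somewhere
  expect_equal(dominates(ov(1, -10, -20), ov(2, -10, -20)), "a")
  expect_equal(dominates(ov(2, -10, -20), ov(1, -10, -20)), "b")
  expect_equal(dominates(ov(1, -10, -20), ov(1, -10, -20)), "neither")
  expect_equal(dominates(ov(1, -20, -10), ov(2, -10, -20)), "neither")
  # two infeasible: ordered by violation, ties non-dominating
  expect_equal(dominates(ov(9, 9, 9, g1 = 1), ov(0, 0, 0, g1 = 2)), "a")
  expect_equal(dominates(ov(0, 0, 0, g1 = 3), ov(9, 9, 9, g1 = 1)), "b")
  expect_equal(dominates(ov(0, 0, 0, g1 = 3), ov(9, 9, 9, g1 = 3)), "neither")
})

test_that("dominance agrees with the reference comparator exhaustively", {
  # systematic grid: each objective better/equal/worse, each violation
  # zero/positive (two levels)
  deltas <- c(-1, 0, 1)
  vlevels <- c(0, 0.5, 2)
  base <- c(5, -5, -10)
  for (d1 in deltas) for (d2 in deltas) for (d3 in deltas)
    for (va in vlevels) for (vb in vlevels) {
      fa <- base; fb <- base + c(d1, d2, d3)
      a <- new("ObjectiveVector", fdist = fa[1], fint = fa[2], fE = fa[3],
               g1 = va, g2 = -1, v = max(va, 0), feasible = va == 0)
      b <- new("ObjectiveVector", fdist = fb[1], fint = fb[2], fE = fb[3],
               g1 = vb, g2 = -1, v = max(vb, 0), feasible = vb == 0)
      expect_equal(dominates(a, b), refComparator(fa, va, fb, vb))
    }
})

test_that("dominance is antisymmetric and never reflexive", {
  set.seed(29)
  for (r in 1:100) {
    fa <- round(stats::runif(3, -20, 20))
    fb <- round(stats::runif(3, -20, 20))
    va <- sample(c(0, 1, 2), 1); vb <- sample(c(0, 1, 2), 1)
    a <- new("ObjectiveVector", fdist = fa[1], fint = fa[2], fE = fa[3],
             g1 = va, g2 = -1, v = va, feasible = va == 0)
    b <- new("ObjectiveVector", fdist = fb[1], fint = fb[2], fE = fb[3],
             g1 = vb, g2 = -1, v = vb, feasible = vb == 0)
    ab <- dominates(a, b); ba <- dominates(b, a)
    if (ab == "a") expect_equal(ba, "b")
    if (ab == "b") expect_equal(ba, "a")
    if (ab == "neither") expect_equal(ba, "neither")
    expect_equal(dominates(a, a), "neither")
  }
})
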