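# mechanistic fork model: closed form, Monte-Carlo oracle, monotonicity

test_that("survival collapses to the boundary cases of the rescue loop", {
  mp <- assignMispair(delta_het())  # T/C on the lagging strand
  # no absorbing rescue (w*r = 0): every insertion eventually extended
  par0 <- unitForkParams(ins = 1, ext = 0.05, wt_delta = 0)
  expect_equal(mutationProbability(par0, mispair = mp), 1)
  # all-wild-type rescue (w*r = 1): only first-pass extensions survive,
  # and insertion is halved by the het pool
  par1 <- unitForkParams(ins = 1, ext = 0.05, wt_delta = 1)
  par1@wtDeltaFraction <- 1
  # lagging-strand insertion now comes from a fully wt pool -> use epsilon
  mpe <- assignMispair(eps_het())
  par1@wtEpsilonFraction <- 0
  expect_equal(mutationProbability(par1, mispair = mpe), 0.05)
})

test_that("closed form matches the hand-evaluated worked example", {
  # e = 0.05, w = 0.5, r = 1: P_survive = 0.05 + 0.95*(0.025/0.525)
  mp <- assignMispair(delta_het())
  par <- unitForkParams(ins = 1, ext = 0.05, wt_delta = 0.5)
  p_het <- mutationProbability(par, mispair = mp)
  expect_equal(p_het, 0.5 * 0.0952381, tolerance = 1e-6)
  par_hom <- unitForkParams(ins = 1, ext = 0.05, wt_delta = 0)
  p_hom <- mutationProbability(par_hom, mispair = mp)
  expect_equal(p_hom / p_het, 21.0, tolerance = 1e-4)
  expect_equal(p_hom / p_het, 2 / oracleSurvive(0.05, 0.5, 1), tolerance = 1e-10)
})

test_that("applyGenotype maps zygosity to pool fractions and msh6 to MMR 0", {
  par <- defaultForkParams()
  p <- applyGenotype(par, StrainGenotype("G148T", "F", msh6 = "del",
                                         pol3 = "het"))
  expect_equal(p@wtDeltaFraction, 0.5)
  expect_equal(p@wtEpsilonFraction, 1)
  expect_equal(p@mmrEfficiency, 0)
  p2 <- applyGenotype(par, StrainGenotype("G148T", "F", msh6 = "wt",
                                          pol2 = "hom"))
  expect_equal(p2@wtEpsilonFraction, 0)
  expect_equal(p2@mmrEfficiency, par@mmrEfficiency)
})

test_that("missing mispair keys raise a configuration error naming the key", {
  par <- unitForkParams()
  par@insProb <- par@insProb[names(par@insProb) != "T/C"]
  mp <- assignMispair(delta_het())
  expect_error(mutationProbability(par, mispair = mp), "T/C")
})

test_that("Monte-Carlo simulator hits the trivial and worked examples", {
  mp <- assignMispair(delta_het())
  sure <- unitForkParams(ins = 1, ext = 1, wt_delta = 0)
  expect_equal(as.numeric(simulateForkMC(sure, mispair = mp,
                                         n_replications = 1000, seed = 1)), 1)
  par <- unitForkParams(ins = 1, ext = 0.05, wt_delta = 0.5)
  est <- simulateForkMC(par, mispair = mp, n_replications = 1e5, seed = 2)
  truth <- 0.5 * 0.0952381
  se <- sqrt(truth * (1 - truth) / 1e5)
  expect_lt(abs(est - truth), 3 * se)
})

test_that("Monte-Carlo agrees with the closed form over random parameter draws", {
  mp <- assignMispair(delta_het())
  set.seed(99)
  n <- 3e4
  for (i in 1:20) {
    e <- runif(1, 0.01, 0.9)
    w <- sample(c(0, 0.5, 1), 1)
    r <- runif(1, 0.2, 1)
    mmr <- sample(c(0, 0.9), 1)
    par <- unitForkParams(ins = 1, ext = e, rescue = r, wt_delta = w,
                          mmr = mmr)
    truth <- mutationProbability(par, mispair = mp)
    est <- simulateForkMC(par, mispair = mp, n_replications = n,
                          seed = 1000 + i)
    se <- sqrt(max(truth * (1 - truth), 1e-12) / n)
    expect_lt(abs(est - truth), 3 * se + 1e-9,
              label = sprintf("draw %d (e=%.3f w=%.1f r=%.2f mmr=%.1f)",
                              i, e, w, r, mmr))
  }
})

test_that("reversion probability is monotone in the model's parameters", {
  mp <- assignMispair(delta_het())
  base <- function(w = 0.5, mmr = 0, ins = 1e-6, ext = 0.05) {
    p <- unitForkParams(ins = ins, ext = ext, wt_delta = w, mmr = mmr)
    mutationProbability(p, mispair = mp)
  }
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  expect_true(all(diff(vapply(ws, function(w) base(w = w), 0)) <= 0))
  mm <- c(0, 0.5, 0.9, 0.99)
  expect_true(all(diff(vapply(mm, function(m) base(mmr = m), 0)) <= 0))
  ii <- c(1e-8, 1e-7, 1e-6, 1e-5)
  expect_true(all(diff(vapply(ii, function(i) base(ins = i), 0)) >= 0))
  ee <- c(0.01, 0.05, 0.2, 0.8)
  expect_true(all(diff(vapply(ee, function(e) base(ext = e), 0)) >= 0))
})

test_that("a proofreading-exempt mispair reverts identically across pol3 genotypes", {
  # primer 8-oxoG opposite A: extension certain, rescue never, but MMR
  # still applies
  key <- "A/oxoG"
  mp <- new("MispairAssignment", polymerase = "delta", strand = "lagging",
            templateBase = "A", primerBase = "oxoG")
  probs <- vapply(c(0, 0.5, 1), function(w) {
    par <- unitForkParams(ins = 1e-4, ext = 0.01, wt_delta = w,
                          exempt = key)
    par@insProb[key] <- 1e-4
    mutationProbability(par, mispair = mp)
  }, 0)
  expect_equal(probs[1], probs[2])
  expect_equal(probs[2], probs[3])
  ests <- vapply(c(0, 0.5, 1), function(w) {
    par <- unitForkParams(ins = 1, ext = 0.01, wt_delta = w, exempt = key)
    as.numeric(simulateForkMC(par, mispair = mp, n_replications = 2e4,
                              seed = 7))
  }, 0)
  expect_equal(ests[1], ests[2])
  expect_equal(ests[2], ests[3])
})

test_that("Pol epsilon het:hom ratio is exactly 2 under a fully wild-type delta pool", {
  mp <- assignMispair(eps_het())
  mk <- function(wt_eps) {
    p <- unitForkParams(ins = 1e-6, ext = 0.05, wt_delta = 1, rescue = 1)
    p@wtEpsilonFraction <- wt_eps
    mutationProbability(p, mispair = mp)
  }
  expect_equal(mk(0) / mk(0.5), 2, tolerance = 1e-12)
})
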