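# oligo transformation: relative ratios, rendering, rank-sum test and
# fork-model predictions

test_that("relative transformation is the mean of per-replicate ratios", {
  rt <- relativeTransformation(rbind(c(50, 50)))
  expect_equal(rt$mean, 1)
  expect_equal(rt$sd, 0)
  rt2 <- relativeTransformation(rbind(c(1, 400), c(2, 400)))
  expect_equal(rt2$mean, 0.00375)
  expect_equal(rt2$rendered, "0.00")
  rt0 <- relativeTransformation(rbind(c(0, 300), c(0, 250)))
  expect_equal(rt0$rendered, "0")
  # zero-control replicates are excluded with a message
  expect_message(rt3 <- relativeTransformation(rbind(c(5, 10), c(3, 0))),
                 "excluded")
  expect_equal(rt3$n, 1)
  expect_equal(rt3$excluded, 1)
  expect_error(relativeTransformation(rbind(c(5, 0))), "control")
})

test_that("rendering keeps the zero / below-1% / value distinction and round-trips", {
  expect_equal(renderRelative(0), "0")
  expect_equal(renderRelative(0.004), "0.00")
  expect_equal(renderRelative(0.25), "0.25")
  expect_equal(renderRelative(2.3), "2.30")
  for (x in c(0, 0.001, 0.0049, 0.01, 0.25, 1, 7)) {
    parsed <- parseRelative(renderRelative(x))
    if (x == 0) expect_equal(parsed$kind, "zero")
    else if (x < 0.005) expect_equal(parsed$kind, "below_0.01")
    else {
      expect_equal(parsed$kind, "value")
      expect_equal(parsed$value, x, tolerance = 0.01)
    }
  }
})

test_that("published relative-transformation values render by the same rules", {
  tab <- read.delim(system.file("extdata", "table2_relative_transformation.tsv",
                                package = "fluctproof"), comment.char = "#")
  rendered <- vapply(tab$mean, renderRelative, "")
  # the printed table distinguishes 0.01 from 0.00-level values
  expect_equal(rendered[tab$genotype == "msh6" & tab$orientation == "F"], "0.01")
  expect_equal(rendered[tab$genotype == "msh6 pol3-5DV" & tab$orientation == "R"], "7.00")
})

test_that("rank-sum test: complete separation and identical samples", {
  sep <- mannWhitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$method, "exact")
  expect_equal(sep$p_value, 2 / choose(6, 3))
  expect_equal(sep$u_statistic, 9)
  same <- mannWhitney(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(same$p_value, 1)
  expect_error(mannWhitney(1, c(1, 2)), "at least 2")
})

test_that("exact p-values match the independent implementation for all n <= 5", {
  set.seed(123)
  for (na in 2:5) for (nb in 2:5) {
    a <- runif(na); b <- runif(nb) + 0.2
    ours <- mannWhitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(ours$method, "exact")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("n=(%d,%d)", na, nb))
    # symmetry under sample swap
    swapped <- mannWhitney(b, a)
    expect_equal(swapped$p_value, ours$p_value)
    expect_equal(swapped$u_statistic, na * nb - ours$u_statistic)
  }
})

test_that("normal approximation tracks the exact test at moderate n", {
  set.seed(7)
  a <- rnorm(10); b <- rnorm(10, 0.8)
  exact <- mannWhitney(a, b)          # n = 20, no ties -> exact
  expect_equal(exact$method, "exact")
  approx <- mannWhitney(c(a, a[1] + 1e-12), b)  # n = 21 -> normal
  expect_equal(approx$method, "normal-approximation")
  expect_lt(abs(exact$p_value - approx$p_value), 0.02)
})

test_that("oligo outcome predictions follow survival x MMR escape", {
  par <- defaultForkParams()
  panel <- list(StrainGenotype("G148T", "R"),
                delta_het("G148T", "R"),
                delta_hom("G148T", "R"))
  # proofreading-exempt oligo: identical prediction in all genotypes
  oxo <- predictOligoOutcome(par, panel, "A/oxoG")
  expect_equal(unname(oxo[1]), unname(oxo[2]))
  expect_equal(unname(oxo[2]), unname(oxo[3]))
  # unextendable mispair: no transformation anywhere
  par0 <- par; par0@extProb["G/A"] <- 0
  ga <- predictOligoOutcome(par0, panel, "G/A")
  expect_true(all(ga == 0))
  # hom/het prediction ratio = 1 / P_survive(het)
  par5 <- par; par5@extProb["T/C"] <- 0.05
  tc <- predictOligoOutcome(par5, panel, "T/C")
  expect_equal(unname(tc[3] / tc[2]), 1 / oracleSurvive(0.05, 0.5, 1),
               tolerance = 1e-10)
  expect_equal(unname(tc[3] / tc[2]), 10.5, tolerance = 0.01)
  expect_error(predictOligoOutcome(par, panel, "X/Y"), "X/Y")
})

test_that("predictions are monotone in extension and anti-monotone in wt fraction", {
  par <- defaultForkParams()
  panel <- list(delta_het("G148T", "R"))
  preds <- vapply(c(0.01, 0.05, 0.2, 0.8), function(e) {
    p <- par; p@extProb["T/C"] <- e
    unname(predictOligoOutcome(p, panel, "T/C"))
  }, 0)
  expect_true(all(diff(preds) > 0))
  byW <- vapply(list(StrainGenotype("G148T", "R"),
                     delta_het("G148T", "R"),
                     delta_hom("G148T", "R")), function(g)
    unname(predictOligoOutcome(par, list(g), "T/C")), 0)
  expect_true(all(diff(byW) > 0))  # wt fraction 1 -> 0.5 -> 0 raises survival
})

test_that("oligo FASTA definitions expose the 3' tag and strand", {
  fa <- readOligoFasta(system.file("extdata", "oligos_synthetic.fasta",
                                   package = "fluctproof"))
  expect_equal(nrow(fa), 6L)
  expect_equal(fa$prime3[fa$oligo_id == "148oxoG_synthetic"], "oxoG")
  expect_equal(fa$prime3[fa$oligo_id == "148C_synthetic"], "C")
  expect_true(all(nchar(fa$sequence) == 40L))
})
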