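## Synthetic-data generation: Lea-Coulson culture simulator driven by
## fork-model true rates.

## one derived seed per experiment: a documented splitting rule so that a
## single study seed yields reproducible but independent experiment streams
.splitSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one fluctuation experiment
#'
#' Lea-Coulson culture simulator: each culture grows deterministically from
#' \code{n0} to \code{n_final} cells; mutation events are Poisson with mean
#' \code{m = mu * (n_final - n0)}; each event founds a mutant clone of size
#' \code{floor(1/U)}, \code{U ~ Uniform(0,1)} (no mutant fitness
#' differential); the mutant total is capped at \code{n_final}; plating a
#' fraction < 1 applies binomial thinning. Deterministic given \code{seed}.
#'
#' @param mu per-cell mutation rate.
#' @param n0 inoculum size (>= 1).
#' @param n_final cells at plating (> n0).
#' @param n_cultures number of parallel cultures.
#' @param plated_fraction fraction of each culture plated, in (0, 1].
#' @param seed integer seed.
#' @param genotype \linkS4class{StrainGenotype} to attach (default a
#'   generic placeholder).
#' @param experimentId identifier for the returned experiment.
#' @return A \linkS4class{FluctuationExperiment}.
#' @examples
#' g <- StrainGenotype("G148T", "R", pol3 = "hom")
#' simulateFluctuationAssay(1e-8, 1e3, 2e8, 24, seed = 7, genotype = g)
#' @export
simulateFluctuationAssay <- function(mu, n0 = 1e3, n_final = 2e8,
                                     n_cultures = 24, plated_fraction = 1,
                                     seed = 1,
                                     genotype = StrainGenotype("G148T", "F", pol3 = "hom"),
                                     experimentId = "sim") {
  stopifnot(n_final > n0, n0 >= 1, n_cultures >= 1, mu >= 0,
            plated_fraction > 0, plated_fraction <= 1)
  if (mu * n_final > 1e4)
    stop("mu * n_final = ", format(mu * n_final, digits = 3),
         " > 1e4: jackpot regime outside the estimator's validity; ",
         "reduce mu or n_final", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m <- mu * (n_final - n0)
  nmut <- rpois(n_cultures, m)
  counts <- vapply(nmut, function(k) {
    if (k == 0L) return(0)
    min(sum(floor(1 / runif(k))), n_final)
  }, 0)
  if (plated_fraction < 1)
    counts <- rbinom(n_cultures, size = as.integer(counts), prob = plated_fraction)
  FluctuationExperiment(experimentId, genotype, counts, n_final,
                        platedFraction = plated_fraction)
}

#' Study design mirroring the reversion assay
#'
#' The full factorial design of the assay: each reporter allele in both
#' orientations crossed with the five genotype classes (msh6 only; msh6
#' with het or hom Pol epsilon proofreading deficiency; msh6 with het or
#' hom Pol delta proofreading deficiency). Four alleles x two orientations
#' x five classes = 40 strains.
#'
#' @param alleles reporter alleles (default the four non-identical-base
#'   alleles).
#' @return list of \linkS4class{StrainGenotype}.
#' @export
paperLikeDesign <- function(alleles = c("G148T", "A149C", "G148A", "A149G")) {
  classes <- list(
    list(pol2 = "wt", pol3 = "wt"),
    list(pol2 = "het", pol3 = "wt"),
    list(pol2 = "hom", pol3 = "wt"),
    list(pol2 = "wt", pol3 = "het"),
    list(pol2 = "wt", pol3 = "hom")
  )
  out <- list()
  for (al in alleles) for (o in c("F", "R")) for (cl in classes)
    out[[length(out) + 1L]] <-
      StrainGenotype(al, o, msh6 = "del", pol2 = cl$pol2, pol3 = cl$pol3)
  out
}

## true per-cell rate for any genotype, including ones with no mutant
## polymerase (background only)
.trueRate <- function(params, genotype) {
  if (genotype@pol2 == "wt" && genotype@pol3 == "wt") {
    p <- applyGenotype(params, genotype)
    return(p@backgroundRate)
  }
  mutationProbability(params, genotype)
}

#' Generate a complete synthetic study
#'
#' Chains the fork model and the culture simulator over a design: computes
#' each genotype's true per-cell reversion rate, simulates a fluctuation
#' experiment for it, and (optionally) writes the standard culture TSV plus
#' a ground-truth sidecar in YAML for parameter-recovery tests.
#'
#' @param params \linkS4class{ForkModelParams}.
#' @param design list of \linkS4class{StrainGenotype} (e.g. from
#'   \code{\link{paperLikeDesign}}).
#' @param n0,n_final,n_cultures,plated_fraction assay settings passed to
#'   \code{\link{simulateFluctuationAssay}}.
#' @param seed study seed; one seed per experiment is derived from it.
#' @param file optional path for the culture TSV.
#' @param sidecar optional path for the YAML ground-truth sidecar (true
#'   rates and, for heterozygous Pol delta mispairs, the true rescued
#'   fraction \code{f = 1 - P_survive(het)}).
#' @return list of \linkS4class{FluctuationExperiment}, with the
#'   ground-truth data.frame as attribute \code{truth}.
#' @export
generateStudy <- function(params, design, n0 = 1e3, n_final = 2e8,
                          n_cultures = 24, plated_fraction = 1, seed = 1,
                          file = NULL, sidecar = NULL) {
  stopifnot(is(params, "ForkModelParams"))
  n <- length(design)
  seeds <- if (n) .splitSeeds(seed, n) else integer()
  experiments <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- design[[i]]
    mu <- .trueRate(params, g)
    id <- sprintf("exp%03d", i)
    experiments[[i]] <- simulateFluctuationAssay(
      mu, n0 = n0, n_final = n_final, n_cultures = n_cultures,
      plated_fraction = plated_fraction, seed = seeds[i],
      genotype = g, experimentId = id)
    polMut <- g@pol2 != "wt" || g@pol3 != "wt"
    f_true <- NA_real_
    if (polMut) {
      gp <- applyGenotype(params, g)
      key <- mispairKey(assignMispair(g))
      ## rescued fraction a het pool would show for this mispair
      hetp <- gp; hetp@wtDeltaFraction <- 0.5
      f_true <- 1 - .surviveProbability(hetp, key)
    }
    truth[[i]] <- data.frame(
      experiment_id = id, genotype = .genotypeLabel(g),
      true_mu = mu, true_m = mu * (n_final - n0),
      true_f_het = f_true, seed = seeds[i], stringsAsFactors = FALSE)
  }
  truthDf <- if (n) do.call(rbind, truth) else
    data.frame(experiment_id = character(), genotype = character(),
               true_mu = numeric(), true_m = numeric(),
               true_f_het = numeric(), seed = integer())
  if (!is.null(file)) writeCultureTSV(experiments, file, seed = seed)
  if (!is.null(sidecar))
    yaml::write_yaml(list(seed = as.integer(seed),
                          experiments = lapply(seq_len(nrow(truthDf)), function(i)
                            as.list(truthDf[i, ]))), sidecar)
  attr(experiments, "truth") <- truthDf
  experiments
}
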