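## Mechanistic replication-fork error model.
##
## A reversion requires that (1) the replicating polymerase inserts the
## reversion-producing mispair, (2) the mispair survives proofreading —
## either the inserting polymerase extends it directly, or after
## dissociation the exposed 3' terminus escapes excision by the wild-type
## Pol delta pool through a re-engagement loop — and (3) the resulting
## mismatch escapes mismatch repair. The rescuing/re-engaging molecule is
## always drawn from the Pol delta pool: Pol delta proofreads exposed
## termini on both strands (in cis and in trans), Pol epsilon never does.

.forkLookup <- function(map, key, what) {
  if (!key %in% names(map))
    stop("mispair key '", key, "' missing from ", what,
         "; add it to the fork-model parameters", call. = FALSE)
  unname(map[[key]])
}

.wtFraction <- function(params, polymerase) {
  if (polymerase == "epsilon") params@wtEpsilonFraction else params@wtDeltaFraction
}

## probability a 3' mispair already at an exposed/engaged state is
## eventually extended (fixed) rather than excised
.surviveProbability <- function(params, key) {
  if (key %in% params@oxoGExempt) return(1)
  e <- .forkLookup(params@extProb, key, "extProb")
  w <- params@wtDeltaFraction
  r <- params@rescueProb
  ## dissociation -> with prob w*r a wild-type Pol delta excises (absorbed),
  ## otherwise a deficient Pol delta re-engages and extends with prob e'
  ## (= e); geometric loop:
  eprime <- e
  denom <- 1 - (1 - w * r) * (1 - eprime)
  ## denom = 0 only when extension never happens and rescue never absorbs:
  ## the terminus is shuttled forever and no reversion is fixed
  p_loop <- if (denom <= 0) 0 else (1 - w * r) * eprime / denom
  e + (1 - e) * p_loop
}

#' Per-replication reversion probability under the fork model
#'
#' Closed-form probability that one replication of the assayed site fixes
#' the reversion: insertion by the replicating polymerase (scaled by the
#' proofreading-deficient fraction of its pool, with a small
#' \code{exoEscape} leak for proficient molecules), survival of the
#' extension/dissociation/rescue chain (rescue is always by the Pol delta
#' pool), escape from mismatch repair, plus a genotype-independent
#' background. Mispairs flagged proofreading-exempt (8-oxoG-A) are invisible
#' to every exonuclease — retained regardless of the pool's proofreading
#' status, extended with certainty, never rescued — but remain visible to
#' mismatch repair.
#'
#' @param params \linkS4class{ForkModelParams}. The pool fractions in
#'   \code{params} are ignored in favour of the genotype's zygosity when
#'   \code{genotype} is supplied.
#' @param genotype \linkS4class{StrainGenotype}, or NULL to use the pool
#'   fractions stored in \code{params} directly.
#' @param mispair \linkS4class{MispairAssignment} identifying the
#'   replicating polymerase and the template/primer bases; defaults to
#'   \code{assignMispair(genotype)}.
#' @return per-replication reversion probability.
#' @examples
#' p <- defaultForkParams()
#' g <- StrainGenotype("G148T", "R", pol3 = "hom")
#' mutationProbability(p, g)
#' @export
mutationProbability <- function(params, genotype = NULL,
                                mispair = if (!is.null(genotype)) assignMispair(genotype)) {
  stopifnot(is(params, "ForkModelParams"), is(mispair, "MispairAssignment"))
  if (!is.null(genotype)) params <- applyGenotype(params, genotype)
  key <- mispairKey(mispair)
  ins <- .forkLookup(params@insProb, key, "insProb")
  wt <- .wtFraction(params, mispair@polymerase)
  ## proofreading-exempt mispairs are invisible to the inserting molecule's
  ## own exonuclease as well, so the pool composition does not matter
  insertion <- if (key %in% params@oxoGExempt) ins else
    ins * ((1 - wt) + wt * params@exoEscape)
  survive <- .surviveProbability(params, key)
  insertion * survive * (1 - params@mmrEfficiency) + params@backgroundRate
}

#' Map a genotype onto fork-model pool fractions
#'
#' Returns a copy of \code{params} whose wild-type pool fractions and MMR
#' efficiency reflect the genotype: zygosity wt/het/hom gives fractions
#' 1/0.5/0, and an \code{msh6} deletion sets MMR efficiency to 0.
#'
#' @param params \linkS4class{ForkModelParams}.
#' @param genotype \linkS4class{StrainGenotype}.
#' @return modified \linkS4class{ForkModelParams}.
#' @export
applyGenotype <- function(params, genotype) {
  frac <- c(wt = 1, het = 0.5, hom = 0)
  params@wtEpsilonFraction <- unname(frac[genotype@pol2])
  params@wtDeltaFraction <- unname(frac[genotype@pol3])
  if (genotype@msh6 == "del") params@mmrEfficiency <- 0
  validObject(params)
  params
}

#' Monte-Carlo fork simulator
#'
#' Event-by-event simulation of the insertion -> (extend | dissociate ->
#' rescue-or-re-engage loop) -> mismatch repair chain; the stochastic
#' oracle for \code{\link{mutationProbability}}. Replications whose
#' re-engagement loop exceeds \code{maxReengagement} count as no reversion
#' and are tallied in the \code{loop_overflows} attribute.
#'
#' @inheritParams mutationProbability
#' @param n_replications number of independent replications of the site.
#' @param seed integer seed.
#' @return estimated reversion probability (fraction of replications that
#'   fixed the reversion), with attribute \code{loop_overflows}.
#' @export
simulateForkMC <- function(params, genotype = NULL,
                           mispair = if (!is.null(genotype)) assignMispair(genotype),
                           n_replications = 1e5, seed = 1) {
  stopifnot(n_replications >= 1)
  if (!is.null(genotype)) params <- applyGenotype(params, genotype)
  key <- mispairKey(mispair)
  ins <- .forkLookup(params@insProb, key, "insProb")
  e <- if (key %in% params@oxoGExempt) 1 else .forkLookup(params@extProb, key, "extProb")
  wt <- .wtFraction(params, mispair@polymerase)
  w <- params@wtDeltaFraction
  r <- params@rescueProb
  exempt <- key %in% params@oxoGExempt
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- as.integer(n_replications)
  ## vectorized stage 1: was a mispair inserted and retained pre-extension?
  mutantMol <- runif(n) < (1 - wt)
  inserted <- runif(n) < ins
  kept <- if (exempt) inserted else
    inserted & (mutantMol | (runif(n) < params@exoEscape))
  idx <- which(kept)
  overflows <- 0L
  fixed <- logical(n)
  if (exempt) {
    fixed[idx] <- TRUE
  } else {
    ## event-by-event extension/dissociation/rescue chain, vectorized
    ## across replications; the engaged molecule (inserter, then any
    ## re-engaging deficient Pol delta) extends with probability e
    active <- idx
    iter <- 0L
    while (length(active)) {
      iter <- iter + 1L
      if (iter > params@maxReengagement) {
        overflows <- length(active)  # counted as no reversion
        break
      }
      extended <- runif(length(active)) < e
      fixed[active[extended]] <- TRUE
      rem <- active[!extended]
      if (!length(rem)) break
      ## dissociation: the engaging Pol delta is wild-type-and-rescuing
      ## with probability w*r, which excises the mispair (absorbing)
      rescued <- runif(length(rem)) < w * r
      active <- rem[!rescued]
    }
  }
  ## mismatch repair acts on surviving mismatches (8-oxoG-A included)
  j <- which(fixed)
  if (length(j) && params@mmrEfficiency > 0)
    fixed[j] <- runif(length(j)) >= params@mmrEfficiency
  ## background events are additive and genotype independent
  bg <- runif(n) < params@backgroundRate
  est <- mean(fixed | bg)
  attr(est, "loop_overflows") <- overflows
  est
}

#' Default fork-model parameters
#'
#' One fixed parameterization used as the package's study conditions for
#' synthetic data. Insertion probabilities sit in the 1e-9 to 1e-7 per-site
#' range and extension probabilities are small and strongly mispair-biased
#' (pyrimidine-primer T-C/C-T mispairs extend far better than A-G/G-A,
#' identical-base mispairs barely extend, and a primer 8-oxoG opposite A is
#' extension-certain and proofreading-exempt), reproducing the qualitative
#' orientation and het/hom structure of the reversion assay. See the
#' package vignette for the rationale behind each value.
#'
#' @return A \linkS4class{ForkModelParams}.
#' @export
defaultForkParams <- function() {
  ins <- c("T/C" = 1.0e-7, "C/T" = 8.0e-8,
           "A/G" = 4.0e-8, "G/A" = 8.0e-9,
           "T/G" = 1.2e-7, "G/T" = 5.0e-8,
           "A/C" = 2.0e-8, "C/A" = 1.0e-8,
           "G/G" = 4.0e-9, "C/C" = 4.0e-9,
           "A/A" = 4.0e-9, "T/T" = 4.0e-9,
           "A/oxoG" = 5.0e-8)
  ext <- c("T/C" = 0.040, "C/T" = 0.035,
           "A/G" = 0.008, "G/A" = 0.002,
           "T/G" = 0.050, "G/T" = 0.020,
           "A/C" = 0.010, "C/A" = 0.005,
           "G/G" = 0.001, "C/C" = 0.001,
           "A/A" = 0.001, "T/T" = 0.001,
           "A/oxoG" = 1.0)
  new("ForkModelParams", insProb = ins, extProb = ext,
      exoEscape = 0, rescueProb = 1,
      wtDeltaFraction = 1, wtEpsilonFraction = 1,
      mmrEfficiency = 0.99, backgroundRate = 1e-10,
      oxoGExempt = "A/oxoG", maxReengagement = 1000)
}
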