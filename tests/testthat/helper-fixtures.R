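# shared fixtures: a minimal fork parameterization with round numbers, and
# convenience constructors used across test files

unitForkParams <- function(ins = 1, ext = 0.05, rescue = 1,
                           wt_delta = 0.5, wt_epsilon = 1, mmr = 0,
                           background = 0, exempt = character()) {
  keys <- c("T/C", "A/G", "C/T", "G/A", "A/C", "T/G", "G/T", "C/A",
            "G/G", "C/C", "A/A", "T/T", "A/oxoG")
  new("ForkModelParams",
      insProb = setNames(rep(ins, length(keys)), keys),
      extProb = setNames(rep(ext, length(keys)), keys),
      exoEscape = 0, rescueProb = rescue,
      wtDeltaFraction = wt_delta, wtEpsilonFraction = wt_epsilon,
      mmrEfficiency = mmr, backgroundRate = background,
      oxoGExempt = exempt, maxReengagement = 1000)
}

# closed-form survival of an engaged 3' mispair (independent re-derivation
# of the geometric series used by the package, kept here as the oracle)
oracleSurvive <- function(e, w, r) {
  absorb <- w * r
  if (absorb == 0) return(1)
  p_loop <- (1 - absorb) * e / (1 - (1 - absorb) * (1 - e))
  e + (1 - e) * p_loop
}

delta_het <- function(allele = "G148T", orientation = "R")
  StrainGenotype(allele, orientation, pol3 = "het")
delta_hom <- function(allele = "G148T", orientation = "R")
  StrainGenotype(allele, orientation, pol3 = "hom")
eps_het <- function(allele = "G148T", orientation = "F")
  StrainGenotype(allele, orientation, pol2 = "het")
eps_hom <- function(allele = "G148T", orientation = "F")
  StrainGenotype(allele, orientation, pol2 = "hom")

rateEstimateFromInterval <- function(mu, lo, hi, level = 0.83,
                                     genotype = delta_het(), id = "x") {
  ci <- list(c(lo, hi))
  names(ci) <- format(level, digits = 12, trim = TRUE)
  new("RateEstimate", experimentId = id, genotype = genotype,
      mHat = mu * 1e8, cellsPlated = 1e8, muHat = mu, ci = ci,
      logLikAtMLE = 0)
}
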