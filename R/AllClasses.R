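#' @import methods
#' @importFrom stats optimize qchisq qnorm pnorm rpois rbinom runif median setNames
#' @importFrom utils combn write.table read.delim packageVersion
#' @importFrom Biostrings readDNAStringSet
#' @useDynLib fluctproof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## reporter alleles assayed by the reversion system; each reverts via a
## single base-pair substitution
.ALLELES <- c("G148T", "A149C", "G148A", "A149G", "G148C", "A149T")
.ZYGOSITY <- c("wt", "het", "hom")
.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' StrainGenotype: diploid strain description
#'
#' Captures the parts of a strain's genotype that determine its expected
#' reversion behaviour: which \code{trp5} reporter allele it carries, the
#' orientation of the reporter relative to the replication origin, whether
#' MutSalpha-dependent mismatch repair is intact (\code{msh6}), and the
#' zygosity of the proofreading-dead alleles of Pol epsilon (\code{pol2})
#' and Pol delta (\code{pol3}).
#'
#' @slot allele character(1), one of \code{G148T, A149C, G148A, A149G,
#'   G148C, A149T}.
#' @slot orientation character(1), \code{"F"} or \code{"R"}: reporter
#'   orientation relative to the replication origin; swapping it swaps
#'   which sequence strand is replicated as leading vs lagging.
#' @slot msh6 character(1), \code{"wt"} or \code{"del"}.
#' @slot pol2 character(1), zygosity of the Pol epsilon exonuclease-dead
#'   allele: \code{"wt"}, \code{"het"} or \code{"hom"}.
#' @slot pol3 character(1), zygosity of the Pol delta exonuclease-dead
#'   allele, same encoding.
#' @export
setClass("StrainGenotype",
  representation(
    allele = "character",
    orientation = "character",
    msh6 = "character",
    pol2 = "character",
    pol3 = "character"
  ),
  prototype(msh6 = "del", pol2 = "wt", pol3 = "wt")
)

setValidity("StrainGenotype", function(object) {
  msg <- character()
  if (length(object@allele) != 1L || !object@allele %in% .ALLELES)
    msg <- c(msg, sprintf("allele must be one of: %s",
                          paste(.ALLELES, collapse = ", ")))
  if (length(object@orientation) != 1L || !object@orientation %in% c("F", "R"))
    msg <- c(msg, "orientation must be 'F' or 'R'")
  if (!object@msh6 %in% c("wt", "del"))
    msg <- c(msg, "msh6 must be 'wt' or 'del'")
  if (!object@pol2 %in% .ZYGOSITY || !object@pol3 %in% .ZYGOSITY)
    msg <- c(msg, "pol2/pol3 must be 'wt', 'het' or 'hom'")
  if (length(msg)) msg else TRUE
})

#' Construct a StrainGenotype
#'
#' @param allele trp5 reporter allele.
#' @param orientation "F" or "R".
#' @param msh6 "wt" or "del" (default "del": the assay is run without
#'   MutSalpha so proofreading errors are visible).
#' @param pol2,pol3 zygosity of the proofreading-dead polymerase alleles.
#' @return A \linkS4class{StrainGenotype}.
#' @examples
#' StrainGenotype("G148T", "F", pol2 = "hom")
#' @export
StrainGenotype <- function(allele, orientation, msh6 = "del",
                           pol2 = "wt", pol3 = "wt") {
  new("StrainGenotype", allele = allele, orientation = orientation,
      msh6 = msh6, pol2 = pol2, pol3 = pol3)
}

#' MispairAssignment: the mispair behind a reversion event
#'
#' The (template base, primer base) combination, replicating polymerase and
#' strand inferred to be responsible for reversion in a proofreading-
#' deficient strain. The assay's standing assumption ties polymerase to
#' strand: Pol epsilon replicates the leading strand, Pol delta the lagging
#' strand.
#'
#' @slot polymerase "delta" or "epsilon".
#' @slot strand "leading" or "lagging".
#' @slot templateBase single base on the template strand.
#' @slot primerBase single base inserted on the nascent (primer) strand;
#'   "oxoG" is allowed for the 8-oxoG oligo model.
#' @slot extrapolated logical(1); TRUE for identical-base alleles whose
#'   assignment follows the generic rule but is not printed in the source
#'   comparisons.
#' @export
setClass("MispairAssignment",
  representation(
    polymerase = "character",
    strand = "character",
    templateBase = "character",
    primerBase = "character",
    extrapolated = "logical"
  ),
  prototype(extrapolated = FALSE)
)

setValidity("MispairAssignment", function(object) {
  msg <- character()
  if (!object@polymerase %in% c("delta", "epsilon"))
    msg <- c(msg, "polymerase must be 'delta' or 'epsilon'")
  if (!object@strand %in% c("leading", "lagging"))
    msg <- c(msg, "strand must be 'leading' or 'lagging'")
  ok <- (object@polymerase == "epsilon") == (object@strand == "leading")
  if (!ok)
    msg <- c(msg, "polymerase/strand mismatch: epsilon<->leading, delta<->lagging")
  if (!object@templateBase %in% names(.COMPLEMENT))
    msg <- c(msg, "templateBase must be A, C, G or T")
  if (!object@primerBase %in% c(names(.COMPLEMENT), "oxoG"))
    msg <- c(msg, "primerBase must be A, C, G, T or oxoG")
  if (length(msg)) msg else TRUE
})

#' ForkModelParams: mechanistic replication-fork error model parameters
#'
#' Parameterizes the insertion -> (extend | dissociate -> rescue or
#' re-engage) -> mismatch repair chain that converts a polymerase
#' misinsertion into a fixed reversion. Probabilities are per replication
#' of the assayed site.
#'
#' @slot insProb named numeric: probability that a proofreading-deficient
#'   polymerase inserts the given mispair (names are "template/primer"
#'   keys such as "T/C").
#' @slot exoEscape probability a proofreading-proficient polymerase fails
#'   to excise its own misinsertion (default 0).
#' @slot extProb named numeric: probability the engaged polymerase extends
#'   the 3' mispair before dissociating.
#' @slot rescueProb probability a wild-type Pol delta engaging an exposed
#'   3' mispair excises it (default 1).
#' @slot wtDeltaFraction fraction of the Pol delta pool that is
#'   proofreading proficient (1, 0.5 or 0 for the assayed genotypes).
#' @slot wtEpsilonFraction analogous fraction for the Pol epsilon pool.
#' @slot mmrEfficiency probability mismatch repair removes a surviving
#'   mismatch (0 for msh6 strains).
#' @slot backgroundRate genotype-independent reversion probability per
#'   cell division (damage-driven floor).
#' @slot oxoGExempt character vector of mispair keys invisible to
#'   proofreading (extension certain, rescue never), e.g. "A/oxoG".
#' @slot maxReengagement iteration cap on the dissociation/re-engagement
#'   loop in the Monte-Carlo simulator.
#' @export
setClass("ForkModelParams",
  representation(
    insProb = "numeric",
    exoEscape = "numeric",
    extProb = "numeric",
    rescueProb = "numeric",
    wtDeltaFraction = "numeric",
    wtEpsilonFraction = "numeric",
    mmrEfficiency = "numeric",
    backgroundRate = "numeric",
    oxoGExempt = "character",
    maxReengagement = "numeric"
  ),
  prototype(exoEscape = 0, rescueProb = 1, wtDeltaFraction = 1,
            wtEpsilonFraction = 1, mmrEfficiency = 0,
            backgroundRate = 1e-10, oxoGExempt = character(),
            maxReengagement = 1000)
)

setValidity("ForkModelParams", function(object) {
  msg <- character()
  p01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (is.null(names(object@insProb)) || !p01(object@insProb))
    msg <- c(msg, "insProb must be a named vector of probabilities in [0,1]")
  if (is.null(names(object@extProb)) || !p01(object@extProb))
    msg <- c(msg, "extProb must be a named vector of probabilities in [0,1]")
  for (s in c("exoEscape", "rescueProb", "wtDeltaFraction",
              "wtEpsilonFraction", "mmrEfficiency", "backgroundRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !p01(v)) msg <- c(msg, sprintf("%s must be a single probability in [0,1]", s))
  }
  if (length(object@maxReengagement) != 1L || object@maxReengagement < 1)
    msg <- c(msg, "maxReengagement must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FluctuationExperiment: one strain x one fluctuation experiment
#'
#' Per-culture revertant colony counts from parallel cultures of a single
#' strain, plus the number of viable cells plated per culture. This is the
#' raw input of Luria-Delbruck rate estimation.
#'
#' @slot experimentId character(1) identifier.
#' @slot genotype the \linkS4class{StrainGenotype} of the strain.
#' @slot counts integer vector of revertant colonies, one per culture.
#' @slot cellsPlated cells at plating (shared by the cultures).
#' @slot platedFraction fraction of each culture plated (1 = full
#'   plating, which the estimator assumes).
#' @export
setClass("FluctuationExperiment",
  representation(
    experimentId = "character",
    genotype = "StrainGenotype",
    counts = "integer",
    cellsPlated = "numeric",
    platedFraction = "numeric"
  ),
  prototype(platedFraction = 1)
)

setValidity("FluctuationExperiment", function(object) {
  msg <- character()
  if (length(object@counts) < 1L || anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "counts must be a non-empty vector of non-negative integers")
  if (length(object@cellsPlated) != 1L || object@cellsPlated < max(1, object@counts))
    msg <- c(msg, "cellsPlated must be a single value >= max(counts)")
  if (length(object@platedFraction) != 1L ||
      object@platedFraction <= 0 || object@platedFraction > 1)
    msg <- c(msg, "platedFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FluctuationExperiment
#'
#' @param experimentId identifier string.
#' @param genotype a \linkS4class{StrainGenotype}.
#' @param counts integer revertant colony counts, one per culture.
#' @param cellsPlated viable cells at plating.
#' @param platedFraction fraction of each culture plated.
#' @return A \linkS4class{FluctuationExperiment}.
#' @export
FluctuationExperiment <- function(experimentId, genotype, counts,
                                  cellsPlated, platedFraction = 1) {
  new("FluctuationExperiment", experimentId = experimentId,
      genotype = genotype, counts = as.integer(counts),
      cellsPlated = as.numeric(cellsPlated),
      platedFraction = platedFraction)
}

#' RateEstimate: fitted mutation rate with confidence intervals
#'
#' @slot experimentId identifier of the experiment the estimate came from.
#' @slot genotype the strain's \linkS4class{StrainGenotype}.
#' @slot mHat maximum-likelihood mutations per culture (m).
#' @slot cellsPlated cells at plating used to convert m to a per-cell rate.
#' @slot muHat per-cell rate, \code{mHat / cellsPlated}.
#' @slot ci named list: coverage level (e.g. "0.95") -> c(lower, upper) on
#'   the mu scale.
#' @slot logLikAtMLE log-likelihood at the MLE.
#' @export
setClass("RateEstimate",
  representation(
    experimentId = "character",
    genotype = "StrainGenotype",
    mHat = "numeric",
    cellsPlated = "numeric",
    muHat = "numeric",
    ci = "list",
    logLikAtMLE = "numeric"
  )
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (length(object@mHat) != 1L || object@mHat < 0)
    msg <- c(msg, "mHat must be a single value >= 0")
  for (lev in names(object@ci)) {
    int <- object@ci[[lev]]
    if (length(int) != 2L || int[1] > object@muHat + 1e-12 ||
        int[2] < object@muHat - 1e-12)
      msg <- c(msg, sprintf("interval at level %s must bracket muHat", lev))
  }
  if (length(msg)) msg else TRUE
})
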