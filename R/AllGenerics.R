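#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes; prefer these over
#' direct slot access.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotype", function(object) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("cultureCounts", function(object) standardGeneric("cultureCounts"))
#' @rdname accessors
#' @export
setGeneric("cellsPlated", function(object) standardGeneric("cellsPlated"))
#' @rdname accessors
#' @export
setGeneric("mHat", function(object) standardGeneric("mHat"))
#' @rdname accessors
#' @export
setGeneric("muHat", function(object) standardGeneric("muHat"))

#' Confidence interval accessor
#'
#' @param object a \linkS4class{RateEstimate}.
#' @param level coverage level, e.g. 0.95.
#' @return numeric(2): lower and upper endpoints on the per-cell rate scale.
#' @export
setGeneric("confInt", function(object, level) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setMethod("genotype", "FluctuationExperiment", function(object) object@genotype)
#' @rdname accessors
#' @export
setMethod("genotype", "RateEstimate", function(object) object@genotype)
#' @rdname accessors
#' @export
setMethod("cultureCounts", "FluctuationExperiment", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("cellsPlated", "FluctuationExperiment", function(object) object@cellsPlated)
#' @rdname accessors
#' @export
setMethod("cellsPlated", "RateEstimate", function(object) object@cellsPlated)
#' @rdname accessors
#' @export
setMethod("mHat", "RateEstimate", function(object) object@mHat)
#' @rdname accessors
#' @export
setMethod("muHat", "RateEstimate", function(object) object@muHat)

#' @rdname confInt
#' @export
setMethod("confInt", "RateEstimate", function(object, level) {
  key <- .levelKey(level)
  if (!key %in% names(object@ci))
    stop("no interval stored at level ", level,
         "; recompute with profileCI()/estimateRate(levels = ...)", call. = FALSE)
  object@ci[[key]]
})

.levelKey <- function(level) format(level, digits = 12, trim = TRUE)

## compact genotype label used in tables and output files
.genotypeLabel <- function(g) {
  bits <- c(g@allele, g@orientation,
            if (g@msh6 == "del") "msh6",
            if (g@pol2 != "wt") paste0("pol2-4", if (g@pol2 == "het") "+/-"),
            if (g@pol3 != "wt") paste0("pol3-5DV", if (g@pol3 == "het") "+/-"))
  paste(bits, collapse = " ")
}

setMethod("show", "StrainGenotype", function(object) {
  cat("StrainGenotype:", .genotypeLabel(object), "\n")
})

setMethod("show", "MispairAssignment", function(object) {
  cat(sprintf("MispairAssignment: %s/%s (template/primer) on the %s strand (Pol %s)%s\n",
              object@templateBase, object@primerBase, object@strand,
              object@polymerase,
              if (object@extrapolated) " [extrapolated]" else ""))
})

setMethod("show", "FluctuationExperiment", function(object) {
  cat(sprintf("FluctuationExperiment '%s': %d cultures, %.3g cells plated\n",
              object@experimentId, length(object@counts), object@cellsPlated))
  cat("  genotype:", .genotypeLabel(object@genotype), "\n")
  cat("  counts:", paste(utils::head(object@counts, 12), collapse = " "),
      if (length(object@counts) > 12) "...", "\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate '%s' (%s)\n", object@experimentId,
              .genotypeLabel(object@genotype)))
  cat(sprintf("  m = %.4g mutations/culture, mu = %.4g per cell\n",
              object@mHat, object@muHat))
  for (lev in names(object@ci)) {
    int <- object@ci[[lev]]
    cat(sprintf("  %s%% CI: [%.4g, %.4g]\n",
                format(100 * as.numeric(lev)), int[1], int[2]))
  }
})

setMethod("show", "ForkModelParams", function(object) {
  cat("ForkModelParams\n")
  cat("  mispairs:", paste(names(object@insProb), collapse = " "), "\n")
  cat(sprintf("  wt fractions: delta %.2g, epsilon %.2g; rescue %.2g; MMR %.2g\n",
              object@wtDeltaFraction, object@wtEpsilonFraction,
              object@rescueProb, object@mmrEfficiency))
  if (length(object@oxoGExempt))
    cat("  proofreading-exempt:", paste(object@oxoGExempt, collapse = " "), "\n")
})
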