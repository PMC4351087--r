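## Comparative proofreading inference: het/hom and cross-polymerase rate
## ratios, and the rescued fraction f implied by a het/hom ratio.
##
## If half the polymerase pool is proofreading dead and no wild-type
## molecule can correct its errors, a heterozygote should show half the
## homozygote's rate (ratio 2). A ratio R > 2 implies that a fraction
## f = 1 - 2/R of the mutant molecules' errors is excised by wild-type
## molecules before fixation.

#' Ratio of two reversion rates with a significance flag
#'
#' @param a,b \linkS4class{RateEstimate} objects (numerator, denominator).
#' @param level interval coverage used for the overlap significance rule
#'   (default 0.83, the level at which non-overlap corresponds to about
#'   alpha = 0.05).
#' @return list with \code{ratio} (NA with \code{defined = FALSE} when the
#'   denominator rate is 0), \code{significant}, \code{level_used},
#'   \code{implied_alpha}, and the two genotype labels.
#' @export
rateRatio <- function(a, b, level = 0.83) {
  defined <- muHat(b) > 0 && muHat(a) > 0
  ov <- ciOverlapTest(a, b, level)
  list(ratio = if (defined) muHat(a) / muHat(b) else NA_real_,
       defined = defined,
       significant = ov$significant,
       level_used = level, implied_alpha = ov$implied_alpha,
       numerator = .genotypeLabel(genotype(a)),
       denominator = .genotypeLabel(genotype(b)))
}

#' Rescued-error fraction from a hom/het rate ratio
#'
#' Formalizes the half-rate expectation: with ratio
#' \code{R = mu_hom / mu_het}, the fraction of mutant-polymerase errors
#' rescued by wild-type proofreading in the heterozygote is
#' \code{f = 1 - 2/R}. Ratios below 2 carry no rescue signal: f is
#' reported as 0 with \code{valid = FALSE}.
#'
#' @param hom,het \linkS4class{RateEstimate} for the homozygous and
#'   heterozygous proofreading-deficient strains of the same allele,
#'   orientation and polymerase.
#' @return list with \code{ratio}, \code{f}, \code{valid}.
#' @examples
#' # a 32-fold hom/het difference implies ~94% of errors are rescued
#' 1 - 2 / 32
#' @export
inferRescueFraction <- function(hom, het) {
  gh <- genotype(hom); gt <- genotype(het)
  same <- gh@allele == gt@allele && gh@orientation == gt@orientation &&
    gh@msh6 == gt@msh6
  polHom <- if (gh@pol2 == "hom") "epsilon" else if (gh@pol3 == "hom") "delta" else NA
  polHet <- if (gt@pol2 == "het") "epsilon" else if (gt@pol3 == "het") "delta" else NA
  if (!same || is.na(polHom) || is.na(polHet) || polHom != polHet)
    stop("inferRescueFraction needs hom and het strains of the same ",
         "allele/orientation/polymerase", call. = FALSE)
  if (muHat(het) <= 0)
    return(list(ratio = NA_real_, f = NA_real_, valid = FALSE))
  rescueFractionFromRatio(muHat(hom) / muHat(het))
}

#' Rescued fraction from a numeric ratio
#'
#' @param ratio hom/het rate ratio (> 0).
#' @return list with \code{ratio}, \code{f = max(0, 1 - 2/ratio)},
#'   \code{valid = ratio >= 2}.
#' @export
rescueFractionFromRatio <- function(ratio) {
  stopifnot(length(ratio) == 1L, is.finite(ratio), ratio > 0)
  list(ratio = ratio, f = max(0, 1 - 2 / ratio), valid = ratio >= 2)
}

.findEstimate <- function(rates, allele, orientation, pol2 = "wt", pol3 = "wt") {
  for (est in rates) {
    g <- genotype(est)
    if (g@allele == allele && g@orientation == orientation &&
        g@pol2 == pol2 && g@pol3 == pol3) return(est)
  }
  NULL
}

#' Build the het/hom and cross-polymerase comparison tables
#'
#' From a set of per-genotype (aggregated) rate estimates, assembles (1) a
#' het-vs-hom ratio table per allele/orientation/polymerase, with
#' significance by interval overlap (83\% intervals for the Pol epsilon
#' comparisons, whose two-fold differences are too small to separate at
#' 95\%; 95\% elsewhere), and (2) a cross-polymerase table comparing rates
#' attributable to the same mispair in Pol delta- versus Pol epsilon-mutant
#' strains of opposite orientation, at both het and hom zygosity, flagging
#' ratios whose intervals overlap as not significantly different from 1.
#' Missing genotypes yield NA cells, not errors.
#'
#' @param rates list of \linkS4class{RateEstimate}, one per genotype.
#' @param alleles alleles to tabulate.
#' @return list with data.frames \code{het_vs_hom} and
#'   \code{equivalent_mispairs}.
#' @export
buildComparisonTables <- function(rates,
                                  alleles = c("G148T", "A149C", "G148A", "A149G")) {
  hetHom <- list()
  for (al in alleles) for (o in c("F", "R")) for (pol in c("epsilon", "delta")) {
    lev <- if (pol == "epsilon") 0.83 else 0.95
    if (pol == "epsilon") {
      hom <- .findEstimate(rates, al, o, pol2 = "hom")
      het <- .findEstimate(rates, al, o, pol2 = "het")
    } else {
      hom <- .findEstimate(rates, al, o, pol3 = "hom")
      het <- .findEstimate(rates, al, o, pol3 = "het")
    }
    row <- data.frame(allele = al, orientation = o, polymerase = pol,
                      ratio = NA_real_, significant = NA, level_used = lev,
                      f = NA_real_, f_valid = NA, stringsAsFactors = FALSE)
    if (!is.null(hom) && !is.null(het) && muHat(het) > 0 && muHat(hom) > 0) {
      rr <- rateRatio(hom, het, level = lev)
      inf <- rescueFractionFromRatio(rr$ratio)
      row$ratio <- rr$ratio
      row$significant <- rr$significant
      row$f <- inf$f
      row$f_valid <- inf$valid
    }
    hetHom[[length(hetHom) + 1L]] <- row
  }
  hetHom <- do.call(rbind, hetHom)

  pairs <- equivalentMispairPairs(alleles)
  eq <- list()
  for (i in seq_len(nrow(pairs))) for (zyg in c("het", "hom")) {
    p <- pairs[i, ]
    e2 <- .findEstimate(rates, p$allele, p$pol2_orientation,
                        pol2 = zyg)
    e3 <- .findEstimate(rates, p$allele, p$pol3_orientation,
                        pol3 = zyg)
    row <- data.frame(allele = p$allele, template = p$template,
                      primer = p$primer, zygosity = zyg,
                      pol3_orientation = p$pol3_orientation,
                      pol2_orientation = p$pol2_orientation,
                      ratio = NA_real_, not_different_from_1 = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(e2) && !is.null(e3) && muHat(e2) > 0) {
      rr <- rateRatio(e3, e2, level = 0.95)
      row$ratio <- rr$ratio
      row$not_different_from_1 <- !rr$significant
    }
    eq[[length(eq) + 1L]] <- row
  }
  eq <- do.call(rbind, eq)
  list(het_vs_hom = hetHom, equivalent_mispairs = eq)
}

#' Render comparison tables as an aligned text report
#'
#' @param tables output of \code{\link{buildComparisonTables}}.
#' @return character vector of report lines.
#' @export
formatComparisonReport <- function(tables) {
  hh <- tables$het_vs_hom
  eq <- tables$equivalent_mispairs
  fmt <- function(x, d = 2) ifelse(is.na(x), "--", formatC(x, format = "f", digits = d))
  lines <- c("Het vs hom reversion-rate ratios (hom/het)",
             sprintf("%-7s %-3s %-8s %7s %5s %6s  %s",
                     "allele", "or", "pol", "ratio", "sig", "f", "note"))
  for (i in seq_len(nrow(hh))) {
    note <- if (!is.na(hh$significant[i]) && !hh$significant[i])
      sprintf("ns at %d%% CIs", round(100 * hh$level_used[i])) else ""
    lines <- c(lines, sprintf("%-7s %-3s %-8s %7s %5s %6s  %s",
                              hh$allele[i], hh$orientation[i], hh$polymerase[i],
                              fmt(hh$ratio[i], 1),
                              ifelse(is.na(hh$significant[i]), "--",
                                     ifelse(hh$significant[i], "*", "")),
                              fmt(hh$f[i], 3), note))
  }
  lines <- c(lines, "",
             "Equivalent-mispair ratios (Pol delta strain / Pol epsilon strain)",
             sprintf("%-7s %-4s %-4s %-4s %7s  %s",
                     "allele", "tmpl", "prim", "zyg", "ratio", "note"))
  for (i in seq_len(nrow(eq))) {
    note <- if (!is.na(eq$not_different_from_1[i]) && eq$not_different_from_1[i])
      "not significantly different from 1" else ""
    lines <- c(lines, sprintf("%-7s %-4s %-4s %-4s %7s  %s",
                              eq$allele[i], eq$template[i], eq$primer[i],
                              eq$zygosity[i], fmt(eq$ratio[i], 1), note))
  }
  lines
}
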