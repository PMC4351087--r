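## Luria-Delbruck maximum-likelihood rate estimation.
##
## The number of revertant colonies in a culture follows the Lea-Coulson
## form of the Luria-Delbruck distribution with a single parameter m, the
## expected number of mutation events per culture. The per-cell rate is
## mu = m / N with N the cells at plating. Confidence intervals invert the
## likelihood-ratio statistic against the chi-square(1) quantile.

.JACKPOT_LIMIT <- 1e5   # counts above this draw a jackpot warning
.CENSOR_CAP <- 5000     # counts above this enter the likelihood as a tail mass

#' Luria-Delbruck mutant-count probabilities
#'
#' Probability mass function of the number of mutant colonies per culture
#' under the Lea-Coulson model, computed by the Ma-Sandri-Sarkar recursion
#' \eqn{p_0 = e^{-m}}, \eqn{p_n = (m/n) \sum_{i=0}^{n-1} p_i/(n-i+1)}.
#'
#' @param m expected mutation events per culture (>= 0).
#' @param n_max largest count to evaluate.
#' @return numeric vector of \code{p_0 .. p_{n_max}}; partial sums are < 1
#'   (the distribution is heavy-tailed).
#' @examples
#' ldPmf(1, 2)  # exp(-1), exp(-1)/2, ...
#' @export
ldPmf <- function(m, n_max) {
  if (length(m) != 1L || is.na(m) || m < 0) stop("m must be a single value >= 0")
  .ld_pmf_cpp(as.numeric(m), as.integer(n_max))
}

## log-likelihood of counts at m, censoring counts > cap into the tail
.ldLogLik <- function(counts, m, cap = .CENSOR_CAP) {
  if (m == 0) return(if (any(counts > 0)) -Inf else 0)
  big <- counts > cap
  nmax <- if (any(!big)) max(counts[!big]) else 0L
  p <- ldPmf(m, nmax)
  ll <- sum(log(pmax(p[counts[!big] + 1L], 1e-300)))
  if (any(big)) {
    tail <- max(1 - sum(p), 1e-300)
    ll <- ll + sum(big) * log(tail)
  }
  ll
}

.checkCounts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || anyNA(counts) || any(counts < 0L))
    stop("counts must be non-empty, non-negative integers", call. = FALSE)
  if (any(counts > .JACKPOT_LIMIT))
    warning("counts above ", format(.JACKPOT_LIMIT, scientific = FALSE),
            " (jackpot cultures) enter the likelihood only as tail mass ",
            "above ", format(.CENSOR_CAP, scientific = FALSE), call. = FALSE)
  counts
}

#' Maximum-likelihood mutations per culture
#'
#' Maximizes the Luria-Delbruck log-likelihood over m on a log scale,
#' bracketed in [1e-8, 1e3]. All-zero counts give the boundary value 0.
#' The zero-fraction (p0) estimate \eqn{-\log f_0} is used to centre the
#' search bracket when some counts are zero.
#'
#' @param counts integer revertant counts, one per culture.
#' @return m_hat (>= 0).
#' @examples
#' estimateM(c(0L, 0L, 1L, 0L, 2L, 0L))
#' @export
estimateM <- function(counts) {
  counts <- .checkCounts(counts)
  if (all(counts == 0L)) return(0)
  f <- function(logm) .ldLogLik(counts, exp(logm))
  opt <- optimize(f, interval = log(c(1e-8, 1e3)), maximum = TRUE,
                  tol = 1e-6)
  exp(opt$maximum)
}

#' Profile-likelihood confidence interval for m
#'
#' Endpoints are the values of m where twice the log-likelihood drop from
#' the MLE equals the chi-square(1 df) quantile of the requested coverage,
#' located by bisection on each side (tolerance 1e-8 relative on m). When
#' m_hat = 0 the lower endpoint is 0 and only the upper endpoint is solved.
#'
#' @param counts the counts used to obtain \code{m_hat}.
#' @param m_hat MLE from \code{\link{estimateM}} on the same counts.
#' @param level coverage in (0, 1); 0.83 uses the chi-square quantile
#'   ~1.883, 0.95 uses 3.841.
#' @return numeric(2): lower and upper endpoints for m.
#' @export
profileCI <- function(counts, m_hat, level = 0.95) {
  if (length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  counts <- .checkCounts(counts)
  crit <- qchisq(level, df = 1)
  if (m_hat == 0) {
    ## ell(m) = -m * C for all-zero counts: closed-form upper endpoint
    upper <- crit / (2 * length(counts))
    return(c(0, upper))
  }
  llhat <- .ldLogLik(counts, m_hat)
  drop2 <- function(m) 2 * (llhat - .ldLogLik(counts, m)) - crit
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if ((drop2(mid) > 0) == (drop2(lo) > 0)) lo <- mid else hi <- mid
      if ((hi - lo) / hi < 1e-8) break
    }
    sqrt(lo * hi)
  }
  lo <- m_hat
  repeat {
    lo <- lo / 4
    if (lo < 1e-12 || drop2(lo) > 0) break
  }
  lower <- if (lo < 1e-12 && drop2(lo) <= 0) 0 else bisect(lo, m_hat)
  hi <- m_hat
  repeat {
    hi <- hi * 4
    if (drop2(hi) > 0 || hi > 1e8) break
  }
  upper <- bisect(m_hat, hi)
  c(lower, upper)
}

#' Convert mutations per culture to a per-cell rate
#'
#' @param m m value(s) or interval endpoints.
#' @param cells_plated cells at plating (>= 1).
#' @return \code{m / cells_plated}, preserving ordering.
#' @export
rateFromM <- function(m, cells_plated) {
  if (cells_plated < 1) stop("cells_plated must be >= 1", call. = FALSE)
  m / cells_plated
}

#' Estimate the mutation rate of one experiment
#'
#' Convenience wrapper: MLE of m, profile intervals at the requested
#' coverage levels, and conversion to the per-cell scale.
#'
#' @param experiment a \linkS4class{FluctuationExperiment}.
#' @param levels coverage levels for profile intervals (default 0.95 and
#'   0.83, the two levels used by the interval-overlap significance rules).
#' @return A \linkS4class{RateEstimate}.
#' @examples
#' g <- StrainGenotype("G148T", "F", pol3 = "hom")
#' fe <- FluctuationExperiment("ex1", g, c(0, 1, 0, 3, 0, 0, 2, 1), 2e8)
#' estimateRate(fe)
#' @export
estimateRate <- function(experiment, levels = c(0.95, 0.83)) {
  stopifnot(is(experiment, "FluctuationExperiment"))
  if (experiment@platedFraction < 1)
    warning("platedFraction < 1: estimation assumes full plating; ",
            "the estimate is biased downward", call. = FALSE)
  counts <- experiment@counts
  m_hat <- estimateM(counts)
  N <- experiment@cellsPlated
  ci <- lapply(levels, function(lv) rateFromM(profileCI(counts, m_hat, lv), N))
  names(ci) <- vapply(levels, .levelKey, "")
  new("RateEstimate", experimentId = experiment@experimentId,
      genotype = experiment@genotype, mHat = m_hat, cellsPlated = N,
      muHat = rateFromM(m_hat, N), ci = ci,
      logLikAtMLE = if (m_hat > 0) .ldLogLik(counts, m_hat) else 0)
}

#' Median aggregation of replicate experiments
#'
#' When several experiments were run for the same genotype the estimate
#' whose per-cell rate is the median is carried forward, together with its
#' own confidence intervals. For an even number of replicates the lower
#' median is used; exact ties are broken by experiment id.
#'
#' @param estimates list of \linkS4class{RateEstimate}, all for the same
#'   genotype.
#' @return the median \linkS4class{RateEstimate}.
#' @export
aggregateExperiments <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, is, TRUE, "RateEstimate")))
  labs <- vapply(estimates, function(e) .genotypeLabel(e@genotype), "")
  if (length(unique(labs)) != 1L)
    stop("estimates mix genotypes: ", paste(unique(labs), collapse = " | "),
         call. = FALSE)
  mus <- vapply(estimates, muHat, 0)
  ids <- vapply(estimates, function(e) e@experimentId, "")
  ord <- order(mus, ids)
  estimates[[ord[ceiling(length(mus) / 2)]]]  # lower median when even
}

#' Significance by confidence-interval overlap
#'
#' Two rates are called significantly different when their confidence
#' intervals at the given level are disjoint (touching endpoints count as
#' overlapping). Non-overlap of 95\% intervals corresponds to a two-sided
#' test at about alpha = 0.005, and non-overlap of 83\% intervals to about
#' alpha = 0.05, for independent estimates of comparable precision.
#'
#' @param a,b \linkS4class{RateEstimate} objects carrying intervals at
#'   \code{level}.
#' @param level coverage level of the intervals to compare (default 0.83).
#' @return list with \code{significant}, \code{level_used},
#'   \code{implied_alpha}.
#' @export
ciOverlapTest <- function(a, b, level = 0.83) {
  ia <- confInt(a, level)
  ib <- confInt(b, level)
  disjoint <- ia[2] < ib[1] || ib[2] < ia[1]
  list(significant = disjoint, level_used = level,
       implied_alpha = impliedAlpha(level))
}

#' Two-sided alpha implied by interval non-overlap
#'
#' For two independent Gaussian estimates with equal standard errors,
#' central intervals at coverage \code{level} are disjoint exactly when the
#' standardized difference exceeds \eqn{\sqrt{2} z_{(1+level)/2}}, so the
#' implied two-sided significance level is
#' \eqn{2(1 - \Phi(\sqrt{2} z_{(1+level)/2}))}: about 0.005 for 95\%
#' intervals and about 0.05 for 83\% intervals.
#'
#' @param level interval coverage in (0, 1).
#' @return implied two-sided alpha.
#' @examples
#' impliedAlpha(0.95)  # ~0.0056
#' impliedAlpha(0.83)  # ~0.052
#' @export
impliedAlpha <- function(level) {
  if (any(level <= 0 | level >= 1)) stop("level must be in (0,1)", call. = FALSE)
  z <- qnorm((1 + level) / 2)
  2 * (1 - pnorm(sqrt(2) * z))
}
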