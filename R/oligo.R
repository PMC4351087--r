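## Oligonucleotide transformation analysis. Test oligos create the
## reversion mispair at their 3' terminus; transformation requires that the
## terminal mispair is extended rather than proofread. Each replicate is
## normalized to an internal-control oligo carrying a central mismatch
## (immune to proofreading), giving a relative transformation ratio.

#' Relative transformation of a 3'-mismatch oligo
#'
#' Per-replicate ratio of test to control colonies, summarized as mean and
#' SD. Replicates with zero control colonies have no defined ratio: they
#' are excluded and reported in the \code{excluded} field.
#'
#' @param replicates two-column matrix or data.frame: test colonies,
#'   control colonies (one row per replicate).
#' @return list with \code{mean}, \code{sd}, \code{n}, \code{ratios},
#'   \code{excluded} (number of zero-control replicates dropped) and
#'   \code{rendered} (see \code{\link{renderRelative}}).
#' @examples
#' relativeTransformation(rbind(c(50, 50), c(40, 60)))
#' @export
relativeTransformation <- function(replicates) {
  replicates <- as.matrix(replicates)
  stopifnot(ncol(replicates) == 2L, nrow(replicates) >= 1L,
            all(replicates >= 0))
  ok <- replicates[, 2] > 0
  if (!any(ok))
    stop("no replicate has control colonies > 0; ratios undefined",
         call. = FALSE)
  if (any(!ok))
    message(sum(!ok), " replicate(s) with zero control colonies excluded")
  ratios <- replicates[ok, 1] / replicates[ok, 2]
  m <- mean(ratios)
  list(mean = m,
       sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
       n = sum(ok), ratios = unname(ratios), excluded = sum(!ok),
       rendered = renderRelative(m))
}

#' Render a relative-transformation value
#'
#' Three-way rendering convention: a true zero (no revertants at all)
#' prints \code{"0"}; a positive mean below 0.005 prints \code{"0.00"}
#' (revertants seen, but fewer than 1/100 of the control); anything else
#' prints with two decimals.
#'
#' @param x mean relative transformation (>= 0).
#' @return character(1).
#' @export
renderRelative <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x >= 0)
  if (x == 0) "0"
  else if (x < 0.005) "0.00"
  else formatC(x, format = "f", digits = 2)
}

#' Parse a rendered relative-transformation value
#'
#' Inverse of \code{\link{renderRelative}} up to the three-way distinction
#' it encodes: \code{"0"} -> exact zero, \code{"0.00"} -> positive but
#' below 1/100, otherwise the printed number.
#'
#' @param s rendered string.
#' @return list with \code{kind} ("zero", "below_0.01" or "value") and
#'   \code{value} (NA for "below_0.01").
#' @export
parseRelative <- function(s) {
  if (s == "0") list(kind = "zero", value = 0)
  else if (s == "0.00") list(kind = "below_0.01", value = NA_real_)
  else list(kind = "value", value = as.numeric(s))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two samples of relative-transformation ratios.
#' When the pooled sample has at most 20 observations and no ties, the
#' p-value is exact: all \code{choose(n, n_a)} assignments of ranks to the
#' first sample are enumerated and the fraction whose U statistic deviates
#' from its null mean at least as much as the observed one is reported.
#' Larger or tied samples use midranks with the normal approximation and
#' tie correction.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with \code{u_statistic}, \code{p_value}, \code{method}
#'   ("exact" or "normal-approximation"), \code{n_a}, \code{n_b}.
#' @examples
#' mannWhitney(c(4, 5, 6), c(1, 2, 3))  # exact p = 2/choose(6,3) = 0.1
#' @export
mannWhitney <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  ranks <- rank(pooled)
  U <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  noTies <- !anyDuplicated(pooled)
  if (n <= 20 && noTies) {
    ## exact: enumerate every split of the n ranks into the two samples
    splits <- combn(n, na)
    rankSums <- colSums(matrix(seq_len(n)[splits], nrow = na))
    Us <- rankSums - na * (na + 1) / 2
    dev <- abs(Us - na * nb / 2)
    p <- mean(dev >= abs(U - na * nb / 2) - 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * (1 - pnorm(abs(z))))
    }
    method <- "normal-approximation"
  }
  list(u_statistic = U, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Predicted relative transformation under the fork model
#'
#' An oligo's 3' mispair mimics an exposed primer terminus: its fate is the
#' extension/dissociation/rescue chain followed by mismatch repair, so the
#' predicted relative transformation is proportional to
#' \code{P_survive * (1 - mmrEfficiency)} for the genotype. Predictions are
#' returned jointly for a genotype panel because only relative values are
#' interpretable (the overall scale absorbs annealing efficiency and the
#' per-strand preference).
#'
#' @param params \linkS4class{ForkModelParams}.
#' @param genotypes list of \linkS4class{StrainGenotype} forming the panel.
#' @param mispair_key "template/primer" key of the oligo's terminal
#'   mispair, e.g. \code{"T/C"} or the proofreading-exempt \code{"A/oxoG"}.
#' @return named numeric vector of predictions (shared arbitrary scale),
#'   one per genotype.
#' @export
predictOligoOutcome <- function(params, genotypes, mispair_key) {
  stopifnot(is(params, "ForkModelParams"))
  if (!(mispair_key %in% names(params@extProb) ||
        mispair_key %in% params@oxoGExempt))
    stop("mispair key '", mispair_key, "' missing from extProb and not ",
         "proofreading-exempt", call. = FALSE)
  out <- vapply(genotypes, function(g) {
    p <- applyGenotype(params, g)
    .surviveProbability(p, mispair_key) * (1 - p@mmrEfficiency)
  }, 0)
  names(out) <- vapply(genotypes, .genotypeLabel, "")
  out
}

#' Read an oligo-assay TSV
#'
#' Expected columns: allele, orientation, msh6, pol2, pol3, oligo_id,
#' replicate, test_colonies, control_colonies.
#'
#' @param file path.
#' @return data.frame of replicates with a genotype label column attached.
#' @export
readOligoTSV <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("allele", "orientation", "msh6", "pol2", "pol3", "oligo_id",
            "replicate", "test_colonies", "control_colonies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("oligo TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$genotype <- vapply(seq_len(nrow(df)), function(i)
    .genotypeLabel(StrainGenotype(df$allele[i], df$orientation[i],
                                  msh6 = df$msh6[i], pol2 = df$pol2[i],
                                  pol3 = df$pol3[i])), "")
  df
}

#' Read oligo definitions from FASTA
#'
#' Oligo FASTA records carry a \code{3prime=} tag in the description naming
#' the 3'-terminal (mispairing) base — \code{oxoG} for the oxidized-G
#' oligo — and an optional \code{strand=} tag (leading/lagging). Only the
#' terminal base, the tag and the target strand are consumed; the rest of
#' the 40-mer is annealing sequence.
#'
#' @param file FASTA path.
#' @return data.frame with oligo_id, sequence, prime3 (tag value, falling
#'   back to the sequence's last base), strand.
#' @export
readOligoFasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  if (!length(set)) stop("no FASTA records in ", file, call. = FALSE)
  rows <- lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    seq <- as.character(set[[i]])
    id <- strsplit(desc, "\\s+")[[1]][1]
    tag <- regmatches(desc, regexpr("3prime=\\S+", desc))
    prime3 <- if (length(tag)) sub("3prime=", "", tag) else substr(seq, nchar(seq), nchar(seq))
    stag <- regmatches(desc, regexpr("strand=\\S+", desc))
    strand <- if (length(stag)) sub("strand=", "", stag) else NA_character_
    data.frame(oligo_id = id, sequence = seq, prime3 = prime3,
               strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
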