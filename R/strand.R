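## Strand and mispair inference for the trp5 reversion reporter.
##
## Each reporter allele reverts to wild type through a single base-pair
## substitution, so only two template/primer mispairs — one per replication
## strand — can produce a revertant. Knowing the reporter orientation
## relative to the replication origin and which polymerase is proofreading
## deficient pins down the mispair: Pol epsilon replicates the leading
## strand and Pol delta the lagging strand.

## "top strand" = the reporter coding strand carrying the named allele base
## (e.g. the T of G148T). In the F orientation the leading-strand polymerase
## uses the top strand as template (nascent strand is the bottom); in R the
## roles swap. This constant is fixed by the published 16-row
## template/primer assignment table.
.mutantTopBase <- function(allele) substr(allele, 5, 5)
.wildtypeTopBase <- function(allele) substr(allele, 1, 1)

.checkAllele <- function(allele) {
  if (length(allele) != 1L || !allele %in% .ALLELES)
    stop("unknown allele '", allele, "'; expected one of ",
         paste(.ALLELES, collapse = ", "), call. = FALSE)
  invisible(allele)
}

#' Base-pair change required for reversion
#'
#' Each reporter allele can revert only through one base-pair substitution.
#' The change is reported in top-strand convention: mutant top-strand base
#' pair -> wild-type top-strand base pair.
#'
#' @param allele reporter allele, e.g. "G148T".
#' @return character(1) such as \code{"TA->GC"}.
#' @examples
#' reversionMutation("G148T")  # "TA->GC"
#' @export
reversionMutation <- function(allele) {
  .checkAllele(allele)
  mt <- .mutantTopBase(allele)
  wt <- .wildtypeTopBase(allele)
  sprintf("%s%s->%s%s", mt, .COMPLEMENT[[mt]], wt, .COMPLEMENT[[wt]])
}

#' Candidate mispairs for a reporter allele
#'
#' The two strand-specific (template, primer) mispairs that can produce the
#' reversion: one with the nascent strand on top (template = complement of
#' the mutant top base, primer = wild-type top base), one with the nascent
#' strand on the bottom (template = mutant top base, primer = complement of
#' the wild-type top base). The two are reverse-complement images of each
#' other.
#'
#' @param allele reporter allele.
#' @return data.frame with columns \code{nascent} ("top"/"bottom"),
#'   \code{template}, \code{primer}.
#' @examples
#' candidateMispairs("G148T")  # A/G (nascent top) and T/C (nascent bottom)
#' @export
candidateMispairs <- function(allele) {
  .checkAllele(allele)
  mt <- .mutantTopBase(allele)
  wt <- .wildtypeTopBase(allele)
  data.frame(
    nascent = c("top", "bottom"),
    template = c(.COMPLEMENT[[mt]], mt),
    primer = c(wt, .COMPLEMENT[[wt]]),
    stringsAsFactors = FALSE
  )
}

#' Assign the mispair responsible for reversion in a strain
#'
#' Reversion in a proofreading-deficient strain is attributed to the
#' mismatch created on the strand replicated by the mutant polymerase. In
#' the F orientation the leading-strand polymerase (Pol epsilon) copies the
#' top strand as template, so its errors are nascent-bottom mispairs, and
#' the lagging-strand polymerase (Pol delta) makes nascent-top mispairs;
#' in the R orientation the two swap.
#'
#' @param genotype a \linkS4class{StrainGenotype} with exactly one of
#'   \code{pol2}/\code{pol3} non-wild-type.
#' @return A \linkS4class{MispairAssignment}. Identical-base alleles
#'   (G148C, A149T) are flagged \code{extrapolated}: the generic rule
#'   applies but the assignment is not part of the published comparisons.
#' @examples
#' assignMispair(StrainGenotype("G148T", "F", pol2 = "hom"))  # T/C, leading
#' @export
assignMispair <- function(genotype) {
  stopifnot(is(genotype, "StrainGenotype"))
  pol2mut <- genotype@pol2 != "wt"
  pol3mut <- genotype@pol3 != "wt"
  if (pol2mut == pol3mut)
    stop("mispair assignment needs exactly one proofreading-mutant ",
         "polymerase; this genotype has ",
         if (pol2mut) "both pol2 and pol3 mutant" else "neither",
         call. = FALSE)
  polymerase <- if (pol2mut) "epsilon" else "delta"
  strand <- if (pol2mut) "leading" else "lagging"
  cand <- candidateMispairs(genotype@allele)
  ## leading-strand template is the top strand in F, bottom strand in R
  leadingNascent <- if (genotype@orientation == "F") "bottom" else "top"
  nascent <- if (strand == "leading") leadingNascent else
    setdiff(c("top", "bottom"), leadingNascent)
  row <- cand[cand$nascent == nascent, ]
  new("MispairAssignment",
      polymerase = polymerase, strand = strand,
      templateBase = row$template, primerBase = row$primer,
      extrapolated = genotype@allele %in% c("G148C", "A149T"))
}

#' Mispair key string
#'
#' Canonical "template/primer" key used to index the fork-model probability
#' maps.
#'
#' @param x a \linkS4class{MispairAssignment}, or a template base when
#'   \code{primer} is given.
#' @param primer primer base (optional second calling form).
#' @return character(1), e.g. \code{"T/C"}.
#' @export
mispairKey <- function(x, primer) {
  if (is(x, "MispairAssignment"))
    sprintf("%s/%s", x@templateBase, x@primerBase)
  else
    sprintf("%s/%s", x, primer)
}

#' Genotype pairs sharing the same mispair across polymerases
#'
#' Pairs each Pol epsilon-mutant genotype with the Pol delta-mutant
#' genotype of the opposite orientation whose assigned mispair is
#' identical, so rates attributable to the same mismatch can be compared
#' across the two polymerases.
#'
#' @param alleles reporter alleles to pair (default: the four
#'   non-identical-base alleles, which give 8 pairings).
#' @param orientations orientations to consider for the Pol epsilon member.
#' @return data.frame with columns \code{allele}, \code{template},
#'   \code{primer}, \code{pol2_orientation}, \code{pol3_orientation}.
#' @export
equivalentMispairPairs <- function(alleles = c("G148T", "A149C", "G148A", "A149G"),
                                   orientations = c("F", "R")) {
  rows <- lapply(alleles, function(al) {
    do.call(rbind, lapply(orientations, function(o) {
      e <- assignMispair(StrainGenotype(al, o, pol2 = "het"))
      oppo <- setdiff(c("F", "R"), o)
      d <- assignMispair(StrainGenotype(al, oppo, pol3 = "het"))
      stopifnot(mispairKey(e) == mispairKey(d))
      data.frame(allele = al, template = e@templateBase,
                 primer = e@primerBase, pol2_orientation = o,
                 pol3_orientation = oppo, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Full strand-assignment table
#'
#' Enumerates the mispair assignment for every (allele, orientation,
#' mutant polymerase) combination; exportable as TSV.
#'
#' @param alleles alleles to include (default all six).
#' @param file optional path; when given the table is written as
#'   tab-separated text.
#' @return data.frame with columns allele, orientation, polymerase, strand,
#'   template, primer, extrapolated.
#' @export
assignmentTable <- function(alleles = .ALLELES, file = NULL) {
  grid <- expand.grid(allele = alleles, orientation = c("F", "R"),
                      polymerase = c("epsilon", "delta"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- StrainGenotype(grid$allele[i], grid$orientation[i],
                        pol2 = if (grid$polymerase[i] == "epsilon") "hom" else "wt",
                        pol3 = if (grid$polymerase[i] == "delta") "hom" else "wt")
    a <- assignMispair(g)
    data.frame(allele = grid$allele[i], orientation = grid$orientation[i],
               polymerase = a@polymerase, strand = a@strand,
               template = a@templateBase, primer = a@primerBase,
               extrapolated = a@extrapolated, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file))
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
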