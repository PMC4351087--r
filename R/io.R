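## Tab-separated input/output. Every file written by the package carries a
## provenance header: comment lines with package version, seed and (where a
## config file is involved) its md5 checksum.

.provenanceHeader <- function(seed = NA, config = NULL) {
  h <- sprintf("# fluctproof %s", as.character(packageVersion("fluctproof")))
  if (!is.na(seed)) h <- c(h, sprintf("# seed: %s", format(seed)))
  if (!is.null(config) && file.exists(config))
    h <- c(h, sprintf("# config_md5: %s", unname(tools::md5sum(config))))
  h
}

.writeTsvWithHeader <- function(df, file, seed = NA, config = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write fluctuation experiments as a culture TSV
#'
#' One row per culture: experiment_id, allele, orientation, msh6, pol2,
#' pol3, culture_id, revertant_colonies, cells_plated.
#'
#' @param experiments list of \linkS4class{FluctuationExperiment}.
#' @param file output path.
#' @param seed seed recorded in the provenance header.
#' @return the path, invisibly.
#' @export
writeCultureTSV <- function(experiments, file, seed = NA) {
  rows <- lapply(experiments, function(fe) {
    g <- fe@genotype
    data.frame(
      experiment_id = fe@experimentId, allele = g@allele,
      orientation = g@orientation, msh6 = g@msh6, pol2 = g@pol2,
      pol3 = g@pol3, culture_id = seq_along(fe@counts),
      revertant_colonies = fe@counts, cells_plated = fe@cellsPlated,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(experiment_id = character(), allele = character(),
               orientation = character(), msh6 = character(),
               pol2 = character(), pol3 = character(),
               culture_id = integer(), revertant_colonies = integer(),
               cells_plated = numeric())
  .writeTsvWithHeader(df, file, seed = seed)
}

#' Read a culture TSV into FluctuationExperiment objects
#'
#' @param file path to a culture TSV as written by
#'   \code{\link{writeCultureTSV}}.
#' @return list of \linkS4class{FluctuationExperiment}.
#' @export
readCultureTSV <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("experiment_id", "allele", "orientation", "msh6", "pol2",
            "pol3", "culture_id", "revertant_colonies", "cells_plated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("culture TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) return(list())
  bad <- which(is.na(df$revertant_colonies) | df$revertant_colonies < 0)
  if (length(bad))
    stop("malformed revertant_colonies at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (anyDuplicated(unique(df[, c("experiment_id", "culture_id")])))
    stop("duplicate (experiment_id, culture_id) rows", call. = FALSE)
  ids <- unique(df$experiment_id)
  lapply(ids, function(id) {
    sub <- df[df$experiment_id == id, ]
    if (length(unique(sub$cells_plated)) != 1L)
      stop("experiment ", id, " mixes cells_plated values", call. = FALSE)
    g <- StrainGenotype(sub$allele[1], sub$orientation[1],
                        msh6 = sub$msh6[1], pol2 = sub$pol2[1],
                        pol3 = sub$pol3[1])
    FluctuationExperiment(id, g, sub$revertant_colonies, sub$cells_plated[1])
  })
}

#' Write per-genotype rate estimates as TSV
#'
#' One row per genotype: genotype fields, number of experiments aggregated,
#' mu_hat and the 95\% and 83\% interval endpoints, all in scientific
#' notation with 4 significant digits.
#'
#' @param estimates list of aggregated \linkS4class{RateEstimate} objects.
#' @param n_experiments integer vector, experiments behind each estimate.
#' @param file output path.
#' @param seed seed recorded in the provenance header.
#' @return the path, invisibly.
#' @export
writeRatesTSV <- function(estimates, n_experiments, file, seed = NA) {
  sci <- function(x) formatC(x, format = "e", digits = 3)
  rows <- lapply(seq_along(estimates), function(i) {
    est <- estimates[[i]]
    g <- est@genotype
    ci95 <- confInt(est, 0.95)
    ci83 <- confInt(est, 0.83)
    data.frame(allele = g@allele, orientation = g@orientation,
               msh6 = g@msh6, pol2 = g@pol2, pol3 = g@pol3,
               n_experiments = n_experiments[i],
               mu_hat = sci(muHat(est)),
               ci95_lo = sci(ci95[1]), ci95_hi = sci(ci95[2]),
               ci83_lo = sci(ci83[1]), ci83_hi = sci(ci83[2]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .writeTsvWithHeader(df, file, seed = seed)
}
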