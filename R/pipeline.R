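## Pipeline orchestration. These functions back the command-line script in
## inst/scripts/fluctproof.R; each consumes a config list (usually read
## from YAML) and writes provenance-stamped TSV/text outputs.

#' Read a pipeline configuration file
#'
#' YAML with fields: \code{out_dir}, \code{seed}, \code{levels} (default
#' 0.95 and 0.83), \code{culture_tsv}, \code{oligo_tsv}, \code{fork_params}
#' (path to a YAML fork-parameter file, or absent for the defaults),
#' \code{n0}, \code{n_final}, \code{n_cultures}, \code{alleles}.
#'
#' @param path config path.
#' @return config list with defaults filled in and the source path attached.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$path <- path
  cfg <- .fillConfig(cfg)
  cfg
}

.fillConfig <- function(cfg) {
  defaults <- list(out_dir = ".", seed = 1L, levels = c(0.95, 0.83),
                   n0 = 1e3, n_final = 2e8, n_cultures = 24,
                   alleles = c("G148T", "A149C", "G148A", "A149G"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  bad <- cfg$levels <= 0 | cfg$levels >= 1
  if (any(bad)) stop("config: CI levels must lie in (0,1)", call. = FALSE)
  cfg
}

.configForkParams <- function(cfg) {
  if (is.null(cfg$fork_params)) return(defaultForkParams())
  raw <- yaml::read_yaml(cfg$fork_params)
  p <- defaultForkParams()
  setNum <- function(x) {
    v <- unlist(x); storage.mode(v) <- "double"; v
  }
  if (!is.null(raw$ins_prob)) p@insProb <- setNum(raw$ins_prob)
  if (!is.null(raw$ext_prob)) p@extProb <- setNum(raw$ext_prob)
  scalarMap <- c(exo_escape = "exoEscape", rescue_prob = "rescueProb",
                 wt_delta_fraction = "wtDeltaFraction",
                 wt_epsilon_fraction = "wtEpsilonFraction",
                 mmr_efficiency = "mmrEfficiency",
                 background_rate = "backgroundRate",
                 max_reengagement = "maxReengagement")
  for (nm in names(scalarMap))
    if (!is.null(raw[[nm]])) slot(p, scalarMap[[nm]]) <- as.numeric(raw[[nm]])
  if (!is.null(raw$oxog_exempt)) p@oxoGExempt <- as.character(raw$oxog_exempt)
  ok <- validObject(p, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid fork-parameter file '", cfg$fork_params, "': ", ok,
         call. = FALSE)
  p
}

#' Pipeline step: simulate a synthetic study
#'
#' Runs \code{\link{generateStudy}} over the paper-like design and writes
#' the culture TSV (\code{cultures.tsv}) and ground-truth sidecar
#' (\code{truth.yaml}) into \code{out_dir}.
#'
#' @param config config list (see \code{\link{readPipelineConfig}}).
#' @return paths of the files written, invisibly.
#' @export
cmdSimulate <- function(config) {
  config <- .fillConfig(config)
  params <- .configForkParams(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- paperLikeDesign(config$alleles)
  cultures <- file.path(config$out_dir, "cultures.tsv")
  sidecar <- file.path(config$out_dir, "truth.yaml")
  generateStudy(params, design, n0 = config$n0, n_final = config$n_final,
                n_cultures = config$n_cultures, seed = config$seed,
                file = cultures, sidecar = sidecar)
  invisible(c(cultures = cultures, sidecar = sidecar))
}

#' Pipeline step: estimate rates from a culture TSV
#'
#' Reads the culture TSV, estimates each experiment, aggregates replicate
#' experiments per genotype by the median rule and writes
#' \code{rates.tsv}. Returns the aggregated estimates invisibly.
#'
#' @param config config list; \code{culture_tsv} names the input (defaults
#'   to \code{out_dir/cultures.tsv}).
#' @return named list of aggregated \linkS4class{RateEstimate}, invisibly.
#' @export
cmdEstimate <- function(config) {
  config <- .fillConfig(config)
  input <- config$culture_tsv
  if (is.null(input)) input <- file.path(config$out_dir, "cultures.tsv")
  experiments <- readCultureTSV(input)
  if (!length(experiments)) stop("no experiments in ", input, call. = FALSE)
  ests <- lapply(experiments, estimateRate, levels = config$levels)
  labs <- vapply(ests, function(e) .genotypeLabel(genotype(e)), "")
  agg <- lapply(split(ests, labs), aggregateExperiments)
  nexp <- vapply(split(ests, labs), length, 0L)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeRatesTSV(agg, nexp, file.path(config$out_dir, "rates.tsv"),
                seed = config$seed)
  invisible(agg)
}

#' Pipeline step: comparative proofreading inference
#'
#' Chains estimation, strand inference and the comparison tables; writes
#' \code{het_vs_hom.tsv}, \code{equivalent_mispairs.tsv} and a text report
#' \code{report.txt} with significance footnotes. Missing genotypes are
#' marked, not fatal.
#'
#' @param config config list.
#' @return the comparison tables, invisibly.
#' @export
cmdInfer <- function(config) {
  config <- .fillConfig(config)
  agg <- cmdEstimate(config)
  tables <- buildComparisonTables(agg, alleles = config$alleles)
  .writeTsvWithHeader(tables$het_vs_hom,
                      file.path(config$out_dir, "het_vs_hom.tsv"),
                      seed = config$seed, config = config$path)
  .writeTsvWithHeader(tables$equivalent_mispairs,
                      file.path(config$out_dir, "equivalent_mispairs.tsv"),
                      seed = config$seed, config = config$path)
  writeLines(c(.provenanceHeader(config$seed, config$path),
               formatComparisonReport(tables)),
             file.path(config$out_dir, "report.txt"))
  invisible(tables)
}

#' Pipeline step: oligo-transformation analysis
#'
#' Reads the oligo TSV, summarizes relative transformation per strain and
#' oligo, and runs the rank-sum comparison between homozygous and
#' heterozygous Pol delta proofreading-deficient strains for each oligo and
#' orientation where both are present. Writes \code{oligo_summary.tsv}.
#'
#' @param config config list; \code{oligo_tsv} names the input.
#' @return list with \code{summary} and \code{tests} data.frames, invisibly.
#' @export
cmdOligo <- function(config) {
  config <- .fillConfig(config)
  if (is.null(config$oligo_tsv)) stop("config: oligo_tsv not set", call. = FALSE)
  df <- readOligoTSV(config$oligo_tsv)
  keys <- interaction(df$genotype, df$oligo_id, drop = TRUE)
  summ <- lapply(split(df, keys), function(sub) {
    rt <- relativeTransformation(cbind(sub$test_colonies, sub$control_colonies))
    data.frame(genotype = sub$genotype[1], oligo_id = sub$oligo_id[1],
               allele = sub$allele[1], orientation = sub$orientation[1],
               pol3 = sub$pol3[1], mean = rt$mean, sd = rt$sd, n = rt$n,
               rendered = rt$rendered, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  tests <- list()
  for (ol in unique(df$oligo_id)) for (o in unique(df$orientation)) {
    hom <- df[df$oligo_id == ol & df$orientation == o & df$pol3 == "hom", ]
    het <- df[df$oligo_id == ol & df$orientation == o & df$pol3 == "het", ]
    if (nrow(hom) >= 2 && nrow(het) >= 2) {
      mt <- mannWhitney(hom$test_colonies / hom$control_colonies,
                        het$test_colonies / het$control_colonies)
      tests[[length(tests) + 1L]] <-
        data.frame(oligo_id = ol, orientation = o, u = mt$u_statistic,
                   p_value = mt$p_value, method = mt$method,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(oligo_id = character(), orientation = character(),
               u = numeric(), p_value = numeric(), method = character())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsvWithHeader(summary, file.path(config$out_dir, "oligo_summary.tsv"),
                      seed = config$seed, config = config$path)
  invisible(list(summary = summary, tests = tests))
}
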