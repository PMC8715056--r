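# End-to-end orchestration: simulate -> deconfound -> CCA -> bootstrap
# contrast -> PRS -> Bayesian mode-heritability, with artifacts and a
# summary report written as tab-delimited text.

# Tiny rolling hash for provenance stamps (no external digest dependency);
# kept below 2^53 so double arithmetic is exact.
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)),
                           collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  format(h, scientific = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' @param simSpec a \linkS4class{SimSpec} describing the cohort to
#'   generate (ignored when \code{cohort} is supplied to
#'   \code{\link{runPipeline}}).
#' @param K number of CCA modes.
#' @param nBoot bootstrap iterations for the group contrast.
#' @param probs percentile pair for hit detection.
#' @param prsGrid p-value thresholds for \code{\link{optimizeThreshold}}.
#' @param extremeFraction tail fraction for PRS extremes.
#' @param labelColumn group label column name.
#' @param stages character vector of stages to run, in order, from
#'   \code{c("deconfound", "cca", "contrast", "prs", "bayes")}.
#' @param seed seed for contrast resampling and MCMC.
#' @return classed list used by \code{\link{runPipeline}}.
#' @export
runConfig <- function(simSpec, K = 5L, nBoot = 100L, probs = c(0.1, 0.9),
                      prsGrid = c(5e-8, 1e-5, 1e-3, 0.05, 1),
                      extremeFraction = 0.05, labelColumn = "lonely",
                      stages = c("deconfound", "cca", "contrast", "prs",
                                 "bayes"),
                      seed = 1L) {
  structure(list(simSpec = simSpec, K = as.integer(K),
                 nBoot = as.integer(nBoot), probs = probs,
                 prsGrid = prsGrid, extremeFraction = extremeFraction,
                 labelColumn = labelColumn, stages = stages,
                 seed = as.integer(seed)),
            class = "codecompRunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}}; the
#' \code{simSpec} key holds arguments of \code{\link{simSpec}}.
#'
#' @param path YAML file.
#' @return a run configuration.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ss <- do.call(simSpec, y$simSpec)
  y$simSpec <- NULL
  do.call(runConfig, c(list(simSpec = ss), y))
}

#' Run the full codecomposition pipeline
#'
#' Executes the enabled stages in order on a generated (or supplied)
#' cohort and writes every artifact plus a provenance stamp and summary
#' report under \code{outDir}. Any artifact can be regenerated from the
#' configuration and seeds alone.
#'
#' @param config from \code{\link{runConfig}}.
#' @param outDir output directory (created); \code{NULL} skips writing.
#' @param cohort optional pre-built \linkS4class{CohortExperiment};
#'   otherwise \code{config$simSpec} is generated.
#' @return list with the cohort, CCA solution, contrast result, hit
#'   summary, PRS model and the two heritability flag tables (components
#'   present only for stages that ran).
#' @export
runPipeline <- function(config, outDir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "codecompRunConfig"))
  known <- c("deconfound", "cca", "contrast", "prs", "bayes")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  log <- function(...) message(sprintf("[%7.1fs] ", proc.time()[["elapsed"]] - t0),
                               ...)
  if (is.null(cohort)) {
    log("simulate: n = ", config$simSpec@nParticipants)
    cohort <- generateCohort(config$simSpec)
  }
  cd <- SummarizedExperiment::colData(cohort)
  if (!config$labelColumn %in% names(cd))
    stop("label column '", config$labelColumn,
         "' is absent from the cohort")
  out <- list(cohort = cohort)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(outDir, "cohort"))
    yaml::write_yaml(list(config_hash = .configHash(config),
                          seed = config$seed,
                          sim_seed = config$simSpec@seed,
                          stages = config$stages,
                          package_version =
                            as.character(utils::packageVersion("codecomp"))),
                     file.path(outDir, "provenance.yaml"))
  }
  if ("deconfound" %in% config$stages) {
    log("deconfound")
    cohort <- deconfound(cohort)
    out$cohort <- cohort
  }
  assayName <- if ("cleaned" %in% SummarizedExperiment::assayNames(cohort))
    "cleaned" else "volumes"
  sol <- NULL
  if ("cca" %in% config$stages) {
    log("cca: K = ", config$K)
    sol <- fitCCA(volumeMatrix(cohort, "DN", assayName),
                  volumeMatrix(cohort, "HC", assayName), config$K)
    out$cca <- sol
    if (!is.null(outDir)) writeCCASolution(sol, file.path(outDir, "cca"))
  }
  if ("contrast" %in% config$stages) {
    if (is.null(sol)) stop("contrast stage requires the cca stage")
    log("contrast: nBoot = ", config$nBoot)
    ctr <- bootstrapContrast(cohort, K = config$K, nBoot = config$nBoot,
                             seed = config$seed, probs = config$probs,
                             labelColumn = config$labelColumn)
    out$contrast <- ctr
    out$hitSummary <- summarizeHits(ctr)
    if (!is.null(outDir)) {
      utils::write.table(hitTable(ctr), file.path(outDir, "hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$hitSummary$perMode,
                         file.path(outDir, "hits_per_mode.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(out$hitSummary$perGrouping))
        utils::write.table(out$hitSummary$perGrouping,
                           file.path(outDir, "hits_per_grouping.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("prs" %in% config$stages) {
    if (is.null(sol)) stop("prs stage requires the cca stage")
    log("prs: ", config$simSpec@snpSpec$n_snps, " SNPs")
    geno <- generateGenotypes(S4Vectors::metadata(cohort)$simSpec,
                              modeScores = modeExpressions(sol, "HC"),
                              linkModes = seq_len(min(2L, config$K)))
    stats <- qcFilter(geno$stats, panel = geno$panel)
    # dosage columns must be a subset of the QC-passing SNPs
    dosQC <- geno$dosages[, stats$SNP, drop = FALSE]
    opt <- optimizeThreshold(dosQC, cd[[config$labelColumn]],
                             stats, grid = config$prsGrid,
                             panel = geno$panel)
    out$prs <- opt$model
    out$genotypes <- geno
    if (!is.null(outDir)) {
      writeGenotypes(geno, file.path(outDir, "genotypes"))
      utils::write.table(
        data.frame(participant = names(prsScores(opt$model)),
                   prs = unname(prsScores(opt$model))),
        file.path(outDir, "prs_scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  }
  if ("bayes" %in% config$stages) {
    if (is.null(out$prs)) stop("bayes stage requires the prs stage")
    log("bayes: extremes fraction = ", config$extremeFraction)
    ext <- selectExtremes(prsScores(out$prs), config$extremeFraction)
    ids <- c(ext$high, ext$low)
    grp <- rep(c(1L, 0L), c(length(ext$high), length(ext$low)))
    i <- match(ids, colnames(cohort))
    age <- as.vector(scale(cd$age))[i]
    out$heritability <- lapply(
      stats::setNames(c("HC", "DN"), c("HC", "DN")),
      function(sd_) {
        fit <- fitHeritability(modeExpressions(sol, sd_)[i, , drop = FALSE],
                               sex = cd$sex[i], age = age, group = grp,
                               seed = config$seed)
        flagRobust(fit)
      })
    if (!is.null(outDir))
      for (sd_ in names(out$heritability))
        utils::write.table(out$heritability[[sd_]],
                           file.path(outDir,
                                     paste0("heritability_", sd_, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(outDir) && !is.null(sol))
    utils::write.table(
      data.frame(mode = seq_along(canonicalCorrelations(sol)),
                 rho = canonicalCorrelations(sol)),
      file.path(outDir, "report_rhos.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  log("done")
  out
}
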