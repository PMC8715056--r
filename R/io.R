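# Tab-delimited interchange formats: cohort tables with a sidecar
# column-role file, genotype dosage matrices, summary statistics.

#' Write a cohort to tab-delimited text
#'
#' Writes \code{volumes.tsv} (participants x features, header row, first
#' column \code{participant}), \code{confounds.tsv} (confounds plus the
#' label column), and \code{roles.yaml} mapping every column to its role
#' (\code{volume_dn} / \code{volume_hc} / \code{confound} / \code{label}).
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- volumeMatrix(cohort)
  utils::write.table(
    data.frame(participant = rownames(vol), vol, check.names = FALSE),
    file.path(dir, "volumes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  utils::write.table(
    data.frame(participant = rownames(cd), cd, check.names = FALSE),
    file.path(dir, "confounds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  rd <- SummarizedExperiment::rowData(cohort)
  roles <- c(
    stats::setNames(as.list(ifelse(rd$block == "DN", "volume_dn",
                                   "volume_hc")), rownames(cohort)),
    stats::setNames(as.list(rep("confound", ncol(cd) - 1)),
                    setdiff(names(cd), "lonely")),
    list(lonely = "label"))
  yaml::write_yaml(roles, file.path(dir, "roles.yaml"))
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing \code{volumes.tsv},
#'   \code{confounds.tsv} and \code{roles.yaml}.
#' @return A \linkS4class{CohortExperiment} (without ground truth).
#' @export
readCohort <- function(dir) {
  vol <- utils::read.delim(file.path(dir, "volumes.tsv"),
                           check.names = FALSE)
  rownames(vol) <- vol$participant
  vol$participant <- NULL
  cf <- utils::read.delim(file.path(dir, "confounds.tsv"),
                          check.names = FALSE)
  rownames(cf) <- cf$participant
  cf$participant <- NULL
  roles <- yaml::read_yaml(file.path(dir, "roles.yaml"))
  featNames <- names(roles)[unlist(roles) %in% c("volume_dn", "volume_hc")]
  block <- unname(ifelse(unlist(roles[featNames]) == "volume_dn",
                         "DN", "HC"))
  m <- t(as.matrix(vol[, featNames, drop = FALSE]))
  if ("site" %in% names(cf)) cf$site <- factor(cf$site)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volumes = m),
    rowData = S4Vectors::DataFrame(block = block, subregion = featNames,
                                   grouping = NA_character_,
                                   row.names = featNames),
    colData = S4Vectors::DataFrame(cf))
  new("CohortExperiment", se)
}

#' Write genotype dosages and summary statistics
#'
#' Dosages go to \code{dosages.tsv} (participants x SNPs, integer 0/1/2);
#' summary statistics to \code{sumstats.tsv} with columns SNP, A1, A2,
#' BETA, P, MAF, INFO.
#'
#' @param genotypes list from \code{\link{generateGenotypes}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeGenotypes <- function(genotypes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(participant = rownames(genotypes$dosages),
               genotypes$dosages, check.names = FALSE),
    file.path(dir, "dosages.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(genotypes$stats, file.path(dir, "sumstats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
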