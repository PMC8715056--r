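# Additive polygenic-score engine: QC of summary statistics, score
# computation with allele harmonization, p-value threshold selection,
# extreme-tail extraction. Thresholding is deliberately simplified: no LD
# clumping/pruning against a reference panel (loci are simulated
# independent), which every output of this engine documents.

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' Quality-control GWAS summary statistics
#'
#' Removes SNPs with minor allele frequency below 1\%, imputation INFO
#' below 0.8, duplicated ids (all copies), strand-ambiguous allele pairs
#' (A/T and C/G), and — when a genotype-panel allele map is supplied —
#' SNPs whose alleles do not match the panel in either orientation.
#'
#' @param stats data.frame with columns SNP, A1, A2, BETA, P, MAF, INFO.
#' @param panel optional data.frame with columns SNP, A1, A2 giving the
#'   dosage panel's allele coding.
#' @param mafMin,infoMin filter thresholds.
#' @return the filtered summary-statistics table.
#' @examples
#' toy <- data.frame(SNP = c("a", "b"), A1 = c("A", "A"), A2 = c("C", "T"),
#'                   BETA = 0.1, P = 0.5, MAF = 0.3, INFO = 0.99)
#' qcFilter(toy)  # the A/T SNP is dropped as strand-ambiguous
#' @export
qcFilter <- function(stats, panel = NULL, mafMin = 0.01, infoMin = 0.8) {
  .requireCols(stats, c("SNP", "A1", "A2", "BETA", "P", "MAF", "INFO"),
               "summary statistics")
  if (nrow(stats) == 0L) {
    warning("empty summary-statistics table")
    return(stats)
  }
  dup <- stats$SNP %in% stats$SNP[duplicated(stats$SNP)]
  pair <- paste(pmin(stats$A1, stats$A2), pmax(stats$A1, stats$A2))
  ambiguous <- pair %in% c("A T", "C G")
  keep <- stats$MAF >= mafMin & stats$INFO >= infoMin & !dup & !ambiguous
  if (!is.null(panel)) {
    .requireCols(panel, c("SNP", "A1", "A2"), "allele panel")
    i <- match(stats$SNP, panel$SNP)
    matches <- !is.na(i) &
      ((stats$A1 == panel$A1[i] & stats$A2 == panel$A2[i]) |
       (stats$A1 == panel$A2[i] & stats$A2 == panel$A1[i]))
    keep <- keep & matches
  }
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute additive polygenic scores
#'
#' \eqn{prs_j = \sum_i g_{ij} \hat\beta_i} over the SNPs whose p-value is
#' at or below the threshold. Effects are counted on the summary-statistic
#' effect allele: when a SNP's alleles are swapped relative to the dosage
#' panel, its dosage is recoded \eqn{g \to 2 - g} before weighting.
#'
#' @param dosages participants x SNPs matrix with values in \{0, 1, 2\};
#'   column names are SNP ids.
#' @param stats QC-passing summary statistics (see \code{\link{qcFilter}}).
#' @param thresholdP p-value inclusion threshold in (0, 1].
#' @param panel optional allele map of the dosage panel (SNP, A1, A2);
#'   without it the panel is assumed coded on the stats effect allele.
#' @return named per-participant score vector.
#' @export
computePRS <- function(dosages, stats, thresholdP = 1, panel = NULL) {
  dosages <- as.matrix(dosages)
  if (thresholdP <= 0 || thresholdP > 1)
    stop("thresholdP must lie in (0, 1]")
  if (!all(dosages %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1 or 2")
  ids <- colnames(dosages)
  miss <- setdiff(ids, stats$SNP)
  if (length(miss))
    stop("SNP(s) in dosages absent from summary statistics: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  i <- match(ids, stats$SNP)
  beta <- stats$BETA[i]
  pval <- stats$P[i]
  g <- dosages
  if (!is.null(panel)) {
    j <- match(ids, panel$SNP)
    flipped <- !is.na(j) & stats$A1[i] == panel$A2[j] &
      stats$A2[i] == panel$A1[j]
    if (any(flipped)) g[, flipped] <- 2 - g[, flipped]
  }
  use <- pval <= thresholdP
  scores <- as.vector(g[, use, drop = FALSE] %*% beta[use])
  stats::setNames(scores, rownames(dosages))
}

#' Select the p-value inclusion threshold on training data
#'
#' Scores the training participants at every grid threshold and returns
#' the grid value maximizing the squared correlation between score and
#' phenotype. Ties resolve deterministically to the smaller threshold.
#' This replaces the clumping-and-thresholding optimizer of dedicated PRS
#' software with plain thresholding, appropriate for independent loci.
#'
#' @param trainDosages participants x SNPs dosage matrix.
#' @param trainPhenotype binary (or numeric) phenotype vector.
#' @param stats QC-passing summary statistics.
#' @param grid ascending p-value thresholds to try.
#' @param panel optional allele map passed to \code{\link{computePRS}}.
#' @return list with \code{thresholdP}, \code{association} (squared
#'   correlation per grid point), and the fitted \linkS4class{PRSModel}
#'   at the chosen threshold.
#' @export
optimizeThreshold <- function(trainDosages, trainPhenotype, stats,
                              grid = c(5e-8, 1e-5, 1e-3, 0.05, 1),
                              panel = NULL) {
  if (!length(grid)) stop("grid must be nonempty")
  grid <- sort(grid)
  if (stats::var(as.numeric(trainPhenotype)) == 0)
    stop("constant phenotype: association is undefined")
  assoc <- vapply(grid, function(thr) {
    s <- computePRS(trainDosages, stats, thr, panel = panel)
    if (stats::var(s) == 0) 0
    else stats::cor(s, as.numeric(trainPhenotype))^2
  }, numeric(1))
  best <- grid[which.max(assoc)]   # which.max takes the first (smallest) tie
  model <- new("PRSModel",
               includedSnps = stats$SNP[stats$P <= best],
               thresholdP = best,
               scores = computePRS(trainDosages, stats, best, panel = panel),
               stats = stats)
  list(thresholdP = best,
       association = stats::setNames(assoc, format(grid)),
       model = model)
}

#' Extract top and bottom scorers
#'
#' Returns \code{floor(fraction * n)} participants per tail; ties at a
#' cutoff break deterministically by participant id order.
#'
#' @param scores named per-participant score vector.
#' @param fraction tail fraction in (0, 0.5); default 0.05.
#' @return list with \code{high} and \code{low} id vectors.
#' @examples
#' s <- setNames(rnorm(100), sprintf("P%03d", 1:100))
#' lengths(selectExtremes(s))  # 5 and 5
#' @export
selectExtremes <- function(scores, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must lie in (0, 0.5)")
  n <- length(scores)
  k <- floor(fraction * n)
  if (k < 1L)
    stop("fraction ", fraction, " yields no participants per tail at n = ", n)
  ids <- names(scores) %||% as.character(seq_len(n))
  if (stats::var(scores) == 0)
    warning("all scores equal; selection falls back to id order")
  ordLow <- order(scores, ids)
  ordHigh <- order(-scores, ids)
  list(high = ids[ordHigh[seq_len(k)]], low = ids[ordLow[seq_len(k)]])
}

#' @describeIn computePRS score accessor for a \linkS4class{PRSModel}.
#' @param x a \linkS4class{PRSModel}.
#' @export
setMethod("prsScores", "PRSModel", function(x) x@scores)

#' @describeIn computePRS included-SNP accessor.
#' @export
setMethod("includedSnps", "PRSModel", function(x) x@includedSnps)

setMethod("show", "PRSModel", function(object) {
  cat("PRSModel (simplified thresholding; no LD clumping):",
      length(object@includedSnps), "SNPs at p <=",
      format(object@thresholdP), ";", length(object@scores),
      "participants scored\n")
})
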