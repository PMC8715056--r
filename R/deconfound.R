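#' Build the nuisance design matrix
#'
#' Expands the confound table into the regression design used to clean the
#' volume features: intercept; z-scored age, age^2; sex (0/1); sex x age
#' and sex x age^2 interactions; the remaining base confounds (body-mass
#' index, head size, two motion summaries, head position x/y/z, table
#' position); and site indicator columns with one reference level dropped.
#' Age is z-scored before squaring to limit collinearity.
#'
#' @param confounds data.frame (or \code{colData}) with at least
#'   \code{age}, \code{sex} and any columns named in \code{baseTerms};
#'   \code{site} may be a factor/character column.
#' @param baseTerms additional numeric confound columns to include as-is.
#' @param siteColumn name of the categorical site column, or \code{NULL}.
#' @return numeric design matrix with named columns (intercept included).
#' @export
confoundDesign <- function(confounds,
                           baseTerms = c("bmi", "head_size", "motion_task",
                                         "motion_rest", "pos_x", "pos_y",
                                         "pos_z", "table_pos"),
                           siteColumn = "site") {
  confounds <- as.data.frame(confounds)
  missing <- setdiff(c("age", "sex", baseTerms), names(confounds))
  if (length(missing))
    stop("missing confound column(s): ", paste(missing, collapse = ", "))
  zage <- as.vector(scale(confounds$age))
  sx <- as.numeric(confounds$sex)
  D <- cbind(intercept = 1, age = zage, age2 = zage^2, sex = sx,
             sex_age = sx * zage, sex_age2 = sx * zage^2)
  if (length(baseTerms))
    D <- cbind(D, as.matrix(confounds[baseTerms]))
  if (!is.null(siteColumn) && siteColumn %in% names(confounds)) {
    site <- factor(confounds[[siteColumn]])
    if (nlevels(site) > 1) {
      ind <- stats::model.matrix(~ site)[, -1, drop = FALSE]
      colnames(ind) <- paste0("site_", levels(site)[-1])
      D <- cbind(D, ind)
    }
  }
  D
}

#' Residualize volume columns on a nuisance design
#'
#' Regresses every volume column on the design by least squares, keeps the
#' residuals, and z-scores each residual column to mean 0 and unit
#' variance (population denominator n, so the operation is idempotent).
#' Residuals are orthogonal to every design column by construction.
#'
#' @param volumes participants x m numeric matrix, no missing values.
#' @param design numeric design matrix from \code{\link{confoundDesign}}
#'   (or any full-column-rank matrix with matching rows).
#' @return participants x m matrix of z-scored residuals.
#' @examples
#' set.seed(1)
#' v <- matrix(rnorm(200 * 3), 200, 3)
#' d <- cbind(1, rnorm(200))
#' r <- residualize(v, d)
#' max(abs(crossprod(d, r)))  # ~ 0
#' @export
residualize <- function(volumes, design) {
  volumes <- as.matrix(volumes)
  design <- as.matrix(design)
  if (nrow(volumes) != nrow(design))
    stop("volumes and design must have the same number of rows")
  if (anyNA(volumes) || anyNA(design))
    stop("missing values are not allowed")
  if (nrow(design) <= ncol(design))
    stop("need more participants than design columns")
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dropped <- colnames(design)[qrD$pivot[seq(qrD$rank + 1L, ncol(design))]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped %||% "unnamed", collapse = ", "))
  }
  res <- qr.resid(qrD, volumes)
  sdev <- sqrt(colMeans(sweep(res, 2L, colMeans(res), "-")^2))
  zero <- which(sdev < 1e-12 * pmax(1, sqrt(colMeans(volumes^2))))
  if (length(zero))
    stop("zero-variance residual column(s) after deconfounding: ",
         paste(colnames(volumes)[zero] %||% zero, collapse = ", "))
  zscoreColumns(res)
}

#' Deconfound a cohort
#'
#' Applies \code{\link{residualize}} to the \code{"volumes"} assay using
#' the design implied by the cohort's confound columns, and stores the
#' result as a new \code{"cleaned"} assay. Cleaning is computed once on
#' the full cohort (not per analysis subgroup); pass a subset
#' \linkS4class{CohortExperiment} first if subgroup-wise cleaning is
#' wanted.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param ... passed to \code{\link{confoundDesign}}.
#' @return the cohort with an added \code{"cleaned"} assay.
#' @export
deconfound <- function(cohort, ...) {
  stopifnot(is(cohort, "CohortExperiment"))
  design <- confoundDesign(SummarizedExperiment::colData(cohort), ...)
  cleaned <- residualize(volumeMatrix(cohort), design)
  SummarizedExperiment::assay(cohort, "cleaned") <- t(cleaned)
  cohort
}
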