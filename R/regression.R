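#' Multiple regression of a tract target on one subregion block
#'
#' Ordinary least squares of a z-scored target (e.g., fornix fractional
#' anisotropy, accumbens volume) on all z-scored subregion volumes of one
#' block: \eqn{y = x_1 \beta_1 + \dots + x_m \beta_m}. Coefficients are
#' the unique least-squares minimizer; the companion pairwise Pearson
#' profile is returned alongside, because the divergence between marginal
#' and partial association profiles is itself informative (a subregion can
#' correlate strongly with the target yet explain little uniquely).
#'
#' @param target z-scored numeric vector.
#' @param block participants x m z-scored matrix, \code{n > m}.
#' @param tol tolerance of the z-scoring precondition check (both the 1/n
#'   and 1/(n-1) variance conventions are accepted).
#' @return A \linkS4class{RegressionResult}.
#' @examples
#' set.seed(1)
#' b <- scale(matrix(rnorm(500), 100, 5))
#' y <- as.vector(scale(b[, 2]))
#' coef(fitBlockRegression(y, b))
#' @export
fitBlockRegression <- function(target, block, tol = 1e-6) {
  block <- as.matrix(block)
  target <- as.vector(target)
  n <- length(target)
  m <- ncol(block)
  if (nrow(block) != n) stop("target and block sizes disagree")
  if (n <= m) stop("need more participants than predictors (n > m)")
  assertZScored(matrix(target, ncol = 1), tol, "target")
  assertZScored(block, tol, "block")
  sv <- svd(block, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-10)
    stop("singular block covariance; smallest singular value = ",
         format(min(sv)))
  fit <- stats::lm.fit(cbind(1, block), target)
  beta <- fit$coefficients
  rsq <- 1 - sum(fit$residuals^2) / sum((target - mean(target))^2)
  new("RegressionResult",
      coefficients = stats::setNames(beta[-1], colnames(block)),
      intercept = unname(beta[1]),
      rSquared = rsq,
      pairwiseR = pairwiseBlockCorrelation(target, block, tol = tol))
}

#' Pairwise Pearson correlations of a target with each block column
#'
#' The marginal companion of \code{\link{fitBlockRegression}}:
#' \eqn{r_j = corr(y, x_j)}.
#'
#' @inheritParams fitBlockRegression
#' @return named numeric vector of correlations.
#' @export
pairwiseBlockCorrelation <- function(target, block, tol = 1e-6) {
  block <- as.matrix(block)
  sdev <- apply(block, 2L, stats::sd)
  if (any(sdev == 0))
    stop("zero-variance column(s): ",
         paste(colnames(block)[sdev == 0] %||% which(sdev == 0),
               collapse = ", "))
  r <- as.vector(stats::cor(target, block))
  stats::setNames(r, colnames(block))
}

#' @describeIn fitBlockRegression coefficient accessor.
#' @param object a \linkS4class{RegressionResult}.
#' @param ... ignored.
#' @importFrom stats coef
#' @export
setMethod("coef", "RegressionResult", function(object, ...) object@coefficients)

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult:", length(object@coefficients),
      "subregions, R^2 =", sprintf("%.3f", object@rSquared), "\n")
  top <- utils::head(order(-abs(object@coefficients)), 3)
  cat("largest |beta|:",
      paste(sprintf("%s=%.3f", names(object@coefficients)[top],
                    object@coefficients[top]), collapse = ", "), "\n")
})

#' Tabulate marginal and partial association profiles side by side
#'
#' @param result a \linkS4class{RegressionResult}.
#' @return data.frame with subregion, beta (partial) and pairwise_r
#'   (marginal) columns.
#' @export
regressionTable <- function(result) {
  data.frame(subregion = names(result@coefficients),
             beta = unname(result@coefficients),
             pairwise_r = unname(result@pairwiseR),
             row.names = NULL)
}
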