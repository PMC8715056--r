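# Two-block canonical correlation analysis by whitened SVD.

# Symmetric inverse square root with an effective-rank check.
invSqrtSym <- function(S, label) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values) * length(e$values) * .Machine$double.eps
  keep <- e$values > tol
  if (!all(keep))
    stop(label, " block is rank deficient (effective rank ", sum(keep),
         " of ", length(e$values), ")")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit a two-block CCA
#'
#' Finds the paired weight vectors \eqn{v_l, u_l} maximizing
#' \eqn{corr(X v_l, Y u_l)} subject to within-block uncorrelatedness with
#' earlier modes. The algorithm whitens each block by the inverse square
#' root of its covariance and takes the SVD of the whitened
#' cross-covariance; singular values are the canonical correlations,
#' ordered non-increasingly.
#'
#' Canonical variates have unit variance (1/n denominator) on the fitting
#' sample. Because CCA weights are sign-indeterminate, each mode is
#' reflected so that the largest-magnitude entry of the concatenated
#' weight vector \eqn{[v_l; u_l]} is positive; the joint reflection keeps
#' every canonical correlation non-negative and makes refits on identical
#' data bitwise-identical.
#'
#' Columns are centered internally (the pipeline supplies z-scored,
#' deconfounded columns; centering makes bootstrap resamples, whose
#' columns are no longer exactly standardized, well-defined).
#'
#' @param X n x p matrix (first block).
#' @param Y n x q matrix (second block).
#' @param K number of modes, at most \code{min(p, q)}; default 25 capped
#'   at \code{min(p, q)}.
#' @return A \linkS4class{CCASolution}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3)
#' s <- fitCCA(X, X, K = 3)
#' canonicalCorrelations(s)  # all 1
#' @export
fitCCA <- function(X, Y, K = 25L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (K > min(p, q))
    stop("K = ", K, " is too large; at most min(p, q) = ", min(p, q),
         " modes exist")
  if (n <= p + q)
    stop("need n > p + q (", n, " <= ", p + q, ")")
  xc <- colMeans(X)
  yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc, "-")
  Yc <- sweep(Y, 2L, yc, "-")
  Sxx <- crossprod(Xc) / n
  Syy <- crossprod(Yc) / n
  Sxy <- crossprod(Xc, Yc) / n
  Wx <- invSqrtSym(Sxx, "X")
  Wy <- invSqrtSym(Syy, "Y")
  sv <- svd(Wx %*% Sxy %*% Wy, nu = K, nv = K)
  rhos <- pmin(pmax(sv$d[seq_len(K)], 0), 1)
  V <- Wx %*% sv$u
  U <- Wy %*% sv$v
  # deterministic joint sign convention per mode
  for (l in seq_len(K)) {
    w <- c(V[, l], U[, l])
    s <- sign(w[which.max(abs(w))])
    if (s < 0) {
      V[, l] <- -V[, l]
      U[, l] <- -U[, l]
    }
  }
  dimnames(V) <- list(colnames(X), paste0("mode", seq_len(K)))
  dimnames(U) <- list(colnames(Y), paste0("mode", seq_len(K)))
  new("CCASolution", V = V, U = U, rhos = rhos,
      variatesX = Xc %*% V, variatesY = Yc %*% U,
      xCenter = stats::setNames(xc, colnames(X)),
      yCenter = stats::setNames(yc, colnames(Y)),
      n = as.integer(n), p = as.integer(p), q = as.integer(q),
      K = as.integer(K))
}

#' Project new data onto a fitted CCA solution
#'
#' Pure linear projection with the training centering; no refitting.
#' Inputs must be on the training scale (z-scored with the training
#' statistics when the training data were z-scored).
#'
#' @param solution a \linkS4class{CCASolution}.
#' @param X,Y matrices with \code{p} and \code{q} columns.
#' @return list with \code{variatesX} and \code{variatesY}.
#' @export
ccaTransform <- function(solution, X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != solution@p || ncol(Y) != solution@q)
    stop("column counts (", ncol(X), ", ", ncol(Y),
         ") do not match the solution (", solution@p, ", ", solution@q, ")")
  list(variatesX = sweep(X, 2L, solution@xCenter, "-") %*% solution@V,
       variatesY = sweep(Y, 2L, solution@yCenter, "-") %*% solution@U)
}

#' @describeIn fitCCA canonical correlations of a solution.
#' @param x a \linkS4class{CCASolution}.
#' @export
setMethod("canonicalCorrelations", "CCASolution", function(x) x@rhos)

#' @describeIn fitCCA weight matrix of one side (\code{"DN"} = first
#'   block V, \code{"HC"} = second block U).
#' @param side which block.
#' @export
setMethod("canonicalWeights", "CCASolution", function(x, side = c("DN", "HC")) {
  side <- match.arg(side)
  if (side == "DN") x@V else x@U
})

#' @describeIn fitCCA canonical variates (mode expressions) of one side.
#' @export
setMethod("modeExpressions", "CCASolution", function(x, side = c("DN", "HC")) {
  side <- match.arg(side)
  if (side == "DN") x@variatesX else x@variatesY
})

setMethod("show", "CCASolution", function(object) {
  cat("CCASolution: n =", object@n, ", p =", object@p, ", q =", object@q,
      ", K =", object@K, "\n")
  cat("rhos:", paste(sprintf("%.3f", utils::head(object@rhos, 8)),
                     collapse = " "),
      if (object@K > 8) "...\n" else "\n")
})

#' Write a CCA solution to a directory of TSV files
#'
#' Writes V, U, rhos and the two variate matrices as tab-delimited text
#' plus a YAML metadata file recording dimensions and training centers for
#' out-of-sample projection.
#'
#' @param solution a \linkS4class{CCASolution}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCCASolution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, f) utils::write.table(
    data.frame(name = rownames(m) %||% seq_len(nrow(m)), m,
               check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(solution@V, "V.tsv")
  wt(solution@U, "U.tsv")
  utils::write.table(data.frame(mode = seq_along(solution@rhos),
                                rho = solution@rhos),
                     file.path(dir, "rhos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wt(solution@variatesX, "variates_dn.tsv")
  wt(solution@variatesY, "variates_hc.tsv")
  yaml::write_yaml(list(n = solution@n, p = solution@p, q = solution@q,
                        K = solution@K,
                        xCenter = as.list(solution@xCenter),
                        yCenter = as.list(solution@yCenter)),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}
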