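# Internal helpers shared across modules. Nothing here is exported.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that package-internal randomness
#' (keyed by a user-supplied seed plus a fixed per-component offset) never
#' disturbs the caller's RNG stream.
#'
#' @param seed integer seed; must stay below 2^31 - 1.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
withSeed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Fixed sub-stream offsets so each generator component draws from its own
# reproducible stream derived from one cohort seed.
.SEED_OFFSETS <- c(cohort = 0L, genotypes = 104729L, tract = 224737L,
                   bootstrap = 350377L, mcmc = 479909L)

#' Column z-scoring with population denominator
#'
#' Centers each column to mean zero and scales to unit variance using the
#' 1/n (population) variance, so z-scoring a column twice is an exact no-op.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @noRd
zscoreColumns <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu, "-")
  sdev <- sqrt(colMeans(ctr^2))
  bad <- which(sdev < .Machine$double.eps^0.5 * pmax(abs(mu), 1))
  if (length(bad))
    stop("zero-variance column(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "))
  sweep(ctr, 2L, sdev, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Checks that columns are z-scored (either population- or sample-variance
# convention) to the given tolerance.
assertZScored <- function(m, tol = 1e-6, what = "input") {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  v_pop <- colMeans(sweep(m, 2L, mu, "-")^2)
  # accept either denominator convention
  dev <- pmin(abs(sqrt(v_pop) - 1), abs(sqrt(v_pop * n / (n - 1)) - 1))
  if (any(abs(mu) > tol) || any(dev > tol))
    stop(what, " must be z-scored (mean 0, unit variance); ",
         "max |mean| = ", format(max(abs(mu))),
         ", max |sd - 1| = ", format(max(dev)))
  invisible(TRUE)
}

#' Minimum-cost linear assignment (Hungarian method)
#'
#' Shortest-augmenting-path formulation, O(n^3). Used for mode matching,
#' where n = K <= 25, so speed is immaterial; correctness is checked against
#' brute-force enumeration in the test suite.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `perm` with row i assigned to column `perm[i]`.
#' @noRd
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 1L) return(1L)
  u <- numeric(n + 1L)          # row potentials (u[1] is a scratch slot)
  v <- numeric(n + 1L)          # column potentials (v[1] = virtual column)
  p <- integer(n + 1L)          # p[j+1]: row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

# Random matrix with orthonormal columns (first k columns of a QR of a
# Gaussian matrix, sign-fixed so the decomposition is deterministic given
# the RNG stream).
randomOrthonormal <- function(nrow, ncol) {
  q <- qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))
  sweep(q, 2L, sign(q[1L, ] + (q[1L, ] == 0)), "*")
}
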