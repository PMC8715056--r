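# Bayesian regression of PRS-extreme group membership on mode expressions.
# Likelihood is logistic (the response is binary top-vs-bottom tail
# membership); a linear-likelihood option is exposed but not default.
# All coefficients carry standard-normal priors; nuisance structure is
# sex-specific intercepts and sex-specific (z-scored) age slopes, with no
# shared intercept (the two sexes partition the sample, so the model is
# identified).

.heritabilityModelString <- function(likelihood) {
  if (likelihood == "logistic")
    "model {
       eta <- Z %*% theta
       for (i in 1:N) { y[i] ~ dbern(ilogit(eta[i])) }
       for (j in 1:M) { theta[j] ~ dnorm(0, 1) }
     }"
  else
    "model {
       eta <- Z %*% theta
       for (i in 1:N) { y[i] ~ dnorm(eta[i], tau) }
       for (j in 1:M) { theta[j] ~ dnorm(0, 1) }
       tau ~ dgamma(1, 1)
     }"
}

#' Fit the Bayesian mode-heritability regression
#'
#' Regresses binary extreme-tail PRS group membership on per-participant
#' mode expressions with sex-specific intercepts and age slopes:
#' \deqn{logit P(y = 1) = \sum_j x_j \beta_j + \alpha_{men}[sex] +
#'   \alpha_{women}[sex] + \alpha_{men,age}[sex] \cdot age +
#'   \alpha_{women,age}[sex] \cdot age}
#' with \eqn{\beta_j, \alpha \sim N(0, 1)} priors throughout. The
#' posterior is sampled by MCMC (JAGS) with at least three chains;
#' potential scale-reduction diagnostics are computed for every parameter
#' and sampling is automatically extended (up to \code{maxExtensions}
#' times) if any exceeds 1.01, after which non-convergence is an error.
#'
#' Mode expressions are expected to be canonical variates and hence
#' near-uncorrelated; a warning is issued if any pairwise |correlation|
#' exceeds 0.1. With zero observations the posterior equals the prior and
#' exact N(0, 1) draws are returned without invoking the sampler.
#'
#' @param modeExpressions participants x J matrix of canonical variates.
#' @param sex binary vector (1 = male, 0 = female).
#' @param age z-scored age vector.
#' @param group binary response (1 = top tail, 0 = bottom tail).
#' @param chains number of MCMC chains (>= 3).
#' @param drawsPerChain post-warmup draws per chain.
#' @param adapt,burn adaptation and burn-in iterations.
#' @param seed integer; chain RNGs are seeded deterministically from it.
#' @param likelihood \code{"logistic"} (default) or \code{"linear"}.
#' @param maxExtensions extra sampling rounds allowed before declaring
#'   non-convergence.
#' @return A \linkS4class{HeritabilityModel}.
#' @export
fitHeritability <- function(modeExpressions, sex, age, group,
                            chains = 4L, drawsPerChain = 1000L,
                            adapt = 500L, burn = 500L, seed = 1L,
                            likelihood = c("logistic", "linear"),
                            maxExtensions = 2L) {
  likelihood <- match.arg(likelihood)
  modeExpressions <- as.matrix(modeExpressions)
  J <- ncol(modeExpressions)
  modeNames <- colnames(modeExpressions) %||% paste0("mode", seq_len(J))
  parNames <- c(paste0("beta_", modeNames),
                "alpha_men", "alpha_women", "alpha_men_age",
                "alpha_women_age")
  N <- nrow(modeExpressions)
  if (chains < 3L) stop("at least three chains are required")

  if (N == 0L) {
    # posterior = prior exactly; draw from N(0, 1) directly
    draws <- withSeed(seed + .SEED_OFFSETS[["mcmc"]], {
      coda::mcmc.list(lapply(seq_len(chains), function(ch)
        coda::mcmc(matrix(stats::rnorm(drawsPerChain * length(parNames)),
                          drawsPerChain, length(parNames),
                          dimnames = list(NULL, parNames)))))
    })
    return(.buildHeritabilityModel(draws, chains, drawsPerChain, modeNames))
  }
  sex <- as.integer(sex)
  group <- as.integer(group)
  if (length(sex) != N || length(age) != N || length(group) != N)
    stop("sex, age and group must match the number of participants")
  if (J > 1) {
    cc <- stats::cor(modeExpressions)
    mx <- max(abs(cc[upper.tri(cc)]))
    if (mx > 0.1)
      warning("mode expressions are correlated (max |corr| = ",
              sprintf("%.2f", mx), "); canonical variates should be ",
              "near-uncorrelated")
  }
  # crude separation check: one mode perfectly splitting the groups
  for (j in seq_len(J)) {
    x1 <- modeExpressions[group == 1L, j]
    x0 <- modeExpressions[group == 0L, j]
    if (length(x1) && length(x0) &&
        (min(x1) > max(x0) || max(x1) < min(x0))) {
      warning("mode '", modeNames[j], "' perfectly separates the groups; ",
              "the N(0, 1) priors regularize the fit")
      break
    }
  }
  men <- as.numeric(sex == 1L)
  women <- 1 - men
  Z <- cbind(modeExpressions, men, women, men * age, women * age)
  colnames(Z) <- parNames

  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((seed + .SEED_OFFSETS[["mcmc"]] + ch) %%
                                  .Machine$integer.max)))
  tryCatch(rjags::load.module("glm", quiet = TRUE),
           error = function(e) NULL, warning = function(w) NULL)
  jm <- rjags::jags.model(
    textConnection(.heritabilityModelString(likelihood)),
    data = list(y = group, Z = Z, N = N, M = ncol(Z)),
    inits = inits, n.chains = chains, n.adapt = adapt, quiet = TRUE)
  update(jm, burn, progress.bar = "none")
  draws <- rjags::coda.samples(jm, "theta", n.iter = drawsPerChain,
                               progress.bar = "none")
  rhat <- .psrf(draws)
  ext <- 0L
  while (any(rhat > 1.01) && ext < maxExtensions) {
    more <- rjags::coda.samples(jm, "theta", n.iter = drawsPerChain,
                                progress.bar = "none")
    draws <- coda::mcmc.list(Map(function(a, b)
      coda::mcmc(rbind(as.matrix(a), as.matrix(b))), draws, more))
    rhat <- .psrf(draws)
    ext <- ext + 1L
  }
  if (any(rhat > 1.01))
    stop("MCMC did not converge: max scale reduction = ",
         sprintf("%.3f", max(rhat)), " for ",
         parNames[which.max(rhat)])
  draws <- coda::mcmc.list(lapply(draws, function(d) {
    m <- as.matrix(d)
    colnames(m) <- parNames
    coda::mcmc(m)
  }))
  .buildHeritabilityModel(draws, chains, nrow(as.matrix(draws[[1]])),
                          modeNames)
}

.psrf <- function(draws) {
  gd <- coda::gelman.diag(draws, autoburnin = FALSE, multivariate = FALSE)
  gd$psrf[, 1L]
}

.buildHeritabilityModel <- function(draws, chains, drawsPerChain,
                                    modeNames) {
  all <- do.call(rbind, lapply(draws, as.matrix))
  summ <- data.frame(
    parameter = colnames(all),
    mean = colMeans(all),
    sd = apply(all, 2L, stats::sd),
    q05 = apply(all, 2L, stats::quantile, 0.05),
    q95 = apply(all, 2L, stats::quantile, 0.95),
    row.names = NULL)
  rhat <- if (length(draws) > 1) .psrf(draws) else
    stats::setNames(rep(1, ncol(all)), colnames(all))
  names(rhat) <- colnames(all)
  new("HeritabilityModel", draws = draws, summaryTable = summ,
      rhat = rhat, chains = as.integer(chains),
      drawsPerChain = as.integer(drawsPerChain), modeNames = modeNames)
}

#' Flag modes whose coefficient posterior robustly excludes zero
#'
#' A mode is flagged when at least \code{mass} of its coefficient's
#' posterior draws share one sign (the >95\% posterior-mass rule at the
#' default). Raising \code{mass} can only unflag modes.
#'
#' @param model a converged \linkS4class{HeritabilityModel}.
#' @param mass posterior-mass threshold in (0.5, 1).
#' @return data.frame with one row per mode: posterior mean, sd, central
#'   90\% interval, the achieved one-sided posterior mass, and the flag.
#' @export
flagRobust <- function(model, mass = 0.95) {
  if (mass <= 0.5 || mass >= 1)
    stop("mass must lie in (0.5, 1)")
  all <- do.call(rbind, lapply(model@draws, as.matrix))
  cols <- paste0("beta_", model@modeNames)
  out <- lapply(cols, function(cn) {
    d <- all[, cn]
    frac <- max(mean(d > 0), mean(d < 0))
    data.frame(mode = sub("^beta_", "", cn),
               mean = mean(d), sd = stats::sd(d),
               q05 = unname(stats::quantile(d, 0.05)),
               q95 = unname(stats::quantile(d, 0.95)),
               posterior_mass = frac,
               robust = frac >= mass)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @describeIn fitHeritability posterior draws (\code{coda::mcmc.list}).
#' @param x a \linkS4class{HeritabilityModel}.
#' @export
setMethod("posteriorDraws", "HeritabilityModel", function(x) x@draws)

#' @describeIn fitHeritability per-parameter potential scale-reduction
#'   statistics.
#' @export
setMethod("scaleReduction", "HeritabilityModel", function(x) x@rhat)

setMethod("show", "HeritabilityModel", function(object) {
  cat("HeritabilityModel:", length(object@modeNames), "mode coefficients,",
      object@chains, "chains x", object@drawsPerChain, "draws\n")
  cat("max scale reduction:", sprintf("%.4f", max(object@rhat)), "\n")
})
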