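# Shared fixtures: everything is generated in code at test time.

# A small, fast cohort with identifiable planted modes.
smallCohort <- function(n = 800, p = 10, q = 6, rhos = c(0.6, 0.4),
                        seed = 42, ...) {
  generateCohort(simSpec(n, pDN = p, qHC = q, plantedRhos = rhos,
                         seed = seed, ...))
}

# z-scored matrix with exactly orthogonal, mean-zero columns.
orthoBlock <- function(n, m, seed = 1) {
  set.seed(seed)
  raw <- matrix(rnorm(n * m), n, m)
  raw <- sweep(raw, 2, colMeans(raw), "-")
  z <- popZ(qr.Q(qr(raw)))   # diagonal rescaling keeps orthogonality
  colnames(z) <- paste0("x", seq_len(m))
  z
}

# Population z-scoring helper matching the package convention.
popZ <- function(x) {
  x <- as.matrix(x)
  ctr <- sweep(x, 2, colMeans(x), "-")
  sweep(ctr, 2, sqrt(colMeans(ctr^2)), "/")
}

# Brute-force minimum-cost assignment by permutation enumeration (K <= 7).
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- gtoolsPerms(n)
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  perms[which.min(costs), ]
}

# All permutations of 1..n (tiny n only).
gtoolsPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtoolsPerms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# HeritabilityModel built from externally supplied draws (for testing the
# flagging rule in isolation).
modelFromDraws <- function(drawMatrix, modeNames) {
  colnames(drawMatrix) <- paste0("beta_", modeNames)
  dl <- coda::mcmc.list(coda::mcmc(drawMatrix))
  new("HeritabilityModel", draws = dl,
      summaryTable = data.frame(parameter = colnames(drawMatrix)),
      rhat = stats::setNames(rep(1, ncol(drawMatrix)), colnames(drawMatrix)),
      chains = 1L, drawsPerChain = nrow(drawMatrix),
      modeNames = modeNames)
}

# Summary-stats table scoring exactly the causal SNPs at p <= 0.5.
causalOnlyStats <- function(geno) {
  data.frame(SNP = names(geno$trueBeta),
             A1 = geno$stats$A1, A2 = geno$stats$A2,
             BETA = unname(geno$trueBeta),
             P = ifelse(geno$trueBeta != 0, 0, 1),
             MAF = geno$stats$MAF, INFO = 1,
             stringsAsFactors = FALSE)
}
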