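test_that("identical spec and seed reproduce the cohort bitwise", {
  sp <- simSpec(200, pDN = 8, qHC = 5, plantedRhos = c(0.5, 0.3), seed = 9)
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(SummarizedExperiment::assay(a, "volumes"),
                   SummarizedExperiment::assay(b, "volumes"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
})

test_that("spec validation rejects malformed inputs", {
  expect_error(simSpec(100, plantedRhos = c(0.4, 0.5)), "decreasing")
  expect_error(simSpec(100, plantedRhos = c(0.4, 1.2)), "\\(0, 1\\)")
  expect_error(simSpec(100, lonelyFraction = 0), "lonelyFraction")
  expect_error(
    simSpec(100, pDN = 5, qHC = 3, plantedRhos = 0.5,
            effectMap = data.frame(mode = 1L, block = "HC",
                                   feature = 9L, shift = 0.1)),
    "out of range")
  expect_error(
    simSpec(100, pDN = 5, qHC = 3, plantedRhos = 0.5,
            effectMap = data.frame(mode = 1L, block = "XX",
                                   feature = 1L, shift = 0.1)),
    "'DN' or 'HC'")
  expect_error(simSpec(100, snpSpec = list(causal_fraction = 0)),
               "causal_fraction")
  expect_error(simSpec(100, snpSpec = list(maf_range = c(0, 0.6))),
               "maf_range")
})

test_that("a pure-noise cohort looks like independent Gaussian blocks", {
  n <- 500; p <- 6; q <- 4
  sp <- simSpec(n, pDN = p, qHC = q, plantedRhos = numeric(0), seed = 3,
                confoundSpec = as.list(stats::setNames(
                  rep(0, 14), c("age", "age2", "sex", "sex_age", "sex_age2",
                                "bmi", "head_size", "motion_task",
                                "motion_rest", "pos_x", "pos_y", "pos_z",
                                "table_pos", "site"))))
  ce <- generateCohort(sp)
  rho1 <- fitCCA(popZ(volumeMatrix(ce, "DN")), popZ(volumeMatrix(ce, "HC")),
                 K = 1)@rhos
  # oracle: leading canonical correlation of truly independent blocks
  set.seed(11)
  nullRhos <- replicate(30, {
    fitCCA(matrix(rnorm(n * p), n, p), matrix(rnorm(n * q), n, q), K = 1)@rhos
  })
  expect_lt(abs(rho1 - mean(nullRhos)), 4 * sd(nullRhos))
})

test_that("planted canonical correlations are recovered at large n", {
  rhos <- c(0.6, 0.45, 0.3)
  ce <- generateCohort(simSpec(10000, pDN = 20, qHC = 12,
                               plantedRhos = rhos, seed = 5))
  ced <- deconfound(ce)
  est <- fitCCA(volumeMatrix(ced, "DN", "cleaned"),
                volumeMatrix(ced, "HC", "cleaned"), K = 3)@rhos
  expect_lt(max(abs(est - rhos)), 0.03)
})

test_that("dosages are binomial with the requested allele frequencies", {
  sp <- simSpec(2000, pDN = 4, qHC = 3, plantedRhos = 0.5, seed = 7,
                snpSpec = list(n_snps = 60L, maf_range = c(0.5, 0.5)))
  geno <- generateGenotypes(sp, groundTruth(generateCohort(sp))@latentScores)
  expect_true(all(geno$dosages %in% 0:2))
  # mean dosage per SNP ~ 2 * MAF = 1
  expect_lt(max(abs(colMeans(geno$dosages) - 1)), 0.08)
})

test_that("planted SNP effects re-score to the true liability", {
  sp <- simSpec(500, pDN = 4, qHC = 3, plantedRhos = 0.5, seed = 13,
                snpSpec = list(n_snps = 200L, causal_fraction = 0.2))
  geno <- generateGenotypes(sp, groundTruth(generateCohort(sp))@latentScores)
  prs <- computePRS(geno$dosages, causalOnlyStats(geno), thresholdP = 0.5)
  expect_gte(cor(prs, geno$liability), 0.99)
  # the genetic liability carries the designated-mode signal
  lat <- groundTruth(generateCohort(sp))@latentScores[, 1]
  expect_gt(cor(geno$liability, lat), 0.2)
})

test_that("tract targets reduce to the z-scored column when noise-free", {
  ce <- smallCohort(n = 300, seed = 21)
  w <- rep(0, 6); w[4] <- 1
  y <- generateTractTargets(ce, w, noiseSd = 0, block = "HC")
  zc <- popZ(volumeMatrix(ce, "HC"))[, 4]
  expect_lt(max(abs(y - zc)), 1e-10)
  expect_error(generateTractTargets(ce, rep(1, 5), 0, block = "HC"),
               "width")
})

test_that("overwhelming target noise destroys explainable variance", {
  ce <- smallCohort(n = 2000, seed = 22)
  set.seed(1)
  w <- rnorm(6)
  y <- generateTractTargets(ce, w, noiseSd = 200, block = "HC")
  fit <- fitBlockRegression(y, popZ(volumeMatrix(ce, "HC")))
  expect_lt(fit@rSquared, 0.02)
})
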