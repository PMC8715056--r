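test_that("QC rules each remove their intended SNP on a constructed table", {
  toy <- data.frame(
    SNP  = c("rs1",   "rs2",  "rs3", "rs4", "rs4", "rs5"),
    A1   = c("A",     "A",    "A",   "C",   "C",   "G"),
    A2   = c("C",     "G",    "T",   "T",   "T",   "T"),
    BETA = c(0.1,     0.2,    0.1,   0.3,   0.3,   -0.2),
    P    = c(1e-6,    0.01,   0.5,   0.2,   0.2,   0.03),
    MAF  = c(0.3,     0.005,  0.2,   0.4,   0.4,   0.25),
    INFO = c(0.95,    0.9,    0.99,  0.85,  0.85,  0.7),
    stringsAsFactors = FALSE)
  # rs2: MAF < 1%; rs3: A/T ambiguous; rs4: duplicated (both copies);
  # rs5: INFO < 0.8; rs1 is the lone survivor
  kept <- qcFilter(toy)
  expect_identical(kept$SNP, "rs1")
  expect_warning(qcFilter(toy[0, ]), "empty")
  clean <- toy[1, , drop = FALSE]
  expect_identical(qcFilter(clean), {
    x <- clean; rownames(x) <- NULL; x
  })
  expect_error(qcFilter(toy[, -4]), "BETA")
  # allele-mismatch rule against a panel map
  panel <- data.frame(SNP = "rs1", A1 = "G", A2 = "T")
  expect_identical(nrow(qcFilter(toy, panel = panel)), 0L)
  panelSwap <- data.frame(SNP = "rs1", A1 = "C", A2 = "A")
  expect_identical(qcFilter(toy, panel = panelSwap)$SNP, "rs1")
})

test_that("score computation matches the elementwise-loop oracle", {
  set.seed(50)
  n <- 20; m <- 50
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                dimnames = list(sprintf("P%02d", 1:n),
                                sprintf("rs%03d", 1:m)))
  st <- data.frame(SNP = colnames(dos), A1 = "A", A2 = "C",
                   BETA = rnorm(m), P = runif(m), MAF = 0.3, INFO = 0.9)
  thr <- 0.4
  got <- computePRS(dos, st, thr)
  loop <- numeric(n)
  for (j in 1:n) for (i in 1:m)
    if (st$P[i] <= thr) loop[j] <- loop[j] + dos[j, i] * st$BETA[i]
  expect_lt(max(abs(got - loop)), 1e-12)
  # trivial cases
  expect_true(all(computePRS(dos * 0, st, 1) == 0))
  one <- computePRS(matrix(2, 1, 1, dimnames = list("p", "rs001")),
                    st[1, ], 1)
  expect_equal(unname(one), 2 * st$BETA[1])
})

test_that("scores are linear in effects and monotone in threshold", {
  set.seed(51)
  n <- 15; m <- 30
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                dimnames = list(NULL, sprintf("rs%03d", 1:m)))
  st <- data.frame(SNP = colnames(dos), A1 = "A", A2 = "C",
                   BETA = rnorm(m), P = runif(m), MAF = 0.3, INFO = 0.9)
  st2 <- st; st2$BETA <- 2 * st$BETA
  expect_equal(computePRS(dos, st2, 0.5), 2 * computePRS(dos, st, 0.5))
  grid <- c(0.01, 0.1, 0.5, 1)
  sets <- lapply(grid, function(t) st$SNP[st$P <= t])
  for (i in seq_along(grid)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("allele flips shift scores by a constant and preserve ranks", {
  set.seed(52)
  n <- 25; m <- 10
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                dimnames = list(NULL, sprintf("rs%03d", 1:m)))
  st <- data.frame(SNP = colnames(dos), A1 = "A", A2 = "C",
                   BETA = rnorm(m), P = runif(m) / 2, MAF = 0.3, INFO = 0.9)
  base <- computePRS(dos, st, 1)
  # recode SNP 4: panel counts the other allele (g -> 2 - g, beta -> -beta)
  panel <- data.frame(SNP = st$SNP, A1 = st$A1, A2 = st$A2)
  panel$A1[4] <- st$A2[4]; panel$A2[4] <- st$A1[4]
  dosFlip <- dos; dosFlip[, 4] <- 2 - dos[, 4]
  flip <- computePRS(dosFlip, st, 1, panel = panel)
  expect_lt(max(abs(flip - base)), 1e-12)
  stNeg <- st; stNeg$BETA[4] <- -st$BETA[4]
  stNeg$A1[4] <- st$A2[4]; stNeg$A2[4] <- st$A1[4]
  reFlip <- computePRS(dosFlip, stNeg, 1)
  expect_lt(max(abs((reFlip - base) - (reFlip - base)[1])), 1e-12)
  expect_equal(order(reFlip), order(base))
})

test_that("invalid dosage inputs are refused", {
  st <- data.frame(SNP = "rs1", A1 = "A", A2 = "C", BETA = 1, P = 0.1,
                   MAF = 0.2, INFO = 0.9)
  expect_error(computePRS(matrix(3, 1, 1, dimnames = list(NULL, "rs1")),
                          st, 1), "0, 1 or 2")
  expect_error(computePRS(matrix(1, 1, 1, dimnames = list(NULL, "rs9")),
                          st, 1), "absent")
  expect_error(computePRS(matrix(1, 1, 1, dimnames = list(NULL, "rs1")),
                          st, 0), "thresholdP")
})

test_that("threshold selection finds the causal stratum", {
  # causal SNPs all below p = 1e-4, null p-values uniform
  chosen <- sapply(1:12, function(r) {
    set.seed(600 + r)
    n <- 300; m <- 200; nCausal <- 30
    dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                  dimnames = list(NULL, sprintf("rs%03d", 1:m)))
    beta <- c(rnorm(nCausal, 0, 0.5) + 0.3 * sign(rnorm(nCausal)),
              rep(0, m - nCausal))
    st <- data.frame(SNP = colnames(dos), A1 = "A", A2 = "C",
                     BETA = beta,
                     P = c(runif(nCausal, 1e-9, 1e-5),
                           runif(m - nCausal)),
                     MAF = 0.3, INFO = 0.95)
    pheno <- as.integer(dos %*% beta + rnorm(n) >
                          median(dos %*% beta + rnorm(n)))
    optimizeThreshold(dos, pheno, st)$thresholdP
  })
  expect_gte(mean(chosen <= 1e-3), 0.9)
})

test_that("threshold selection edge cases behave", {
  set.seed(53)
  dos <- matrix(sample(0:2, 40, replace = TRUE), 20, 2,
                dimnames = list(NULL, c("rs1", "rs2")))
  st <- data.frame(SNP = c("rs1", "rs2"), A1 = "A", A2 = "C",
                   BETA = c(1, -1), P = c(0.01, 0.2), MAF = 0.3, INFO = 0.9)
  expect_equal(optimizeThreshold(dos, rbinom(20, 1, 0.5), st,
                                 grid = 0.05)$thresholdP, 0.05)
  expect_error(optimizeThreshold(dos, rep(1, 20), st), "constant phenotype")
  expect_error(optimizeThreshold(dos, rbinom(20, 1, 0.5), st,
                                 grid = numeric(0)), "nonempty")
})

test_that("extreme selection uses floor arithmetic and breaks ties by id", {
  s <- stats::setNames(rnorm(100), sprintf("P%03d", 1:100))
  ext <- selectExtremes(s, 0.05)
  expect_length(ext$high, 5)
  expect_length(ext$low, 5)
  expect_identical(ext$high, names(sort(s, decreasing = TRUE))[1:5])
  big <- stats::setNames(rnorm(23423), sprintf("P%05d", 1:23423))
  expect_length(selectExtremes(big, 0.05)$high, 1171)
  flat <- stats::setNames(rep(0, 40), sprintf("P%02d", 1:40))
  expect_warning(extFlat <- selectExtremes(flat, 0.1), "id order")
  expect_identical(extFlat$high, sprintf("P%02d", 1:4))
  expect_error(selectExtremes(rnorm(5), 0.05), "no participants")
  expect_error(selectExtremes(rnorm(100), 0.6), "fraction")
})
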