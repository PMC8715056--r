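test_that("the assignment solver is optimal against brute force", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(rnorm(n * n), n, n)
    got <- codecomp:::solveAssignment(cost)
    best <- bruteAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]),
                 sum(cost[cbind(seq_len(n), best)]),
                 tolerance = 1e-12)
  }
  # ties: identical costs still give a valid bijection
  tie <- codecomp:::solveAssignment(matrix(1, 4, 4))
  expect_setequal(tie, 1:4)
})

test_that("matching a solution against itself is the identity", {
  ce <- smallCohort(n = 400, seed = 33)
  s <- fitCCA(popZ(volumeMatrix(ce, "DN")), popZ(volumeMatrix(ce, "HC")),
              K = 3)
  mm <- matchModes(s, s)
  expect_identical(mm@permutation, 1:3)
  expect_identical(mm@signs, rep(1, 3))
  expect_lt(max(abs(mm@matchScores - 1)), 1e-12)
})

test_that("a constructed reversal with one negated mode is recovered", {
  ce <- smallCohort(n = 400, seed = 34)
  s <- fitCCA(popZ(volumeMatrix(ce, "DN")), popZ(volumeMatrix(ce, "HC")),
              K = 3)
  cand <- list(V = s@V[, 3:1], U = s@U[, 3:1])
  cand$V[, 2] <- -cand$V[, 2]   # mode 2 of the reversed order
  cand$U[, 2] <- -cand$U[, 2]
  mm <- matchModes(s, cand)
  expect_identical(mm@permutation, c(3L, 2L, 1L))
  expect_identical(mm@signs, c(1, -1, 1))
})

test_that("mode matching inverts arbitrary permutation/sign patterns", {
  ce <- smallCohort(n = 400, p = 12, q = 8, rhos = c(0.7, 0.55, 0.4, 0.25),
                    seed = 35)
  s <- fitCCA(popZ(volumeMatrix(ce, "DN")), popZ(volumeMatrix(ce, "HC")),
              K = 4)
  set.seed(35)
  for (i in 1:25) {
    perm <- sample(4)
    sgn <- sample(c(-1, 1), 4, replace = TRUE)
    cand <- list(V = sweep(s@V[, perm], 2, sgn, "*"),
                 U = sweep(s@U[, perm], 2, sgn, "*"))
    mm <- matchModes(s, cand)
    aligned <- alignSolution(cand, mm)
    expect_lt(max(abs(aligned$V - s@V)), 1e-12)
    expect_lt(max(abs(aligned$U - s@U)), 1e-12)
    # the recovered permutation is the inverse of the applied one
    expect_identical(mm@permutation, order(perm))
  }
})

test_that("matching tolerates weight noise at realistic dimensions", {
  set.seed(36)
  K <- 10; p <- 91; q <- 38
  ok <- replicate(100, {
    V <- matrix(rnorm(p * K), p, K)
    U <- matrix(rnorm(q * K), q, K)
    perm <- sample(K)
    sgn <- sample(c(-1, 1), K, replace = TRUE)
    noise <- function(m) m + rnorm(length(m), 0, 0.1 * sd(m))
    cand <- list(V = noise(sweep(V[, perm], 2, sgn, "*")),
                 U = noise(sweep(U[, perm], 2, sgn, "*")))
    mm <- matchModes(list(V = V, U = U), cand)
    identical(mm@permutation, order(perm))
  })
  expect_gte(mean(ok), 0.95)
})

test_that("bootstrap contrasts are reproducible and validated", {
  ce <- deconfound(smallCohort(n = 600, seed = 37, lonelyFraction = 0.5))
  c1 <- bootstrapContrast(ce, K = 2, nBoot = 20, seed = 5)
  c2 <- bootstrapContrast(ce, K = 2, nBoot = 20, seed = 5)
  expect_identical(hitMatrix(c1), hitMatrix(c2))
  expect_identical(c1@diffs, c2@diffs)
  expect_error(bootstrapContrast(ce, K = 2, nBoot = 5, seed = 1), ">= 10")
  tiny <- ce[, 1:30]
  expect_error(bootstrapContrast(tiny, K = 2, nBoot = 20, seed = 1),
               "larger than the feature count")
  expect_error(bootstrapContrast(ce, K = 2, nBoot = 20, seed = 1,
                                 labelColumn = "nope"), "not found")
})

test_that("hits recompute deterministically and shrink with wider intervals", {
  ce <- deconfound(smallCohort(n = 600, seed = 38, lonelyFraction = 0.5))
  ctr <- bootstrapContrast(ce, K = 2, nBoot = 40, seed = 6)
  same <- recomputeHits(ctr)
  expect_identical(hitMatrix(same), hitMatrix(ctr))
  wider <- recomputeHits(ctr, probs = c(0.05, 0.95))
  expect_true(all(hitMatrix(wider) <= hitMatrix(ctr)))
  expect_lte(sum(hitMatrix(wider)), sum(hitMatrix(ctr)))
})

test_that("hit summaries count and percentage correctly", {
  fi <- data.frame(
    subregion = c(paste0("dn", 1:8), paste0("hc", 1:4)),
    block = rep(c("DN", "HC"), c(8, 4)),
    grouping = c(rep(c("temporal", "PFC", "parietal", "PCC-RSC"), 2),
                 rep(c("CA1", "subiculum"), 2)))
  flags <- matrix(FALSE, 3, 12)
  s0 <- summarizeHits(flags, fi)
  expect_true(all(s0$perMode$hits_total == 0))
  expect_true(all(s0$perBlock$hits == 0))
  flags[1, 1:6] <- TRUE   # 6 DN hits in mode 1
  flags[2, 9] <- TRUE     # 1 HC hit in mode 2
  s1 <- summarizeHits(flags, fi)
  expect_equal(s1$perMode$hits_dn, c(6, 0, 0))
  expect_equal(s1$perMode$hits_hc, c(0, 1, 0))
  expect_equal(s1$perBlock$hits[s1$perBlock$block == "DN"], 6)
  pg <- s1$perGrouping
  expect_equal(sum(pg$pct_of_block_hits[pg$block == "DN"]), 100)
  fiBad <- fi
  fiBad$grouping[1] <- "occipital"
  expect_error(summarizeHits(flags, fiBad), "unknown anatomical grouping")
})
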