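test_that("the packaged atlas has the expected cardinalities and labels", {
  atlas <- loadAtlas()
  expect_identical(nrow(atlas@hc), 38L)
  expect_identical(nrow(atlas@dn), 91L)
  expect_false(anyNA(atlas@dn$grouping))
  expect_true(all(atlas@dn$grouping %in%
                    c("temporal", "PFC", "parietal", "PCC-RSC")))
  expect_false(anyDuplicated(atlas@hc$name) > 0)
  expect_match(atlas@dnVersion, "reconstruction")
})

test_that("full-dimension cohorts carry atlas names and groupings", {
  ce <- generateCohort(simSpec(200, plantedRhos = c(0.5, 0.4), seed = 70))
  rd <- SummarizedExperiment::rowData(ce)
  expect_identical(sum(rd$block == "DN"), 91L)
  expect_identical(sum(rd$block == "HC"), 38L)
  expect_false(anyNA(rd$grouping))
})

test_that("cohort tables round-trip through the TSV interchange format", {
  ce <- smallCohort(n = 60, seed = 71)
  dir <- withr::local_tempdir()
  writeCohort(ce, dir)
  back <- readCohort(dir)
  expect_equal(volumeMatrix(back), volumeMatrix(ce), tolerance = 1e-8)
  expect_identical(
    as.integer(SummarizedExperiment::colData(back)$lonely),
    as.integer(SummarizedExperiment::colData(ce)$lonely))
  expect_identical(SummarizedExperiment::rowData(back)$block,
                   SummarizedExperiment::rowData(ce)$block)
})

test_that("CCA solutions serialize to a TSV directory with metadata", {
  ce <- smallCohort(n = 300, seed = 72)
  s <- fitCCA(popZ(volumeMatrix(ce, "DN")), popZ(volumeMatrix(ce, "HC")),
              K = 2)
  dir <- withr::local_tempdir()
  writeCCASolution(s, dir)
  expect_true(all(file.exists(file.path(
    dir, c("V.tsv", "U.tsv", "rhos.tsv", "metadata.yaml")))))
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  expect_identical(meta$K, 2L)
  rhos <- utils::read.delim(file.path(dir, "rhos.tsv"))
  expect_equal(rhos$rho, s@rhos, tolerance = 1e-12)
})

test_that("the pipeline runs end to end, reproducibly, on a demo cohort", {
  cfg <- runConfig(
    simSpec(900, pDN = 10, qHC = 7, plantedRhos = c(0.7, 0.5, 0.3),
            lonelyFraction = 0.4, seed = 73,
            snpSpec = list(n_snps = 150L, causal_fraction = 0.2)),
    K = 3, nBoot = 20, extremeFraction = 0.2, seed = 5)
  dir <- withr::local_tempdir()
  res <- suppressWarnings(suppressMessages(
    runPipeline(cfg, outDir = dir)))
  expect_length(canonicalCorrelations(res$cca), 3)
  expect_s4_class(res$contrast, "ContrastResult")
  expect_true(is.data.frame(res$hitSummary$perMode))
  expect_named(res$heritability, c("HC", "DN"))
  expect_true(all(file.exists(file.path(
    dir, c("provenance.yaml", "hits.tsv", "report_rhos.tsv",
           "heritability_HC.tsv")))))
  res2 <- suppressWarnings(suppressMessages(runPipeline(cfg)))
  expect_identical(hitMatrix(res$contrast), hitMatrix(res2$contrast))
  expect_identical(canonicalCorrelations(res$cca),
                   canonicalCorrelations(res2$cca))
})

test_that("configuration problems are caught before any compute", {
  cfg <- runConfig(simSpec(300, pDN = 6, qHC = 4, plantedRhos = 0.5,
                           seed = 74),
                   K = 2, nBoot = 10, labelColumn = "absent_column",
                   stages = "cca")
  expect_error(suppressMessages(runPipeline(cfg)), "absent_column")
  bad <- runConfig(simSpec(300, seed = 1), stages = "frobnicate")
  expect_error(runPipeline(bad), "unknown stage")
  cfgDep <- runConfig(simSpec(600, pDN = 6, qHC = 4, plantedRhos = 0.5,
                              seed = 75),
                      K = 2, nBoot = 10, stages = "contrast")
  expect_error(suppressMessages(runPipeline(cfgDep)), "requires the cca")
})

test_that("YAML run configurations load through the same constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    simSpec = list(nParticipants = 150, pDN = 6, qHC = 4,
                   plantedRhos = c(0.6, 0.4), seed = 11),
    K = 2, nBoot = 15, stages = list("deconfound", "cca")), path)
  cfg <- readRunConfig(path)
  expect_s4_class(cfg$simSpec, "SimSpec")
  expect_identical(cfg$K, 2L)
  expect_identical(unlist(cfg$stages), c("deconfound", "cca"))
})
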