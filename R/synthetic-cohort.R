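#' Build a simulation specification
#'
#' Constructor with the study-scale defaults: 91 default-network parcels,
#' 38 hippocampal subfields, and planted canonical correlations matching
#' the leading mode strengths the analysis is designed to recover.
#'
#' The generative model is a shared-latent linear factor model. For mode
#' \eqn{l}, unit-variance latent scores \eqn{z_{x,l}} and \eqn{z_{y,l}}
#' correlate at \eqn{\rho^*_l}; each block is the latent scores times an
#' orthonormal loading matrix plus isotropic Gaussian noise with sd
#' \code{noiseSd}. With that structure the population canonical correlation
#' of mode \eqn{l} is \eqn{\rho^*_l / (1 + \code{noiseSd}^2)} in closed
#' form, so the generator plants \eqn{\rho^*_l = \rho_l (1 +
#' \code{noiseSd}^2)} and the population CCA returns exactly the requested
#' \code{plantedRhos}.
#'
#' @param nParticipants cohort size.
#' @param pDN,qHC block widths (defaults 91 and 38).
#' @param plantedRhos strictly decreasing target canonical correlations in
#'   (0, 1); may be empty for a pure-noise cohort.
#' @param lonelyFraction fraction labelled lonely.
#' @param noiseSd additive feature-noise sd.
#' @param effectMap data.frame (\code{mode}, \code{block}, \code{feature},
#'   \code{shift}) of loading shifts applied to lonely participants only.
#' @param confoundSpec named list of coupling strengths (see Details);
#'   entries you supply override the defaults.
#' @param snpSpec list controlling \code{\link{generateGenotypes}};
#'   entries override defaults \code{n_snps = 600},
#'   \code{causal_fraction = 0.1}, \code{maf_range = c(0.05, 0.5)},
#'   \code{effect_sd = 0.02}, \code{n_gwas = 253295},
#'   \code{link_strength = 1}, \code{ambiguous_fraction = 0.05}.
#' @param seed master seed for all component streams.
#' @return A validated \linkS4class{SimSpec}.
#' @details Confound couplings default to values a population-imaging
#'   cohort would show: strong head-size and age effects, moderate sex and
#'   body-mass effects, weak scanner position/motion/site effects. Set a
#'   coupling to 0 to decouple that confound.
#' @export
simSpec <- function(nParticipants,
                    pDN = 91L, qHC = 38L,
                    plantedRhos = c(0.51, 0.42, 0.39, 0.31, 0.27, 0.23),
                    lonelyFraction = 0.2,
                    noiseSd = 0.5,
                    effectMap = data.frame(mode = integer(), block = character(),
                                           feature = integer(), shift = numeric()),
                    confoundSpec = list(),
                    snpSpec = list(),
                    seed = 1L) {
  conf <- list(age = 0.3, age2 = 0.1, sex = 0.2, sex_age = 0.05,
               sex_age2 = 0.03, bmi = 0.1, head_size = 0.4,
               motion_task = 0.05, motion_rest = 0.05,
               pos_x = 0.02, pos_y = 0.02, pos_z = 0.02, table_pos = 0.02,
               site = 0.1, site_levels = 3L)
  conf[names(confoundSpec)] <- confoundSpec
  snp <- list(n_snps = 600L, causal_fraction = 0.1,
              maf_range = c(0.05, 0.5), effect_sd = 0.02,
              n_gwas = 253295L, link_strength = 1,
              ambiguous_fraction = 0.05)
  snp[names(snpSpec)] <- snpSpec
  new("SimSpec",
      nParticipants = as.integer(nParticipants),
      pDN = as.integer(pDN), qHC = as.integer(qHC),
      plantedRhos = as.numeric(plantedRhos),
      lonelyFraction = lonelyFraction,
      noiseSd = noiseSd,
      effectMap = effectMap,
      confoundSpec = conf,
      snpSpec = snp,
      seed = as.integer(seed))
}

# Simulated raw confound table (untransformed units).
simulateConfounds <- function(n, conf) {
  data.frame(
    age = stats::rnorm(n, 55, 7.5),
    sex = stats::rbinom(n, 1L, 0.48),
    bmi = stats::rnorm(n, 27, 4),
    head_size = stats::rnorm(n, 1500, 120),
    motion_task = exp(stats::rnorm(n, log(0.1), 0.4)),
    motion_rest = exp(stats::rnorm(n, log(0.08), 0.4)),
    pos_x = stats::rnorm(n, 0, 5),
    pos_y = stats::rnorm(n, 0, 5),
    pos_z = stats::rnorm(n, 0, 5),
    table_pos = stats::rnorm(n, 0, 5),
    site = factor(sample(paste0("site", seq_len(conf$site_levels)), n,
                         replace = TRUE))
  )
}

# Numeric coupling design: the 13-term nuisance expansion on the raw
# confounds (z-scored age before squaring; site as indicator columns),
# scaled columnwise by the coupling strengths.
couplingDesign <- function(confounds, conf) {
  zage <- as.vector(scale(confounds$age))
  sx <- confounds$sex
  num <- cbind(age = zage, age2 = zage^2 - mean(zage^2),
               sex = sx - mean(sx),
               sex_age = sx * zage, sex_age2 = sx * zage^2,
               bmi = as.vector(scale(confounds$bmi)),
               head_size = as.vector(scale(confounds$head_size)),
               motion_task = as.vector(scale(confounds$motion_task)),
               motion_rest = as.vector(scale(confounds$motion_rest)),
               pos_x = as.vector(scale(confounds$pos_x)),
               pos_y = as.vector(scale(confounds$pos_y)),
               pos_z = as.vector(scale(confounds$pos_z)),
               table_pos = as.vector(scale(confounds$table_pos)))
  strengths <- unlist(conf[colnames(num)])
  site <- stats::model.matrix(~ site, data = confounds)[, -1, drop = FALSE]
  num <- cbind(sweep(num, 2L, strengths, "*"), site * conf$site)
  num
}

#' Generate a synthetic cohort with planted covariation modes
#'
#' Draws a cohort whose two feature blocks share latent modes at the
#' specified population canonical correlations (see \code{\link{simSpec}}
#' for the closed-form construction), whose lonely subgroup carries the
#' loading shifts in \code{effectMap}, and whose volume columns receive
#' linear confound contributions. Deterministic given \code{spec@seed}.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return A \linkS4class{CohortExperiment}; the \linkS4class{GroundTruth}
#'   sits in \code{metadata(.)$groundTruth}.
#' @examples
#' ce <- generateCohort(simSpec(300, pDN = 10, qHC = 6,
#'                              plantedRhos = c(0.6, 0.4), seed = 7))
#' dim(volumeMatrix(ce))
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nParticipants
  p <- spec@pDN
  q <- spec@qHC
  K <- length(spec@plantedRhos)
  rhoAdj <- spec@plantedRhos * (1 + spec@noiseSd^2)
  if (any(rhoAdj >= 1))
    stop("noiseSd too large for the requested plantedRhos: compensated ",
         "latent correlation would reach ", format(max(rhoAdj)))
  withSeed(spec@seed + .SEED_OFFSETS[["cohort"]], {
    nLonely <- round(n * spec@lonelyFraction)
    lonely <- rep(0L, n)
    lonely[sample.int(n, nLonely)] <- 1L

    confounds <- simulateConfounds(n, spec@confoundSpec)

    if (K > 0) {
      zx <- matrix(stats::rnorm(n * K), n, K)
      eps <- matrix(stats::rnorm(n * K), n, K)
      zy <- sweep(zx, 2L, rhoAdj, "*") +
        sweep(eps, 2L, sqrt(1 - rhoAdj^2), "*")
      A <- randomOrthonormal(p, K)
      B <- randomOrthonormal(q, K)
      X <- zx %*% t(A)
      Y <- zy %*% t(B)
      em <- spec@effectMap
      if (nrow(em)) {
        isL <- lonely == 1L
        for (i in seq_len(nrow(em))) {
          if (em$block[i] == "DN")
            X[isL, em$feature[i]] <- X[isL, em$feature[i]] +
              em$shift[i] * zx[isL, em$mode[i]]
          else
            Y[isL, em$feature[i]] <- Y[isL, em$feature[i]] +
              em$shift[i] * zy[isL, em$mode[i]]
        }
      }
    } else {
      zx <- matrix(numeric(0), n, 0)
      A <- matrix(numeric(0), p, 0)
      B <- matrix(numeric(0), q, 0)
      X <- matrix(0, n, p)
      Y <- matrix(0, n, q)
    }
    X <- X + spec@noiseSd * matrix(stats::rnorm(n * p), n, p)
    Y <- Y + spec@noiseSd * matrix(stats::rnorm(n * q), n, q)

    D <- couplingDesign(confounds, spec@confoundSpec)
    X <- X + D %*% matrix(stats::rnorm(ncol(D) * p), ncol(D), p)
    Y <- Y + D %*% matrix(stats::rnorm(ncol(D) * q), ncol(D), q)

    if (p == 91L && q == 38L) {
      atlas <- loadAtlas()
      featNames <- c(atlas@dn$name, atlas@hc$name)
      grouping <- c(atlas@dn$grouping, atlas@hc$grouping)
    } else {
      featNames <- c(paste0("DN-", seq_len(p)), paste0("HC-", seq_len(q)))
      grouping <- rep(NA_character_, p + q)
    }
    vol <- t(cbind(X, Y))
    rownames(vol) <- featNames
    colnames(vol) <- sprintf("P%05d", seq_len(n))

    truth <- new("GroundTruth",
                 latentScores = zx, loadingsDN = A, loadingsHC = B,
                 trueRhos = spec@plantedRhos, effectMap = spec@effectMap,
                 snpEffects = numeric(0), liability = numeric(0))
    cd <- S4Vectors::DataFrame(confounds, lonely = lonely,
                               row.names = colnames(vol))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(volumes = vol),
      rowData = S4Vectors::DataFrame(
        block = rep(c("DN", "HC"), c(p, q)),
        subregion = featNames, grouping = grouping,
        row.names = featNames),
      colData = cd)
    ce <- new("CohortExperiment", se)
    S4Vectors::metadata(ce)$groundTruth <- truth
    S4Vectors::metadata(ce)$simSpec <- spec
    ce
  })
}

#' @describeIn generateCohort participants-by-features volume matrix;
#'   \code{block} restricts to \code{"DN"} or \code{"HC"} columns.
#' @param x a \linkS4class{CohortExperiment}.
#' @param block optional block tag.
#' @param assayName which assay to return (\code{"cleaned"} after
#'   \code{\link{deconfound}}).
#' @export
setMethod("volumeMatrix", "CohortExperiment",
  function(x, block = NULL, assayName = "volumes") {
    m <- t(SummarizedExperiment::assay(x, assayName))
    if (!is.null(block))
      m <- m[, SummarizedExperiment::rowData(x)$block == block, drop = FALSE]
    m
  })

#' @export
setMethod("groundTruth", "CohortExperiment",
          function(x) S4Vectors::metadata(x)$groundTruth)

setMethod("show", "CohortExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("CohortExperiment:", ncol(object), "participants,",
      sum(rd$block == "DN"), "DN +", sum(rd$block == "HC"), "HC features\n")
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
  if ("lonely" %in% names(SummarizedExperiment::colData(object)))
    cat("lonely:", sum(SummarizedExperiment::colData(object)$lonely), "of",
        ncol(object), "\n")
})

#' Generate genotype dosages and GWAS-style summary statistics
#'
#' Draws independent biallelic loci at uniform minor-allele frequencies; a
#' causal subset receives per-allele effects \eqn{\beta_i \sim N(0,
#' \code{effect_sd})}. Causal dosages are drawn with a per-participant
#' allele-frequency tilt proportional to \eqn{\beta_i} times the designated
#' mode score, so the genetic liability \eqn{G\beta} correlates with mode
#' expressions and the downstream heritability regression has signal to
#' recover. Summary statistics emulate a large discovery GWAS:
#' \eqn{\hat\beta_i = \beta_i + N(0, se_i)} with
#' \eqn{se_i = 1/\sqrt{2 n_{gwas} maf_i (1 - maf_i)}}, p-values from the
#' normal approximation, INFO drawn uniformly on [0.5, 1].
#'
#' @param spec a \linkS4class{SimSpec} (its \code{snpSpec} governs counts
#'   and effect sizes).
#' @param modeScores participants x K matrix of mode expressions (e.g., the
#'   ground-truth latent scores or fitted canonical variates).
#' @param linkModes columns of \code{modeScores} the liability loads on
#'   (default: first column).
#' @return list with \code{dosages} (participants x SNPs, values 0/1/2),
#'   \code{stats} (SNP, A1, A2, BETA, P, MAF, INFO), \code{panel}
#'   (SNP/A1/A2 allele map of the dosage panel), \code{trueBeta}, and
#'   \code{liability} (= dosages \%*\% trueBeta).
#' @export
generateGenotypes <- function(spec, modeScores, linkModes = 1L) {
  validObject(spec)
  ss <- spec@snpSpec
  if (is.null(ss$causal_fraction) || ss$causal_fraction <= 0 ||
      ss$causal_fraction > 1)
    stop("snpSpec$causal_fraction must lie in (0, 1]")
  modeScores <- as.matrix(modeScores)
  n <- nrow(modeScores)
  if (n != spec@nParticipants)
    stop("modeScores rows must match spec@nParticipants")
  m <- as.integer(ss$n_snps)
  withSeed(spec@seed + .SEED_OFFSETS[["genotypes"]], {
    maf <- stats::runif(m, ss$maf_range[1], ss$maf_range[2])
    nCausal <- max(1L, round(ss$causal_fraction * m))
    causal <- sort(sample.int(m, nCausal))
    beta <- numeric(m)
    beta[causal] <- stats::rnorm(nCausal, 0, ss$effect_sd)

    lk <- as.matrix(modeScores[, linkModes, drop = FALSE])
    t_j <- rowSums(scale(lk)) / sqrt(ncol(lk))

    G <- matrix(0L, n, m)
    for (i in seq_len(m)) {
      pr <- maf[i]
      if (beta[i] != 0)
        pr <- pmin(pmax(maf[i] + ss$link_strength * beta[i] * t_j,
                        0.005), 0.995)
      G[, i] <- stats::rbinom(n, 2L, pr)
    }
    ids <- sprintf("rs%06d", seq_len(m))
    dimnames(G) <- list(sprintf("P%05d", seq_len(n)), ids)

    # allele pairs: mostly unambiguous, a small fraction strand-ambiguous
    unamb <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    amb <- rbind(c("A", "T"), c("C", "G"))
    isAmb <- stats::runif(m) < ss$ambiguous_fraction
    pickA <- sample.int(2L, m, replace = TRUE)
    pickU <- sample.int(4L, m, replace = TRUE)
    a1 <- ifelse(isAmb, amb[pickA, 1], unamb[pickU, 1])
    a2 <- ifelse(isAmb, amb[pickA, 2], unamb[pickU, 2])
    flip <- stats::runif(m) < 0.5
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp

    se <- 1 / sqrt(2 * ss$n_gwas * maf * (1 - maf))
    betaHat <- beta + stats::rnorm(m, 0, se)
    pval <- 2 * stats::pnorm(-abs(betaHat / se))
    stats <- data.frame(SNP = ids, A1 = a1, A2 = a2, BETA = betaHat,
                        P = pval, MAF = maf,
                        INFO = stats::runif(m, 0.5, 1),
                        stringsAsFactors = FALSE)
    list(dosages = G, stats = stats,
         panel = stats[, c("SNP", "A1", "A2")],
         trueBeta = stats::setNames(beta, ids),
         liability = as.vector(G %*% beta))
  })
}

#' Generate a synthetic tract target (fornix-FA / accumbens stand-in)
#'
#' Builds \code{y = z(volumes) \%*\% weights + N(0, noiseSd)} from one
#' block of the cohort and returns it z-scored, providing a target with
#' known subregion weights for the block regression analyses.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param weights per-subregion weight vector (length = block width).
#' @param noiseSd sd of the additive Gaussian noise.
#' @param block \code{"HC"} (default) or \code{"DN"}.
#' @param seed optional seed; defaults to the cohort's simulation seed.
#' @return z-scored numeric vector, one value per participant.
#' @export
generateTractTargets <- function(cohort, weights, noiseSd, block = "HC",
                                 seed = NULL) {
  m <- volumeMatrix(cohort, block = block)
  if (length(weights) != ncol(m))
    stop("weights length (", length(weights), ") must equal the ", block,
         " block width (", ncol(m), ")")
  if (is.null(seed)) {
    sp <- S4Vectors::metadata(cohort)$simSpec
    seed <- if (is.null(sp)) 0L else sp@seed
  }
  withSeed(seed + .SEED_OFFSETS[["tract"]], {
    y <- zscoreColumns(m) %*% weights
    if (noiseSd > 0) y <- y + stats::rnorm(nrow(m), 0, noiseSd)
    as.vector(zscoreColumns(y))
  })
}
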