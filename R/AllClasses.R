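#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation specification for a synthetic cohort
#'
#' Describes the generative model of the synthetic cohort: two z-scorable
#' feature blocks (default-network parcels and hippocampal subfields)
#' sharing latent modes at specified population canonical correlations,
#' group-specific loading perturbations for the lonely subgroup, linear
#' confound couplings, and sparse SNP effects on mode expressions.
#'
#' @slot nParticipants number of participants.
#' @slot pDN number of default-network (DN) feature columns.
#' @slot qHC number of hippocampus (HC) feature columns.
#' @slot plantedRhos strictly decreasing target canonical correlations in
#'   (0, 1); the population CCA of the generated blocks equals these values
#'   by construction.
#' @slot lonelyFraction fraction of participants labelled lonely, in (0, 1).
#' @slot noiseSd standard deviation of the additive feature noise; the
#'   generator compensates the latent correlations for the resulting
#'   attenuation so the planted rhos are met exactly at the population level.
#' @slot effectMap data.frame with columns \code{mode}, \code{block}
#'   ("DN"/"HC"), \code{feature}, \code{shift}: additive loading shifts
#'   applied only to lonely participants.
#' @slot confoundSpec named list of linear coupling strengths per confound
#'   term plus \code{site_levels}.
#' @slot snpSpec list with \code{n_snps}, \code{causal_fraction},
#'   \code{maf_range}, \code{effect_sd}, \code{n_gwas},
#'   \code{link_modes}, \code{link_strength}.
#' @slot seed integer master seed; all component streams derive from it.
#' @exportClass SimSpec
setClass("SimSpec",
  representation(
    nParticipants = "integer",
    pDN           = "integer",
    qHC           = "integer",
    plantedRhos   = "numeric",
    lonelyFraction = "numeric",
    noiseSd       = "numeric",
    effectMap     = "data.frame",
    confoundSpec  = "list",
    snpSpec       = "list",
    seed          = "integer"
  )
)

setValidity("SimSpec", function(object) {
  msg <- character()
  r <- object@plantedRhos
  if (length(r)) {
    if (any(r <= 0 | r >= 1))
      msg <- c(msg, "plantedRhos must lie in (0, 1)")
    if (length(r) > 1 && any(diff(r) >= 0))
      msg <- c(msg, "plantedRhos must be strictly decreasing")
    if (length(r) > min(object@pDN, object@qHC))
      msg <- c(msg, "length(plantedRhos) must be <= min(pDN, qHC)")
  }
  if (object@lonelyFraction <= 0 || object@lonelyFraction >= 1)
    msg <- c(msg, "lonelyFraction must lie in (0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  em <- object@effectMap
  if (nrow(em)) {
    need <- c("mode", "block", "feature", "shift")
    if (!all(need %in% names(em)))
      msg <- c(msg, "effectMap needs columns mode, block, feature, shift")
    else {
      if (!all(em$block %in% c("DN", "HC")))
        msg <- c(msg, "effectMap$block must be 'DN' or 'HC'")
      if (any(em$mode < 1 | em$mode > max(1L, length(r))))
        msg <- c(msg, "effectMap$mode out of range of plantedRhos")
      wid <- ifelse(em$block == "DN", object@pDN, object@qHC)
      if (any(em$feature < 1 | em$feature > wid))
        msg <- c(msg, "effectMap$feature out of range for its block")
    }
  }
  ss <- object@snpSpec
  if (length(ss)) {
    mr <- ss$maf_range
    if (!is.null(mr) && (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 ||
                         mr[1] > mr[2]))
      msg <- c(msg, "snpSpec$maf_range must be within (0, 0.5]")
    cf <- ss$causal_fraction
    if (!is.null(cf) && (cf <= 0 || cf > 1))
      msg <- c(msg, "snpSpec$causal_fraction must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort container: participants, volume features, confounds, label
#'
#' A thin extension of \linkS4class{SummarizedExperiment}: the
#' \code{"volumes"} assay holds features (rows) by participants (columns);
#' \code{rowData} carries the block tag (\code{"DN"}/\code{"HC"}), subregion
#' name and anatomical grouping; \code{colData} carries the confounds and
#' the binary \code{lonely} label. Generated cohorts keep their
#' \linkS4class{GroundTruth} in \code{metadata(x)$groundTruth}.
#'
#' @exportClass CohortExperiment
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  if (!"volumes" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'volumes' is required")
  else if (anyNA(SummarizedExperiment::assay(object, "volumes")))
    msg <- c(msg, "volumes must not contain missing values")
  rd <- SummarizedExperiment::rowData(object)
  if (!"block" %in% names(rd))
    msg <- c(msg, "rowData must contain a 'block' column")
  else if (!all(rd$block %in% c("DN", "HC")))
    msg <- c(msg, "block tags must be 'DN' or 'HC'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature (subregion) names must be unique")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a generated cohort
#'
#' @slot latentScores participants x K matrix of shared latent mode scores.
#' @slot loadingsDN,loadingsHC orthonormal loading matrices.
#' @slot trueRhos planted population canonical correlations.
#' @slot effectMap the group loading-shift map used.
#' @slot snpEffects per-SNP true effect sizes (filled by
#'   \code{\link{generateGenotypes}}).
#' @slot liability per-participant genetic liability G beta.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    latentScores = "matrix",
    loadingsDN   = "matrix",
    loadingsHC   = "matrix",
    trueRhos     = "numeric",
    effectMap    = "data.frame",
    snpEffects   = "numeric",
    liability    = "numeric"
  )
)

#' Two-block canonical correlation solution
#'
#' @slot V p x K weight matrix for the first (DN) block.
#' @slot U q x K weight matrix for the second (HC) block.
#' @slot rhos K canonical correlations, non-increasing, in [0, 1].
#' @slot variatesX,variatesY n x K canonical variates (unit variance on the
#'   fitting sample).
#' @slot xCenter,yCenter training column means used by
#'   \code{\link{ccaTransform}}.
#' @slot n,p,q,K dimensions.
#' @exportClass CCASolution
setClass("CCASolution",
  representation(
    V = "matrix", U = "matrix", rhos = "numeric",
    variatesX = "matrix", variatesY = "matrix",
    xCenter = "numeric", yCenter = "numeric",
    n = "integer", p = "integer", q = "integer", K = "integer"
  )
)

setValidity("CCASolution", function(object) {
  msg <- character()
  r <- object@rhos
  if (length(r) != object@K) msg <- c(msg, "length(rhos) != K")
  if (any(r < -1e-12 | r > 1 + 1e-12))
    msg <- c(msg, "rhos must lie in [0, 1]")
  if (length(r) > 1 && any(diff(r) > 1e-10))
    msg <- c(msg, "rhos must be non-increasing")
  if (ncol(object@V) != object@K || ncol(object@U) != object@K)
    msg <- c(msg, "weight matrices must have K columns")
  if (nrow(object@V) != object@p || nrow(object@U) != object@q)
    msg <- c(msg, "weight matrix row counts must equal p and q")
  if (length(msg)) msg else TRUE
})

#' Alignment of one CCA solution to a reference
#'
#' @slot permutation K-vector: reference mode l is matched to candidate
#'   mode \code{permutation[l]}.
#' @slot signs K-vector in \{-1, +1\}.
#' @slot matchScores absolute alignment correlations in [0, 1].
#' @exportClass ModeMatch
setClass("ModeMatch",
  representation(permutation = "integer", signs = "numeric",
                 matchScores = "numeric")
)

setValidity("ModeMatch", function(object) {
  msg <- character()
  K <- length(object@permutation)
  if (!setequal(object@permutation, seq_len(K)))
    msg <- c(msg, "permutation must be a bijection on 1..K")
  if (!all(object@signs %in% c(-1, 1)))
    msg <- c(msg, "signs must be -1 or +1")
  if (any(object@matchScores < -1e-12 | object@matchScores > 1 + 1e-12))
    msg <- c(msg, "matchScores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Bootstrap group-contrast result
#'
#' @slot diffs nBoot x K x (p+q) array of aligned canonical-vector
#'   differences (lonely minus nonlonely).
#' @slot ciLow,ciHigh K x (p+q) percentile bounds.
#' @slot hits K x (p+q) logical flags: interval excludes zero.
#' @slot probs the two percentile probabilities (default 0.1, 0.9).
#' @slot nBoot,seed bookkeeping.
#' @slot featureInfo DataFrame with block/subregion/grouping per feature.
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(
    diffs = "array", ciLow = "matrix", ciHigh = "matrix", hits = "matrix",
    probs = "numeric", nBoot = "integer", seed = "integer",
    featureInfo = "DataFrame"
  )
)

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (any(object@ciLow > object@ciHigh + 1e-12))
    msg <- c(msg, "ciLow must be <= ciHigh everywhere")
  expect <- object@ciLow > 0 | object@ciHigh < 0
  if (!identical(as.vector(expect), as.vector(object@hits)))
    msg <- c(msg, "hits must equal (0 not in [ciLow, ciHigh])")
  if (length(msg)) msg else TRUE
})

#' Polygenic-score model
#'
#' @slot includedSnps SNP ids entering the score at the chosen threshold.
#' @slot thresholdP p-value inclusion threshold.
#' @slot scores named per-participant scores.
#' @slot stats the quality-controlled summary-statistics table used.
#' @exportClass PRSModel
setClass("PRSModel",
  representation(includedSnps = "character", thresholdP = "numeric",
                 scores = "numeric", stats = "data.frame")
)

setValidity("PRSModel", function(object) {
  msg <- character()
  if (!all(object@includedSnps %in% object@stats$SNP))
    msg <- c(msg, "includedSnps must be a subset of the QC-passing SNPs")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Bayesian mode-heritability regression fit
#'
#' @slot draws \code{coda::mcmc.list} of posterior draws (one element per
#'   chain); columns are the mode coefficients followed by the four
#'   sex-specific nuisance terms.
#' @slot summaryTable per-parameter posterior mean, sd, interval.
#' @slot rhat per-parameter potential scale-reduction statistic.
#' @slot chains,drawsPerChain sampler bookkeeping.
#' @slot modeNames names of the mode-coefficient columns.
#' @exportClass HeritabilityModel
setClass("HeritabilityModel",
  representation(
    draws = "ANY", summaryTable = "data.frame", rhat = "numeric",
    chains = "integer", drawsPerChain = "integer", modeNames = "character"
  )
)

setValidity("HeritabilityModel", function(object) {
  if (length(object@rhat) &&
      !all(names(object@rhat) %in% object@summaryTable$parameter))
    "rhat must cover the summarized parameters" else TRUE
})

#' Subregion atlas specification
#'
#' @slot hc data.frame of 38 hippocampal subfield entries (name, hemisphere,
#'   division, grouping).
#' @slot dn data.frame of 91 default-network parcel entries (name,
#'   hemisphere, grouping in temporal/PFC/parietal/PCC-RSC).
#' @slot hcVersion,dnVersion version tags of the two schemes.
#' @exportClass AtlasSpec
setClass("AtlasSpec",
  representation(hc = "data.frame", dn = "data.frame",
                 hcVersion = "character", dnVersion = "character")
)

setValidity("AtlasSpec", function(object) {
  msg <- character()
  if (nrow(object@hc) != 38L) msg <- c(msg, "atlas must have 38 HC entries")
  if (nrow(object@dn) != 91L) msg <- c(msg, "atlas must have 91 DN entries")
  if (!all(c("name", "hemisphere", "grouping") %in% names(object@dn)) ||
      anyNA(object@dn$grouping) ||
      !all(object@dn$grouping %in% c("temporal", "PFC", "parietal", "PCC-RSC")))
    msg <- c(msg, "every DN entry needs a grouping in temporal/PFC/parietal/PCC-RSC")
  if (length(msg)) msg else TRUE
})

#' Block regression result
#'
#' Multiple regression of one z-scored target on all subregion volumes of a
#' block, together with the pairwise Pearson companion profile.
#'
#' @slot coefficients per-subregion partial slopes (z-units).
#' @slot intercept fitted intercept.
#' @slot rSquared coefficient of determination.
#' @slot pairwiseR per-subregion marginal Pearson correlations.
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(coefficients = "numeric", intercept = "numeric",
                 rSquared = "numeric", pairwiseR = "numeric")
)

setValidity("RegressionResult", function(object) {
  msg <- character()
  if (length(object@pairwiseR) &&
      any(abs(object@pairwiseR) > 1 + 1e-12))
    msg <- c(msg, "pairwiseR entries must lie in [-1, 1]")
  if (length(object@pairwiseR) &&
      length(object@coefficients) != length(object@pairwiseR))
    msg <- c(msg, "coefficient count must equal block width")
  if (length(msg)) msg else TRUE
})
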