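# Bootstrap group-contrast machinery: mode matching, per-group CCA
# resampling, percentile-interval hit detection, hit summaries.

.weightsOf <- function(x) {
  if (is(x, "CCASolution")) rbind(x@V, x@U)
  else rbind(as.matrix(x$V), as.matrix(x$U))
}

#' Match the modes of one CCA solution to a reference
#'
#' CCA mode order and sign are not identified across fits, so two
#' solutions must be aligned before their canonical vectors can be
#' compared. This builds the K x K matrix of Pearson correlations between
#' the concatenated canonical-vector pairs \eqn{[v_l; u_l]} of reference
#' and candidate, solves the assignment problem maximizing total absolute
#' correlation (Hungarian method, optimal rather than greedy), and takes
#' each matched correlation's sign as the reflection to apply. A matched
#' correlation of exactly zero gets sign +1; assignment ties resolve to
#' the lower candidate index.
#'
#' @param reference,candidate \linkS4class{CCASolution} objects (or lists
#'   with elements \code{V}, \code{U}) with equal p, q and K.
#' @return A \linkS4class{ModeMatch}: reference mode l corresponds to
#'   candidate mode \code{permutation[l]} after multiplying by
#'   \code{signs[l]}.
#' @export
matchModes <- function(reference, candidate) {
  wr <- .weightsOf(reference)
  wc <- .weightsOf(candidate)
  if (!all(dim(wr) == dim(wc)))
    stop("reference and candidate dimensions (p, q, K) must match")
  K <- ncol(wr)
  M <- stats::cor(wr, wc)
  perm <- solveAssignment(-abs(M))
  sgn <- vapply(seq_len(K), function(l) {
    s <- sign(M[l, perm[l]])
    if (s == 0) 1 else s
  }, numeric(1))
  new("ModeMatch", permutation = as.integer(perm), signs = sgn,
      matchScores = vapply(seq_len(K),
                           function(l) abs(M[l, perm[l]]), numeric(1)))
}

#' Apply a mode match to a candidate solution
#'
#' Reorders and reflects the candidate's weight matrices (and canonical
#' correlations) so its modes line up with the reference that produced
#' \code{match}.
#'
#' @param candidate \linkS4class{CCASolution} or list with \code{V},
#'   \code{U} and optionally \code{rhos}.
#' @param match a \linkS4class{ModeMatch}.
#' @return list with aligned \code{V}, \code{U} and \code{rhos} (if
#'   available).
#' @export
alignSolution <- function(candidate, match) {
  V <- if (is(candidate, "CCASolution")) candidate@V else as.matrix(candidate$V)
  U <- if (is(candidate, "CCASolution")) candidate@U else as.matrix(candidate$U)
  rhos <- if (is(candidate, "CCASolution")) candidate@rhos else candidate$rhos
  p <- match@permutation
  out <- list(V = sweep(V[, p, drop = FALSE], 2L, match@signs, "*"),
              U = sweep(U[, p, drop = FALSE], 2L, match@signs, "*"))
  if (!is.null(rhos)) out$rhos <- rhos[p]
  out
}

#' Bootstrap group-difference test on canonical vectors
#'
#' The central inferential procedure: in each of \code{nBoot} bootstrap
#' iterations, each group (lonely / nonlonely) is resampled with
#' replacement at its own size and one CCA is fitted per group; both group
#' solutions are aligned (order and sign) to the full-cohort reference
#' fit via \code{\link{matchModes}}; the aligned canonical vectors are
#' subtracted elementwise (lonely minus nonlonely) for every mode and
#' subregion. After all iterations the 10th/90th empirical percentiles
#' (linear interpolation) of each (mode, subregion) difference
#' distribution are computed and a subregion is flagged a \emph{hit} when
#' that interval excludes zero.
#'
#' Alignment to a common full-cohort reference (rather than only matching
#' the two group solutions to each other) keeps mode identity stable
#' across iterations so differences can be aggregated mode by mode.
#'
#' @param cohort a deconfounded \linkS4class{CohortExperiment} (the
#'   \code{"cleaned"} assay is used when present).
#' @param K number of modes.
#' @param nBoot bootstrap iterations (>= 10; default 100).
#' @param seed integer seed controlling all resampling.
#' @param probs the two percentile probabilities (default \code{c(0.1,
#'   0.9)}).
#' @param labelColumn name of the binary group label in \code{colData}.
#' @return A \linkS4class{ContrastResult}.
#' @export
bootstrapContrast <- function(cohort, K = 25L, nBoot = 100L, seed = 1L,
                              probs = c(0.1, 0.9), labelColumn = "lonely") {
  stopifnot(is(cohort, "CohortExperiment"))
  if (nBoot < 10L)
    stop("nBoot must be >= 10 for the stated percentile interval")
  cd <- SummarizedExperiment::colData(cohort)
  if (!labelColumn %in% names(cd))
    stop("label column '", labelColumn, "' not found")
  label <- as.integer(cd[[labelColumn]])
  assayName <- if ("cleaned" %in% SummarizedExperiment::assayNames(cohort))
    "cleaned" else "volumes"
  X <- volumeMatrix(cohort, block = "DN", assayName = assayName)
  Y <- volumeMatrix(cohort, block = "HC", assayName = assayName)
  p <- ncol(X)
  q <- ncol(Y)
  g1 <- which(label == 1L)
  g0 <- which(label == 0L)
  if (length(g1) <= p + q || length(g0) <= p + q)
    stop("both groups must be larger than the feature count p + q = ", p + q,
         " (sizes: ", length(g1), ", ", length(g0), ")")
  reference <- fitCCA(rbind(X[g1, ], X[g0, ]), rbind(Y[g1, ], Y[g0, ]), K)
  featNames <- c(colnames(X), colnames(Y))
  diffs <- array(NA_real_, dim = c(nBoot, K, p + q),
                 dimnames = list(NULL, paste0("mode", seq_len(K)), featNames))
  withSeed(seed + .SEED_OFFSETS[["bootstrap"]], {
    for (b in seq_len(nBoot)) {
      i1 <- g1[sample.int(length(g1), replace = TRUE)]
      i0 <- g0[sample.int(length(g0), replace = TRUE)]
      s1 <- fitCCA(X[i1, , drop = FALSE], Y[i1, , drop = FALSE], K)
      s0 <- fitCCA(X[i0, , drop = FALSE], Y[i0, , drop = FALSE], K)
      a1 <- alignSolution(s1, matchModes(reference, s1))
      a0 <- alignSolution(s0, matchModes(reference, s0))
      diffs[b, , ] <- t(rbind(a1$V, a1$U) - rbind(a0$V, a0$U))
    }
  })
  ci <- apply(diffs, c(2L, 3L), stats::quantile, probs = probs,
              names = FALSE, type = 7)
  ciLow <- matrix(ci[1L, , ], K, p + q,
                  dimnames = dimnames(diffs)[2:3])
  ciHigh <- matrix(ci[2L, , ], K, p + q,
                   dimnames = dimnames(diffs)[2:3])
  rd <- SummarizedExperiment::rowData(cohort)
  fi <- S4Vectors::DataFrame(
    subregion = featNames,
    block = rep(c("DN", "HC"), c(p, q)),
    grouping = rd$grouping[match(featNames, rownames(cohort))])
  new("ContrastResult", diffs = diffs,
      ciLow = ciLow, ciHigh = ciHigh,
      hits = ciLow > 0 | ciHigh < 0,
      probs = probs, nBoot = as.integer(nBoot), seed = as.integer(seed),
      featureInfo = fi)
}

#' Recompute percentile intervals and hit flags from stored differences
#'
#' Hits are a deterministic function of the difference array; this
#' recomputes them, optionally at different percentiles (widening the
#' interval can only remove hits).
#'
#' @param result a \linkS4class{ContrastResult}.
#' @param probs percentile pair.
#' @return a new \linkS4class{ContrastResult} with updated intervals.
#' @export
recomputeHits <- function(result, probs = result@probs) {
  ci <- apply(result@diffs, c(2L, 3L), stats::quantile, probs = probs,
              names = FALSE, type = 7)
  dm <- dim(result@diffs)[2:3]
  lo <- matrix(ci[1L, , ], dm[1], dm[2], dimnames = dimnames(result@hits))
  hi <- matrix(ci[2L, , ], dm[1], dm[2], dimnames = dimnames(result@hits))
  initialize(result, ciLow = lo, ciHigh = hi,
             hits = lo > 0 | hi < 0, probs = probs)
}

#' @describeIn bootstrapContrast K x (p+q) logical hit matrix.
#' @param x a \linkS4class{ContrastResult}.
#' @export
setMethod("hitMatrix", "ContrastResult", function(x) x@hits)

setMethod("show", "ContrastResult", function(object) {
  fi <- object@featureInfo
  cat("ContrastResult:", object@nBoot, "bootstrap iterations,",
      nrow(object@hits), "modes x", ncol(object@hits), "subregions\n")
  cat("interval:", paste(object@probs * 100, collapse = "/"),
      "% percentiles; hits:", sum(object@hits[, fi$block == "HC"]), "HC,",
      sum(object@hits[, fi$block == "DN"]), "DN\n")
})

#' Long-format hit table
#'
#' @param result a \linkS4class{ContrastResult}.
#' @param onlyHits keep only flagged rows.
#' @return data.frame with mode, block, subregion, ci_low, ci_high, hit.
#' @export
hitTable <- function(result, onlyHits = FALSE) {
  K <- nrow(result@hits)
  fi <- as.data.frame(result@featureInfo)
  out <- data.frame(
    mode = rep(seq_len(K), times = ncol(result@hits)),
    block = rep(fi$block, each = K),
    subregion = rep(fi$subregion, each = K),
    ci_low = as.vector(result@ciLow),
    ci_high = as.vector(result@ciHigh),
    hit = as.vector(result@hits))
  if (onlyHits) out <- out[out$hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize hit counts per mode, subregion, block and anatomical grouping
#'
#' Tabulates the flagged subregions of a contrast: counts per mode, per
#' subregion (across modes), per block, and per anatomical grouping
#' (temporal / PFC / parietal / PCC-RSC for the DN; named subfields for
#' the HC), with percentage breakdowns always recomputed from the table's
#' own counts.
#'
#' @param result a \linkS4class{ContrastResult} (or a logical K x (p+q)
#'   matrix of flags, in which case \code{featureInfo} must be supplied).
#' @param featureInfo data.frame with \code{subregion}, \code{block},
#'   \code{grouping} per feature; defaults to the result's own metadata.
#' @return list of data.frames: \code{perMode}, \code{perSubregion},
#'   \code{perBlock}, \code{perGrouping}.
#' @export
summarizeHits <- function(result, featureInfo = NULL) {
  if (is(result, "ContrastResult")) {
    hits <- result@hits
    if (is.null(featureInfo)) featureInfo <- as.data.frame(result@featureInfo)
  } else {
    hits <- as.matrix(result)
    if (is.null(featureInfo))
      stop("featureInfo is required when passing a raw flag matrix")
  }
  featureInfo <- as.data.frame(featureInfo)
  stopifnot(nrow(featureInfo) == ncol(hits))
  dnGroups <- c("temporal", "PFC", "parietal", "PCC-RSC")
  badDN <- featureInfo$block == "DN" & !is.na(featureInfo$grouping) &
    !featureInfo$grouping %in% dnGroups
  if (any(badDN))
    stop("unknown anatomical grouping label(s): ",
         paste(unique(featureInfo$grouping[badDN]), collapse = ", "))
  K <- nrow(hits)
  isDN <- featureInfo$block == "DN"
  perMode <- data.frame(
    mode = seq_len(K),
    hits_dn = rowSums(hits[, isDN, drop = FALSE]),
    hits_hc = rowSums(hits[, !isDN, drop = FALSE]))
  perMode$hits_total <- perMode$hits_dn + perMode$hits_hc
  perSubregion <- data.frame(
    subregion = featureInfo$subregion,
    block = featureInfo$block,
    grouping = featureInfo$grouping,
    hits = colSums(hits))
  blockTotals <- tapply(perSubregion$hits, perSubregion$block, sum)
  perBlock <- data.frame(block = names(blockTotals),
                         hits = as.integer(blockTotals),
                         row.names = NULL)
  perGrouping <- NULL
  if (!all(is.na(featureInfo$grouping))) {
    agg <- stats::aggregate(hits ~ block + grouping, data = perSubregion,
                            FUN = sum)
    tot <- as.numeric(blockTotals[agg$block])
    agg$pct_of_block_hits <- as.numeric(ifelse(tot > 0,
                                               100 * agg$hits / tot, 0))
    perGrouping <- agg[order(agg$block, -agg$hits), , drop = FALSE]
    rownames(perGrouping) <- NULL
  }
  list(perMode = perMode, perSubregion = perSubregion,
       perBlock = perBlock, perGrouping = perGrouping)
}
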