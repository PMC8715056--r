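#' @include AllClasses.R
NULL

#' @export
setGeneric("canonicalCorrelations",
           function(x, ...) standardGeneric("canonicalCorrelations"))

#' @export
setGeneric("canonicalWeights",
           function(x, side = c("DN", "HC"), ...)
             standardGeneric("canonicalWeights"))

#' @export
setGeneric("modeExpressions",
           function(x, side = c("DN", "HC"), ...)
             standardGeneric("modeExpressions"))

#' @export
setGeneric("volumeMatrix", function(x, block = NULL, ...)
  standardGeneric("volumeMatrix"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("hitMatrix", function(x) standardGeneric("hitMatrix"))

#' @export
setGeneric("prsScores", function(x) standardGeneric("prsScores"))

#' @export
setGeneric("includedSnps", function(x) standardGeneric("includedSnps"))

#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @export
setGeneric("scaleReduction", function(x) standardGeneric("scaleReduction"))
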