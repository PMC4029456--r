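#' @export
setGeneric("trainModel", function(spec, data, ...)
  standardGeneric("trainModel"))

#' @export
setGeneric("predictScores", function(model, newdata, ...)
  standardGeneric("predictScores"))

#' @export
setGeneric("decisionThreshold", function(model)
  standardGeneric("decisionThreshold"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @export
setGeneric("subsetFeatures", function(x, set, ...)
  standardGeneric("subsetFeatures"))

#' @export
setGeneric("meanAuc", function(x) standardGeneric("meanAuc"))

#' @export
setGeneric("sdAuc", function(x) standardGeneric("sdAuc"))

#' @export
setGeneric("meanError", function(x) standardGeneric("meanError"))

#' @export
setGeneric("sdError", function(x) standardGeneric("sdError"))

#' @export
setGeneric("importanceDecisions", function(x) standardGeneric("importanceDecisions"))

#' @export
setGeneric("importanceZ", function(x) standardGeneric("importanceZ"))

#' @export
setGeneric("expectedFalseDiscoveries", function(x)
  standardGeneric("expectedFalseDiscoveries"))

#' @export
setGeneric("trackValues", function(x, chrom) standardGeneric("trackValues"))

#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @export
setGeneric("pwmId", function(x) standardGeneric("pwmId"))

#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
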