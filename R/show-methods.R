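setMethod("show", "SignalTrack", function(object) {
  nw <- sum(lengths(object@values))
  cat(sprintf("SignalTrack '%s': %d-bp windows, %d windows on %d chromosome(s)\n",
              object@mark, object@window, nw, length(object@values)))
})

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM '%s': %d positions\n", object@id, nrow(object@matrix)))
})

setMethod("show", "EnhancerFeatureSet", function(object) {
  lab <- table(regionLabels(object))
  tag <- S4Vectors::metadata(object)$featureSet
  cat(sprintf("EnhancerFeatureSet: %d regions (%d positive, %d negative) x %d features%s\n",
              nrow(object), lab[["positive"]], lab[["negative"]],
              ncol(object),
              if (!is.null(tag) && !is.na(tag)) sprintf(" [%s]", tag) else ""))
  types <- table(featureType(object))
  cat("  feature types:",
      paste(sprintf("%s=%d", names(types), types), collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec kind='%s' (seed %d)\n", object@kind, object@seed))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("%s-fold %scross-validation, %s model [%s]\n", object@k,
              if (object@reversed) "reversed " else "", object@modelKind,
              object@featureSetTag))
  cat(sprintf("  AUC   %.3f +/- %.3f\n", meanAuc(object), sdAuc(object)))
  cat(sprintf("  error %.3f +/- %.3f\n", meanError(object), sdError(object)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d chromosome(s) (%s bp), %d enhancers, %d motifs, %d marks\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ","),
              length(object@positives), length(object@pwms),
              length(object@tracks)))
  cat("  drivers:", paste(object@truth$driverMotifs, collapse = ", "), "\n")
  cat("  informative marks:",
      paste(object@truth$informativeMarks, collapse = ", "), "\n")
})

setMethod("show", "ImportanceReport", function(object) {
  dec <- table(object@decisions)
  cat(sprintf("ImportanceReport over %d repetitions: %d confirmed, %d rejected, %d tentative\n",
              object@nRepetitions, dec[["confirmed"]], dec[["rejected"]],
              dec[["tentative"]]))
  cat(sprintf("  expected false discoveries per repetition: %.2f\n",
              object@expectedFalseDiscoveries))
})
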