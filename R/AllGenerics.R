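#' Accessors for causalTF classes
#'
#' Small accessor generics so slots never need to be touched directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edgeKind", function(x) standardGeneric("edgeKind"))

#' @rdname accessors
#' @export
setGeneric("edgeRecords", function(x) standardGeneric("edgeRecords"))

#' @rdname accessors
#' @export
setGeneric("tfRoster", function(x) standardGeneric("tfRoster"))

#' @rdname accessors
#' @export
setGeneric("transcriptionEdges", function(x) standardGeneric("transcriptionEdges"))

#' @rdname accessors
#' @export
setGeneric("modificationEdges", function(x) standardGeneric("modificationEdges"))

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname accessors
#' @export
setGeneric("geneProduct", function(x) standardGeneric("geneProduct"))

#' @rdname accessors
#' @export
setGeneric("degGenes", function(x) standardGeneric("degGenes"))

#' @rdname accessors
#' @export
setGeneric("degCriterion", function(x) standardGeneric("degCriterion"))

#' @rdname accessors
#' @export
setGeneric("measuredUniverse", function(x) standardGeneric("measuredUniverse"))

#' @rdname accessors
#' @export
setGeneric("focalTF", function(x) standardGeneric("focalTF"))

#' @rdname accessors
#' @export
setGeneric("modelSets", function(x) standardGeneric("modelSets"))

#' @rdname accessors
#' @export
setGeneric("modelMediators", function(x) standardGeneric("modelMediators"))

#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname accessors
#' @export
setGeneric("acceptabilityTable", function(x) standardGeneric("acceptabilityTable"))

#' @rdname accessors
#' @export
setGeneric("isAcceptable", function(x) standardGeneric("isAcceptable"))

setMethod("edgeKind", "EdgeTable", function(x) x@kind)
setMethod("edgeRecords", "EdgeTable", function(x) x@records)

setMethod("tfRoster", "RegulatoryNetwork", function(x) x@tfRoster)
setMethod("transcriptionEdges", "RegulatoryNetwork", function(x) x@transcription)
setMethod("modificationEdges", "RegulatoryNetwork", function(x) x@modification)
setMethod("geneProduct", "RegulatoryNetwork", function(x) x@geneProduct)

setMethod("geneUniverse", "RegulatoryNetwork", function(x) {
  unique(x@transcription$target)
})

setMethod("degGenes", "DEGSet", function(x) x@genes)
setMethod("degCriterion", "DEGSet", function(x) x@criterion)
setMethod("measuredUniverse", "DEGSet", function(x) x@measuredUniverse)

setMethod("focalTF", "DownstreamSets", function(x) x@tf)
setMethod("modelSets", "DownstreamSets", function(x) x@sets)
setMethod("modelMediators", "DownstreamSets", function(x) x@mediators)

setMethod("focalTF", "EnrichmentResult", function(x) x@tf)
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)

setMethod("acceptabilityTable", "ModelAcceptability", function(x) x@table)
setMethod("isAcceptable", "ModelAcceptability", function(x) {
  stats::setNames(x@table$acceptable, x@table$model)
})

setMethod("show", "EdgeTable", function(object) {
  cat(sprintf("EdgeTable (%s) with %d record(s)\n",
              object@kind, nrow(object@records)))
  if (nrow(object@records))
    print(utils::head(object@records, 5L), row.names = FALSE)
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork\n",
      sprintf("  TFs:                 %d\n", length(object@tfRoster)),
      sprintf("  transcription edges: %d\n", nrow(object@transcription)),
      sprintf("  modification edges:  %d\n", nrow(object@modification)),
      sprintf("  gene universe:       %d\n",
              length(unique(object@transcription$target))), sep = "")
})

setMethod("show", "DEGSet", function(object) {
  cat(sprintf("DEGSet with %d gene(s)", length(object@genes)))
  if (length(object@criterion))
    cat(sprintf(" [%s %s %s]", object@criterion$statistic,
                object@criterion$direction, object@criterion$threshold))
  if (length(object@measuredUniverse))
    cat(sprintf(", measured universe %d", length(object@measuredUniverse)))
  cat("\n")
})

setMethod("show", "DownstreamSets", function(object) {
  cat(sprintf("DownstreamSets for TF %s\n", object@tf))
  sizes <- vapply(object@sets[MODEL_IDS], length, integer(1))
  print(sizes)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult for TF %s (n = %d DEGs, N = %d)\n",
              object@tf, object@n, object@N))
  print(object@table, row.names = FALSE)
})

setMethod("show", "ModelAcceptability", function(object) {
  cat(sprintf("ModelAcceptability (alpha = %g)\n", object@alpha))
  print(object@table, row.names = FALSE)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: TP %d, FP %d, FN %d, Jaccard %.3f\n",
              object@tp, object@fp, object@fn, object@jaccard))
  if (length(object@unprofiled))
    cat("  unprofiled (excluded):", paste(object@unprofiled, collapse = ", "), "\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario\n",
      sprintf("  network: %d TFs, %d genes, mean out-degree %g, cascade %g\n",
              object@nTF, object@nGenes, object@meanOutDegree,
              object@cascadeFraction),
      sprintf("  PTM: %d kinase edges, %d modulators\n",
              object@nKinaseEdges, object@nModulators),
      sprintf("  truth: TF '%s' via Model %s; tpr %g, fpr %g; seed %d\n",
              object@trueTF, object@trueModel, object@tpr, object@fpr,
              object@seed), sep = "")
})
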