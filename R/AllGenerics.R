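#' @rdname CoexNetwork-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("netMatrix", function(x) standardGeneric("netMatrix"))

#' @rdname CoexNetwork-class
#' @export
setGeneric("netKind", function(x) standardGeneric("netKind"))

#' @rdname CoexNetwork-class
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))

#' @rdname MergedExpression-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("cellExpr", function(x) standardGeneric("cellExpr"))

#' @rdname MergedExpression-class
#' @export
setGeneric("tumorExpr", function(x) standardGeneric("tumorExpr"))

#' @rdname MergedExpression-class
#' @export
setGeneric("sampleDataset", function(x) standardGeneric("sampleDataset"))

#' @rdname ModuleSet-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleNames", function(x) standardGeneric("moduleNames"))

#' @rdname EigengeneSet-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("eigengeneScores", function(x) standardGeneric("eigengeneScores"))

#' @rdname EigengeneSet-class
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname PreservationStats-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("preservationTable",
           function(x) standardGeneric("preservationTable"))

#' Preserved modules at a Z-summary threshold
#'
#' @param x a [PreservationStats-class] object.
#' @param threshold Z-summary cutoff; modules strictly above it are preserved
#'   (default 5).
#' @return character vector of preserved module names.
#' @export
setGeneric("preservedModules",
           function(x, threshold = 5) standardGeneric("preservedModules"))

#' @rdname DoseResponsePanel-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("panelViability", function(x) standardGeneric("panelViability"))

#' @rdname DoseResponsePanel-class
#' @export
setGeneric("panelResponse", function(x) standardGeneric("panelResponse"))

#' @rdname DoseResponsePanel-class
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname DoseResponsePanel-class
#' @export
setGeneric("removedConcentrations",
           function(x) standardGeneric("removedConcentrations"))

#' @rdname DoseResponsePanel-class
#' @export
setGeneric("panelDrugs", function(x) standardGeneric("panelDrugs"))

#' @rdname DoseResponsePanel-class
#' @export
setGeneric("panelCellLines", function(x) standardGeneric("panelCellLines"))

#' @rdname FingerprintMatrix-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("fingerprintCor", function(x) standardGeneric("fingerprintCor"))

#' @rdname ConsensusClusterResult-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("clusterMembership",
           function(x) standardGeneric("clusterMembership"))

#' @rdname ConsensusClusterResult-class
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname ConsensusClusterResult-class
#' @export
setGeneric("clusterDiagnostics",
           function(x) standardGeneric("clusterDiagnostics"))

#' @rdname ComboPrediction-class
#' @param x a coDrugNet S4 object.
#' @export
setGeneric("comboScore", function(x) standardGeneric("comboScore"))
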