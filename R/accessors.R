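#' @rdname CoexNetwork-class
setMethod("netMatrix", "CoexNetwork", function(x) x@mat)

#' @rdname CoexNetwork-class
setMethod("netKind", "CoexNetwork", function(x) x@kind)

#' @rdname CoexNetwork-class
setMethod("softPower", "CoexNetwork", function(x) x@beta)

setMethod("show", "CoexNetwork", function(object) {
  cat(sprintf("CoexNetwork [%s], %d genes, beta = %s\n",
              object@kind, nrow(object@mat),
              ifelse(is.na(object@beta), "NA", format(object@beta))))
})

#' @rdname MergedExpression-class
setMethod("cellExpr", "MergedExpression", function(x) x@cell)

#' @rdname MergedExpression-class
setMethod("tumorExpr", "MergedExpression", function(x) x@tumor)

#' @rdname MergedExpression-class
setMethod("sampleDataset", "MergedExpression", function(x) {
  setNames(
    rep(c("cell_line", "tumor"), c(ncol(x@cell), ncol(x@tumor))),
    c(colnames(x@cell), colnames(x@tumor))
  )
})

setMethod("show", "MergedExpression", function(object) {
  cat(sprintf(
    "MergedExpression: %d genes; %d cell-line + %d tumor samples (standardized)\n",
    nrow(object@cell), ncol(object@cell), ncol(object@tumor)))
})

#' @rdname ModuleSet-class
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname ModuleSet-class
setMethod("moduleSizes", "ModuleSet", function(x) {
  tab <- table(x@labels)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  grey <- sizes[names(sizes) == "grey"]
  rest <- sizes[names(sizes) != "grey"]
  c(sort(rest, decreasing = TRUE), grey)
})

#' @rdname ModuleSet-class
setMethod("moduleNames", "ModuleSet", function(x) {
  setdiff(names(moduleSizes(x)), "grey")
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat(sprintf("ModuleSet: %d genes, %d modules (+ grey)\n",
              length(object@labels), sum(names(sz) != "grey")))
  print(sz)
})

#' @rdname EigengeneSet-class
setMethod("eigengeneScores", "EigengeneSet", function(x) x@scores)

#' @rdname EigengeneSet-class
setMethod("varianceExplained", "EigengeneSet",
          function(x) x@varianceExplained)

setMethod("show", "EigengeneSet", function(object) {
  cat(sprintf("EigengeneSet: %d modules x %d samples\n",
              nrow(object@scores), ncol(object@scores)))
})

#' @rdname PreservationStats-class
setMethod("preservationTable", "PreservationStats", function(x) x@table)

#' @rdname preservedModules
setMethod("preservedModules", "PreservationStats",
  function(x, threshold = 5) {
    tab <- x@table
    tab$module[!is.na(tab$Zsummary) & tab$Zsummary > threshold]
  })

setMethod("show", "PreservationStats", function(object) {
  cat(sprintf("PreservationStats (%d permutations, seed %s)\n",
              object@nPerm, format(object@seed)))
  print(object@table, row.names = FALSE)
})

#' @rdname DoseResponsePanel-class
setMethod("panelViability", "DoseResponsePanel", function(x) x@viability)

#' @rdname DoseResponsePanel-class
setMethod("panelResponse", "DoseResponsePanel", function(x) x@response)

#' @rdname DoseResponsePanel-class
setMethod("concentrations", "DoseResponsePanel", function(x) x@concentrations)

#' @rdname DoseResponsePanel-class
setMethod("removedConcentrations", "DoseResponsePanel",
          function(x) x@removedConcentrations)

#' @rdname DoseResponsePanel-class
setMethod("panelDrugs", "DoseResponsePanel",
          function(x) dimnames(x@viability)[[1]])

#' @rdname DoseResponsePanel-class
setMethod("panelCellLines", "DoseResponsePanel",
          function(x) dimnames(x@viability)[[2]])

setMethod("show", "DoseResponsePanel", function(object) {
  d <- dim(object@viability)
  cat(sprintf("DoseResponsePanel: %d drugs x %d cell lines x %d concentrations%s\n",
              d[1], d[2], d[3],
              if (length(object@removedConcentrations))
                sprintf(" (trimmed; removed %s)",
                        paste(format(object@removedConcentrations),
                              collapse = ", "))
              else ""))
})

#' @rdname FingerprintMatrix-class
setMethod("fingerprintCor", "FingerprintMatrix", function(x) x@cor)

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d drugs x %d modules (%d cell lines; %d missing entries)\n",
              nrow(object@cor), ncol(object@cor), object@nPoints,
              sum(is.na(object@cor))))
})

#' @rdname ConsensusClusterResult-class
setMethod("clusterMembership", "ConsensusClusterResult",
          function(x) x@membership)

#' @rdname ConsensusClusterResult-class
setMethod("consensusMatrix", "ConsensusClusterResult", function(x) x@consensus)

#' @rdname ConsensusClusterResult-class
setMethod("clusterDiagnostics", "ConsensusClusterResult",
          function(x) x@diagnostics)

setMethod("show", "ConsensusClusterResult", function(object) {
  cat(sprintf("ConsensusClusterResult: %d drugs in k = %d clusters\n",
              length(object@membership), object@k))
  print(table(cluster = object@membership))
})

#' @rdname ComboPrediction-class
setMethod("comboScore", "ComboPrediction", function(x) x@score)

setMethod("show", "ComboPrediction", function(object) {
  cat(sprintf(
    "ComboPrediction %s + %s: IDAcombo score %.3f at (%.4g, %.4g) uM\n  mean combo viability %.2f vs best monotherapy %.2f (%d shared lines)\n",
    object@drugA, object@drugB, object@score,
    object@bestPair[["cA"]], object@bestPair[["cB"]],
    object@meanCombo, object@meanMono, nrow(object@detail)))
})
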