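## gene filtering and dataset merging ahead of network construction

#' Filter genes by raw Mean Absolute Deviation
#'
#' Retains exactly the genes whose unscaled MAD — the median of absolute
#' deviations from the gene's median, with no 1.4826 consistency constant —
#' is strictly greater than `threshold`. The default threshold of 1000 is
#' meant for linear-scale normalized expression units and enriches highly
#' expressed, variable genes; set `log2 = TRUE` to filter on log2(x + 1)
#' values instead when the input is on a linear scale but the threshold is
#' meant for log units.
#'
#' The raw (unscaled) MAD is used deliberately: a threshold stated in
#' expression units would silently select a different gene set if the
#' normal-consistency constant were applied.
#'
#' @param expr genes x samples matrix or `SummarizedExperiment`.
#' @param threshold keep genes with `MAD > threshold` (strict; default 1000).
#' @param log2 filter on `log2(x + 1)` instead of raw values (default FALSE).
#' @return object of the same class as `expr`, subset to surviving genes in
#'   their original order. An empty result triggers a warning; downstream
#'   steps refuse empty matrices.
#' @export
#' @examples
#' m <- rbind(flat = rep(5, 6), spread = c(0, 2000, 4000, 6000, 8000, 10000))
#' colnames(m) <- paste0("s", 1:6)
#' rownames(madFilter(m, 1000))
madFilter <- function(expr, threshold = 1000, log2 = FALSE) {
  if (threshold < 0) stop("threshold must be >= 0")
  mat <- .asExprMatrix(expr)
  vals <- if (log2) base::log2(mat + 1) else mat
  madv <- apply(vals, 1, mad, constant = 1)
  keep <- madv > threshold
  if (!any(keep))
    warning("MAD filter removed every gene; downstream steps will refuse an empty matrix")
  if (methods::is(expr, "SummarizedExperiment")) expr[keep, ] else mat[keep, , drop = FALSE]
}

#' Intersect gene sets and standardize the two expression datasets
#'
#' Restricts both datasets to their shared genes (cell-line order preserved)
#' and standardizes each gene to mean 0 / sd 1 *within* each dataset, the
#' scale on which correlation networks and module eigengenes are computed.
#' By convention the MAD filter is applied to the cell-line matrix before
#' merging and the tumor matrix is simply subset to the survivors.
#'
#' @param cell cell-line expression (matrix or `SummarizedExperiment`),
#'   typically already passed through [madFilter()].
#' @param tumor tumor expression on the same gene-id universe.
#' @param minShared minimum number of shared genes required (default 200).
#' @return a [MergedExpression-class].
#' @export
intersectAndMerge <- function(cell, tumor, minShared = 200) {
  cm <- .asExprMatrix(cell)
  tm <- .asExprMatrix(tumor)
  if (nrow(cm) == 0 || ncol(cm) == 0)
    stop("cell-line matrix is empty (did the MAD filter remove everything?)")
  shared <- intersect(rownames(cm), rownames(tm))
  if (length(shared) < minShared)
    stop(sprintf(
      "only %d shared genes (need >= %d); cell-line universe has %d genes (e.g. %s), tumor universe %d genes (e.g. %s)",
      length(shared), minShared,
      nrow(cm), paste(head(rownames(cm), 3), collapse = ","),
      nrow(tm), paste(head(rownames(tm), 3), collapse = ",")))
  ## keep the cell-line gene order
  shared <- rownames(cm)[rownames(cm) %in% shared]
  new("MergedExpression",
      cell = .stdRows(cm[shared, , drop = FALSE]),
      tumor = .stdRows(tm[shared, , drop = FALSE]))
}
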