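## weighted co-expression network construction

#' Soft-thresholded co-expression adjacency
#'
#' Builds the unsigned weighted adjacency `a_ij = |cor(gene_i, gene_j)|^beta`
#' from a genes x samples matrix. Zero-variance genes get zero adjacency to
#' everything (with a warning); the diagonal is forced to 1.
#'
#' @param expr genes x samples matrix (or `SummarizedExperiment`) with at
#'   least 3 samples.
#' @param beta soft-thresholding power (default 8).
#' @return a [CoexNetwork-class] of kind `"adjacency"`.
#' @export
adjacencyFromExpr <- function(expr, beta = 8) {
  mat <- .asExprMatrix(expr)
  if (ncol(mat) < 3) stop("need >= 3 samples to compute correlations")
  s <- apply(mat, 1, sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad))
    warning(sprintf("zero-variance gene(s) get zero adjacency: %s",
                    paste(rownames(mat)[bad], collapse = ", ")))
  r <- suppressWarnings(cor(t(mat)))
  r[!is.finite(r)] <- 0
  a <- abs(r)^beta
  diag(a) <- 1
  .CoexNetwork(a, "adjacency", beta)
}

#' Topological overlap matrix
#'
#' Converts an adjacency into the (unsigned) topological overlap similarity
#' `w_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, where
#' `L_ij = sum_{u != i,j} a_iu a_uj` counts shared-neighbor weight and
#' `k_i = sum_{u != i} a_iu` is the connectivity. The diagonal is 1. Note TOM
#' is not bounded below by the adjacency in general; it is bounded in
#' \[0, 1\].
#'
#' @param adj a [CoexNetwork-class] of kind `"adjacency"`.
#' @return a [CoexNetwork-class] of kind `"tom"`.
#' @export
tomSimilarity <- function(adj) {
  stopifnot(is(adj, "CoexNetwork"))
  if (netKind(adj) != "adjacency")
    stop("tomSimilarity expects an adjacency-kind network")
  a <- netMatrix(adj)
  k <- rowSums(a) - 1                     # diag is 1
  ## (A %*% A)_ij includes u = i and u = j terms (a_ii = a_jj = 1): subtract 2 a_ij
  L <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  w <- (L + a) / denom
  diag(w) <- 1
  .CoexNetwork(w, "tom", softPower(adj))
}

#' Consensus topological overlap of two datasets
#'
#' Puts the two TOMs on a common scale by multiplying the tumor TOM so that
#' its 95th-percentile off-diagonal entry matches the cell-line TOM's
#' (quantile scaling, capped at 1), then takes the elementwise minimum. An
#' edge is therefore only as strong as its weaker (scaled) dataset supports.
#'
#' @param tomCell,tomTumor [CoexNetwork-class] objects of kind `"tom"` on the
#'   same genes in the same order.
#' @param scaleQuantile quantile used for the scaling (default 0.95).
#' @return a [CoexNetwork-class] of kind `"consensus"`.
#' @export
consensusTOM <- function(tomCell, tomTumor, scaleQuantile = 0.95) {
  stopifnot(is(tomCell, "CoexNetwork"), is(tomTumor, "CoexNetwork"))
  if (netKind(tomCell) != "tom" || netKind(tomTumor) != "tom")
    stop("consensusTOM expects two tom-kind networks")
  a <- netMatrix(tomCell)
  b <- netMatrix(tomTumor)
  if (!identical(rownames(a), rownames(b)))
    stop("node mismatch: the two TOMs must cover the same genes in the same order")
  qa <- quantile(.offDiag(a), scaleQuantile)
  qb <- quantile(.offDiag(b), scaleQuantile)
  if (qb > 0) b <- pmin(b * (qa / qb), 1)
  cons <- pmin(a, b)
  diag(cons) <- 1
  .CoexNetwork(cons, "consensus", softPower(tomCell))
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency in each dataset, computes
#' connectivities `k_i`, bins them into equal-width bins, and fits
#' `log10 p(k) ~ log10 k`. The signed fit index is `-sign(slope) * R^2`, so a
#' decaying (scale-free-like) degree distribution scores positively. The
#' chosen power is the smallest candidate whose signed R^2 reaches
#' `rsqCut` in *both* datasets; if no candidate qualifies (or the fit is
#' undefined, e.g. too few genes to bin), the configured default is used.
#'
#' @param merged a [MergedExpression-class].
#' @param candidates candidate powers (default `c(1:10, 12, 14, 16, 18, 20)`).
#' @param rsqCut signed R^2 criterion (default 0.8).
#' @param default fallback power when the criterion is never met (default 8).
#' @param nBins number of equal-width connectivity bins (default 10).
#' @return list with `power` (the chosen beta), `criterionMet` (logical) and
#'   `report` (data.frame: power, dataset, rsq, meanK).
#' @export
pickSoftPower <- function(merged, candidates = c(1:10, 12, 14, 16, 18, 20),
                          rsqCut = 0.8, default = 8, nBins = 10) {
  stopifnot(is(merged, "MergedExpression"))
  if (length(candidates) < 2) stop("need at least 2 candidate powers")
  datasets <- list(cell_line = cellExpr(merged), tumor = tumorExpr(merged))
  report <- do.call(rbind, lapply(names(datasets), function(ds) {
    mat <- datasets[[ds]]
    r <- suppressWarnings(cor(t(mat)))
    r[!is.finite(r)] <- 0
    absr <- abs(r)
    do.call(rbind, lapply(candidates, function(beta) {
      a <- absr^beta
      diag(a) <- 1
      k <- rowSums(a) - 1
      data.frame(power = beta, dataset = ds,
                 rsq = .scaleFreeRsq(k, nBins), meanK = mean(k))
    }))
  }))
  ok <- vapply(candidates, function(beta) {
    rs <- report$rsq[report$power == beta]
    all(!is.na(rs)) && all(rs >= rsqCut)
  }, logical(1))
  if (any(ok)) {
    list(power = min(candidates[ok]), criterionMet = TRUE, report = report)
  } else {
    list(power = default, criterionMet = FALSE, report = report)
  }
}

## signed scale-free fit index: -sign(slope) * R^2 of log10 p(k) ~ log10 k
## over equal-width connectivity bins; NA when the fit is undefined
.scaleFreeRsq <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(k) < nBins || max(k) == min(k)) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nBins)
  mid <- vapply(split(k, bin), function(v) if (length(v)) mean(v) else NA_real_,
                numeric(1))
  keep <- freq > 0 & is.finite(mid) & mid > 0
  if (sum(keep) < 3) return(NA_real_)
  p <- freq[keep] / sum(freq)
  fit <- lm(log10(p) ~ log10(mid[keep]))
  slope <- coef(fit)[2]
  -sign(slope) * summary(fit)$r.squared
}
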