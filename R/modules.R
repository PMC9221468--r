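## module detection, eigengenes, and cross-dataset preservation

#' Detect co-expression modules from a TOM-kind network
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed height. Clusters smaller than `minModuleSize` are assigned
#' to `"grey"`. Modules whose eigengenes (computed on `expr`) correlate above
#' `1 - mergeCut` are then merged iteratively, closest pair first. Surviving
#' modules are named by a fixed colour sequence in order of descending size,
#' so module names are deterministic.
#'
#' The static height cut plus eigengene merging is a fully specified,
#' deterministic stand-in for hybrid dynamic tree cutting; the exact module
#' count on real data is parameter-sensitive either way.
#'
#' @param network a [CoexNetwork-class] of kind `"tom"` or `"consensus"`.
#' @param expr expression used for merge eigengenes: a genes x samples matrix
#'   or a [MergedExpression-class] (cell and tumor samples are then
#'   concatenated).
#' @param minModuleSize smallest allowed module (default 30).
#' @param cutHeight static tree-cut height on `1 - TOM` (default 0.995).
#' @param mergeCut modules with eigengene correlation `> 1 - mergeCut` are
#'   merged (default 0.25, i.e. r > 0.75).
#' @return a [ModuleSet-class]. If every gene ends up unassigned the result
#'   is all-grey and a message is emitted.
#' @export
detectModules <- function(network, expr, minModuleSize = 30,
                          cutHeight = 0.995, mergeCut = 0.25) {
  stopifnot(is(network, "CoexNetwork"))
  if (!netKind(network) %in% c("tom", "consensus"))
    stop("detectModules expects a tom- or consensus-kind network")
  mat <- netMatrix(network)
  exprMat <- if (is(expr, "MergedExpression"))
    cbind(cellExpr(expr), tumorExpr(expr)) else .asExprMatrix(expr)
  if (!all(rownames(mat) %in% rownames(exprMat)))
    stop("expression must cover every network gene")
  exprMat <- exprMat[rownames(mat), , drop = FALSE]

  tree <- hclust(as.dist(1 - mat), method = "average")
  cl <- cutree(tree, h = cutHeight)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < minModuleSize])] <- 0L

  if (all(cl == 0L)) {
    message("no modules: every cluster fell below minModuleSize")
    return(new("ModuleSet",
               labels = setNames(rep("grey", nrow(mat)), rownames(mat)),
               minModuleSize = minModuleSize))
  }

  ## iterative eigengene merging, closest pair first
  repeat {
    ids <- setdiff(sort(unique(cl)), 0L)
    if (length(ids) < 2) break
    tmp <- new("ModuleSet",
               labels = setNames(ifelse(cl == 0L, "grey", paste0("c", cl)),
                                 rownames(mat)),
               minModuleSize = minModuleSize)
    eig <- moduleEigengenes(exprMat, tmp)
    sc <- eigengeneScores(eig)[paste0("c", ids), , drop = FALSE]
    r <- cor(t(sc))
    diag(r) <- -Inf
    best <- which(r == max(r), arr.ind = TRUE)[1, ]
    if (max(r) <= 1 - mergeCut) break
    keep <- ids[min(best)]
    drop <- ids[max(best)]
    cl[cl == drop] <- keep
  }

  ## deterministic colour names by descending size (ties: lower cluster id first)
  ids <- setdiff(sort(unique(cl)), 0L)
  ord <- ids[order(-tabulate(match(cl, ids)), ids)]
  palette <- if (length(ord) <= length(.modColors)) .modColors[seq_along(ord)]
  else c(.modColors, sprintf("module%03d", seq_len(length(ord) - length(.modColors))))
  names(palette) <- as.character(ord)
  labels <- ifelse(cl == 0L, "grey", palette[as.character(cl)])
  new("ModuleSet", labels = setNames(labels, rownames(mat)),
      minModuleSize = minModuleSize)
}

#' Module eigengenes (first principal component per module)
#'
#' For each non-grey module, genes are standardized and the first right
#' singular vector of the gene x sample block is taken as the module
#' eigengene. It is scaled to unit standard deviation and oriented so the
#' mean correlation with the module's genes is non-negative; the fraction of
#' block variance it explains is reported. A single-gene module's eigengene
#' is that gene's standardized profile.
#'
#' @param expr genes x samples matrix (or `SummarizedExperiment`, or
#'   [MergedExpression-class] whose blocks are concatenated).
#' @param modules a [ModuleSet-class]; genes must be present in `expr`.
#' @return an [EigengeneSet-class], modules ordered by descending size.
#' @export
moduleEigengenes <- function(expr, modules) {
  stopifnot(is(modules, "ModuleSet"))
  exprMat <- if (is(expr, "MergedExpression"))
    cbind(cellExpr(expr), tumorExpr(expr)) else .asExprMatrix(expr)
  labs <- moduleLabels(modules)
  mods <- moduleNames(modules)
  if (!length(mods)) stop("no non-grey modules to summarize")
  missing <- setdiff(names(labs)[labs != "grey"], rownames(exprMat))
  if (length(missing))
    stop(sprintf("module genes absent from expression: %s",
                 paste(head(missing, 5), collapse = ", ")))
  scores <- matrix(NA_real_, length(mods), ncol(exprMat),
                   dimnames = list(mods, colnames(exprMat)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    X <- .stdRows(exprMat[names(labs)[labs == m], , drop = FALSE], warn = FALSE)
    if (nrow(X) == 1) {
      v <- as.numeric(X)
      ve[m] <- 1
    } else {
      sv <- svd(X, nu = 0, nv = 1)
      v <- sv$v[, 1]
      ve[m] <- sv$d[1]^2 / sum(sv$d^2)
      if (mean(X %*% v) < 0) v <- -v   # orientation: mean gene correlation >= 0
    }
    sdv <- sd(v)
    if (sdv > 0) v <- v / sdv
    scores[m, ] <- v
  }
  new("EigengeneSet", scores = scores, varianceExplained = ve)
}

#' Eigengene adjacency
#'
#' Similarity between module eigengenes, `A_IJ = (1 + cor(E_I, E_J)) / 2`:
#' 1 for identical, 0.5 for uncorrelated, 0 for anti-correlated eigengenes.
#'
#' @param eig an [EigengeneSet-class] with at least 2 modules.
#' @return symmetric module x module matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
eigengeneAdjacency <- function(eig) {
  stopifnot(is(eig, "EigengeneSet"))
  sc <- eigengeneScores(eig)
  if (nrow(sc) < 2) stop("need >= 2 modules for an eigengene adjacency")
  a <- (1 + cor(t(sc))) / 2
  diag(a) <- 1
  a
}

#' Module preservation Z-summary between two datasets
#'
#' Quantifies whether modules defined on a reference dataset (cell lines)
#' remain coherent in a test dataset (tumors). For each non-grey module of
#' size >= 3 two statistics are observed in the test set:
#' \describe{
#'   \item{density}{mean off-diagonal intramodular adjacency (test set);}
#'   \item{connectivity}{correlation between the intramodular connectivity
#'     vectors of the reference and the test set.}
#' }
#' A permutation null replaces the module by random gene sets of equal size;
#' `Z = (observed - null mean) / null sd` per statistic and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Modules with `Zsummary > 5`
#' are conventionally called preserved (see [preservedModules()]).
#'
#' The intramodular adjacencies behind both statistics use the raw unsigned
#' correlation (`beta = 1`) by default, independently of the power used for
#' network construction: raising noisy correlation estimates to a high power
#' amplifies their sampling error roughly `beta`-fold and washes out the
#' permutation contrast, while the Z normalization makes the statistic scale
#' free anyway.
#'
#' @param exprRef reference (cell-line) genes x samples matrix or
#'   `SummarizedExperiment`; modules must be defined on this set.
#' @param exprTest test (tumor) matrix on a shared gene universe.
#' @param modules a [ModuleSet-class].
#' @param beta soft power for the intramodular adjacencies (default 1; see
#'   Details).
#' @param nPerm number of permutations (>= 50; default 100).
#' @param seed RNG seed for the permutation null.
#' @return a [PreservationStats-class]; modules of size < 3 get NA rows.
#' @export
preservationZsummary <- function(exprRef, exprTest, modules, beta = 1,
                                 nPerm = 100, seed = 1) {
  stopifnot(is(modules, "ModuleSet"))
  if (nPerm < 50) stop("nPerm must be >= 50 for a usable permutation null")
  ref <- .asExprMatrix(exprRef)
  test <- .asExprMatrix(exprTest)
  universe <- intersect(rownames(ref), rownames(test))
  if (length(universe) < 10) stop("too few shared genes between datasets")
  labs <- moduleLabels(modules)
  mods <- moduleNames(modules)

  modStats <- function(genes) {
    aR <- abs(suppressWarnings(cor(t(ref[genes, , drop = FALSE]))))^beta
    aT <- abs(suppressWarnings(cor(t(test[genes, , drop = FALSE]))))^beta
    aR[!is.finite(aR)] <- 0; aT[!is.finite(aT)] <- 0
    diag(aR) <- 1; diag(aT) <- 1
    kR <- rowSums(aR) - 1
    kT <- rowSums(aT) - 1
    conn <- if (sd(kR) > 0 && sd(kT) > 0) cor(kR, kT) else NA_real_
    c(density = mean(.offDiag(aT)), connectivity = conn)
  }

  .withSeed(seed, {
    rows <- lapply(mods, function(m) {
      genes <- intersect(names(labs)[labs == m], universe)
      s <- length(genes)
      if (s < 3)
        return(data.frame(module = m, size = s, Zdensity = NA_real_,
                          Zconnectivity = NA_real_, Zsummary = NA_real_))
      obs <- modStats(genes)
      null <- vapply(seq_len(nPerm),
                     function(i) modStats(sample(universe, s)), numeric(2))
      ## degenerate null (e.g. test set equal to reference makes every
      ## permuted connectivity exactly 1): no contrast, Z = 0
      zscore <- function(o, nullv) {
        mu <- mean(nullv, na.rm = TRUE)
        s0 <- sd(nullv, na.rm = TRUE)
        if (!is.finite(s0) || s0 < 1e-12) {
          if (is.finite(o) && abs(o - mu) < 1e-8) 0 else NA_real_
        } else (o - mu) / s0
      }
      zd <- zscore(obs[["density"]], null[1, ])
      zc <- zscore(obs[["connectivity"]], null[2, ])
      data.frame(module = m, size = s, Zdensity = zd,
                 Zconnectivity = zc, Zsummary = (zd + zc) / 2)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$size), ]
    rownames(tab) <- NULL
    new("PreservationStats", table = tab, nPerm = nPerm, seed = seed)
  })
}
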