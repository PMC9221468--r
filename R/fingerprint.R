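## drug fingerprints and resampling consensus clustering

#' Drug-by-module fingerprint correlations
#'
#' For every drug and every preserved module, the Pearson correlation between
#' the drug's per-cell-line summary responses and the module eigengene over
#' the matched cell lines. The eigengenes must be computed on cell-line
#' samples (drug responses only exist there). Zero variance on either side
#' yields a missing entry with a reason code rather than a silent 0.
#'
#' @param response drug x cell line summary-response matrix, or a
#'   [DoseResponsePanel-class].
#' @param eig an [EigengeneSet-class] on cell-line samples.
#' @param preserved modules (columns) to keep, e.g. from
#'   [preservedModules()]; default: all modules in `eig`.
#' @param drugs optional subset of drugs (e.g. the pre-filter survivors).
#' @return a [FingerprintMatrix-class].
#' @export
drugModuleCorrelations <- function(response, eig, preserved = NULL,
                                   drugs = NULL) {
  resp <- if (is(response, "DoseResponsePanel")) panelResponse(response)
  else as.matrix(response)
  if (!is.null(drugs)) resp <- resp[intersect(drugs, rownames(resp)), , drop = FALSE]
  sc <- eigengeneScores(eig)
  if (is.null(preserved)) preserved <- rownames(sc)
  missingMods <- setdiff(preserved, rownames(sc))
  if (length(missingMods))
    stop(sprintf("modules absent from eigengene set: %s",
                 paste(missingMods, collapse = ", ")))
  sc <- sc[preserved, , drop = FALSE]
  shared <- intersect(colnames(resp), colnames(sc))
  if (length(shared) < 3)
    stop(sprintf("only %d matched cell lines; need >= 3 for correlations",
                 length(shared)))
  resp <- resp[, shared, drop = FALSE]
  sc <- sc[, shared, drop = FALSE]

  r <- matrix(NA_real_, nrow(resp), nrow(sc),
              dimnames = list(rownames(resp), rownames(sc)))
  reasons <- character(0)
  sdD <- apply(resp, 1, sd)
  sdM <- apply(sc, 1, sd)
  okD <- sdD > 0
  okM <- sdM > 0
  if (any(okD) && any(okM))
    r[okD, okM] <- cor(t(resp[okD, , drop = FALSE]),
                       t(sc[okM, , drop = FALSE]))
  for (d in rownames(resp)[!okD])
    for (m in rownames(sc)) reasons[paste(d, m, sep = "|")] <- "zero_variance_drug"
  for (m in rownames(sc)[!okM])
    for (d in rownames(resp)[okD]) reasons[paste(d, m, sep = "|")] <- "zero_variance_eigengene"
  new("FingerprintMatrix", cor = r, nPoints = length(shared),
      missingReason = reasons)
}

#' Consensus clustering of drugs by fingerprint
#'
#' Monti-style resampling consensus: repeatedly subsample a fraction of the
#' drugs, cluster the subsample's fingerprint rows by average-linkage
#' hierarchical clustering with distance `1 - Pearson r` between rows, and
#' cut at each candidate `k`. The consensus matrix entry for a drug pair is
#' the fraction of co-samplings in which they co-clustered.
#'
#' Two rules for choosing the number of clusters are computed and reported:
#' the proportion of ambiguous clustering (PAC — the fraction of off-diagonal
#' consensus entries between 0.05 and 0.95; smaller means crisper), and the
#' delta-area elbow on the area under the consensus CDF (step through
#' increasing `k` while the proportional area increase exceeds `deltaCut`,
#' stop at the first flattening). The default rule is PAC (smallest
#' ambiguity; ties broken toward the largest such `k`), which is robust when
#' classes are crisply separated and the CDF area keeps growing through
#' reproducible micro-splits; the elbow rule and a forced `k` are available.
#' The final partition is average-linkage clustering of `1 - consensus` cut
#' at the chosen `k`.
#'
#' Drugs with any missing fingerprint entry (or a zero-variance fingerprint,
#' for which the correlation distance is undefined) are dropped with a
#' warning rather than imputed.
#'
#' @param fp a [FingerprintMatrix-class].
#' @param kRange candidate cluster numbers, within 2..12 (default `2:6`).
#' @param nResample number of subsamples (>= 20; default 100).
#' @param itemFraction fraction of drugs per subsample, in (0.5, 1\]
#'   (default 0.8).
#' @param seed RNG seed.
#' @param k optional forced cluster number (overrides both rules).
#' @param kRule `"pac"` (default) or `"deltaArea"`; see Details.
#' @param deltaCut proportional area increase below which extra clusters are
#'   considered noise under the elbow rule (default 0.1).
#' @return a [ConsensusClusterResult-class].
#' @export
consensusClusterDrugs <- function(fp, kRange = 2:6, nResample = 100,
                                  itemFraction = 0.8, seed = 1, k = NULL,
                                  kRule = c("pac", "deltaArea"),
                                  deltaCut = 0.1) {
  kRule <- match.arg(kRule)
  stopifnot(is(fp, "FingerprintMatrix"))
  if (nResample < 20) stop("nResample < 20 is refused: consensus too unstable")
  if (any(kRange < 2) || any(kRange > 12)) stop("kRange must lie within 2..12")
  if (itemFraction <= 0.5 || itemFraction > 1)
    stop("itemFraction must lie in (0.5, 1]")
  X <- fingerprintCor(fp)
  bad <- apply(X, 1, function(v) anyNA(v) || sd(v) == 0)
  if (any(bad)) {
    warning(sprintf("dropping %d drug(s) with missing or flat fingerprints: %s",
                    sum(bad), paste(head(rownames(X)[bad], 5), collapse = ", ")))
    X <- X[!bad, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < max(kRange) + 1) stop("too few drugs for the requested kRange")
  drugs <- rownames(X)
  kRange <- sort(unique(as.integer(kRange)))

  .withSeed(seed, {
    m <- ceiling(itemFraction * n)
    cosampled <- matrix(0, n, n)
    coclust <- array(0, c(n, n, length(kRange)))
    for (b in seq_len(nResample)) {
      idx <- sort(sample(n, m))
      d <- as.dist(1 - cor(t(X[idx, , drop = FALSE])))
      tree <- hclust(d, method = "average")
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
      for (j in seq_along(kRange)) {
        cl <- cutree(tree, k = kRange[j])
        same <- outer(cl, cl, "==") * 1
        coclust[idx, idx, j] <- coclust[idx, idx, j] + same
      }
    }
    if (any(.offDiag(cosampled) == 0))
      warning("some drug pairs were never co-sampled; their consensus is set to 0 — increase nResample or itemFraction")
    denom <- cosampled
    denom[denom == 0] <- 1
    consensusByK <- lapply(seq_along(kRange), function(j) {
      cm <- coclust[, , j] / denom
      diag(cm) <- 1
      dimnames(cm) <- list(drugs, drugs)
      cm
    })

    ## per-k diagnostics: CDF area, delta area, PAC
    areas <- vapply(consensusByK, function(cm) {
      v <- sort(.offDiag(cm))
      cdf <- seq_along(v) / length(v)
      sum(diff(v) * cdf[-length(cdf)])
    }, numeric(1))
    delta <- c(areas[1], diff(areas) / head(areas, -1))
    pac <- vapply(consensusByK, function(cm) {
      off <- .offDiag(cm)
      mean(off > 0.05 & off < 0.95)
    }, numeric(1))
    diagnostics <- data.frame(k = kRange, area = areas, deltaArea = delta,
                              pac = pac)
    chosen <- if (!is.null(k)) {
      as.integer(k)
    } else if (kRule == "pac") {
      ## least ambiguous consensus; ties go to the largest crisp k
      max(kRange[pac <= min(pac) + 1e-12])
    } else if (delta[1] <= deltaCut) {
      kRange[1]
    } else {
      flat <- which(delta[-1] <= deltaCut)   # delta[-1] aligns with kRange[-1]
      if (length(flat)) kRange[flat[1]] else kRange[length(kRange)]
    }
    j <- match(chosen, kRange)
    if (is.na(j)) stop("forced k must be inside kRange")
    cm <- consensusByK[[j]]
    membership <- cutree(hclust(as.dist(1 - cm), method = "average"),
                         k = chosen)
    ## relabel clusters 1..k in order of first appearance for determinism
    membership <- as.integer(factor(membership, levels = unique(membership)))
    names(membership) <- drugs
    new("ConsensusClusterResult", membership = membership,
        k = chosen, consensus = cm, diagnostics = diagnostics,
        settings = list(kRange = kRange, nResample = nResample,
                        itemFraction = itemFraction, seed = seed,
                        innerLinkage = "average"))
  })
}
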