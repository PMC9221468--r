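## two-drug combination prediction under independent drug action (IDA)

#' Remove the two extreme screening concentrations
#'
#' Drops the lowest and highest concentration columns of the panel (the two
#' positions, not specific values: an already-trimmed panel loses its own
#' extremes). On the default 11-point grid this removes 0.000780415 and
#' 46.08294931 uM and retains the 9 interior points used for combination
#' prediction.
#'
#' @param panel a [DoseResponsePanel-class] with >= 4 concentrations.
#' @return the trimmed panel; removed values are recorded in
#'   [removedConcentrations()].
#' @export
trimConcentrations <- function(panel) {
  stopifnot(is(panel, "DoseResponsePanel"))
  conc <- concentrations(panel)
  nc <- length(conc)
  if (nc < 4) stop("need >= 4 concentrations to trim the two extremes")
  keep <- 2:(nc - 1)
  new("DoseResponsePanel",
      viability = panel@viability[, , keep, drop = FALSE],
      concentrations = conc[keep],
      response = panel@response,
      removedConcentrations = c(panel@removedConcentrations,
                                conc[c(1, nc)]))
}

## viability matrix (lines x conc) for one drug, restricted to given lines
.drugSlice <- function(panel, drug, lines = NULL) {
  v <- panelViability(panel)
  if (!drug %in% dimnames(v)[[1]])
    stop(sprintf("drug '%s' not in panel", drug))
  m <- v[drug, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(panelCellLines(panel), NULL))
  if (!is.null(lines)) m <- m[lines, , drop = FALSE]
  m
}

## cell lines with complete measurements for both drugs
.sharedLines <- function(panel, drugA, drugB) {
  a <- .drugSlice(panel, drugA)
  b <- .drugSlice(panel, drugB)
  ok <- rowSums(!is.finite(a)) == 0 & rowSums(!is.finite(b)) == 0
  shared <- rownames(a)[ok]
  if (!length(shared))
    stop(sprintf("no shared cell lines for %s + %s", drugA, drugB))
  shared
}

#' IDA combination viability at one concentration pair
#'
#' Under independent drug action each cell line responds as if treated only
#' by the drug most effective for it, so the per-line combination viability
#' is `min(V(line, A, cA), V(line, B, cB))` over the shared cell lines.
#'
#' @param panel a [DoseResponsePanel-class] (typically trimmed).
#' @param drugA,drugB drug ids.
#' @param cA,cB concentrations (must be grid points of the panel).
#' @return list with `perLine` (named viability vector) and `mean`.
#' @export
idaComboViability <- function(panel, drugA, cA, drugB, cB) {
  conc <- concentrations(panel)
  iA <- match(cA, conc)
  iB <- match(cB, conc)
  if (is.na(iA) || is.na(iB))
    stop("cA and cB must be concentrations on the panel grid")
  shared <- .sharedLines(panel, drugA, drugB)
  vA <- .drugSlice(panel, drugA, shared)[, iA]
  vB <- .drugSlice(panel, drugB, shared)[, iB]
  per <- pmin(vA, vB)
  list(perLine = per, mean = mean(per))
}

#' IDAcombo score of a drug pair
#'
#' For every concentration pair `(cA, cB)` on the trimmed grid the gain of
#' the mean IDA combination over the best mean monotherapy is
#' `score(cA, cB) = min(mean_i V(i,A,cA), mean_i V(i,B,cB)) -
#' mean_i min(V(i,A,cA), V(i,B,cB))`, in viability percentage points. The
#' reported IDAcombo score is the maximum over pairs, with the attaining
#' concentrations. Since the mean of minima never exceeds the minimum of
#' means, the score is non-negative; values above 1 point are conventionally
#' flagged as worthwhile combinations.
#'
#' @param panel a [DoseResponsePanel-class] (typically trimmed).
#' @param drugA,drugB drug ids sharing at least one cell line.
#' @return a [ComboPrediction-class].
#' @export
idaComboScore <- function(panel, drugA, drugB) {
  shared <- .sharedLines(panel, drugA, drugB)
  conc <- concentrations(panel)
  a <- .drugSlice(panel, drugA, shared)   # lines x conc
  b <- .drugSlice(panel, drugB, shared)
  meanA <- colMeans(a)
  meanB <- colMeans(b)
  best <- c(score = -Inf, iA = NA, iB = NA)
  for (iA in seq_along(conc)) {
    ## mean over lines of pmin(a[,iA], b[,iB]) for all iB at once
    ## (matrix first: pmin keeps the dims of its first argument)
    comboMeans <- colMeans(pmin(b, a[, iA]))
    monoMeans <- pmin(meanA[iA], meanB)
    scores <- unname(monoMeans - comboMeans)
    iB <- which.max(scores)
    if (scores[iB] > best[["score"]])
      best <- c(score = scores[iB], iA = iA, iB = iB)
  }
  iA <- best[["iA"]]; iB <- best[["iB"]]
  per <- pmin(a[, iA], b[, iB])
  detail <- data.frame(cell_line = shared, viabilityA = a[, iA],
                       viabilityB = b[, iB], comboViability = per,
                       row.names = NULL, stringsAsFactors = FALSE)
  new("ComboPrediction", drugA = drugA, drugB = drugB,
      score = max(best[["score"]], 0),
      bestPair = c(cA = conc[iA], cB = conc[iB]),
      meanCombo = mean(per), meanMono = min(meanA[iA], meanB[iB]),
      detail = detail)
}

#' Enumerate and score fingerprint-guided drug combinations
#'
#' Two strategies: `"vertical"` scores all pairs within the anchor-like set
#' (the anchor plus its advanced-status fingerprint neighbours from
#' [similarFingerprintDrugs()]) — same-axis combinations that may forestall
#' resistance; `"horizontal"` pairs the anchor with every advanced-status
#' member of a complementary partner cluster. Each pair is scored with
#' [idaComboScore()]; results are ranked by descending score and pairs above
#' `scoreThreshold` (default 1 viability point) are flagged.
#'
#' @param strategy `"vertical"` or `"horizontal"`.
#' @param panel a trimmed [DoseResponsePanel-class].
#' @param fp a [FingerprintMatrix-class].
#' @param anchor anchor drug id.
#' @param clusters a [ConsensusClusterResult-class]; required for
#'   `"horizontal"`.
#' @param partnerCluster partner cluster id; required for `"horizontal"`.
#' @param ann annotation data.frame for status filtering.
#' @param statuses admissible partner statuses (default
#'   [advancedStatuses()]).
#' @param minSimilarity similarity cutoff for the vertical anchor-like set
#'   (default 0.8).
#' @param scoreThreshold flag combos scoring above this (default 1).
#' @return data.frame: drugA, drugB, strategy, score, cA_uM, cB_uM,
#'   mean_combo_viability, mean_mono_viability, n_shared_lines,
#'   aboveThreshold; ranked by descending score. Empty (with a warning) when
#'   no candidate pairs exist.
#' @export
enumerateCombinations <- function(strategy = c("vertical", "horizontal"),
                                  panel, fp, anchor, clusters = NULL,
                                  partnerCluster = NULL, ann = NULL,
                                  statuses = advancedStatuses(),
                                  minSimilarity = 0.8, scoreThreshold = 1) {
  strategy <- match.arg(strategy)
  drugsInPanel <- panelDrugs(panel)
  if (!anchor %in% drugsInPanel)
    stop(sprintf("anchor drug '%s' not in the panel", anchor))

  if (strategy == "vertical") {
    sim <- similarFingerprintDrugs(fp, anchor, minSimilarity, ann, statuses)
    set <- intersect(c(anchor, sim$drug), drugsInPanel)
    pairs <- if (length(set) >= 2) t(utils::combn(set, 2)) else
      matrix(character(0), 0, 2)
  } else {
    if (is.null(clusters) || is.null(partnerCluster))
      stop("horizontal strategy needs clusters and a partnerCluster")
    mem <- clusterMembership(clusters)
    partners <- names(mem)[mem == partnerCluster]
    if (!is.null(ann)) {
      statusOf <- setNames(ann$status, ann$drug)
      partners <- partners[!is.na(statusOf[partners]) &
                             statusOf[partners] %in% statuses]
    }
    partners <- setdiff(intersect(partners, drugsInPanel), anchor)
    pairs <- cbind(rep(anchor, length(partners)), partners)
  }

  if (!nrow(pairs)) {
    warning("no candidate drug pairs for this strategy")
    return(data.frame(drugA = character(0), drugB = character(0),
                      strategy = character(0), score = numeric(0),
                      cA_uM = numeric(0), cB_uM = numeric(0),
                      mean_combo_viability = numeric(0),
                      mean_mono_viability = numeric(0),
                      n_shared_lines = integer(0),
                      aboveThreshold = logical(0)))
  }

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cp <- idaComboScore(panel, pairs[i, 1], pairs[i, 2])
    data.frame(drugA = cp@drugA, drugB = cp@drugB, strategy = strategy,
               score = cp@score, cA_uM = cp@bestPair[["cA"]],
               cB_uM = cp@bestPair[["cB"]],
               mean_combo_viability = cp@meanCombo,
               mean_mono_viability = cp@meanMono,
               n_shared_lines = nrow(cp@detail),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$drugA, out$drugB), ]
  out$aboveThreshold <- out$score > scoreThreshold
  rownames(out) <- NULL
  out
}

#' All-pairs IDAcombo score matrix
#'
#' Symmetric matrix of [idaComboScore()] values for a drug set, e.g. the
#' vertical anchor-like set (heatmap substrate).
#'
#' @param panel a trimmed [DoseResponsePanel-class].
#' @param drugs drug ids to pair.
#' @return symmetric numeric matrix (diagonal 0: a drug adds nothing to
#'   itself).
#' @export
comboScoreMatrix <- function(panel, drugs) {
  drugs <- intersect(drugs, panelDrugs(panel))
  n <- length(drugs)
  m <- matrix(0, n, n, dimnames = list(drugs, drugs))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- comboScore(idaComboScore(panel, drugs[i], drugs[j]))
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}
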