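## candidate ranking and fingerprint-similarity search

.advancedStatuses <- c("FDA-approved", "Phase III", "Phase II")

#' Default advanced-status set
#'
#' Drugs that are FDA-approved or in Phase II/III trials: candidates with
#' existing human safety data, hence the default status filter when ranking.
#'
#' @return character vector of the three advanced statuses.
#' @export
advancedStatuses <- function() .advancedStatuses

#' Rank advanced-status drug candidates per cluster
#'
#' Scores each drug by its most negative fingerprint correlation across
#' preserved modules (`score = min_M r(drug, M)`), keeps advanced-status
#' drugs with a strictly negative score (a negative correlation means module
#' genes are down-regulated where the drug bites), sorts ascending within
#' each cluster (most negative first, ties broken by drug name) and returns
#' the top `topN` per cluster, together with the module attaining the score.
#'
#' @param fp a [FingerprintMatrix-class].
#' @param clusters a [ConsensusClusterResult-class] on (a superset of) the
#'   fingerprint drugs.
#' @param ann annotation data.frame (`drug`, `status`).
#' @param topN candidates kept per cluster (default 15).
#' @param statuses admissible statuses (default [advancedStatuses()]).
#' @return data.frame: cluster, drug, score, module, status — the
#'   candidate list. Deterministic: no randomness enters the ranking.
#' @export
rankCandidates <- function(fp, clusters, ann, topN = 15,
                           statuses = advancedStatuses()) {
  stopifnot(is(fp, "FingerprintMatrix"), is(clusters, "ConsensusClusterResult"))
  bad <- setdiff(statuses, .statusVocab)
  if (length(bad))
    stop(sprintf("unknown status '%s'; allowed: %s", bad[1],
                 paste(.statusVocab, collapse = ", ")))
  r <- fingerprintCor(fp)
  mem <- clusterMembership(clusters)
  drugs <- intersect(rownames(r), names(mem))
  statusOf <- setNames(ann$status, ann$drug)

  score <- apply(r[drugs, , drop = FALSE], 1, min, na.rm = TRUE)
  module <- colnames(r)[apply(r[drugs, , drop = FALSE], 1, which.min)]
  tab <- data.frame(cluster = mem[drugs], drug = drugs, score = score,
                    module = module, status = statusOf[drugs],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$status) & tab$status %in% statuses & tab$score < 0, ]

  out <- do.call(rbind, lapply(sort(unique(mem)), function(cl) {
    sub <- tab[tab$cluster == cl, ]
    if (!nrow(sub)) {
      warning(sprintf("cluster %d has no advanced-status candidate", cl))
      return(NULL)
    }
    sub <- sub[order(sub$score, sub$drug), ]
    head(sub, topN)
  }))
  if (is.null(out))
    out <- tab[0, ]
  rownames(out) <- NULL
  out
}

#' Drugs with a fingerprint similar to an anchor drug
#'
#' Returns the drugs whose fingerprint row correlates with the anchor's row
#' at or above `minSimilarity` (default 0.8), sorted by descending
#' similarity. The anchor itself is excluded, and an annotation table can
#' restrict the result to advanced-status drugs — the use case is finding
#' candidates that phenocopy a reference compound (e.g. a MEK inhibitor) for
#' vertical combinations.
#'
#' @param fp a [FingerprintMatrix-class].
#' @param anchor anchor drug id (must be present in `fp`).
#' @param minSimilarity minimum fingerprint-row Pearson correlation
#'   (default 0.8).
#' @param ann optional annotation data.frame for status filtering.
#' @param statuses statuses kept when `ann` is given (default
#'   [advancedStatuses()]).
#' @return data.frame: drug, similarity (descending).
#' @export
similarFingerprintDrugs <- function(fp, anchor, minSimilarity = 0.8,
                                    ann = NULL,
                                    statuses = advancedStatuses()) {
  stopifnot(is(fp, "FingerprintMatrix"))
  r <- fingerprintCor(fp)
  if (!anchor %in% rownames(r))
    stop(sprintf("anchor drug '%s' not present in the fingerprint matrix", anchor))
  ok <- !apply(r, 1, anyNA) & apply(r, 1, sd) > 0
  if (!ok[anchor]) stop("anchor fingerprint is missing or flat")
  sim <- as.vector(cor(t(r[ok, , drop = FALSE]), r[anchor, ]))
  names(sim) <- rownames(r)[ok]
  sim <- sim[names(sim) != anchor]
  if (!is.null(ann)) {
    statusOf <- setNames(ann$status, ann$drug)
    sim <- sim[!is.na(statusOf[names(sim)]) & statusOf[names(sim)] %in% statuses]
  }
  sim <- sim[sim >= minSimilarity]
  sim <- sort(sim, decreasing = TRUE)
  data.frame(drug = names(sim), similarity = unname(sim),
             stringsAsFactors = FALSE)
}
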