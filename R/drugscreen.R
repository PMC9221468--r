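## dose-response ingestion, summary responses, pre-selection filters

#' Normalized area under a viability curve
#'
#' Trapezoidal integral of percent viability over log10(concentration),
#' divided by the log-concentration span. The result lives on the same 0-100
#' viability scale as the curve itself (a flat curve returns its own level),
#' which keeps the `< 55`-percent pre-selection cutoff dimensionally coherent
#' with an "AUC" response.
#'
#' @param viability numeric vector of percent viabilities.
#' @param conc strictly increasing concentration grid (same length, >= 2).
#' @return normalized AUC, bounded by the curve's min and max.
#' @export
#' @examples
#' computeAUC(c(100, 80, 40, 10), c(0.01, 0.1, 1, 10))
computeAUC <- function(viability, conc) {
  if (length(conc) < 2) stop("need >= 2 concentration points")
  if (length(viability) != length(conc))
    stop("viability and concentration grids differ in length")
  if (is.unsorted(conc, strictly = TRUE))
    stop("concentration grid must be strictly increasing")
  .aucViability(viability, conc)
}

#' Construct a dose-response panel
#'
#' Wraps a drug x cell line x concentration viability array into a
#' [DoseResponsePanel-class]. If a per-drug per-line summary response is not
#' supplied it is computed with [computeAUC()]; a deposited summary column,
#' when available, is used verbatim so ingested screens stay faithful to
#' their source.
#'
#' @param viability 3-d array (drug x cell line x concentration) of percent
#'   viabilities, with dimnames; values outside \[0, 200\] are clipped on
#'   ingest.
#' @param conc strictly increasing concentration grid (uM).
#' @param response optional drug x cell line summary-response matrix.
#' @return a [DoseResponsePanel-class].
#' @export
doseResponsePanel <- function(viability, conc, response = NULL) {
  viability <- pmin(pmax(viability, 0), 200)
  if (is.null(response)) {
    response <- apply(viability, c(1, 2), computeAUC, conc = conc)
    dimnames(response) <- dimnames(viability)[1:2]
  }
  new("DoseResponsePanel", viability = viability, concentrations = conc,
      response = as.matrix(response), removedConcentrations = numeric(0))
}

#' Read a long-format dose-response file
#'
#' Expects columns `drug`, `cell_line`, `concentration_uM`, `viability_pct`
#' (CSV or TSV, sniffed from the extension). The grid must be complete; an
#' optional `summaryResponseFile` (CSV: `drug`, one column per line) supplies
#' a deposited summary response.
#'
#' @param path long-format dose-response file.
#' @param summaryResponseFile optional per-drug summary-response CSV.
#' @return a [DoseResponsePanel-class].
#' @export
readDoseResponse <- function(path, summaryResponseFile = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  long <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("drug", "cell_line", "concentration_uM", "viability_pct")
  if (!all(need %in% colnames(long)))
    stop(sprintf("dose-response file needs columns: %s",
                 paste(need, collapse = ", ")))
  drugs <- sort(unique(long$drug))
  lines <- sort(unique(long$cell_line))
  conc <- sort(unique(long$concentration_uM))
  v <- array(NA_real_, c(length(drugs), length(lines), length(conc)),
             dimnames = list(drugs, lines, format(conc)))
  v[cbind(match(long$drug, drugs), match(long$cell_line, lines),
          match(long$concentration_uM, conc))] <- long$viability_pct
  if (anyNA(v)) stop("dose-response grid is incomplete")
  response <- NULL
  if (!is.null(summaryResponseFile)) {
    rs <- read.csv(summaryResponseFile, stringsAsFactors = FALSE)
    response <- as.matrix(rs[, -1, drop = FALSE])
    rownames(response) <- rs[[1]]
    response <- response[drugs, lines, drop = FALSE]
  }
  doseResponsePanel(v, conc, response)
}

#' Read a drug annotation table
#'
#' CSV with columns `drug`, `status` and optionally `targets`, `pchembl`.
#' Statuses must come from [drugStatusVocabulary()].
#'
#' @param path annotation CSV.
#' @return data.frame with validated `status` column.
#' @export
readDrugAnnotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "status") %in% colnames(ann)))
    stop("annotation file needs columns: drug, status")
  bad <- setdiff(unique(ann$status), .statusVocab)
  if (length(bad))
    stop(sprintf("unknown status '%s'; allowed: %s", bad[1],
                 paste(.statusVocab, collapse = ", ")))
  ann
}

#' Pre-select drugs by median summary viability
#'
#' Keeps drugs whose median-across-lines summary response is *strictly* below
#' the cutoff (default 55 percent viability), i.e. drugs that reduce median
#' viability by more than 45 points.
#'
#' @param panel a [DoseResponsePanel-class] (or a drug x line summary-response
#'   matrix).
#' @param cutoff viability cutoff in (0, 100\] (default 55).
#' @param cellLines optional subset of cell lines over which the median is
#'   taken (default: all lines in the panel).
#' @return character vector of surviving drug ids.
#' @export
viabilityPrefilter <- function(panel, cutoff = 55, cellLines = NULL) {
  if (cutoff <= 0 || cutoff > 100) stop("cutoff must be in (0, 100]")
  resp <- if (is(panel, "DoseResponsePanel")) panelResponse(panel)
  else as.matrix(panel)
  if (!is.null(cellLines)) {
    missing <- setdiff(cellLines, colnames(resp))
    if (length(missing))
      stop(sprintf("unknown cell line(s): %s", paste(missing, collapse = ", ")))
    resp <- resp[, cellLines, drop = FALSE]
  }
  med <- apply(resp, 1, median)
  rownames(resp)[med < cutoff]
}

#' Filter drugs by annotation quality and clinical status
#'
#' Keeps drugs with `pchembl` *strictly* greater than `minPchembl` and, when
#' a status filter is given, status inside it. Drugs with missing pChEMBL are
#' kept by default (screening libraries include tool compounds without
#' curated potencies) but can be dropped.
#'
#' @param ann annotation data.frame (`drug`, `status`, optional `pchembl`).
#' @param minPchembl pChEMBL cutoff, strict (default 6).
#' @param statuses optional subset of [drugStatusVocabulary()]; `NULL` or
#'   empty means no status filtering.
#' @param missingPchembl `"keep"` (default) or `"drop"` drugs without a
#'   pChEMBL value.
#' @return character vector of surviving drug ids.
#' @export
annotationFilter <- function(ann, minPchembl = 6, statuses = NULL,
                             missingPchembl = c("keep", "drop")) {
  missingPchembl <- match.arg(missingPchembl)
  if (!is.null(statuses) && length(statuses)) {
    bad <- setdiff(statuses, .statusVocab)
    if (length(bad))
      stop(sprintf("unknown status '%s'; allowed: %s", bad[1],
                   paste(.statusVocab, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(ann))
  if ("pchembl" %in% colnames(ann)) {
    pc <- ann$pchembl
    keep <- ifelse(is.na(pc), missingPchembl == "keep", pc > minPchembl)
  }
  if (!is.null(statuses) && length(statuses))
    keep <- keep & ann$status %in% statuses
  ann$drug[keep]
}
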