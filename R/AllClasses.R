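#' @import methods
#' @importFrom stats cor median sd mad quantile hclust cutree as.dist dist
#'   phyper p.adjust runif rnorm uniroot setNames lm coef var aggregate
#' @importFrom utils head tail read.table write.table read.csv write.csv
NULL

## closed vocabulary for clinical annotation status
.statusVocab <- c("FDA-approved", "Phase III", "Phase II", "Phase I", "preclinical")

## deterministic module colour sequence (descending module size); "grey" is
## reserved for unassigned genes
.modColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna", "yellowgreen", "skyblue3",
  "plum", "orangered", "mediumpurple"
)

#' Clinical status vocabulary
#'
#' The closed vocabulary used by drug annotation tables, ordered from most to
#' least clinically advanced. The first three levels ("FDA-approved",
#' "Phase III", "Phase II") form the default advanced-status filter used when
#' ranking candidates.
#'
#' @return Character vector of admissible clinical status strings.
#' @export
#' @examples
#' drugStatusVocabulary()
drugStatusVocabulary <- function() .statusVocab

.checkSymmetric <- function(m, tol = 1e-10) {
  max(abs(m - t(m))) <= tol
}

#' Co-expression network matrix
#'
#' A symmetric gene-by-gene similarity in \[0, 1\] with unit diagonal. The
#' `kind` slot records whether the matrix is a soft-thresholded adjacency
#' (`"adjacency"`), a topological overlap matrix (`"tom"`), or a cross-dataset
#' consensus TOM (`"consensus"`).
#'
#' @slot mat numeric matrix, symmetric, entries in \[0, 1\], diagonal 1,
#'   dimnames = gene ids.
#' @slot kind one of `"adjacency"`, `"tom"`, `"consensus"`.
#' @slot beta soft-thresholding power used to build the underlying adjacency.
#' @export
setClass("CoexNetwork",
  representation(mat = "matrix", kind = "character", beta = "numeric"),
  validity = function(object) {
    m <- object@mat
    if (nrow(m) != ncol(m)) return("matrix must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      return("matrix needs identical row/col gene ids")
    if (!object@kind %in% c("adjacency", "tom", "consensus"))
      return("kind must be adjacency/tom/consensus")
    if (anyNA(m)) return("network entries must be finite")
    if (min(m) < -1e-10 || max(m) > 1 + 1e-10)
      return("network entries must lie in [0, 1]")
    if (max(abs(diag(m) - 1)) > 1e-10) return("diagonal must equal 1")
    if (!.checkSymmetric(m)) return("matrix must be symmetric (tol 1e-10)")
    TRUE
  }
)

.CoexNetwork <- function(mat, kind, beta = NA_real_) {
  ## clamp away numerical dust before validity kicks in
  mat[mat < 0] <- 0
  mat[mat > 1] <- 1
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 1
  new("CoexNetwork", mat = mat, kind = kind, beta = beta)
}

#' Gene-intersected, per-dataset standardized expression pair
#'
#' Holds the cell-line and tumor expression blocks after gene intersection and
#' per-gene standardization (mean 0, sd 1 within each dataset). Rows (genes)
#' are identical and identically ordered in both blocks.
#'
#' @slot cell genes x cell-line samples matrix, standardized per gene.
#' @slot tumor genes x tumor samples matrix, standardized per gene.
#' @export
setClass("MergedExpression",
  representation(cell = "matrix", tumor = "matrix"),
  validity = function(object) {
    if (!identical(rownames(object@cell), rownames(object@tumor)))
      return("cell and tumor blocks must share identical gene rows")
    if (is.null(rownames(object@cell))) return("gene ids required")
    TRUE
  }
)

#' Gene-to-module assignment
#'
#' Maps every gene to a module colour; `"grey"` marks unassigned genes.
#' Non-grey module names follow a fixed colour sequence ordered by descending
#' module size, so assignments are deterministic.
#'
#' @slot labels named character vector, gene id -> module colour.
#' @slot minModuleSize the minimum size below which clusters were greyed out.
#' @export
setClass("ModuleSet",
  representation(labels = "character", minModuleSize = "numeric"),
  validity = function(object) {
    if (is.null(names(object@labels))) return("labels must be named by gene id")
    if (anyDuplicated(names(object@labels))) return("duplicate gene ids")
    TRUE
  }
)

#' Module eigengenes
#'
#' One score per module per sample: the first right singular vector of the
#' module's standardized gene-by-sample block, scaled to unit standard
#' deviation and oriented so that the mean correlation with the module's genes
#' is non-negative.
#'
#' @slot scores module x sample matrix of eigengene values (per-module sd 1).
#' @slot varianceExplained named numeric, fraction of module variance carried
#'   by the eigengene.
#' @export
setClass("EigengeneSet",
  representation(scores = "matrix", varianceExplained = "numeric"),
  validity = function(object) {
    if (is.null(rownames(object@scores))) return("module names required")
    if (!identical(rownames(object@scores), names(object@varianceExplained)))
      return("varianceExplained must be named like the score rows")
    TRUE
  }
)

#' Module preservation statistics
#'
#' Permutation Z statistics measuring whether modules defined on a reference
#' dataset remain coherent in a test dataset. `Zsummary` is the mean of the
#' density and connectivity Z scores; values above 5 flag preserved modules.
#'
#' @slot table data.frame with columns module, size, Zdensity, Zconnectivity,
#'   Zsummary.
#' @slot nPerm number of permutations behind the null.
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("PreservationStats",
  representation(table = "data.frame", nPerm = "numeric", seed = "numeric"),
  validity = function(object) {
    need <- c("module", "size", "Zdensity", "Zconnectivity", "Zsummary")
    if (!all(need %in% colnames(object@table)))
      return(paste("table needs columns:", paste(need, collapse = ", ")))
    ok <- stats::complete.cases(object@table[, c("Zdensity", "Zconnectivity")])
    zs <- object@table$Zsummary[ok]
    zm <- (object@table$Zdensity[ok] + object@table$Zconnectivity[ok]) / 2
    if (length(zs) && max(abs(zs - zm)) > 1e-8)
      return("Zsummary must equal (Zdensity + Zconnectivity)/2")
    TRUE
  }
)

#' Dose-response panel
#'
#' Viability (percent) of every drug on every cell line over an increasing
#' concentration grid, plus the per-drug per-line summary response (normalized
#' area under the viability curve over log10 concentration, same 0-100 scale).
#'
#' @slot viability drug x cell line x concentration array, percent viability.
#' @slot concentrations strictly increasing concentration grid (uM).
#' @slot response drug x cell line summary-response matrix (AUC viability).
#' @slot removedConcentrations concentrations dropped by
#'   [trimConcentrations()]; empty for an untrimmed panel.
#' @export
setClass("DoseResponsePanel",
  representation(viability = "array", concentrations = "numeric",
                 response = "matrix", removedConcentrations = "numeric"),
  validity = function(object) {
    d <- dim(object@viability)
    if (length(d) != 3) return("viability must be a 3-d array")
    if (d[3] != length(object@concentrations))
      return("third array dim must match concentration grid")
    if (is.unsorted(object@concentrations, strictly = TRUE))
      return("concentrations must be strictly increasing")
    v <- object@viability
    if (any(v < 0 | v > 200, na.rm = TRUE))
      return("viability must lie in [0, 200]")
    if (!identical(dim(object@response), d[1:2]))
      return("response matrix must be drug x cell line")
    if (is.null(dimnames(object@viability)[[1]]))
      return("drug ids required as array dimnames")
    TRUE
  }
)

#' Drug fingerprint matrix
#'
#' Pearson correlations between each drug's per-cell-line summary responses
#' and each preserved module's eigengene over the matched cell lines. Missing
#' entries (zero variance on either side) carry a reason code.
#'
#' @slot cor drug x module correlation matrix; NA where undefined.
#' @slot nPoints number of matched cell lines per correlation.
#' @slot missingReason named character, reason codes for NA entries
#'   ("zero_variance_drug" / "zero_variance_eigengene").
#' @export
setClass("FingerprintMatrix",
  representation(cor = "matrix", nPoints = "integer",
                 missingReason = "character"),
  validity = function(object) {
    r <- object@cor
    if (any(abs(r) > 1 + 1e-10, na.rm = TRUE))
      return("correlations must lie in [-1, 1]")
    if (is.null(rownames(r)) || is.null(colnames(r)))
      return("drug and module names required")
    TRUE
  }
)

#' Resampling consensus clustering of drugs
#'
#' Result of Monti-style consensus clustering: subsample drugs, cluster each
#' subsample, and record how often each pair co-clusters when co-sampled. The
#' number of clusters is chosen by the proportional increase in the area under
#' the consensus CDF (delta-area rule), unless overridden.
#'
#' @slot membership named integer, drug -> cluster id (1..k).
#' @slot k chosen number of clusters.
#' @slot consensus drug x drug co-clustering proportion matrix at the chosen k.
#' @slot diagnostics per-k data.frame: k, area under consensus CDF, delta area.
#' @slot settings list of resampling settings (kRange, nResample,
#'   itemFraction, seed, innerLinkage).
#' @export
setClass("ConsensusClusterResult",
  representation(membership = "integer", k = "integer", consensus = "matrix",
                 diagnostics = "data.frame", settings = "list"),
  validity = function(object) {
    cm <- object@consensus
    if (min(cm) < -1e-10 || max(cm) > 1 + 1e-10)
      return("consensus entries must be proportions in [0, 1]")
    if (max(abs(diag(cm) - 1)) > 1e-10) return("consensus diagonal must be 1")
    if (!.checkSymmetric(cm, 1e-10)) return("consensus must be symmetric")
    k <- object@k
    mem <- object@membership
    if (!all(sort(unique(mem)) == seq_len(k)))
      return("cluster ids must be 1..k with no empty cluster")
    TRUE
  }
)

#' Two-drug combination prediction under independent drug action
#'
#' The IDA expectation for a pair: on each shared cell line the combination
#' viability is the minimum of the two monotherapy viabilities; the IDAcombo
#' score is the largest gain (in viability percentage points) of the mean IDA
#' combination over the best mean monotherapy, across all concentration pairs
#' of the trimmed grid.
#'
#' @slot drugA,drugB drug ids.
#' @slot score IDAcombo score, viability percentage points (>= 0).
#' @slot bestPair named numeric, attaining concentrations (cA, cB) in uM.
#' @slot meanCombo mean IDA combination viability at the best pair.
#' @slot meanMono mean best-monotherapy viability at the best pair.
#' @slot detail per-shared-line data.frame at the best pair.
#' @export
setClass("ComboPrediction",
  representation(drugA = "character", drugB = "character", score = "numeric",
                 bestPair = "numeric", meanCombo = "numeric",
                 meanMono = "numeric", detail = "data.frame"),
  validity = function(object) {
    if (object@score < -1e-9) return("IDAcombo score must be non-negative")
    if (object@meanCombo > object@meanMono + 1e-9)
      return("mean combo viability cannot exceed best monotherapy viability")
    TRUE
  }
)
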