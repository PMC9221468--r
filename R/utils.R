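## internal helpers shared across modules

## standardize matrix rows to mean 0 / sd 1; zero-variance rows become all-0
.stdRows <- function(mat, warn = TRUE) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad) && warn)
    warning(sprintf("%d zero-variance gene(s) standardized to 0: %s",
                    sum(bad), paste(head(rownames(mat)[bad], 5), collapse = ", ")))
  s[bad] <- 1
  out <- (mat - mu) / s
  out[bad, ] <- 0
  out
}

.offDiag <- function(m) m[row(m) != col(m)]

## local RNG scope: run expr under a seed without clobbering the caller's stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## accept a SummarizedExperiment or a plain matrix; return genes x samples matrix
.asExprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("expression input must be a matrix or SummarizedExperiment")
  }
  if (nrow(m) == 0) {
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.null(rownames(m))) stop("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  storage.mode(m) <- "double"
  m
}

#' Tag an expression matrix as a SummarizedExperiment
#'
#' Convenience constructor wrapping a genes x samples matrix into a
#' [SummarizedExperiment::SummarizedExperiment] whose metadata records which
#' dataset (cell lines or tumors) the samples come from.
#'
#' @param mat genes x samples numeric matrix with gene ids as rownames.
#' @param dataset `"cell_line"` or `"tumor"`.
#' @return A `SummarizedExperiment` with one assay `"expr"` and
#'   `metadata()$datasetTag` set.
#' @export
taggedExpression <- function(mat, dataset = c("cell_line", "tumor")) {
  dataset <- match.arg(dataset)
  mat <- .asExprMatrix(mat)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(expr = mat))
  S4Vectors::metadata(se)$datasetTag <- dataset
  se
}

#' Dataset tag of a tagged expression object
#'
#' @param x a `SummarizedExperiment` created by [taggedExpression()].
#' @return `"cell_line"`, `"tumor"`, or `NA` if untagged.
#' @export
datasetTag <- function(x) {
  if (!methods::is(x, "SummarizedExperiment")) return(NA_character_)
  tag <- S4Vectors::metadata(x)$datasetTag
  if (is.null(tag)) NA_character_ else tag
}

#' Match detected modules to a reference labeling by majority overlap
#'
#' For each detected (non-grey) module, finds the reference label carried by
#' the plurality of its genes. Useful for comparing a detected [ModuleSet-class]
#' with simulation ground truth, whose module names differ.
#'
#' @param modules a [ModuleSet-class].
#' @param reference named character vector, gene id -> reference label.
#' @return named character vector: detected module -> majority reference label.
#' @export
matchModules <- function(modules, reference) {
  labs <- moduleLabels(modules)
  common <- intersect(names(labs), names(reference))
  labs <- labs[common]
  ref <- reference[common]
  mods <- setdiff(unique(labs), "grey")
  out <- vapply(mods, function(m) {
    tab <- sort(table(ref[labs == m]), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  out
}

## deterministic TSV/CSV writers (fixed quoting and precision policy)
.writeTSV <- function(df, path, rownames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = TRUE)
}

.writeCSV <- function(df, path) {
  write.csv(df, path, quote = TRUE, row.names = FALSE)
}

## provenance sidecar: <output>.prov.json with parameters/seed/version/inputs.
## no timestamps: reruns with identical inputs must be byte-identical.
.writeProvenance <- function(path, stage, params, seed = NULL, inputs = NULL) {
  prov <- list(
    stage = stage,
    package = "coDrugNet",
    version = as.character(utils::packageVersion("coDrugNet")),
    parameters = params
  )
  if (!is.null(seed)) prov$seed <- seed
  if (!is.null(inputs)) {
    inputs <- inputs[file.exists(inputs)]
    if (length(inputs))
      prov$input_md5 <- as.list(tools::md5sum(inputs))
  }
  jsonlite::write_json(prov, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
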