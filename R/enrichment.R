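## generic over-representation testing of module gene sets

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Gene order is preserved; duplicate genes within a set are
#' deduplicated. Lines with fewer than 3 fields raise an error naming the
#' line; an empty file returns an empty collection with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> gene ids), with the
#'   descriptions in `attr(, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: returning an empty collection")
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 short[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "description") <- setNames(
    vapply(fields, `[`, character(1), 2), names(sets))
  sets
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between the module genes and each gene set, within the analysis universe
#' (conventionally the MAD-filtered network gene space, not the genome).
#' Sets are intersected with the universe first; sets empty after
#' intersection are dropped. P-values are Benjamini-Hochberg adjusted across
#' the tested sets and the table is sorted by p.
#'
#' @param moduleGenes character vector of module gene ids; must be a subset
#'   of `universe`.
#' @param universe character vector, the analysis gene universe.
#' @param sets gene-set collection from [readGMT()] (or any named list of
#'   gene-id vectors).
#' @return data.frame: set, setSize (K, within universe), overlap (k),
#'   moduleSize (n), universeSize (N), p, q — sorted by p.
#' @export
hypergeomEnrich <- function(moduleGenes, universe, sets) {
  universe <- unique(universe)
  moduleGenes <- unique(moduleGenes)
  outside <- setdiff(moduleGenes, universe)
  if (length(outside))
    stop(sprintf("module genes outside the universe: %s",
                 paste(head(outside, 5), collapse = ", ")))
  sets <- lapply(sets, intersect, y = universe)
  keep <- lengths(sets) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d set(s) empty after universe intersection",
                    sum(!keep)))
    sets <- sets[keep]
  }
  if (!length(sets))
    return(data.frame(set = character(0), setSize = integer(0),
                      overlap = integer(0), moduleSize = integer(0),
                      universeSize = integer(0), p = numeric(0),
                      q = numeric(0)))
  N <- length(universe)
  n <- length(moduleGenes)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, moduleGenes)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), setSize = unname(K),
                    overlap = unname(k), moduleSize = n, universeSize = N,
                    p = unname(p), q = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
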