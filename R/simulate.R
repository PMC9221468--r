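## synthetic paired transcriptomes + drug screen with planted ground truth

.defaultConc <- sort(c(0.000780415, 0.007023779, 0.002341244, 0.02107129,
                       0.063213917, 0.189641751, 0.5689253, 1.706775899,
                       5.120327696, 15.36098309, 46.08294931))

#' Default 11-point screening concentration grid
#'
#' The eleven-point, roughly 3-fold dilution series (uM) used by the
#' high-throughput viability screen this package models, in increasing order.
#'
#' @return numeric vector of 11 concentrations (uM).
#' @export
defaultConcentrationGrid <- function() .defaultConc

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: planted
#' co-expression modules shared (or not) between a cell-line and a tumor
#' expression set, and drug responses linearly coupled to module eigengenes.
#'
#' Planted module genes follow a single-latent-factor (spiked covariance)
#' model: `gene = loading * factor(sample) + noiseSd * eps`, scaled by
#' `moduleScale` so module genes pass a raw-MAD filter while background genes
#' (pure noise at `backgroundScale`) do not. Preserved modules re-use the same
#' loadings with a fresh factor realization in the tumor set; non-preserved
#' modules are independent noise there, so they carry no tumor co-expression.
#'
#' Drug summary responses are
#' `clip(base + amplitude * sum_m couplings[d, m] * E_m(line) + amplitude *
#' drugNoiseSd * eps, 0, 100)` so a positive coupling means viability rises
#' with the eigengene (and the drug's killing effect rises where the eigengene
#' is low). Dose-response curves are Hill curves whose per-line EC50 is solved
#' so the log-concentration AUC reproduces the summary response, making
#' potency monotone in response.
#'
#' @param nGenes total gene count.
#' @param moduleSizes integer vector of planted module sizes; their sum must
#'   not exceed `nGenes`, the remainder is background.
#' @param preserved logical per module: shared latent factor in the tumor set?
#' @param nCellLines,nTumors sample counts (defaults 5 and 13).
#' @param nDrugs number of screened drugs.
#' @param couplings optional drugs x modules matrix of signed couplings in
#'   \[-1, 1\]; `NULL` draws a sparse random matrix (1-3 modules per drug,
#'   magnitudes in \[0.3, 1\]).
#' @param drugClass optional integer vector (length `nDrugs`) of planted drug
#'   classes; requires `classCouplings`.
#' @param classCouplings optional class x module coupling prototypes; drugs
#'   inherit their class prototype (plus `classJitterSd` noise).
#' @param classJitterSd per-drug jitter around the class prototype (default 0).
#' @param nConcentrations points in the dose-response grid (default 11).
#' @param concGrid the grid itself; defaults to
#'   [defaultConcentrationGrid()] when `nConcentrations == 11`, otherwise a
#'   log-spaced grid over the same span.
#' @param noiseSd expression noise sd relative to unit factor variance.
#' @param drugNoiseSd drug-response noise, in units of `amplitude`.
#' @param amplitude viability percentage points per eigengene sd (default 15).
#' @param baseActive,baseInactive,activeFraction baseline viabilities for
#'   planted active/inactive drugs and the fraction of actives.
#' @param moduleScale,backgroundScale expression-unit scales for module and
#'   background genes (chosen so the raw-MAD > 1000 filter separates them).
#' @param loadingRange range of per-gene factor loadings.
#' @param hillSlope Hill coefficient of simulated dose-response curves.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return a validated `simConfig` list (class `"simConfig"`).
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 300, moduleSizes = c(60, 50),
#'                  preserved = c(TRUE, FALSE), nDrugs = 10, seed = 7)
simConfig <- function(nGenes = 2000,
                      moduleSizes = c(300, 250, 200, 150, 120, 100, 80, 60),
                      preserved = c(rep(TRUE, 6), rep(FALSE, 2)),
                      nCellLines = 5, nTumors = 13, nDrugs = 100,
                      couplings = NULL, drugClass = NULL,
                      classCouplings = NULL, classJitterSd = 0,
                      nConcentrations = 11, concGrid = NULL,
                      noiseSd = 0.5, drugNoiseSd = 0.1, amplitude = 15,
                      baseActive = 40, baseInactive = 90,
                      activeFraction = 0.95,
                      moduleScale = 3000, backgroundScale = 100,
                      loadingRange = c(0.7, 1), hillSlope = 2, seed = 1) {
  if (sum(moduleSizes) > nGenes)
    stop("configuration error: sum(moduleSizes) exceeds nGenes")
  if (length(preserved) != length(moduleSizes))
    stop("configuration error: preserved flags must match moduleSizes")
  M <- length(moduleSizes)
  if (!is.null(couplings)) {
    couplings <- as.matrix(couplings)
    if (nrow(couplings) != nDrugs || ncol(couplings) != M)
      stop("configuration error: couplings must be nDrugs x nModules")
    if (max(abs(couplings)) > 1)
      stop("configuration error: couplings must lie in [-1, 1]")
  }
  if (!is.null(drugClass)) {
    if (is.null(classCouplings))
      stop("configuration error: drugClass requires classCouplings")
    classCouplings <- as.matrix(classCouplings)
    if (length(drugClass) != nDrugs)
      stop("configuration error: drugClass must have length nDrugs")
    if (any(drugClass < 1 | drugClass > nrow(classCouplings)))
      stop("configuration error: drugClass references a missing prototype")
    if (ncol(classCouplings) != M)
      stop("configuration error: classCouplings must reference valid modules")
  }
  if (is.null(concGrid)) {
    concGrid <- if (nConcentrations == 11) .defaultConc
    else 10^seq(log10(min(.defaultConc)), log10(max(.defaultConc)),
                length.out = nConcentrations)
  }
  if (length(concGrid) != nConcentrations || is.unsorted(concGrid, strictly = TRUE))
    stop("configuration error: concGrid must be strictly increasing and match nConcentrations")
  cfg <- list(nGenes = nGenes, moduleSizes = as.integer(moduleSizes),
              preserved = preserved, nCellLines = nCellLines,
              nTumors = nTumors, nDrugs = nDrugs, couplings = couplings,
              drugClass = drugClass, classCouplings = classCouplings,
              classJitterSd = classJitterSd,
              nConcentrations = nConcentrations, concGrid = concGrid,
              noiseSd = noiseSd, drugNoiseSd = drugNoiseSd,
              amplitude = amplitude, baseActive = baseActive,
              baseInactive = baseInactive, activeFraction = activeFraction,
              moduleScale = moduleScale, backgroundScale = backgroundScale,
              loadingRange = loadingRange, hillSlope = hillSlope, seed = seed)
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate the paired cell-line / tumor expression datasets
#'
#' Draws the two expression matrices of a [simConfig()] and the ground truth
#' needed for parameter-recovery testing. See [simConfig()] for the
#' generative model.
#'
#' @param config a [simConfig()] object.
#' @return list with elements
#'   \describe{
#'     \item{cell}{`SummarizedExperiment`, genes x `nCellLines`, tag
#'       `"cell_line"`.}
#'     \item{tumor}{`SummarizedExperiment`, genes x `nTumors`, tag `"tumor"`.}
#'     \item{truth}{list: `moduleOfGene` (gene -> `"M1"`.. or
#'       `"background"`), `preserved` (named logical per module),
#'       `loadings` (named numeric for module genes).}
#'   }
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed, {
    nG <- config$nGenes
    sizes <- config$moduleSizes
    M <- length(sizes)
    genes <- sprintf("g%05d", seq_len(nG))
    modNames <- paste0("M", seq_len(M))
    moduleOf <- rep("background", nG)
    idx <- 0
    memberIdx <- vector("list", M)
    for (m in seq_len(M)) {
      memberIdx[[m]] <- idx + seq_len(sizes[m])
      moduleOf[memberIdx[[m]]] <- modNames[m]
      idx <- idx + sizes[m]
    }
    names(moduleOf) <- genes

    loadings <- setNames(rep(NA_real_, nG), genes)
    nMod <- sum(sizes)
    loadings[seq_len(nMod)] <- runif(nMod, config$loadingRange[1],
                                     config$loadingRange[2])

    fCell <- matrix(rnorm(M * config$nCellLines), M, config$nCellLines)
    fTum <- matrix(rnorm(M * config$nTumors), M, config$nTumors)

    mkBlock <- function(nSamp, factors, sharedMask) {
      x <- matrix(rnorm(nG * nSamp), nG, nSamp,
                  dimnames = list(genes, NULL))
      out <- x * config$backgroundScale          # background default
      for (m in seq_len(M)) {
        rows <- memberIdx[[m]]
        if (sharedMask[m]) {
          sig <- outer(loadings[rows], factors[m, ]) +
            config$noiseSd * x[rows, , drop = FALSE]
        } else {
          ## non-preserved in this dataset: independent noise, module-level
          ## scale kept so gene variability is comparable
          sig <- x[rows, , drop = FALSE] *
            sqrt(mean(config$loadingRange)^2 + config$noiseSd^2)
        }
        out[rows, ] <- config$moduleScale * sig
      }
      out
    }

    cellMat <- mkBlock(config$nCellLines, fCell, rep(TRUE, M))
    tumMat <- mkBlock(config$nTumors, fTum, config$preserved)
    colnames(cellMat) <- sprintf("line%02d", seq_len(config$nCellLines))
    colnames(tumMat) <- sprintf("tumor%02d", seq_len(config$nTumors))

    list(cell = taggedExpression(cellMat, "cell_line"),
         tumor = taggedExpression(tumMat, "tumor"),
         truth = list(moduleOfGene = moduleOf,
                      preserved = setNames(config$preserved, modNames),
                      loadings = loadings[seq_len(nMod)]))
  })
}

#' Ground-truth module assignment as a ModuleSet
#'
#' Converts the generator's `truth$moduleOfGene` labeling into a
#' [ModuleSet-class] (background genes become `"grey"`), e.g. to compute the
#' true module eigengenes that the drug-screen generator couples to.
#'
#' @param truth the `truth` element returned by [simulateExpression()].
#' @return a [ModuleSet-class] with labels `"M1"`, ..., `"grey"`.
#' @export
trueModuleSet <- function(truth) {
  labs <- truth$moduleOfGene
  labs[labs == "background"] <- "grey"
  new("ModuleSet", labels = labs, minModuleSize = 0)
}

## normalized trapezoid AUC of viability over log10(concentration);
## shared by computeAUC() and the Hill-curve solver
.aucViability <- function(viab, conc) {
  x <- log10(conc)
  n <- length(x)
  area <- sum(diff(x) * (viab[-1] + viab[-n]) / 2)
  area / (x[n] - x[1])
}

## four-parameter Hill curve, top 100, bottom 0, fixed slope
.hillCurve <- function(conc, ec50, slope) {
  100 - 100 * conc^slope / (conc^slope + ec50^slope)
}

## EC50 such that the log-concentration AUC of the Hill curve equals target
.solveEC50 <- function(target, conc, slope) {
  lo <- log10(min(conc)) - 6
  hi <- log10(max(conc)) + 6
  f <- function(lec) .aucViability(.hillCurve(conc, 10^lec, slope), conc) - target
  if (f(lo) >= 0) return(10^lo)   # target at/below the achievable floor
  if (f(hi) <= 0) return(10^hi)   # target at/above the achievable ceiling
  10^uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Simulate the drug screen coupled to module eigengenes
#'
#' Generates a [DoseResponsePanel-class] whose per-drug per-line summary
#' responses are linear in the supplied module eigengenes (see [simConfig()]
#' for the response model), plus a clinical annotation table with randomized
#' statuses and pChEMBL values spanning the usual > 6 cutoff. Hill
#' dose-response curves are solved per drug and line so their
#' log-concentration AUC reproduces the summary response.
#'
#' @param config a [simConfig()].
#' @param truth the `truth` element of [simulateExpression()].
#' @param eigengenes an [EigengeneSet-class] computed on the generated
#'   cell-line samples (e.g. via [moduleEigengenes()] with
#'   [trueModuleSet()]); its sample count must equal `config$nCellLines`.
#' @return list with elements `panel` ([DoseResponsePanel-class]),
#'   `annotations` (data.frame: drug, status, targets, pchembl), and
#'   `truth` (list: `couplings` drugs x modules, `drugClass` or NULL,
#'   `active` logical).
#' @export
simulateDrugScreen <- function(config, truth, eigengenes) {
  stopifnot(inherits(config, "simConfig"))
  E <- eigengeneScores(eigengenes)
  if (ncol(E) != config$nCellLines)
    stop(sprintf("dimension error: eigengenes have %d samples but config expects %d cell lines",
                 ncol(E), config$nCellLines))
  M <- length(config$moduleSizes)
  modNames <- paste0("M", seq_len(M))

  .withSeed(config$seed + 1L, {
    nD <- config$nDrugs
    drugs <- sprintf("drug%03d", seq_len(nD))
    lines <- colnames(E)

    ## couplings: explicit > class prototypes > sparse random
    if (!is.null(config$couplings)) {
      C <- config$couplings
      drugClass <- config$drugClass
    } else if (!is.null(config$drugClass)) {
      C <- config$classCouplings[config$drugClass, , drop = FALSE]
      if (config$classJitterSd > 0)
        C <- C + matrix(rnorm(length(C), sd = config$classJitterSd), nrow(C))
      C <- pmin(pmax(C, -1), 1)
      drugClass <- config$drugClass
    } else {
      C <- matrix(0, nD, M)
      for (d in seq_len(nD)) {
        k <- sample(seq_len(min(3, M)), 1)
        targets <- sample(seq_len(M), k)
        C[d, targets] <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.3, 1)
      }
      drugClass <- NULL
    }
    dimnames(C) <- list(drugs, modNames)

    active <- rep(FALSE, nD)
    active[sample(nD, round(config$activeFraction * nD))] <- TRUE
    base <- ifelse(active, config$baseActive, config$baseInactive)

    Em <- E[modNames[modNames %in% rownames(E)], , drop = FALSE]
    Cm <- C[, rownames(Em), drop = FALSE]
    eff <- Cm %*% Em                                   # drugs x lines
    noise <- matrix(rnorm(nD * length(lines)), nD)
    response <- base + config$amplitude * eff +
      config$amplitude * config$drugNoiseSd * noise
    response <- pmin(pmax(response, 0), 100)
    dimnames(response) <- list(drugs, lines)

    conc <- config$concGrid
    viab <- array(NA_real_, c(nD, length(lines), length(conc)),
                  dimnames = list(drugs, lines, format(conc)))
    for (d in seq_len(nD)) {
      for (l in seq_along(lines)) {
        s <- response[d, l]
        if (s >= 99.95) {
          viab[d, l, ] <- 100            # inert: zero maximal effect
        } else {
          ec <- .solveEC50(s, conc, config$hillSlope)
          viab[d, l, ] <- pmin(pmax(.hillCurve(conc, ec, config$hillSlope), 0), 100)
        }
      }
    }

    ann <- data.frame(
      drug = drugs,
      status = sample(.statusVocab, nD, replace = TRUE,
                      prob = c(0.2, 0.1, 0.2, 0.2, 0.3)),
      targets = vapply(seq_len(nD), function(i)
        paste(sprintf("TGT%02d", sample(50, sample(1:3, 1))), collapse = ";"),
        character(1)),
      pchembl = ifelse(runif(nD) < 0.15, NA_real_, runif(nD, 3.5, 9.5)),
      stringsAsFactors = FALSE
    )

    panel <- new("DoseResponsePanel", viability = viab, concentrations = conc,
                 response = response, removedConcentrations = numeric(0))
    list(panel = panel, annotations = ann,
         truth = list(couplings = C, drugClass = drugClass, active = active))
  })
}

#' Write a simulated bundle to disk as plain-text files
#'
#' Serializes a simulated study (expression pair, screen, annotations, ground
#' truth) in the file formats [runPipeline()] ingests: TSV expression
#' matrices, long-format dose-response CSV, annotation CSV, and a ground-truth
#' JSON.
#'
#' @param sim result of [simulateExpression()].
#' @param screen result of [simulateDrugScreen()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimBundle <- function(sim, screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cell = file.path(dir, "expression_cell_lines.tsv"),
             tumor = file.path(dir, "expression_tumors.tsv"),
             screen = file.path(dir, "drug_screen.csv"),
             response = file.path(dir, "drug_response_summary.csv"),
             annotations = file.path(dir, "drug_annotations.csv"),
             truth = file.path(dir, "ground_truth.json"))
  .writeTSV(as.data.frame(SummarizedExperiment::assay(sim$cell)),
            paths["cell"], rownames = TRUE)
  .writeTSV(as.data.frame(SummarizedExperiment::assay(sim$tumor)),
            paths["tumor"], rownames = TRUE)

  panel <- screen$panel
  v <- panelViability(panel)
  long <- expand.grid(drug = panelDrugs(panel),
                      cell_line = panelCellLines(panel),
                      concentration_uM = concentrations(panel),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$viability_pct <- as.vector(v)
  .writeCSV(long, paths["screen"])

  resp <- as.data.frame(panelResponse(panel))
  resp <- cbind(drug = rownames(resp), resp)
  .writeCSV(resp, paths["response"])
  .writeCSV(screen$annotations, paths["annotations"])

  jsonlite::write_json(
    list(moduleOfGene = as.list(sim$truth$moduleOfGene),
         preserved = as.list(sim$truth$preserved),
         couplings = screen$truth$couplings,
         drugClass = screen$truth$drugClass,
         active = screen$truth$active),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
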