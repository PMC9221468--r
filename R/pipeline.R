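## end-to-end orchestration with provenance

#' Pipeline configuration
#'
#' Assembles and validates the full parameter set for [runPipeline()].
#' Inputs can be file paths (TSV expression, long-format screen CSV,
#' annotation CSV, optional GMT) or in-memory objects; every stage parameter
#' has the pipeline's default. A single global `seed` is fanned out to fixed
#' per-stage sub-seeds so stages can be rerun in isolation reproducibly.
#'
#' @param cell,tumor expression inputs: file paths (TSV, genes x samples) or
#'   matrices / `SummarizedExperiment`s.
#' @param screen dose-response input: long-format file path (see
#'   [readDoseResponse()]) or a [DoseResponsePanel-class].
#' @param annotations annotation input: CSV path or data.frame.
#' @param gmt optional GMT file path for module enrichment.
#' @param outdir output directory for artifacts.
#' @param madThreshold,madLog2 MAD filter settings (see [madFilter()]).
#' @param power soft power: a number, or `"auto"` for [pickSoftPower()]
#'   (default 8).
#' @param minModuleSize,cutHeight,mergeCut module detection settings.
#' @param scaleQuantile consensus TOM scaling quantile (default 0.95).
#' @param detectOn `"consensus"` (default, cross-dataset modules) or
#'   `"reference"` (cell-line TOM).
#' @param nPerm,preservationThreshold preservation settings (defaults 100, 5).
#' @param viabilityCutoff median-viability pre-selection cutoff (default 55).
#' @param minPchembl,statuses annotation filter settings.
#' @param kRange,nResample,itemFraction,k consensus clustering settings.
#' @param topN candidates per cluster (default 15).
#' @param anchorDrug anchor for combination strategies; `NULL` picks the
#'   top-ranked candidate.
#' @param partnerCluster partner cluster for the horizontal strategy; `NULL`
#'   picks the cluster whose mean fingerprint is most anti-correlated with
#'   the anchor's.
#' @param minSimilarity,scoreThreshold combination settings (defaults 0.8, 1).
#' @param seed global RNG seed (default 1).
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(cell, tumor, screen, annotations, gmt = NULL,
                           outdir = tempfile("codrugnet"),
                           madThreshold = 1000, madLog2 = FALSE,
                           power = 8, minModuleSize = 30, cutHeight = 0.995,
                           mergeCut = 0.25, scaleQuantile = 0.95,
                           detectOn = c("consensus", "reference"),
                           nPerm = 100, preservationThreshold = 5,
                           viabilityCutoff = 55, minPchembl = 6,
                           statuses = advancedStatuses(), kRange = 2:6,
                           nResample = 100, itemFraction = 0.8, k = NULL,
                           topN = 15, anchorDrug = NULL,
                           partnerCluster = NULL, minSimilarity = 0.8,
                           scoreThreshold = 1, seed = 1) {
  detectOn <- match.arg(detectOn)
  for (x in list(cell, tumor, screen, annotations, gmt)) {
    if (is.character(x) && length(x) == 1 && !file.exists(x))
      stop(sprintf("input file not found: %s", x))
  }
  if (!identical(power, "auto") && (!is.numeric(power) || power < 1))
    stop("power must be a number >= 1 or \"auto\"")
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

## fixed per-stage sub-seed derivation from the global seed
.stageSeed <- function(seed, idx) (abs(seed) %% 1000000L) * 1000L + idx

#' Run the full drug-mining pipeline
#'
#' Executes preprocess -> network -> module detection -> eigengenes ->
#' preservation -> screen filters -> fingerprint -> consensus clustering ->
#' candidate ranking -> IDA combinations (-> enrichment when a GMT is given),
#' writing every artifact as plain text under `config$outdir` with a JSON
#' provenance sidecar (parameters, sub-seed, package version, input
#' checksums; no timestamps, so reruns with identical inputs are
#' byte-identical). A stage failure halts with the stage name; artifacts
#' already written are retained.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list of all stage results plus `paths` of written
#'   files.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  inputFiles <- unlist(Filter(is.character,
                              config[c("cell", "tumor", "screen",
                                       "annotations", "gmt")]))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  emit <- function(obj, file, stageName, params, seed = NULL,
                   writer = .writeCSV, ...) {
    p <- file.path(config$outdir, file)
    writer(obj, p, ...)
    .writeProvenance(p, stageName, params, seed, inputFiles)
    paths[[file]] <<- p
    p
  }
  readExpr <- function(x) {
    if (is.character(x))
      as.matrix(read.table(x, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE))
    else .asExprMatrix(x)
  }

  ## -- preprocess ----------------------------------------------------------
  merged <- stage("preprocess", {
    cellMat <- readExpr(config$cell)
    tumMat <- readExpr(config$tumor)
    filtered <- madFilter(cellMat, config$madThreshold, config$madLog2)
    if (nrow(filtered) == 0) stop("MAD filter removed every gene")
    m <- intersectAndMerge(filtered, tumMat)
    report <- list(genes_in = nrow(cellMat), genes_after_mad = nrow(filtered),
                   genes_merged = nrow(cellExpr(m)),
                   mad_threshold = config$madThreshold,
                   mad_log2 = config$madLog2)
    p <- file.path(config$outdir, "preprocess_report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
    paths[["preprocess_report.json"]] <- p
    m
  })

  ## -- network -------------------------------------------------------------
  net <- stage("network", {
    if (identical(config$power, "auto")) {
      sp <- pickSoftPower(merged)
      emit(sp$report, "soft_power.csv", "network",
           list(mode = "auto", chosen = sp$power,
                criterionMet = sp$criterionMet))
      beta <- sp$power
    } else beta <- config$power
    adjCell <- adjacencyFromExpr(cellExpr(merged), beta)
    adjTum <- adjacencyFromExpr(tumorExpr(merged), beta)
    tomCell <- tomSimilarity(adjCell)
    tomTum <- tomSimilarity(adjTum)
    cons <- consensusTOM(tomCell, tomTum, config$scaleQuantile)
    list(beta = beta, tomCell = tomCell, tomTum = tomTum, consensus = cons)
  })

  ## -- modules -------------------------------------------------------------
  modules <- stage("modules", {
    target <- if (config$detectOn == "consensus") net$consensus else net$tomCell
    mods <- detectModules(target, merged, config$minModuleSize,
                          config$cutHeight, config$mergeCut)
    if (!length(moduleNames(mods))) stop("no modules detected")
    emit(data.frame(gene = names(moduleLabels(mods)),
                    module = unname(moduleLabels(mods))),
         "module_assignment.tsv", "modules",
         list(minModuleSize = config$minModuleSize,
              cutHeight = config$cutHeight, mergeCut = config$mergeCut,
              detectOn = config$detectOn, power = net$beta),
         writer = .writeTSV)
    mods
  })

  eig <- stage("eigengenes", {
    combined <- moduleEigengenes(merged, modules)
    cellOnly <- moduleEigengenes(cellExpr(merged), modules)
    emit(as.data.frame(eigengeneScores(combined)), "eigengenes_combined.tsv",
         "eigengenes", list(), writer = .writeTSV, rownames = TRUE)
    emit(as.data.frame(eigengeneScores(cellOnly)), "eigengenes_cell.tsv",
         "eigengenes", list(), writer = .writeTSV, rownames = TRUE)
    if (length(moduleNames(modules)) >= 2)
      emit(as.data.frame(eigengeneAdjacency(combined)),
           "eigengene_adjacency.tsv", "eigengenes", list(),
           writer = .writeTSV, rownames = TRUE)
    list(combined = combined, cell = cellOnly)
  })

  pres <- stage("preservation", {
    ps <- preservationZsummary(cellExpr(merged), tumorExpr(merged), modules,
                               nPerm = config$nPerm,
                               seed = .stageSeed(config$seed, 1L))
    emit(preservationTable(ps), "preservation.tsv", "preservation",
         list(nPerm = config$nPerm, beta = 1,
              threshold = config$preservationThreshold),
         seed = .stageSeed(config$seed, 1L), writer = .writeTSV)
    ps
  })
  preserved <- preservedModules(pres, config$preservationThreshold)

  ## -- drug screen ---------------------------------------------------------
  screenRes <- stage("drugscreen", {
    panel <- if (is.character(config$screen)) readDoseResponse(config$screen)
    else config$screen
    ann <- if (is.character(config$annotations))
      readDrugAnnotations(config$annotations) else config$annotations
    passViab <- viabilityPrefilter(panel, config$viabilityCutoff)
    passAnn <- annotationFilter(ann, config$minPchembl, statuses = NULL)
    survivors <- intersect(passViab, passAnn)
    med <- apply(panelResponse(panel), 1, median)
    emit(data.frame(drug = names(med), median_response = unname(med),
                    pass_viability = names(med) %in% passViab,
                    pass_annotation = names(med) %in% passAnn,
                    selected = names(med) %in% survivors),
         "prefilter_survivors.csv", "drugscreen",
         list(viabilityCutoff = config$viabilityCutoff,
              minPchembl = config$minPchembl))
    list(panel = panel, ann = ann, survivors = survivors)
  })

  ## -- fingerprint + clustering -------------------------------------------
  fp <- stage("fingerprint", {
    if (!length(preserved))
      stop("no preserved modules (Zsummary threshold too strict?)")
    f <- drugModuleCorrelations(screenRes$panel, eig$cell, preserved,
                                drugs = screenRes$survivors)
    emit(as.data.frame(fingerprintCor(f)), "fingerprint.tsv", "fingerprint",
         list(preserved = preserved,
              threshold = config$preservationThreshold),
         writer = .writeTSV, rownames = TRUE)
    f
  })

  clusters <- stage("cluster", {
    cc <- consensusClusterDrugs(fp, config$kRange, config$nResample,
                                config$itemFraction,
                                seed = .stageSeed(config$seed, 2L),
                                k = config$k)
    emit(as.data.frame(consensusMatrix(cc)), "consensus_matrix.tsv",
         "cluster", list(k = cc@k), writer = .writeTSV, rownames = TRUE)
    emit(clusterDiagnostics(cc), "cluster_diagnostics.csv", "cluster",
         cc@settings, seed = .stageSeed(config$seed, 2L))
    emit(data.frame(drug = names(clusterMembership(cc)),
                    cluster = unname(clusterMembership(cc))),
         "drug_clusters.csv", "cluster", cc@settings,
         seed = .stageSeed(config$seed, 2L))
    cc
  })

  candidates <- stage("candidates", {
    cand <- withCallingHandlers(
      rankCandidates(fp, clusters, screenRes$ann, config$topN,
                     config$statuses),
      warning = function(w) invokeRestart("muffleWarning"))
    emit(cand, "candidate_list1.csv", "candidates",
         list(topN = config$topN, statuses = config$statuses))
    cand
  })

  ## -- combinations --------------------------------------------------------
  combos <- stage("idacombo", {
    trimmed <- trimConcentrations(screenRes$panel)
    anchor <- config$anchorDrug
    if (is.null(anchor) && nrow(candidates))
      anchor <- candidates$drug[which.min(candidates$score)]
    if (is.null(anchor)) {
      warning("no anchor drug available; skipping combination prediction")
      return(NULL)
    }
    vert <- suppressWarnings(enumerateCombinations(
      "vertical", trimmed, fp, anchor, ann = screenRes$ann,
      statuses = config$statuses, minSimilarity = config$minSimilarity,
      scoreThreshold = config$scoreThreshold))
    partner <- config$partnerCluster
    if (is.null(partner)) {
      mem <- clusterMembership(clusters)
      r <- fingerprintCor(fp)
      if (anchor %in% names(mem) && anchor %in% rownames(r)) {
        own <- mem[[anchor]]
        other <- setdiff(sort(unique(mem)), own)
        if (length(other)) {
          compl <- vapply(other, function(cl) {
            members <- intersect(names(mem)[mem == cl], rownames(r))
            if (!length(members)) return(NA_real_)
            mean(cor(t(r[members, , drop = FALSE]), r[anchor, ]))
          }, numeric(1))
          if (any(is.finite(compl))) partner <- other[which.min(compl)]
        }
      }
    }
    horiz <- if (!is.null(partner)) suppressWarnings(enumerateCombinations(
      "horizontal", trimmed, fp, anchor, clusters, partner,
      ann = screenRes$ann, statuses = config$statuses,
      scoreThreshold = config$scoreThreshold)) else NULL
    list2 <- rbind(vert, horiz)
    emit(list2, "candidate_list2.csv", "idacombo",
         list(anchor = anchor, partnerCluster = partner,
              minSimilarity = config$minSimilarity,
              scoreThreshold = config$scoreThreshold,
              removed_concentrations = removedConcentrations(trimmed)))
    vertSet <- unique(c(anchor, vert$drugA, vert$drugB))
    if (length(vertSet) >= 2)
      emit(as.data.frame(comboScoreMatrix(trimmed, vertSet)),
           "combo_score_matrix.tsv", "idacombo", list(anchor = anchor),
           writer = .writeTSV, rownames = TRUE)
    list(anchor = anchor, partnerCluster = partner, table = list2)
  })

  ## -- enrichment (optional) ----------------------------------------------
  enrich <- NULL
  if (!is.null(config$gmt)) {
    enrich <- stage("enrichment", {
      sets <- readGMT(config$gmt)
      universe <- rownames(cellExpr(merged))
      labs <- moduleLabels(modules)
      res <- lapply(preserved, function(m) {
        tab <- suppressWarnings(
          hypergeomEnrich(names(labs)[labs == m], universe, sets))
        emit(tab, sprintf("enrichment_%s.csv", m), "enrichment",
             list(module = m, universe_size = length(universe)))
        tab
      })
      names(res) <- preserved
      res
    })
  }

  summary <- list(
    genes = nrow(cellExpr(merged)),
    power = net$beta,
    modules = length(moduleNames(modules)),
    preserved_modules = preserved,
    drugs_selected = length(screenRes$survivors),
    chosen_k = clusters@k,
    anchor = if (!is.null(combos)) combos$anchor else NULL,
    partner_cluster = if (!is.null(combos)) combos$partnerCluster else NULL,
    seed = config$seed
  )
  pSum <- file.path(config$outdir, "run_summary.json")
  jsonlite::write_json(summary, pSum, auto_unbox = TRUE, digits = NA)
  paths[["run_summary.json"]] <- pSum

  invisible(list(merged = merged, network = net, modules = modules,
                 eigengenes = eig, preservation = pres,
                 preserved = preserved, screen = screenRes,
                 fingerprint = fp, clusters = clusters,
                 candidates = candidates, combos = combos,
                 enrichment = enrich, summary = summary, paths = paths))
}
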