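## shared fixtures, all generated in code

## small paired-expression study with 4 planted modules (3 preserved)
smallStudy <- function(seed = 42, nCellLines = 15, nTumors = 15) {
  cfg <- simConfig(
    nGenes = 600, moduleSizes = c(120, 100, 80, 60),
    preserved = c(TRUE, TRUE, TRUE, FALSE),
    nCellLines = nCellLines, nTumors = nTumors, nDrugs = 60, seed = seed)
  sim <- simulateExpression(cfg)
  list(cfg = cfg, sim = sim)
}

## hand-built dose-response panel from a lines x conc viability matrix per drug
handPanel <- function(drugViab, conc) {
  drugs <- names(drugViab)
  lines <- rownames(drugViab[[1]])
  v <- array(NA_real_, c(length(drugs), length(lines), length(conc)),
             dimnames = list(drugs, lines, format(conc)))
  for (d in drugs) v[d, , ] <- drugViab[[d]]
  doseResponsePanel(v, conc)
}

## flat-viability panel: every drug x line sits at a constant level
flatPanel <- function(levels, lines = c("L1", "L2"), conc = c(0.01, 0.1, 1, 10)) {
  drugViab <- lapply(levels, function(lv)
    matrix(lv, length(lines), length(conc), dimnames = list(lines, NULL)))
  handPanel(drugViab, conc)
}

## adjacency-kind network straight from a symmetric matrix
mkAdjacency <- function(m, beta = 1) {
  diag(m) <- 1
  new("CoexNetwork", mat = m, kind = "adjacency", beta = beta)
}

## brute-force TOM: literal triple loop over the defining formula
bruteTOM <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  k <- rowSums(a) - 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    w[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

## exact upper-tail hypergeometric by enumeration over all possible overlaps
bruteHyper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## brute-force IDAcombo score: exhaustive double loop over concentration pairs
bruteIdaScore <- function(panel, drugA, drugB) {
  v <- panelViability(panel)
  conc <- concentrations(panel)
  a <- v[drugA, , ]
  b <- v[drugB, , ]
  best <- -Inf
  for (iA in seq_along(conc)) for (iB in seq_along(conc)) {
    mono <- min(mean(a[, iA]), mean(b[, iB]))
    combo <- mean(pmin(a[, iA], b[, iB]))
    best <- max(best, mono - combo)
  }
  best
}

ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

## synthetic bundle on disk for the orchestrator: class-structured couplings so
## that anchor-like drugs (vertical combos) exist
pipelineBundle <- function(dir, seed = 101) {
  proto <- rbind(c(0.8, 0.7, -0.6, 0), c(-0.8, -0.6, 0.7, 0))
  cfg <- simConfig(nGenes = 600, moduleSizes = c(120, 100, 80, 60),
                   preserved = c(TRUE, TRUE, TRUE, FALSE),
                   nCellLines = 15, nTumors = 15, nDrugs = 40,
                   drugNoiseSd = 0.1, drugClass = rep(1:2, each = 20),
                   classCouplings = proto, classJitterSd = 0.05, seed = seed)
  sim <- simulateExpression(cfg)
  eig <- moduleEigengenes(SummarizedExperiment::assay(sim$cell),
                          trueModuleSet(sim$truth))
  scr <- simulateDrugScreen(cfg, sim$truth, eig)
  writeSimBundle(sim, scr, dir)
}

pipelineCfg <- function(paths, outdir, seed = 7) {
  pipelineConfig(
    cell = unname(paths[["cell"]]), tumor = unname(paths[["tumor"]]),
    screen = unname(paths[["screen"]]),
    annotations = unname(paths[["annotations"]]),
    outdir = outdir, nPerm = 60, nResample = 60, kRange = 2:4,
    minPchembl = 0, seed = seed)
}
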