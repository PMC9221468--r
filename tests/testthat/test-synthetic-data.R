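test_that("simConfig validates its invariants", {
  expect_error(simConfig(nGenes = 100, moduleSizes = c(60, 60),
                         preserved = c(TRUE, TRUE)),
               "exceeds nGenes")
  expect_error(simConfig(moduleSizes = c(50, 50), preserved = TRUE),
               "preserved")
  expect_error(simConfig(nDrugs = 4, drugClass = rep(5, 4),
                         classCouplings = matrix(0, 2, 8)),
               "missing prototype")
  expect_error(simConfig(nDrugs = 4,
                         couplings = matrix(2, 4, 8)),
               "couplings")
})

test_that("a fixed seed gives byte-identical simulations", {
  cfg <- simConfig(nGenes = 200, moduleSizes = c(40, 30),
                   preserved = c(TRUE, FALSE), nDrugs = 12, seed = 9)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(a$cell),
                   SummarizedExperiment::assay(b$cell))
  expect_identical(SummarizedExperiment::assay(a$tumor),
                   SummarizedExperiment::assay(b$tumor))
  expect_identical(a$truth, b$truth)
  eig <- moduleEigengenes(SummarizedExperiment::assay(a$cell),
                          trueModuleSet(a$truth))
  s1 <- simulateDrugScreen(cfg, a$truth, eig)
  s2 <- simulateDrugScreen(cfg, a$truth, eig)
  expect_identical(panelViability(s1$panel), panelViability(s2$panel))
  expect_identical(s1$annotations, s2$annotations)
})

test_that("noise-free planted modules are perfectly coherent in both datasets", {
  cfg <- simConfig(nGenes = 60, moduleSizes = 30, preserved = TRUE,
                   nCellLines = 8, nTumors = 8, nDrugs = 5,
                   noiseSd = 0, seed = 4)
  sim <- simulateExpression(cfg)
  for (se in list(sim$cell, sim$tumor)) {
    mat <- SummarizedExperiment::assay(se)
    genes <- names(sim$truth$moduleOfGene)[sim$truth$moduleOfGene == "M1"]
    r <- cor(t(mat[genes, ]))
    expect_equal(unname(r), matrix(1, 30, 30), tolerance = 1e-12)
  }
})

test_that("module genes pass the MAD filter and background genes do not", {
  st <- smallStudy(seed = 8)
  mat <- SummarizedExperiment::assay(st$sim$cell)
  madv <- apply(mat, 1, mad, constant = 1)
  inModule <- st$sim$truth$moduleOfGene != "background"
  expect_gt(mean(madv[inModule] > 1000), 0.9)
  expect_equal(sum(madv[!inModule] > 1000), 0)
})

test_that("screen viabilities are bounded and Hill curves are monotone", {
  st <- smallStudy(seed = 5)
  eig <- moduleEigengenes(SummarizedExperiment::assay(st$sim$cell),
                          trueModuleSet(st$sim$truth))
  scr <- simulateDrugScreen(st$cfg, st$sim$truth, eig)
  v <- panelViability(scr$panel)
  expect_true(all(v >= 0 & v <= 100))
  expect_true(all(panelResponse(scr$panel) >= 0 &
                    panelResponse(scr$panel) <= 100))
  diffs <- apply(v, c(1, 2), function(curve) max(diff(curve)))
  expect_true(all(diffs <= 1e-9))
})

test_that("an inert drug stays at 100 percent viability with AUC 100", {
  cfg <- simConfig(nGenes = 100, moduleSizes = 40, preserved = TRUE,
                   nCellLines = 6, nTumors = 6, nDrugs = 4,
                   couplings = matrix(0, 4, 1), amplitude = 0,
                   drugNoiseSd = 0, activeFraction = 0,
                   baseInactive = 100, seed = 2)
  sim <- simulateExpression(cfg)
  eig <- moduleEigengenes(SummarizedExperiment::assay(sim$cell),
                          trueModuleSet(sim$truth))
  scr <- simulateDrugScreen(cfg, sim$truth, eig)
  expect_equal(unname(panelViability(scr$panel)[1, 1, ]),
               rep(100, 11))
  expect_equal(unname(panelResponse(scr$panel)),
               matrix(100, 4, 6))
  expect_equal(computeAUC(panelViability(scr$panel)[1, 1, ],
                          concentrations(scr$panel)), 100)
})

test_that("screen generation checks the eigengene sample dimension", {
  cfg <- simConfig(nGenes = 100, moduleSizes = 40, preserved = TRUE,
                   nCellLines = 6, nTumors = 4, nDrugs = 4, seed = 2)
  sim <- simulateExpression(cfg)
  ## eigengenes on tumor samples: wrong sample count for the screen
  eigWrong <- moduleEigengenes(SummarizedExperiment::assay(sim$tumor),
                               trueModuleSet(sim$truth))
  expect_error(simulateDrugScreen(cfg, sim$truth, eigWrong), "dimension")
})

test_that("planted coupling signs survive the Hill/AUC round trip", {
  cfg <- simConfig(nGenes = 300, moduleSizes = c(80, 60), preserved = c(TRUE, TRUE),
                   nCellLines = 10, nTumors = 6, nDrugs = 30,
                   drugNoiseSd = 0, seed = 13)
  sim <- simulateExpression(cfg)
  eig <- moduleEigengenes(SummarizedExperiment::assay(sim$cell),
                          trueModuleSet(sim$truth))
  scr <- simulateDrugScreen(cfg, sim$truth, eig)
  ## recompute responses from the curves instead of trusting the planted summary
  panel <- doseResponsePanel(panelViability(scr$panel), concentrations(scr$panel))
  fp <- drugModuleCorrelations(panel, eig)
  r <- fingerprintCor(fp)
  C <- scr$truth$couplings[, colnames(r)]
  strong <- abs(C) > 0.5 & !is.na(r)
  expect_true(all(sign(r[strong]) == sign(C[strong])))
})

test_that("writeSimBundle round-trips through the file readers", {
  st <- smallStudy(seed = 3, nCellLines = 6, nTumors = 6)
  eig <- moduleEigengenes(SummarizedExperiment::assay(st$sim$cell),
                          trueModuleSet(st$sim$truth))
  scr <- simulateDrugScreen(st$cfg, st$sim$truth, eig)
  dir <- withr::local_tempdir()
  paths <- writeSimBundle(st$sim, scr, dir)
  expect_true(all(file.exists(paths)))
  panel <- readDoseResponse(paths[["screen"]])
  expect_equal(panelViability(panel)[panelDrugs(scr$panel), , ],
               panelViability(scr$panel), tolerance = 1e-12)
  ann <- readDrugAnnotations(paths[["annotations"]])
  expect_identical(ann$status, scr$annotations$status)
})
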