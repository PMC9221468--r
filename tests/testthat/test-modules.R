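## noise-free two-block expression shared by several tests
twoBlockExpr <- function(n1 = 50, n2 = 50, nSamp = 12, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(nSamp)
  f2 <- rnorm(nSamp)
  mat <- rbind(outer(runif(n1, 0.7, 1), f1), outer(runif(n2, 0.7, 1), f2))
  dimnames(mat) <- list(sprintf("g%03d", seq_len(n1 + n2)),
                        paste0("s", seq_len(nSamp)))
  mat
}

test_that("two noise-free blocks are split exactly into two modules", {
  mat <- twoBlockExpr()
  tom <- tomSimilarity(adjacencyFromExpr(mat, 6))
  mods <- detectModules(tom, mat, minModuleSize = 10)
  expect_setequal(moduleNames(mods), c("turquoise", "blue"))
  truth <- rep(c("A", "B"), each = 50)
  expect_equal(ariOf(moduleLabels(mods), truth), 1)
  ## minModuleSize above every cluster greys everything out
  expect_message(all_grey <- detectModules(tom, mat, minModuleSize = 60),
                 "no modules")
  expect_identical(unname(unique(moduleLabels(all_grey))), "grey")
})

test_that("module detection is invariant to gene input order", {
  mat <- twoBlockExpr(seed = 6)
  tom <- tomSimilarity(adjacencyFromExpr(mat, 6))
  mods <- detectModules(tom, mat, minModuleSize = 10)
  perm <- sample(nrow(mat))
  matP <- mat[perm, ]
  tomP <- tomSimilarity(adjacencyFromExpr(matP, 6))
  modsP <- detectModules(tomP, matP, minModuleSize = 10)
  common <- rownames(mat)
  expect_equal(ariOf(moduleLabels(mods)[common], moduleLabels(modsP)[common]), 1)
})

test_that("eigengenes match a dense eigendecomposition oracle", {
  set.seed(11)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  mods <- new("ModuleSet",
              labels = setNames(rep("m1", 20), rownames(X)),
              minModuleSize = 0)
  eig <- moduleEigengenes(X, mods)
  v <- eigengeneScores(eig)["m1", ]
  ## oracle: leading eigenvector of the standardized block's sample covariance
  Xs <- t(scale(t(X)))
  ev <- eigen(t(Xs) %*% Xs, symmetric = TRUE)
  w <- ev$vectors[, 1]
  w <- w / sd(w)
  expect_lt(min(max(abs(v - w)), max(abs(v + w))), 1e-8)
  expect_equal(unname(varianceExplained(eig)["m1"]),
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
})

test_that("eigengene orientation and rank-1 blocks behave as specified", {
  set.seed(12)
  profile <- rnorm(8)
  X <- outer(runif(6, 0.5, 2), profile) + 5   # identical shapes, scaled
  dimnames(X) <- list(paste0("g", 1:6), paste0("s", 1:8))
  mods <- new("ModuleSet", labels = setNames(rep("m1", 6), rownames(X)),
              minModuleSize = 0)
  eig <- moduleEigengenes(X, mods)
  expect_equal(unname(varianceExplained(eig)["m1"]), 1, tolerance = 1e-12)
  v <- eigengeneScores(eig)["m1", ]
  expect_equal(unname(cor(v, profile)), 1, tolerance = 1e-10)
  ## negating all module genes negates the eigengene deterministically: the
  ## orientation rule keeps it positively correlated with the (negated) genes
  eigNeg <- moduleEigengenes(-X, mods)
  expect_equal(eigengeneScores(eigNeg)["m1", ], -v, tolerance = 1e-10)
  expect_gte(mean(cor(t(-X), eigengeneScores(eigNeg)["m1", ])), 0)
  ## single-gene module: the standardized profile itself
  mods1 <- new("ModuleSet", labels = setNames("m1", "g1"), minModuleSize = 0)
  eig1 <- moduleEigengenes(X[1, , drop = FALSE], mods1)
  expect_equal(unname(eigengeneScores(eig1)["m1", ]),
               unname(as.numeric(scale(X[1, ]))), tolerance = 1e-12)
})

test_that("eigengene adjacency maps correlation to [0, 1]", {
  s <- rnorm(10)
  sc <- rbind(m1 = s, m2 = s * 2 + 1, m3 = -s)
  colnames(sc) <- paste0("s", 1:10)
  eig <- new("EigengeneSet", scores = sc,
             varianceExplained = setNames(rep(1, 3), rownames(sc)))
  A <- eigengeneAdjacency(eig)
  expect_equal(A["m1", "m2"], 1)       # identical up to affine map
  expect_equal(A["m1", "m3"], 0)       # anti-correlated
  expect_equal(unname(diag(A)), rep(1, 3))
  x <- as.numeric(scale(rnorm(10)))
  y <- unname(resid(lm(rnorm(10) ~ x)))          # exactly uncorrelated with x
  sc2 <- rbind(m1 = x, m2 = y)
  colnames(sc2) <- paste0("s", 1:10)
  eig2 <- new("EigengeneSet", scores = sc2,
              varianceExplained = setNames(c(1, 1), c("m1", "m2")))
  expect_equal(eigengeneAdjacency(eig2)["m1", "m2"], 0.5, tolerance = 1e-10)
})

test_that("a coherent module present in both datasets scores Zsummary far above 5", {
  st <- smallStudy(seed = 31)
  filt <- madFilter(st$sim$cell, 1000)
  merged <- intersectAndMerge(filt, st$sim$tumor)
  tm <- trueModuleSet(st$sim$truth)
  keep <- names(moduleLabels(tm)) %in% rownames(cellExpr(merged))
  tm <- new("ModuleSet", labels = moduleLabels(tm)[keep], minModuleSize = 0)
  ## test set identical to reference: preservation is maximal
  ps <- preservationZsummary(cellExpr(merged), cellExpr(merged), tm,
                             nPerm = 60, seed = 3)
  tab <- preservationTable(ps)
  expect_true(all(tab$Zsummary[tab$module == "M1"] > 20))
  expect_equal(tab$Zsummary, (tab$Zdensity + tab$Zconnectivity) / 2)
})

test_that("random background modules score |Zsummary| below 2", {
  cfg <- simConfig(nGenes = 500, moduleSizes = c(60, 50),
                   preserved = c(TRUE, TRUE), nCellLines = 15, nTumors = 15,
                   nDrugs = 5, seed = 17)
  sim <- simulateExpression(cfg)
  cell <- SummarizedExperiment::assay(sim$cell)
  tum <- SummarizedExperiment::assay(sim$tumor)
  bg <- names(sim$truth$moduleOfGene)[sim$truth$moduleOfGene == "background"]
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    fake <- sample(bg, 40)
    labs <- setNames(rep("grey", nrow(cell)), rownames(cell))
    labs[fake] <- "fake"
    ms <- new("ModuleSet", labels = labs, minModuleSize = 0)
    z <- preservationTable(
      preservationZsummary(cell, tum, ms, nPerm = 60, seed = s))$Zsummary
    abs(z) < 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("preservation Z is seeded-reproducible and converges across seeds", {
  cfg <- simConfig(nGenes = 300, moduleSizes = c(60, 50),
                   preserved = c(TRUE, TRUE), nCellLines = 15, nTumors = 15,
                   nDrugs = 5, seed = 23)
  sim <- simulateExpression(cfg)
  cell <- SummarizedExperiment::assay(sim$cell)
  tum <- SummarizedExperiment::assay(sim$tumor)
  tm <- trueModuleSet(sim$truth)
  a <- preservationZsummary(cell, tum, tm, nPerm = 60, seed = 9)
  b <- preservationZsummary(cell, tum, tm, nPerm = 60, seed = 9)
  expect_identical(preservationTable(a), preservationTable(b))
  zs <- vapply(1:5, function(s)
    preservationTable(preservationZsummary(cell, tum, tm, nPerm = 200,
                                           seed = s))$Zsummary[1],
    numeric(1))
  expect_lt(sd(zs) / abs(mean(zs)), 0.15)
})

test_that("small modules are reported as missing, not guessed", {
  mat <- twoBlockExpr(n1 = 40, n2 = 40, seed = 3)
  mat <- mat + matrix(rnorm(length(mat), sd = 0.3), nrow(mat))
  labs <- setNames(rep("grey", 80), rownames(mat))
  labs[1:40] <- "big"
  labs[41:42] <- "tiny"     # size 2 < 3
  ms <- new("ModuleSet", labels = labs, minModuleSize = 0)
  ps <- preservationZsummary(mat, mat, ms, nPerm = 60, seed = 1)
  tab <- preservationTable(ps)
  expect_true(is.na(tab$Zsummary[tab$module == "tiny"]))
  expect_false(is.na(tab$Zsummary[tab$module == "big"]))
})
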