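## eigengene set + response matrix with exactly known correlations
mkEigResp <- function(nLines = 8, seed = 14) {
  set.seed(seed)
  e1 <- as.numeric(scale(rnorm(nLines)))
  e2 <- as.numeric(scale(rnorm(nLines)))
  sc <- rbind(blue = e1, brown = e2)
  colnames(sc) <- paste0("L", seq_len(nLines))
  eig <- new("EigengeneSet", scores = sc,
             varianceExplained = setNames(c(1, 1), rownames(sc)))
  resp <- rbind(dSelf = e1,              # r = 1 with blue
                dAnti = -e1,             # r = -1 with blue
                dFlat = rep(42, nLines), # zero variance
                dAff = 3 * e2 + 10)      # affine image of brown
  colnames(resp) <- colnames(sc)
  list(eig = eig, resp = resp)
}

test_that("fingerprint correlations hit the exact self/anti cases", {
  x <- mkEigResp()
  fp <- drugModuleCorrelations(x$resp, x$eig)
  r <- fingerprintCor(fp)
  expect_equal(r["dSelf", "blue"], 1, tolerance = 1e-12)
  expect_equal(r["dAnti", "blue"], -1, tolerance = 1e-12)
  expect_equal(r["dAff", "brown"], 1, tolerance = 1e-12)   # affine invariance
  ## zero-variance drug: missing with a reason, not zero
  expect_true(all(is.na(r["dFlat", ])))
  expect_true(all(fp@missingReason[paste("dFlat", colnames(r), sep = "|")] ==
                    "zero_variance_drug"))
  ## affine rescaling of responses leaves correlations unchanged
  fp2 <- drugModuleCorrelations(x$resp * 1.7 + 3, x$eig)
  expect_equal(fingerprintCor(fp2), r)
})

test_that("fingerprints demand 3 matched lines and known modules", {
  x <- mkEigResp(nLines = 8)
  expect_error(drugModuleCorrelations(x$resp[, 1:2], x$eig), "matched cell lines")
  expect_error(drugModuleCorrelations(x$resp, x$eig, preserved = "magenta"),
               "absent")
})

test_that("planted couplings are recovered in sign and magnitude", {
  cfg <- simConfig(nGenes = 600, moduleSizes = c(120, 100, 80),
                   preserved = rep(TRUE, 3), nCellLines = 10, nTumors = 6,
                   nDrugs = 50, drugNoiseSd = 0.1, seed = 33)
  sim <- simulateExpression(cfg)
  eig <- moduleEigengenes(SummarizedExperiment::assay(sim$cell),
                          trueModuleSet(sim$truth))
  scr <- simulateDrugScreen(cfg, sim$truth, eig)
  fp <- drugModuleCorrelations(scr$panel, eig)
  r <- fingerprintCor(fp)
  C <- scr$truth$couplings[, colnames(r)]
  strong <- abs(C) > 0.5
  expect_gte(mean(sign(r[strong]) == sign(C[strong])), 0.95)
})

test_that("consensus clustering separates planted fingerprint classes", {
  proto <- rbind(c(0.8, 0.8, -0.8, 0), c(-0.8, -0.8, 0.8, 0))
  cfg <- simConfig(nGenes = 700, moduleSizes = c(120, 100, 80, 60),
                   preserved = rep(TRUE, 4), nCellLines = 10, nTumors = 6,
                   nDrugs = 30, drugNoiseSd = 0.1, activeFraction = 1,
                   drugClass = rep(1:2, each = 15), classCouplings = proto,
                   seed = 41)
  sim <- simulateExpression(cfg)
  eig <- moduleEigengenes(SummarizedExperiment::assay(sim$cell),
                          trueModuleSet(sim$truth))
  scr <- simulateDrugScreen(cfg, sim$truth, eig)
  fp <- drugModuleCorrelations(scr$panel, eig)
  cc <- consensusClusterDrugs(fp, kRange = 2:6, nResample = 100, seed = 6)
  expect_equal(cc@k, 2L)
  cls <- scr$truth$drugClass
  expect_equal(ariOf(clusterMembership(cc), cls), 1)
  cm <- consensusMatrix(cc)
  same <- outer(cls, cls, "==")
  diag(same) <- NA
  expect_gt(min(cm[which(same)]), 0.95)
  expect_lt(max(cm[which(!same)]), 0.05)
  ## label partition is stable across resampling seeds
  cc2 <- consensusClusterDrugs(fp, kRange = 2:6, nResample = 100, seed = 99)
  expect_equal(ariOf(clusterMembership(cc), clusterMembership(cc2)), 1)
  ## and identical under an identical seed
  cc3 <- consensusClusterDrugs(fp, kRange = 2:6, nResample = 100, seed = 6)
  expect_identical(clusterMembership(cc), clusterMembership(cc3))
  expect_identical(consensusMatrix(cc), consensusMatrix(cc3))
})

test_that("duplicated drugs always co-cluster and NAs are dropped loudly", {
  set.seed(8)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(paste0("d", 1:10), paste0("m", 1:4)))
  dup <- rbind(base, dup1 = base["d1", ], dup2 = base["d2", ])
  fp <- new("FingerprintMatrix", cor = pmin(pmax(dup, -1), 1) * 0.5,
            nPoints = 8L, missingReason = character(0))
  cc <- consensusClusterDrugs(fp, kRange = 2:4, nResample = 50, seed = 2)
  cm <- consensusMatrix(cc)
  expect_equal(cm["d1", "dup1"], 1)
  expect_equal(cm["d2", "dup2"], 1)
  withNA <- fp
  withNA@cor["d3", 2] <- NA
  expect_warning(ccNA <- consensusClusterDrugs(withNA, kRange = 2:3,
                                               nResample = 50, seed = 2),
                 "d3")
  expect_false("d3" %in% names(clusterMembership(ccNA)))
  expect_error(consensusClusterDrugs(fp, kRange = 2:3, nResample = 10, seed = 1),
               "unstable")
  expect_error(consensusClusterDrugs(fp, kRange = 2:3, nResample = 50,
                                     itemFraction = 0.4, seed = 1),
               "itemFraction")
})
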