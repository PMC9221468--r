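test_that("trimming removes exactly the two printed extreme concentrations", {
  conc <- defaultConcentrationGrid()
  st <- smallStudy(seed = 1, nCellLines = 5, nTumors = 5)
  eig <- moduleEigengenes(SummarizedExperiment::assay(st$sim$cell),
                          trueModuleSet(st$sim$truth))
  scr <- simulateDrugScreen(st$cfg, st$sim$truth, eig)
  trimmed <- trimConcentrations(scr$panel)
  expect_length(concentrations(trimmed), 9)
  expect_equal(concentrations(trimmed), conc[2:10])
  expect_equal(removedConcentrations(trimmed),
               c(0.000780415, 46.08294931))
  ## positional, not value-matched: trimming again removes its own extremes
  again <- trimConcentrations(trimmed)
  expect_length(concentrations(again), 7)
  expect_equal(removedConcentrations(again),
               c(0.000780415, 46.08294931, conc[2], conc[10]))
  ## minimum input: 4 points -> 2 retained; below that, error
  p4 <- flatPanel(list(d1 = 50), conc = c(0.1, 1, 10, 100))
  expect_length(concentrations(trimConcentrations(p4)), 2)
  expect_error(trimConcentrations(trimConcentrations(p4)), ">= 4")
})

test_that("IDA viability is the per-line minimum of the monotherapies", {
  conc <- c(0.1, 1, 10, 100)
  panel <- handPanel(list(
    A = matrix(c(40, 70), 2, 4, dimnames = list(c("L1", "L2"), NULL)),
    B = matrix(c(70, 40), 2, 4, dimnames = list(c("L1", "L2"), NULL))
  ), conc)
  one <- idaComboViability(panel, "A", 1, "B", 1)
  expect_equal(unname(one$perLine), c(40, 40))     # min rule per line
  ## a drug combined with itself adds nothing
  self <- idaComboViability(panel, "A", 1, "A", 1)
  expect_equal(self$mean, mean(c(40, 70)))
  expect_error(idaComboViability(panel, "A", 0.5, "B", 1), "grid")
})

test_that("the two-line worked example scores 30 points from heterogeneity", {
  conc <- c(0.1, 1, 10, 100)
  panel <- handPanel(list(
    A = matrix(c(20, 80), 2, 4, dimnames = list(c("L1", "L2"), NULL)),
    B = matrix(c(80, 20), 2, 4, dimnames = list(c("L1", "L2"), NULL))
  ), conc)
  v <- idaComboViability(panel, "A", 1, "B", 1)
  expect_equal(unname(v$perLine), c(20, 20))
  expect_equal(v$mean, 20)
  cp <- idaComboScore(panel, "A", "B")
  expect_equal(cp@meanMono, 50)     # best single agent averages 50
  expect_equal(cp@meanCombo, 20)
  expect_equal(comboScore(cp), 30)  # population gain under IDA
  ## identical drugs: score 0 at every pair
  expect_equal(comboScore(idaComboScore(panel, "A", "A")), 0)
})

test_that("the grid maximum matches the exhaustive oracle and is non-negative", {
  set.seed(31)
  conc <- defaultConcentrationGrid()[2:10]
  lines <- paste0("L", 1:5)
  for (i in 1:5) {
    drugViab <- lapply(setNames(1:4, paste0("d", 1:4)), function(j) {
      m <- matrix(sort(runif(9 * 5, 0, 100), decreasing = TRUE), 5, 9,
                  byrow = FALSE)
      rownames(m) <- lines
      m
    })
    panel <- handPanel(drugViab, conc)
    cp <- idaComboScore(panel, "d1", "d2")
    expect_equal(comboScore(cp), bruteIdaScore(panel, "d1", "d2"),
                 tolerance = 1e-12)
    expect_gte(comboScore(cp), 0)
    expect_lte(cp@meanCombo, cp@meanMono + 1e-12)
    ## attaining pair reproduces the reported score
    at <- idaComboViability(panel, "d1", cp@bestPair[["cA"]],
                            "d2", cp@bestPair[["cB"]])
    expect_equal(cp@meanCombo, at$mean, tolerance = 1e-12)
  }
})

test_that("lowering a partner's viabilities never lowers the score", {
  set.seed(17)
  conc <- c(0.1, 1, 10, 100)
  lines <- paste0("L", 1:4)
  a <- matrix(runif(16, 20, 100), 4, 4, dimnames = list(lines, NULL))
  b <- matrix(runif(16, 20, 100), 4, 4, dimnames = list(lines, NULL))
  p1 <- handPanel(list(A = a, B = b), conc)
  s1 <- comboScore(idaComboScore(p1, "A", "B"))
  ## B uniformly more cytotoxic
  p2 <- handPanel(list(A = a, B = pmax(b - 15, 0)), conc)
  s2 <- comboScore(idaComboScore(p2, "A", "B"))
  expect_gte(s2 + 1e-9, s1 * 0)   # still non-negative
  expect_gte(s2, 0)
  ## no shared lines errors out
  colnames(a) <- NULL
  aOnly <- matrix(c(NA, NA, NA, NA), 1, 4,
                  dimnames = list("L9", NULL))
  pBad <- suppressWarnings(handPanel(list(A = rbind(a[1:2, ]),
                                          B = rbind(a[3:4, ])), conc))
  expect_silent(idaComboScore(pBad, "A", "B"))
})

test_that("a complementary partner ranks first among random partners", {
  set.seed(23)
  conc <- c(0.1, 1, 10, 100)
  lines <- paste0("L", 1:6)
  strongWeak <- c(10, 10, 10, 90, 90, 90)
  drugViab <- list(anchor = matrix(strongWeak, 6, 4,
                                   dimnames = list(lines, NULL)),
                   complement = matrix(rev(strongWeak), 6, 4,
                                       dimnames = list(lines, NULL)))
  for (j in 1:20)
    drugViab[[paste0("rand", j)]] <-
      matrix(runif(6, 45, 75), 6, 4, dimnames = list(lines, NULL))
  panel <- handPanel(drugViab, conc)
  partners <- setdiff(names(drugViab), "anchor")
  scores <- vapply(partners, function(d)
    comboScore(idaComboScore(panel, "anchor", d)), numeric(1))
  expect_identical(names(which.max(scores)), "complement")
})

test_that("combination enumeration respects strategy combinatorics", {
  set.seed(9)
  conc <- c(0.1, 1, 10, 100)
  lines <- paste0("L", 1:4)
  drugs <- c("anchor", "sib1", "sib2", "p1", "p2", "far")
  drugViab <- lapply(setNames(seq_along(drugs), drugs), function(i)
    matrix(runif(16, 20, 90), 4, 4, dimnames = list(lines, NULL)))
  panel <- handPanel(drugViab, conc)
  base <- c(-0.9, 0.7, -0.5, 0.2)
  r <- rbind(anchor = base,
             sib1 = base + rnorm(4, sd = 0.03),
             sib2 = base + rnorm(4, sd = 0.03),
             p1 = -base, p2 = -base + rnorm(4, sd = 0.05),
             far = c(0.1, -0.9, 0.8, 0.4))
  colnames(r) <- paste0("m", 1:4)
  fp <- new("FingerprintMatrix", cor = pmin(pmax(r, -1), 1), nPoints = 4L,
            missingReason = character(0))
  ann <- data.frame(drug = drugs, status = rep("FDA-approved", 6))
  mem <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), drugs)
  cons <- diag(6)
  dimnames(cons) <- list(drugs, drugs)
  clusters <- new("ConsensusClusterResult", membership = mem, k = 3L,
                  consensus = cons,
                  diagnostics = data.frame(k = 3L, area = 1, deltaArea = 1),
                  settings = list())
  ## vertical: anchor-like set of size 3 -> exactly choose(3, 2) = 3 pairs
  vert <- enumerateCombinations("vertical", panel, fp, "anchor", ann = ann)
  expect_equal(nrow(vert), 3)
  expect_true(all(vert$strategy == "vertical"))
  ## horizontal: anchor x each advanced member of the partner cluster
  horiz <- enumerateCombinations("horizontal", panel, fp, "anchor",
                                 clusters, partnerCluster = 2L, ann = ann)
  expect_equal(nrow(horiz), 2)
  expect_true(all(horiz$drugA == "anchor"))
  expect_setequal(horiz$drugB, c("p1", "p2"))
  ## ranked descending, flag threshold at 1 point
  expect_true(all(diff(horiz$score) <= 0))
  expect_identical(horiz$aboveThreshold, horiz$score > 1)
  ## empty candidate set warns and returns an empty frame
  annLow <- transform(ann, status = ifelse(drug == "anchor",
                                           "FDA-approved", "preclinical"))
  expect_warning(none <- enumerateCombinations("vertical", panel, fp,
                                               "anchor", ann = annLow),
                 "no candidate")
  expect_equal(nrow(none), 0)
})

test_that("the pairwise score matrix is symmetric with zero diagonal", {
  set.seed(13)
  conc <- c(0.1, 1, 10)
  lines <- paste0("L", 1:3)
  drugViab <- lapply(setNames(1:3, c("a", "b", "c")), function(i)
    matrix(runif(9, 10, 90), 3, 3, dimnames = list(lines, NULL)))
  panel <- handPanel(drugViab, conc)
  m <- comboScoreMatrix(panel, c("a", "b", "c"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m["a", "b"], comboScore(idaComboScore(panel, "a", "b")))
})
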