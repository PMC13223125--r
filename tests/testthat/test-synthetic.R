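test_that("identical seeds reproduce identical cohorts", {
  cfg <- simConfig(nCellLines = 15, nGenes = 20, nDrugs = 3, seed = 5,
                   plantedCausalGenes = 4)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(as.data.frame(responseTable(a$cohort)),
                   as.data.frame(responseTable(b$cohort)))
  expect_identical(omicsBlock(a$cohort, "expression"),
                   omicsBlock(b$cohort, "expression"))
  expect_identical(as.character(refSequences(a$cohort)),
                   as.character(refSequences(b$cohort)))
  expect_identical(a$truth, b$truth)
})

test_that("zero effect size leaves labels independent of causal genes", {
  sim <- generateCohort(simConfig(nCellLines = 200, nGenes = 30, nDrugs = 10,
                                  effectSize = 0, plantedCausalGenes = 5,
                                  seed = 3))
  rt <- as.data.frame(responseTable(sim$cohort))
  y <- as.integer(rt$label == "sensitive")
  expr <- omicsBlock(sim$cohort, "expression")
  # mean causal expression vs label: correlation within Monte-Carlo noise
  act <- colMeans(expr[sim$truth$causal_gene_ids, rt$cell_line_id])
  expect_lt(abs(cor(act, y)), 0.08)
  expect_true(abs(aurocScore(act, y) - 0.5) < 0.06)
})

test_that("a regularized linear probe on causal genes separates strong-effect cohorts", {
  sim <- generateCohort(simConfig(nCellLines = 100, nGenes = 50, nDrugs = 10,
                                  effectSize = 2, plantedCausalGenes = 10,
                                  seed = 13))
  rt <- as.data.frame(responseTable(sim$cohort))
  y <- as.integer(rt$label == "sensitive")
  expr <- omicsBlock(sim$cohort, "expression")
  X <- t(expr[sim$truth$causal_gene_ids, rt$cell_line_id])
  # add drug-target match so the probe sees the interaction context
  X <- cbind(X, match = sim$truth$drug_match[rt$drug_id],
             inter = colMeans(expr[sim$truth$causal_gene_ids,
                                   rt$cell_line_id]) *
                     sim$truth$drug_match[rt$drug_id])
  set.seed(1)
  tr <- sample(nrow(X), 700)
  fit <- glmnet::glmnet(X[tr, ], y[tr], family = "binomial", lambda = 0.01)
  sc <- as.numeric(predict(fit, X[-tr, ], type = "response"))
  expect_gt(aurocScore(sc, y[-tr]), 0.9)
})

test_that("label prevalence tracks the configured value at n >= 1000", {
  for (prev in c(0.3, 0.5)) {
    sim <- generateCohort(simConfig(nCellLines = 100, nGenes = 20,
                                    nDrugs = 10, prevalence = prev,
                                    plantedCausalGenes = 4, seed = 21))
    cb <- classBalance(sim$cohort)
    expect_lt(abs(cb$percent[cb$label == "sensitive"] - 100 * prev), 3)
  }
})

test_that("mutateSequences constructs each planted event literally", {
  ref <- Biostrings::DNAStringSet(c(g = paste(rep("ACGT", 10), collapse = "")))
  # duplication of the 4-mer at position 9
  dup <- mutateSequences(ref, data.frame(gene = "g", event = "duplication",
                                         pos = 9, len = 4))
  expect_equal(substring(as.character(dup[["g"]]), 9, 16), "ACGTACGT")
  expect_equal(nchar(as.character(dup[["g"]])), 44)
  # inversion: reversed reference 6-mer appears at the planted site
  ref2 <- Biostrings::DNAStringSet(c(g = "AAAACGTTGCAAAA"))
  inv <- mutateSequences(ref2, data.frame(gene = "g", event = "inversion",
                                          pos = 4, len = 6))
  orig <- substring(as.character(ref2[["g"]]), 4, 9)
  got <- substring(as.character(inv[["g"]]), 4, 9)
  expect_equal(got, paste(rev(strsplit(orig, "")[[1]]), collapse = ""))
  # empty plan is the identity
  same <- mutateSequences(ref, data.frame(gene = character(),
                                          event = character(),
                                          pos = integer(), len = integer()))
  expect_identical(as.character(same), as.character(ref))
  # overlapping events are rejected
  expect_error(
    mutateSequences(ref, data.frame(gene = "g",
                                    event = c("deletion", "duplication"),
                                    pos = c(5, 8), len = c(6, 4))),
    "overlap")
})

test_that("synthetic plates are exact 4PL evaluations at zero noise", {
  pl <- generatePlate(ic50_uM = 1, hill = -1, bottom = 20, noiseSd = 0,
                      reps = 1)
  # midpoint: v(IC50) = (100 + B) / 2
  expect_equal(pl$viability_pct[pl$concentration_uM == 1], 60)
  # top asymptote as c -> 0
  lowc <- generatePlate(1, -2, bottom = 0, concentrations_uM = c(1e-6, 1),
                        reps = 1, noiseSd = 0)
  expect_equal(lowc$viability_pct[1], 100, tolerance = 1e-4)
  # default grid is the seven-point 0.01-10 uM series
  expect_equal(sort(unique(pl$concentration_uM)),
               c(0.01, 0.032, 0.1, 0.32, 1.0, 3.2, 10))
})

test_that("gene-set generation plants the causal set and round-trips GMT", {
  sim <- smallSim()
  sets <- generateGeneSets(sim$truth, geneIds(sim$cohort), nSets = 10,
                           seed = 2)
  expect_identical(sets[[1]], sim$truth$causal_gene_ids)
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sets, path)
  back <- readGMT(path)
  expect_identical(back, sets)
})
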