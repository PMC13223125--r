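test_that("curation applies the three exclusion steps in order with a telescoping log", {
  raw <- simulateCurationCohort(nInitial = 8146, excl = c(854, 4179, 499),
                                nSensitive = 1241, seed = 1)
  cur <- curateCohort(raw)
  log <- as.data.frame(curationLog(cur))
  expect_equal(log$retained, c(8146, 7292, 3113, 2614))
  expect_equal(log$excluded[-1], c(854, 4179, 499))
  expect_equal(nrow(responseTable(cur)), 2614)
  # telescoping invariant
  for (k in 2:nrow(log)) {
    expect_equal(log$retained[k] + log$excluded[k], log$retained[k - 1])
  }
})

test_that("a defect-free cohort passes curation untouched", {
  raw <- tinyRawCohort()
  rt <- responseTable(raw)
  rt <- rt[rt$drug_id != "d3", ]  # drop the structureless drug's pairs
  clean <- CdrCohort(profiles = profiles(raw),
                     drugs = drugTable(raw)[1:2, ],
                     responses = as.data.frame(rt))
  cur <- curateCohort(clean)
  expect_equal(as.data.frame(curationLog(cur))$excluded[-1], c(0, 0, 0))
  expect_equal(nrow(responseTable(cur)), nrow(rt))
})

test_that("a drug lacking both SMILES and InChI is excluded at step 3 only", {
  cur <- curateCohort(tinyRawCohort())
  log <- as.data.frame(curationLog(cur))
  expect_equal(log$excluded[-1], c(0, 0, 3))  # d3 has 3 pairs
  expect_false("d3" %in% drugTable(cur)$id)
})

test_that("curating an empty cohort raises an explicit error", {
  raw <- tinyRawCohort()
  rt <- as.data.frame(responseTable(raw))
  rt$ic50_uM <- NA_real_
  bad <- CdrCohort(profiles = profiles(raw), drugs = drugTable(raw),
                   responses = rt)
  expect_error(curateCohort(bad), "empty cohort")
})

test_that("labels follow the strict 1 uM threshold", {
  raw <- tinyRawCohort()
  cur <- assignLabels(curateCohort(raw))
  rt <- as.data.frame(responseTable(cur))
  lab <- function(ic) rt$label[which(abs(rt$ic50_uM - ic) < 1e-9)[1]]
  expect_equal(lab(0.2), "sensitive")
  expect_equal(lab(1.7), "resistant")
  expect_equal(lab(2.5), "resistant")
  # boundary: exactly the threshold is resistant
  rt2 <- rt; rt2$ic50_uM[1] <- 1.0
  cur2 <- CdrCohort(profiles = profiles(cur), drugs = drugTable(cur),
                    responses = rt2)
  expect_equal(as.data.frame(responseTable(assignLabels(cur2)))$label[1],
               "resistant")
  # paper panel values
  expect_true(0.32 < 1)   # MCF7 sensitive
  expect_true(3.42 >= 1)  # A549 resistant
})

test_that("labeling is idempotent and threshold-monotone", {
  cur <- assignLabels(curateCohort(tinyRawCohort()))
  expect_identical(responseTable(assignLabels(cur))$label,
                   responseTable(cur)$label)
  sensAt <- function(th) {
    rt <- as.data.frame(responseTable(assignLabels(cur, th)))
    sum(rt$label == "sensitive")
  }
  ths <- c(0.1, 0.5, 1, 2, 5, 10)
  counts <- vapply(ths, sensAt, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("class balance reports counts and half-up percentages", {
  cur <- assignLabels(curateCohort(tinyRawCohort()))
  cb <- classBalance(cur)
  expect_equal(sum(cb$count), nrow(responseTable(cur)))
  expect_equal(sum(cb$percent), 100, tolerance = 0.02)
  # 40 of 100 -> 40.00
  expect_equal(ExplainDR:::roundHalfUp(100 * 40 / 100, 2), 40.00)
  # all-sensitive toy cohort
  rt <- as.data.frame(responseTable(cur)); rt$ic50_uM <- 0.1
  allS <- assignLabels(CdrCohort(profiles = profiles(cur),
                                 drugs = drugTable(cur), responses = rt))
  expect_equal(classBalance(allS)$percent, c(100, 0))
})

test_that("missing IC50 on a curated record is a labeling error", {
  cur <- curateCohort(tinyRawCohort())
  rt <- as.data.frame(responseTable(cur))
  rt$ic50_uM[2] <- NA
  broken <- CdrCohort(profiles = profiles(cur), drugs = drugTable(cur),
                      responses = rt)
  expect_error(assignLabels(broken), "curation contract")
})

test_that("cohort write/read round-trips all fields", {
  sim <- smallSim()
  dir <- withr::local_tempdir()
  writeCohort(sim$cohort, dir)
  back <- readCohort(dir)
  expect_equal(as.data.frame(responseTable(back)),
               as.data.frame(responseTable(sim$cohort)))
  expect_equal(omicsBlock(back, "expression"),
               omicsBlock(sim$cohort, "expression"))
  expect_equal(omicsBlock(back, "mutation"), omicsBlock(sim$cohort, "mutation"))
  expect_identical(as.character(refSequences(back)),
                   as.character(refSequences(sim$cohort)))
  expect_equal(as.data.frame(drugTable(back)),
               as.data.frame(drugTable(sim$cohort)))
})

test_that("the reader converts IC50 units under an explicit flag", {
  sim <- smallSim()
  dir <- withr::local_tempdir()
  writeCohort(sim$cohort, dir)
  resp <- read.csv(file.path(dir, "responses.csv"))
  ic <- resp$ic50_uM
  resp$ic50_uM <- ic / 1e6
  write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE)
  backM <- readCohort(dir, ic50_units = "M")
  expect_equal(responseTable(backM)$ic50_uM, ic, tolerance = 1e-12)
  resp$ic50_uM <- log(ic)
  write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE)
  backL <- readCohort(dir, ic50_units = "ln_uM")
  expect_equal(responseTable(backL)$ic50_uM, ic, tolerance = 1e-12)
})
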