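test_that("the default design lays out 2 cycles of 280 s at TR 2.6", {
  des <- makeDesign()
  ep <- epochTable(des)
  expect_identical(sum(ep$duration), 560)
  expect_identical(nScans(des), 215L)           # complete TRs in 560 s
  u <- inputMatrix(des)
  dt <- 2.6 / 16
  # 2 x 120 s per condition, up to one bin of quantization per epoch edge
  expect_lt(abs(sum(u[1, ]) * dt - 240), 2 * dt)
  expect_lt(abs(sum(u[2, ]) * dt - 240), 2 * dt)
  expect_true(all(colSums(u) <= 1))             # conditions never overlap
})

test_that("degenerate designs are rejected", {
  expect_error(makeDesign(designSpec(nCycles = 0L)), "at least one cycle")
  expect_error(designSpec(soaMs = 20, stimMs = 50))
})

test_that("stimulus arithmetic reproduces the block bookkeeping", {
  expect_identical(stimulusCount(120, 250), 480L)
  expect_identical(targetCount(stimulusCount(120, 250), 0.25), 120L)
  expect_identical(stimulusCount(120, 120 * 1000), 1L)
})

test_that("zero-SD truth specs reproduce the group means exactly", {
  hc <- hcTruthSpec(3L)
  hc@intrinsic$sd[] <- 0; hc@modLow$sd[] <- 0; hc@modHigh$sd[] <- 0
  hc@driving$sd[] <- 0
  truths <- sampleGroupTruth(hc, tpl, seed = 1)
  expect_length(truths, 3L)
  idx <- tcdcm:::.connectionIndex("Thal->dPFC", tpl@regions)
  for (p in truths) {
    expect_equal(p@a[idx], 0.09, tolerance = 1e-12)       # HC group mean
    expect_equal(p@bLow[idx], 0.23, tolerance = 1e-12)
    expect_equal(p@bHigh[idx], 0.28, tolerance = 1e-12)
  }
})

test_that("sampled modulation matches the specified group distribution", {
  hc <- hcTruthSpec(10000L)
  truths <- sampleGroupTruth(hc, tpl, seed = 2)
  idx <- tcdcm:::.connectionIndex("Thal->dPFC", tpl@regions)
  draws <- vapply(truths, function(p) p@bLow[idx], 0)
  expect_lt(abs(mean(draws) - 0.23), 0.01)     # mean 0.23, SD 0.27
  expect_lt(abs(sd(draws) - 0.27), 0.01)
  # seeded determinism
  again <- sampleGroupTruth(hcTruthSpec(10000L), tpl, seed = 2)
  expect_identical(draws[1:50],
                   vapply(again[1:50], function(p) p@bLow[idx], 0))
})

test_that("unknown pathways in a truth spec are rejected", {
  hc <- hcTruthSpec(2L)
  hc@intrinsic$pathway[1] <- "V1->dPFC"
  expect_error(sampleGroupTruth(hc, tpl, seed = 1), "outside the template")
})

test_that("a noiseless cohort equals each subject's own prediction", {
  des <- smallDesign()
  cohort <- generateCohort(hcTruthSpec(2L, noiseSd = 0),
                           ocdTruthSpec(2L, noiseSd = 0),
                           des, tpl, masterSeed = 5L)
  expect_length(cohortSubjects(cohort), 4L)
  for (s in cohortSubjects(cohort)) {
    pred <- simulateBold(s$truth, des, noiseSd = 0)
    expect_lt(max(abs(boldMatrix(s$bold) - boldMatrix(pred))), 1e-9)
  }
})

test_that("the default cohort has 62 subjects of 6 x 215 scans", {
  cohort <- generateCohort(masterSeed = 3L)
  subs <- cohortSubjects(cohort)
  expect_length(subs, 62L)
  groups <- vapply(subs, function(s) s$group, "")
  expect_identical(sum(groups == "HC"), 32L)
  expect_identical(sum(groups == "OCD"), 30L)
  expect_identical(dim(boldMatrix(subs[[1]]$bold)), c(6L, 215L))
  expect_gt(cohort@noiseSd, 0)                  # automatic SNR-1 calibration
})

test_that("cohorts are regenerable bit-exactly from the master seed", {
  des <- smallDesign()
  c1 <- generateCohort(hcTruthSpec(2L), ocdTruthSpec(2L), des, tpl,
                       masterSeed = 11L)
  c2 <- generateCohort(hcTruthSpec(2L), ocdTruthSpec(2L), des, tpl,
                       masterSeed = 11L)
  expect_identical(c1@truth, c2@truth)
  expect_identical(boldMatrix(cohortSubjects(c1)[[3]]$bold),
                   boldMatrix(cohortSubjects(c2)[[3]]$bold))
  c3 <- generateCohort(hcTruthSpec(2L), ocdTruthSpec(2L), des, tpl,
                       masterSeed = 12L)
  expect_false(identical(c1@truth, c3@truth))
})

test_that("cohort bundles round-trip through the TSV/JSON layout", {
  des <- smallDesign()
  cohort <- generateCohort(hcTruthSpec(2L), ocdTruthSpec(2L), des, tpl,
                           masterSeed = 7L)
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readCohort(dir)
  expect_length(back$subjects, 4L)
  orig <- cohortSubjects(cohort)[["sub-03"]]
  expect_identical(back$subjects[["sub-03"]]$group, orig$group)
  expect_lt(max(abs(boldMatrix(back$subjects[["sub-03"]]$bold) -
                    boldMatrix(orig$bold))), 1e-12)
  expect_identical(nScans(back$design), nScans(des))
  expect_identical(inputMatrix(back$design), inputMatrix(des))
})
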