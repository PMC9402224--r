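test_that("default template has the 8 fixed and 5 permuted pathways", {
  expect_length(tpl@fixed, 8L)
  expect_length(tpl@permuted3, 4L)
  expect_length(tpl@permuted2, 1L)
  # the union is the 13 reported pathways
  expect_setequal(templatePathways(tpl),
                  c("V1->SPC", "V1->Thal", "SPC->Thal", "SPC->BG", "Thal->BG",
                    "Thal->dACC", "Thal->dPFC", "BG->Thal", "BG->dPFC",
                    "dACC->Thal", "dACC->BG", "dPFC->Thal", "dPFC->BG"))
  expect_length(intersect(tpl@fixed, permutedPathways(tpl)), 0L)
  expect_identical(tpl@permuted3,
                   c("Thal->dPFC", "dPFC->Thal", "Thal->dACC", "dACC->Thal"))
  expect_identical(tpl@permuted2, "dPFC->BG")
})

test_that("enumeration yields 3^4 x 2 = 162 models in a stable order", {
  expect_length(modelSpace, 162L)
  expect_identical(vapply(modelSpace, modelId, 1L), 1:162)
  # deterministic: a second enumeration gives identical state mappings
  again <- enumerateModels(tpl)
  expect_identical(lapply(again, connectionStates),
                   lapply(modelSpace, connectionStates))
  # lexicographic: first model all-ABSENT, last all-PRESENT_MODULATED
  expect_true(all(connectionStates(modelSpace[[1]]) == "ABSENT"))
  expect_true(all(connectionStates(modelSpace[[162]]) == "PRESENT_MODULATED"))
})

test_that("degenerate and small permutation sets enumerate correctly", {
  noPerm <- new("NetworkTemplate", regions = tpl@regions, fixed = tpl@fixed,
                permuted3 = character(), permuted2 = character(),
                drivingTargets = "V1")
  expect_length(enumerateModels(noPerm), 1L)
  small <- new("NetworkTemplate", regions = tpl@regions, fixed = tpl@fixed,
               permuted3 = "Thal->dPFC", permuted2 = "dPFC->BG",
               drivingTargets = "V1")
  expect_length(enumerateModels(small), 6L)
})

test_that("masks implement the fixed-skeleton and joint-modulation rules", {
  allAbsent <- modelMasks(modelSpace[[1]], tpl)
  expect_identical(sum(allAbsent@aMask), 8L)
  expect_true(all(allAbsent@bMaskLow == 0))
  allMod <- modelMasks(modelSpace[[162]], tpl)
  expect_identical(sum(allMod@aMask), 13L)
  expect_identical(sum(allMod@bMaskLow), 5L)
  expect_identical(sum(allMod@bMaskHigh), 5L)
  fixedIdx <- tcdcm:::.connectionIndex(tpl@fixed, tpl@regions)
  for (m in modelSpace[seq(1, 162, by = 13)]) {
    mk <- modelMasks(m, tpl)
    expect_identical(mk@bMaskLow, mk@bMaskHigh)
    expect_true(all(mk@aMask[fixedIdx] == 1L))       # skeleton nesting
    expect_true(all(mk@bMaskLow <= mk@aMask))
    expect_true(all(diag(mk@aMask) == 0L))
  }
})

test_that("all 162 mask sets are pairwise distinct", {
  keys <- vapply(modelSpace, function(m) {
    mk <- modelMasks(m, tpl)
    paste(c(mk@aMask, mk@bMaskLow), collapse = "")
  }, "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("mask construction rejects state/template mismatches", {
  bad <- new("ModelSpec", modelId = 1L,
             states = setNames(rep("ABSENT", 4), tpl@permuted3))
  expect_error(modelMasks(bad, tpl), "permuted connections")
  badState <- new("ModelSpec", modelId = 1L,
                  states = setNames(c(rep("ABSENT", 4), "PRESENT"),
                                    c(tpl@permuted3, tpl@permuted2)))
  expect_error(modelMasks(badState, tpl), "two-state")
})

test_that("free-parameter counts match the mask structure", {
  expect_identical(nFreeParameters(modelMasks(modelSpace[[162]], tpl), tpl),
                   25L)
  expect_identical(nFreeParameters(modelMasks(modelSpace[[1]], tpl), tpl),
                   10L)
})

test_that("model space round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeModelSpace(modelSpace[1:5], path)
  back <- readModelSpace(path)
  expect_identical(vapply(back, modelId, 1L), 1:5)
  expect_identical(lapply(back, connectionStates),
                   lapply(modelSpace[1:5], connectionStates))
})
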