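test_that("default priors count and scale the free parameters", {
  mkFull <- modelMasks(modelSpace[[162]], tpl)
  prFull <- defaultPriors(mkFull, tpl)
  expect_length(prFull@mean, 25L)           # 13 A + 5 + 5 B + 2 C
  mkSkel <- modelMasks(modelSpace[[1]], tpl)
  prSkel <- defaultPriors(mkSkel, tpl)
  expect_length(prSkel@mean, 10L)           # 8 A + 2 C
  expect_true(all(prFull@variance > 0))
  expect_identical(unique(prFull@variance[grep("^(A|B)", prFull@paramNames)]),
                   1 / 16)
  expect_identical(unique(prFull@variance[grep("^C", prFull@paramNames)]),
                   1 / 4)
})

test_that("free energy reduces to the log likelihood at the prior", {
  pri <- new("DcmPriors", mean = rep(0, 3), variance = rep(0.5, 3),
             paramNames = paste0("A:", 1:3), lambdaMean = 0, lambdaVar = 1)
  y <- matrix(rnorm(2 * 10), 2, 10)
  lambda <- c(0.2, -0.1)
  f <- computeFreeEnergy(y, y, pri@mean, diag(0.5, 3), pri, lambda)
  expect_equal(f, sum(10 / 2 * (lambda - log(2 * pi))), tolerance = 1e-12)
})

test_that("free energy at the analytic posterior equals the log evidence", {
  set.seed(1)
  n <- 40; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  v0 <- rep(0.5, p); s <- 4
  y <- as.vector(X %*% rnorm(p, 0, sqrt(v0))) + rnorm(n, 0, 1 / sqrt(s))
  o <- linearGaussOracle(X, y, v0, s)
  pri <- new("DcmPriors", mean = rep(0, p), variance = v0,
             paramNames = paste0("A:", 1:p), lambdaMean = 0, lambdaVar = 1)
  f <- computeFreeEnergy(matrix(y, 1), matrix(as.vector(X %*% o$mu), 1),
                         o$mu, o$sigma, pri, log(s), jacobian = X)
  expect_lt(abs(f - o$logEv), 1e-6)
  # identifiable parameters are not inflated beyond their prior variance
  expect_true(all(diag(o$sigma) <= v0 + 1e-12))
})

test_that("a parameter with no effect on predictions cannot raise F", {
  set.seed(2)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  v0 <- rep(0.5, 2); s <- 2
  y <- as.vector(X %*% c(0.4, -0.3)) + rnorm(n, 0, 1 / sqrt(s))
  o2 <- linearGaussOracle(X, y, v0, s)
  pri2 <- new("DcmPriors", mean = rep(0, 2), variance = v0,
              paramNames = paste0("A:", 1:2), lambdaMean = 0, lambdaVar = 1)
  f2 <- computeFreeEnergy(matrix(y, 1), matrix(as.vector(X %*% o2$mu), 1),
                          o2$mu, o2$sigma, pri2, log(s), jacobian = X)
  # augment with a dead parameter (zero Jacobian column, posterior = prior)
  X3 <- cbind(X, 0)
  mu3 <- c(o2$mu, 0)
  sig3 <- rbind(cbind(o2$sigma, 0), c(0, 0, 0.5))
  pri3 <- new("DcmPriors", mean = rep(0, 3), variance = rep(0.5, 3),
              paramNames = paste0("A:", 1:3), lambdaMean = 0, lambdaVar = 1)
  f3 <- computeFreeEnergy(matrix(y, 1), matrix(as.vector(X3 %*% mu3), 1),
                          mu3, sig3, pri3, log(s), jacobian = X3)
  expect_lte(f3, f2 + 1e-9)
})

test_that("noiseless data from prior-mean parameters are recovered exactly", {
  des <- smallDesign()
  mask <- modelMasks(recoveryModel(), tpl)
  p0 <- maskParameters(dcmParameters(matrix(0, 6, 6)), mask)
  y0 <- simulateBold(p0, des, noiseSd = 0)
  est <- invertModel(y0, des, mask, tpl)
  expect_lt(max(abs(est@mu)), 0.01)
  expect_true(est@converged)
})

test_that("inversion is deterministic and F is monotone over iterations", {
  des <- smallDesign()
  mask <- modelMasks(recoveryModel(), tpl)
  truth <- recoveryTruth()
  y <- simulateBold(truth, des, noiseSd = 1.0, seed = 3)
  e1 <- invertModel(y, des, mask, tpl,
                    settings = inversionSettings(maxIter = 12L))
  e2 <- invertModel(y, des, mask, tpl,
                    settings = inversionSettings(maxIter = 12L))
  expect_lt(abs(e1@freeEnergy - e2@freeEnergy), 1e-9)
  expect_identical(e1@mu, e2@mu)
  expect_true(all(diff(e1@fHistory) >= 0))
  expect_lt(max(abs(e1@sigma - t(e1@sigma))), 1e-10)
})

test_that("model evidence separates the generating model from a pruned one", {
  des <- smallDesign()
  genModel <- findModelByStates(c("PRESENT", "PRESENT", "PRESENT", "PRESENT",
                                  "ABSENT"))
  genMask <- modelMasks(genModel, tpl)
  r <- regionNames()
  a <- matrix(0, 6, 6, dimnames = list(r, r))
  a <- setEntry(a, "V1", "SPC", 0.25); a <- setEntry(a, "V1", "Thal", 0.30)
  a <- setEntry(a, "Thal", "dPFC", 0.40)   # strong permuted connection
  a <- setEntry(a, "Thal", "dACC", 0.30)
  cm <- matrix(0, 6, 2); cm[1, ] <- 0.25
  truth <- maskParameters(dcmParameters(a, c = cm), genMask)
  y <- simulateBold(truth, des, noiseSd = 0)
  fTrue <- freeEnergy(invertModel(y, des, genMask, tpl))
  pruned <- findModelByStates(c("ABSENT", "PRESENT", "PRESENT", "PRESENT",
                                "ABSENT"))
  fPruned <- freeEnergy(invertModel(y, des, modelMasks(pruned, tpl), tpl))
  expect_gt(fTrue, fPruned)
})

test_that("posterior serialization writes the documented JSON fields", {
  des <- smallDesign()
  mask <- modelMasks(modelSpace[[1]], tpl)
  y <- simulateBold(recoveryTruth(), des, noiseSd = 1, seed = 5)
  est <- invertModel(y, des, mask, tpl,
                     settings = inversionSettings(maxIter = 4L))
  path <- withr::local_tempfile(fileext = ".json")
  writePosterior(est, 1L, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$model_id, 1L)
  expect_equal(back$F, est@freeEnergy)
  expect_named(back$mu, est@paramNames)
})
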