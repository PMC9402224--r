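test_that("zero driving input leaves the system at the zero fixed point", {
  des <- smallDesign()
  p <- maskParameters(recoveryTruth(), modelMasks(recoveryModel(), tpl))
  p@c[] <- 0
  x <- integrateNeural(p, des)
  expect_true(all(x == 0))
  y <- simulateBold(p, des, noiseSd = 0)
  expect_true(all(boldMatrix(y) == 0))
})

test_that("a single decaying region follows exp(-selfDecay * t)", {
  tr <- 1; bins <- 100L; nScans <- 6L
  des <- new("TaskDesign", u = matrix(0, 2, nScans * bins), tr = tr,
             microtimeBins = bins,
             epochs = data.frame(condition = "rest", onset = 0, duration = 6),
             nScans = nScans)
  p <- dcmParameters(matrix(0, 1, 1), selfDecay = 0.5)
  x <- integrateNeural(p, des, x0 = 1)
  tgrid <- (seq_len(ncol(x)) - 1) * (tr / bins)
  expect_lt(max(abs(x[1, ] - exp(-0.5 * tgrid))), 1e-9)
})

test_that("RK4 matches a matrix-exponential stepper on random stable systems", {
  skip_if_not_installed("Matrix")
  set.seed(5)
  bins <- 100L; tr <- 1; nScans <- 6L
  T <- bins * nScans; dt <- tr / bins
  u <- matrix(0, 2, T)
  u[1, 100:300] <- 1
  u[2, 350:550] <- 1
  des <- new("TaskDesign", u = u, tr = tr, microtimeBins = bins,
             epochs = data.frame(condition = c("low", "high"),
                                 onset = c(1, 3.5), duration = c(2, 2)),
             nScans = nScans)
  for (rep in 1:3) {
    a <- matrix(rnorm(36, 0, 0.15), 6, 6); diag(a) <- 0
    bl <- matrix(rnorm(36, 0, 0.05), 6, 6); diag(bl) <- 0
    bh <- matrix(rnorm(36, 0, 0.05), 6, 6); diag(bh) <- 0
    cm <- matrix(c(rep(0.4, 2), rep(0, 10)), 6, 2, byrow = TRUE)
    p <- dcmParameters(a, bl, bh, cm)
    aEff <- a - diag(0.5, 6)
    expect_lt(max(Re(eigen(aEff + bl)$values)), 0)
    x <- integrateNeural(p, des)
    # oracle: exact per-bin propagation for piecewise-constant inputs
    xo <- matrix(0, 6, T)
    prop <- list()
    for (t in seq_len(T - 1)) {
      key <- paste(u[, t], collapse = "")
      if (is.null(prop[[key]])) {
        M <- aEff + u[1, t] * bl + u[2, t] * bh
        E <- as.matrix(Matrix::expm(M * dt))
        prop[[key]] <- list(E = E, d = solve(M, (E - diag(6)) %*%
                                                   (cm %*% u[, t])))
      }
      xo[, t + 1] <- prop[[key]]$E %*% xo[, t] + prop[[key]]$d
    }
    expect_lt(max(abs(x - xo)), 1e-6)
  }
})

test_that("hemodynamics map rest and zero-efficacy input to zero BOLD", {
  z <- matrix(0, 6, 200)
  expect_true(all(hemodynamics(z, dt = 0.1) == 0))
  x <- matrix(rnorm(6 * 200, 0, 0.3), 6, 200)
  h0 <- defaultHemoParams(epsilon = 0)
  expect_true(all(hemodynamics(x, h0, dt = 0.1) == 0))
})

test_that("constant neural input converges to the analytic steady state", {
  xbar <- 0.3
  h <- defaultHemoParams()
  x <- matrix(xbar, 1, 4000)
  y <- hemodynamics(x, h, dt = 0.05)   # 200 s, ample settling time
  fss <- 1 + h$epsilon * xbar / h$gamma
  vss <- fss^h$alpha
  Ess <- 1 - (1 - h$e0)^(1 / fss)
  qss <- fss * Ess / h$e0 * vss^(1 - 1 / h$alpha)
  k1 <- 7 * h$e0; k2 <- 2; k3 <- 2 * h$e0 - 0.2
  yss <- 100 * h$v0 * (k1 * (1 - qss) + k2 * (1 - qss / vss) + k3 * (1 - vss))
  expect_lt(abs(y[1, 4000] - yss), 1e-6)
})

test_that("simulateBold is seed-deterministic and calibrated in noise", {
  des <- smallDesign()
  p <- recoveryTruth()
  y1 <- simulateBold(p, des, noiseSd = 0.3, seed = 7)
  y2 <- simulateBold(p, des, noiseSd = 0.3, seed = 7)
  expect_identical(boldMatrix(y1), boldMatrix(y2))
  y3 <- simulateBold(p, des, noiseSd = 0.3, seed = 8)
  expect_false(identical(boldMatrix(y1), boldMatrix(y3)))

  # noise calibration: a silent region over many scans shows the requested sd
  long <- new("TaskDesign", u = matrix(0, 2, 10000 * 4L), tr = 2.6,
              microtimeBins = 4L,
              epochs = data.frame(condition = "rest", onset = 0,
                                  duration = 26000),
              nScans = 10000L)
  p1 <- dcmParameters(matrix(0, 1, 1))
  yn <- simulateBold(p1, long, noiseSd = 0.5, seed = 99)
  expect_gt(sd(boldMatrix(yn)[1, ]), 0.49)
  expect_lt(sd(boldMatrix(yn)[1, ]), 0.51)
})

test_that("the neural stage is linear in the driving input when B = 0", {
  des <- smallDesign()
  p <- recoveryTruth()
  p@bLow[] <- 0; p@bHigh[] <- 0
  x1 <- integrateNeural(p, des)
  p2 <- p; p2@c <- 2 * p@c
  x2 <- integrateNeural(p2, des)
  expect_lt(max(abs(x2 - 2 * x1)) / max(abs(x1)), 1e-9)
})

test_that("noiseless BOLD is converged in the integration step", {
  # epoch lengths commensurate with both grids (117 = 720 x 0.1625 s,
  # 19.5 = 120 x 0.1625 s) so the input boxcars are identical and only the
  # integrator step changes
  p <- recoveryTruth()
  y16 <- simulateBold(p, makeDesign(designSpec(taskEpochS = 117,
                                               restEpochS = 19.5,
                                               nCycles = 1L)), noiseSd = 0)
  y32 <- simulateBold(p, makeDesign(designSpec(taskEpochS = 117,
                                               restEpochS = 19.5,
                                               nCycles = 1L,
                                               microtimeBins = 32L)),
                      noiseSd = 0)
  expect_lt(max(abs(boldMatrix(y16) - boldMatrix(y32))), 1e-4)
})

test_that("stronger low-demand modulation raises the target's response", {
  des <- makeDesign(designSpec(nCycles = 1L))
  lowBins <- which(inputMatrix(des)[1, (seq_len(nScans(des)) - 1L) *
                                        des@microtimeBins + 1L] == 1)
  p <- recoveryTruth()
  integral <- vapply(c(0, 0.15, 0.3), function(b) {
    p@bLow["dPFC", "Thal"] <- b
    y <- simulateBold(p, des, noiseSd = 0)
    sum(boldMatrix(y)["dPFC", lowBins])
  }, 0)
  expect_true(all(diff(integral) > 0))
})

test_that("row-sum-stable couplings stay bounded over long runs", {
  # Gershgorin: trajectories are bounded whenever each row's absolute
  # off-diagonal coupling sum stays below the self-decay
  set.seed(31)
  des <- makeDesign(designSpec(nCycles = 2L, microtimeBins = 8L))  # 560 s
  for (i in 1:5) {
    a <- matrix(rnorm(36, 0, 0.2), 6, 6); diag(a) <- 0
    scale <- 0.45 / max(rowSums(abs(a)))
    a <- a * min(1, scale)
    cm <- matrix(0, 6, 2); cm[1, ] <- 0.3
    x <- integrateNeural(dcmParameters(a, c = cm), des)
    expect_true(all(is.finite(x)))
    expect_lt(max(abs(x)), 10)
  }
})

test_that("unstable parameters raise an error naming the first bad bin", {
  des <- smallDesign()
  a <- matrix(2, 6, 6); diag(a) <- 0
  cm <- matrix(0, 6, 2); cm[1, ] <- 0.5
  p <- dcmParameters(a, c = cm)
  expect_error(simulateBold(p, des, noiseSd = 0), "microtime bin")
})
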