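test_that("one-sample t matches hand calculation and the null case", {
  # 16 values with mean 1 and sample sd exactly 1: t = 1 / (1/4) = 4
  x <- 1 + rep(c(-1, 1) * sqrt(15 / 16), each = 8)
  r <- oneSampleT(x)
  expect_equal(r$t, 4, tolerance = 1e-12)
  expect_identical(r$df, 15L)
  x0 <- c(-2, -1, 1, 2)
  r0 <- oneSampleT(x0)
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
})

test_that("one-sample t agrees with the textbook formula", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(8 + i, 0.2, 1)
    r <- oneSampleT(x)
    tRef <- mean(x) / (sd(x) / sqrt(length(x)))
    pRef <- 2 * pt(-abs(tRef), length(x) - 1)
    expect_lt(abs(r$t - tRef), 1e-10)
    expect_lt(abs(r$p - pRef), 1e-10)
  }
})

test_that("zero-variance samples are flagged, not mis-tested", {
  r <- oneSampleT(rep(0.4, 5))
  expect_true(r$degenerate)
  expect_true(is.na(r$t))
  r2 <- twoSampleTPooled(rep(1, 4), rep(1, 4))
  expect_true(r2$degenerate)
})

test_that("pooled two-sample t agrees with the textbook formula and flips
           sign with direction", {
  set.seed(12)
  g1 <- rnorm(12, 0.3, 1); g2 <- rnorm(15, 0, 1)
  r <- twoSampleTPooled(g1, g2)
  sp2 <- ((11 * var(g1)) + 14 * var(g2)) / 25
  tRef <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  expect_lt(abs(r$t - tRef), 1e-10)
  expect_identical(r$df, 25L)
  rFlip <- twoSampleTPooled(g1, g2, direction = "g2-g1")
  expect_equal(rFlip$t, -r$t, tolerance = 1e-12)
  expect_equal(rFlip$p, r$p, tolerance = 1e-12)
  expect_equal(twoSampleTPooled(g1, g1)$t, 0, tolerance = 1e-12)
})

test_that("summary-statistic form reproduces printed worked examples", {
  # high-demand ascending relay: OCD(0.09, 0.30, 30) vs HC(0.28, 0.29, 32)
  r <- twoSampleTPooledSummary(0.09, 0.30, 30, 0.28, 0.29, 32)
  expect_lt(abs(r$t - (-2.54)), 0.02)
  # low-demand descending relay: OCD(-0.03, 0.27, 30) vs HC(0.04, 0.22, 32)
  r2 <- twoSampleTPooledSummary(-0.03, 0.27, 30, 0.04, 0.22, 32)
  expect_lt(abs(r2$t - (-1.12)), 0.02)
})

test_that("the stats table composes the elementary tests without rounding", {
  set.seed(13)
  nm <- fullParameterNames(tpl)
  hc <- matrix(rnorm(32 * length(nm), 0.05, 0.2), 32, length(nm),
               dimnames = list(NULL, nm))
  ocd <- matrix(rnorm(30 * length(nm), 0, 0.2), 30, length(nm),
                dimnames = list(NULL, nm))
  tab <- buildStatsTable(hc, ocd)
  expect_identical(nrow(tab), 23L)      # 13 intrinsic + 5 + 5 modulation
  expect_setequal(unique(tab$class),
                  c("intrinsic", "modulation-low", "modulation-high"))
  i <- which(tab$parameter == "A:V1->SPC")
  ref1 <- oneSampleT(hc[, "A:V1->SPC"])
  expect_identical(tab$hc_t[i], ref1$t)
  expect_identical(tab$hc_mean[i], ref1$mean)
  ref2 <- twoSampleTPooled(hc[, "A:V1->SPC"], ocd[, "A:V1->SPC"])
  expect_identical(tab$inter_t[i], ref2$t)       # intrinsic: HC - OCD
  expect_identical(tab$inter_direction[i], "HC-OCD")
  j <- which(tab$parameter == "Blow:Thal->dPFC")
  ref3 <- twoSampleTPooled(ocd[, "Blow:Thal->dPFC"], hc[, "Blow:Thal->dPFC"])
  expect_identical(tab$inter_t[j], ref3$t)       # modulation: OCD - HC
  expect_identical(tab$inter_direction[j], "OCD-HC")
  # BH column present, flags respect alpha without correction
  expect_true(all(tab$inter_p_bh >= tab$inter_p - 1e-12))
  expect_identical(tab$inter_sig, !is.na(tab$inter_p) & tab$inter_p < 0.05)
})

test_that("swapping the group arguments flips every two-sample sign", {
  set.seed(14)
  nm <- fullParameterNames(tpl)
  hc <- matrix(rnorm(10 * length(nm)), 10, length(nm),
               dimnames = list(NULL, nm))
  ocd <- matrix(rnorm(9 * length(nm)), 9, length(nm),
                dimnames = list(NULL, nm))
  t1 <- buildStatsTable(hc, ocd)
  t2 <- buildStatsTable(ocd, hc)
  expect_equal(t2$inter_t, -t1$inter_t, tolerance = 1e-12)
  expect_equal(t2$inter_p, t1$inter_p, tolerance = 1e-12)
})

test_that("mismatched parameter names are rejected", {
  hc <- matrix(0, 4, 2, dimnames = list(NULL, c("A:V1->SPC", "A:V1->Thal")))
  ocd <- matrix(0, 4, 2, dimnames = list(NULL, c("A:V1->SPC", "A:SPC->BG")))
  expect_error(buildStatsTable(hc, ocd), "do not match")
})
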