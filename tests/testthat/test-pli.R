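test_that("PLI hits its extremes for constant lags and identical phases", {
  t <- (0:999) / 1250
  phi1 <- wrapPhase(2 * pi * 10 * t)
  lagged <- cbind(phi1, wrapPhase(2 * pi * 10 * t - pi / 4))
  expect_equal(pliValues(phaseLagIndex(phasePanel(lagged)))[1, 2], 1)
  same <- cbind(phi1, phi1)
  expect_equal(pliValues(phaseLagIndex(phasePanel(same)))[1, 2], 0)
})

test_that("PLI is the absolute mean sign of the lag sequence", {
  a <- 0.5
  dphi <- c(a, a, -a, a)
  phases <- cbind(dphi, rep(0, 4))
  expect_equal(pliValues(phaseLagIndex(phasePanel(phases)))[1, 2], 0.5)
})

test_that("PLI equals the double-loop reference on random phases", {
  set.seed(71)
  phases <- matrix(runif(200 * 5, -pi, pi), 200, 5)
  got <- pliValues(phaseLagIndex(phasePanel(phases)))
  expect_equal(unname(got), pliDoubleLoop(phases), tolerance = 1e-12)
})

test_that("PLI is invariant under common phase offsets and channel swaps", {
  set.seed(72)
  phases <- matrix(runif(300 * 3, -pi, pi), 300, 3)
  base <- pliValues(phaseLagIndex(phasePanel(phases)))
  offset <- runif(300, -1, 1) # common time-varying offset
  shifted <- wrapPhase(phases + offset)
  expect_equal(pliValues(phaseLagIndex(phasePanel(shifted))), base,
               ignore_attr = TRUE)
  swapped <- phases[, c(2, 1, 3)]
  got <- pliValues(phaseLagIndex(phasePanel(swapped)))
  expect_equal(got[1, 2], base[1, 2])
  expect_equal(got[1, 3], base[2, 3])
})

test_that("epoch averaging is the entrywise mean of unthresholded PLIs", {
  labels <- c("A", "B", "C")
  mk <- function(m) PLIMatrix(m, labels, source = "empirical")
  m1 <- matrix(c(0, .2, .4, .2, 0, .6, .4, .6, 0), 3)
  m2 <- matrix(c(0, .4, .2, .4, 0, .8, .2, .8, 0), 3)
  expect_equal(pliValues(epochAveragePLI(list(mk(m1)))), pliValues(mk(m1)))
  expect_equal(unname(pliValues(epochAveragePLI(list(mk(m1), mk(m2))))),
               (m1 + m2) / 2)

  set.seed(73)
  ms <- lapply(1:7, function(i) {
    v <- matrix(0, 3, 3)
    v[upper.tri(v)] <- runif(3)
    mk(v + t(v))
  })
  avg <- pliValues(epochAveragePLI(ms))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (e in 1:7) s <- s + pliValues(ms[[e]])[i, j]
    oracle[i, j] <- s / 7
  }
  expect_equal(unname(avg), oracle)

  bad <- PLIMatrix(m1, c("X", "Y", "Z"), source = "empirical")
  expect_error(epochAveragePLI(list(mk(m1), bad)), "mismatched labels")
  expect_error(epochAveragePLI(list(thresholdPLI(mk(m1), 30), mk(m2))),
               "thresholded")
})

test_that("percentile thresholding zeroes the smallest pairs per the
           sort-and-cut oracle", {
  labels <- sprintf("R%02d", 1:4)
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- c(.15, .35, .25, .65, .45, .55)
  pli <- PLIMatrix(v + t(v), labels, source = "empirical")

  expect_equal(pliValues(thresholdPLI(pli, 0)), pliValues(pli))
  thr <- thresholdPLI(pli, 50)
  ut <- pliValues(thr)[upper.tri(v)]
  expect_equal(sum(ut == 0), 3L)
  expect_setequal(ut[ut > 0], c(.65, .45, .55))
  expect_equal(pliValues(thr), t(pliValues(thr)))
  expect_equal(pliThreshold(thr), list(kind = "percentile", level = 50))
  expect_error(thresholdPLI(pli, 100), "100")
  expect_error(thresholdPLI(thr, 10), "already thresholded")

  # all-equal entries: floor(P/2) zeroed under the stable tie rule
  w <- matrix(0.3, 4, 4)
  diag(w) <- 0
  tied <- thresholdPLI(PLIMatrix(w, labels, source = "empirical"), 50)
  expect_equal(sum(pliValues(tied)[upper.tri(w)] == 0), 3L)
})

test_that("thresholding is monotone in the retained set", {
  set.seed(74)
  v <- matrix(0, 8, 8)
  v[upper.tri(v)] <- runif(28)
  pli <- PLIMatrix(v + t(v), sprintf("R%02d", 1:8), source = "empirical")
  for (pLow in c(10, 30, 50)) {
    hi <- pliValues(thresholdPLI(pli, 70))
    lo <- pliValues(thresholdPLI(pli, pLow))
    expect_true(all(lo[hi > 0] > 0))
  }
})

test_that("median thresholding zeroes entries strictly below the median", {
  labels <- sprintf("R%02d", 1:4)
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- c(.1, .2, .3, .4, .35, .15)
  pli <- PLIMatrix(v + t(v), labels, source = "empirical")
  out <- medianThresholdPLI(pli)
  med <- median(c(.1, .2, .3, .4, .35, .15))
  expect_equal(unname(pliValues(out)[upper.tri(v)]),
               ifelse(c(.1, .2, .3, .4, .35, .15) < med, 0,
                      c(.1, .2, .3, .4, .35, .15)))

  allEq <- matrix(0.4, 4, 4)
  diag(allEq) <- 0
  same <- medianThresholdPLI(PLIMatrix(allEq, labels, source = "empirical"))
  expect_equal(pliValues(same), allEq, ignore_attr = TRUE)

  set.seed(75)
  v10 <- matrix(0, 10, 10)
  v10[upper.tri(v10)] <- runif(45)
  p10 <- PLIMatrix(v10 + t(v10), sprintf("R%02d", 1:10), source = "empirical")
  got <- pliValues(medianThresholdPLI(p10))
  oracle <- v10 + t(v10)
  oracle[oracle < median(v10[upper.tri(v10)])] <- 0
  expect_equal(unname(got), oracle)
})

test_that("PLI matrices round-trip through CSV with provenance", {
  v <- matrix(0, 3, 3)
  v[upper.tri(v)] <- c(.3, .5, .7)
  pli <- thresholdPLI(PLIMatrix(v + t(v), c("A", "B", "C"),
                                source = "empirical"), 30)
  f <- withr::local_tempfile(fileext = ".csv")
  writePLI(pli, f)
  back <- readPLI(f)
  expect_equal(pliValues(back), pliValues(pli))
  expect_equal(pliSource(back), "empirical")
  expect_equal(pliThreshold(back)$kind, "percentile")
})
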