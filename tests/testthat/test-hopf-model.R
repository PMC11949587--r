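test_that("drift matches the model equations", {
  # origin is a fixed point of an isolated node
  p <- HopfParameters(K = 0, lambda = 1, omega = 2 * pi * 10)
  expect_equal(hopfDrift(0 + 0i, p, matrix(0, 1, 1)), 0 + 0i)

  # on the limit cycle |z| = sqrt(lambda) the radial term cancels
  p2 <- HopfParameters(K = 0, lambda = 4, omega = 2 * pi * 10)
  d <- hopfDrift(2 + 0i, p2, matrix(0, 1, 1))
  expect_equal(d, 1i * 4 * pi * 10)

  # 2-node coupled system against term-by-term symbolic evaluation
  W <- matrix(c(0, 1, 1, 0), 2)
  om <- c(3, 5)
  p3 <- HopfParameters(K = 1, lambda = 0, omega = om, C = 20)
  z <- c(1 + 0i, 0 + 1i)
  x <- Re(z)
  expected <- z * (0 + 1i * om - Mod(z)^2) +
    1 * tanh(20 * as.vector(W %*% x))
  expect_equal(hopfDrift(z, p3, W), expected)

  expect_error(hopfDrift(c(NaN + 0i), p, matrix(0, 1, 1)), "non-finite")
})

test_that("initial-condition sampling is seeded, uniform and distinct", {
  a <- sampleInitialConditions(5, 10, seed = 3)
  b <- sampleInitialConditions(5, 10, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a[[1]], a[[2]]))

  big <- sampleInitialConditions(1000, 78, seed = 4)
  re <- unlist(lapply(big, Re))
  im <- unlist(lapply(big, Im))
  sdU <- sqrt(1 / 3) # sd of U[-1, 1]
  tol <- 3 * sdU / sqrt(1000 * 78)
  expect_lt(abs(mean(re)), tol)
  expect_lt(abs(mean(im)), tol)
  expect_true(all(abs(re) <= 1) && all(abs(im) <= 1))
})

test_that("subcritical isolated nodes decay to the origin", {
  p <- HopfParameters(K = 0, lambda = -1, omega = 2 * pi * 10)
  s <- SimulationSettings(durationS = 9, burnInS = 1, fsHz = 250)
  ts <- simulateHopf(p, matrix(0, 1, 1), 0.8 + 0.5i, s)
  # |z| decays at least like exp(lambda * t)
  expect_lt(abs(tail(tsValues(ts)[, 1], 1)), 1e-3)
})

test_that("supercritical oscillation has radius sqrt(lambda) and the
           natural frequency", {
  p <- HopfParameters(K = 0, lambda = 4, omega = 2 * pi * 10)
  s <- SimulationSettings(durationS = 6, burnInS = 1, fsHz = 250)
  out <- simulateHopf(p, matrix(0, 1, 1), 0.3 - 0.2i, s, full = TRUE)
  x <- tsValues(out$x)[, 1]
  expect_equal(max(abs(tail(x, 500))), 2, tolerance = 0.01)
  expect_equal(periodogramArgmax(x, 250), 10, tolerance = 0.21)
})

test_that("the native adaptive integrator matches deSolve and a fixed-step
           RK4 reference on a short coupled system", {
  W <- matrix(c(0, 1, 1, 0), 2)
  p <- HopfParameters(K = 1, lambda = 0, omega = 2 * pi * c(9.5, 10.5), C = 20)
  ic <- c(1 + 0i, 0 + 1i)
  s <- SimulationSettings(durationS = 2, burnInS = 0.1, fsHz = 1250,
                          absTol = 1e-9, relTol = 1e-6)
  tsN <- simulateHopf(p, W, ic, s)
  tsD <- simulateHopf(p, W, ic, s, engine = "deSolve")
  ref <- rk4Reference(ic, 2, 1e-4, p, W)
  grid <- seq(0.1, 2, by = 1 / 1250)
  refx <- Re(ref$states[round(grid / 1e-4) + 1L, ])
  expect_lt(max(abs(tsValues(tsN) - refx)), 1e-3)
  expect_lt(max(abs(tsValues(tsN) - tsValues(tsD))), 1e-3)
})

test_that("simulation is equivariant under region relabeling", {
  W <- toyConnectome(5, seed = 8)
  om <- makeNaturalFrequencies(5, seed = 9)
  ic <- sampleInitialConditions(1, 5, 10)[[1]]
  p <- HopfParameters(K = 2, lambda = 5, omega = om, C = 20)
  s <- fastSettings()
  base <- tsValues(simulateHopf(p, connWeights(W), ic, s))
  perm <- c(3L, 1L, 5L, 2L, 4L)
  pPerm <- HopfParameters(K = 2, lambda = 5, omega = om[perm], C = 20)
  permuted <- tsValues(simulateHopf(pPerm, connWeights(W)[perm, perm],
                                    ic[perm], s))
  expect_equal(permuted, base[, perm], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("normalized coupling and the matched-k rescaling behave as the
           square-root law requires", {
  expect_equal(normalizedCoupling(2, 4), 1)
  expect_equal(normalizedCoupling(0, 9), 0)
  expect_equal(normalizedCoupling(4.94, 40), 4.94 / sqrt(40))
  expect_error(normalizedCoupling(1, 0), "lambda > 0")

  om <- rep(2 * pi * 10, 3)
  p <- HopfParameters(K = 2, lambda = 4, omega = om)
  up <- rescaledEquivalent(p, 16)
  expect_equal(up@K, 4)
  expect_equal(up@lambda, 16)
  expect_equal(rescaledEquivalent(p, 4)@K, p@K)

  set.seed(31)
  for (i in 1:20) {
    K <- runif(1, 0, 10)
    lam <- runif(1, 0.1, 50)
    tgt <- runif(1, 0.1, 50)
    q <- rescaledEquivalent(HopfParameters(K = K, lambda = lam, omega = om),
                            tgt)
    expect_equal(normalizedCoupling(q@K, q@lambda),
                 normalizedCoupling(K, lam), tolerance = 1e-12)
  }
  expect_error(rescaledEquivalent(p, -1), "positive")
})

test_that("matched-k invariance degrades near criticality", {
  # the square-root law presumes self-sustained local oscillation; pairs
  # straddling the small-lambda regime correlate visibly worse than pairs
  # well beyond the bifurcation
  W <- makeConnectome(20, 0.3, seed = 101)
  om <- makeNaturalFrequencies(20, seed = 102)
  s <- SimulationSettings()
  ics <- sampleInitialConditions(3, 20, 201)
  k <- 1.2649
  matchedCor <- function(lamA, lamB) {
    pA <- HopfParameters(K = k * sqrt(lamA), lambda = lamA, omega = om,
                         C = 20)
    pB <- rescaledEquivalent(pA, lamB)
    mean(vapply(ics, function(ic) {
      a <- pliValues(simulatePLI(pA, W, ic * sqrt(lamA), s))
      b <- pliValues(simulatePLI(pB, W, rescaleInitialCondition(
        ic * sqrt(lamA), lamA, lamB), s))
      cor(a[upper.tri(a)], b[upper.tri(b)])
    }, numeric(1)))
  }
  beyond <- matchedCor(10, 40)
  nearCrit <- matchedCor(0.1, 40)
  expect_gt(beyond, 0.9)
  expect_lt(nearCrit, beyond)
})

test_that("time-series panels round-trip through TSV with sidecar", {
  p <- HopfParameters(K = 0, lambda = 1, omega = 2 * pi * c(10, 10))
  ts <- simulateHopf(p, matrix(0, 2, 2) + diag(0, 2), c(0.5 + 0i, 0 - 0.5i),
                     fastSettings())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTimeSeries(ts, f, meta = list(seed = 1))
  back <- readTimeSeries(f)
  expect_equal(tsValues(back), tsValues(ts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(samplingRate(back), samplingRate(ts))
})
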