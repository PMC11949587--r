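mkPli <- function(v, labels = sprintf("R%02d", seq_len(nrow(v))),
                  source = "empirical") {
  PLIMatrix(v, labels, source = source)
}

randomPli <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  mkPli(v + t(v))
}

test_that("the Pearson objective matches the textbook formula and its
           fixed points", {
  sim <- randomPli(4, 81)
  expect_equal(goodnessOfFit(sim, sim), 1)
  rev <- mkPli(pmax(1 - pliValues(sim), 0) - diag(1, 4))
  expect_equal(goodnessOfFit(sim, rev), -1)

  emp <- randomPli(4, 82)
  a <- pliValues(sim)[upper.tri(pliValues(sim))]
  b <- pliValues(emp)[upper.tri(pliValues(emp))]
  expect_equal(goodnessOfFit(sim, emp), textbookPearson(a, b),
               tolerance = 1e-12)
})

test_that("the objective respects exclusions and degenerate input", {
  sim <- randomPli(6, 83)
  emp <- randomPli(6, 84)
  # masking equals computing on the submatrices directly
  keep <- c(1L, 3L, 4L, 6L)
  sub <- function(p) mkPli(pliValues(p)[keep, keep],
                           labels = regionLabels(p)[keep])
  expect_equal(goodnessOfFit(sim, emp, exclude = c(2L, 5L)),
               goodnessOfFit(sub(sim), sub(emp)))
  expect_error(goodnessOfFit(sim, emp, exclude = 1:4), "fewer than 3")

  flat <- mkPli(matrix(0.5, 6, 6) - diag(0.5, 6))
  expect_error(goodnessOfFit(flat, emp), "zero variance")

  # invariance under simultaneous permutation
  perm <- sample(6)
  permute <- function(p) mkPli(pliValues(p)[perm, perm],
                               labels = regionLabels(p)[perm])
  expect_equal(goodnessOfFit(permute(sim), permute(emp)),
               goodnessOfFit(sim, emp))
})

test_that("optimal-coupling extraction is a per-lambda argmax with
           smallest-K ties", {
  KG <- c(1, 2, 4, 8)
  r <- array(NA_real_, dim = c(4, 2, 3))
  r[, 1, ] <- matrix(c(.1, .5, .3, .2), 4, 3) # argmax K=2 for every ic
  r[, 2, ] <- 0.4 # flat: tie toward K=1
  g <- new("FitGrid", KValues = KG, lambdaValues = c(10, 40), r = r,
           seed = 1L)
  curve <- optimalCouplingCurve(g)
  expect_equal(unname(curve@optimalK[1, ]), rep(2, 3))
  expect_equal(unname(curve@optimalK[2, ]), rep(1, 3))

  set.seed(85)
  rr <- array(runif(4 * 2 * 3), dim = c(4, 2, 3))
  g2 <- new("FitGrid", KValues = KG, lambdaValues = c(10, 40), r = rr,
            seed = 1L)
  c2 <- optimalCouplingCurve(g2)
  for (li in 1:2) for (ii in 1:3) {
    best <- -Inf
    bestK <- NA_real_
    for (ki in 1:4) if (rr[ki, li, ii] > best) {
      best <- rr[ki, li, ii]
      bestK <- KG[ki]
    }
    expect_equal(unname(c2@optimalK[li, ii]), bestK)
  }
})

test_that("the normalized-coupling regression matches its closed form", {
  lam <- c(10, 20, 40)
  exact <- new("CouplingCurve", lambdaValues = lam,
               optimalK = matrix(3 * sqrt(lam), 3, 5), KValues = 3 * sqrt(lam))
  fit <- fitNormalizedCoupling(exact, lambdaMin = 5)
  expect_equal(fit@k, 3)
  expect_equal(fit@rss, 0, tolerance = 1e-20)

  single <- new("CouplingCurve", lambdaValues = 4,
                optimalK = matrix(2, 1, 3), KValues = 2)
  expect_equal(fitNormalizedCoupling(single, lambdaMin = 0)@k, 1)

  set.seed(86)
  noisyK <- 2 * sqrt(lam) + rnorm(3, 0, 0.3)
  noisy <- new("CouplingCurve", lambdaValues = lam,
               optimalK = matrix(noisyK, 3, 1), KValues = noisyK)
  expect_equal(fitNormalizedCoupling(noisy, lambdaMin = 5)@k,
               sum(noisyK * sqrt(lam)) / sum(lam), tolerance = 1e-12)

  neg <- new("CouplingCurve", lambdaValues = c(-5, 0),
             optimalK = matrix(1, 2, 1), KValues = 1)
  expect_error(fitNormalizedCoupling(neg, lambdaMin = 0), "no positive")
})

test_that("grid search shares initial conditions, reproduces evaluateCell,
           and is order-invariant", {
  W <- toyConnectome(6, seed = 87)
  om <- makeNaturalFrequencies(6, seed = 88)
  s <- fastSettings()
  emp <- makeEmpiricalPLI(W, om, 3, 10, epochs = 1, noiseSd = 0,
                          seed = 89, settings = s)
  g <- gridSearch(W, om, emp, KGrid = 3, lambdaGrid = 10, nIc = 2,
                  seed = 90, settings = s)
  ics <- sampleInitialConditions(2, 6, 90)
  direct <- evaluateCell(3, 10, W, om, emp, ics, settings = s)
  expect_equal(as.vector(g@r[1, 1, ]), direct)

  # duplicate initial condition gives duplicate r (determinism)
  dup <- evaluateCell(3, 10, W, om, emp, list(ics[[1]], ics[[1]]),
                      settings = s)
  expect_equal(dup[1], dup[2])

  # permuting grid order yields the same surface up to reindexing
  g2 <- gridSearch(W, om, emp, KGrid = c(5, 1, 3), lambdaGrid = c(20, 10),
                   nIc = 2, seed = 90, settings = s)
  g3 <- gridSearch(W, om, emp, KGrid = c(1, 3, 5), lambdaGrid = c(10, 20),
                   nIc = 2, seed = 90, settings = s)
  expect_equal(g2@KValues, c(1, 3, 5))
  expect_equal(g2@r, g3@r)

  # 2x2 toy grid against an exhaustive independent loop
  g4 <- gridSearch(W, om, emp, KGrid = c(1, 3), lambdaGrid = c(10, 20),
                   nIc = 2, seed = 90, settings = s)
  for (ki in 1:2) for (li in 1:2) {
    rs <- evaluateCell(c(1, 3)[ki], c(10, 20)[li], W, om, emp, ics,
                       settings = s)
    expect_equal(as.vector(g4@r[ki, li, ]), rs)
  }
})

test_that("threshold selection scans candidates and picks the best mean
           fit", {
  W <- toyConnectome(6, seed = 91)
  om <- makeNaturalFrequencies(6, seed = 92)
  s <- fastSettings()
  emp <- makeEmpiricalPLI(W, om, 3, 10, epochs = 1, noiseSd = 0,
                          seed = 93, settings = s)
  one <- selectOptimalThreshold(emp, W, om, thresholdGrid = 20,
                                KGrid = 3, lambdaGrid = 10, nIc = 1,
                                seed = 94, settings = s)
  expect_equal(as.numeric(one), 20)

  grid <- c(0, 30, 60)
  sel <- selectOptimalThreshold(emp, W, om, thresholdGrid = grid,
                                KGrid = c(1, 3), lambdaGrid = 10, nIc = 1,
                                seed = 94, settings = s)
  bestR <- attr(sel, "bestR")
  # exhaustive loop over thresholds
  oracle <- vapply(grid, function(p) {
    g <- gridSearch(W, om, thresholdPLI(emp, p), c(1, 3), 10, 1, 94,
                    settings = s)
    max(meanSurface(g), na.rm = TRUE)
  }, numeric(1))
  expect_equal(unname(bestR), oracle)
  expect_equal(as.numeric(sel), grid[which.max(oracle)])
  expect_error(selectOptimalThreshold(emp, W, om, thresholdGrid = 100,
                                      KGrid = 1, lambdaGrid = 10, nIc = 1,
                                      seed = 1, settings = s), "< 100")
})

test_that("the generating cell and initial condition dominate a toy grid", {
  W <- toyConnectome(8, seed = 95)
  om <- makeNaturalFrequencies(8, seed = 96)
  s <- SimulationSettings(durationS = 5, burnInS = 0.5, fsHz = 250)
  ics <- sampleInitialConditions(3, 8, 97)
  trueK <- 8
  trueLambda <- 10
  # one noiseless epoch: emp is exactly the PLI of the run from ics[[1]]
  emp <- makeEmpiricalPLI(W, om, trueK, trueLambda, epochs = 1, noiseSd = 0,
                          seed = 97, settings = s)
  cells <- expand.grid(K = c(0.05, trueK, 25), lambda = c(5, trueLambda, 30))
  means <- mapply(function(K, lam)
    mean(evaluateCell(K, lam, W, om, emp, ics, settings = s), na.rm = TRUE),
    cells$K, cells$lambda)
  rGen <- evaluateCell(trueK, trueLambda, W, om, emp, ics, settings = s)
  # the generating initial condition reproduces emp exactly ...
  expect_equal(rGen[1], 1)
  # ... and beats every other cell's mean
  expect_true(all(rGen[1] >= means - 1e-12))
  # a near-uncoupled cell fits a strongly coupled run worse
  expect_lt(means[cells$K == 0.05 & cells$lambda == trueLambda],
            mean(rGen))
})
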