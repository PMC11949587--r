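# Independent oracles and small fixtures shared across the suite.  These
# deliberately re-derive results by brute force (loops, enumeration,
# fixed-step integration) and never call the code paths they check.

# Short, coarsely sampled protocol for tests that only need qualitative
# dynamics; the alpha band stays well inside Nyquist at 250 Hz.
fastSettings <- function()
  SimulationSettings(durationS = 3, burnInS = 0.5, fsHz = 250)

toyConnectome <- function(N = 6, density = 0.8, seed = 1)
  makeConnectome(N, density, seed = seed)

# Fixed-step classical RK4 on the complex state, via the package's drift
# (the drift itself is checked symbolically elsewhere).
rk4Reference <- function(z0, tEnd, dt, params, W) {
  f <- function(z) hopfDrift(z, params, W)
  n <- round(tEnd / dt)
  states <- matrix(NA_complex_, n + 1L, length(z0))
  states[1L, ] <- z <- z0
  for (i in seq_len(n)) {
    k1 <- f(z)
    k2 <- f(z + dt / 2 * k1)
    k3 <- f(z + dt / 2 * k2)
    k4 <- f(z + dt * k3)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    states[i + 1L, ] <- z
  }
  list(times = (0:n) * dt, states = states)
}

# Naive per-pair, per-sample PLI.
pliDoubleLoop <- function(phases) {
  N <- ncol(phases)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      s <- 0
      for (t in seq_len(nrow(phases))) {
        d <- sin(phases[t, i] - phases[t, j])
        s <- s + sign(d)
      }
      out[i, j] <- abs(s / nrow(phases))
    }
  }
  out
}

# Pearson correlation from the textbook sum formula.
textbookPearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exact two-sided rank-sum p-value by enumerating all C(n+m, n) group
# assignments of the pooled sample (no ties assumed).
rankSumEnumeration <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(length(pooled), n)
  u <- apply(splits, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  pLo <- mean(u <= uObs)
  pHi <- mean(u >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# patterns (no ties among |d|, no zeros assumed).
signedRankEnumeration <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v <- as.vector(signs %*% r)
  pLo <- mean(v <= vObs)
  pHi <- mean(v >= vObs)
  min(1, 2 * min(pLo, pHi))
}

# Multi-restart Lloyd's algorithm; returns the best within-cluster sum of
# squares over the restarts.
lloydBestWss <- function(pts, k, nRestarts = 1000L, seed = 1L) {
  set.seed(seed)
  best <- Inf
  n <- nrow(pts)
  for (r in seq_len(nRestarts)) {
    centers <- pts[sample(n, k), , drop = FALSE]
    assign <- rep(1L, n)
    for (it in 1:100) {
      d2 <- sapply(seq_len(k), function(c)
        colSums((t(pts) - centers[c, ])^2))
      newAssign <- max.col(-d2)
      for (c in seq_len(k)) {
        if (!any(newAssign == c))
          newAssign[sample(n, 1L)] <- c # revive empty cluster
        centers[c, ] <- colMeans(pts[newAssign == c, , drop = FALSE])
      }
      if (identical(newAssign, assign)) break
      assign <- newAssign
    }
    wss <- sum((pts - centers[assign, , drop = FALSE])^2)
    if (wss < best) best <- wss
  }
  best
}

# Welch-free periodogram argmax (plain FFT of the full signal).
periodogramArgmax <- function(x, fsHz, minHz = 4) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * fsHz / n
  half <- f <= fsHz / 2
  f <- f[half]
  p <- p[half]
  f[f > minHz][which.max(p[f > minHz])]
}

# Wrap phases into (-pi, pi].
wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

phasePanel <- function(phases, fsHz = 1250, labels = NULL) {
  labels <- labels %||% sprintf("R%02d", seq_len(ncol(phases)))
  new("PhasePanel", phases = phases, fsHz = fsHz, labels = labels,
      band = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
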