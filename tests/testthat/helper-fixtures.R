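# Shared fixtures and independent brute-force oracles used across tests.

# A fine uniform forest ramp: one cell per metre of elevation.
uniformForestGrid <- function(lo = 1000, hi = 2000, by = 1, area = 1) {
  e <- seq(lo, hi, by = by)
  ForestGrid(e, rep(TRUE, length(e)), cellArea = area)
}

# Burn mask covering given elevations of a 1-row grid.
burnAt <- function(grid, elevs, year = 2000L) {
  e <- elevations(grid)
  AnnualBurn(year, matrix(e %in% elevs, nrow(e), ncol(e)))
}

# Brute-force weighted check-loss minimisation over a slope x intercept grid.
gridSearchQR <- function(x, y, w, tau, slopes, intercepts) {
  loss <- function(a, b) {
    u <- y - a - b * x
    sum(w * ifelse(u >= 0, tau * u, (tau - 1) * u))
  }
  best <- c(NA, NA, Inf)
  for (b in slopes) for (a in intercepts) {
    l <- loss(a, b)
    if (l < best[3]) best <- c(a, b, l)
  }
  list(intercept = best[1], slope = best[2], loss = best[3])
}

# Pair-enumeration Mann-Kendall S.
bruteMKS <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i])
  s
}

# Empirical-CDF sup difference (two-sample KS statistic).
bruteKS <- function(a, b) {
  pts <- sort(c(a, b))
  max(abs(vapply(pts, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}

# A small seeded random landscape + one year of random contiguous-ish burns,
# for property-style checks.
randomGridAndBurn <- function(seed) {
  set.seed(seed)
  lo <- runif(1, 300, 2000)
  g <- generateLandscape(landscapeConfig(
    nx = 24L, ny = 24L,
    elevRange = c(lo, lo + runif(1, 800, 2000)),
    reliefRoughness = runif(1, 0.2, 0.8),
    forestBand = c(0, 4500), taperWidth = 0, seed = seed))
  forest <- forestMask(g)
  p <- runif(1, 0.1, 0.8)
  burn <- forest & matrix(runif(length(forest)) < p, nrow(forest))
  list(grid = g, burn = AnnualBurn(2000L, burn))
}
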