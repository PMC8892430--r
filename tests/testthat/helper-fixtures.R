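# Shared fixtures and the independent brute-force oracle used by the
# screening-equivalence tests.  The oracle re-derives every check of the
# standard tracer rule set directly from its published constants and plain
# loops; it deliberately shares no code with the package's rule engine.

DM_ORACLE <- 1.0033548378

# most intense centroid within +-ppm of target; ties by smaller |dmz|
oracle_match <- function(mz, intensity, target, ppm = 5) {
  ok <- which(abs(mz - target) / target <= ppm * 1e-6)
  if (!length(ok)) return(NA_real_)
  best <- ok[intensity[ok] == max(intensity[ok])]
  if (length(best) > 1L) best <- best[which.min(abs(mz[best] - target))]
  intensity[best]
}

# brute-force scan-level screen with the standard tracer rules:
# X >= 1e5; X+2, X+4 >= 5e4; X+1..X+4 present; X-1, X-2 <= 5 % of X;
# X+2 in 10-300 % of X; X+4 in 10-300 % of X+2; X+1 in 10-200 % of X and of
# X+2; X+3 in 10-200 % of X+2 and of X+4; (X + X+2)/X+1 and (X+2 + X+4)/X+3
# equal within a relative 10 %.
brute_force_screen <- function(run, ppm = 5) {
  hits <- list()
  for (s in run$scans) {
    for (i in seq_along(s$mz)) {
      X <- s$intensity[i]
      if (X < 1e5) next
      g <- function(nu) oracle_match(s$mz, s$intensity,
                                     s$mz[i] + nu * DM_ORACLE, ppm)
      I1 <- g(1); I2 <- g(2); I3 <- g(3); I4 <- g(4)
      Im1 <- g(-1); Im2 <- g(-2)
      if (anyNA(c(I1, I2, I3, I4))) next
      if (I2 < 5e4 || I4 < 5e4) next
      if (!is.na(Im1) && Im1 > 0.05 * X) next
      if (!is.na(Im2) && Im2 > 0.05 * X) next
      if (I2 / X < 0.1 || I2 / X > 3) next
      if (I4 / I2 < 0.1 || I4 / I2 > 3) next
      if (I1 / X < 0.1 || I1 / X > 2) next
      if (I1 / I2 < 0.1 || I1 / I2 > 2) next
      if (I3 / I2 < 0.1 || I3 / I2 > 2) next
      if (I3 / I4 < 0.1 || I3 / I4 > 2) next
      r1 <- (X + I2) / I1; r2 <- (I2 + I4) / I3
      if (abs(r1 - r2) / min(r1, r2) > 0.10) next
      hits[[length(hits) + 1L]] <- c(scan = s$scan_index, mz = s$mz[i])
    }
  }
  hits
}

candidate_keys <- function(x)
  sort(vapply(x, function(h) sprintf("%d@%.6f", as.integer(h[["scan"]] %||%
                                                             h[["scan_index"]]),
                                     h[["mz"]] %||% h[["x_mz"]]), character(1)))
`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny random run: up to 5 scans x up to ~50 centroids; about half the scans
# carry a planted pattern-like centroid family whose intensity fractions
# straddle the rule boundaries, the rest is uniform noise
random_tiny_run <- function(seed) {
  set.seed(seed)
  nscan <- sample(2:5, 1)
  scans <- vector("list", nscan)
  for (k in seq_len(nscan)) {
    n_noise <- sample(10:30, 1)
    mz <- runif(n_noise, 150, 950)
    int <- 10^runif(n_noise, 3, 5.6)
    if (runif(1) < 0.7) {          # plant a pattern-ish family
      B <- runif(1, 200, 900)
      X <- 10^runif(1, 4.8, 6.3)
      f2 <- runif(1, 0.05, 3.3)
      f4 <- runif(1, 0.05, 3.3)
      f1 <- runif(1, 0.05, 2.3)
      I2 <- X * f2; I4 <- I2 * f4; I1 <- X * f1
      # I3 near the value that balances the paired ratios, jittered across
      # the +-10 % boundary
      I3 <- (I2 + I4) / ((X + I2) / I1) * runif(1, 0.8, 1.25)
      fam_mz <- B + c(0, 1, 2, 3, 4) * DM_ORACLE
      fam_in <- c(X, I1, I2, I3, I4)
      if (runif(1) < 0.3) {        # sometimes a forbidden satellite
        fam_mz <- c(fam_mz, B - DM_ORACLE)
        fam_in <- c(fam_in, X * runif(1, 0.01, 0.12))
      }
      drop <- runif(1) < 0.15      # sometimes a missing satellite
      if (drop) { j <- sample(2:5, 1); fam_mz <- fam_mz[-j]; fam_in <- fam_in[-j] }
      jit <- 1 + rnorm(length(fam_mz), 0, 1e-6)   # ~1 ppm jitter
      mz <- c(mz, fam_mz * jit); int <- c(int, fam_in)
    }
    scans[[k]] <- mass_spectrum(k - 1L, rt = 10 * k, mz = mz, intensity = int)
  }
  ms_run(sprintf("tiny%03d", seed), scans)
}

# EIC with planted Gaussians: centers, sigmas, heights in seconds/counts
gaussian_eic <- function(rt, centers, sigmas, heights, noise_sd = 0) {
  y <- numeric(length(rt))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(rt - centers[i])^2 / (2 * sigmas[i]^2))
  if (noise_sd > 0) y <- pmax(0, y * (1 + rnorm(length(y), 0, noise_sd)))
  structure(list(target_mz = 500, ppm_window = 5, rt = rt, intensity = y,
                 scan_index = seq_along(rt) - 1L),
            class = "eic")
}
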