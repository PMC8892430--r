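#' @title Chromatographic verification
#' @description
#' Peak picking on extracted ion chromatograms with a Mexican-hat
#' continuous wavelet transform (ridge lines over peak-width-bounded
#' scales), Pearson coelution testing, and peak-area-based rule
#' re-verification of scan-level candidates.
#' @name chromatography
NULL

## Mexican-hat (Ricker) wavelet sampled at integer lags for scale s (in
## samples), L2-normalised so that for a Gaussian peak of sigma = s the
## coefficient-vs-scale curve peaks exactly at s.
ricker <- function(s, half = ceiling(5 * s)) {
  t <- (-half):half
  u <- t / s
  (1 - u^2) * exp(-u^2 / 2) / sqrt(s)
}

## CWT coefficients of y at one scale (in samples), same length as y
cwt_row <- function(y, s) {
  w <- ricker(s)
  half <- (length(w) - 1L) / 2L
  n <- length(y)
  ypad <- c(numeric(half), y, numeric(half))
  stats::convolve(ypad, w, type = "filter")[seq_len(n)]
}

local_maxima <- function(v, min_val = 0) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf) & v > min_val)
}

## three-point log-parabolic refinement of the best scale on a log grid
refine_scale <- function(scales, coefs, i) {
  if (i == 1L || i == length(scales)) return(scales[i])
  y <- coefs[(i - 1):(i + 1)]
  if (anyNA(y)) return(scales[i])
  x <- log(scales[(i - 1):(i + 1)])
  den <- y[1] - 2 * y[2] + y[3]
  if (den >= 0) return(scales[i])
  exp(x[2] - 0.5 * (x[3] - x[1]) / 2 * (y[3] - y[1]) / den)
}

#' CWT-based peak picking on an EIC
#'
#' Ridge-line detection over log-spaced Mexican-hat wavelet scales spanning
#' the configured chromatographic peak-width range.  A ridge must persist
#' over at least `min_ridge` adjacent scales; its best scale (log-parabolic
#' refinement of the coefficient maximum) estimates the peak sigma, and only
#' peaks whose estimated width (4 sigma) lies within `[min_width, max_width]`
#' and whose apex signal-to-noise ratio reaches `snr_min` are kept.  Peak
#' boundaries descend from the apex to local minima (or the baseline); the
#' area is the trapezoidal integral between them.
#'
#' @param eic an [extract_eic()] result.
#' @param min_width,max_width allowed chromatographic peak width range in
#'   seconds (width is taken as 4 sigma of a Gaussian peak).
#' @param snr_min minimum apex signal-to-noise ratio; noise is the median
#'   absolute deviation of the EIC outside detected peak cores (floored at
#'   1 count).
#' @param n_scales number of log-spaced wavelet scales.
#' @param min_ridge minimum number of adjacent scales a ridge must span.
#' @return list of peaks, each `list(apex_rt, apex_index, bounds,
#'   bound_index, area, apex_intensity, sigma, snr)`, ordered by apex rt.
#' @export
pick_peaks <- function(eic, min_width = 5, max_width = 25, snr_min = 3,
                       n_scales = 16L, min_ridge = 3L) {
  stopifnot(min_width < max_width)
  y <- eic$intensity
  n <- length(y)
  dt <- if (n > 1L) stats::median(diff(eic$rt)) else return(list())
  if (n < ceiling(min_width / dt) || !any(y > 0)) return(list())
  ## For a Gaussian peak of sigma the coefficient-vs-scale curve of this
  ## wavelet normalisation peaks at scale sqrt(5)*sigma (response is
  ## s^(5/2)/(s^2+sigma^2)^(3/2)), so the scale grid is laid out in sigma
  ## units times sqrt(5), with margins so in-range widths refine accurately
  ## and out-of-range widths still ridge (and then fail the width filter)
  s5 <- sqrt(5)
  sig <- s5 * exp(seq(log(min_width / 4 * 0.6), log(max_width / 4 * 1.6),
                      length.out = n_scales))
  scl <- sig / dt
  cw <- vapply(scl, function(s) cwt_row(y, s), numeric(n))  # n x n_scales
  ## ridge linking from the largest scale downwards
  ridges <- list()
  active <- list()
  for (j in rev(seq_len(n_scales))) {
    mx <- local_maxima(cw[, j])
    taken <- rep(FALSE, length(mx))
    win <- max(2, scl[j] / 2)
    for (k in seq_along(active)) {
      r <- active[[k]]
      if (is.null(r)) next
      d <- abs(mx - r$pos[length(r$pos)])
      cand <- which(!taken & d <= win)
      if (length(cand)) {
        pick <- cand[which.min(d[cand])]
        taken[pick] <- TRUE
        r$pos <- c(r$pos, mx[pick])
        r$scale_i <- c(r$scale_i, j)
        r$coef <- c(r$coef, cw[mx[pick], j])
        r$miss <- 0L
        active[[k]] <- r
      } else {
        r$miss <- r$miss + 1L
        if (r$miss > 2L) { ridges[[length(ridges) + 1L]] <- r; active[k] <- list(NULL) }
        else active[[k]] <- r
      }
    }
    for (m in mx[!taken])
      active[[length(active) + 1L]] <- list(pos = m, scale_i = j,
                                            coef = cw[m, j], miss = 0L)
  }
  ridges <- c(ridges, Filter(Negate(is.null), active))
  ridges <- Filter(function(r) length(r$pos) >= min_ridge, ridges)
  if (!length(ridges)) return(list())

  peaks <- list()
  core <- rep(FALSE, n)   # scans inside any candidate peak core, for noise
  cand <- list()
  for (r in ridges) {
    b <- which.max(r$coef)
    co <- rep(NA_real_, n_scales)
    co[r$scale_i] <- r$coef
    s_best <- refine_scale(sig, co, r$scale_i[b]) / s5
    ## apex: raw-intensity maximum near the ridge position at the best scale
    p0 <- r$pos[b]
    wloc <- max(1L, round(s_best / dt))
    ii <- max(1L, p0 - wloc):min(n, p0 + wloc)
    apex <- ii[which.max(y[ii])]
    cand[[length(cand) + 1L]] <- list(apex = apex, sigma = s_best)
    lo <- max(1L, apex - round(3 * s_best / dt))
    hi <- min(n, apex + round(3 * s_best / dt))
    core[lo:hi] <- TRUE
  }
  noise <- stats::mad(y[!core], center = 0)
  if (!is.finite(noise) || noise < 1) noise <- 1
  seen <- integer(0)
  for (ck in cand) {
    apex <- ck$apex
    if (apex %in% seen) next
    width <- 4 * ck$sigma
    if (width < min_width || width > max_width) next
    if (y[apex] / noise < snr_min) next
    bb <- descend_bounds(y, apex)
    if (bb[2] <= bb[1]) next
    seen <- c(seen, apex)
    idx <- bb[1]:bb[2]
    area <- sum(diff(eic$rt[idx]) *
                  (y[idx][-1] + y[idx][-length(idx)]) / 2)
    if (area <= 0) next
    peaks[[length(peaks) + 1L]] <- list(
      apex_rt = eic$rt[apex], apex_index = apex,
      bounds = c(eic$rt[bb[1]], eic$rt[bb[2]]), bound_index = bb,
      area = area, apex_intensity = y[apex], sigma = ck$sigma,
      snr = y[apex] / noise)
  }
  peaks[order(vapply(peaks, `[[`, numeric(1), "apex_rt"))]
}

## walk outwards from the apex while the signal keeps descending (with a
## tolerance for noise upticks); bound sits at the running minimum
descend_bounds <- function(y, apex, rise_factor = 2, floor_frac = 0.001) {
  n <- length(y)
  floor_v <- floor_frac * y[apex]
  walk <- function(step) {
    i <- apex; m <- y[apex]; mi <- apex
    while ((i + step) >= 1L && (i + step) <= n) {
      i <- i + step
      if (y[i] < m) { m <- y[i]; mi <- i }
      if (m <= floor_v) break
      if (y[i] > rise_factor * m + floor_v) break
    }
    mi
  }
  c(walk(-1L), walk(1L))
}

#' Pearson coelution of two EICs
#'
#' @param eic_a,eic_b EICs sampled on the same scan grid.
#' @param window optional `[low, high]` retention-time window in seconds
#'   (typically the X peak bounds); default full overlap.
#' @return Pearson correlation of the two intensity vectors inside the
#'   window, or `NA` when fewer than 4 points fall inside or either vector
#'   has zero variance (treated as a coelution failure downstream).
#' @export
coelution_r <- function(eic_a, eic_b, window = NULL) {
  keep <- if (is.null(window)) rep(TRUE, length(eic_a$rt))
          else eic_a$rt >= window[1] & eic_a$rt <= window[2]
  a <- eic_a$intensity[keep]; b <- eic_b$intensity[keep]
  if (length(a) < 4L || length(a) != length(b)) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Chromatographic verification of a feature candidate
#'
#' EICs are extracted for every rule-referenced offset at the theoretical
#' satellite m/z of the candidate's mean X m/z.  Each X peak found inside the
#' candidate's retention window is verified independently (so isomers yield
#' separate features): every presence-rule offset must have a picked peak
#' whose apex lies within the X peak bounds; all pairwise Pearson
#' correlations of the required-offset EICs inside the X peak bounds must
#' reach `r_min`; a coeluting peak at a forbidden offset with area above the
#' absence tolerance rejects the candidate; finally the rule set is
#' re-evaluated on the offset -> peak-area map.
#'
#' @param run the [ms_run()] the candidate came from.
#' @param candidate one feature candidate from [cluster_candidates()].
#' @param ruleset the [rule_set()].
#' @param params a [processing_params()] list.
#' @return list of verified features (class `"ts_feature"`), each
#'   `list(x_mz, apex_rt, rt_bounds, peaks, areas, coelution_r, sample_id)`;
#'   empty when rejected.  Attribute `"rejections"` collects the rejection
#'   reasons.
#' @export
verify_feature <- function(run, candidate, ruleset, params = processing_params()) {
  offs <- ruleset_offsets(ruleset)
  req <- required_offsets(ruleset)
  forb <- forbidden_offsets(ruleset)
  dm <- C13_MASS_DIFF / ruleset$charge
  pad <- params$peak_width[2]
  win <- c(candidate$rt_window[1] - pad, candidate$rt_window[2] + pad)
  win[1] <- max(win[1], min(run$rt)); win[2] <- min(win[2], max(run$rt))
  eics <- lapply(offs, function(o)
    extract_eic(run, candidate$mean_mz + o * dm, params$eic_ppm, rt_range = win))
  names(eics) <- offs
  xi <- as.character(0L)
  xpeaks <- pick_peaks(eics[[xi]], params$peak_width[1], params$peak_width[2],
                       params$snr_min)
  apad <- params$peak_width[1]
  xpeaks <- Filter(function(p)
    p$apex_rt >= candidate$rt_window[1] - apad &&
    p$apex_rt <= candidate$rt_window[2] + apad, xpeaks)
  rejections <- character(0)
  feats <- list()
  if (!length(xpeaks))
    return(structure(list(), rejections = "no chromatographic peak for X"))
  satpeaks <- lapply(setdiff(offs, 0L), function(o)
    pick_peaks(eics[[as.character(o)]], params$peak_width[1],
               params$peak_width[2], params$snr_min))
  names(satpeaks) <- setdiff(offs, 0L)
  for (xp in xpeaks) {
    bounds <- xp$bounds
    in_bounds <- function(p) p$apex_rt >= bounds[1] && p$apex_rt <= bounds[2]
    peak_of <- list(); peak_of[[xi]] <- xp
    areas <- c("0" = xp$area)
    ok <- TRUE
    for (o in setdiff(req, 0L)) {
      hits <- Filter(in_bounds, satpeaks[[as.character(o)]])
      if (!length(hits)) {
        rejections <- c(rejections,
                        sprintf("no coeluting peak for offset %d at rt %.1f",
                                o, xp$apex_rt))
        ok <- FALSE; break
      }
      best <- hits[[which.min(vapply(hits, function(p)
        abs(p$apex_rt - xp$apex_rt), numeric(1)))]]
      peak_of[[as.character(o)]] <- best
      areas[as.character(o)] <- best$area
    }
    if (!ok) next
    ## pairwise coelution of all required offsets inside the X peak bounds
    rmin_seen <- 1
    for (i in seq_along(req)) {
      for (j in seq_along(req)) {
        if (j <= i) next
        r <- coelution_r(eics[[as.character(req[i])]],
                         eics[[as.character(req[j])]], window = bounds)
        if (is.na(r) || r < params$coelution_r_min) {
          rejections <- c(rejections,
                          sprintf("coelution failure offsets %d vs %d (r = %.3f) at rt %.1f",
                                  req[i], req[j], if (is.na(r)) NA else r,
                                  xp$apex_rt))
          ok <- FALSE
        } else rmin_seen <- min(rmin_seen, r)
        if (!ok) break
      }
      if (!ok) break
    }
    if (!ok) next
    ## coeluting peaks at forbidden offsets enter the area map (the absence
    ## rule then bounds them); no peak means area 0
    for (o in forb) {
      hits <- Filter(in_bounds, satpeaks[[as.character(o)]])
      areas[as.character(o)] <-
        if (length(hits)) max(vapply(hits, `[[`, numeric(1), "area")) else 0
    }
    v <- evaluate_rules(ruleset, areas)
    if (!v$pass) {
      rejections <- c(rejections,
                      sprintf("area re-check failed at rt %.1f: %s",
                              xp$apex_rt, v$reason))
      next
    }
    feats[[length(feats) + 1L]] <- structure(
      list(x_mz = candidate$mean_mz, apex_rt = xp$apex_rt,
           rt_bounds = bounds, peaks = peak_of, areas = areas,
           coelution_r = rmin_seen, sample_id = run$sample_id),
      class = "ts_feature")
  }
  structure(feats, rejections = rejections)
}

#' @export
print.ts_feature <- function(x, ...) {
  cat(sprintf("<feature> m/z %.4f, rt %.1f s, %d isotopolog peaks, min r %.3f\n",
              x$x_mz, x$apex_rt, length(x$peaks), x$coelution_r))
  invisible(x)
}
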