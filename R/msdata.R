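#' @title Centroided LC-HRMS run access
#' @description Reading mzXML/mzML runs via mzR, per-scan m/z-window lookup
#'   and extracted-ion-chromatogram (EIC) construction.
#' @name msdata
NULL

#' Construct a single mass spectrum
#'
#' @param scan_index integer scan number (0-based within the run).
#' @param rt retention time in seconds.
#' @param mz numeric vector of centroid m/z values (will be sorted).
#' @param intensity numeric vector of centroid intensities (counts, >= 0).
#' @param polarity `"+"` or `"-"`.
#' @param ms_level MS level; only level 1 is processed downstream.
#' @return an object of class `"mass_spectrum"`.
#' @export
mass_spectrum <- function(scan_index, rt, mz, intensity, polarity = "-",
                          ms_level = 1L) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(list(scan_index = as.integer(scan_index), rt = rt,
                 polarity = polarity, ms_level = as.integer(ms_level),
                 mz = mz[o], intensity = intensity[o]),
            class = "mass_spectrum")
}

#' Construct a run from a list of spectra
#'
#' @param sample_id sample identifier (text).
#' @param scans list of [mass_spectrum()] objects, ordered in retention time.
#' @param polarity `"+"` or `"-"`; all scans must share it.
#' @return an object of class `"ms_run"`.
#' @export
ms_run <- function(sample_id, scans, polarity = "-") {
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  if (is.unsorted(rt, strictly = TRUE))
    stop("scan retention times must be strictly increasing")
  structure(list(sample_id = sample_id, scans = scans, polarity = polarity,
                 rt = rt),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  n <- length(x$scans)
  cat(sprintf("<ms_run> '%s': %d MS1 scans, polarity %s, rt %.1f-%.1f s\n",
              x$sample_id, n, x$polarity,
              if (n) min(x$rt) else NA, if (n) max(x$rt) else NA))
  invisible(x)
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> scan %d, rt %.2f s, %d centroids\n",
              x$scan_index, x$rt, length(x$mz)))
  invisible(x)
}

.polarity_code <- c("-" = 0, "+" = 1)

#' Read a centroided LC-HRMS run from mzXML or mzML
#'
#' Only MS1 scans of the requested polarity inside `rt_range` are retained;
#' mixed-polarity files are thereby split on read.  Peak arrays may be 32- or
#' 64-bit encoded.  A crude profile-mode heuristic (median centroid count per
#' scan above `profile_peak_bound` together with near-contiguous m/z spacing)
#' triggers a warning, not an error.
#'
#' @param path mzXML or mzML file with centroided MS1 spectra.
#' @param polarity `"+"`, `"-"`, or `NULL` to auto-detect (errors on files
#'   containing both polarities).
#' @param rt_range optional `[low, high]` retention-time window in seconds.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param profile_peak_bound centroids-per-scan bound for the profile-mode
#'   heuristic.
#' @return an [ms_run()].
#' @export
read_run <- function(path, polarity = NULL, rt_range = NULL,
                     sample_id = NULL,
                     profile_peak_bound = 5000) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file: ", path)
  h <- tryCatch({
    f <- mzR::openMSfile(path)
    on.exit(mzR::close(f), add = TRUE)
    mzR::header(f)
  }, error = function(e)
    stop("parse error in '", path, "': ", conditionMessage(e), call. = FALSE))
  if (nrow(h) == 0) stop("parse error: no scans in ", path)
  keep <- h$msLevel == 1L
  pol_codes <- unique(h$polarity[keep])
  if (is.null(polarity)) {
    pol_codes <- pol_codes[pol_codes %in% c(0, 1)]
    if (length(pol_codes) > 1)
      stop("file contains both polarities; pass polarity = \"+\" or \"-\"")
    polarity <- if (length(pol_codes) == 0 || pol_codes == 0) "-" else "+"
  }
  if (any(h$polarity[keep] %in% c(0, 1)))
    keep <- keep & (h$polarity == .polarity_code[[polarity]] | h$polarity < 0)
  if (!is.null(rt_range))
    keep <- keep & h$retentionTime >= rt_range[1] & h$retentionTime <= rt_range[2]
  idx <- which(keep)
  idx <- idx[order(h$retentionTime[idx])]
  scans <- vector("list", length(idx))
  pk <- if (length(idx)) mzR::peaks(f, idx) else list()
  if (length(idx) == 1L) pk <- list(pk)
  for (k in seq_along(idx)) {
    p <- pk[[k]]
    scans[[k]] <- mass_spectrum(scan_index = k - 1L,
                                rt = h$retentionTime[idx[k]],
                                mz = p[, 1], intensity = p[, 2],
                                polarity = polarity)
  }
  npeaks <- vapply(scans, function(s) length(s$mz), integer(1))
  if (length(npeaks) && stats::median(npeaks) > profile_peak_bound) {
    sp <- unlist(lapply(scans[seq_len(min(5, length(scans)))],
                        function(s) diff(s$mz)))
    if (length(sp) && stats::median(sp) < 0.01)
      warning("data look like profile mode (", stats::median(npeaks),
              " centroids/scan with near-contiguous spacing); ",
              "centroid before processing", call. = FALSE)
  }
  ms_run(sample_id %||% sub("\\.[^.]+$", "", basename(path)), scans,
         polarity = polarity)
}

#' Most intense centroid within a ppm window of a scan
#'
#' @param scan a [mass_spectrum()] (m/z sorted ascending).
#' @param mz query m/z in Da.
#' @param ppm half-width of the match window in ppm.
#' @return `list(mz =, intensity =)` of the most intense in-window centroid
#'   (ties broken by smaller |delta m/z|), or `NULL` if none.
#' @export
lookup <- function(scan, mz, ppm) {
  i <- match_window(scan$mz, scan$intensity, mz, ppm)
  if (is.na(i)) NULL else list(mz = scan$mz[i], intensity = scan$intensity[i])
}

## vectorised over targets: index of most intense centroid within +-ppm of
## each target (NA if none); deterministic tie-break by smaller |dmz|
match_window <- function(mz, intensity, targets, ppm) {
  d <- ppm * 1e-6
  lo <- findInterval(targets * (1 - d), mz, left.open = TRUE) + 1L
  hi <- findInterval(targets * (1 + d), mz)
  out <- rep(NA_integer_, length(targets))
  for (k in seq_along(targets)) {
    if (lo[k] > hi[k]) next
    ii <- lo[k]:hi[k]
    best <- ii[intensity[ii] == max(intensity[ii])]
    if (length(best) > 1L)
      best <- best[which.min(abs(mz[best] - targets[k]))]
    out[k] <- best
  }
  out
}

#' Extract an ion chromatogram
#'
#' One intensity per scan inside `rt_range`: the sum of all centroids within
#' `+-ppm` of `mz` (0 when no centroid falls inside the window).
#'
#' @param run an [ms_run()].
#' @param mz target m/z in Da.
#' @param ppm half-width of the extraction window in ppm.
#' @param rt_range optional `[low, high]` window in seconds; default full run.
#' @param aggregate `"sum"` (default) or `"max"` over in-window centroids.
#' @return an object of class `"eic"` with fields `target_mz`, `ppm_window`,
#'   `rt`, `intensity`, `scan_index`.
#' @export
extract_eic <- function(run, mz, ppm, rt_range = NULL,
                        aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  idx <- seq_along(run$scans)
  if (!is.null(rt_range)) {
    if (rt_range[2] <= rt_range[1]) stop("empty rt_range")
    idx <- which(run$rt >= rt_range[1] & run$rt <= rt_range[2])
  }
  d <- ppm * 1e-6
  lo <- mz * (1 - d); hi <- mz * (1 + d)
  int <- vapply(run$scans[idx], function(s) {
    i1 <- findInterval(lo, s$mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, s$mz)
    if (i1 > i2) 0
    else if (aggregate == "sum") sum(s$intensity[i1:i2])
    else max(s$intensity[i1:i2])
  }, numeric(1))
  structure(list(target_mz = mz, ppm_window = ppm,
                 rt = run$rt[idx], intensity = int,
                 scan_index = idx - 1L),
            class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> m/z %.4f +-%g ppm, %d scans, max %.3g\n",
              x$target_mz, x$ppm_window, length(x$rt),
              if (length(x$intensity)) max(x$intensity) else NA))
  invisible(x)
}
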