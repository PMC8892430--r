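#' @title Scan-level pattern search and candidate clustering
#' @description
#' Every centroid of every MS1 scan is initially considered to be the
#' principal isotopolog X of a putative metabolite ion; rule-referenced
#' satellite offsets are looked up at their theoretical m/z within the
#' intra-scan mass accuracy and the rule set is evaluated on the matched
#' intensities.  Surviving scan-level candidates are then clustered on X m/z
#' (time-aware, so non-coeluting isomers separate) into feature candidates.
#' @name screening
NULL

#' Scan-level rule screening of a run
#'
#' @param run an [ms_run()].
#' @param ruleset a [rule_set()].
#' @param intra_ppm intra-scan mass accuracy in ppm (satellite lookup
#'   window around each theoretical m/z).
#' @return list of scan candidates, each
#'   `list(scan_index, rt, x_mz, x_intensity, matched)` where `matched` is
#'   the offset -> intensity map the rules were evaluated on.  Attribute
#'   `"attrition"` holds the cumulative candidate counts after the intensity,
#'   absence and ratio rule stages (non-increasing by construction).
#' @export
screen_run <- function(run, ruleset, intra_ppm = 5) {
  offs <- ruleset_offsets(ruleset)
  sat_offs <- offs[offs != 0L]
  xmin <- min_x_intensity(ruleset)
  dm <- C13_MASS_DIFF / ruleset$charge
  out <- vector("list", 1000L); nout <- 0L
  n_int <- 0L; n_abs <- 0L; n_rat <- 0L
  for (scan in run$scans) {
    if (!length(scan$mz)) next
    xs <- which(scan$intensity >= xmin)
    for (xi in xs) {
      xmz <- scan$mz[xi]
      targets <- xmz + sat_offs * dm
      mi <- match_window(scan$mz, scan$intensity, targets, intra_ppm)
      intens <- c(scan$intensity[xi], scan$intensity[mi])
      names(intens) <- c("0", sat_offs)
      v <- evaluate_rules(ruleset, intens)
      sp <- v$stages_passed
      if (sp[["intensity"]]) {
        n_int <- n_int + 1L
        if (sp[["absence"]]) {
          n_abs <- n_abs + 1L
          if (sp[["ratio"]]) n_rat <- n_rat + 1L
        }
      }
      if (!v$pass) next
      nout <- nout + 1L
      if (nout > length(out)) out <- c(out, vector("list", length(out)))
      mzs <- c(xmz, scan$mz[mi])
      names(mzs) <- names(intens)
      out[[nout]] <- list(scan_index = scan$scan_index, rt = scan$rt,
                          x_mz = xmz, x_intensity = scan$intensity[xi],
                          matched_mz = mzs, matched = intens)
    }
  }
  structure(out[seq_len(nout)],
            attrition = c(intensity = n_int, absence = n_abs, ratio = n_rat))
}

#' Cluster scan candidates into feature candidates
#'
#' Agglomerative (complete linkage) clustering on X m/z, with the dendrogram
#' cut so that no subcluster's relative m/z spread exceeds the inter-scan
#' mass deviation; each m/z subcluster is then split at scan-index gaps
#' larger than `max_scan_gap`, so non-coeluting isomers of identical mass end
#' up in different feature candidates.  Groups with fewer than `min_members`
#' member scans are discarded (a real chromatographic peak spans several
#' consecutive scans).
#'
#' @param candidates list of scan candidates from [screen_run()].
#' @param inter_ppm inter-scan mass deviation window in ppm (maximum
#'   relative m/z spread of a cluster).
#' @param max_scan_gap largest tolerated gap between member scan indices.
#' @param min_members minimum number of member scans of a feature candidate.
#' @return list of feature candidates, each
#'   `list(mean_mz, rt_window, scan_range, members)` with `members` the
#'   member scan candidates ordered by scan index.
#' @export
cluster_candidates <- function(candidates, inter_ppm = 8, max_scan_gap = 3L,
                               min_members = 3L) {
  if (!length(candidates)) return(list())
  mz <- vapply(candidates, `[[`, numeric(1), "x_mz")
  scan <- vapply(candidates, `[[`, integer(1), "scan_index")
  ## complete linkage on log(m/z): cluster diameter in log space bounds the
  ## relative spread, so cutting at inter_ppm*1e-6 enforces the window
  grp <- if (length(mz) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(log(mz)), method = "complete")
    stats::cutree(hc, h = inter_ppm * 1e-6)
  }
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(scan[idx])]
    gap <- c(0L, diff(scan[idx]))
    piece <- cumsum(gap > max_scan_gap)
    for (pp in unique(piece)) {
      ii <- idx[piece == pp]
      if (length(ii) < min_members) next
      mem <- candidates[ii]
      rts <- vapply(mem, `[[`, numeric(1), "rt")
      out[[length(out) + 1L]] <- list(
        mean_mz = mean(vapply(mem, `[[`, numeric(1), "x_mz")),
        rt_window = range(rts),
        scan_range = range(vapply(mem, `[[`, integer(1), "scan_index")),
        members = mem)
    }
  }
  out
}
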