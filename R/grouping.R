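#' @title Cross-sample bracketing, convolution, reintegration and reporting
#' @description
#' Verified features are matched across measurement files by m/z and
#' retention-time tolerance (bracketing), co-eluting correlated brackets are
#' grouped into metabolite-level feature groups (convolution), samples
#' without a detected feature get their peak areas reintegrated over the
#' consensus peak window, and the result is written as a tab-separated data
#' matrix.
#' @name grouping
NULL

#' Bracket features across samples
#'
#' Greedy centroid-based merging in descending order of summed isotopolog
#' area: the strongest unassigned feature seeds a bracket, and the nearest
#' unassigned feature of every other sample within `|drt| <= rt_tol` and
#' `|dmz|/mz <= mz_ppm * 1e-6` joins it.  Each sample contributes at most one
#' feature per bracket; consensus m/z and rt are the member means.
#'
#' @param features_by_sample named list (sample id -> list of features from
#'   [verify_feature()]).
#' @param rt_tol retention-time tolerance in seconds.
#' @param mz_ppm m/z tolerance in ppm.
#' @return list of brackets (class `"ts_bracket"`), each
#'   `list(consensus_mz, consensus_rt, consensus_bounds, per_sample)`;
#'   `per_sample` maps sample id to `list(feature, areas, flag)` with flag
#'   `"detected"` (later possibly `"reintegrated"` / `"missing"`).
#' @export
bracket <- function(features_by_sample, rt_tol = 6, mz_ppm = 5) {
  tab <- list()
  for (sid in names(features_by_sample))
    for (f in features_by_sample[[sid]])
      tab[[length(tab) + 1L]] <- list(sid = sid, f = f,
                                      strength = sum(f$areas))
  if (!length(tab)) return(list())
  ord <- order(-vapply(tab, `[[`, numeric(1), "strength"))
  assigned <- rep(FALSE, length(tab))
  mzs <- vapply(tab, function(t) t$f$x_mz, numeric(1))
  rts <- vapply(tab, function(t) t$f$apex_rt, numeric(1))
  sids <- vapply(tab, `[[`, character(1), "sid")
  brackets <- list()
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    members <- i
    for (sid in setdiff(unique(sids), sids[i])) {
      j <- which(!assigned & sids == sid &
                 abs(rts - rts[i]) <= rt_tol &
                 abs(mzs - mzs[i]) / mzs[i] <= mz_ppm * 1e-6)
      if (!length(j)) next
      j <- j[which.min(abs(rts[j] - rts[i]))]
      assigned[j] <- TRUE
      members <- c(members, j)
    }
    per_sample <- stats::setNames(lapply(members, function(k)
      list(feature = tab[[k]]$f, areas = tab[[k]]$f$areas,
           flag = "detected")), sids[members])
    bmat <- vapply(members, function(k) tab[[k]]$f$rt_bounds, numeric(2))
    brackets[[length(brackets) + 1L]] <- structure(
      list(consensus_mz = mean(mzs[members]),
           consensus_rt = mean(rts[members]),
           consensus_bounds = c(stats::median(bmat[1, ]),
                                stats::median(bmat[2, ])),
           per_sample = per_sample),
      class = "ts_bracket")
  }
  brackets
}

#' @export
print.ts_bracket <- function(x, ...) {
  cat(sprintf("<bracket> m/z %.4f, rt %.2f min, %d sample(s)\n",
              x$consensus_mz, x$consensus_rt / 60, length(x$per_sample)))
  invisible(x)
}

#' Convolute brackets into metabolite-level feature groups
#'
#' Brackets whose consensus retention times differ by at most `rt_tol` and
#' whose X EICs correlate with a Pearson coefficient of at least `r_min` in at least one shared
#' sample are connected; connected components become feature groups (ions of
#' one metabolite: adducts, in-source fragments and the like).
#'
#' @param brackets list from [bracket()].
#' @param runs named list (sample id -> [ms_run()]).
#' @param r_min minimum Pearson correlation.
#' @param rt_tol consensus retention-time tolerance in seconds.
#' @param eic_ppm EIC extraction window in ppm.
#' @return list of feature groups, each
#'   `list(group_id, members, annotations)`.
#' @export
convolute <- function(brackets, runs, r_min = 0.85, rt_tol = 6, eic_ppm = 5) {
  nb <- length(brackets)
  if (!nb) return(list())
  parent <- seq_len(nb)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (j <= i) next
      bi <- brackets[[i]]; bj <- brackets[[j]]
      if (abs(bi$consensus_rt - bj$consensus_rt) > rt_tol) next
      shared <- intersect(names(bi$per_sample), names(bj$per_sample))
      shared <- intersect(shared, names(runs))
      linked <- FALSE
      for (sid in shared) {
        win <- range(bi$consensus_bounds, bj$consensus_bounds)
        ei <- extract_eic(runs[[sid]], bi$consensus_mz, eic_ppm, rt_range = win)
        ej <- extract_eic(runs[[sid]], bj$consensus_mz, eic_ppm, rt_range = win)
        r <- coelution_r(ei, ej)
        if (!is.na(r) && r >= r_min) { linked <- TRUE; break }
      }
      if (linked) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(nb), find, integer(1))
  groups <- list()
  for (g in unique(comp)) {
    idx <- which(comp == g)
    groups[[length(groups) + 1L]] <- list(
      group_id = length(groups) + 1L,
      members = brackets[idx],
      annotations = rep("", length(idx)))
  }
  groups
}

#' Reintegrate missing samples of a bracket
#'
#' For samples with no detected feature, the X and satellite EICs are
#' integrated over the consensus peak bounds and recorded as areas flagged
#' `"reintegrated"`; a missing run yields flag `"missing"` with `NA` areas.
#' Detected members are never altered.
#'
#' @param bracket_obj a bracket from [bracket()].
#' @param runs named list (sample id -> [ms_run()]).
#' @param offsets integer isotopolog offsets to integrate (typically
#'   `required_offsets(ruleset)`).
#' @param eic_ppm EIC extraction window in ppm.
#' @param charge charge state for satellite m/z computation.
#' @return the bracket with `per_sample` completed for every run.
#' @export
reintegrate <- function(bracket_obj, runs, offsets = 0L, eic_ppm = 5,
                        charge = 1L) {
  dm <- C13_MASS_DIFF / charge
  for (sid in names(runs)) {
    if (!is.null(bracket_obj$per_sample[[sid]])) next
    run <- runs[[sid]]
    if (is.null(run)) {
      bracket_obj$per_sample[[sid]] <- list(feature = NULL, areas = NULL,
                                            flag = "missing")
      next
    }
    win <- bracket_obj$consensus_bounds
    areas <- stats::setNames(vapply(offsets, function(o) {
      e <- extract_eic(run, bracket_obj$consensus_mz + o * dm, eic_ppm,
                       rt_range = win)
      if (length(e$rt) < 2L) return(0)
      sum(diff(e$rt) * (e$intensity[-1] + e$intensity[-length(e$intensity)]) / 2)
    }, numeric(1)), as.character(offsets))
    bracket_obj$per_sample[[sid]] <- list(feature = NULL, areas = areas,
                                          flag = "reintegrated")
  }
  bracket_obj
}

#' Write the results data matrix as TSV
#'
#' One row per bracketed feature: consensus m/z, consensus rt in minutes,
#' charge, feature-group id, and per sample one area column per isotopolog
#' offset plus a detection flag (`detected` / `reintegrated` / `missing`).
#' UTF-8, Unix newlines, tab separators, '.' decimal mark; header stable.
#'
#' @param groups list of feature groups from [convolute()].
#' @param path output file path.
#' @param offsets isotopolog offsets reported per sample.
#' @param sample_ids sample id order of the per-sample column blocks; default
#'   all ids seen in the groups.
#' @param charge charge state written to the matrix.
#' @return invisibly, the written data.frame.
#' @export
write_results_tsv <- function(groups, path, offsets = 0L, sample_ids = NULL,
                              charge = 1L) {
  if (is.null(sample_ids))
    sample_ids <- sort(unique(unlist(lapply(groups, function(g)
      unlist(lapply(g$members, function(b) names(b$per_sample)))))))
  off_lab <- ifelse(offsets >= 0, paste0("X+", offsets), paste0("X", offsets))
  off_lab <- sub("^X\\+0$", "X", off_lab)
  cols <- c("group_id", "feature_id", "mz", "rt_min", "charge")
  for (sid in sample_ids)
    cols <- c(cols, paste0(sid, "_area_", off_lab), paste0(sid, "_flag"))
  rows <- list()
  fid <- 0L
  for (g in groups) {
    for (b in g$members) {
      fid <- fid + 1L
      row <- list(group_id = g$group_id, feature_id = fid,
                  mz = round(b$consensus_mz, 6),
                  rt_min = round(b$consensus_rt / 60, 4), charge = charge)
      for (sid in sample_ids) {
        ps <- b$per_sample[[sid]]
        a <- stats::setNames(rep(NA_real_, length(offsets)),
                             as.character(offsets))
        flag <- "missing"
        if (!is.null(ps)) {
          flag <- ps$flag
          if (!is.null(ps$areas)) {
            common <- intersect(names(a), names(ps$areas))
            a[common] <- ps$areas[common]
          }
        }
        row <- c(row, stats::setNames(as.list(round(unname(a), 2)),
                                      paste0(sid, "_area_", off_lab)),
                 stats::setNames(list(flag), paste0(sid, "_flag")))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- if (length(rows))
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  else as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols),
                     check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(df)
}
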