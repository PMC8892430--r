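#' Processing parameters
#'
#' Defaults follow common high-resolution Orbitrap-type acquisition:
#' intra-scan mass accuracy and EIC window of 5 ppm, scan-to-scan mass
#' deviation of 8 ppm, retention-time window 3-36 min, chromatographic peak
#' widths 5-25 s, minimum Pearson coelution 0.85, bracketing tolerances of
#' 0.1 min and 5 ppm.
#'
#' @param intra_scan_ppm intra-scan mass accuracy in ppm.
#' @param inter_scan_ppm scan-to-scan mass deviation in ppm (candidate
#'   clustering window).
#' @param eic_ppm EIC extraction window in ppm.
#' @param rt_window processed retention-time window in minutes.
#' @param peak_width allowed chromatographic peak width range in seconds.
#' @param coelution_r_min minimum Pearson correlation for coeluting peaks.
#' @param bracket_rt_tol bracketing retention-time tolerance in minutes.
#' @param bracket_ppm bracketing m/z tolerance in ppm.
#' @param charge charge state.
#' @param snr_min minimum peak signal-to-noise ratio.
#' @param max_scan_gap largest tolerated member scan gap in a candidate
#'   cluster.
#' @param min_cluster_size minimum member scans of a candidate cluster.
#' @return a named list of class `"processing_params"`.
#' @export
processing_params <- function(intra_scan_ppm = 5, inter_scan_ppm = 8,
                              eic_ppm = 5, rt_window = c(3, 36),
                              peak_width = c(5, 25), coelution_r_min = 0.85,
                              bracket_rt_tol = 0.1, bracket_ppm = 5,
                              charge = 1L, snr_min = 3, max_scan_gap = 3L,
                              min_cluster_size = 3L) {
  stopifnot(rt_window[1] < rt_window[2], peak_width[1] < peak_width[2],
            intra_scan_ppm > 0, inter_scan_ppm > 0, eic_ppm > 0,
            coelution_r_min > 0, bracket_rt_tol > 0, bracket_ppm > 0)
  structure(list(intra_scan_ppm = intra_scan_ppm,
                 inter_scan_ppm = inter_scan_ppm, eic_ppm = eic_ppm,
                 rt_window = rt_window, peak_width = peak_width,
                 coelution_r_min = coelution_r_min,
                 bracket_rt_tol = bracket_rt_tol, bracket_ppm = bracket_ppm,
                 charge = as.integer(charge), snr_min = snr_min,
                 max_scan_gap = as.integer(max_scan_gap),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "processing_params")
}

#' Run the full screening pipeline
#'
#' Executes read -> scan-level screening -> candidate clustering ->
#' chromatographic verification per sample, then bracketing, convolution,
#' reintegration and TSV reporting across samples.  The per-stage log
#' reports candidate counts, including the stepwise rule attrition (counts
#' after the intensity, absence and ratio rule stages).
#'
#' @param inputs character vector of mzXML/mzML paths, or a (named) list of
#'   [ms_run()] objects.
#' @param ruleset a [rule_set()], or `"standard"` / `"reversed"` for the
#'   built-in sets, or a path to a rule-set config file.
#' @param params a [processing_params()] list.
#' @param out optional results TSV path.
#' @param polarity polarity passed to [read_run()] for file inputs.
#' @param apply_rt_window logical; restrict scans to `params$rt_window`
#'   (always applied to file inputs; for in-memory runs the default keeps
#'   all scans so that short synthetic runs need no offsetting).
#' @param verbose print the per-stage log as it accumulates.
#' @return invisibly, `list(groups, brackets, features_by_sample, log,
#'   results)`; `results` is the written data.frame.  Exits with an error
#'   naming the stage and file when a stage fails.
#' @export
run_pipeline <- function(inputs, ruleset = "standard",
                         params = processing_params(), out = NULL,
                         polarity = NULL, apply_rt_window = NULL,
                         verbose = FALSE) {
  if (is.character(ruleset)) {
    ruleset <- if (ruleset %in% c("standard", "reversed"))
      switch(ruleset, standard = standard_tracer_ruleset(charge = params$charge),
             reversed = reversed_tracer_ruleset(charge = params$charge))
    else read_ruleset(ruleset)
  }
  from_files <- is.character(inputs)
  if (is.null(apply_rt_window)) apply_rt_window <- from_files
  say <- function(...) if (verbose) message(sprintf(...))
  logs <- list()
  runs <- list(); features_by_sample <- list()
  for (i in seq_along(inputs)) {
    input <- inputs[[i]]
    run <- if (from_files) {
      tryCatch(read_run(input, polarity = polarity,
                        rt_range = if (apply_rt_window) params$rt_window * 60),
               error = function(e) stop("stage 'read' failed for ", input,
                                        ": ", conditionMessage(e), call. = FALSE))
    } else input
    if (!from_files && apply_rt_window) {
      keep <- run$rt >= params$rt_window[1] * 60 & run$rt <= params$rt_window[2] * 60
      run <- ms_run(run$sample_id, run$scans[keep], run$polarity)
    }
    sid <- run$sample_id
    cands <- tryCatch(screen_run(run, ruleset, params$intra_scan_ppm),
                      error = function(e) stop("stage 'screen' failed for ",
                                               sid, ": ", conditionMessage(e),
                                               call. = FALSE))
    attrition <- attr(cands, "attrition")
    clusters <- cluster_candidates(cands, params$inter_scan_ppm,
                                   params$max_scan_gap, params$min_cluster_size)
    feats <- list()
    for (cl in clusters) {
      vf <- tryCatch(verify_feature(run, cl, ruleset, params),
                     error = function(e) stop("stage 'verify' failed for ",
                                              sid, ": ", conditionMessage(e),
                                              call. = FALSE))
      feats <- c(feats, vf)
    }
    runs[[sid]] <- run
    features_by_sample[[sid]] <- feats
    logs[[sid]] <- c(scans = length(run$scans),
                     pass_intensity = unname(attrition["intensity"]),
                     pass_absence = unname(attrition["absence"]),
                     pass_ratio = unname(attrition["ratio"]),
                     scan_candidates = length(cands),
                     feature_candidates = length(clusters),
                     verified_features = length(feats))
    say("[%s] scans %d | attrition %d -> %d -> %d | clusters %d | features %d",
        sid, length(run$scans), attrition["intensity"], attrition["absence"],
        attrition["ratio"], length(clusters), length(feats))
  }
  brackets <- bracket(features_by_sample,
                      rt_tol = params$bracket_rt_tol * 60,
                      mz_ppm = params$bracket_ppm)
  groups <- convolute(brackets, runs, r_min = params$coelution_r_min,
                      rt_tol = params$bracket_rt_tol * 60,
                      eic_ppm = params$eic_ppm)
  offs <- required_offsets(ruleset)
  groups <- lapply(groups, function(g) {
    g$members <- lapply(g$members, reintegrate, runs = runs, offsets = offs,
                        eic_ppm = params$eic_ppm, charge = params$charge)
    g
  })
  say("bracketed %d features into %d brackets, %d groups",
      sum(vapply(features_by_sample, length, integer(1))),
      length(brackets), length(groups))
  results <- NULL
  if (!is.null(out))
    results <- write_results_tsv(groups, out, offsets = offs,
                                 sample_ids = names(runs),
                                 charge = params$charge)
  invisible(list(groups = groups, brackets = brackets,
                 features_by_sample = features_by_sample,
                 log = logs, results = results))
}
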