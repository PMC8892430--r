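#' @title Synthetic tracer-incorporation runs
#' @description
#' Ground-truthed synthetic LC-HRMS runs with planted isotopolog patterns.
#' Metabolites built from malonate-derived C2 extension units incorporate a
#' random number of tracer-derived units; each incorporated unit shifts the
#' ion by two carbon exchanges, producing the even-offset staircase, while
#' tracer isotopic impurity and natural 13C abundance produce the odd-offset
#' satellites in between.
#' @name synthetic
NULL

#' Tracer-incorporation model for one ion
#'
#' @param n_units number of C2 extension units in the carbon skeleton.
#' @param q probability that an extension unit is tracer-derived.
#' @param tracer_purity per-carbon isotopic purity of the tracer's two
#'   carbons (13C purity in the standard approach; 12C purity of the native
#'   tracer in the reversed approach).
#' @param nat_13c natural 13C abundance of the native carbon source.
#' @param n_carbons total number of carbon atoms in the ion
#'   (>= 2 * n_units).
#' @param direction `"standard"` (13C tracer, native background; offsets at
#'   or above 0) or `"reversed"` (native tracer, globally 13C-labelled
#'   background; offsets at or below 0).
#' @param label_purity per-carbon 13C purity of the global label in the
#'   reversed approach (the uniformly labelled carbon source is not 100 %
#'   pure).
#' @return an object of class `"incorporation_model"`.
#' @export
incorporation_model <- function(n_units, q, tracer_purity = 0.99,
                                nat_13c = 0.0107, n_carbons = 2L * n_units,
                                direction = c("standard", "reversed"),
                                label_purity = 0.99) {
  direction <- match.arg(direction)
  stopifnot(q >= 0, q <= 1, tracer_purity >= 0, tracer_purity <= 1,
            nat_13c >= 0, nat_13c <= 1, label_purity >= 0, label_purity <= 1,
            n_carbons >= 2 * n_units, n_units >= 1)
  structure(list(n_units = as.integer(n_units), q = q,
                 tracer_purity = tracer_purity, nat_13c = nat_13c,
                 n_carbons = as.integer(n_carbons), direction = direction,
                 label_purity = label_purity),
            class = "incorporation_model")
}

## Shared core on the "exchange" scale: offset u >= 0 counts exchanges away
## from the reference isotopolog (heavy gains in the standard approach, light
## gains in the reversed one).  p = per-carbon purity of a tracer unit's
## carbons, eps = per-carbon exchange probability of all other carbons.
##
## First-order model: the even backbone is the leading-order weight of k
## incorporated units, E_k = C(n,k) q^k (1-q)^(n-k) p^(2k) (1-eps)^(nc-2k);
## each odd satellite draws from its two even neighbours with one constant
## effective single-exchange rate, O_k = c (E_k + E_{k+1}),
## c = [(nc - 2nq) eps/(1-eps) + 2nq (1-p)/p] / 2.  The constant c makes the
## paired sum ratios (E_k + E_{k+1})/O_k identical for every k, the property
## the ratio-equality rule filters on.
##
## Exact model: full carbon-level enumeration (convolution of binomials);
## physically complete, but its paired sum ratios are only approximately
## constant.
pattern_core <- function(n_units, q, p, eps, nc, model) {
  if (model == "exact") {
    out <- numeric(nc + 1L)
    for (m in 0:n_units) {
      w <- stats::dbinom(m, n_units, q)
      d1 <- stats::dbinom(0:(2 * m), 2 * m, p)
      d2 <- stats::dbinom(0:(nc - 2 * m), nc - 2 * m, eps)
      d <- numeric(nc + 1L)
      for (i in seq_along(d1))
        d[i:(i + length(d2) - 1L)] <- d[i:(i + length(d2) - 1L)] + d1[i] * d2
      out <- out + w * d
    }
    return(out)
  }
  k <- 0:n_units
  E <- stats::dbinom(k, n_units, q) * p^(2 * k) * (1 - eps)^(nc - 2 * k)
  cc <- ((nc - 2 * n_units * q) * eps / (1 - eps) +
           2 * n_units * q * (1 - p) / max(p, .Machine$double.eps)) / 2
  O <- cc * (E + c(E[-1], 0))
  out <- numeric(2 * n_units + 2L)
  out[2 * k + 1L] <- E
  out[2 * k + 2L] <- O
  out[seq_len(min(length(out), nc + 1L))]
}

#' Theoretical isotopolog pattern of a tracer-incorporating ion
#'
#' Computes the relative intensities of all isotopologs of one ion under an
#' [incorporation_model()].  Two model variants are available.  The default
#' `"first_order"` combines the binomial staircase of fully incorporated
#' tracer units (even offsets) with a constant effective single-exchange rate
#' for the odd satellites arising from tracer isotopic impurity and natural
#' 13C abundance; by construction its paired sum ratios, e.g.
#' `(X + X+2)/X+1` and `(X+2 + X+4)/X+3`, are exactly identical, which is the
#' diagnostic property the ratio-equality rule exploits.  `"exact"` performs
#' the full carbon-level enumeration (convolution of binomials over every
#' carbon); it is physically complete but its paired sum ratios are only
#' approximately constant (see the methods vignette).
#'
#' @param model an [incorporation_model()].
#' @param variant `"first_order"` (default) or `"exact"`.
#' @param min_rel isotopologs below this fraction of the most intense one are
#'   dropped from the result.
#' @return named numeric vector of relative intensities, names are signed
#'   offsets, maximum normalised to 1; attribute `"mass"` holds the
#'   corresponding probability masses (summing to 1).
#' @examples
#' m <- incorporation_model(n_units = 9, q = 0.1, n_carbons = 18)
#' theoretical_pattern(m)[1:6]
#' @export
theoretical_pattern <- function(model, variant = c("first_order", "exact"),
                                min_rel = 1e-6) {
  variant <- match.arg(variant)
  rev_mode <- model$direction == "reversed"
  eps <- if (rev_mode) 1 - model$label_purity else model$nat_13c
  v <- pattern_core(model$n_units, model$q, model$tracer_purity, eps,
                    model$n_carbons, variant)
  mass <- v / sum(v)
  offs <- seq_along(v) - 1L
  if (rev_mode) offs <- -offs
  names(mass) <- offs
  rel <- mass / max(mass)
  keep <- rel >= min_rel
  ## "mass" keeps every offset so that it remains a full probability
  ## distribution; the returned relative pattern drops negligible tails
  structure(rel[keep], mass = mass)
}

#' Maximum number of C2 extension units of a molecular formula
#'
#' @param formula molecular formula text, e.g. `"C30H18O12"`.
#' @return `floor(carbon_count / 2)`.
#' @examples
#' max_extension_units("C30H18O12")  # 15
#' @export
max_extension_units <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("malformed formula: ", deparse(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula)
  counts <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) +
      (if (nzchar(n)) as.integer(n) else 1L)
  }
  nC <- counts["C"]
  if (is.na(nC) || nC < 2) stop("formula must contain at least 2 carbons: ", formula)
  as.integer(nC %/% 2)
}

#' A compound planted into a synthetic run
#'
#' @param x_mz m/z of the principal isotopolog X.
#' @param rt_apex chromatographic apex in seconds.
#' @param peak_sigma Gaussian peak sigma in seconds (peak width is about
#'   4 sigma).
#' @param height apex intensity of X in counts.
#' @param model an [incorporation_model()].
#' @param decoy `NULL` for a compliant compound, or one of
#'   `"missing_isotopolog"` (a required odd satellite is absent),
#'   `"forbidden_isotopolog"` (a forbidden offset present at 15 % of X),
#'   `"ratio_distortion"` (the first odd satellite inflated 3-fold, breaking
#'   the paired-ratio equality while staying inside the plain range bounds),
#'   `"shifted_satellite"` (the first even satellite's peak shifted by
#'   3.5 sigma, breaking coelution only).
#' @param id compound identifier.
#' @return an object of class `"planted_compound"`.
#' @export
planted_compound <- function(x_mz, rt_apex, peak_sigma, height, model,
                             decoy = NULL, id = NULL) {
  if (!is.null(decoy))
    decoy <- match.arg(decoy, c("missing_isotopolog", "forbidden_isotopolog",
                                "ratio_distortion", "shifted_satellite"))
  structure(list(x_mz = x_mz, rt_apex = rt_apex, peak_sigma = peak_sigma,
                 height = height, model = model, decoy = decoy,
                 id = id %||% sprintf("cpd_mz%.4f", x_mz)),
            class = "planted_compound")
}

## expand a compound into per-isotopolog traces: offset, mz, relative height
## (vs X), apex rt.  decoy violations are applied here.
compound_traces <- function(cpd, charge = 1L) {
  patt <- theoretical_pattern(cpd$model)
  rel <- patt / patt[["0"]]
  offs <- as.integer(names(rel))
  sgn <- if (cpd$model$direction == "reversed") -1L else 1L
  apex <- rep(cpd$rt_apex, length(offs))
  if (!is.null(cpd$decoy)) {
    if (cpd$decoy == "missing_isotopolog") {
      drop <- offs != sgn * 3L
      rel <- rel[drop]; offs <- offs[drop]; apex <- apex[drop]
    } else if (cpd$decoy == "forbidden_isotopolog") {
      offs <- c(offs, -sgn * 1L)
      rel <- c(rel, 0.15)
      apex <- c(apex, cpd$rt_apex)
    } else if (cpd$decoy == "ratio_distortion") {
      rel[offs == sgn * 1L] <- rel[offs == sgn * 1L] * 3
    } else if (cpd$decoy == "shifted_satellite") {
      apex[offs == sgn * 2L] <- cpd$rt_apex + 3.5 * cpd$peak_sigma
    }
  }
  data.frame(offset = offs,
             mz = expected_mz(cpd$x_mz, offs, charge),
             rel = as.numeric(rel), apex = apex)
}

#' Assemble a ground-truthed set of planted compounds
#'
#' Samples compliant compounds and single-rule-violation decoys on a regular
#' retention-time ladder.  Model parameters are drawn from ranges chosen so
#' that every compliant compound's theoretical pattern passes the respective
#' built-in rule set (verified at construction; see the methods vignette for
#' the ranges' rationale): ions of 16-30 carbons (18-30 reversed), tracer
#' incorporation probability per unit 0.07-0.15, tracer purity 0.99, natural
#' 13C abundance 0.0107, global label purity 0.99.
#'
#' @param n_compliant number of rule-compliant compounds.
#' @param n_decoy number of decoys; violation types are cycled (see
#'   [planted_compound()]).
#' @param direction `"standard"` or `"reversed"`.
#' @param seed integer seed; the truth is reproducible from it.
#' @param rt_start apex of the first compound in seconds.
#' @param rt_spacing apex spacing in seconds.
#' @param mz_range m/z range for X.
#' @return an object of class `"synthetic_truth"`: fields `compounds`,
#'   `seed`, `direction`; each compound carries its expected verdict.
#' @export
make_synthetic_truth <- function(n_compliant, n_decoy,
                                 direction = c("standard", "reversed"),
                                 seed = 1L, rt_start = 60, rt_spacing = 40,
                                 mz_range = c(250, 900)) {
  direction <- match.arg(direction)
  n <- n_compliant + n_decoy
  withr_seed(seed, {
    nc_min <- if (direction == "reversed") 18L else 16L
    decoy_types <- c("missing_isotopolog", "forbidden_isotopolog",
                     "ratio_distortion", "shifted_satellite")
    role <- sample(rep(c(TRUE, FALSE), c(n_compliant, n_decoy)))
    ruleset <- if (direction == "standard") standard_tracer_ruleset()
               else reversed_tracer_ruleset()
    cpds <- vector("list", n)
    k_decoy <- 0L
    for (i in seq_len(n)) {
      nc <- 2L * sample(seq(nc_min / 2L, 15L), 1)
      model <- incorporation_model(
        n_units = nc %/% 2L, q = stats::runif(1, 0.07, 0.15),
        n_carbons = nc, direction = direction)
      patt <- theoretical_pattern(model)
      rel <- patt / patt[["0"]]
      req <- as.character(required_offsets(ruleset))
      h_min <- max(1e5, 5e4 / min(rel[req])) * 1.4
      decoy <- NULL
      if (!role[i]) {
        k_decoy <- k_decoy + 1L
        decoy <- decoy_types[(k_decoy - 1L) %% length(decoy_types) + 1L]
      } else {
        v <- evaluate_rules(ruleset, h_min * rel[req])
        if (!v$pass)
          stop("internal error: sampled compliant compound violates rules: ",
               v$reason)
      }
      cpds[[i]] <- planted_compound(
        x_mz = stats::runif(1, mz_range[1], mz_range[2]),
        rt_apex = rt_start + (i - 1) * rt_spacing,
        peak_sigma = stats::runif(1, 2.5, 5),
        height = stats::runif(1, h_min, 3 * h_min),
        model = model, decoy = decoy,
        id = sprintf("%s_%02d_%s", substr(direction, 1, 3), i,
                     if (is.null(decoy)) "compliant" else decoy))
    }
    structure(list(compounds = cpds, seed = as.integer(seed),
                   direction = direction),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  dec <- vapply(x$compounds, function(c) !is.null(c$decoy), logical(1))
  cat(sprintf("<synthetic_truth> %s: %d compliant + %d decoys (seed %d)\n",
              x$direction, sum(!dec), sum(dec), x$seed))
  invisible(x)
}

#' Ground-truth table of a synthetic truth object
#'
#' @param truth a [make_synthetic_truth()] object.
#' @return data.frame with one row per planted compound, including the
#'   expected pipeline verdict.
#' @export
truth_table <- function(truth) {
  do.call(rbind, lapply(truth$compounds, function(c)
    data.frame(id = c$id, x_mz = c$x_mz, rt_apex = c$rt_apex,
               peak_sigma = c$peak_sigma, height = c$height,
               n_units = c$model$n_units, q = c$model$q,
               n_carbons = c$model$n_carbons,
               decoy = c$decoy %||% "none",
               expected = if (is.null(c$decoy)) "detect" else "reject")))
}

## evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic centroided run
#'
#' Every planted compound contributes, per scan, one centroid per isotopolog
#' at its theoretical m/z with intensity `height * relative_intensity *
#' Gaussian(rt)`, subject to multiplicative log-normal intensity noise and
#' ppm-scale m/z jitter.  Decoys carry their stated single-rule violation.
#' Uniform random noise centroids (m/z uniform over `mz_range`, intensities
#' uniform up to `noise_max_intensity`) are added per scan.  Deterministic
#' given `seed`.
#'
#' @param truth a [make_synthetic_truth()] object (or any list of
#'   [planted_compound()]s plus a `seed`).
#' @param rt_range run retention-time span in seconds; default covers all
#'   compounds with a 30 s margin.
#' @param scan_interval scan spacing in seconds.
#' @param mz_noise_ppm standard deviation of centroid m/z jitter in ppm.
#' @param intensity_noise_cv coefficient of variation of multiplicative
#'   log-normal intensity noise.
#' @param n_noise_peaks number of random noise centroids per scan.
#' @param noise_max_intensity upper bound of noise-centroid intensities.
#' @param mz_range m/z range of noise centroids.
#' @param sample_id sample identifier for the resulting run.
#' @param rt_shift whole-run retention-time shift in seconds (inter-sample
#'   jitter for bracketing studies).
#' @param mz_shift_ppm whole-run m/z shift in ppm (inter-sample calibration
#'   jitter).
#' @param polarity run polarity.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @param floor_intensity centroids below this intensity are dropped.
#' @return an [ms_run()]; write it with [write_mzxml()].
#' @export
generate_run <- function(truth, rt_range = NULL, scan_interval = 0.5,
                         mz_noise_ppm = 0, intensity_noise_cv = 0,
                         n_noise_peaks = 0, noise_max_intensity = 4.9e4,
                         mz_range = c(100, 1000), sample_id = "synthetic",
                         rt_shift = 0, mz_shift_ppm = 0, polarity = "-",
                         seed = NULL, floor_intensity = 50) {
  cpds <- truth$compounds
  if (is.null(rt_range)) {
    if (length(cpds)) {
      apx <- vapply(cpds, `[[`, numeric(1), "rt_apex")
      rt_range <- c(max(0, min(apx) - 30), max(apx) + 30)
    } else rt_range <- c(0, 60)
  }
  rts <- seq(rt_range[1], rt_range[2], by = scan_interval) + rt_shift
  traces <- lapply(cpds, compound_traces)
  withr_seed(seed %||% truth$seed, {
    sdlog <- sqrt(log(1 + intensity_noise_cv^2))
    scans <- vector("list", length(rts))
    for (si in seq_along(rts)) {
      t <- rts[si]
      mzv <- numeric(0); iv <- numeric(0)
      for (ci in seq_along(cpds)) {
        tr <- traces[[ci]]
        sg <- cpds[[ci]]$peak_sigma
        dtt <- t - (tr$apex + rt_shift)
        g <- ifelse(abs(dtt) > 4.5 * sg, 0, exp(-dtt^2 / (2 * sg^2)))
        int <- cpds[[ci]]$height * tr$rel * g
        on <- int >= floor_intensity
        if (!any(on)) next
        mzv <- c(mzv, tr$mz[on]); iv <- c(iv, int[on])
      }
      if (intensity_noise_cv > 0 && length(iv))
        iv <- iv * stats::rlnorm(length(iv), -sdlog^2 / 2, sdlog)
      if (mz_noise_ppm > 0 && length(mzv))
        mzv <- mzv * (1 + stats::rnorm(length(mzv), 0, mz_noise_ppm * 1e-6))
      if (n_noise_peaks > 0) {
        mzv <- c(mzv, stats::runif(n_noise_peaks, mz_range[1], mz_range[2]))
        iv <- c(iv, stats::runif(n_noise_peaks, floor_intensity,
                                 noise_max_intensity))
      }
      if (mz_shift_ppm != 0) mzv <- mzv * (1 + mz_shift_ppm * 1e-6)
      scans[[si]] <- mass_spectrum(scan_index = si - 1L, rt = t,
                                   mz = mzv, intensity = iv,
                                   polarity = polarity)
    }
    ms_run(sample_id, scans, polarity = polarity)
  })
}
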