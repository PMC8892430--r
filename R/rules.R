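#' @title Isotopolog pattern rules
#' @description
#' A rule set describes the isotopolog pattern that is searched for, relative
#' to the principal isotopolog X (offset 0).  Satellite isotopologs are
#' addressed by a signed integer offset nu: `+nu` means nu 12C atoms are
#' exchanged for 13C relative to X (standard tracer approach), `-nu` means nu
#' 13C atoms are exchanged for 12C (reversed approach, where X is the fully
#' labelled species).  Rules are evaluated on a map offset -> intensity; the
#' identical engine runs on scan intensities and on chromatographic peak
#' areas.
#' @name rules
NULL

## exact 13C - 12C mass difference in Da; not isotope-specific code elsewhere,
## so a different tracer element only needs a different delta here.
C13_MASS_DIFF <- 1.0033548378

#' Theoretical m/z of an isotopolog satellite
#'
#' @param x_mz m/z of the principal isotopolog X, in Da.
#' @param nu signed number of 12C <-> 13C exchanges relative to X.
#' @param charge absolute charge state (>= 1).
#' @param delta_mass mass difference per exchange in Da; defaults to the
#'   exact 13C - 12C difference.
#' @return m/z of the satellite, `x_mz + nu * delta_mass / charge`.
#' @examples
#' expected_mz(300, 2)   # X+2 of a singly charged ion
#' expected_mz(300, -2)  # X-2
#' @export
expected_mz <- function(x_mz, nu, charge = 1L, delta_mass = C13_MASS_DIFF) {
  stopifnot(charge >= 1)
  x_mz + nu * delta_mass / charge
}

new_rule <- function(class, stage, fields) {
  structure(fields, class = c(class, "iso_rule"), stage = stage)
}

#' Presence rule
#'
#' The listed isotopologs must all be present.  Optionally each must exceed a
#' minimum intensity, and each may be constrained to a relative intensity
#' range against one or more anchor isotopologs (checked against every anchor
#' separately).
#'
#' @param offsets integer vector of isotopolog offsets that must be present.
#' @param min_intensity named numeric vector of minimum intensities in counts;
#'   names are offsets (e.g. `c("0" = 1e5)`).  Offsets without an entry carry
#'   no intensity floor.
#' @param relative_ranges named list; one entry per constrained offset, each a
#'   `list(anchors =, lo =, hi =)` giving anchor offsets and the allowed
#'   fractional range of this offset's intensity relative to each anchor.
#' @param verify_chrom_peak_similarity logical; if `TRUE` the offsets must
#'   later also form coeluting chromatographic peaks (enforced in the
#'   chromatographic verification stage, not by [evaluate_rules()]).
#' @return a rule object.
#' @export
presence_rule <- function(offsets, min_intensity = NULL, relative_ranges = NULL,
                          verify_chrom_peak_similarity = TRUE) {
  offsets <- as.integer(offsets)
  if (!is.null(relative_ranges)) {
    for (rr in relative_ranges) {
      stopifnot(rr$lo > 0, rr$lo < rr$hi)
    }
  }
  new_rule("presence_rule", stage = "intensity",
           list(offsets = offsets, min_intensity = min_intensity,
                relative_ranges = relative_ranges,
                verify_chrom_peak_similarity = isTRUE(verify_chrom_peak_similarity)))
}

#' Absence rule
#'
#' The listed isotopologs must not be present; signals up to
#' `max_fraction_of_x` of the intensity of X are tolerated as noise.
#'
#' @param offsets integer vector of forbidden offsets.
#' @param max_fraction_of_x tolerated intensity as a fraction of X (in [0, 1)).
#' @return a rule object.
#' @export
absence_rule <- function(offsets, max_fraction_of_x = 0.05) {
  stopifnot(max_fraction_of_x >= 0, max_fraction_of_x < 1)
  new_rule("absence_rule", stage = "absence",
           list(offsets = as.integer(offsets),
                max_fraction_of_x = max_fraction_of_x))
}

#' Ratio rule
#'
#' In `mode = "range"` the ratio of the summed intensities of the numerator
#' offsets to the summed intensities of the denominator offsets of the single
#' group must fall inside `range`.  In `mode = "equality"` the group ratios
#' must agree pairwise: `|r_i - r_j| / min(r_i, r_j) <= rel_tolerance`.
#'
#' @param groups list of `list(num =, den =)` integer offset vectors.
#' @param mode `"range"` or `"equality"`.
#' @param range numeric length 2, allowed ratio range (mode `"range"`).
#' @param rel_tolerance maximum pairwise relative deviation (mode `"equality"`).
#' @return a rule object.
#' @export
ratio_rule <- function(groups, mode = c("equality", "range"),
                       range = NULL, rel_tolerance = 0.10) {
  mode <- match.arg(mode)
  if (mode == "range") stopifnot(length(groups) == 1L, length(range) == 2L)
  if (mode == "equality") stopifnot(length(groups) >= 2L)
  new_rule("ratio_rule", stage = "ratio",
           list(groups = groups, mode = mode, range = range,
                rel_tolerance = rel_tolerance))
}

#' Intensity threshold rules
#'
#' `any_intensity_rule`: at least one of the offsets must exceed `threshold`.
#' `all_intensity_rule`: every offset must exceed `threshold`.
#'
#' @param offsets integer offsets.
#' @param threshold intensity threshold in counts (> 0).
#' @return a rule object.
#' @export
any_intensity_rule <- function(offsets, threshold) {
  stopifnot(threshold > 0)
  new_rule("any_intensity_rule", stage = "intensity",
           list(offsets = as.integer(offsets), threshold = threshold))
}

#' @rdname any_intensity_rule
#' @export
all_intensity_rule <- function(offsets, threshold) {
  stopifnot(threshold > 0)
  new_rule("all_intensity_rule", stage = "intensity",
           list(offsets = as.integer(offsets), threshold = threshold))
}

#' Assemble a rule set
#'
#' @param ... rule objects (see [presence_rule()], [absence_rule()],
#'   [ratio_rule()], [any_intensity_rule()], [all_intensity_rule()], or
#'   user-defined subclasses of `"iso_rule"`).
#' @param charge absolute charge state of the target ions.
#' @param description free-text description.
#' @return an object of class `"rule_set"`.
#' @export
rule_set <- function(..., charge = 1L, description = "") {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1]]) && !inherits(rules[[1]], "iso_rule"))
    rules <- rules[[1]]
  stopifnot(all(vapply(rules, inherits, logical(1), "iso_rule")), charge >= 1)
  structure(list(rules = rules, charge = as.integer(charge),
                 description = description),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %s (charge %d, %d rules)\n",
              x$description, x$charge, length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  - %-18s offsets: %s\n", class(r)[1],
                paste(rule_offsets(r), collapse = ", ")))
  invisible(x)
}

#' Offsets referenced by a rule
#'
#' Generic used by the screening engine to know which satellite m/z values to
#' look up.  User-defined rule subclasses must provide a method.
#'
#' @param rule a rule object.
#' @return integer vector of offsets.
#' @export
rule_offsets <- function(rule) UseMethod("rule_offsets")

#' @export
rule_offsets.presence_rule <- function(rule) {
  unique(c(rule$offsets,
           unlist(lapply(rule$relative_ranges, `[[`, "anchors"), use.names = FALSE)))
}
#' @export
rule_offsets.absence_rule <- function(rule) rule$offsets
#' @export
rule_offsets.ratio_rule <- function(rule)
  unique(unlist(lapply(rule$groups, function(g) c(g$num, g$den)), use.names = FALSE))
#' @export
rule_offsets.any_intensity_rule <- function(rule) rule$offsets
#' @export
rule_offsets.all_intensity_rule <- function(rule) rule$offsets

#' All offsets referenced anywhere in a rule set
#' @param ruleset a [rule_set()].
#' @return sorted integer vector including 0.
#' @export
ruleset_offsets <- function(ruleset) {
  sort(unique(c(0L, unlist(lapply(ruleset$rules, rule_offsets), use.names = FALSE))))
}

#' Offsets that must be present / must be absent
#' @param ruleset a [rule_set()].
#' @return sorted integer offsets.
#' @export
required_offsets <- function(ruleset) {
  off <- unlist(lapply(ruleset$rules, function(r)
    if (inherits(r, "presence_rule")) r$offsets else integer(0)), use.names = FALSE)
  sort(unique(c(0L, off)))
}

#' @rdname required_offsets
#' @export
forbidden_offsets <- function(ruleset) {
  off <- unlist(lapply(ruleset$rules, function(r)
    if (inherits(r, "absence_rule")) r$offsets else integer(0)), use.names = FALSE)
  sort(unique(off))
}

## minimum intensity required for X; used as a cheap screening prefilter
min_x_intensity <- function(ruleset) {
  m <- 0
  for (r in ruleset$rules) {
    if (inherits(r, "presence_rule") && !is.null(r$min_intensity) &&
        "0" %in% names(r$min_intensity))
      m <- max(m, r$min_intensity[["0"]])
    if (inherits(r, "all_intensity_rule") && 0L %in% r$offsets)
      m <- max(m, r$threshold)
  }
  m
}

## fetch intensity for an offset; absence offsets default to 0, others to NA
.iget <- function(intens, off, default = NA_real_) {
  v <- intens[as.character(off)]
  v <- unname(v)
  v[is.na(v)] <- default
  v
}

#' Evaluate a single rule on an offset -> intensity map
#'
#' S3 generic; user-defined rule subclasses provide methods and thereby take
#' part in [evaluate_rules()] without any change to the engine.
#'
#' @param rule a rule object.
#' @param intens named numeric vector, names are signed offsets as characters;
#'   offsets with no matched signal are absent from the vector (or `NA`).
#' @return `TRUE` if the rule holds, otherwise a character string naming the
#'   violation.
#' @export
evaluate_rule <- function(rule, intens) UseMethod("evaluate_rule")

#' @export
evaluate_rule.presence_rule <- function(rule, intens) {
  v <- .iget(intens, rule$offsets)
  if (anyNA(v) || any(v <= 0))
    return(sprintf("missing isotopolog (offset %s)",
                   paste(rule$offsets[is.na(v) | v <= 0], collapse = ",")))
  if (!is.null(rule$min_intensity)) {
    mi <- .iget(intens, names(rule$min_intensity))
    low <- mi < unname(rule$min_intensity)
    if (any(low))
      return(sprintf("intensity below minimum (offset %s)",
                     paste(names(rule$min_intensity)[low], collapse = ",")))
  }
  for (off in names(rule$relative_ranges)) {
    rr <- rule$relative_ranges[[off]]
    x <- .iget(intens, off)
    for (a in rr$anchors) {
      ref <- .iget(intens, a)
      if (is.na(ref) || ref <= 0)
        return(sprintf("missing anchor isotopolog (offset %d)", a))
      f <- x / ref
      if (is.na(f) || f < rr$lo || f > rr$hi)
        return(sprintf("offset %s outside %.0f-%.0f%% of offset %d",
                       off, 100 * rr$lo, 100 * rr$hi, a))
    }
  }
  TRUE
}

#' @export
evaluate_rule.absence_rule <- function(rule, intens) {
  x <- .iget(intens, 0L)
  if (is.na(x) || x <= 0) return("missing isotopolog (offset 0)")
  v <- .iget(intens, rule$offsets, default = 0)
  bad <- v > rule$max_fraction_of_x * x
  if (any(bad))
    return(sprintf("forbidden isotopolog present (offset %s)",
                   paste(rule$offsets[bad], collapse = ",")))
  TRUE
}

#' @export
evaluate_rule.ratio_rule <- function(rule, intens) {
  ratios <- vapply(rule$groups, function(g) {
    num <- .iget(intens, g$num); den <- .iget(intens, g$den)
    if (anyNA(num) || anyNA(den)) return(NA_real_)
    s <- sum(den)
    if (s <= 0) return(NA_real_)
    sum(num) / s
  }, numeric(1))
  if (anyNA(ratios)) return("missing isotopolog in ratio group")
  if (rule$mode == "range") {
    if (ratios[1] < rule$range[1] || ratios[1] > rule$range[2])
      return(sprintf("ratio %.3f outside [%.3f, %.3f]",
                     ratios[1], rule$range[1], rule$range[2]))
    return(TRUE)
  }
  for (i in seq_along(ratios)) for (j in seq_along(ratios)) {
    if (j <= i) next
    dev <- abs(ratios[i] - ratios[j]) / min(ratios[i], ratios[j])
    if (dev > rule$rel_tolerance)
      return(sprintf("ratio deviation %.3f exceeds %.3f (groups %d vs %d)",
                     dev, rule$rel_tolerance, i, j))
  }
  TRUE
}

#' @export
evaluate_rule.any_intensity_rule <- function(rule, intens) {
  v <- .iget(intens, rule$offsets, default = 0)
  if (any(v >= rule$threshold)) TRUE
  else sprintf("no offset of (%s) reaches %.3g counts",
               paste(rule$offsets, collapse = ","), rule$threshold)
}

#' @export
evaluate_rule.all_intensity_rule <- function(rule, intens) {
  v <- .iget(intens, rule$offsets, default = 0)
  low <- v < rule$threshold
  if (any(low))
    sprintf("offset %s below %.3g counts",
            paste(rule$offsets[low], collapse = ","), rule$threshold)
  else TRUE
}

RULE_STAGES <- c("intensity", "absence", "ratio", "other")

rule_stage <- function(rule) {
  s <- attr(rule, "stage")
  if (is.null(s) || !s %in% RULE_STAGES) "other" else s
}

#' Evaluate a rule set on an offset -> intensity map
#'
#' Rules are evaluated in order; the verdict is a pass only if every rule
#' holds.  The function is pure and works identically on scan intensities and
#' on chromatographic peak areas.  For the stepwise-attrition readout the
#' outcome of each rule *stage* (intensity, absence, ratio) is reported
#' separately: `stages_passed[s]` is `TRUE` when all rules of stage `s` hold.
#'
#' @param ruleset a [rule_set()].
#' @param intensities named numeric vector (names are signed offsets) or a
#'   list coercible to one; must contain an entry for offset 0.
#' @return `list(pass, failed_rule, reason, stages_passed)`; `failed_rule` is
#'   the index of the first violated rule (or `NA`).
#' @examples
#' rs <- standard_tracer_ruleset()
#' evaluate_rules(rs, c("0" = 1e6, "1" = 2e5, "2" = 5e5, "3" = 1e5, "4" = 2.5e5))
#' @export
evaluate_rules <- function(ruleset, intensities) {
  intens <- unlist(intensities)
  if (!"0" %in% names(intens))
    stop("intensity map must contain an entry for offset 0 (X)")
  stages <- vapply(ruleset$rules, rule_stage, character(1))
  ok <- logical(length(ruleset$rules))
  reason <- NA_character_; failed <- NA_integer_
  for (i in seq_along(ruleset$rules)) {
    res <- evaluate_rule(ruleset$rules[[i]], intens)
    ok[i] <- isTRUE(res)
    if (!ok[i] && is.na(failed)) { failed <- i; reason <- as.character(res) }
  }
  sp <- vapply(RULE_STAGES, function(s) all(ok[stages == s]), logical(1))
  list(pass = all(ok), failed_rule = failed, reason = reason,
       stages_passed = sp)
}

#' Built-in rule set for the standard tracer approach
#'
#' Detects isotopolog patterns of native (all-12C) metabolite ions that have
#' incorporated one or more fully 13C-labelled C2 extension units.  The
#' default encodes: X at >= 1e5 counts; X+2 and X+4 present at >= 5e4 counts,
#' within 10-300 % of X and X+2 respectively; X+1 and X+3 present within
#' 10-200 % of each of their two even-numbered neighbours; X-1 and X-2 absent
#' (<= 5 % of X tolerated); and the satellite-ratio constancy check
#' (X + X+2)/X+1 = (X+2 + X+4)/X+3 within a relative tolerance of 10 %.
#' Coelution of X..X+4 as chromatographic peaks (Pearson r >= 0.85) is
#' enforced during chromatographic verification.
#'
#' @param min_x minimum intensity of X in counts.
#' @param min_satellite minimum intensity of the even satellites in counts.
#' @param absence_max tolerated forbidden-offset intensity as fraction of X.
#' @param even_range allowed range of each even satellite relative to the
#'   previous even isotopolog.
#' @param odd_range allowed range of each odd satellite relative to each of
#'   its two even neighbours.
#' @param equality_tol maximum relative deviation of the paired sum ratios.
#' @param charge absolute charge state.
#' @return a [rule_set()].
#' @export
standard_tracer_ruleset <- function(min_x = 1e5, min_satellite = 5e4,
                                    absence_max = 0.05,
                                    even_range = c(0.1, 3.0),
                                    odd_range = c(0.1, 2.0),
                                    equality_tol = 0.10, charge = 1L) {
  rule_set(
    presence_rule(
      offsets = 0:4,
      min_intensity = c("0" = min_x, "2" = min_satellite, "4" = min_satellite),
      relative_ranges = list(
        "2" = list(anchors = 0L, lo = even_range[1], hi = even_range[2]),
        "4" = list(anchors = 2L, lo = even_range[1], hi = even_range[2]),
        "1" = list(anchors = c(0L, 2L), lo = odd_range[1], hi = odd_range[2]),
        "3" = list(anchors = c(2L, 4L), lo = odd_range[1], hi = odd_range[2])),
      verify_chrom_peak_similarity = TRUE),
    absence_rule(c(-1L, -2L), max_fraction_of_x = absence_max),
    ratio_rule(groups = list(list(num = c(0L, 2L), den = 1L),
                             list(num = c(2L, 4L), den = 3L)),
               mode = "equality", rel_tolerance = equality_tol),
    charge = charge,
    description = "standard tracer approach (13C tracer, native background)")
}

#' Built-in rule set for the reversed tracer approach
#'
#' Mirror image of [standard_tracer_ruleset()], extended to three extension
#' units: X is the uniformly 13C-labelled ion; required satellites are X-1 ..
#' X-6, forbidden ones X+1 and X+2, and three paired sum ratios
#' (X + X-2)/X-1, (X-2 + X-4)/X-3 and (X-4 + X-6)/X-5 must agree within the
#' relative tolerance.
#'
#' @inheritParams standard_tracer_ruleset
#' @return a [rule_set()].
#' @export
reversed_tracer_ruleset <- function(min_x = 1e5, min_satellite = 5e4,
                                    absence_max = 0.05,
                                    even_range = c(0.1, 3.0),
                                    odd_range = c(0.1, 2.0),
                                    equality_tol = 0.10, charge = 1L) {
  rule_set(
    presence_rule(
      offsets = -(0:6),
      min_intensity = c("0" = min_x, "-2" = min_satellite,
                        "-4" = min_satellite, "-6" = min_satellite),
      relative_ranges = list(
        "-2" = list(anchors = 0L,  lo = even_range[1], hi = even_range[2]),
        "-4" = list(anchors = -2L, lo = even_range[1], hi = even_range[2]),
        "-6" = list(anchors = -4L, lo = even_range[1], hi = even_range[2]),
        "-1" = list(anchors = c(0L, -2L),  lo = odd_range[1], hi = odd_range[2]),
        "-3" = list(anchors = c(-2L, -4L), lo = odd_range[1], hi = odd_range[2]),
        "-5" = list(anchors = c(-4L, -6L), lo = odd_range[1], hi = odd_range[2])),
      verify_chrom_peak_similarity = TRUE),
    absence_rule(c(1L, 2L), max_fraction_of_x = absence_max),
    ratio_rule(groups = list(list(num = c(0L, -2L), den = -1L),
                             list(num = c(-2L, -4L), den = -3L),
                             list(num = c(-4L, -6L), den = -5L)),
               mode = "equality", rel_tolerance = equality_tol),
    charge = charge,
    description = "reversed tracer approach (native tracer, 13C background)")
}

#' Read a rule set from a YAML or JSON configuration file
#'
#' The configuration has keys `charge`, optional `description`, and `rules`,
#' a list of entries with `type` in `presence`, `absence`, `ratio_range`,
#' `ratio_equality`, `any_intensity`, `all_intensity`.  Offsets are signed
#' integers, thresholds counts, fractions decimals.
#'
#' @param path file path (`.yml`/`.yaml`/`.json`).
#' @return a [rule_set()].
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("rule-set config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$rules)) stop("rule-set config has no 'rules' key: ", path)
  rules <- lapply(cfg$rules, function(r) {
    switch(as.character(r$type),
      presence = {
        mi <- if (!is.null(r$min_intensity)) unlist(r$min_intensity)
        rr <- if (!is.null(r$relative_ranges))
          lapply(r$relative_ranges, function(x)
            list(anchors = as.integer(unlist(x$anchors)),
                 lo = x$lo, hi = x$hi))
        presence_rule(unlist(r$offsets), min_intensity = mi, relative_ranges = rr,
                      verify_chrom_peak_similarity =
                        !isFALSE(r$verify_chrom_peak_similarity))
      },
      absence = absence_rule(unlist(r$offsets),
                             max_fraction_of_x = r$max_fraction_of_x %||% 0.05),
      ratio_range = ratio_rule(
        groups = list(list(num = as.integer(unlist(r$num)),
                           den = as.integer(unlist(r$den)))),
        mode = "range", range = unlist(r$range)),
      ratio_equality = ratio_rule(
        groups = lapply(r$groups, function(g)
          list(num = as.integer(unlist(g$num)), den = as.integer(unlist(g$den)))),
        mode = "equality", rel_tolerance = r$rel_tolerance %||% 0.10),
      any_intensity = any_intensity_rule(unlist(r$offsets), r$threshold),
      all_intensity = all_intensity_rule(unlist(r$offsets), r$threshold),
      stop("unknown rule type: ", r$type))
  })
  rule_set(rules, charge = cfg$charge %||% 1L,
           description = cfg$description %||% basename(path))
}

#' Validate a rule-set configuration file
#'
#' Parses the file and reports structural problems without running a search.
#'
#' @param path config file path.
#' @return invisibly, the parsed [rule_set()]; errors describe the problem.
#' @export
lint_ruleset <- function(path) {
  rs <- read_ruleset(path)
  off <- ruleset_offsets(rs)
  if (!0L %in% off) stop("rule set never references offset 0 (X)")
  both <- intersect(required_offsets(rs), forbidden_offsets(rs))
  if (length(both))
    stop("offsets both required and forbidden: ", paste(both, collapse = ", "))
  message(sprintf("OK: %d rules, charge %d, offsets %s",
                  length(rs$rules), rs$charge, paste(off, collapse = ", ")))
  invisible(rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
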