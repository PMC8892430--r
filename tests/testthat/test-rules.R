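test_that("expected_mz places satellites at multiples of the 13C-12C mass difference", {
  expect_identical(expected_mz(300, 0, 1), 300)
  expect_equal(expected_mz(300, 2, 1), 302.0067096756)
  expect_equal(expected_mz(300, -2, 1), 297.9932903244)
  # doubly charged ions move by half the spacing
  expect_equal(expected_mz(300, 2, 2), 300 + 1.0033548378)
})

test_that("built-in standard rule set encodes the published constants", {
  rs <- standard_tracer_ruleset()
  expect_identical(required_offsets(rs), 0:4)
  expect_identical(forbidden_offsets(rs), c(-2L, -1L))
  pres <- rs$rules[[1]]
  expect_equal(pres$min_intensity[["0"]], 1e5)
  expect_equal(pres$min_intensity[["2"]], 5e4)
  expect_equal(pres$min_intensity[["4"]], 5e4)
  expect_equal(pres$relative_ranges[["2"]], list(anchors = 0L, lo = 0.1, hi = 3))
  expect_equal(pres$relative_ranges[["1"]]$anchors, c(0L, 2L))
  expect_equal(pres$relative_ranges[["1"]]$hi, 2)
  expect_equal(rs$rules[[2]]$max_fraction_of_x, 0.05)
  rat <- rs$rules[[3]]
  expect_identical(rat$mode, "equality")
  expect_equal(rat$rel_tolerance, 0.10)
  expect_length(rat$groups, 2L)
})

test_that("built-in reversed rule set mirrors and extends to three units", {
  rs <- reversed_tracer_ruleset()
  expect_identical(required_offsets(rs), c(-6:0))
  expect_length(required_offsets(rs), 7L)
  expect_identical(forbidden_offsets(rs), c(1L, 2L))
  pres <- rs$rules[[1]]
  expect_equal(pres$min_intensity[["0"]], 1e5)
  expect_equal(unname(pres$min_intensity[c("-2", "-4", "-6")]), rep(5e4, 3))
  expect_length(rs$rules[[3]]$groups, 3L)
})

test_that("rule evaluation reproduces hand-computed verdicts", {
  rs <- standard_tracer_ruleset()
  good <- c("0" = 1e6, "1" = 2e5, "2" = 5e5, "3" = 1e5, "4" = 2.5e5,
            "-1" = 0, "-2" = 0)
  expect_true(evaluate_rules(rs, good)$pass)      # both paired ratios 7.5

  bad_abs <- good; bad_abs[["-1"]] <- 6e4         # 6 % of X > 5 % tolerance
  v <- evaluate_rules(rs, bad_abs)
  expect_false(v$pass)
  expect_match(v$reason, "forbidden")
  expect_true(v$stages_passed[["intensity"]])
  expect_false(v$stages_passed[["absence"]])

  bad_ratio <- good; bad_ratio[["3"]] <- 3e5      # 7.5 vs 2.5: deviation 2
  v <- evaluate_rules(rs, bad_ratio)
  expect_false(v$pass)
  expect_true(v$stages_passed[["absence"]])
  expect_false(v$stages_passed[["ratio"]])

  missing <- good[names(good) != "3"]
  v <- evaluate_rules(rs, missing)
  expect_false(v$pass)
  expect_match(v$reason, "missing isotopolog")
})

test_that("verdicts are invariant under intensity-map permutation", {
  rs <- standard_tracer_ruleset()
  set.seed(11)
  for (i in 1:20) {
    v <- c("0" = 10^runif(1, 5, 6.5), "1" = 10^runif(1, 4, 6),
           "2" = 10^runif(1, 4.8, 6.3), "3" = 10^runif(1, 4, 6),
           "4" = 10^runif(1, 4.8, 6.3), "-1" = 10^runif(1, 2, 5))
    ref <- evaluate_rules(rs, v)
    perm <- evaluate_rules(rs, sample(v))
    expect_identical(perm$pass, ref$pass)
    expect_identical(perm$failed_rule, ref$failed_rule)
  }
})

test_that("a mirrored intensity vector passes the reversed set", {
  # a standard-compliant pattern, offset-negated and extended consistently by
  # a third unit (X-5, X-6 keeping the same paired ratio), passes the
  # reversed set
  std <- standard_tracer_ruleset(); rev <- reversed_tracer_ruleset()
  v <- c("0" = 1e6, "1" = 2e5, "2" = 5e5, "3" = 1e5, "4" = 2.5e5)
  expect_true(evaluate_rules(std, v)$pass)
  m <- stats::setNames(v, as.character(-(0:4)))
  m[["-6"]] <- 1.25e5                       # X-6 / X-4 = 50 % as before
  m[["-5"]] <- (m[["-4"]] + m[["-6"]]) / 7.5
  expect_true(evaluate_rules(rev, m)$pass)
  # breaking the appended pair breaks only the reversed set
  m2 <- m; m2[["-5"]] <- m2[["-5"]] * 2
  expect_false(evaluate_rules(rev, m2)$pass)
})

test_that("user-defined rule subtypes participate in evaluation", {
  # a parity rule: X+2 must exceed X+1 (no engine change required)
  parity_rule <- function() {
    structure(list(), class = c("parity_rule", "iso_rule"), stage = "other")
  }
  registerS3method("evaluate_rule", "parity_rule",
                   function(rule, intens) {
                     if (intens[["2"]] > intens[["1"]]) TRUE
                     else "X+2 not above X+1"
                   }, envir = globalenv())
  registerS3method("rule_offsets", "parity_rule",
                   function(rule) c(1L, 2L), envir = globalenv())
  rs <- rule_set(any_intensity_rule(0L, 1e3), parity_rule())
  expect_true(evaluate_rules(rs, c("0" = 1e4, "1" = 1, "2" = 2))$pass)
  v <- evaluate_rules(rs, c("0" = 1e4, "1" = 2, "2" = 1))
  expect_false(v$pass)
  expect_match(v$reason, "X\\+2 not above")
  expect_true(2L %in% ruleset_offsets(rs))
})

test_that("rule sets round-trip through a YAML config", {
  cfg <- list(
    charge = 1L, description = "test",
    rules = list(
      list(type = "presence", offsets = 0:2,
           min_intensity = list("0" = 1e5),
           relative_ranges = list("2" = list(anchors = 0L, lo = 0.1, hi = 3))),
      list(type = "absence", offsets = -1L, max_fraction_of_x = 0.05),
      list(type = "ratio_equality",
           groups = list(list(num = 0L, den = 1L),
                         list(num = 2L, den = 1L)),
           rel_tolerance = 0.2),
      list(type = "any_intensity", offsets = 0L, threshold = 5e4)))
  f <- tempfile(fileext = ".yml")
  yaml::write_yaml(cfg, f)
  rs <- read_ruleset(f)
  expect_length(rs$rules, 4L)
  expect_identical(required_offsets(rs), 0:2)
  expect_identical(forbidden_offsets(rs), -1L)
  v <- c("0" = 1e6, "1" = 4e5, "2" = 1e6)   # both group ratios 2.5
  expect_true(evaluate_rules(rs, v)$pass)
  expect_false(evaluate_rules(rs, c("0" = 1e6, "1" = 4e5, "2" = 4e6))$pass)
  expect_silent(suppressMessages(lint_ruleset(f)))
})
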