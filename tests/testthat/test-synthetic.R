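test_that("degenerate incorporation models collapse to single lines", {
  m0 <- incorporation_model(2, q = 0, tracer_purity = 1, nat_13c = 0,
                            n_carbons = 4)
  p0 <- theoretical_pattern(m0)
  expect_identical(names(p0), "0")
  expect_equal(unname(p0), 1, ignore_attr = TRUE)

  m1 <- incorporation_model(2, q = 1, tracer_purity = 1, nat_13c = 0,
                            n_carbons = 4)
  p1 <- theoretical_pattern(m1)
  expect_identical(names(p1), "4")   # forced full labelling: all at X+4
  expect_equal(unname(p1), 1, ignore_attr = TRUE)
})

test_that("patterns are proper probability distributions", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    m <- incorporation_model(n, runif(1, 0.02, 0.5),
                             n_carbons = 2 * n + sample(0:4, 1),
                             direction = sample(c("standard", "reversed"), 1))
    for (v in c("first_order", "exact"))
      expect_equal(sum(attr(theoretical_pattern(m, variant = v), "mass")), 1,
                   tolerance = 1e-12)
  }
})

test_that("low-incorporation patterns form a staircase with diagnostic satellites", {
  # at nq/(1-q) < 1 the even-offset intensities strictly decrease and every
  # odd satellite lies below the mean of its even neighbours
  m <- incorporation_model(4, q = 0.15, n_carbons = 8)
  p <- theoretical_pattern(m, min_rel = 0)
  even <- p[as.character(seq(0, 8, 2))]
  expect_true(all(diff(even) < 0))
  for (k in 0:3) {
    odd <- p[[as.character(2 * k + 1)]]
    expect_lt(odd, (p[[as.character(2 * k)]] + p[[as.character(2 * k + 2)]]) / 2)
  }
})

test_that("paired sum ratios are constant in the first-order model", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:14, 1)
    m <- incorporation_model(n, runif(1, 0.03, 0.3),
                             tracer_purity = runif(1, 0.95, 0.999),
                             nat_13c = 0.0107,
                             n_carbons = 2 * n + sample(0:6, 1))
    p <- theoretical_pattern(m, min_rel = 0)
    r1 <- (p[["0"]] + p[["2"]]) / p[["1"]]
    r2 <- (p[["2"]] + p[["4"]]) / p[["3"]]
    expect_lt(abs(r1 - r2) / min(r1, r2), 1e-9)
  }
})

test_that("the exact enumeration only approximates ratio constancy", {
  # the full carbon-level model drifts because the binomial staircase is not
  # geometric; this documents why the first-order variant is the default
  m <- incorporation_model(9, q = 0.1, n_carbons = 18)
  p <- theoretical_pattern(m, variant = "exact", min_rel = 0)
  r1 <- (p[["0"]] + p[["2"]]) / p[["1"]]
  r2 <- (p[["2"]] + p[["4"]]) / p[["3"]]
  expect_gt(abs(r1 - r2) / min(r1, r2), 0.05)
})

test_that("reversed patterns mirror standard patterns for mirrored parameters", {
  set.seed(44)
  for (v in c("first_order", "exact")) {
    for (i in 1:10) {
      n <- sample(4:10, 1); nc <- 2 * n + sample(0:4, 1)
      q <- runif(1, 0.03, 0.3); p <- runif(1, 0.95, 0.999)
      a <- runif(1, 0.005, 0.02)
      std <- theoretical_pattern(incorporation_model(
        n, q, tracer_purity = p, nat_13c = a, n_carbons = nc,
        direction = "standard"), variant = v, min_rel = 0)
      rev <- theoretical_pattern(incorporation_model(
        n, q, tracer_purity = p, n_carbons = nc, direction = "reversed",
        label_purity = 1 - a), variant = v, min_rel = 0)
      expect_identical(as.integer(names(rev)), -as.integer(names(std)))
      expect_lt(max(abs(unname(rev) - unname(std))), 1e-12)
    }
  }
})

test_that("extension-unit counts derive from the carbon count", {
  expect_identical(max_extension_units("C30H18O12"), 15L)
  expect_identical(max_extension_units("C2H4O2"), 1L)
  expect_identical(max_extension_units("C8H16O2"), 4L)
  expect_identical(max_extension_units("CH3COOC2H5"), 2L)  # repeated elements
  expect_error(max_extension_units("H2O"), "carbons")
  expect_error(max_extension_units(""), "malformed")
  expect_error(max_extension_units("c30"), "carbons|malformed")
})

test_that("run generation is deterministic given the seed", {
  truth <- make_synthetic_truth(2, 2, "standard", seed = 9)
  r1 <- generate_run(truth, intensity_noise_cv = 0.05, mz_noise_ppm = 1,
                     n_noise_peaks = 10)
  r2 <- generate_run(truth, intensity_noise_cv = 0.05, mz_noise_ppm = 1,
                     n_noise_peaks = 10)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_mzxml(r1, f1); write_mzxml(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and the truth itself is reproducible from its seed
  truth2 <- make_synthetic_truth(2, 2, "standard", seed = 9)
  expect_identical(truth_table(truth), truth_table(truth2))
})

test_that("an empty truth yields a run of empty scans", {
  truth <- structure(list(compounds = list(), seed = 1L),
                     class = "synthetic_truth")
  run <- generate_run(truth, rt_range = c(0, 10), scan_interval = 1)
  expect_identical(length(run$scans), 11L)
  expect_true(all(vapply(run$scans, function(s) length(s$mz) == 0L, logical(1))))
})

test_that("compliant compounds pass and decoys violate the scan-level rules", {
  for (dir in c("standard", "reversed")) {
    rs <- if (dir == "standard") standard_tracer_ruleset()
          else reversed_tracer_ruleset()
    truth <- make_synthetic_truth(5, 4, dir, seed = 13)
    for (cpd in truth$compounds) {
      tr <- tracerscreen:::compound_traces(cpd)
      intens <- stats::setNames(cpd$height * tr$rel, tr$offset)
      verdict <- evaluate_rules(rs, intens)
      if (is.null(cpd$decoy)) expect_true(verdict$pass)
      else if (cpd$decoy != "shifted_satellite")
        # shifted satellites still pass at the apex scan and are only caught
        # in the chromatographic domain
        expect_false(verdict$pass)
    }
  }
})
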