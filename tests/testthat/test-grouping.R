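# construct a minimal verified feature without running the pipeline
fake_feature <- function(mz, rt, area = 1e6, sid = "s1") {
  structure(list(x_mz = mz, apex_rt = rt, rt_bounds = c(rt - 8, rt + 8),
                 peaks = list(), areas = c("0" = area),
                 coelution_r = 1, sample_id = sid),
            class = "ts_feature")
}

test_that("jittered features of one compound bracket into one row", {
  fbs <- list(
    s1 = list(fake_feature(500.0000, 100.0, sid = "s1")),
    s2 = list(fake_feature(500.0000 * (1 + 2e-6), 102.0, sid = "s2")),
    s3 = list(fake_feature(500.0000 * (1 - 2e-6), 98.0, sid = "s3")))
  br <- bracket(fbs, rt_tol = 6, mz_ppm = 5)
  expect_length(br, 1L)
  expect_length(br[[1]]$per_sample, 3L)
  expect_equal(br[[1]]$consensus_rt, 100, tolerance = 1e-9)
})

test_that("features separated by 0.2 min stay in separate brackets", {
  fbs <- list(s1 = list(fake_feature(500, 100, sid = "s1")),
              s2 = list(fake_feature(500, 112, sid = "s2")))
  br <- bracket(fbs, rt_tol = 6, mz_ppm = 5)  # 0.1 min tolerance
  expect_length(br, 2L)
})

test_that("a single sample brackets into its own features", {
  fbs <- list(s1 = list(fake_feature(400, 50), fake_feature(600, 150)))
  br <- bracket(fbs, 6, 5)
  expect_length(br, 2L)
  expect_setequal(vapply(br, `[[`, numeric(1), "consensus_mz"), c(400, 600))
})

test_that("no bracket holds two features of one sample; bracketing is idempotent", {
  set.seed(3)
  fbs <- list(
    s1 = lapply(1:6, function(i) fake_feature(300 + 10 * i, 30 * i, sid = "s1")),
    s2 = lapply(1:6, function(i) fake_feature((300 + 10 * i) * (1 + 3e-6),
                                              30 * i + 2, sid = "s2")))
  br <- bracket(fbs, 6, 5)
  for (b in br)
    expect_identical(anyDuplicated(names(b$per_sample)), 0L)
  # re-bracketing the consensus features changes nothing
  fbs2 <- list(cons = lapply(br, function(b)
    fake_feature(b$consensus_mz, b$consensus_rt, sid = "cons")))
  br2 <- bracket(fbs2, 6, 5)
  expect_identical(length(br2), length(br))
  expect_equal(sort(vapply(br2, `[[`, numeric(1), "consensus_mz")),
               sort(vapply(br, `[[`, numeric(1), "consensus_mz")))
})

test_that("convolution groups co-eluting correlated ions and splits the rest", {
  # one compound plus a co-eluting companion ion (adduct-like), another
  # compound 100 s away
  model <- incorporation_model(9, 0.1, n_carbons = 18)
  truth <- structure(list(compounds = list(
    planted_compound(500, 100, 4, 2e6, model),
    planted_compound(522, 100, 4, 1e6, model),    # companion, same elution
    planted_compound(700, 200, 4, 2e6, model)),
    seed = 4L), class = "synthetic_truth")
  run <- generate_run(truth, rt_range = c(60, 240))
  fbs <- list(syn = list(fake_feature(500, 100, sid = "syn"),
                         fake_feature(522, 100, sid = "syn"),
                         fake_feature(700, 200, sid = "syn")))
  br <- bracket(fbs, 6, 5)
  gr <- convolute(br, list(syn = run), r_min = 0.85, rt_tol = 6)
  sizes <- sort(vapply(gr, function(g) length(g$members), integer(1)))
  expect_identical(sizes, c(1L, 2L))
  # a trace with no signal at the same rt: zero variance -> NA -> no link
  fbs3 <- list(syn = list(fake_feature(500, 100, sid = "syn"),
                          fake_feature(640, 100, sid = "syn")))
  gr3 <- convolute(bracket(fbs3, 6, 5), list(syn = run), 0.85, 6)
  expect_length(gr3, 2L)
})

test_that("reintegration fills undetected samples and never alters detected ones", {
  model <- incorporation_model(9, 0.1, n_carbons = 18)
  truth_a <- structure(list(compounds = list(
    planted_compound(500, 100, 4, 2e6, model)), seed = 6L),
    class = "synthetic_truth")
  run_a <- generate_run(truth_a, rt_range = c(60, 140), sample_id = "A")
  blank <- generate_run(structure(list(compounds = list(), seed = 7L),
                                  class = "synthetic_truth"),
                        rt_range = c(60, 140), sample_id = "B")
  f <- fake_feature(500, 100, area = 123, sid = "A")
  br <- bracket(list(A = list(f)), 6, 5)[[1]]
  out <- reintegrate(br, list(A = run_a, B = blank), offsets = 0:2)
  expect_identical(out$per_sample$A$flag, "detected")
  expect_identical(out$per_sample$A$areas, c("0" = 123))   # untouched
  expect_identical(out$per_sample$B$flag, "reintegrated")
  expect_equal(unname(out$per_sample$B$areas[["0"]]), 0)   # blank: nothing
  # a compound present but undetected in B reintegrates to the planted area
  run_b2 <- generate_run(truth_a, rt_range = c(60, 140), sample_id = "B")
  out2 <- reintegrate(br, list(A = run_a, B = run_b2), offsets = 0L)
  analytic <- 2e6 * 4 * sqrt(2 * pi)
  expect_lt(abs(out2$per_sample$B$areas[["0"]] - analytic) / analytic, 0.10)
  # missing run
  out3 <- reintegrate(br, list(A = run_a, C = NULL), offsets = 0L)
  expect_identical(out3$per_sample$C$flag, "missing")
})

test_that("the results TSV is stable, parseable and round-trips", {
  f <- tempfile(fileext = ".tsv")
  # empty result: header-only file
  df0 <- write_results_tsv(list(), f, offsets = 0:2, sample_ids = c("a", "b"))
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_match(lines, "^group_id\tfeature_id\tmz\trt_min\tcharge\ta_area_X\t")

  br <- bracket(list(a = list(fake_feature(500, 120, 1e6, "a")),
                     b = list(fake_feature(500, 121, 2e6, "b"))), 6, 5)
  groups <- list(list(group_id = 1L, members = br, annotations = ""))
  df <- write_results_tsv(groups, f, offsets = 0L, sample_ids = c("a", "b"))
  expect_identical(nrow(df), 1L)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_identical(dim(back), dim(df))
  expect_identical(names(back), names(df))
  expect_equal(back$mz, df$mz)
  expect_equal(back$a_area_X, df$a_area_X)
  expect_identical(back$b_flag, df$b_flag)
  expect_equal(back$rt_min, round(120.5 / 60, 4))
})
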