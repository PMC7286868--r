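test_that("sampling series validation rejects malformed input", {
  expect_error(sampling_series("glucose", c(0, 10, 10), c(5, 5, 5), "mmol/l"),
               "non-monotone")
  expect_error(sampling_series("glucose", c(0, 10), c(5, -1), "mmol/l"),
               "negative")
  expect_error(tracer_series("D2", c(0, 10), c(0.01, 0.3)), "0.2")
  s <- sampling_series("glucose", c(-20, 0, 10), c(5, 5.2, 6), "mmol/l")
  expect_equal(basal_value(s), 5.1)
})

test_that("low basal enrichment raises the tracer quality flag", {
  t <- c(-30, -20, -10, 0, 10)
  expect_true(tracer_series("D2", t, rep(0.005, 5))$low_enrichment)
  expect_false(tracer_series("D2", t, rep(0.02, 5))$low_enrichment)
})

test_that("trapezoidal AUC matches closed forms", {
  const <- sampling_series("x", seq(0, 100, 10), rep(5, 11), "mmol/l")
  expect_equal(auc(const, c(0, 100)), 500)
  # incremental AUC of a constant at its own basal is zero
  basal <- sampling_series("x", c(-10, seq(0, 100, 10)), rep(5, 12), "mmol/l")
  expect_equal(auc(basal, c(0, 100), incremental = TRUE), 0)
  tri <- sampling_series("x", c(0, 10, 20), c(0, 10, 0), "mmol/l")
  expect_equal(auc(tri, c(0, 20)), 100)
  # endpoint interpolation: half the triangle
  expect_equal(auc(tri, c(5, 10)), 0.5 * 5 * (5 + 10))
  expect_error(auc(tri, c(10, 10)), "empty")
})

test_that("AUC is additive over adjacent windows", {
  set.seed(42)
  s <- sampling_series("x", seq(0, 360, 10),
                       5 + cumsum(rnorm(37, 0, 0.2))^2, "mmol/l")
  for (split in c(55, 120, 200.5)) {
    expect_equal(auc(s, c(0, split)) + auc(s, c(split, 360)),
                 auc(s, c(0, 360)), tolerance = 1e-9)
  }
})

test_that("interpolating spline reproduces lines and passes through points", {
  t <- seq(0, 360, 10)
  line <- sampling_series("glucose", t, 4 + 0.01 * t, "mmol/l")
  sm <- smooth_and_differentiate(line, lambda = 0)
  expect_equal(sm$deriv, rep(0.01, length(sm$times)), tolerance = 1e-10)
  const <- sampling_series("glucose", t, rep(5, length(t)), "mmol/l")
  smc <- smooth_and_differentiate(const, lambda = 0)
  expect_equal(max(abs(smc$deriv)), 0, tolerance = 1e-12)
  set.seed(7)
  vals <- 5 + abs(rnorm(length(t)))
  noisy <- sampling_series("glucose", t, vals, "mmol/l")
  smn <- smooth_and_differentiate(noisy, lambda = 0)
  expect_equal(smn$fun(t), vals, tolerance = 1e-8)
  expect_error(smooth_and_differentiate(
    sampling_series("glucose", c(0, 10, 20, 30), 1:4, "mmol/l"), 0),
    "at least 5")
})

test_that("spline derivative of a sine tracks the analytic derivative", {
  # period 360 min: the curve's second derivative vanishes at both ends,
  # matching the natural spline's end conditions
  t <- seq(0, 360, 10)
  omega <- 2 * pi / 360
  s <- sampling_series("x", t, 5 + sin(omega * t), "mmol/l")
  sm <- smooth_and_differentiate(s, lambda = 0)
  err <- max(abs(sm$deriv - omega * cos(omega * sm$times)))
  expect_lt(err, 0.02 * omega)
})

test_that("session round trip through CSV + YAML is lossless", {
  o <- cached_oral_session()
  p1 <- file.path(tempdir(), "s1.csv")
  p2 <- file.path(tempdir(), "s2.csv")
  write_session(o$session, p1)
  r1 <- read_session(p1)
  write_session(r1, p2)
  r2 <- read_session(p2)
  expect_equal(r1, r2)
  expect_equal(r1$glucose$values, o$session$glucose$values)
  expect_equal(r1$tracers$C13$ttr, o$session$tracers$C13$ttr)
  expect_equal(r1$subject$weight, o$session$subject$weight)
  expect_identical(length(r1$glucose$times[r1$glucose$times >= 0]), 37L)
})

test_that("session reader rejects corrupt files with clear errors", {
  o <- cached_oral_session()
  p <- file.path(tempdir(), "bad.csv")
  write_session(o$session, p)
  df <- utils::read.csv(p, stringsAsFactors = FALSE)
  dup <- df[df$analyte == "glucose", ][5, ]
  df2 <- rbind(df, dup)
  df2 <- df2[order(match(df2$analyte, unique(df2$analyte))), ]
  utils::write.csv(df2, p, row.names = FALSE, quote = FALSE)
  expect_error(read_session(p), "non-monotone")
})

test_that("unit mismatches are hard errors naming the analyte", {
  o <- cached_oral_session()
  s <- o$session
  bad <- s$insulin; bad$unit <- "mU/l"
  expect_error(
    session_record(s$subject, s$route, s$glucose, bad, s$cpeptide, s$glp1,
                   s$glucagon, s$metabolites, s$tracers, s$infusions),
    "unit mismatch for insulin")
})

test_that("route invariants of the session record are enforced", {
  o <- cached_oral_session()
  s <- o$session
  no_c13 <- s$tracers["D2"]
  expect_error(
    session_record(s$subject, "oral", s$glucose, s$insulin, s$cpeptide,
                   s$glp1, s$glucagon, s$metabolites, no_c13, s$infusions),
    "C13")
  iv_inf <- infusion_schedule(oral_loads = NULL,
                              dextrose_rates = data.frame(time = 0, rate = 10))
  expect_error(
    session_record(s$subject, "igivi", s$glucose, s$insulin, s$cpeptide,
                   s$glp1, s$glucagon, s$metabolites, s$tracers, iv_inf),
    "oral tracer")
})

test_that("infusion schedule demands exactly one glucose route", {
  expect_error(infusion_schedule(oral_loads = NULL, dextrose_rates = NULL),
               "exactly one")
  expect_error(infusion_schedule(
    oral_loads = default_oral_loads(),
    dextrose_rates = data.frame(time = 0, rate = 1)), "exactly one")
})

test_that("cumulative dextrose integrates the piecewise-constant schedule", {
  inf <- infusion_schedule(oral_loads = NULL,
    dextrose_rates = data.frame(time = c(0, 10, 20), rate = c(1, 3, 0)))
  expect_equal(cumulative_dextrose(inf, c(-5, 0, 5, 10, 15, 20, 40)),
               c(0, 0, 5, 10, 25, 40, 40))
  expect_equal(dextrose_rate_at(inf, c(-1, 5, 12, 25)), c(0, 1, 3, 0))
})
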