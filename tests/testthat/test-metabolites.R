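test_that("exponential decay fit is exact on exact data", {
  t <- seq(0, 360, 20)
  s <- sampling_series("lactate", c(-20, t), c(2, 2 * exp(-0.001 * t)),
                       "mmol/l")
  fit <- fit_decay(s)
  expect_equal(fit$beta, 0.001, tolerance = 1e-8)
  expect_equal(fit$c0, 2, tolerance = 1e-8)
  expect_lt(rmse(fit$fitted, fit$observed), 1e-10)
})

test_that("a constant series fits beta = 0 within its standard error", {
  s <- sampling_series("lactate", c(-20, seq(0, 360, 20)), rep(1.5, 20),
                       "mmol/l")
  fit <- suppressWarnings(fit_decay(s))
  expect_lt(abs(fit$beta), max(fit$se, 1e-10) + 1e-10)
})

test_that("nls decay slope agrees with log-linear regression on exact data", {
  t <- seq(0, 360, 20)
  s <- sampling_series("aa", c(-20, t), c(1, exp(-0.0014 * t)), "mmol/l")
  fit <- fit_decay(s)
  ll <- stats::lm(log(exp(-0.0014 * t)) ~ t)
  expect_equal(fit$beta, -stats::coef(ll)[[2]], tolerance = 1e-8)
})

test_that("decay recovery under multiplicative noise is nearly unbiased", {
  # 8% noise on a true coefficient of 0.0014 1/min, many replicates
  t <- seq(0, 360, 20)
  set.seed(11)
  betas <- replicate(200, {
    v <- pmax(1.2 * exp(-0.0014 * t) * (1 + rnorm(length(t), 0, 0.08)),
              1e-4)
    fit_decay(sampling_series("lactate", t, v, "mmol/l"),
              window = c(0, 360))$beta
  })
  expect_lt(abs(stats::median(betas) - 0.0014) / 0.0014, 0.10)
})

test_that("insulin normalisation divides by mean insulin", {
  t <- seq(0, 360, 20)
  s <- sampling_series("lactate", c(-20, t), c(2, 2 * exp(-0.002 * t)),
                       "mmol/l")
  fit <- fit_decay(s)
  ins <- sampling_series("insulin", c(-20, t), rep(400, length(t) + 1),
                         "pmol/l")
  expect_equal(normalize_beta(fit, ins), 0.002 / 400, tolerance = 1e-8)
  ins2 <- sampling_series("insulin", c(-20, t), rep(800, length(t) + 1),
                          "pmol/l")
  expect_equal(normalize_beta(fit, ins2), normalize_beta(fit, ins) / 2,
               tolerance = 1e-10)
})

test_that("Z-test on decay coefficients matches normal-theory quantiles", {
  a <- list(beta = 0.002, se = 0.0002)
  b <- list(beta = 0.002, se = 0.0002)
  z0 <- ztest_betas(a, b)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  b2 <- list(beta = 0.002 - 1.96 * sqrt(2 * 0.0002^2), se = 0.0002)
  expect_equal(ztest_betas(a, b2)$p, 0.05, tolerance = 0.001)
  # antisymmetry
  expect_equal(ztest_betas(a, b2)$z, -ztest_betas(b2, a)$z)
})

test_that("Z-test type-I error is calibrated on simulated null pairs", {
  t <- seq(0, 360, 20)
  set.seed(21)
  reject <- replicate(2000, {
    fits <- lapply(1:2, function(k) {
      v <- 1.2 * exp(-0.0014 * t) + rnorm(length(t), 0, 0.05)
      fit_decay(sampling_series("lactate", t, pmax(v, 1e-4), "mmol/l"))
    })
    ztest_betas(fits[[1]], fits[[2]])$p < 0.05
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("percent delta compares the last sample with the basal mean", {
  s <- sampling_series("x", c(-20, 0, 100, 200), c(2, 2, 1.8, 1.5),
                       "mmol/l")
  expect_equal(percent_delta(s), -25)
  flat <- sampling_series("x", c(-20, 0, 100), rep(1, 3), "mmol/l")
  expect_equal(percent_delta(flat), 0)
  # linear fall to half the baseline
  half <- sampling_series("x", c(0, 180, 360), c(2, 1.5, 1), "mmol/l")
  expect_equal(percent_delta(half), -50)
})

test_that("heat-map rows are z-scored under the configured convention", {
  m <- matrix(rep(3, 18), nrow = 1,
              dimnames = list("met", paste0("c", 1:18)))
  z <- heatmap_matrix(m, cluster_rows = FALSE)
  expect_true(all(z$z == 0))
  # two-cell toy: sample-SD (ddof = 1) gives |z| = 1/sqrt(2), population
  # SD gives |z| = 1
  m2 <- matrix(c(1, 3), nrow = 1, dimnames = list("met", c("a", "b")))
  expect_equal(as.numeric(heatmap_matrix(m2, cluster_rows = FALSE)$z),
               c(-1, 1) / sqrt(2))
  expect_equal(as.numeric(heatmap_matrix(m2, sd_convention = "population",
                                         cluster_rows = FALSE)$z),
               c(-1, 1))
  # z-scored rows have mean 0 and sample SD 1
  set.seed(5)
  m3 <- matrix(rexp(54), nrow = 3,
               dimnames = list(paste0("m", 1:3), paste0("c", 1:18)))
  z3 <- heatmap_matrix(m3)$z
  expect_equal(rowMeans(z3), rep(0, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(z3, 1, stats::sd), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("feature matrix assembly is permutation-invariant in subjects", {
  cfg <- cohort_config(n_per_group = c(NGT = 2L, IGT = 2L, T2D = 2L),
                       seed = 9)
  coh <- simulate_cohort(cfg)
  m1 <- metabolite_cell_means(coh)
  perm <- rev(seq_along(coh))
  coh2 <- coh[perm]
  class(coh2) <- class(coh)
  m2 <- metabolite_cell_means(coh2)
  expect_equal(m1, m2)
  expect_identical(dim(m1), c(12L, 18L))
})

test_that("route-dependent decay shows blunted oral suppression", {
  cfg <- cohort_config(n_per_group = c(NGT = 3L, IGT = 0L, T2D = 0L),
                       seed = 13)
  coh <- simulate_cohort(cfg)
  lac <- cohort_decay_fits(coh, "lactate", group = "all")
  expect_lt(lac$oral$beta, lac$igivi$beta)
  # insulin-normalised gap widens: oral insulin is higher at lower raw beta
  ins_o <- coh[[1]]$oral$session$insulin
  ins_i <- coh[[1]]$igivi$session$insulin
  expect_lt(normalize_beta(lac$oral, ins_o) /
              normalize_beta(lac$igivi, ins_i),
            lac$oral$beta / lac$igivi$beta)
  # fatty-acid cells fall more under oral dosing in the late segment
  cm <- metabolite_cell_means(coh)
  expect_lt(cm["palmitic", "NGT_oral_T3"], cm["palmitic", "NGT_igivi_T3"])
})
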