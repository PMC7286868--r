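make_flat_series <- function(analyte, value, unit, step = 10) {
  sampling_series(analyte, c(-20, seq(0, 360, step)),
                  rep(value, length(seq(0, 360, step)) + 1), unit)
}

test_that("MCR/I unit arithmetic and scaling behave as defined", {
  g <- make_flat_series("glucose", 5, "mmol/l")
  i <- make_flat_series("insulin", 500, "pmol/l", step = 20)
  times <- seq(0, 360, 1)
  rd <- rep(20, length(times))
  expect_equal(mcr_i(rd, times, g, i), 1000 * (20 / 5) / 500)  # = 8
  i2 <- make_flat_series("insulin", 1000, "pmol/l", step = 20)
  expect_equal(mcr_i(rd, times, g, i2), 4)
  i0 <- make_flat_series("insulin", 0, "pmol/l", step = 20)
  expect_error(mcr_i(rd, times, g, i0), "non-positive insulin")
  bad_unit <- make_flat_series("insulin", 500, "mU/l", step = 20)
  expect_error(mcr_i(rd, times, g, bad_unit))
})

test_that("hepatic insulin resistance index is the EGP-insulin product", {
  i <- make_flat_series("insulin", 100, "pmol/l", step = 20)
  times <- seq(0, 360, 1)
  expect_equal(hepatic_ir(rep(10, length(times)), times, i)$mean, 1000)
  expect_equal(hepatic_ir(rep(0, length(times)), times, i)$mean, 0)
})

test_that("insulinogenic index is the ratio of incremental AUCs", {
  t_i <- c(-20, seq(0, 360, 20)); t_g <- c(-20, seq(0, 360, 10))
  ins <- sampling_series("insulin", t_i,
                         c(100, 100 + rep(1000 / 360, 19)), "pmol/l")
  glu <- sampling_series("glucose", t_g, c(5, 5 + rep(10 / 360, 37)),
                         "mmol/l")
  got <- insulinogenic_index(ins, glu)
  expect_equal(got, auc(ins, c(0, 360), incremental = TRUE) /
                 auc(glu, c(0, 360), incremental = TRUE))
  flat_i <- make_flat_series("insulin", 100, "pmol/l", 20)
  expect_equal(insulinogenic_index(flat_i, glu), 0)
  flat_g <- make_flat_series("glucose", 5, "mmol/l")
  expect_error(insulinogenic_index(ins, flat_g), "zero")
})

test_that("insulin clearance collapses to ISR/I at steady state", {
  kin <- cpeptide_kinetics(4.55, 33.1, 0.78, V1 = 5)
  cp <- make_flat_series("cpeptide", 1.0, "nmol/l", 20)
  dec <- deconvolve_isr(cp, kin)
  ins <- make_flat_series("insulin", 200, "pmol/l", 20)
  cl <- insulin_clearance(dec, ins, weight = 150)
  expect_equal(cl, basal_isr(kin, 1.0) / 200, tolerance = 1e-8)
})

test_that("disposition index multiplies secretion by sensitivity", {
  kin <- cpeptide_kinetics(4.55, 33.1, 0.78, V1 = 5)
  cp <- make_flat_series("cpeptide", 1.0, "nmol/l", 20)
  dec <- deconvolve_isr(cp, kin)
  g <- make_flat_series("glucose", 5, "mmol/l")
  i <- make_flat_series("insulin", 500, "pmol/l", 20)
  times <- seq(0, 360, 1)
  rd <- rep(20, length(times))
  di <- disposition_index(dec, rd, times, g, i)
  expect_equal(di, 8 * basal_isr(kin, 1.0), tolerance = 1e-8)
  expect_equal(disposition_index(dec, rep(0, length(times)), times, g, i), 0)
})

test_that("Adipo-IR sums configured fatty-acid means times mean insulin", {
  i <- make_flat_series("insulin", 200, "pmol/l", 20)
  mets <- list(palmitic = make_flat_series("palmitic", 0.5, "mmol/l", 20))
  expect_equal(adipo_ir(mets, i, fa_names = "palmitic"), 100)
  expect_error(adipo_ir(mets, i, fa_names = character(0)), "empty")
  expect_error(adipo_ir(mets, i, fa_names = c("palmitic", "oleic")),
               "missing")
})

test_that("required sample size reproduces the power computation", {
  expect_identical(required_sample_size(4.6, 5.98, 0.9, 0.05, 0.90, 0.25),
                   24L)
  expect_identical(required_sample_size(4.6, 5.98, 0.9, 0.05, 0.90, 0),
                   18L)
  # infinite effect size: smallest possible trial inflated for attrition
  expect_identical(required_sample_size(0, 1e9, 0.9, 0.05, 0.90, 0.25), 3L)
  expect_error(required_sample_size(5, 5, 0.9))
})

test_that("indices are invariant under grid refinement by interpolation", {
  o <- cached_oral_session()
  fl <- reconstruct_fluxes(o$session, lambda = 0)
  g <- o$session$glucose; i <- o$session$insulin
  base <- mcr_i(fl$rd, fl$times, g, i)
  # refine the post-load record by linear interpolation to a 2-min grid,
  # keeping the original basal samples (the basal mean is defined on them)
  refine <- function(s, step) {
    tt <- c(s$times[s$times < 0], seq(0, max(s$times), by = step))
    sampling_series(s$analyte, tt,
                    stats::approx(s$times, s$values, tt)$y, s$unit)
  }
  fine <- mcr_i(fl$rd, fl$times, refine(g, 2), refine(i, 2))
  expect_equal(fine, base, tolerance = 1e-6)
  ii_base <- insulinogenic_index(i, g)
  ii_fine <- insulinogenic_index(refine(i, 2), refine(g, 2))
  expect_equal(ii_fine, ii_base, tolerance = 1e-6)
})

test_that("index panel assembles every study index for a session", {
  o <- cached_oral_session()
  an <- analyze_session(o$session, lambda = 0)
  p <- an$panel
  expect_s3_class(p, "index_panel")
  expect_length(p$mcr_i_segments, 3)
  expect_equal(p$mcr_i, mean(p$mcr_i_segments))
  expect_true(all(c(p$mcr_i, p$insulin_clearance, p$di, p$isr_mean,
                    p$adipo_ir) > 0))
  df <- as.data.frame(p)
  expect_identical(nrow(df), 1L)
  expect_output(print(p), "MCR/I")
})

test_that("the paired index contrast matches the generator's ground truth", {
  o <- cached_oral_session()
  iv <- cached_igivi_session()
  est <- sapply(list(o, iv), function(e) {
    fl <- reconstruct_fluxes(e$session, lambda = 0)
    mcr_i(fl$rd, fl$times, e$session$glucose, e$session$insulin,
          glucose_values = fl$glucose_smooth)
  })
  tru <- sapply(list(o, iv), function(e)
    mean(1000 * (e$truth$rd / e$truth$glucose) / e$truth$insulin))
  # the measured oral/intravenous sensitivity ratio reproduces the true
  # ratio (the imprint of the oral-resistance multiplier kappa)
  expect_lt(abs(est[1] / est[2] - tru[1] / tru[2]), 0.15 * tru[1] / tru[2])
  expect_lt(est[1] / est[2], 1)
})

test_that("weaker hepatic insulin signalling raises the hepatic IR index", {
  subj <- default_subject()
  cfg <- noise_free_config()
  set.seed(8)
  ctrl <- simulate_oral_session(true_physiology(), subj, cfg)
  set.seed(8)
  resist <- simulate_oral_session(true_physiology(k_egp_I = 0.005), subj,
                                  cfg)
  h_ctrl <- mean(ctrl$truth$egp * ctrl$truth$insulin)
  h_res <- mean(resist$truth$egp * resist$truth$insulin)
  expect_gt(h_res, h_ctrl)
})
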