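# Shared fixtures: one default subject and cached noise-free sessions.
# Everything is generated in code at test time; nothing is read from disk.

default_subject <- function() {
  subject_profile("NGT-01", "NGT", age = 46, weight = 152.4, bmi = 53.7,
                  basal_glucose = 5.35, basal_insulin = 120,
                  basal_cpeptide = 1.25)
}

noise_free_config <- function(seed = 1) zero_noise(cohort_config(seed = seed))

# cache expensive simulations across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached_oral_session <- function() {
  if (is.null(.fixture_env$oral)) {
    set.seed(1)
    .fixture_env$oral <- simulate_oral_session(true_physiology(),
                                               default_subject(),
                                               noise_free_config())
  }
  .fixture_env$oral
}

cached_igivi_session <- function() {
  if (is.null(.fixture_env$igivi)) {
    o <- cached_oral_session()
    tgt <- stats::approxfun(o$truth$times, o$truth$glucose, rule = 2)
    set.seed(1)
    .fixture_env$igivi <- simulate_igivi_session(true_physiology(),
                                                 default_subject(), tgt,
                                                 noise_free_config())
  }
  .fixture_env$igivi
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

trapz_num <- function(x, y)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
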