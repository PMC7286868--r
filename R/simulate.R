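#' Ground-truth physiology for the forward simulator
#'
#' Parameters of the generative model from which paired oral and
#' isoglycaemic-intravenous sessions are simulated. Route-dependent biology
#' enters through exactly three knobs, one per study claim:
#' \code{kappa} (multiplier < 1 on insulin sensitivity under oral dosing,
#' i.e. oral-route insulin resistance), \code{incretin_gain} (multiplier > 1
#' on suprabasal insulin secretion under oral dosing) and the pair of
#' hepatic-extraction fractions (lower after oral glucose, reducing insulin
#' clearance); a fourth, the per-species metabolite oral factors, blunts the
#' anti-lipolytic/anti-proteolytic action of insulin under oral dosing.
#'
#' @param S_I_iv insulin sensitivity under intravenous glucose,
#'   min-1 per pmol/l.
#' @param kappa oral-route multiplier on S_I, in (0, 1].
#' @param S_G glucose effectiveness, 1/min.
#' @param p2 remote-insulin rate constant, 1/min.
#' @param V_g single-pool glucose distribution volume, ml/kg. The default
#'   equals the Steele pool fraction times the analyst's distribution volume
#'   (0.65 x 160) so the reconstruction modules share the generator's pool.
#' @param beta_true per-segment static beta cell sensitivities,
#'   pmol min-1 per mmol/l above threshold (length 3).
#' @param kd_true per-segment dynamic sensitivities, pmol per mmol/l
#'   (length 3).
#' @param h secretion threshold, mmol/l; NULL means 1 mmol/l below the
#'   subject's basal glucose, keeping the secretion drive linear around the
#'   fasting operating point (basal equilibrium is enforced by subtracting
#'   the basal static drive).
#' @param tau provision delay of the static secretion component, min.
#' @param hepatic_extraction named fractions \code{c(oral = , iv = )}.
#' @param incretin_gain multiplier on suprabasal secretion during oral
#'   dosing.
#' @param EGP_b basal endogenous glucose production, umol kg-1 min-1.
#' @param k_egp_I EGP suppression slope by insulin, umol kg-1 min-1 per
#'   pmol/l.
#' @param k_egp_G EGP suppression slope by glucose, umol kg-1 min-1 per
#'   mmol/l.
#' @param absorption_shape,absorption_scale gamma-density absorption of each
#'   oral load (defaults place ~95\% of the dose inside its 120-min segment).
#' @param metabolite_route_blunting scalar in [0, 1] scaling the
#'   per-species oral blunting of insulin-driven metabolite decay
#'   (1 = full study-like blunting, 0 = none; the species-level oral
#'   factors live in the \code{metabolites} table).
#' @param metabolites data.frame of simulated metabolites with columns
#'   \code{name}, \code{c0} (mmol/l), \code{k_m} (min-1 per pmol/l of
#'   recent-mean insulin), \code{class} (\code{"aa"}, \code{"fa"},
#'   \code{"other"}) and \code{oral_factor} (multiplier on k_m under oral
#'   dosing; < 1 encodes blunted insulin action).
#' @param glp1_basal,glp1_gain,glucagon_basal descriptive gut-hormone shape
#'   parameters (ng/l; ng/l per g of glucose).
#' @return object of class \code{true_physiology}.
#' @export
true_physiology <- function(S_I_iv = 7e-5, kappa = 0.6, S_G = 0.03,
                            p2 = 0.025, V_g = 104,
                            beta_true = c(130, 130, 130),
                            kd_true = c(2200, 2200, 2200),
                            h = NULL, tau = 10,
                            hepatic_extraction = c(oral = 0.5, iv = 0.65),
                            incretin_gain = 1.8,
                            EGP_b = 11, k_egp_I = 0.02, k_egp_G = 0.8,
                            absorption_shape = 3, absorption_scale = 17,
                            metabolite_route_blunting = 1,
                            metabolites = default_metabolites(),
                            glp1_basal = 10, glp1_gain = 45,
                            glucagon_basal = 70) {
  stopifnot(kappa > 0, kappa <= 1,
            all(hepatic_extraction >= 0), all(hepatic_extraction < 0.9),
            S_I_iv >= 0, S_G >= 0, p2 > 0, V_g > 0, tau > 0,
            all(beta_true >= 0), all(kd_true >= 0),
            length(beta_true) == 3, length(kd_true) == 3)
  structure(list(S_I_iv = S_I_iv, kappa = kappa, S_G = S_G, p2 = p2,
                 V_g = V_g, beta_true = beta_true, kd_true = kd_true,
                 h = h, tau = tau, hepatic_extraction = hepatic_extraction,
                 incretin_gain = incretin_gain, EGP_b = EGP_b,
                 k_egp_I = k_egp_I, k_egp_G = k_egp_G,
                 absorption_shape = absorption_shape,
                 absorption_scale = absorption_scale,
                 metabolite_route_blunting = metabolite_route_blunting,
                 metabolites = metabolites,
                 glp1_basal = glp1_basal, glp1_gain = glp1_gain,
                 glucagon_basal = glucagon_basal),
            class = "true_physiology")
}

#' Route-neutral physiology for null-cohort checks
#'
#' Sets every route-dependent knob to neutral (kappa = 1, incretin gain = 1,
#' equal hepatic extraction, metabolite route factor = 1) so paired oral and
#' intravenous indices are exchangeable up to noise.
#'
#' @param ... overrides passed to \code{\link{true_physiology}}.
#' @return object of class \code{true_physiology}.
#' @export
null_physiology <- function(...) {
  true_physiology(kappa = 1, incretin_gain = 1,
                  hepatic_extraction = c(oral = 0.575, iv = 0.575),
                  metabolite_route_blunting = 0, ...)
}

#' Default simulated metabolite panel
#'
#' Fasting concentrations (mmol/l) and insulin-driven decay constants
#' (min-1 per pmol/l of recent-mean insulin) for the amino acids, fatty
#' acids, lactate and 3-hydroxybutyrate the study profiles. The lactate
#' constant is set so the intravenous-session decay coefficient lands near
#' the study's printed 0.0014 1/min at typical insulin exposure.
#'
#' @return data.frame with columns name, c0, k_m, class.
#' @export
default_metabolites <- function() {
  data.frame(
    name = c("isoleucine", "leucine", "valine", "threonine", "methionine",
             "palmitic", "oleic", "stearic", "linoleic", "myristic",
             "lactate", "hydroxybutyrate"),
    c0 = c(0.060, 0.120, 0.220, 0.140, 0.025,
           0.120, 0.200, 0.040, 0.080, 0.010,
           1.000, 0.200),
    k_m = c(8e-6, 8e-6, 7e-6, 6e-6, 7e-6,
            1.0e-5, 1.0e-5, 9e-6, 1.1e-5, 1.0e-5,
            6.4e-6, 1.3e-5),
    class = c(rep("aa", 5), rep("fa", 5), "other", "other"),
    ## oral blunting of insulin's clearing action differs by class: amino
    ## acids and fatty acids still fall faster orally (higher insulin wins)
    ## while lactate disappearance is more strongly blunted
    oral_factor = c(rep(0.85, 5), rep(0.85, 5), 0.45, 0.85),
    stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Sample sizes, between-subject variability, measurement-noise model and the
#' mandatory random seed. Defaults reproduce the study arm sizes (9 NGT,
#' 7 IGT, 7 type 2 diabetes) and assay-realistic noise.
#'
#' @param n_per_group named integer vector \code{c(NGT=, IGT=, T2D=)}.
#' @param seed integer seed (mandatory; all randomness flows from it, with
#'   per-subject substreams derived by counter).
#' @param subject_cv between-subject lognormal CV applied to the key
#'   physiological parameters.
#' @param noise list of measurement-noise settings: multiplicative CVs for
#'   glucose, insulin, cpeptide, glp1, glucagon and metabolites, and an
#'   additive SD for tracer-to-tracee ratios.
#' @param day_to_day within-subject between-session parameter CV (default 0;
#'   the study reports none).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_group = c(NGT = 9L, IGT = 7L, T2D = 7L),
                          seed,
                          subject_cv = 0.2,
                          noise = list(glucose = 0.015, insulin = 0.05,
                                       cpeptide = 0.05, glp1 = 0.08,
                                       glucagon = 0.08, metabolites = 0.08,
                                       ttr_sd = 3e-4),
                          day_to_day = 0) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(all(unlist(noise) >= 0), day_to_day >= 0)
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 subject_cv = subject_cv, noise = noise,
                 day_to_day = day_to_day),
            class = "cohort_config")
}

#' Zero-noise variant of a noise configuration
#' @param cfg a \code{cohort_config}.
#' @return the configuration with all noise terms set to zero.
#' @export
zero_noise <- function(cfg) {
  cfg$noise <- lapply(cfg$noise, function(x) 0)
  cfg
}

MW_GLUCOSE <- 180.156  # g/mol

## time constant (min) of the first-order filter applied to dG/dt before it
## drives the dynamic secretion component, shared with the beta cell fitter
SECRETION_DERIV_TAU <- 8

#' Oral glucose appearance rate of a load schedule
#'
#' Gamma-density absorption: each load of \code{dose_g} grams appears in the
#' circulation at rate dose x gamma pdf (shape, scale), about 95\% of it
#' inside the load's own 120-min segment with the default shape.
#'
#' @param t times, min (vectorised).
#' @param loads data.frame time/dose_g/tracer_g.
#' @param weight kg.
#' @param shape,scale gamma absorption parameters.
#' @param labelled if TRUE return the appearance rate of the oral tracer
#'   (i.e. scaled by each load's drink enrichment tracer_g/dose_g).
#' @return rate, umol kg-1 min-1.
#' @export
oral_appearance <- function(t, loads, weight, shape = 2, scale = 25,
                            labelled = FALSE) {
  out <- numeric(length(t))
  if (is.null(loads) || nrow(loads) == 0) return(out)
  for (i in seq_len(nrow(loads))) {
    dose_umol_kg <- loads$dose_g[i] * 1e6 / MW_GLUCOSE / weight
    frac <- if (labelled) loads$tracer_g[i] / loads$dose_g[i] else 1
    dt <- t - loads$time[i]
    on <- dt > 0
    out[on] <- out[on] +
      frac * dose_umol_kg * stats::dgamma(dt[on], shape = shape,
                                          scale = scale)
  }
  out
}

segment_index_of <- function(t) pmin(pmax(findInterval(t, c(0, 120, 240)), 1L), 3L)

## Derivative field of the generative model. State vector layout:
## G, X, SRs, CP1, CP2, I, Iavg, QD2, QC13, Dg (filtered dG/dt), then
## metabolites. The dynamic secretion component responds to the filtered
## glucose slope (beta cells sense rise rate on a ~10-min scale, not
## minute-scale wiggles).
sim_deriv <- function(t, st, ctx) {
  G <- st[1]; X <- st[2]; SRs <- st[3]; CP1 <- st[4]; CP2 <- st[5]
  I <- st[6]; Iavg <- st[7]; QD2 <- st[8]; QC13 <- st[9]; Dg <- st[10]
  Cm <- st[-(1:10)]
  p <- ctx$phys
  ra_oral <- if (ctx$route == "oral" && t > 0)
    oral_appearance(t, ctx$loads, ctx$weight, p$absorption_shape,
                    p$absorption_scale) else 0
  ra_oral_lab <- if (ctx$route == "oral" && t > 0)
    oral_appearance(t, ctx$loads, ctx$weight, p$absorption_shape,
                    p$absorption_scale, labelled = TRUE) else 0
  gir <- if (ctx$route == "igivi" && t >= 0) ctx$gir_fun(t) else 0
  egp <- max(0, p$EGP_b - p$k_egp_I * (I - ctx$I_b) -
                p$k_egp_G * (G - ctx$G_b))
  ## basal disposal balances basal EGP plus the constant tracer infusion:
  ## the measured fasting glucose is the tracer-equilibrated steady state
  rd <- max(0, ctx$V_g * (p$S_G * (G - ctx$G_b) + X * G) +
                 p$EGP_b + ctx$F_trc)
  ra_total <- ra_oral + egp + ctx$F_trc + gir
  dG <- (ra_total - rd) / ctx$V_g
  dX <- -p$p2 * (X - ctx$kappa_eff * p$S_I_iv * (I - ctx$I_b))
  seg <- segment_index_of(t)
  static_target <- p$beta_true[seg] * max(G - ctx$h, 0)
  dSRs <- (-SRs + static_target) / p$tau
  ## signed rate sensitivity: falling glucose suppresses secretion below
  ## the static component just as rising glucose stimulates it
  srd <- p$kd_true[seg] * Dg
  sr_total <- ctx$SR_b +
    ctx$gain_eff * (SRs - ctx$SRs_basal + srd)
  sr_total <- max(sr_total, 0)
  kin <- ctx$kin
  dCP1 <- -(kin$k01 + kin$k21) * CP1 + kin$k12 * CP2 +
    sr_total / (1000 * kin$V1)
  dCP2 <- kin$k21 * CP1 - kin$k12 * CP2
  ## route-dependent hepatic extraction applies to suprabasal secretion;
  ## basal extraction is common to both sessions so the basal state is the
  ## same equilibrium on both days
  posthep <- (1 - ctx$HE_b) * min(sr_total, ctx$SR_b) +
    (1 - ctx$HE) * max(sr_total - ctx$SR_b, 0)
  dI <- posthep / ctx$V_I - ctx$k_I * I
  dIavg <- (I - Iavg) / 30
  kclr <- rd / (G * ctx$V_g)
  dQD2 <- ctx$F_trc + ctx$enr * gir - kclr * QD2
  dQC13 <- ra_oral_lab - kclr * QC13
  dDg <- (dG - Dg) / SECRETION_DERIV_TAU
  km_eff <- p$metabolites$k_m * ctx$route_factor
  dCm <- -km_eff * Iavg * Cm
  c(dG, dX, dSRs, dCP1, dCP2, dI, dIavg, dQD2, dQC13, dDg, dCm)
}

rk4_run <- function(t0, t1, dt, state, ctx) {
  n <- round((t1 - t0) / dt)
  times <- t0 + dt * (0:n)
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(state))
  out[1, ] <- state
  extras <- matrix(NA_real_, nrow = n + 1L, ncol = 6L)
  colnames(extras) <- c("ra_oral", "egp", "rd", "ra_total", "isr", "gir")
  extras[1, ] <- sim_extras(times[1], state, ctx)
  for (i in seq_len(n)) {
    t <- times[i]
    k1 <- sim_deriv(t, state, ctx)
    k2 <- sim_deriv(t + dt / 2, state + dt / 2 * k1, ctx)
    k3 <- sim_deriv(t + dt / 2, state + dt / 2 * k2, ctx)
    k4 <- sim_deriv(t + dt, state + dt * k3, ctx)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state)) || state[1] <= 0)
      stop("simulation failure (non-finite or non-positive glucose) at t = ",
           t, "; parameters: kappa=", ctx$phys$kappa,
           " gain=", ctx$phys$incretin_gain)
    out[i + 1L, ] <- state
    extras[i + 1L, ] <- sim_extras(times[i + 1L], state, ctx)
  }
  list(times = times, states = out, extras = extras, state = state)
}

## Recompute the algebraic fluxes at a grid point (for the ground truth).
sim_extras <- function(t, st, ctx) {
  G <- st[1]; X <- st[2]; SRs <- st[3]; I <- st[6]; Dg <- st[10]
  p <- ctx$phys
  ra_oral <- if (ctx$route == "oral" && t > 0)
    oral_appearance(t, ctx$loads, ctx$weight, p$absorption_shape,
                    p$absorption_scale) else 0
  gir <- if (ctx$route == "igivi" && t >= 0) ctx$gir_fun(t) else 0
  egp <- max(0, p$EGP_b - p$k_egp_I * (I - ctx$I_b) -
                p$k_egp_G * (G - ctx$G_b))
  rd <- max(0, ctx$V_g * (p$S_G * (G - ctx$G_b) + X * G) + p$EGP_b)
  ra_total <- ra_oral + egp + ctx$F_trc + gir
  seg <- segment_index_of(t)
  srd <- p$kd_true[seg] * Dg
  isr <- max(0, ctx$SR_b + ctx$gain_eff * (SRs - ctx$SRs_basal + srd))
  c(ra_oral, egp, rd, ra_total, isr, gir)
}

build_ctx <- function(phys, subject, route, kin, gir_fun = NULL) {
  G_b <- subject$basal_glucose
  I_b <- subject$basal_insulin
  CP_b <- subject$basal_cpeptide
  h <- if (is.null(phys$h)) G_b - 1 else phys$h
  SR_b <- 1000 * kin$k01 * kin$V1 * CP_b   # pmol/min
  HE <- unname(phys$hepatic_extraction[if (route == "oral") "oral" else "iv"])
  HE_b <- unname(phys$hepatic_extraction["iv"])  # fasting extraction
  V_I <- 0.14 * subject$weight             # insulin distribution volume, l
  k_I <- (1 - HE_b) * SR_b / (V_I * I_b)   # 1/min, basal equilibrium
  list(phys = phys, route = route, weight = subject$weight,
       loads = NULL, gir_fun = gir_fun,
       G_b = G_b, I_b = I_b, CP_b = CP_b, h = h,
       SR_b = SR_b, SRs_basal = phys$beta_true[1] * max(G_b - h, 0),
       HE = HE, HE_b = HE_b, V_I = V_I, k_I = k_I,
       V_g = phys$V_g,
       kappa_eff = if (route == "oral") phys$kappa else 1,
       gain_eff = if (route == "oral") phys$incretin_gain else 1,
       route_factor = if (route == "oral")
         1 - phys$metabolite_route_blunting *
           (1 - phys$metabolites$oral_factor)
       else rep(1, nrow(phys$metabolites)),
       F_trc = 0.22, enr = 0.025, kin = kin)
}

initial_state <- function(ctx, prime) {
  kin <- ctx$kin
  c(G = ctx$G_b, X = 0, SRs = ctx$SRs_basal,
    CP1 = ctx$CP_b, CP2 = kin$k21 / kin$k12 * ctx$CP_b,
    I = ctx$I_b, Iavg = ctx$I_b, QD2 = prime, QC13 = 0, Dg = 0,
    stats::setNames(ctx$phys$metabolites$c0, ctx$phys$metabolites$name))
}

add_cv_noise <- function(x, cv) if (cv <= 0) x else pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0)

glp1_curve <- function(t, phys, route, loads) {
  if (route != "oral") return(rep(phys$glp1_basal, length(t)))
  out <- rep(phys$glp1_basal, length(t))
  for (i in seq_len(nrow(loads))) {
    dt <- t - loads$time[i]
    on <- dt > 0
    out[on] <- out[on] + phys$glp1_gain * loads$dose_g[i] *
      stats::dgamma(dt[on], shape = 2, scale = 30)
  }
  out
}

glucagon_curve <- function(t, phys) {
  phys$glucagon_basal * (0.65 + 0.35 * exp(-pmax(t, 0) / 150))
}

sample_session <- function(run, ctx, phys, subject, route, cfg, schedule) {
  tt <- run$times
  at <- function(ts, col) run$states[match(ts, tt), col]
  glu_t <- c(-30, -20, -10, seq(0, 360, 10))
  hor_t <- c(-40, -20, seq(0, 360, 20))
  noise <- cfg$noise
  G <- at(glu_t, 1)
  I <- at(hor_t, 6)
  CP <- at(hor_t, 4)
  ttr_d2 <- at(glu_t, 8) / (at(glu_t, 1) * ctx$V_g)
  mets <- list()
  for (j in seq_len(nrow(phys$metabolites))) {
    nm <- phys$metabolites$name[j]
    mv <- add_cv_noise(at(hor_t, 10 + j), noise$metabolites)
    mets[[nm]] <- sampling_series(nm, hor_t, mv, "mmol/l")
  }
  tracers <- list(D2 = tracer_series("D2", glu_t,
    pmax(ttr_d2 + stats::rnorm(length(glu_t), 0, noise$ttr_sd), 0)))
  if (route == "oral") {
    ttr_c13 <- at(glu_t, 9) / (at(glu_t, 1) * ctx$V_g)
    tracers$C13 <- tracer_series("C13", glu_t,
      pmax(ttr_c13 + stats::rnorm(length(glu_t), 0, noise$ttr_sd), 0))
  }
  session_record(
    subject, route,
    glucose = sampling_series("glucose", glu_t,
                              add_cv_noise(G, noise$glucose), "mmol/l"),
    insulin = sampling_series("insulin", hor_t,
                              add_cv_noise(I, noise$insulin), "pmol/l"),
    cpeptide = sampling_series("cpeptide", hor_t,
                               add_cv_noise(CP, noise$cpeptide), "nmol/l"),
    glp1 = sampling_series("glp1", hor_t,
      add_cv_noise(glp1_curve(hor_t, phys, route,
                              schedule$oral_loads), noise$glp1), "ng/l"),
    glucagon = sampling_series("glucagon", hor_t,
      add_cv_noise(glucagon_curve(hor_t, phys), noise$glucagon), "ng/l"),
    metabolites = mets, tracers = tracers, infusions = schedule)
}

ground_truth <- function(run, ctx, phys, route) {
  keep <- run$times >= 0
  kin <- ctx$kin
  list(times = run$times[keep],
       glucose = run$states[keep, 1],
       insulin = run$states[keep, 6],
       cpeptide = run$states[keep, 4],
       isr = run$extras[keep, "isr"],
       ra_oral = run$extras[keep, "ra_oral"],
       egp = run$extras[keep, "egp"],
       rd = run$extras[keep, "rd"],
       ra_total = run$extras[keep, "ra_total"],
       gir = run$extras[keep, "gir"],
       isr_basal = ctx$SR_b,
       beta_eff = ctx$gain_eff * phys$beta_true,
       kd_eff = ctx$gain_eff * phys$kd_true,
       h = ctx$h, tau = phys$tau,
       ## session-level true insulin clearance: secretion over exposure from
       ## the latent trajectories (the estimand of the Jung-style formula)
       clearance = trapz(run$times[keep], run$extras[keep, "isr"]) /
         trapz(run$times[keep], run$states[keep, 6]),
       clearance_suprabasal = ctx$k_I * ctx$V_I / (1 - ctx$HE),
       hepatic_extraction = ctx$HE,
       peripheral_clearance = ctx$k_I * ctx$V_I,
       V_g = ctx$V_g, route = route)
}

#' Simulate one oral session
#'
#' Forward-simulates the triple sequential oral protocol (25/75/100 g at
#' 0/120/240 min, each spiked with 0.9 g oral tracer, on top of a primed
#' constant tracer infusion started at -150 min) on a 1-min grid and samples
#' it on the study grids (glucose/TTR every 10 min, hormones and metabolites
#' every 20 min) with configurable measurement noise.
#'
#' @param phys a \code{true_physiology}.
#' @param subject a \code{subject_profile}.
#' @param cfg a \code{cohort_config} (noise model; its seed is NOT set here —
#'   callers control the stream).
#' @param kin C-peptide kinetics; default \code{population_kinetics(subject)}.
#' @return list with \code{session} (a \code{session_record}) and
#'   \code{truth} (latent trajectories and true parameters).
#' @export
simulate_oral_session <- function(phys, subject, cfg, kin = NULL) {
  if (is.null(kin)) kin <- population_kinetics(subject)
  ctx <- build_ctx(phys, subject, "oral", kin)
  schedule <- infusion_schedule(oral_loads = default_oral_loads())
  ctx$loads <- schedule$oral_loads
  run <- rk4_run(-150, 360, 1, initial_state(ctx, prime = 22), ctx)
  session <- sample_session(run, ctx, phys, subject, "oral", cfg, schedule)
  truth <- ground_truth(run, ctx, phys, "oral")
  check_label_balance(run, ctx)
  list(session = session, truth = truth)
}

## Tracer mass conservation: circulating label never exceeds administered.
check_label_balance <- function(run, ctx) {
  t <- run$times
  d2 <- run$states[, 8]
  admin_d2 <- 22 + 0.22 * (t - t[1]) +
    if (ctx$route == "igivi") {
      g <- vapply(t, function(x) if (x >= 0) ctx$gir_fun(x) else 0, 0)
      0.025 * cumsum(c(0, diff(t)) * g)
    } else 0
  if (any(d2 > admin_d2 + 1e-6))
    stop("tracer mass balance violated for D2 label")
  if (ncol(run$states) >= 9 && ctx$route == "oral") {
    c13 <- run$states[, 9] * ctx$weight * MW_GLUCOSE / 1e6  # g in pool
    admin <- vapply(t, function(x)
      sum(ctx$loads$tracer_g[ctx$loads$time < x]), 0)
    if (any(c13 > admin + 1e-9))
      stop("tracer mass balance violated for oral label")
  }
  invisible(TRUE)
}

#' Derive the isoglycaemic intravenous infusion for a target profile
#'
#' Simulates the intravenous session in 10-min blocks; at every block
#' boundary a proportional-integral tracking controller (with a
#' volume-scaled feedforward of the target slope, clamped at zero) updates
#' the piecewise-constant 20\% dextrose rate so simulated glucose follows
#' the oral session's profile. For the intravenous session the incretin gain
#' and the oral-resistance multiplier are reset to 1 and the dextrose
#' carries 2.5\% tracer enrichment.
#'
#' @param phys a \code{true_physiology}.
#' @param subject a \code{subject_profile}.
#' @param target_fun function of t returning the target glucose (mmol/l);
#'   typically built from the oral session's latent trajectory.
#' @param cfg a \code{cohort_config}.
#' @param kin C-peptide kinetics; default population values.
#' @param rms_tol abort tolerance for the tracking RMS error (mmol/l).
#' @return list with \code{session}, \code{truth}, \code{schedule} and the
#'   achieved \code{rms_error}.
#' @export
simulate_igivi_session <- function(phys, subject, target_fun, cfg,
                                   kin = NULL, rms_tol = 0.8) {
  if (is.null(kin)) kin <- population_kinetics(subject)
  ctx <- build_ctx(phys, subject, "igivi", kin)
  rate_now <- 0
  ctx$gir_fun <- function(t) rate_now
  state <- initial_state(ctx, prime = 22)
  basal <- rk4_run(-150, 0, 1, state, ctx)
  state <- basal$state
  Kp <- ctx$V_g / 10       # null the measured error over one block
  Ki <- 0.3
  e_int <- 0
  blocks <- seq(0, 350, by = 10)
  rates <- numeric(length(blocks))
  runs <- list(basal)
  err2 <- 0; nerr <- 0
  g_prev <- state[1]
  for (b in seq_along(blocks)) {
    t0 <- blocks[b]
    e <- target_fun(t0) - state[1]
    e_int <- e_int + e * 10
    # feedforward: volume-scaled slope of the target over the coming block
    # evaluated with a 3-min lead (compensates the half-block lag of
    # piecewise-constant rates), plus the net disappearance observed over
    # the previous block (a disturbance estimate the integral term refines)
    ff <- ctx$V_g * (target_fun(t0 + 13) - target_fun(t0 + 3)) / 10
    d_est <- if (b == 1) 0 else
      rates[b - 1] - ctx$V_g * (state[1] - g_prev) / 10
    # linear extrapolation of the disturbance trend (disposal keeps
    # growing while insulin action builds up)
    d_pred <- if (b <= 2) d_est else 2 * d_est - d_prev
    d_prev <- d_est
    g_prev <- state[1]
    rate_now <- max(0, ff + d_pred + Kp * e + Ki * e_int)
    rates[b] <- rate_now
    blk <- rk4_run(t0, t0 + 10, 1, state, ctx)
    state <- blk$state
    runs[[b + 1]] <- blk
    gsim <- blk$states[, 1]
    gt <- vapply(blk$times, target_fun, 0)
    err2 <- err2 + sum((gsim - gt)^2); nerr <- nerr + length(gsim)
  }
  rms <- sqrt(err2 / nerr)
  if (rms > rms_tol)
    stop(sprintf("isoglycaemic tracking failed: RMS error %.3f mmol/l", rms))
  times <- unlist(lapply(runs, `[[`, "times"))
  ## at block boundaries keep the later run's row, whose algebraic fluxes
  ## carry the updated infusion rate (the piecewise-constant convention)
  dup <- !duplicated(times, fromLast = TRUE)
  run <- list(times = times[dup],
              states = do.call(rbind, lapply(runs, `[[`, "states"))[dup, ],
              extras = do.call(rbind, lapply(runs, `[[`, "extras"))[dup, ])
  schedule <- infusion_schedule(
    oral_loads = NULL,
    dextrose_rates = data.frame(time = blocks, rate = rates))
  ## re-expose a reproducible lookup for downstream consumers
  ctx$gir_fun <- function(t) dextrose_rate_at(schedule, t)
  session <- sample_session(run, ctx, phys, subject, "igivi", cfg, schedule)
  truth <- ground_truth(run, ctx, phys, "igivi")
  truth$rms_error <- rms
  check_label_balance(run, ctx)
  list(session = session, truth = truth, schedule = schedule,
       rms_error = rms)
}

#' Derive only the infusion schedule matching an oral session
#'
#' Convenience wrapper around \code{\link{simulate_igivi_session}} returning
#' the piecewise-constant dextrose schedule.
#'
#' @inheritParams simulate_igivi_session
#' @return an \code{infusion_schedule}.
#' @export
derive_igivi_infusion <- function(phys, subject, target_fun, cfg,
                                  kin = NULL, rms_tol = 0.8) {
  simulate_igivi_session(phys, subject, target_fun, cfg, kin, rms_tol)$schedule
}

group_profile_defaults <- function() {
  list(NGT = list(G_b = 5.35, weight = 152.4, bmi = 53.7, age = 46,
                  I_b = 120, CP_b = 1.25, si_mult = 1.0, beta_mult = 1.0,
                  glp1_mult = 1.0),
       IGT = list(G_b = 5.7, weight = 135.3, bmi = 49.1, age = 41,
                  I_b = 140, CP_b = 1.35, si_mult = 0.85, beta_mult = 0.8,
                  glp1_mult = 0.9),
       T2D = list(G_b = 7.1, weight = 153.6, bmi = 53.0, age = 47,
                  I_b = 150, CP_b = 1.40, si_mult = 0.7, beta_mult = 0.5,
                  glp1_mult = 0.6))
}

## per-quantity between-subject CVs, scaled by the configured subject_cv
## relative to its default of 0.2
subject_cv_profile <- function(subject_cv) {
  base <- c(age = 0.15, weight = 0.15, bmi = 0.10, G_b = 0.08,
            I_b = 0.25, CP_b = 0.18, S_I = 0.25, beta = 0.25)
  base * subject_cv / 0.2
}

lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Simulate a paired-cohort study
#'
#' Draws a cohort of subjects from group-level means, simulates the oral
#' session for each, derives the matching isoglycaemic intravenous session,
#' and returns all paired records with their ground truths. Reproducible:
#' the same seed gives byte-identical output; per-subject substreams are
#' derived from the seed by counter.
#'
#' @param cfg a \code{cohort_config}.
#' @param phys base \code{true_physiology}; per-subject parameters are
#'   jittered around it by the configured between-subject CV.
#' @return object of class \code{simulated_cohort}: a list of per-subject
#'   entries, each with \code{subject}, \code{oral}, \code{igivi}
#'   (session + truth) and the subject's own \code{phys}.
#' @export
simulate_cohort <- function(cfg, phys = true_physiology()) {
  stopifnot(inherits(cfg, "cohort_config"))
  defs <- group_profile_defaults()
  out <- list()
  counter <- 0L
  for (grp in names(cfg$n_per_group)) {
    d <- defs[[grp]]
    for (i in seq_len(cfg$n_per_group[[grp]])) {
      counter <- counter + 1L
      set.seed((cfg$seed %% 100000L) * 10000L + counter)
      cvs <- subject_cv_profile(cfg$subject_cv)
      m <- vapply(cvs, function(cv) lognorm_mult(1, cv), 0)
      subject <- subject_profile(
        sprintf("%s-%02d", grp, i), grp, age = round(d$age * m["age"]),
        weight = d$weight * m["weight"], bmi = max(31, d$bmi * m["bmi"]),
        basal_glucose = d$G_b * m["G_b"], basal_insulin = d$I_b * m["I_b"],
        basal_cpeptide = d$CP_b * m["CP_b"])
      p <- phys
      p$S_I_iv <- phys$S_I_iv * d$si_mult * m["S_I"]
      p$beta_true <- phys$beta_true * d$beta_mult * m["beta"]
      p$kd_true <- phys$kd_true * d$beta_mult * m["beta"]
      p$glp1_gain <- phys$glp1_gain * d$glp1_mult
      kin <- population_kinetics(subject)
      oral <- simulate_oral_session(p, subject, cfg, kin)
      tgt <- stats::approxfun(oral$truth$times, oral$truth$glucose,
                              rule = 2)
      igivi <- simulate_igivi_session(p, subject, tgt, cfg, kin)
      out[[subject$subject_id]] <- list(subject = subject, phys = p,
                                        oral = oral, igivi = igivi)
    }
  }
  structure(out, class = "simulated_cohort", seed = cfg$seed)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  grp <- table(vapply(x, function(s) s$subject$group, ""))
  cat(sprintf("<simulated_cohort> %d subjects (%s), seed %d\n", length(x),
              paste(names(grp), grp, sep = "=", collapse = ", "),
              attr(x, "seed")))
  invisible(x)
}
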