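#' Insulin-normalised glucose clearance (MCR/I)
#'
#' Pointwise MCR/I(t) = 1000 (Rd / G) / I in ml min-1 kg-1 per nmol/l (the
#' factor 1000 converts the per-pmol/l value); segment values are
#' time-averages (AUC over window width) with insulin linearly interpolated
#' onto the flux grid.
#'
#' @param rd vector Rd on \code{times}, umol kg-1 min-1.
#' @param times flux grid, min.
#' @param glucose glucose \code{sampling_series} (mmol/l).
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @param window averaging window, min (default one segment or the session).
#' @param glucose_values optional reconstructed glucose on the flux grid
#'   (e.g. the flux chain's detrended spline, which restores the known
#'   infusion-driven intra-block structure of intravenous sessions);
#'   default a spline through the measured samples.
#' @return time-averaged MCR/I over the window.
#' @export
mcr_i <- function(rd, times, glucose, insulin, window = c(0, 360),
                  glucose_values = NULL) {
  stopifnot(identical(glucose$unit, "mmol/l"),
            identical(insulin$unit, "pmol/l"))
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 2) stop("window outside flux grid")
  tt <- times[keep]
  G <- if (is.null(glucose_values))
    interp_series(glucose, tt) else glucose_values[keep]
  I <- interp_series(insulin, tt)
  if (any(I <= 0)) stop("non-positive insulin in MCR/I window")
  v <- 1000 * (rd[keep] / G) / I
  trapz(tt, v) / diff(range(tt))
}

interp_series <- function(series, tt) {
  stats::approx(series$times, series$values, xout = tt, rule = 2)$y
}

#' Hepatic insulin resistance index (EGP x insulin)
#'
#' Pointwise product of EGP and circulating insulin, plus its time-average
#' over a window.
#'
#' @param egp vector EGP on \code{times}, umol kg-1 min-1.
#' @param times flux grid, min.
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @param window averaging window, min.
#' @return list with \code{series} (pointwise product) and \code{mean}.
#' @export
hepatic_ir <- function(egp, times, insulin, window = c(0, 360)) {
  stopifnot(identical(insulin$unit, "pmol/l"))
  keep <- times >= window[1] & times <= window[2]
  tt <- times[keep]
  I <- interp_series(insulin, tt)
  v <- egp[keep] * I
  list(times = tt, series = v, mean = trapz(tt, v) / diff(range(tt)))
}

#' Insulinogenic index
#'
#' Ratio of the incremental insulin AUC to the incremental glucose AUC over
#' a window (basal levels from the fasting samples).
#'
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @param glucose glucose \code{sampling_series} (mmol/l).
#' @param window minutes.
#' @return dimensionless ratio (pmol per mmol).
#' @export
insulinogenic_index <- function(insulin, glucose, window = c(0, 360)) {
  stopifnot(identical(insulin$unit, "pmol/l"),
            identical(glucose$unit, "mmol/l"))
  dg <- auc(glucose, window, incremental = TRUE)
  if (abs(dg) < 1e-12) stop("incremental glucose AUC is zero")
  auc(insulin, window, incremental = TRUE) / dg
}

#' Insulin clearance (secretion-to-exposure with volume correction)
#'
#' CL = AUC_ISR / AUC_I - V (I_end - I_0) / AUC_I with the insulin
#' distribution volume V = 0.14 l/kg x weight; computed over the full
#' session by default, or any window (e.g. one segment).
#'
#' @param isr an \code{isr_deconvolution} (pmol/min).
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @param weight kg.
#' @param window minutes.
#' @return clearance, l/min.
#' @export
insulin_clearance <- function(isr, insulin, weight, window = c(0, 360)) {
  stopifnot(identical(insulin$unit, "pmol/l"))
  V <- 0.14 * weight
  auc_isr <- total_isr(isr, window) * diff(window)        # pmol
  auc_i <- auc(insulin, window)                           # pmol/l * min
  i0 <- stats::approx(insulin$times, insulin$values, xout = window[1],
                      rule = 2)$y
  i1 <- stats::approx(insulin$times, insulin$values, xout = window[2],
                      rule = 2)$y
  auc_isr / auc_i - V * (i1 - i0) / auc_i
}

#' Disposition index
#'
#' Pointwise product of ISR and MCR/I on a common grid, time-averaged over
#' the window.
#'
#' @param isr an \code{isr_deconvolution}.
#' @param rd,times,glucose,insulin as in \code{\link{mcr_i}}.
#' @param window minutes.
#' @return DI, ml min-1 kg-1 (nmol/l)-1 pmol/min.
#' @export
disposition_index <- function(isr, rd, times, glucose, insulin,
                              window = c(0, 360), glucose_values = NULL) {
  keep <- times >= window[1] & times <= window[2]
  tt <- times[keep]
  G <- if (is.null(glucose_values))
    interp_series(glucose, tt) else glucose_values[keep]
  I <- interp_series(insulin, tt)
  if (any(I <= 0)) stop("non-positive insulin in DI window")
  mcr_t <- 1000 * (rd[keep] / G) / I
  isr_t <- predict(isr, tt)
  v <- mcr_t * isr_t
  trapz(tt, v) / diff(range(tt))
}

#' Adipose tissue insulin resistance index
#'
#' Sum of the session-mean concentrations of the configured fatty-acid
#' species multiplied by the session-mean insulin.
#'
#' @param metabolites named list of \code{sampling_series}.
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @param fa_names fatty-acid species to sum (default the five species the
#'   study highlights).
#' @param window minutes.
#' @return Adipo-IR, (fatty-acid units) x pmol/l.
#' @export
adipo_ir <- function(metabolites, insulin,
                     fa_names = c("palmitic", "oleic", "stearic",
                                  "linoleic", "myristic"),
                     window = c(0, 360)) {
  if (length(fa_names) == 0) stop("empty fatty-acid list")
  missing_fa <- setdiff(fa_names, names(metabolites))
  if (length(missing_fa) > 0)
    stop("fatty-acid series missing: ", paste(missing_fa, collapse = ", "))
  width <- diff(window)
  fa_mean <- sum(vapply(fa_names, function(nm)
    auc(metabolites[[nm]], window) / width, 0))
  i_mean <- auc(insulin, window) / width
  fa_mean * i_mean
}

#' Required sample size for a two-group mean comparison
#'
#' Normal-approximation two-sample formula
#' n = 2 (z_{1-alpha/2} + z_{1-beta})^2 sigma^2 / delta^2 per group
#' (ceiling), doubled, then inflated by dividing by (1 - attrition) and
#' rounding up. With the study's inputs (means 4.6 vs 5.98, SD 0.9,
#' alpha 0.05, power 0.90, attrition 0.25) this returns 24 participants.
#'
#' @param mean_a,mean_b group means.
#' @param sd common standard deviation.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param attrition anticipated attrition fraction in [0, 1).
#' @return total required N (integer).
#' @export
required_sample_size <- function(mean_a, mean_b, sd, alpha = 0.05,
                                 power = 0.90, attrition = 0) {
  stopifnot(attrition >= 0, attrition < 1, sd > 0)
  delta <- abs(mean_b - mean_a)
  if (delta == 0) stop("zero effect size")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_group <- ceiling(2 * z^2 * sd^2 / delta^2)
  n_group <- max(n_group, 1L)
  total <- 2 * n_group
  as.integer(ceiling(total / (1 - attrition)))
}

#' Full index panel for one analysed session
#'
#' Computes every closed-form index of the study for one session: MCR/I per
#' segment and their mean (the headline value) plus the full-session
#' average, hepatic insulin resistance, insulinogenic index, insulin
#' clearance (session and per segment), disposition index, and Adipo-IR.
#'
#' @param session a \code{session_record}.
#' @param flux a \code{flux_result} for the session.
#' @param isr an \code{isr_deconvolution} for the session.
#' @return object of class \code{index_panel}.
#' @export
index_panel <- function(session, flux, isr) {
  segs <- segments()
  wins <- lapply(segs, `[[`, "window")
  gv <- flux$glucose_smooth
  mcr_seg <- vapply(wins, function(w)
    mcr_i(flux$rd, flux$times, session$glucose, session$insulin, w,
          glucose_values = gv), 0)
  di_seg <- vapply(wins, function(w)
    disposition_index(isr, flux$rd, flux$times, session$glucose,
                      session$insulin, w, glucose_values = gv), 0)
  cl_seg <- vapply(wins, function(w)
    insulin_clearance(isr, session$insulin, session$subject$weight, w), 0)
  isr_seg <- vapply(wins, function(w) total_isr(isr, w), 0)
  hir <- hepatic_ir(flux$egp, flux$times, session$insulin)
  structure(list(
    subject_id = session$subject$subject_id,
    group = session$subject$group, route = session$route,
    mcr_i_segments = mcr_seg, mcr_i = mean(mcr_seg),
    mcr_i_session = mcr_i(flux$rd, flux$times, session$glucose,
                          session$insulin, glucose_values = gv),
    hepatic_ir = hir$mean,
    insulinogenic_index = insulinogenic_index(session$insulin,
                                              session$glucose),
    insulin_clearance = insulin_clearance(isr, session$insulin,
                                          session$subject$weight),
    insulin_clearance_segments = cl_seg,
    di_segments = di_seg, di = mean(di_seg),
    isr_segments = isr_seg, isr_mean = total_isr(isr),
    adipo_ir = adipo_ir(session$metabolites, session$insulin)),
    class = "index_panel")
}

#' @export
print.index_panel <- function(x, ...) {
  cat(sprintf("<index_panel> %s (%s), %s route\n", x$subject_id, x$group,
              x$route))
  cat(sprintf("  MCR/I %.2f (segments %s) ml/min/kg per nmol/l\n",
              x$mcr_i, paste(signif(x$mcr_i_segments, 3), collapse = ", ")))
  cat(sprintf("  mean ISR %.0f pmol/min; clearance %.2f l/min; DI %.0f\n",
              x$isr_mean, x$insulin_clearance, x$di))
  cat(sprintf("  hepatic IR %.0f; insulinogenic %.1f; Adipo-IR %.0f\n",
              x$hepatic_ir, x$insulinogenic_index, x$adipo_ir))
  invisible(x)
}

#' @export
as.data.frame.index_panel <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, route = x$route,
             mcr_i = x$mcr_i, mcr_i_session = x$mcr_i_session,
             hepatic_ir = x$hepatic_ir,
             insulinogenic_index = x$insulinogenic_index,
             insulin_clearance = x$insulin_clearance,
             di = x$di, isr_mean = x$isr_mean, adipo_ir = x$adipo_ir,
             stringsAsFactors = FALSE)
}
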