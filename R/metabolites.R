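#' Fit an exponential decay to a metabolite series
#'
#' Nonlinear least squares of C(t) = C0 exp(-beta t) over a window, with the
#' standard error of beta from the asymptotic covariance. For near-noiseless
#' data this agrees with the log-linear regression slope (cross-checked in
#' the test-suite). The default window is the full 0-360 min record; with
#' \code{from_peak = TRUE} the fit starts at the series maximum inside the
#' window instead.
#'
#' @param series a \code{sampling_series} with positive values.
#' @param window minutes.
#' @param from_peak start the fit at the in-window maximum?
#' @return object of class \code{decay_fit} with \code{c0}, \code{beta}
#'   (1/min), \code{se}, \code{window}.
#' @export
fit_decay <- function(series, window = c(0, 360), from_peak = FALSE) {
  keep <- series$times >= window[1] & series$times <= window[2]
  tt <- series$times[keep]; vv <- series$values[keep]
  if (from_peak) {
    p <- which.max(vv)
    tt <- tt[p:length(tt)]; vv <- vv[p:length(vv)]
  }
  if (length(tt) < 4) stop("need at least 4 points to fit a decay")
  if (any(vv <= 0)) stop("non-positive values in decay window for '",
                         series$analyte, "'")
  t0 <- tt - tt[1]
  ll <- stats::lm(log(vv) ~ t0)
  start <- list(c0 = exp(stats::coef(ll)[[1]]),
                beta = -stats::coef(ll)[[2]])
  fit <- tryCatch(
    stats::nls(vv ~ c0 * exp(-beta * t0), start = start,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["beta"]],
                   error = function(e) NA_real_)
    fitted_v <- stats::fitted(fit)
  } else {
    ## degenerate cases (e.g. an exactly constant series gives nls a
    ## singular gradient): fall back to the log-linear estimator, whose
    ## slope SE is the asymptotic SE of beta
    est <- c(c0 = start$c0, beta = start$beta)
    se <- summary(ll)$coefficients["t0", "Std. Error"]
    fitted_v <- start$c0 * exp(-start$beta * t0)
  }
  structure(list(analyte = series$analyte, c0 = est[["c0"]],
                 beta = est[["beta"]], se = se,
                 window = c(tt[1], tt[length(tt)]),
                 times = tt, observed = vv,
                 fitted = fitted_v),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: beta %.5g 1/min (SE %.2g), C0 %.4g on [%g, %g]\n",
              x$analyte, x$beta, x$se, x$c0, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(c0 = object$c0, beta = object$beta)
}

#' Insulin-normalised decay coefficient
#'
#' beta divided by the session-mean insulin over the fit window.
#'
#' @param fit a \code{decay_fit}.
#' @param insulin insulin \code{sampling_series} (pmol/l).
#' @return beta_norm, 1/min per pmol/l.
#' @export
normalize_beta <- function(fit, insulin) {
  w <- fit$window
  fit$beta / (auc(insulin, w) / diff(w))
}

#' Z-test comparing two decay coefficients
#'
#' z = (beta_a - beta_b) / sqrt(SE_a^2 + SE_b^2), two-sided p from the
#' standard normal.
#'
#' @param fit_a,fit_b \code{decay_fit} objects (or lists with \code{beta},
#'   \code{se}).
#' @return list with \code{z} and \code{p}.
#' @export
ztest_betas <- function(fit_a, fit_b) {
  z <- (fit_a$beta - fit_b$beta) / sqrt(fit_a$se^2 + fit_b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Percentage change from baseline
#'
#' 100 (C_final - C_baseline) / C_baseline with C_final the last sample and
#' C_baseline the basal (t <= 0) mean.
#'
#' @param series a \code{sampling_series}.
#' @return percent change.
#' @export
percent_delta <- function(series) {
  base <- basal_value(series)
  if (base <= 0) stop("non-positive baseline in percent_delta")
  100 * (series$values[length(series$values)] - base) / base
}

#' Assemble the group x procedure x segment feature matrix
#'
#' Rows are metabolites, columns the 18 cells (3 glycaemic groups x 2
#' procedures x 3 segments) of per-cell mean concentrations; rows are
#' z-scored (sample-SD convention by default) and ordered by hierarchical
#' clustering (euclidean distance, complete linkage). Significance flags
#' arrive as input (the mixed-effects stage producing them is upstream) and
#' filter the rows.
#'
#' @param cell_means numeric matrix, metabolites x 18 columns named
#'   \code{group_procedure_segment}.
#' @param significant optional logical vector per row; rows flagged FALSE
#'   are dropped.
#' @param sd_convention \code{"sample"} (ddof = 1, default) or
#'   \code{"population"}.
#' @param cluster_rows order rows by hierarchical clustering?
#' @return object of class \code{feature_matrix} with the z-scored matrix,
#'   row order and the clustering parameters used.
#' @export
heatmap_matrix <- function(cell_means, significant = NULL,
                           sd_convention = c("sample", "population"),
                           cluster_rows = TRUE) {
  sd_convention <- match.arg(sd_convention)
  m <- as.matrix(cell_means)
  if (!is.null(significant)) m <- m[significant, , drop = FALSE]
  zrow <- function(v) {
    s <- if (sd_convention == "sample") stats::sd(v)
         else sqrt(mean((v - mean(v))^2))
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z <- t(apply(m, 1, zrow))
  dimnames(z) <- dimnames(m)
  ord <- seq_len(nrow(z))
  if (cluster_rows && nrow(z) > 2) {
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
    ord <- hc$order
  }
  structure(list(z = z[ord, , drop = FALSE], row_order = ord,
                 sd_convention = sd_convention,
                 clustering = list(distance = "euclidean",
                                   linkage = "complete",
                                   applied = cluster_rows)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d metabolites x %d cells (z-scored, %s SD)\n",
              nrow(x$z), ncol(x$z), x$sd_convention))
  invisible(x)
}

#' Per-cell metabolite means of a simulated cohort
#'
#' Mean concentration of every metabolite per (group, procedure, segment)
#' cell, averaged first over each subject's segment window then across the
#' subjects of the group. Column names follow group_procedure_segment.
#'
#' @param cohort a \code{simulated_cohort}.
#' @return numeric matrix, metabolites x 18.
#' @export
metabolite_cell_means <- function(cohort) {
  mets <- names(cohort[[1]]$oral$session$metabolites)
  groups <- c("NGT", "IGT", "T2D")
  routes <- c("oral", "igivi")
  cols <- as.vector(outer(outer(groups, routes, paste, sep = "_"),
                          paste0("T", 1:3), paste, sep = "_"))
  out <- matrix(NA_real_, nrow = length(mets), ncol = length(cols),
                dimnames = list(mets, cols))
  for (g in groups) for (r in routes) for (s in 1:3) {
    col <- paste(g, r, paste0("T", s), sep = "_")
    win <- segments(s)$window
    subj <- Filter(function(e) e$subject$group == g, cohort)
    vals <- sapply(mets, function(m)
      mean(vapply(subj, function(e)
        auc(e[[r]]$session$metabolites[[m]], win) / diff(win), 0)))
    out[, col] <- vals
  }
  out
}

#' Group-mean decay fits per metabolite and procedure
#'
#' Averages each metabolite's curve across the subjects of a glycaemic
#' group (the default fitting mode), then fits the exponential decay per
#' procedure. Per-participant mode fits each subject separately and is
#' available via \code{per_subject = TRUE}.
#'
#' @param cohort a \code{simulated_cohort}.
#' @param metabolite metabolite name (or \code{"amino_acids"} for the summed
#'   amino-acid series).
#' @param group \code{"NGT"}, \code{"IGT"}, \code{"T2D"} or \code{"all"}.
#' @param per_subject fit each participant separately?
#' @param aa_names amino-acid species summed by \code{"amino_acids"}.
#' @return for group-mean mode a list with \code{oral} and \code{igivi}
#'   \code{decay_fit}s; for per-subject mode a list of such pairs.
#' @export
cohort_decay_fits <- function(cohort, metabolite = "lactate", group = "all",
                              per_subject = FALSE,
                              aa_names = c("isoleucine", "leucine", "valine",
                                           "threonine", "methionine")) {
  subj <- if (group == "all") cohort
          else Filter(function(e) e$subject$group == group, cohort)
  get_series <- function(entry, route) {
    mets <- entry[[route]]$session$metabolites
    if (metabolite == "amino_acids") {
      tt <- mets[[aa_names[1]]]$times
      vv <- Reduce(`+`, lapply(aa_names, function(a) mets[[a]]$values))
      sampling_series("amino_acids", tt, vv, mets[[aa_names[1]]]$unit)
    } else mets[[metabolite]]
  }
  if (per_subject) {
    return(lapply(subj, function(e)
      list(oral = fit_decay(get_series(e, "oral")),
           igivi = fit_decay(get_series(e, "igivi")))))
  }
  mean_series <- function(route) {
    ser <- lapply(subj, get_series, route = route)
    tt <- ser[[1]]$times
    vv <- Reduce(`+`, lapply(ser, `[[`, "values")) / length(ser)
    sampling_series(metabolite, tt, vv, ser[[1]]$unit)
  }
  list(oral = fit_decay(mean_series("oral")),
       igivi = fit_decay(mean_series("igivi")))
}
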