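#' Sampled concentration time series
#'
#' Container for one analyte measured on a sampling grid. Times are minutes
#' relative to the first glucose load; the basal (fasting) period occupies
#' negative times down to -150 min. Values must be non-negative
#' concentrations; the unit travels with the series as a string and is checked
#' by consumers, never silently converted.
#'
#' @param analyte name of the analyte (e.g. \code{"glucose"}).
#' @param times sampling times in minutes, strictly increasing.
#' @param values concentrations, same length as \code{times}, all \code{>= 0}.
#' @param unit unit string (e.g. \code{"mmol/l"}, \code{"pmol/l"}).
#' @return An object of class \code{sampling_series}.
#' @export
sampling_series <- function(analyte, times, values, unit) {
  stopifnot(is.character(analyte), length(analyte) == 1L)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0))
    stop("non-monotone times in series '", analyte, "'")
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop("negative or non-finite values in series '", analyte, "'")
  structure(list(analyte = analyte, times = times,
                 values = pmax(values, 0), unit = unit),
            class = "sampling_series")
}

#' @export
print.sampling_series <- function(x, ...) {
  cat(sprintf("<sampling_series> %s [%s], %d samples on [%g, %g] min\n",
              x$analyte, x$unit, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Tracer-to-tracee ratio series
#'
#' Plasma enrichment of one glucose tracer species expressed as the
#' dimensionless tracer-to-tracee ratio (TTR). Ratios must stay below 0.2;
#' a basal-plateau mean below 1\% is flagged (quality gate, not an error).
#'
#' @param species \code{"D2"} for the infused dideuterated tracer or
#'   \code{"C13"} for the orally ingested uniformly labelled tracer.
#' @param times sampling times in minutes.
#' @param ttr tracer-to-tracee ratios, \code{0 <= ttr < 0.2}.
#' @return An object of class \code{tracer_series} with a logical
#'   \code{low_enrichment} quality flag (TRUE when the basal-plateau mean
#'   TTR falls below 0.01).
#' @export
tracer_series <- function(species, times, ttr) {
  species <- match.arg(species, c("D2", "C13"))
  times <- as.numeric(times); ttr <- as.numeric(ttr)
  if (length(times) != length(ttr)) stop("times and ttr must have equal length")
  if (any(diff(times) <= 0)) stop("non-monotone times in tracer series")
  if (any(ttr < -1e-9)) stop("negative TTR")
  if (any(ttr >= 0.2)) stop("TTR >= 0.2: implausible enrichment")
  ttr <- pmax(ttr, 0)
  basal <- ttr[times <= 0]
  low <- length(basal) > 0 && species == "D2" && mean(basal) < 0.01
  structure(list(species = species, times = times, ttr = ttr,
                 low_enrichment = low),
            class = "tracer_series")
}

#' @export
print.tracer_series <- function(x, ...) {
  cat(sprintf("<tracer_series> %s, %d samples, mean TTR %.4f%s\n",
              x$species, length(x$times), mean(x$ttr),
              if (isTRUE(x$low_enrichment)) " [low enrichment]" else ""))
  invisible(x)
}

#' Basal (fasting) value of a series
#'
#' The mean of all samples at \code{t <= 0}.
#'
#' @param series a \code{sampling_series}.
#' @return numeric scalar.
#' @export
basal_value <- function(series) {
  idx <- series$times <= 0
  if (!any(idx)) stop("no basal samples (t <= 0) in series '",
                      series$analyte, "'")
  mean(series$values[idx])
}

#' Trapezoidal area under the curve
#'
#' Integrates a sampled series over a time window by the trapezoidal rule,
#' linearly interpolating the window endpoints when they fall between samples.
#' The incremental variant subtracts \code{basal * (t1 - t0)} and may be
#' negative unless \code{floor_zero} is set.
#'
#' @param series a \code{sampling_series}.
#' @param window numeric length-2, \code{c(t0, t1)} in minutes.
#' @param incremental subtract the basal value times the window length?
#' @param basal basal level used by the incremental variant; defaults to
#'   \code{basal_value(series)}.
#' @param floor_zero floor an incremental AUC at zero (default off).
#' @return AUC in unit·min.
#' @export
auc <- function(series, window, incremental = FALSE, basal = NULL,
                floor_zero = FALSE) {
  stopifnot(inherits(series, "sampling_series"), length(window) == 2L)
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stop("empty or reversed AUC window")
  tt <- series$times; vv <- series$values
  if (t0 < tt[1] || t1 > tt[length(tt)])
    stop("AUC window [", t0, ", ", t1, "] outside sampled range of '",
         series$analyte, "'")
  inside <- tt > t0 & tt < t1
  xs <- c(t0, tt[inside], t1)
  ys <- stats::approx(tt, vv, xout = xs, rule = 1)$y
  if (sum(inside) + 2L < 2L) stop("fewer than 2 points in AUC window")
  a <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  if (incremental) {
    if (is.null(basal)) basal <- basal_value(series)
    a <- a - basal * (t1 - t0)
    if (floor_zero) a <- max(a, 0)
  }
  a
}

#' Smooth a series and take its first derivative
#'
#' Fits a cubic spline to the samples and evaluates the curve and its analytic
#' first derivative on a 1-min grid. With \code{lambda = 0} the spline
#' interpolates every sample (natural cubic spline); with \code{lambda > 0} a
#' penalised smoothing spline is used; with \code{lambda = NULL} the smoothing
#' weight is chosen by generalised cross-validation (appropriate for noisy
#' measurements).
#'
#' @param series a \code{sampling_series} or \code{tracer_series}.
#' @param lambda smoothing weight (0 = interpolate, NULL = GCV).
#' @param grid evaluation grid in minutes; default a 1-min grid spanning the
#'   samples.
#' @return list with \code{times}, \code{values}, \code{deriv} (per minute)
#'   and \code{fun}/\code{dfun} evaluator functions.
#' @export
smooth_and_differentiate <- function(series, lambda = 0, grid = NULL) {
  if (inherits(series, "tracer_series")) {
    tt <- series$times; vv <- series$ttr
  } else {
    tt <- series$times; vv <- series$values
  }
  smooth_raw(tt, vv, lambda = lambda, grid = grid)
}

## internal workhorse: spline arbitrary (possibly negative, e.g. detrended)
## sampled values and return curve + analytic first derivative
smooth_raw <- function(tt, vv, lambda = 0, grid = NULL) {
  if (length(tt) < 5L) stop("need at least 5 samples to smooth")
  if (is.null(grid)) grid <- seq(tt[1], tt[length(tt)], by = 1)
  if (!is.null(lambda) && lambda == 0) {
    f <- stats::splinefun(tt, vv, method = "natural")
    fun <- function(t) f(t)
    dfun <- function(t) f(t, deriv = 1L)
  } else {
    ss <- if (is.null(lambda))
      stats::smooth.spline(tt, vv, cv = FALSE)
    else
      stats::smooth.spline(tt, vv, lambda = lambda)
    fun <- function(t) stats::predict(ss, t)$y
    dfun <- function(t) stats::predict(ss, t, deriv = 1L)$y
  }
  list(times = grid, values = fun(grid), deriv = dfun(grid),
       fun = fun, dfun = dfun)
}

#' The three 120-min load segments
#'
#' The triple sequential protocol partitions 0-360 min into three windows,
#' one per increasing glucose load.
#'
#' @param index optional 1, 2 or 3 to return one segment.
#' @return list of segments, each \code{list(index, window)}, or one segment.
#' @export
segments <- function(index = NULL) {
  segs <- list(list(index = 1L, window = c(0, 120)),
               list(index = 2L, window = c(120, 240)),
               list(index = 3L, window = c(240, 360)))
  if (is.null(index)) return(segs)
  stopifnot(index %in% 1:3)
  segs[[index]]
}
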