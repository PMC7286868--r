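#' Two-compartment C-peptide kinetics
#'
#' Population parameterisation of C-peptide distribution and degradation:
#' the post-bolus plasma decay is the biexponential
#' F e^(-lambda1 t) + (1-F) e^(-lambda2 t); the rate constants of the
#' underlying two-compartment system follow by algebraic inversion:
#' k12 = (1-F) lambda1 + F lambda2, k01 = lambda1 lambda2 / k12,
#' k21 = lambda1 + lambda2 - k01 - k12.
#'
#' @param t_half_short short-component half-life, min.
#' @param t_half_long long-component half-life, min.
#' @param fraction amplitude fraction of the short component, in (0,1).
#' @param V1 central distribution volume, litres.
#' @return object of class \code{cpeptide_kinetics} with the derived
#'   \code{lambda1}, \code{lambda2}, \code{k01}, \code{k12}, \code{k21}.
#' @export
cpeptide_kinetics <- function(t_half_short, t_half_long, fraction, V1) {
  stopifnot(t_half_short < t_half_long, fraction > 0, fraction < 1, V1 > 0)
  l1 <- log(2) / t_half_short
  l2 <- log(2) / t_half_long
  k12 <- (1 - fraction) * l1 + fraction * l2
  k01 <- l1 * l2 / k12
  k21 <- l1 + l2 - k01 - k12
  if (min(k01, k12, k21) <= 0) stop("derived rate constants must be positive")
  structure(list(t_half_short = t_half_short, t_half_long = t_half_long,
                 fraction = fraction, V1 = V1,
                 lambda1 = l1, lambda2 = l2,
                 k01 = k01, k12 = k12, k21 = k21),
            class = "cpeptide_kinetics")
}

#' @export
print.cpeptide_kinetics <- function(x, ...) {
  cat(sprintf(paste0("<cpeptide_kinetics> t1/2 %.2f/%.1f min, F=%.2f, ",
                     "V1=%.2f l (k01=%.4f k12=%.4f k21=%.4f 1/min)\n"),
              x$t_half_short, x$t_half_long, x$fraction, x$V1,
              x$k01, x$k12, x$k21))
  invisible(x)
}

#' Population C-peptide kinetics for a subject
#'
#' Maps a subject to the standard population parameter set: obese
#' (4.55, 33.1, 0.78), type 2 diabetes (4.52, 35.1, 0.78) or lean normal
#' (4.95, 29.2, 0.76) as (short half-life, long half-life, short fraction);
#' V1 scales with DuBois body surface area. All study participants are
#' obese, so NGT/IGT map to the obese set and T2D to the diabetic set; the
#' lean set is retained for generality.
#'
#' @param subject a \code{subject_profile}.
#' @param set parameter set: \code{"auto"} (by group and BMI),
#'   \code{"obese"}, \code{"t2d"} or \code{"lean"}.
#' @param v1_per_bsa central-volume scaling constant, l/m2.
#' @return a \code{cpeptide_kinetics}.
#' @export
population_kinetics <- function(subject, set = "auto", v1_per_bsa = 2.1) {
  set <- match.arg(set, c("auto", "obese", "t2d", "lean"))
  if (set == "auto")
    set <- if (subject$group == "T2D") "t2d"
           else if (subject$bmi >= 30) "obese" else "lean"
  par <- switch(set,
                obese = c(4.55, 33.1, 0.78),
                t2d   = c(4.52, 35.1, 0.78),
                lean  = c(4.95, 29.2, 0.76))
  cpeptide_kinetics(par[1], par[2], par[3],
                    V1 = v1_per_bsa * body_surface_area(subject))
}

#' Impulse response of the C-peptide system
#'
#' Central-compartment concentration (nmol/l) following a unit input of
#' 1 pmol into the central compartment.
#'
#' @param kin a \code{cpeptide_kinetics}.
#' @param t times since the impulse, min.
#' @return concentrations, nmol/l per pmol.
#' @export
cpeptide_impulse_response <- function(kin, t) {
  (kin$fraction * exp(-kin$lambda1 * t) +
     (1 - kin$fraction) * exp(-kin$lambda2 * t)) / (1000 * kin$V1)
}

#' Basal insulin secretion rate at C-peptide equilibrium
#'
#' @param kin a \code{cpeptide_kinetics}.
#' @param cp_basal basal C-peptide, nmol/l.
#' @return ISR, pmol/min (= k01 V1 CP_b in consistent units).
#' @export
basal_isr <- function(kin, cp_basal) 1000 * kin$k01 * kin$V1 * cp_basal

## Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x>=0.
## Small dense problems only (the deconvolution design is ~25 columns).
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.solve(Ap, b)
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

## Integral of the impulse response over [t-a, t-b] expressed analytically;
## design entry for piecewise-constant input on [s0, s1) observed at t.
ir_integral <- function(kin, t, s0, s1) {
  s1 <- pmin(s1, t)
  out <- numeric(length(t))
  ok <- s1 > s0 & t > s0
  if (!any(ok)) return(out)
  f <- kin$fraction; l1 <- kin$lambda1; l2 <- kin$lambda2
  tt <- t[ok]; a0 <- pmax(s0, -Inf)
  e <- function(l) (exp(-l * (tt - s1[ok])) - exp(-l * (tt - a0))) / l
  out[ok] <- (f * e(l1) + (1 - f) * e(l2)) / (1000 * kin$V1)
  out
}

#' Deconvolve the insulin secretion rate from C-peptide
#'
#' Represents ISR as a non-negative piecewise-constant function on the
#' sampling intervals and minimises
#' ||predicted - observed C-peptide||^2 + reg ||delta ISR||^2 subject to
#' ISR >= 0 (regularised non-negative least squares, solved by an active-set
#' method). The system starts at basal equilibrium with
#' ISR_b = k01 V1 CP_b.
#'
#' @param cpeptide a \code{sampling_series} in nmol/l with basal samples.
#' @param kin a \code{cpeptide_kinetics}.
#' @param reg first-difference regularisation weight (default 0.25, chosen
#'   by L-curve on synthetic fixtures and frozen).
#' @return object of class \code{isr_deconvolution} with knot times,
#'   piecewise-constant \code{isr} (pmol/min), fitted C-peptide and
#'   residuals.
#' @export
deconvolve_isr <- function(cpeptide, kin, reg = 0.25) {
  stopifnot(inherits(cpeptide, "sampling_series"),
            inherits(kin, "cpeptide_kinetics"))
  cp_b <- basal_value(cpeptide)
  keep <- cpeptide$times >= 0
  t_obs <- cpeptide$times[keep]
  y <- cpeptide$values[keep]
  if (length(t_obs) < 3) stop("need at least 3 post-load C-peptide samples")
  knots <- t_obs
  n <- length(knots) - 1L          # intervals [knots_j, knots_{j+1})
  isr_b <- basal_isr(kin, cp_b)
  ## suprabasal response: CP(t) = cp_b + sum_j A_ij (x_j - isr_b)
  A <- matrix(0, nrow = length(t_obs), ncol = n)
  for (j in seq_len(n))
    A[, j] <- ir_integral(kin, t_obs, knots[j], knots[j + 1L])
  b <- y - cp_b + as.numeric(A %*% rep(isr_b, n))
  D <- diff(diag(n))
  scale_reg <- sqrt(reg) * mean(abs(A)[abs(A) > 0])
  Astack <- rbind(A, scale_reg * D)
  bstack <- c(b, numeric(nrow(D)))
  x <- nnls_solve(Astack, bstack)
  fitted <- cp_b + as.numeric(A %*% (x - isr_b))
  res <- y - fitted
  if (sqrt(mean(res^2)) > 0.5 * max(stats::sd(y), 1e-6))
    stop("deconvolution failed to converge; residual RMS ",
         signif(sqrt(mean(res^2)), 3), " nmol/l")
  structure(list(knots = knots, isr = x, isr_basal = isr_b,
                 times = t_obs, observed = y, fitted = fitted,
                 residuals = res, kinetics = kin, reg = reg),
            class = "isr_deconvolution")
}

#' @export
print.isr_deconvolution <- function(x, ...) {
  cat(sprintf(paste0("<isr_deconvolution> %d intervals on [%g, %g] min; ",
                     "basal ISR %.0f pmol/min; residual RMS %.4f nmol/l\n"),
              length(x$isr), min(x$knots), max(x$knots), x$isr_basal,
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
fitted.isr_deconvolution <- function(object, ...) object$fitted

#' @export
residuals.isr_deconvolution <- function(object, ...) object$residuals

#' ISR value at arbitrary times (piecewise constant)
#'
#' @param object an \code{isr_deconvolution}.
#' @param t times, min.
#' @param ... unused.
#' @return ISR, pmol/min.
#' @export
predict.isr_deconvolution <- function(object, t, ...) {
  idx <- findInterval(t, object$knots, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(object$isr))
  object$isr[idx]
}

#' Time-averaged ISR over a window
#'
#' @param res an \code{isr_deconvolution}.
#' @param window length-2 window in minutes (default one of the three
#'   protocol segments via \code{\link{segments}}).
#' @return mean ISR, pmol/min.
#' @export
total_isr <- function(res, window = c(0, 360)) {
  t0 <- max(window[1], min(res$knots)); t1 <- min(window[2], max(res$knots))
  if (t1 <= t0) stop("window outside deconvolution support")
  lo <- pmax(utils::head(res$knots, -1), t0)
  hi <- pmin(utils::tail(res$knots, -1), t1)
  w <- pmax(hi - lo, 0)
  sum(res$isr * w) / sum(w)
}
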