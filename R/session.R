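#' Subject profile
#'
#' Anthropometrics and fasting levels for one participant. The study
#' population is morbidly obese (BMI > 30 kg/m2); the constructor enforces
#' that by default but can be relaxed for non-study cohorts.
#'
#' @param subject_id opaque identifier.
#' @param group glycaemic group: \code{"NGT"}, \code{"IGT"} or \code{"T2D"}.
#' @param age years.
#' @param weight kg.
#' @param bmi kg/m2.
#' @param basal_glucose mmol/l.
#' @param basal_insulin pmol/l.
#' @param basal_cpeptide nmol/l.
#' @param require_obese enforce BMI > 30 (study inclusion criterion).
#' @return object of class \code{subject_profile}.
#' @export
subject_profile <- function(subject_id, group, age, weight, bmi,
                            basal_glucose, basal_insulin, basal_cpeptide,
                            require_obese = TRUE) {
  group <- match.arg(group, c("NGT", "IGT", "T2D"))
  if (weight <= 0) stop("weight must be positive")
  if (require_obese && bmi <= 30)
    stop("BMI must exceed 30 kg/m2 for the study population")
  if (basal_glucose < 0 || basal_insulin < 0 || basal_cpeptide < 0)
    stop("basal concentrations must be non-negative")
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = age, weight = weight, bmi = bmi,
                 basal_glucose = basal_glucose,
                 basal_insulin = basal_insulin,
                 basal_cpeptide = basal_cpeptide),
            class = "subject_profile")
}

#' Body surface area (DuBois)
#'
#' Height is recovered from weight and BMI; BSA uses the DuBois formula.
#'
#' @param subject a \code{subject_profile}.
#' @return BSA in m2.
#' @export
body_surface_area <- function(subject) {
  height_m <- sqrt(subject$weight / subject$bmi)
  0.007184 * subject$weight^0.425 * (height_m * 100)^0.725
}

#' Tracer and glucose infusion schedule
#'
#' Describes every exogenous glucose input of a session: the primed-constant
#' deuterated-tracer infusion, the oral loads (with their oral tracer spikes),
#' and for the intravenous session the piecewise-constant variable dextrose
#' infusion with its deuterated enrichment. Exactly one of
#' \code{oral_loads} / \code{dextrose_rates} may be non-empty.
#'
#' @param tracer_prime priming dose, umol/kg (default 22).
#' @param tracer_rate constant infusion, umol kg-1 min-1 (default 0.22).
#' @param oral_loads data.frame with columns \code{time} (min), \code{dose_g},
#'   \code{tracer_g}; default the triple 25/75/100 g protocol, each load
#'   spiked with 0.9 g of labelled glucose.
#' @param dextrose_rates data.frame with columns \code{time} (min, 10-min
#'   breakpoints) and \code{rate} (umol kg-1 min-1), piecewise-constant from
#'   each breakpoint to the next; NULL for oral sessions.
#' @param dextrose_enrichment tracer enrichment of the dextrose (default
#'   0.025).
#' @return object of class \code{infusion_schedule}.
#' @export
infusion_schedule <- function(tracer_prime = 22, tracer_rate = 0.22,
                              oral_loads = default_oral_loads(),
                              dextrose_rates = NULL,
                              dextrose_enrichment = 0.025) {
  has_oral <- !is.null(oral_loads) && nrow(oral_loads) > 0
  has_iv <- !is.null(dextrose_rates) && nrow(dextrose_rates) > 0
  if (has_oral == has_iv)
    stop("exactly one of oral_loads / dextrose_rates must be non-empty")
  if (has_oral) {
    stopifnot(all(c("time", "dose_g", "tracer_g") %in% names(oral_loads)))
    if (any(oral_loads$tracer_g > oral_loads$dose_g))
      stop("oral tracer mass exceeds load mass")
  }
  if (has_iv) {
    stopifnot(all(c("time", "rate") %in% names(dextrose_rates)))
    if (any(dextrose_rates$rate < 0)) stop("negative dextrose rate")
    if (any(dextrose_rates$time %% 10 != 0))
      stop("dextrose breakpoints must lie on the 10-min grid")
  }
  structure(list(tracer_prime = tracer_prime, tracer_rate = tracer_rate,
                 oral_loads = if (has_oral) oral_loads else
                   data.frame(time = numeric(), dose_g = numeric(),
                              tracer_g = numeric()),
                 dextrose_rates = if (has_iv) dextrose_rates else
                   data.frame(time = numeric(), rate = numeric()),
                 dextrose_enrichment = dextrose_enrichment),
            class = "infusion_schedule")
}

#' Default triple oral load protocol
#'
#' 25 g at 0 min, 75 g at 120 min, 100 g at 240 min, each containing 0.9 g of
#' orally ingested labelled glucose (drink enrichments 0.036, 0.012, 0.009).
#'
#' @return data.frame with columns time, dose_g, tracer_g.
#' @export
default_oral_loads <- function() {
  data.frame(time = c(0, 120, 240), dose_g = c(25, 75, 100),
             tracer_g = c(0.9, 0.9, 0.9))
}

#' Dextrose infusion rate at time t
#'
#' Piecewise-constant lookup (umol kg-1 min-1); zero before the first
#' breakpoint and zero for oral sessions.
#'
#' @param infusions an \code{infusion_schedule}.
#' @param t times (min), vectorised.
#' @return rates, umol kg-1 min-1.
#' @export
dextrose_rate_at <- function(infusions, t) {
  dr <- infusions$dextrose_rates
  if (nrow(dr) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, dr$time)
  out <- ifelse(idx == 0, 0, dr$rate[pmax(idx, 1L)])
  as.numeric(out)
}

#' Cumulative dextrose infusion
#'
#' Exact integral of the piecewise-constant dextrose schedule from 0 to t,
#' umol/kg (0 for t <= 0 and for oral sessions).
#'
#' @param infusions an \code{infusion_schedule}.
#' @param t times, min (vectorised).
#' @return cumulative infused glucose, umol/kg.
#' @export
cumulative_dextrose <- function(infusions, t) {
  dr <- infusions$dextrose_rates
  if (nrow(dr) == 0) return(rep(0, length(t)))
  vapply(t, function(x) {
    if (x <= dr$time[1]) return(0)
    i <- findInterval(x, dr$time)
    sum(dr$rate[seq_len(i - 1)] * diff(dr$time)[seq_len(i - 1)]) +
      dr$rate[i] * (x - dr$time[i])
  }, 0)
}

#' One subject-session record
#'
#' Bundles everything measured in one oral or isoglycaemic-intravenous
#' session: concentration series, tracer enrichments and the infusion
#' schedule. Route-specific invariants are enforced: an oral session carries
#' oral loads and the oral tracer; an intravenous session carries dextrose
#' rates and no oral tracer.
#'
#' @param subject a \code{subject_profile}.
#' @param route \code{"oral"} or \code{"igivi"}.
#' @param glucose,insulin,cpeptide,glp1,glucagon \code{sampling_series}.
#' @param metabolites named list of \code{sampling_series}.
#' @param tracers named list of \code{tracer_series} (\code{D2}, and
#'   \code{C13} for oral sessions).
#' @param infusions an \code{infusion_schedule}.
#' @return object of class \code{session_record}.
#' @export
session_record <- function(subject, route, glucose, insulin, cpeptide,
                           glp1, glucagon, metabolites, tracers, infusions) {
  route <- match.arg(route, c("oral", "igivi"))
  stopifnot(inherits(subject, "subject_profile"),
            inherits(infusions, "infusion_schedule"))
  expected_units <- c(glucose = "mmol/l", insulin = "pmol/l",
                      cpeptide = "nmol/l", glp1 = "ng/l", glucagon = "ng/l")
  for (nm in names(expected_units)) {
    s <- get(nm)
    if (!inherits(s, "sampling_series")) stop(nm, " must be a sampling_series")
    if (!identical(s$unit, unname(expected_units[nm])))
      stop("unit mismatch for ", nm, ": expected ", expected_units[nm],
           ", got ", s$unit)
    if (!any(s$times <= 0)) stop("missing basal samples for ", nm)
  }
  if (route == "oral") {
    if (nrow(infusions$oral_loads) == 0)
      stop("oral session requires oral loads")
    if (!"C13" %in% names(tracers))
      stop("oral session requires the oral C13 tracer series")
  } else {
    if (nrow(infusions$dextrose_rates) == 0)
      stop("intravenous session requires dextrose rates")
    if ("C13" %in% names(tracers))
      stop("intravenous session must not carry an oral tracer series")
  }
  if (!"D2" %in% names(tracers)) stop("D2 tracer series required")
  structure(list(subject = subject, route = route, glucose = glucose,
                 insulin = insulin, cpeptide = cpeptide, glp1 = glp1,
                 glucagon = glucagon, metabolites = metabolites,
                 tracers = tracers, infusions = infusions),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> subject %s (%s), route %s\n",
              x$subject$subject_id, x$subject$group, x$route))
  cat(sprintf("  glucose: %d samples; hormones: %d; metabolites: %d series\n",
              length(x$glucose$times), length(x$insulin$times),
              length(x$metabolites)))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session to disk
#'
#' Long-format CSV (\code{time_min, analyte, value, unit}) plus a YAML
#' sidecar (same path with extension \code{.yaml}) holding the subject,
#' route and infusion schedule. Numeric values are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param session a \code{session_record}.
#' @param path CSV file path.
#' @return the CSV path, invisibly.
#' @export
write_session <- function(session, path) {
  rows <- list()
  add <- function(s, name, unit) {
    data.frame(time_min = fmt_num(s$times), analyte = name,
               value = fmt_num(if (inherits(s, "tracer_series")) s$ttr
                               else s$values),
               unit = unit, stringsAsFactors = FALSE)
  }
  for (nm in c("glucose", "insulin", "cpeptide", "glp1", "glucagon"))
    rows[[nm]] <- add(session[[nm]], nm, session[[nm]]$unit)
  for (nm in names(session$metabolites))
    rows[[paste0("m_", nm)]] <- add(session$metabolites[[nm]], nm,
                                    session$metabolites[[nm]]$unit)
  for (nm in names(session$tracers))
    rows[[paste0("ttr_", nm)]] <- add(session$tracers[[nm]],
                                      paste0("ttr_", nm), "ratio")
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    subject = unclass(session$subject),
    route = session$route,
    metabolite_analytes = as.list(names(session$metabolites)),
    infusions = list(
      tracer_prime = session$infusions$tracer_prime,
      tracer_rate = session$infusions$tracer_rate,
      dextrose_enrichment = session$infusions$dextrose_enrichment,
      oral_loads = lapply(seq_len(nrow(session$infusions$oral_loads)),
        function(i) as.list(session$infusions$oral_loads[i, ])),
      dextrose_rates = lapply(seq_len(nrow(session$infusions$dextrose_rates)),
        function(i) as.list(session$infusions$dextrose_rates[i, ]))))
  yaml::write_yaml(side, sidecar_path(path), precision = 17L)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".yaml", path)

#' Read a session from disk
#'
#' Reads the long-format CSV and its YAML sidecar written by
#' \code{\link{write_session}} and validates the result. Hard errors on
#' missing basal samples, non-monotone times or unit mismatches.
#'
#' @param path CSV file path.
#' @return a \code{session_record}.
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "analyte", "value", "unit")
  if (!all(need %in% names(df)))
    stop("session CSV must have columns ", paste(need, collapse = ", "))
  side <- yaml::read_yaml(sidecar_path(path))
  sub <- side$subject
  subject <- subject_profile(sub$subject_id, sub$group, sub$age, sub$weight,
                             sub$bmi, sub$basal_glucose, sub$basal_insulin,
                             sub$basal_cpeptide, require_obese = FALSE)
  inf <- side$infusions
  bindrows <- function(lst, cols) {
    if (length(lst) == 0)
      return(NULL)
    do.call(rbind, lapply(lst, function(r) as.data.frame(r[cols])))
  }
  infusions <- infusion_schedule(
    tracer_prime = inf$tracer_prime, tracer_rate = inf$tracer_rate,
    oral_loads = bindrows(inf$oral_loads, c("time", "dose_g", "tracer_g")),
    dextrose_rates = bindrows(inf$dextrose_rates, c("time", "rate")),
    dextrose_enrichment = inf$dextrose_enrichment)
  pick <- function(name) {
    d <- df[df$analyte == name, , drop = FALSE]
    if (nrow(d) == 0) stop("analyte '", name, "' missing from session file")
    if (any(diff(d$time_min) <= 0)) stop("non-monotone times for '", name, "'")
    list(times = d$time_min, values = d$value, unit = unique(d$unit))
  }
  series_of <- function(name) {
    p <- pick(name)
    sampling_series(name, p$times, p$values, p$unit)
  }
  mets <- list()
  for (nm in unlist(side$metabolite_analytes))
    mets[[nm]] <- series_of(nm)
  tracers <- list()
  for (sp in c("D2", "C13")) {
    if (any(df$analyte == paste0("ttr_", sp))) {
      p <- pick(paste0("ttr_", sp))
      tracers[[sp]] <- tracer_series(sp, p$times, p$values)
    }
  }
  session_record(subject, side$route, series_of("glucose"),
                 series_of("insulin"), series_of("cpeptide"),
                 series_of("glp1"), series_of("glucagon"),
                 mets, tracers, infusions)
}
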