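#' Analyse one session end to end
#'
#' Runs the full analysis chain on a session record: flux reconstruction
#' (Steele), C-peptide deconvolution and the closed-form index panel.
#' Smoothing defaults to generalised cross-validation, appropriate for
#' measured (noisy) data; pass \code{lambda = 0} for noise-free synthetic
#' input.
#'
#' @param session a \code{session_record}.
#' @param pool a \code{pool_model}.
#' @param kin C-peptide kinetics; default population values for the subject.
#' @param lambda smoothing weight (NULL = GCV).
#' @param reg deconvolution regularisation weight.
#' @param fit_betacell also fit the three-load beta cell model? (slower)
#' @return object of class \code{session_analysis} with \code{flux},
#'   \code{secretion}, \code{panel} and optionally \code{betacell}.
#' @export
analyze_session <- function(session, pool = pool_model(), kin = NULL,
                            lambda = NULL, reg = 0.25,
                            fit_betacell = FALSE) {
  if (is.null(kin)) kin <- population_kinetics(session$subject)
  flux <- reconstruct_fluxes(session, pool, lambda = lambda)
  secretion <- deconvolve_isr(session$cpeptide, kin, reg = reg)
  panel <- index_panel(session, flux, secretion)
  bc <- if (fit_betacell) fit_three_segment(session, kin) else NULL
  structure(list(flux = flux, secretion = secretion, panel = panel,
                 betacell = bc, pool = pool, kinetics = kin,
                 lambda = lambda, reg = reg),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  print(x$panel)
  invisible(x)
}

paired_pvals <- function(oral, igivi) {
  ok <- is.finite(oral) & is.finite(igivi)
  if (sum(ok) < 3) return(c(t = NA_real_, wilcoxon = NA_real_))
  c(t = stats::t.test(oral[ok], igivi[ok], paired = TRUE)$p.value,
    wilcoxon = suppressWarnings(
      stats::wilcox.test(oral[ok], igivi[ok], paired = TRUE)$p.value))
}

#' Run the paired-cohort study analysis
#'
#' Simulates (or accepts) a paired cohort, analyses every session, and
#' assembles per-subject index panels, paired oral-minus-intravenous deltas,
#' cohort summaries with paired t and Wilcoxon p-values, and a recovery
#' report comparing estimates with the generator's ground truth.
#'
#' @param cohort a \code{simulated_cohort} (from
#'   \code{\link{simulate_cohort}}).
#' @param lambda smoothing weight passed to the flux chain (NULL = GCV,
#'   right for noisy cohorts; 0 for noise-free).
#' @param fit_betacell fit the beta cell model for every session? (slow;
#'   off by default).
#' @return object of class \code{cohort_study}.
#' @export
run_cohort_study <- function(cohort, lambda = NULL, fit_betacell = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  panels <- list()
  for (id in names(cohort)) {
    e <- cohort[[id]]
    kin <- population_kinetics(e$subject)
    for (r in c("oral", "igivi")) {
      an <- analyze_session(e[[r]]$session, kin = kin, lambda = lambda,
                            fit_betacell = fit_betacell)
      panels[[paste(id, r, sep = ".")]] <- an$panel
    }
  }
  df <- do.call(rbind, lapply(panels, as.data.frame))
  idx_names <- c("mcr_i", "isr_mean", "insulin_clearance", "di",
                 "hepatic_ir", "insulinogenic_index", "adipo_ir")
  oral <- df[df$route == "oral", ]
  iv <- df[df$route == "igivi", ]
  iv <- iv[match(oral$subject_id, iv$subject_id), ]
  deltas <- oral[idx_names] - iv[idx_names]
  rownames(deltas) <- oral$subject_id
  summary_tab <- do.call(rbind, lapply(idx_names, function(nm) {
    p <- paired_pvals(oral[[nm]], iv[[nm]])
    data.frame(index = nm,
               oral_mean = mean(oral[[nm]]), oral_sd = stats::sd(oral[[nm]]),
               igivi_mean = mean(iv[[nm]]), igivi_sd = stats::sd(iv[[nm]]),
               p_paired_t = p[["t"]], p_wilcoxon = p[["wilcoxon"]],
               stringsAsFactors = FALSE)
  }))
  truth_mcr <- vapply(names(cohort), function(id) {
    tr <- cohort[[id]]$oral$truth
    g <- tr$glucose; i <- tr$insulin
    mean(1000 * (tr$rd / g) / i)
  }, 0)
  est_mcr <- oral$mcr_i_session[match(names(cohort), oral$subject_id)]
  recovery <- data.frame(subject_id = names(cohort),
                         mcr_i_true = truth_mcr, mcr_i_est = est_mcr,
                         stringsAsFactors = FALSE)
  structure(list(panels = df, deltas = deltas, summary = summary_tab,
                 recovery = recovery, n = nrow(oral)),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study> %d paired subjects\n", x$n))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s oral %10.3g +/- %-9.3g IGIVI %10.3g +/- %-9.3g p(t)=%.3g\n",
                s$index[i], s$oral_mean[i], s$oral_sd[i],
                s$igivi_mean[i], s$igivi_sd[i], s$p_paired_t[i]))
  invisible(x)
}

#' Study reference values for qualitative comparison
#'
#' Published subject-level study means shipped as a static citations table;
#' used only for side-by-side qualitative display, never as a fitting or
#' acceptance target for synthetic cohorts.
#'
#' @return data.frame with index, oral and intravenous reference means.
#' @export
study_reference_values <- function() {
  path <- system.file("extdata", "study_reference_values.csv",
                      package = "glucoroute")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Human-readable cohort report
#'
#' Prints the cohort summary next to the published study means (labelled
#' qualitative-only) and returns the combined machine-readable structure.
#'
#' @param study a \code{cohort_study}.
#' @param file optional path for a JSON copy of the report.
#' @return invisibly, the report list.
#' @export
report <- function(study, file = NULL) {
  stopifnot(inherits(study, "cohort_study"))
  ref <- study_reference_values()
  cat("Paired oral vs isoglycaemic-intravenous cohort report\n")
  cat("=====================================================\n")
  print(study)
  cat("\nPublished study means (qualitative comparison only):\n")
  for (i in seq_len(nrow(ref)))
    cat(sprintf("  %-20s oral %8.4g   IGIVI %8.4g  [%s]\n",
                ref$index[i], ref$oral[i], ref$igivi[i], ref$unit[i]))
  dirs <- direction_table(study)
  cat("\nPaired direction of the synthetic cohort (oral vs IGIVI):\n")
  for (nm in names(dirs))
    cat(sprintf("  %-20s %s\n", nm, dirs[[nm]]))
  out <- list(summary = study$summary, reference = ref, directions = dirs)
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(out)
}

#' Paired sign pattern of the headline indices
#'
#' @param study a \code{cohort_study}.
#' @return named character vector: "lower"/"higher" under oral dosing.
#' @export
direction_table <- function(study) {
  s <- study$summary
  dir_of <- function(nm) {
    row <- s[s$index == nm, ]
    if (row$oral_mean < row$igivi_mean) "lower under oral" else
      "higher under oral"
  }
  vapply(c("mcr_i", "isr_mean", "insulin_clearance", "di", "adipo_ir"),
         dir_of, "")
}
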