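# Orchestration of the study-level analyses: per-indication and pooled
# model comparisons with and without the biomarker covariate, the
# exploratory/validated sub-analysis, and per-phase hazard summaries.

.report_sample_sizes <- function(panel) {
  n_in <- function(s) length(unique(panel$drug_id[
    !is.na(panel$state) & panel$state == s]))
  c(phase1 = n_in(1L), phase2 = n_in(2L), phase3 = n_in(3L),
    approved = n_in(4L), failed = n_in(5L))
}

.drug_level <- function(panel, cols) {
  first <- panel[!duplicated(panel$drug_id), , drop = FALSE]
  first[, cols, drop = FALSE]
}

# Core two-model comparison on one cohort for a binary covariate.
.run_analysis <- function(panel, label, covariate = "biomarker",
                          attachment = "per_transition",
                          on = "progression") {
  spec0 <- trial_model_spec()
  fit0 <- fit_msm(panel, spec0)
  drugs <- .drug_level(panel, c("drug_id", covariate))
  levels_present <- unique(drugs[[covariate]])
  diagnostics <- character()

  fit1 <- lrt <- overall <- fit_shared <- NULL
  per_phase <- NULL
  if (length(levels_present) < 2L) {
    diagnostics <- c(diagnostics, paste0(
      "covariate '", covariate, "' has a single level in this cohort; ",
      "covariate model skipped"))
  } else {
    spec1 <- trial_model_spec(covariate, attachment = attachment, on = on)
    fit1 <- fit_msm(panel, spec1)
    lrt <- likelihood_ratio_test(fit0, fit1)
    z0 <- setNames(0, covariate)
    z1 <- setNames(1, covariate)
    prog <- .progression_transitions
    h0 <- transition_intensities(fit1, z0)
    h1 <- transition_intensities(fit1, z1)
    h0 <- h0[h0$transition %in% prog, ]
    h1 <- h1[h1$transition %in% prog, ]
    h0$level <- paste0("no_", covariate)
    h1$level <- covariate
    per_phase <- rbind(h0, h1)
    rownames(per_phase) <- NULL
    # phase-independent ("overall") effect: one shared log intensity
    # ratio across the progression transitions
    spec_sh <- trial_model_spec(covariate, attachment = "shared", on = on)
    fit_shared <- fit_msm(panel, spec_sh)
    hrow <- fit_shared$hazard_ratios[
      fit_shared$hazard_ratios$param == covariate, ]
    overall <- c(hr = hrow$hr, lower = hrow$lower, upper = hrow$upper)
  }

  structure(
    list(indication = label,
         covariate = covariate,
         fit_no_covariate = fit0,
         fit_with_covariate = fit1,
         fit_shared = fit_shared,
         lrt = lrt,
         per_phase_hazards = per_phase,
         overall_hr = overall,
         sample_sizes = .report_sample_sizes(panel),
         counts = table(drugs[[covariate]]),
         n_drugs = nrow(drugs),
         diagnostics = diagnostics),
    class = "analysis_report")
}

#' Analyse one indication: biomarker vs no-biomarker Markov models
#'
#' Filters the panel to one indication, fits the multi-state model with
#' and without the biomarker covariate, compares them by likelihood
#' ratio, and summarizes per-phase transition hazards at each covariate
#' level plus the phase-independent (shared) hazard ratio.
#'
#' @param panel Panel data.frame with an `indication` column and the
#'   covariate column.
#' @param indication One of `"breast"`, `"colorectal"`, `"melanoma"`,
#'   `"nsclc"`.
#' @param covariate Binary covariate column (default `"biomarker"`).
#' @param attachment Covariate attachment for the per-phase model
#'   (`"per_transition"` or `"shared"`).
#' @param on Transitions carrying the effect (`"progression"` or
#'   `"all"`).
#' @return An `"analysis_report"`.
#' @export
run_indication_analysis <- function(panel, indication,
                                    covariate = "biomarker",
                                    attachment = "per_transition",
                                    on = "progression") {
  if (!indication %in% .indications)
    stop("unknown indication: ", indication)
  sub <- panel[panel$indication == indication, , drop = FALSE]
  if (!nrow(sub)) stop("no drugs for indication ", indication)
  .run_analysis(sub, indication, covariate, attachment, on)
}

#' Pooled analysis across all indications
#'
#' As [run_indication_analysis()] but on the full cohort, irrespective
#' of indication.
#'
#' @inheritParams run_indication_analysis
#' @return An `"analysis_report"` with `indication = "pooled"`.
#' @export
run_pooled_analysis <- function(panel, covariate = "biomarker",
                                attachment = "per_transition",
                                on = "progression") {
  .run_analysis(panel, "pooled", covariate, attachment, on)
}

#' Exploratory / validated biomarker sub-analysis
#'
#' Splits biomarker drugs into exploratory and validated (reference: no
#' biomarker) and compares nested Markov models: any-biomarker vs none
#' (one common effect per transition across both biomarker types vs no
#' effect), exploratory-vs-validated (type-specific effects vs the
#' common-effect model), and exploratory-vs-none (biomarker effect
#' fitted on the cohort excluding validated-biomarker drugs).  The
#' headline exploratory-vs-none hazard ratio uses the shared
#' (phase-independent) attachment.
#'
#' @param panel Panel data.frame with `exploratory` and `validated`
#'   0/1 drug-level columns (reference level: both zero).
#' @param attachment Attachment for the type-specific model.
#' @param on Transitions carrying the effects.
#' @return Object of class `"subtype_report"`: the three fits, the three
#'   LRTs, `exploratory_vs_none_hr`, per-phase hazards by level, and
#'   level counts.
#' @export
run_biomarker_subtype_analysis <- function(panel,
                                           attachment = "per_transition",
                                           on = "progression") {
  drugs <- .drug_level(panel, c("drug_id", "exploratory", "validated"))
  lvl <- ifelse(drugs$validated > 0, "validated",
                ifelse(drugs$exploratory > 0, "exploratory", "none"))
  counts <- table(factor(lvl, levels = c("none", "exploratory",
                                         "validated")))
  diagnostics <- character()
  covs <- c("exploratory", "validated")

  spec0 <- trial_model_spec()
  fit0 <- fit_msm(panel, spec0)

  fit_any <- fit_typed <- NULL
  lrt_any_vs_none <- lrt_expl_vs_val <- lrt_expl_vs_none <- NULL
  expl_hr <- NULL
  per_phase <- NULL

  if (counts["exploratory"] + counts["validated"] == 0 ||
      counts["none"] == 0) {
    diagnostics <- c(diagnostics,
                     "degenerate biomarker levels; covariate fits skipped")
  } else {
    # common effect of either biomarker type: the two indicator
    # covariates share one parameter per transition
    tr_on <- if (on == "progression") .progression_transitions else
      rownames(phase_transitions())
    bm_any <- expand.grid(transition = tr_on, covariate = covs,
                          stringsAsFactors = FALSE)
    bm_any$param <- if (attachment == "per_transition")
      paste(bm_any$transition, "anybiomarker", sep = ":") else
        "anybiomarker"
    spec_any <- model_spec(5L, phase_transitions(), covariates = covs,
                           beta_map = bm_any, exact_states = c(4L, 5L))
    fit_any <- fit_msm(panel, spec_any)
    lrt_any_vs_none <- likelihood_ratio_test(fit0, fit_any)

    if (counts["exploratory"] > 0 && counts["validated"] > 0) {
      spec_typed <- trial_model_spec(covs, attachment = attachment,
                                     on = on)
      fit_typed <- fit_msm(panel, spec_typed)
      lrt_expl_vs_val <- likelihood_ratio_test(fit_any, fit_typed)
      for (lv in c("none", "exploratory", "validated")) {
        z <- setNames(as.numeric(covs == lv), covs)
        h <- transition_intensities(fit_typed, z)
        h <- h[h$transition %in% .progression_transitions, ]
        h$level <- lv
        per_phase <- rbind(per_phase, h)
      }
      rownames(per_phase) <- NULL
    } else {
      diagnostics <- c(diagnostics, paste0(
        "empty biomarker level; exploratory-vs-validated contrast skipped"))
    }

    if (counts["exploratory"] > 0) {
      keep <- drugs$drug_id[lvl != "validated"]
      sub <- panel[panel$drug_id %in% keep, , drop = FALSE]
      spec_e0 <- trial_model_spec()
      spec_e1 <- trial_model_spec("exploratory", attachment = "shared",
                                  on = on)
      f_e0 <- fit_msm(sub, spec_e0)
      f_e1 <- fit_msm(sub, spec_e1)
      lrt_expl_vs_none <- likelihood_ratio_test(f_e0, f_e1)
      hrow <- f_e1$hazard_ratios[
        f_e1$hazard_ratios$param == "exploratory", ]
      expl_hr <- c(hr = hrow$hr, lower = hrow$lower, upper = hrow$upper)
    } else {
      diagnostics <- c(diagnostics,
                       "no exploratory drugs; exploratory-vs-none skipped")
    }
  }

  structure(
    list(indication = "pooled",
         fit_no_covariate = fit0,
         fit_any_biomarker = fit_any,
         fit_by_type = fit_typed,
         lrt_any_vs_none = lrt_any_vs_none,
         lrt_exploratory_vs_validated = lrt_expl_vs_val,
         lrt_exploratory_vs_none = lrt_expl_vs_none,
         exploratory_vs_none_hr = expl_hr,
         per_phase_hazards = per_phase,
         sample_sizes = .report_sample_sizes(panel),
         counts = counts,
         n_drugs = nrow(drugs),
         diagnostics = diagnostics),
    class = "subtype_report")
}

#' @export
print.analysis_report <- function(x, digits = 4, ...) {
  cat("Analysis report:", x$indication, "(", x$n_drugs, "drugs )\n")
  cat("  drugs in Phase I/II/III:",
      paste(x$sample_sizes[1:3], collapse = " / "), "\n")
  if (!is.null(x$lrt)) {
    cat("  model comparison (", x$covariate, "): ", sep = "")
    print(x$lrt)
    cat("  phase-independent HR:",
        sprintf("%.3g [%.3g, %.3g]\n", x$overall_hr["hr"],
                x$overall_hr["lower"], x$overall_hr["upper"]))
  }
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

#' @export
print.subtype_report <- function(x, digits = 4, ...) {
  cat("Biomarker sub-analysis (", x$n_drugs, "drugs )\n")
  cat("  levels:", paste(names(x$counts), as.integer(x$counts),
                         sep = "=", collapse = ", "), "\n")
  if (!is.null(x$lrt_any_vs_none)) {
    cat("  any-biomarker vs none: ")
    print(x$lrt_any_vs_none)
  }
  if (!is.null(x$lrt_exploratory_vs_validated)) {
    cat("  exploratory vs validated: ")
    print(x$lrt_exploratory_vs_validated)
  }
  if (!is.null(x$lrt_exploratory_vs_none)) {
    cat("  exploratory vs none: ")
    print(x$lrt_exploratory_vs_none)
    cat("  exploratory-vs-none HR:",
        sprintf("%.3g [%.3g, %.3g]\n", x$exploratory_vs_none_hr["hr"],
                x$exploratory_vs_none_hr["lower"],
                x$exploratory_vs_none_hr["upper"]))
  }
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}
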