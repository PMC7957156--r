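# Run configuration: one validated object holding every analysis
# option, loadable from YAML so a whole analysis is reproducible from a
# config file plus a data file.

.config_defaults <- function() {
  list(
    indication = "all",          # all | breast|colorectal|melanoma|nsclc
    covariate = "biomarker",     # biomarker | biomarker3
    attachment = "per_transition",  # per_transition | shared
    on = "progression",          # progression | all
    biomarker_rule = "any",      # any | all (drug-level flag)
    reference_date = NULL,       # analysis snapshot (ISO-8601)
    seed = 20210223L
  )
}

#' Analysis run configuration
#'
#' Collects every tunable option of the classification and modelling
#' pipeline, with documented defaults; unknown options are rejected.
#'
#' @param ... Options overriding the defaults: `indication` (`"all"` or
#'   one indication), `covariate` (`"biomarker"` for the binary model,
#'   `"biomarker3"` for the exploratory/validated sub-analysis),
#'   `attachment` (`"per_transition"` or `"shared"`), `on`
#'   (`"progression"` or `"all"` transitions), `biomarker_rule`
#'   (`"any"` or `"all"` trials), `reference_date` (ISO-8601), `seed`.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(...) {
  opts <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown))
    stop("unknown configuration option(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, opts)
  stopifnot(cfg$indication %in% c("all", .indications),
            cfg$covariate %in% c("biomarker", "biomarker3"),
            cfg$attachment %in% c("per_transition", "shared"),
            cfg$on %in% c("progression", "all"),
            cfg$biomarker_rule %in% c("any", "all"))
  if (!is.null(cfg$reference_date))
    cfg$reference_date <- as.Date(cfg$reference_date)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] options.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the configured analysis on a panel dataset
#'
#' Dispatches to [run_pooled_analysis()], [run_indication_analysis()]
#' or [run_biomarker_subtype_analysis()] according to the
#' configuration.
#'
#' @param panel Panel data.frame.
#' @param config A [run_config()].
#' @return An `"analysis_report"` or `"subtype_report"`.
#' @export
analyze_cohort <- function(panel, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$covariate == "biomarker3") {
    sub <- if (config$indication == "all") panel else
      panel[panel$indication == config$indication, , drop = FALSE]
    return(run_biomarker_subtype_analysis(sub,
                                          attachment = config$attachment,
                                          on = config$on))
  }
  if (config$indication == "all")
    run_pooled_analysis(panel, covariate = "biomarker",
                        attachment = config$attachment, on = config$on)
  else
    run_indication_analysis(panel, config$indication,
                            covariate = "biomarker",
                            attachment = config$attachment,
                            on = config$on)
}
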