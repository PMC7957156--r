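# Readers and writers: the trial-record CSV, the biomarker approval
# registry, panel CSVs and deterministic JSON reports.

.trials_schema <- c("drug_id", "indication", "phase", "start_date",
                    "completion_date", "uses_biomarker_selection",
                    "biomarker_ids", "fda_approved", "approval_date",
                    "withdrawn", "failed_endpoint")

.parse_date <- function(x) {
  out <- as.Date(rep(NA), origin = "1970-01-01")
  out <- as.Date(ifelse(is.na(x) | !nzchar(x), NA, x),
                 format = "%Y-%m-%d")
  out
}

#' Read and validate a trial-record CSV
#'
#' One row per trial: `drug_id`, `indication`
#' (breast/colorectal/melanoma/nsclc), `phase` (I, I_II, II, III),
#' `start_date` and `completion_date` (ISO-8601; completion empty while
#' the trial is running), `uses_biomarker_selection` (0/1),
#' `biomarker_ids` (semicolon-separated), `fda_approved` (0/1),
#' `approval_date`, `withdrawn` (0/1), `failed_endpoint` (0/1).
#'
#' Malformed rows (bad dates, unknown phase or indication, completion
#' before start) are collected into a `problems` attribute and dropped
#' with a warning; a missing column is an error.
#'
#' @param path CSV file path.
#' @return Validated data.frame of trial records with parsed dates;
#'   attribute `"problems"` lists rejected rows (line, message).
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.trials_schema, names(raw))
  if (length(miss))
    stop("trial CSV lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  problems <- data.frame(line = integer(), message = character(),
                         stringsAsFactors = FALSE)
  note <- function(i, msg) {
    problems <<- rbind(problems, data.frame(
      line = i + 1L, message = msg, stringsAsFactors = FALSE))
  }
  start <- .parse_date(raw$start_date)
  comp <- .parse_date(raw$completion_date)
  appr <- .parse_date(raw$approval_date)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!nzchar(raw$drug_id[i])) { note(i, "empty drug_id"); keep[i] <- FALSE; next }
    if (!raw$indication[i] %in% .indications) {
      note(i, paste0("unknown indication '", raw$indication[i], "'"))
      keep[i] <- FALSE; next
    }
    if (!raw$phase[i] %in% .phase_levels) {
      note(i, paste0("unknown phase '", raw$phase[i], "'"))
      keep[i] <- FALSE; next
    }
    if (is.na(start[i])) {
      note(i, "unparseable start_date"); keep[i] <- FALSE; next
    }
    if (nzchar(raw$completion_date[i]) && is.na(comp[i])) {
      note(i, "unparseable completion_date"); keep[i] <- FALSE; next
    }
    if (!is.na(comp[i]) && comp[i] < start[i]) {
      note(i, "completion_date before start_date"); keep[i] <- FALSE; next
    }
    if (raw$fda_approved[i] %in% "1" && is.na(appr[i]) &&
        nzchar(raw$approval_date[i])) {
      note(i, "unparseable approval_date"); keep[i] <- FALSE; next
    }
  }
  if (nrow(problems))
    warning(nrow(problems), " malformed trial row(s) dropped; see ",
            "attr(., 'problems')", call. = FALSE)
  out <- data.frame(
    drug_id = raw$drug_id,
    indication = raw$indication,
    phase = raw$phase,
    start_date = start,
    completion_date = comp,
    uses_biomarker_selection = as.integer(raw$uses_biomarker_selection),
    biomarker_ids = raw$biomarker_ids,
    fda_approved = as.integer(raw$fda_approved),
    approval_date = appr,
    withdrawn = as.integer(raw$withdrawn),
    failed_endpoint = as.integer(raw$failed_endpoint),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Write a trial table back to CSV (inverse of [read_trials_csv()])
#' @param trials Validated trial data.frame.
#' @param path Output path.
#' @export
write_trials_csv <- function(trials, path) {
  out <- trials
  for (col in c("start_date", "completion_date", "approval_date"))
    out[[col]] <- ifelse(is.na(out[[col]]),
                         "", format(out[[col]], "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a biomarker approval registry CSV
#'
#' Columns: `biomarker_id`, `indication`, `fda_approval_date`
#' (ISO-8601).
#' @param path CSV file path.
#' @return Data frame with parsed approval dates.
#' @export
read_biomarker_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("biomarker_id", "indication", "fda_approval_date")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry CSV lacks column(s): ", paste(miss, collapse = ", "))
  reg$fda_approval_date <- .parse_date(reg$fda_approval_date)
  if (anyNA(reg$fda_approval_date))
    stop("registry contains unparseable fda_approval_date values")
  bad <- setdiff(unique(reg$indication), .indications)
  if (length(bad))
    stop("registry contains unknown indication(s): ",
         paste(bad, collapse = ", "))
  reg
}

#' Write / read a panel dataset CSV
#'
#' @param panel Panel data.frame (`drug_id`, `time`, `state`,
#'   `censor_set`, covariate columns).
#' @param path File path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(drug_id = "character"))
  if ("censor_set" %in% names(p)) {
    p$censor_set <- as.character(p$censor_set)
    p$censor_set[is.na(p$censor_set)] <- ""
  }
  p
}

# --- deterministic JSON reports --------------------------------------

.jsonify <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "msm_fit")) {
    out <- list(
      log_likelihood = .num(x$log_likelihood),
      converged = x$converged,
      n_subjects = x$n_subjects,
      n_observations = x$n_observations,
      log_baseline = .jsonify(x$estimate$log_baseline),
      beta = .jsonify(x$estimate$beta),
      se = .jsonify(x$se),
      hazard_ratios = if (is.null(x$hazard_ratios)) NULL else
        lapply(seq_len(nrow(x$hazard_ratios)), function(i)
          .jsonify(as.list(x$hazard_ratios[i, ]))))
    out[vapply(out, is.null, TRUE)] <- NULL
    return(out[order(names(out))])
  }
  if (inherits(x, "msm_lrt"))
    return(list(df = x$df, p_value = .num(x$p_value),
                statistic = .num(x$statistic)))
  if (is.data.frame(x))
    return(lapply(seq_len(nrow(x)), function(i) .jsonify(as.list(x[i, ]))))
  if (inherits(x, "table")) {
    out <- as.list(setNames(as.integer(x), names(x)))
    return(out[order(names(out))])
  }
  if (is.list(x)) {
    out <- lapply(x, .jsonify)
    out[vapply(out, is.null, TRUE)] <- NULL
    if (!is.null(names(out)) && length(out))
      out <- out[order(names(out))]
    return(out)
  }
  if (is.numeric(x)) {
    x <- .num(x)
    if (length(x) == 1L && is.null(names(x))) return(x)
    x <- as.list(x)
    if (!is.null(names(x))) x <- x[order(names(x))]
    return(x)
  }
  x
}

# fixed significant-digit rounding; non-finite values become NA so the
# JSON writer emits null, never NaN/Inf
.num <- function(x) {
  nm <- names(x)
  x <- signif(as.numeric(x), 10)
  x[!is.finite(x)] <- NA_real_
  names(x) <- nm
  x
}

#' Serialize an analysis report to deterministic JSON
#'
#' Keys are sorted, floats carry 10 significant digits, and absent or
#' non-finite quantities (e.g. a CI from a singular information matrix)
#' are written as JSON `null` so that write-read-write round-trips are
#' byte-identical.
#'
#' @param report An `"analysis_report"`, `"subtype_report"`,
#'   `"recovery_summary"`, or plain list of scalar summaries.
#' @param path Output path.
#' @return Invisibly, the serialized list.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "analysis_report") ||
      inherits(report, "subtype_report") ||
      inherits(report, "recovery_summary")) {
    x <- unclass(report)
  } else x <- report
  out <- .jsonify(x)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(out)
}

#' Read back a JSON report
#' @param path File written by [write_report()].
#' @return Nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
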