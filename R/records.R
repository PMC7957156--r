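# Domain rules turning raw drug-development records into multi-state
# histories.
#
# A drug program is everything known about one drug in one indication:
# its trials (with phases and dates), whether it was FDA-approved,
# withdrawn by its manufacturer, or declared to have missed its primary
# endpoints.  The classification rules are deterministic:
#   * Phase I (or I/II) is successful if the drug advanced to Phase II in
#     the same indication; Phase II if it advanced to Phase III; Phase
#     III if the drug was FDA-approved.
#   * A phase is a failure if more than 2 years pass after the completion
#     of its latest trial with no further development, or the
#     manufacturer withdrew the drug, or declared the primary endpoints
#     missed.
#   * Otherwise the phase is ongoing and the program is right-censored
#     there: earlier phases count as successes, the current phase is
#     known only to be "not yet failed or approved".

.indications <- c("breast", "colorectal", "melanoma", "nsclc")
.phase_levels <- c("I", "I_II", "II", "III")

# 2-year windows, calendar-exact; the boundary day counts as within-window
.two_years_days <- 730L

.years_between <- function(later, earlier) {
  as.numeric(difftime(as.Date(later), as.Date(earlier), units = "days")) /
    365.25
}

# Collapse I/II hybrids onto Phase I for state assignment.
.state_phase <- function(phase) {
  p <- as.character(phase)
  p[p == "I_II"] <- "I"
  factor(p, levels = c("I", "II", "III"))
}

#' Assemble drug programs from a validated trial table
#'
#' Groups one row-per-trial data into one object per drug x indication.
#'
#' @param trials Data frame as returned by [read_trials_csv()].
#' @return Named list of `"drug_program"` objects, each with `drug_id`,
#'   `indication`, `trials` (the rows), `fda_approved`, `approval_date`,
#'   `withdrawn`, `failed_endpoint`.
#' @export
as_drug_programs <- function(trials) {
  trials <- as.data.frame(trials)
  key <- paste(trials$drug_id, trials$indication, sep = "\r")
  lapply(split(trials, factor(key, levels = unique(key))), function(d) {
    approved <- any(d$fda_approved > 0)
    if (approved && all(is.na(d$approval_date)))
      stop("drug ", d$drug_id[1L], ": fda_approved without approval_date")
    structure(
      list(drug_id = d$drug_id[1L],
           indication = d$indication[1L],
           trials = d,
           fda_approved = approved,
           approval_date = if (approved) min(d$approval_date, na.rm = TRUE)
                           else as.Date(NA),
           withdrawn = any(d$withdrawn > 0),
           failed_endpoint = any(d$failed_endpoint > 0)),
      class = "drug_program")
  })
}

#' Classify the outcome of one development phase of a drug program
#'
#' Applies the deterministic phase-outcome rules (see the module
#' description above) at a reference date.
#'
#' @param program A `"drug_program"`.
#' @param phase `"I"`, `"II"` or `"III"` (I/II hybrid trials count as
#'   Phase I).
#' @param reference_date Date of the analysis snapshot.
#' @return List with `phase` and `status` in
#'   `c("success", "failure", "ongoing")`.
#' @export
classify_phase_outcome <- function(program, phase, reference_date) {
  phase <- match.arg(as.character(phase), c("I", "II", "III"))
  reference_date <- as.Date(reference_date)
  ph <- .state_phase(program$trials$phase)
  mine <- program$trials[which(ph == phase), , drop = FALSE]
  if (!nrow(mine))
    stop("phase absent: program ", program$drug_id,
         " has no phase ", phase, " trial")
  status <- NULL
  if (phase == "III") {
    if (program$fda_approved) status <- "success"
  } else {
    idx <- as.integer(.state_phase(program$trials$phase)) >
      match(phase, c("I", "II", "III"))
    if (any(idx, na.rm = TRUE) || (phase != "III" && program$fda_approved))
      status <- "success"
  }
  if (is.null(status)) {
    inactive <- FALSE
    if (any(!is.na(mine$completion_date))) {
      last_done <- max(mine$completion_date, na.rm = TRUE)
      if (last_done > reference_date)
        stop("completion date after the reference date for program ",
             program$drug_id)
      # strictly more than 2 calendar years of inactivity
      inactive <- all(!is.na(mine$completion_date)) &&
        as.numeric(reference_date - last_done) > .two_years_days
    }
    if (program$withdrawn || program$failed_endpoint || inactive)
      status <- "failure"
    else
      status <- "ongoing"
  }
  list(phase = phase, status = status)
}

#' Classify a biomarker as none / exploratory / validated
#'
#' A biomarker used for patient enrolment or exclusion is "exploratory"
#' until 2 years after its first FDA approval in the same indication
#' (use on or before the 2-year boundary still counts as exploratory),
#' and "validated" thereafter.  No biomarker at all is "none".
#'
#' @param biomarker_id Identifier, or `NA`/`""` when no biomarker was
#'   used.
#' @param indication One of `"breast"`, `"colorectal"`, `"melanoma"`,
#'   `"nsclc"`.
#' @param usage_date Date the biomarker was used (trial start).
#' @param approval_registry Data frame with columns `biomarker_id`,
#'   `indication`, `fda_approval_date`.
#' @return List with `label` in `c("none", "exploratory", "validated")`
#'   and `biomarker_id`.
#' @export
classify_biomarker_status <- function(biomarker_id, indication, usage_date,
                                      approval_registry) {
  if (!indication %in% .indications)
    stop("unknown indication: ", indication)
  if (is.na(biomarker_id) || !nzchar(biomarker_id))
    return(list(label = "none", biomarker_id = NA_character_))
  usage_date <- as.Date(usage_date)
  reg <- approval_registry[
    approval_registry$biomarker_id == biomarker_id &
      approval_registry$indication == indication, , drop = FALSE]
  if (!nrow(reg))
    return(list(label = "exploratory", biomarker_id = biomarker_id))
  approval <- min(as.Date(reg$fda_approval_date))
  label <- if (approval > usage_date ||
               as.numeric(usage_date - approval) <= .two_years_days)
    "exploratory" else "validated"
  list(label = label, biomarker_id = biomarker_id)
}

#' Drug-level biomarker covariates
#'
#' A drug counts as biomarker-based when any of its trials used a
#' biomarker for patient enrolment or exclusion (the permissive,
#' any-trial rule; set `rule = "all"` to require every trial).  The
#' three-level status is classified at the drug's first biomarker use.
#'
#' @param program A `"drug_program"`.
#' @param approval_registry See [classify_biomarker_status()].
#' @param rule `"any"` (default) or `"all"`.
#' @return List: `biomarker` (0/1), `label`, `mixed` (TRUE when some but
#'   not all trials used a biomarker).
#' @export
drug_biomarker_status <- function(program, approval_registry = NULL,
                                  rule = c("any", "all")) {
  rule <- match.arg(rule)
  used <- program$trials$uses_biomarker_selection > 0
  flag <- if (rule == "any") any(used) else all(used)
  if (!flag)
    return(list(biomarker = 0L, label = "none", mixed = any(used)))
  first <- program$trials[used, , drop = FALSE]
  first <- first[order(first$start_date), , drop = FALSE][1L, ]
  ids <- strsplit(first$biomarker_ids %||% "", ";", fixed = TRUE)[[1]]
  id <- if (length(ids)) ids[1L] else NA_character_
  label <- if (is.null(approval_registry) || is.na(id)) "exploratory" else
    classify_biomarker_status(id, program$indication, first$start_date,
                              approval_registry)$label
  list(biomarker = 1L, label = label, mixed = any(used) && !all(used))
}

#' Build the multi-state observation history of one drug program
#'
#' Emits panel observations: one exact-state observation at each phase
#' entry (time in years from the first phase entry), an Approved
#' observation at the approval date, a Failed observation at the
#' completion date of the failing phase's last trial (the 2-year
#' inactivity rule is a discovery delay, not an event time), or a
#' terminal censoring observation at the reference date with possible
#' states {current phase, later transient phases, Approved} for ongoing
#' programs.
#'
#' @param program A `"drug_program"`.
#' @param reference_date Analysis snapshot date.
#' @return Data frame: `drug_id`, `time` (years), `state` (1-5, `NA` for
#'   the censored terminal row), `censor_set`, `obs_exact` (1 on
#'   exactly-timed entry rows).
#' @export
build_state_history <- function(program, reference_date) {
  reference_date <- as.Date(reference_date)
  tr <- program$trials
  ph <- .state_phase(tr$phase)
  phases <- levels(ph)[sort(unique(as.integer(ph)))]
  entry <- vapply(phases, function(p)
    min(tr$start_date[ph == p]), as.Date("1970-01-01"))
  entry <- as.Date(entry, origin = "1970-01-01")
  if (is.unsorted(as.numeric(entry), strictly = TRUE))
    stop("phase entry dates are not strictly increasing for program ",
         program$drug_id)
  origin <- entry[1L]
  states <- match(phases, c("I", "II", "III"))
  rows <- data.frame(
    drug_id = program$drug_id,
    time = .years_between(entry, origin),
    state = states,
    censor_set = "",
    obs_exact = c(0L, rep(1L, length(states) - 1L)),
    stringsAsFactors = FALSE)

  outcomes <- lapply(phases, function(p)
    classify_phase_outcome(program, p, reference_date)$status)
  names(outcomes) <- phases
  statuses <- unlist(outcomes)
  terminal_phase <- phases[length(phases)]
  if (any(statuses[-length(statuses)] != "success"))
    stop("program ", program$drug_id, ": phase ",
         phases[which(statuses != "success")[1L]],
         " did not succeed but later-phase trials exist")

  final <- statuses[[terminal_phase]]
  if (final == "success") {
    # only possible for phase III: approval
    t_app <- .years_between(program$approval_date, origin)
    if (t_app <= rows$time[nrow(rows)])
      stop("approval date does not follow the last phase entry for ",
           program$drug_id)
    rows <- rbind(rows, data.frame(
      drug_id = program$drug_id, time = t_app, state = 4L,
      censor_set = "", obs_exact = 1L, stringsAsFactors = FALSE))
  } else if (final == "failure") {
    mine <- tr[ph == terminal_phase, , drop = FALSE]
    if (all(is.na(mine$completion_date)))
      stop("program ", program$drug_id, ": failed phase ",
           terminal_phase, " has no completion date")
    t_fail <- .years_between(max(mine$completion_date, na.rm = TRUE),
                             origin)
    if (t_fail <= rows$time[nrow(rows)])
      stop("failure time does not follow the last phase entry for ",
           program$drug_id)
    rows <- rbind(rows, data.frame(
      drug_id = program$drug_id, time = t_fail, state = 5L,
      censor_set = "", obs_exact = 1L, stringsAsFactors = FALSE))
  } else {
    cur <- states[length(states)]
    t_ref <- .years_between(reference_date, origin)
    if (t_ref <= rows$time[nrow(rows)])
      stop("reference date does not follow the last phase entry for ",
           program$drug_id)
    rows <- rbind(rows, data.frame(
      drug_id = program$drug_id, time = t_ref, state = NA_integer_,
      censor_set = paste(c(seq.int(cur, 3L), 4L), collapse = ","),
      obs_exact = 0L, stringsAsFactors = FALSE))
  }
  rows
}

#' Build a panel dataset from a trial table
#'
#' Runs the full classification stage: groups trials into drug programs,
#' classifies outcomes, builds each program's state history, and attaches
#' the drug-level biomarker covariates.
#'
#' @param trials Validated trial table (see [read_trials_csv()]).
#' @param reference_date Analysis snapshot date.
#' @param approval_registry Optional biomarker approval registry for the
#'   exploratory/validated sub-classification.
#' @param biomarker_rule Drug-level flag rule, see
#'   [drug_biomarker_status()].
#' @return Panel data.frame: `drug_id`, `time`, `state`, `censor_set`,
#'   `indication`, `biomarker`, `exploratory`, `validated`.
#' @export
build_panel <- function(trials, reference_date, approval_registry = NULL,
                        biomarker_rule = "any") {
  programs <- as_drug_programs(trials)
  out <- lapply(programs, function(pr) {
    h <- build_state_history(pr, reference_date)
    bs <- drug_biomarker_status(pr, approval_registry, biomarker_rule)
    h$indication <- pr$indication
    h$biomarker <- bs$biomarker
    h$exploratory <- as.integer(bs$label == "exploratory")
    h$validated <- as.integer(bs$label == "validated")
    h
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
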