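#' Transition structure of the five-state phase-progression model
#'
#' The development of one drug in one indication is modelled on five states:
#' 1 = Phase I, 2 = Phase II, 3 = Phase III, 4 = Approved, 5 = Failed.
#' Progression transitions move a drug one phase forward (1->2, 2->3, 3->4);
#' each transient phase also has a competing failure transition into the
#' absorbing Failed state (1->5, 2->5, 3->5).  Approved and Failed are
#' absorbing.
#'
#' @return A two-column integer matrix of allowed (from, to) state pairs,
#'   with row names of the form `"1-2"`.
#' @export
phase_transitions <- function() {
  tr <- rbind(
    c(1L, 2L), c(1L, 5L),
    c(2L, 3L), c(2L, 5L),
    c(3L, 4L), c(3L, 5L)
  )
  colnames(tr) <- c("from", "to")
  rownames(tr) <- paste(tr[, 1], tr[, 2], sep = "-")
  tr
}

#' State labels of the phase-progression model
#' @return Named integer vector mapping state labels to state numbers.
#' @export
phase_states <- function() {
  c(PhaseI = 1L, PhaseII = 2L, PhaseIII = 3L, Approved = 4L, Failed = 5L)
}

.progression_transitions <- c("1-2", "2-3", "3-4")
.failure_transitions <- c("1-5", "2-5", "3-5")

#' Define a continuous-time multi-state model
#'
#' A model specification holds the state space, the set of allowed
#' instantaneous transitions, the covariates, and the mapping from
#' (transition, covariate) pairs to log-intensity-ratio parameters.  The
#' same parameter name may be mapped to several transitions, giving a
#' shared (common) covariate effect; distinct names give per-transition
#' effects.
#'
#' @param n_states Number of states.
#' @param transitions Two-column integer matrix of allowed (from, to)
#'   pairs.  No transition may leave an absorbing state and the directed
#'   graph must be acyclic (progressive model).
#' @param covariates Character vector of covariate names (columns expected
#'   in the panel data).
#' @param beta_map Data frame with columns `transition` (a row label of
#'   `transitions`, e.g. `"1-2"`), `covariate`, and `param` (the name of
#'   the log intensity-ratio parameter).  `NULL` means no covariate
#'   effects.
#' @param exact_states Integer vector of absorbing states whose entry
#'   times are treated as exactly observed (the "exact death time"
#'   likelihood term) rather than panel-observed.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(n_states, transitions, covariates = character(),
                       beta_map = NULL, exact_states = integer()) {
  transitions <- as.matrix(transitions)
  storage.mode(transitions) <- "integer"
  if (ncol(transitions) != 2L) stop("'transitions' must have two columns")
  if (any(transitions < 1L | transitions > n_states))
    stop("transition states out of range")
  if (any(transitions[, 1] == transitions[, 2]))
    stop("self-transitions are not allowed")
  rownames(transitions) <- paste(transitions[, 1], transitions[, 2], sep = "-")
  if (anyDuplicated(rownames(transitions)))
    stop("duplicate transitions")
  absorbing <- setdiff(seq_len(n_states), unique(transitions[, 1]))
  if (any(transitions[, 1] %in% absorbing))
    stop("transitions out of an absorbing state")
  # progressive (acyclic) check by depth-first search for a back edge
  adj <- split(transitions[, 2], transitions[, 1])
  visited <- integer(n_states)  # 0 unseen, 1 on stack, 2 done
  visit <- function(v) {
    visited[v] <<- 1L
    for (w in adj[[as.character(v)]]) {
      if (visited[w] == 1L) stop("transition graph contains a cycle")
      if (visited[w] == 0L) visit(w)
    }
    visited[v] <<- 2L
  }
  for (v in unique(transitions[, 1])) if (visited[v] == 0L) visit(v)

  if (!is.null(beta_map)) {
    beta_map <- as.data.frame(beta_map, stringsAsFactors = FALSE)
    stopifnot(all(c("transition", "covariate", "param") %in% names(beta_map)))
    bad <- setdiff(beta_map$transition, rownames(transitions))
    if (length(bad)) stop("beta_map refers to unknown transitions: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(beta_map$covariate, covariates)
    if (length(bad)) stop("beta_map refers to unknown covariates: ",
                          paste(bad, collapse = ", "))
    if (anyDuplicated(beta_map[c("transition", "covariate")]))
      stop("duplicate (transition, covariate) rows in beta_map")
  } else {
    beta_map <- data.frame(transition = character(), covariate = character(),
                           param = character(), stringsAsFactors = FALSE)
  }
  if (length(exact_states) && !all(exact_states %in% absorbing))
    stop("'exact_states' must be absorbing states")
  structure(
    list(n_states = as.integer(n_states),
         transitions = transitions,
         covariates = covariates,
         beta_map = beta_map,
         exact_states = as.integer(exact_states),
         absorbing = as.integer(absorbing)),
    class = "model_spec"
  )
}

#' The phase-progression model specification
#'
#' Convenience constructor for the five-state clinical development model
#' with optional proportional covariate effects on the transition
#' intensities.
#'
#' @param covariates Covariate names, e.g. `"biomarker"` (0/1 use of a
#'   biomarker for patient enrolment or exclusion), or
#'   `c("exploratory", "validated")` for the three-level biomarker
#'   sub-analysis (reference level: no biomarker).
#' @param attachment `"per_transition"` gives each attached transition its
#'   own log intensity-ratio parameter per covariate; `"shared"` uses one
#'   common parameter per covariate across all attached transitions (the
#'   phase-independent, "overall" effect).
#' @param on `"progression"` attaches covariate effects to the forward
#'   transitions 1->2, 2->3, 3->4 only (the default: reported effects
#'   concern advancement and approval); `"all"` also attaches them to the
#'   failure transitions.
#' @param exact_approval,exact_failure Treat entry into Approved / Failed
#'   as exactly observed (approval and failure dates are public events).
#' @return A `"model_spec"` object.
#' @export
trial_model_spec <- function(covariates = character(),
                             attachment = c("per_transition", "shared"),
                             on = c("progression", "all"),
                             exact_approval = TRUE, exact_failure = TRUE) {
  attachment <- match.arg(attachment)
  on <- match.arg(on)
  tr <- phase_transitions()
  attached <- if (on == "progression") .progression_transitions else
    rownames(tr)
  beta_map <- NULL
  if (length(covariates)) {
    beta_map <- expand.grid(transition = attached, covariate = covariates,
                            stringsAsFactors = FALSE)
    beta_map$param <- if (attachment == "per_transition")
      paste(beta_map$transition, beta_map$covariate, sep = ":")
    else beta_map$covariate
  }
  exact <- c(if (exact_approval) 4L, if (exact_failure) 5L)
  model_spec(5L, tr, covariates = covariates, beta_map = beta_map,
             exact_states = exact %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_spec <- function(x, ...) {
  cat("Multi-state model:", x$n_states, "states,",
      nrow(x$transitions), "allowed transitions\n")
  cat("  transitions:", paste(rownames(x$transitions), collapse = ", "), "\n")
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
    cat("  effect parameters:",
        paste(unique(x$beta_map$param), collapse = ", "), "\n")
  }
  if (length(x$exact_states))
    cat("  exactly observed absorbing states:",
        paste(x$exact_states, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter layout of a model specification
#'
#' @param spec A `"model_spec"`.
#' @return Character vector of free-parameter names: one log baseline
#'   intensity per allowed transition (named after the transition), then
#'   one log intensity-ratio per unique `param` in the beta map.
#' @export
param_names <- function(spec) {
  c(rownames(spec$transitions), unique(spec$beta_map$param))
}

# Split a flat parameter vector into log-baselines and betas.
.split_params <- function(spec, par) {
  nb <- nrow(spec$transitions)
  pn <- param_names(spec)
  if (length(par) != length(pn))
    stop("parameter vector has length ", length(par), ", expected ",
         length(pn))
  names(par) <- pn
  list(log_baseline = par[seq_len(nb)],
       beta = if (length(pn) > nb) par[(nb + 1L):length(pn)] else
         setNames(numeric(0), character(0)))
}
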