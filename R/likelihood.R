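# Panel-data preparation and the panel likelihood.
#
# A panel dataset is a data.frame with one row per observation:
#   drug_id    subject identifier
#   time       years since the subject's first observation (per subject,
#              strictly increasing)
#   state      exact observed state (integer), or NA when only a set of
#              possible states is known
#   censor_set comma-separated possible states for censored rows
#              (e.g. "2,3,4"); empty/NA for exact rows
# plus one column per model covariate.

# observation-pair types
.PAIR_PANEL <- 1L  # both endpoint states known, observation times
                   # uninformative (snapshot / check-up scheme)
.PAIR_EXACT <- 2L  # entry into an exactly-observed absorbing state
.PAIR_CENS  <- 3L  # terminal observation known only up to a state set
.PAIR_JUMP  <- 4L  # exactly-timed entry into a transient state: the
                   # subject held the start state over the whole
                   # interval and jumped at its end (obs_exact = 1)

.parse_censor_set <- function(x, n_states) {
  s <- as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  if (!length(s) || anyNA(s) || any(s < 1L | s > n_states))
    stop("invalid censor_set: ", x)
  sort(unique(s))
}

# Validates a panel data.frame against a spec and precomputes the
# observation-pair structure grouped by covariate pattern, so repeated
# likelihood evaluations during optimization touch no data.frame code.
.prepare_panel <- function(data, spec) {
  data <- as.data.frame(data)
  need <- c("drug_id", "time", "state")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("panel data lacks columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss))
    stop("panel data lacks covariate columns: ",
         paste(miss, collapse = ", "))
  n <- spec$n_states
  if (nrow(data) == 0L)
    return(list(groups = list(), n_subjects = 0L, n_obs = 0L,
                events = matrix(0, n, n), exposure = numeric(n)))
  if (!"censor_set" %in% names(data)) data$censor_set <- ""
  data$censor_set[is.na(data$censor_set)] <- ""
  if (!"obs_exact" %in% names(data)) data$obs_exact <- 0L
  data$obs_exact[is.na(data$obs_exact)] <- 0L

  ids <- as.character(data$drug_id)
  data <- data[order(match(ids, unique(ids)), data$time), , drop = FALSE]
  ids <- as.character(data$drug_id)
  state <- as.integer(data$state)
  time <- as.numeric(data$time)
  if (any(time < 0, na.rm = TRUE)) stop("observation times must be >= 0")
  censored <- is.na(state) | nzchar(data$censor_set)

  first <- !duplicated(ids)
  last <- !duplicated(ids, fromLast = TRUE)
  if (any(censored & is.na(state) & !last))
    stop("censored observations must be terminal within a subject")
  if (any(!is.na(state) & (state < 1L | state > n)))
    stop("state out of range")
  if (any(!last & !is.na(state) & state %in% spec$absorbing))
    stop("absorbing states must be terminal: no observation may follow ",
         "entry into an absorbing state")
  dt_all <- c(NA, diff(time))
  dt_all[first] <- NA
  if (any(dt_all <= 0, na.rm = TRUE))
    stop("observation times must strictly increase within a subject")

  pair <- which(!first)
  from <- state[pair - 1L]
  if (anyNA(from))
    stop("interval start states must be exactly observed")
  to <- state[pair]
  dt <- dt_all[pair]
  type <- rep(.PAIR_PANEL, length(pair))
  type[is.na(to)] <- .PAIR_CENS
  # an absorbing entry with a known date but panel-observed history in
  # between uses the exact-event-time mixture term; a row flagged
  # obs_exact asserts the start state was held over the whole interval,
  # so the pure jump term applies whatever the destination
  type[!is.na(to) & to %in% spec$exact_states] <- .PAIR_EXACT
  exact_entry <- !is.na(to) & data$obs_exact[pair] > 0
  if (any(exact_entry & to == from))
    stop("an exactly-timed entry observation (obs_exact = 1) must ",
         "record a state change")
  type[exact_entry] <- .PAIR_JUMP
  cens <- matrix(0, length(pair), n)
  for (j in which(type == .PAIR_CENS)) {
    cens[j, .parse_censor_set(data$censor_set[pair[j]], n)] <- 1
  }

  if (length(spec$covariates)) {
    zmat <- as.matrix(data[pair - 1L, spec$covariates, drop = FALSE])
    storage.mode(zmat) <- "double"
    if (anyNA(zmat)) stop("missing covariate values")
    key <- apply(zmat, 1L, paste, collapse = "\r")
  } else {
    zmat <- matrix(0, length(pair), 0L)
    key <- rep("", length(pair))
  }
  groups <- lapply(split(seq_along(pair), key), function(idx) {
    list(z = setNames(as.numeric(zmat[idx[1L], ]), spec$covariates),
         dt = dt[idx], from = from[idx], to = to[idx],
         type = type[idx], cens = cens[idx, , drop = FALSE])
  })

  # crude transition counts and state exposure, for initial values
  events <- matrix(0, n, n)
  ok <- !is.na(to)
  for (j in which(ok & from != to))
    events[from[j], to[j]] <- events[from[j], to[j]] + 1
  exposure <- vapply(seq_len(n), function(s) sum(dt[from == s]), 0)

  list(groups = groups, n_subjects = length(unique(ids)),
       n_obs = nrow(data), events = events, exposure = exposure)
}

# Log-likelihood from a prepared panel structure.
.loglik_prepared <- function(prep, spec, par) {
  if (!length(prep$groups)) return(0)
  n <- spec$n_states
  ll <- 0
  for (g in prep$groups) {
    q <- build_intensity_matrix(spec, par, g$z)
    if (any(!is.finite(q))) {
      out <- -Inf
      attr(out, "diagnostic") <- "non-finite intensities at these parameters"
      return(out)
    }
    m <- length(g$dt)
    contrib <- numeric(m)
    i_jump <- which(g$type == .PAIR_JUMP)
    if (length(i_jump)) {
      # held `from` over the interval, jumped exactly at its end
      contrib[i_jump] <-
        exp(diag(q)[g$from[i_jump]] * g$dt[i_jump]) *
        q[cbind(g$from[i_jump], g$to[i_jump])]
    }
    # transition probabilities only for the rows that need them
    i_need <- which(g$type != .PAIR_JUMP)
    pflat <- if (length(i_need)) .pmat_batch(q, g$dt[i_need]) else NULL
    pcol <- integer(m)
    pcol[i_need] <- seq_along(i_need)
    i_panel <- which(g$type == .PAIR_PANEL)
    if (length(i_panel)) {
      lin <- g$from[i_panel] + (g$to[i_panel] - 1L) * n
      contrib[i_panel] <- pflat[cbind(lin, pcol[i_panel])]
    }
    i_exact <- which(g$type == .PAIR_EXACT)
    if (length(i_exact)) {
      # exact absorbing entry at the end of the interval: density
      # sum_m P_{r m}(dt) q_{m, s} over transient feeder states m
      acc <- numeric(length(i_exact))
      for (s in unique(g$to[i_exact])) {
        sel <- which(g$to[i_exact] == s)
        rows <- i_exact[sel]
        for (mm in which(q[, s] > 0)) {
          lin <- g$from[rows] + (mm - 1L) * n
          acc[sel] <- acc[sel] + pflat[cbind(lin, pcol[rows])] * q[mm, s]
        }
      }
      contrib[i_exact] <- acc
    }
    i_cens <- which(g$type == .PAIR_CENS)
    if (length(i_cens)) {
      acc <- numeric(length(i_cens))
      for (s in seq_len(n)) {
        w <- g$cens[i_cens, s]
        if (any(w > 0)) {
          lin <- g$from[i_cens] + (s - 1L) * n
          acc <- acc + w * pflat[cbind(lin, pcol[i_cens])]
        }
      }
      contrib[i_cens] <- acc
    }
    if (any(!is.finite(contrib) | contrib <= 0)) {
      bad <- which(!is.finite(contrib) | contrib <= 0)[1L]
      out <- -Inf
      attr(out, "diagnostic") <- sprintf(
        "zero-probability observation pair (from state %d, dt=%.4g)",
        g$from[bad], g$dt[bad])
      return(out)
    }
    ll <- ll + sum(log(contrib))
  }
  ll
}

#' Panel log-likelihood of a multi-state Markov model
#'
#' Sums, over subjects and consecutive observation pairs, the log
#' transition terms of the panel-observed continuous-time Markov model:
#' a panel-observed pair (r at t, s at t + dt) contributes
#' log P_rs(dt; z); a terminal observation censored into a state set C
#' contributes log of the sum of P_rs(dt; z) over s in C; entry into an
#' exactly observed absorbing state a contributes the exact-event-time
#' density, log of the sum over transient m of P_rm(dt; z) q_ma(z).
#' An exact-state row flagged `obs_exact = 1` marks the exactly-timed
#' entry into its (transient) state: the subject held the previous state
#' over the whole interval and jumped at its end, contributing
#' log(exp(q_rr dt) q_rs) -- the standard exact-transition-time term.
#' Rows without the flag (or with no `obs_exact` column) use the panel
#' term, appropriate when observation times are uninformative snapshots.
#'
#' @param data Panel data.frame (see [fit_msm()] for the format).
#' @param spec A [model_spec()].
#' @param params Flat parameter vector (log baselines then betas), or a
#'   list with `log_baseline` and `beta`.
#' @return The log-likelihood; `-Inf` (with a `"diagnostic"` attribute)
#'   when some observed pair has probability zero under the model.
#' @export
log_likelihood <- function(data, spec, params) {
  if (is.list(params)) params <- c(params$log_baseline, params$beta)
  prep <- .prepare_panel(data, spec)
  .loglik_prepared(prep, spec, params)
}
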