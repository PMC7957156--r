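# Synthetic drug-development cohorts from a known continuous-time Markov
# ground truth, for validating classification, likelihood, fitting and
# reporting end to end.

#' Configuration of a synthetic development cohort
#'
#' Defaults emulate the structure of a large oncology development cohort
#' observed over a 19-year window (1998-2017 in calendar terms): 745
#' drugs across four indications in the observed proportions, roughly
#' half using biomarker-based patient selection, baseline phase
#' intensities giving mean sojourns of about 1.5 / 2.5 / 3 years in
#' Phases I-III with phase success probabilities near 0.6 / 0.3 / 0.5
#' (about 90% of non-biomarker drugs failing before approval), and a
#' five-fold intensity ratio on the progression transitions for
#' biomarker drugs.
#'
#' @param n_drugs Cohort size.
#' @param indication_mix Probability vector over
#'   breast/colorectal/melanoma/nsclc.
#' @param p_biomarker Probability a drug uses a biomarker.
#' @param p_validated Probability a biomarker drug's biomarker is
#'   validated (rest exploratory).
#' @param baseline_intensities Named per-transition rates (per year).
#' @param beta Named log intensity ratios, names `"transition:covariate"`
#'   (e.g. `"1-2:biomarker"`).  Covariates available to the generator:
#'   `biomarker`, `exploratory`, `validated`.
#' @param observation `"exact_entry"` (default): every state entry is
#'   observed at its true time (trial start, approval and failure dates
#'   are public events) and flagged `obs_exact`; `"sparse"`: transient
#'   states are only seen at fixed check-ups every `checkup_interval`
#'   years (a pure panel scheme exercising the interval-censored
#'   likelihood; absorbing entries stay exactly dated).
#' @param checkup_interval Check-up spacing for the sparse scheme,
#'   years.
#' @param enrolment_window Years over which program starts are uniform.
#' @param admin_censor_time Administrative censoring horizon, years from
#'   the start of the enrolment window (`Inf` disables censoring).
#' @param seed Master seed; per-drug streams are derived from
#'   `(seed, drug_index)` so growing the cohort leaves existing drugs
#'   unchanged.
#' @return Object of class `"sim_config"`.
#' @export
simulation_config <- function(
    n_drugs = 745L,
    indication_mix = c(breast = 183, colorectal = 195, melanoma = 81,
                       nsclc = 286) / 745,
    p_biomarker = 381 / 745,
    p_validated = 80 / 193,
    baseline_intensities = c("1-2" = 0.40, "1-5" = 0.27,
                             "2-3" = 0.12, "2-5" = 0.28,
                             "3-4" = 0.17, "3-5" = 0.17),
    beta = c("1-2:biomarker" = log(5), "2-3:biomarker" = log(5),
             "3-4:biomarker" = log(5)),
    observation = c("exact_entry", "sparse"),
    checkup_interval = 1,
    enrolment_window = 19,
    admin_censor_time = 19,
    seed = 20210223L) {
  observation <- match.arg(observation)
  stopifnot(n_drugs >= 1,
            all(indication_mix >= 0),
            abs(sum(indication_mix) - 1) < 1e-8,
            p_biomarker >= 0, p_biomarker <= 1,
            p_validated >= 0, p_validated <= 1,
            all(baseline_intensities > 0),
            checkup_interval > 0,
            enrolment_window > 0,
            admin_censor_time >= enrolment_window)
  labs <- rownames(phase_transitions())
  if (!setequal(names(baseline_intensities), labs))
    stop("baseline_intensities must be named by the allowed transitions")
  if (length(beta)) {
    parts <- strsplit(names(beta), ":", fixed = TRUE)
    ok <- vapply(parts, function(p)
      length(p) == 2L && p[1] %in% labs &&
        p[2] %in% c("biomarker", "exploratory", "validated"), TRUE)
    if (!all(ok)) stop("beta names must be 'transition:covariate'")
  }
  structure(
    list(n_drugs = as.integer(n_drugs), indication_mix = indication_mix,
         p_biomarker = p_biomarker, p_validated = p_validated,
         baseline_intensities = baseline_intensities[labs], beta = beta,
         observation = observation, checkup_interval = checkup_interval,
         enrolment_window = enrolment_window,
         admin_censor_time = admin_censor_time, seed = as.integer(seed)),
    class = "sim_config")
}

# Reproducible per-drug substream: cohort growth must not reshuffle
# earlier drugs.  Keeps derived seeds inside 32-bit integer range.
.drug_seed <- function(seed, drug_index) {
  as.integer(((as.double(seed) %% 1e6) * 2039 + 7919 * drug_index) %%
               2147483647)
}

.sim_intensity <- function(config, z) {
  tr <- phase_transitions()
  q <- matrix(0, 5L, 5L)
  eta <- log(config$baseline_intensities)
  if (length(config$beta)) {
    parts <- strsplit(names(config$beta), ":", fixed = TRUE)
    for (j in seq_along(config$beta)) {
      lab <- parts[[j]][1]
      cov <- parts[[j]][2]
      eta[lab] <- eta[lab] + config$beta[[j]] * z[[cov]]
    }
  }
  q[tr] <- exp(eta)
  diag(q) <- -rowSums(q)
  q
}

#' Simulate one drug-development program
#'
#' Simulates the latent continuous-time chain by competing exponential
#' clocks in each transient phase (progression vs failure, with
#' proportional covariate multipliers), truncates at the administrative
#' censoring horizon, and emits both the latent trajectory and the
#' observed panel records: exact observations at phase entries and at
#' entry into Approved/Failed, or a terminal censoring observation at
#' the horizon.
#'
#' @param config A [simulation_config()].
#' @param drug_index 1-based index of the drug in the cohort.
#' @param seed Master seed (default: the config's).
#' @return List: `latent` (data.frame of true jump times and states),
#'   `record` (drug-level truth: indication, covariates, start time),
#'   `panel` (observation rows as consumed by [fit_msm()]).
#' @export
simulate_program <- function(config, drug_index, seed = config$seed) {
  s <- .sim_one(config, drug_index, seed)
  list(latent = data.frame(drug_id = s$id, time = s$lat_t,
                           state = s$lat_s, stringsAsFactors = FALSE),
       record = data.frame(
         drug_id = s$id, indication = s$indication, biomarker = s$z[[1]],
         exploratory = s$z[[2]], validated = s$z[[3]], start = s$start,
         censored = s$censored, final_state = s$lat_s[length(s$lat_s)],
         stringsAsFactors = FALSE),
       panel = data.frame(
         drug_id = s$id, time = s$obs_t, state = s$obs_s,
         censor_set = s$obs_c, obs_exact = s$obs_e,
         indication = s$indication, biomarker = s$z[[1]],
         exploratory = s$z[[2]], validated = s$z[[3]],
         stringsAsFactors = FALSE))
}

# One drug as plain vectors (hot path: cohort assembly avoids building
# per-drug data.frames)
.sim_one <- function(config, drug_index, seed = config$seed) {
  set.seed(.drug_seed(seed, drug_index))
  id <- sprintf("D%05d", drug_index)
  indication <- sample(names(config$indication_mix), 1L,
                       prob = config$indication_mix)
  bm <- as.integer(stats::runif(1) < config$p_biomarker)
  validated <- 0L
  exploratory <- 0L
  if (bm == 1L) {
    validated <- as.integer(stats::runif(1) < config$p_validated)
    exploratory <- 1L - validated
  }
  z <- c(biomarker = bm, exploratory = exploratory, validated = validated)
  start <- stats::runif(1, 0, config$enrolment_window)
  horizon <- config$admin_censor_time - start

  q <- .sim_intensity(config, z)
  s <- 1L
  t <- 0
  lat_t <- 0
  lat_s <- 1L
  censored <- FALSE
  repeat {
    rates <- q[s, ]
    rates[rates < 0] <- 0
    total <- sum(rates)
    if (total <= 0) break        # absorbing
    soj <- stats::rexp(1, total)
    if (t + soj > horizon) { censored <- TRUE; break }
    t <- t + soj
    s <- sample.int(5L, 1L, prob = rates)
    lat_t <- c(lat_t, t)
    lat_s <- c(lat_s, s)
  }
  obs <- config$observation %||% "exact_entry"
  if (obs == "exact_entry") {
    obs_t <- lat_t
    obs_s <- lat_s
    obs_e <- c(0L, rep(1L, length(lat_t) - 1L))
  } else {
    # fixed calendar check-ups; the state between them is latent
    final_t <- lat_t[length(lat_t)]
    absorbed <- !censored
    stop_t <- if (absorbed) final_t else horizon
    times <- seq(0, max(stop_t, config$checkup_interval),
                 by = config$checkup_interval)
    times <- unique(c(0, times[times < stop_t - 1e-12]))
    obs_s <- vapply(times, function(tt)
      lat_s[max(which(lat_t <= tt + 1e-12))], 0L)
    obs_t <- times
    if (absorbed) {
      # absorbing entry dates are public even under sparse check-ups
      obs_t <- c(obs_t, final_t)
      obs_s <- c(obs_s, lat_s[length(lat_s)])
    }
    obs_e <- rep(0L, length(obs_t))
  }
  obs_c <- rep("", length(obs_t))
  if (censored) {
    cur <- obs_s[length(obs_s)]
    cset <- if (obs == "exact_entry") {
      # every transition is a public event, so a program with no
      # events by the horizon is known to still hold its last state
      as.character(cur)
    } else {
      # unchecked since the last visit: any onward transient state or
      # approval is possible (absorbing events would have been seen)
      paste(c(seq.int(cur, 3L), 4L), collapse = ",")
    }
    obs_t <- c(obs_t, horizon)
    obs_s <- c(obs_s, NA_integer_)
    obs_c <- c(obs_c, cset)
    obs_e <- c(obs_e, 0L)
  }
  list(id = id, indication = indication,
       z = c(biomarker = bm, exploratory = exploratory,
             validated = validated),
       start = start, censored = censored,
       lat_t = lat_t, lat_s = lat_s,
       obs_t = obs_t, obs_s = obs_s, obs_c = obs_c, obs_e = obs_e)
}

#' Simulate a full synthetic cohort
#'
#' @param config A [simulation_config()].
#' @return List: `panel` (stacked panel data.frame), `truth` (drug-level
#'   ground truth), `latent` (stacked latent trajectories), `config`.
#' @export
simulate_cohort <- function(config) {
  sims <- lapply(seq_len(config$n_drugs), function(i)
    .sim_one(config, i))
  n_obs <- vapply(sims, function(s) length(s$obs_t), 0L)
  n_lat <- vapply(sims, function(s) length(s$lat_t), 0L)
  ids <- vapply(sims, `[[`, "", "id")
  inds <- vapply(sims, `[[`, "", "indication")
  zs <- t(vapply(sims, `[[`, numeric(3), "z"))
  panel <- data.frame(
    drug_id = rep(ids, n_obs),
    time = unlist(lapply(sims, `[[`, "obs_t")),
    state = unlist(lapply(sims, `[[`, "obs_s")),
    censor_set = unlist(lapply(sims, `[[`, "obs_c")),
    obs_exact = unlist(lapply(sims, `[[`, "obs_e")),
    indication = rep(inds, n_obs),
    biomarker = rep(zs[, 1], n_obs),
    exploratory = rep(zs[, 2], n_obs),
    validated = rep(zs[, 3], n_obs),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    drug_id = ids, indication = inds,
    biomarker = zs[, 1], exploratory = zs[, 2], validated = zs[, 3],
    start = vapply(sims, `[[`, 0, "start"),
    censored = vapply(sims, `[[`, TRUE, "censored"),
    final_state = vapply(sims, function(s) s$lat_s[length(s$lat_s)], 0L),
    stringsAsFactors = FALSE)
  latent <- data.frame(
    drug_id = rep(ids, n_lat),
    time = unlist(lapply(sims, `[[`, "lat_t")),
    state = unlist(lapply(sims, `[[`, "lat_s")),
    stringsAsFactors = FALSE)
  list(panel = panel, truth = truth, latent = latent, config = config)
}

# The generator's true parameter vector in the layout of a given spec,
# for bias/coverage bookkeeping.  Betas in the spec but absent from the
# generator are 0.
.true_params <- function(config, spec) {
  pn <- param_names(spec)
  out <- setNames(numeric(length(pn)), pn)
  out[rownames(spec$transitions)] <- log(config$baseline_intensities)
  if (nrow(spec$beta_map)) {
    key <- paste(spec$beta_map$transition, spec$beta_map$covariate,
                 sep = ":")
    have <- key %in% names(config$beta)
    # a shared spec parameter must map to a single true value
    for (p in unique(spec$beta_map$param)) {
      rows <- spec$beta_map$param == p
      vals <- ifelse(have[rows], config$beta[key[rows]], 0)
      if (length(unique(vals)) > 1L)
        stop("generator betas are not constant within shared parameter ",
             p)
      out[p] <- vals[1L]
    }
  }
  out
}

#' Parameter-recovery and test-calibration experiment
#'
#' Simulates `n_replicates` independent cohorts from `config`, fits the
#' no-covariate and with-covariate models to each, and aggregates
#' estimator bias, RMSE, Wald 95% CI coverage of every parameter, and
#' the likelihood-ratio rejection rate at `alpha`.  Non-convergent
#' replicates are counted and excluded from the summaries rather than
#' failing the run.
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of independent cohorts (>= 2).
#' @param spec Alternative-model specification fitted to each cohort
#'   (default: per-transition biomarker effects on progression, matching
#'   the generator's default truth).
#' @param alpha LRT size.
#' @return Object of class `"recovery_summary"`: `per_parameter`
#'   (data.frame: truth, mean estimate, bias, Monte-Carlo SE of the
#'   mean, RMSE, CI coverage), `lrt_rejection_rate`, `n_converged`,
#'   `n_replicates`, `alpha`.
#' @export
recovery_experiment <- function(config, n_replicates,
                                spec = trial_model_spec("biomarker"),
                                alpha = 0.05) {
  stopifnot(n_replicates >= 2)
  truth <- .true_params(config, spec)
  spec0 <- trial_model_spec()
  pn <- param_names(spec)
  est <- matrix(NA_real_, n_replicates, length(pn),
                dimnames = list(NULL, pn))
  cover <- matrix(NA, n_replicates, length(pn),
                  dimnames = list(NULL, pn))
  pvals <- rep(NA_real_, n_replicates)
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer((as.double(config$seed) + 104729 * r) %%
                             2147483647)
    sim <- simulate_cohort(cfg)
    f1 <- tryCatch(fit_msm(sim$panel, spec), error = function(e) NULL)
    f0 <- tryCatch(fit_msm(sim$panel, spec0), error = function(e) NULL)
    if (is.null(f1) || is.null(f0) || !f1$converged || !f0$converged)
      next
    conv[r] <- TRUE
    est[r, ] <- f1$par
    se <- f1$se
    cover[r, ] <- abs(f1$par - truth) <= 1.96 * se
    pvals[r] <- likelihood_ratio_test(f0, f1)$p_value
  }
  ok <- conv
  n_ok <- sum(ok)
  per <- data.frame(
    param = pn,
    truth = unname(truth),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(truth),
    mc_se = apply(est[ok, , drop = FALSE], 2, stats::sd) / sqrt(n_ok),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(truth, each = n_ok))^2)),
    coverage = colMeans(cover[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(per_parameter = per,
         lrt_rejection_rate = mean(pvals[ok] < alpha),
         p_values = pvals[ok],
         n_converged = n_ok, n_replicates = n_replicates, alpha = alpha),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, digits = 4, ...) {
  cat("Parameter recovery over", x$n_converged, "of", x$n_replicates,
      "converged replicates\n")
  print(x$per_parameter, digits = digits)
  cat("LRT rejection rate at alpha =", x$alpha, ":",
      format(x$lrt_rejection_rate, digits = 3), "\n")
  invisible(x)
}
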