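#' Fit a multi-state Markov model to panel data by maximum likelihood
#'
#' Maximizes the panel likelihood (see [log_likelihood()]) by
#' quasi-Newton (BFGS) ascent on the unconstrained parameterization: log
#' baseline intensities and log intensity ratios.  The covariance of the
#' estimates is the inverse of the numerically differentiated observed
#' information at the optimum, and hazard ratios are exp(beta) with Wald
#' 95% intervals exp(beta +/- 1.96 se).
#'
#' @param data Panel data.frame with columns `drug_id`, `time` (years),
#'   `state` (1..n, NA for censored rows), optional `censor_set`
#'   (comma-separated possible states for censored terminal rows), and
#'   one column per covariate in `spec`.
#' @param spec A [model_spec()].
#' @param init Optional initial flat parameter vector.  Default: log
#'   crude rates (observed transition counts over total time at risk,
#'   floored at 1e-6 per year) for the baselines and 0 for the betas.
#' @param seed Seed for any stochastic restart (the default fit is
#'   deterministic; the seed is fixed so restarts are reproducible).
#' @param control Passed to [stats::optim()] (merged over the defaults
#'   `maxit = 500`, `reltol = 1e-10`).
#' @return An object of class `"msm_fit"`: list with `estimate`
#'   (`log_baseline`, `beta`), `par` (flat), `log_likelihood`,
#'   `covariance`, `hazard_ratios` (data.frame), `converged`,
#'   `n_subjects`, `n_observations`, and the `spec`.
#' @export
fit_msm <- function(data, spec, init = NULL, seed = 20210223L,
                    control = list()) {
  prep <- .prepare_panel(data, spec)
  if (prep$n_subjects == 0L) stop("empty panel dataset")
  pn <- param_names(spec)
  nb <- nrow(spec$transitions)

  # warn about transitions never observed (even indirectly) in the data
  obs_any <- prep$events[spec$transitions] > 0
  if (any(!obs_any))
    warning("no observed events for transition(s) ",
            paste(rownames(spec$transitions)[!obs_any], collapse = ", "),
            "; the corresponding intensities are weakly identified",
            call. = FALSE)

  if (is.null(init)) {
    crude <- prep$events[spec$transitions] /
      pmax(prep$exposure[spec$transitions[, 1]], 1e-12)
    init <- c(log(pmax(crude, 1e-6)), rep(0, length(pn) - nb))
  }
  if (length(init) != length(pn))
    stop("'init' must have length ", length(pn))
  names(init) <- pn

  set.seed(seed)
  negll <- function(par) {
    v <- .loglik_prepared(prep, spec, par)
    if (!is.finite(v)) return(1e10)
    -v
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- stats::optim(init, negll, method = "BFGS", control = ctrl)
  est <- opt$par
  ll <- -opt$value
  converged <- opt$convergence == 0L

  hess <- tryCatch(stats::optimHess(est, negll), error = function(e) NULL)
  covmat <- NULL
  if (!is.null(hess)) {
    covmat <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(covmat) && any(!is.finite(covmat))) covmat <- NULL
    if (!is.null(covmat)) dimnames(covmat) <- list(pn, pn)
  }
  se <- if (is.null(covmat)) rep(NA_real_, length(pn)) else {
    d <- diag(covmat)
    ifelse(d >= 0, sqrt(d), NA_real_)
  }
  names(se) <- pn

  split <- .split_params(spec, est)
  hr <- NULL
  if (length(split$beta)) {
    upar <- unique(spec$beta_map$param)
    hr <- data.frame(
      param = upar,
      transitions = vapply(upar, function(p) paste(
        spec$beta_map$transition[spec$beta_map$param == p],
        collapse = ","), ""),
      covariate = vapply(upar, function(p)
        spec$beta_map$covariate[spec$beta_map$param == p][1L], ""),
      hr = exp(split$beta[upar]),
      lower = exp(split$beta[upar] - 1.96 * se[upar]),
      upper = exp(split$beta[upar] + 1.96 * se[upar]),
      se_log = se[upar],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }

  structure(
    list(estimate = split, par = est, log_likelihood = ll,
         covariance = covmat, se = se, hazard_ratios = hr,
         converged = converged, n_subjects = prep$n_subjects,
         n_observations = prep$n_obs, spec = spec,
         counts = list(events = prep$events, exposure = prep$exposure)),
    class = "msm_fit"
  )
}

#' @export
print.msm_fit <- function(x, digits = 4, ...) {
  cat("Multi-state Markov model fit (",
      x$n_subjects, " subjects, ", x$n_observations, " observations)\n",
      sep = "")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  cat("\nBaseline transition intensities (per year):\n")
  lb <- x$estimate$log_baseline
  se <- x$se[names(lb)]
  tab <- data.frame(
    transition = names(lb),
    intensity = exp(lb),
    lower = exp(lb - 1.96 * se),
    upper = exp(lb + 1.96 * se), row.names = NULL)
  print(tab, digits = digits)
  if (!is.null(x$hazard_ratios)) {
    cat("\nHazard (intensity) ratios:\n")
    print(x$hazard_ratios[c("param", "transitions", "hr", "lower", "upper")],
          digits = digits)
  }
  invisible(x)
}

#' Hazard (intensity) ratio of a covariate on one transition
#'
#' @param fit An `"msm_fit"`.
#' @param transition Transition label, e.g. `"3-4"`.
#' @param covariate Covariate name.
#' @return Named numeric vector `(hr, lower, upper)`: the exp-transformed
#'   point estimate and Wald 95% interval.
#' @export
hazard_ratio <- function(fit, transition, covariate) {
  bm <- fit$spec$beta_map
  row <- bm$transition == transition & bm$covariate == covariate
  if (!any(row))
    stop("covariate '", covariate, "' is not attached to transition '",
         transition, "'")
  p <- bm$param[row][1L]
  hr <- fit$hazard_ratios
  i <- match(p, hr$param)
  c(hr = hr$hr[i], lower = hr$lower[i], upper = hr$upper[i])
}

#' Fitted transition intensities at a covariate level
#'
#' Evaluates each allowed transition's fitted intensity
#' q_rs(z) = exp(log q0_rs + beta_rs' z) with a delta-method Wald 95%
#' interval on the log scale.
#'
#' @param fit An `"msm_fit"`.
#' @param covariates Named covariate vector `z` (default all zero).
#' @return Data frame: transition, intensity, lower, upper.
#' @export
transition_intensities <- function(fit, covariates = NULL) {
  spec <- fit$spec
  z <- setNames(numeric(length(spec$covariates)), spec$covariates)
  if (!is.null(covariates)) z[names(covariates)] <- covariates
  pn <- param_names(spec)
  labs <- rownames(spec$transitions)
  out <- lapply(labs, function(lab) {
    grad <- setNames(numeric(length(pn)), pn)
    grad[lab] <- 1
    rows <- spec$beta_map$transition == lab
    if (any(rows)) {
      for (j in which(rows)) {
        grad[spec$beta_map$param[j]] <- grad[spec$beta_map$param[j]] +
          z[spec$beta_map$covariate[j]]
      }
    }
    eta <- sum(grad * fit$par)
    se <- if (is.null(fit$covariance)) NA_real_ else {
      v <- drop(t(grad) %*% fit$covariance %*% grad)
      if (v >= 0) sqrt(v) else NA_real_
    }
    data.frame(transition = lab, intensity = exp(eta),
               lower = exp(eta - 1.96 * se), upper = exp(eta + 1.96 * se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Structural nesting of two specs sharing a transition structure.  The
# null is nested in the alternative when (i) every (transition,
# covariate) pair carrying an effect under the null also carries one
# under the alternative (a pair absent from the null is constrained to
# beta = 0), and (ii) the null's grouping of pairs into shared
# parameters is a coarsening of the alternative's, so the null is
# reachable by equating/zeroing alternative parameters.
.is_nested <- function(spec0, spec1) {
  if (!identical(unname(spec0$transitions), unname(spec1$transitions)))
    return(FALSE)
  b0 <- spec0$beta_map
  b1 <- spec1$beta_map
  if (!nrow(b0)) return(TRUE)
  key0 <- paste(b0$transition, b0$covariate)
  key1 <- paste(b1$transition, b1$covariate)
  if (!all(key0 %in% key1)) return(FALSE)
  # pairs sharing a param in the alternative must share one in the null
  p0 <- b0$param[match(key1, key0)]   # NA for pairs zeroed in the null
  for (grp in split(p0, b1$param)) {
    if (length(unique(grp)) > 1L) return(FALSE)
  }
  length(param_names(spec0)) <= length(param_names(spec1))
}

#' Likelihood-ratio test between nested multi-state model fits
#'
#' @param fit_null,fit_alt Fits of the null (restricted) and alternative
#'   model on the same data.  Nesting is checked structurally: the two
#'   specs must share the transition structure and the null model's free
#'   parameters must be a subset of the alternative's.
#' @return Object of class `"msm_lrt"`: `statistic` (2 * delta
#'   log-likelihood, clamped at 0), `df` (free-parameter difference),
#'   `p_value` (chi-square upper tail).
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  if (!identical(rownames(fit_null$spec$transitions),
                 rownames(fit_alt$spec$transitions)))
    stop("models are not nested: different transition structures")
  if (!.is_nested(fit_null$spec, fit_alt$spec))
    stop("models are not nested: the null model's constraints are not ",
         "a restriction of the alternative's parameterization")
  if (fit_null$n_observations != fit_alt$n_observations)
    stop("fits are not on the same data")
  df <- length(param_names(fit_alt$spec)) -
    length(param_names(fit_null$spec))
  if (df == 0L) df <- 1L  # identical specs: degenerate comparison
  stat <- max(0, 2 * (fit_alt$log_likelihood - fit_null$log_likelihood))
  structure(
    list(statistic = stat, df = as.integer(df),
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
    class = "msm_lrt"
  )
}

#' @export
print.msm_lrt <- function(x, ...) {
  cat("Likelihood ratio test: chi-square =",
      format(x$statistic, digits = 5), "on", x$df, "df, p =",
      format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
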