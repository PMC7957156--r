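test_that("model specifications reject invalid transition structures", {
  expect_error(model_spec(3, rbind(c(1, 2), c(2, 1))), "cycle")
  expect_error(model_spec(3, rbind(c(1, 1))), "self-transitions")
  expect_error(model_spec(3, rbind(c(1, 4))), "out of range")
  spec <- trial_model_spec("biomarker")
  expect_identical(spec$absorbing, c(4L, 5L))
  expect_length(param_names(spec), 9L)
  expect_length(param_names(trial_model_spec("biomarker",
                                             attachment = "shared")), 7L)
})

test_that("intensity matrices satisfy generator invariants", {
  spec <- trial_model_spec("biomarker")
  par <- c(log(c(0.3, 0.1, 0.2, 0.15, 0.25, 0.1)), rep(0, 3))
  q <- build_intensity_matrix(spec, par)
  expect_equal(rowSums(q), rep(0, 5))
  expect_true(all(q[row(q) != col(q)] >= 0))
  expect_equal(q[4, ], rep(0, 5))  # absorbing rows
  expect_equal(q[5, ], rep(0, 5))
  expect_equal(q[1, 1], -0.4)      # diagonal balances the row
  disallowed <- matrix(TRUE, 5, 5)
  disallowed[phase_transitions()] <- FALSE
  diag(disallowed) <- FALSE
  expect_true(all(q[disallowed] == 0))
  # zero betas leave the baseline untouched for any covariate value
  q1 <- build_intensity_matrix(spec, par, c(biomarker = 1))
  expect_equal(q1, q)
  # beta = ln 2 doubles exactly its own transition
  par2 <- par
  par2[7] <- log(2)  # "1-2:biomarker"
  q2 <- build_intensity_matrix(spec, par2, c(biomarker = 1))
  expect_equal(q2[1, 2], 2 * q[1, 2])
  expect_equal(q2[cbind(c(1, 2, 2, 3, 3), c(5, 3, 5, 4, 5))],
               q[cbind(c(1, 2, 2, 3, 3), c(5, 3, 5, 4, 5))])
  expect_equal(rowSums(q2), rep(0, 5))
})

test_that("transition probabilities match exponential closed forms", {
  # single transition: pure exponential survival
  spec2 <- model_spec(2, rbind(c(1, 2)))
  q <- build_intensity_matrix(spec2, log(0.5))
  p <- transition_probability(q, 2)
  expect_equal(p[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(p[1, 2], 1 - exp(-1), tolerance = 1e-12)
  expect_identical(transition_probability(q, 0), diag(2))
  # one transient state feeding two absorbing states
  spec3 <- model_spec(3, rbind(c(1, 2), c(1, 3)))
  q3 <- build_intensity_matrix(spec3, log(c(0.3, 0.1)))
  p3 <- transition_probability(q3, 1)
  expect_equal(p3[1, 1], exp(-0.4), tolerance = 1e-12)
  expect_equal(p3[1, 2], 0.75 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_equal(p3[1, 3], 0.25 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_error(transition_probability(q3, -1), "non-negative")
})

test_that("P(t) is stochastic and satisfies Chapman-Kolmogorov", {
  set.seed(2040)
  for (i in 1:20) {
    q <- random_phase_q()
    s <- runif(1, 0.1, 4)
    t <- runif(1, 0.1, 4)
    ps <- transition_probability(q, s)
    pt <- transition_probability(q, t)
    pst <- transition_probability(q, s + t)
    expect_lt(max(abs(rowSums(pst) - 1)), 1e-8)
    expect_true(all(pst >= 0 & pst <= 1))
    expect_lt(max(abs(ps %*% pt - pst)), 1e-8)
  }
})

test_that("the batched spectral path agrees with the Pade exponential", {
  set.seed(99)
  for (i in 1:10) {
    q <- random_phase_q()
    ts <- runif(7, 0.01, 6)
    pf <- trialpath:::.pmat_batch(q, ts)
    for (j in seq_along(ts)) {
      expect_lt(max(abs(pf[, j] -
                          as.vector(transition_probability(q, ts[j])))),
                1e-9)
    }
  }
  # a defective generator (repeated eigenvalue, single eigenvector)
  # must fall back to the Pade route and still be correct
  qd <- matrix(c(-1, 1, 0, 0, -1, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  pf <- trialpath:::.pmat_batch(qd, c(0.5, 2))
  expect_equal(pf[, 1], as.vector(as.matrix(Matrix::expm(qd * 0.5))),
               tolerance = 1e-9)
})

test_that("panel likelihood matches hand-computed closed forms", {
  spec2 <- model_spec(2, rbind(c(1, 2)))
  # empty data
  empty <- data.frame(drug_id = character(), time = numeric(),
                      state = integer())
  expect_identical(log_likelihood(empty, spec2, log(0.5)), 0)
  # panel pair 1 -> 2 over dt = 2 with q12 = 0.5
  d <- data.frame(drug_id = "a", time = c(0, 2), state = c(1L, 2L))
  expect_equal(log_likelihood(d, spec2, log(0.5)), log(1 - exp(-1)),
               tolerance = 1e-12)
  # same pair flagged as an exactly-timed jump: survival x hazard
  dj <- data.frame(drug_id = "a", time = c(0, 2), state = c(1L, 2L),
                   obs_exact = c(0L, 1L))
  expect_equal(log_likelihood(dj, spec2, log(0.5)),
               -0.5 * 2 + log(0.5), tolerance = 1e-12)
  # impossible transition gives -Inf with a diagnostic, not an error
  d21 <- data.frame(drug_id = "a", time = c(0, 1), state = c(2L, 1L))
  expect_error(log_likelihood(d21, spec2, log(0.5)),
               "absorbing")  # state 2 is absorbing here
  spec3 <- model_spec(3, rbind(c(1, 2), c(2, 3)))
  d13 <- data.frame(drug_id = "a", time = c(0, 1), state = c(1L, 3L),
                    obs_exact = c(0L, 1L))  # claims a direct 1->3 jump
  ll <- log_likelihood(d13, spec3, log(c(0.5, 0.5)))
  expect_identical(unclass(ll)[1], -Inf)
  expect_match(attr(ll, "diagnostic"), "zero-probability")
})

test_that("the exact-event-time term is the density of absorption", {
  # d/dt P_15(t) must equal the exact-entry likelihood term
  # sum_m P_1m(t) q_m5; checked by central finite differences of the
  # independently computed transition probability
  spec <- trial_model_spec()
  par <- log(c(0.4, 0.27, 0.12, 0.28, 0.17, 0.17))
  q <- build_intensity_matrix(spec, par)
  for (t0 in c(0.5, 1.5, 4)) {
    h <- 1e-5
    dnum <- (transition_probability(q, t0 + h)[1, 5] -
               transition_probability(q, t0 - h)[1, 5]) / (2 * h)
    d <- data.frame(drug_id = "a", time = c(0, t0), state = c(1L, 5L))
    term <- exp(log_likelihood(d, spec, par))
    expect_equal(term, dnum, tolerance = 1e-6)
  }
})

test_that("enlarging a terminal censoring set never lowers the likelihood", {
  spec <- trial_model_spec()
  par <- log(c(0.4, 0.27, 0.12, 0.28, 0.17, 0.17))
  base <- data.frame(drug_id = "a", time = c(0, 1.3),
                     state = c(1L, NA_integer_))
  sets <- c("1", "1,2", "1,2,3", "1,2,3,4", "1,2,3,4,5")
  lls <- vapply(sets, function(cs) {
    d <- base
    d$censor_set <- c("", cs)
    log_likelihood(d, spec, par)
  }, 0)
  expect_true(all(diff(lls) >= -1e-12))
  expect_equal(lls[["1,2,3,4,5"]], 0, tolerance = 1e-12)  # full set
})

test_that("fitting exactly observed exponential data recovers the analytic MLE", {
  # on fully observed trajectories the ML intensities are
  # (#transitions r->s) / (total time at risk in r)
  set.seed(515)
  spec2 <- model_spec(2, rbind(c(1, 2)))
  n <- 400
  soj <- rexp(n, 0.5)
  d <- data.frame(
    drug_id = rep(sprintf("d%03d", 1:n), each = 2),
    time = as.vector(rbind(0, soj)),
    state = rep(c(1L, 2L), n),
    obs_exact = rep(c(0L, 1L), n))
  fit <- fit_msm(d, spec2)
  expect_true(fit$converged)
  expect_equal(exp(fit$estimate$log_baseline[["1-2"]]), n / sum(soj),
               tolerance = 1e-5)
})

test_that("degenerate cohorts warn and stay honest", {
  # no drug ever reaches phase III: 2-3 and onward are unidentified
  set.seed(77)
  cfg <- simulation_config(n_drugs = 60, seed = 3,
                           baseline_intensities = c(
                             "1-2" = 0.3, "1-5" = 0.9, "2-3" = 1e-9,
                             "2-5" = 0.9, "3-4" = 0.2, "3-5" = 0.2),
                           beta = c("1-2:biomarker" = 0))
  sim <- simulate_cohort(cfg)
  expect_false(any(sim$panel$state %in% 3L, na.rm = TRUE))
  expect_warning(fit <- fit_msm(sim$panel, trial_model_spec()),
                 "no observed events")
  expect_true(is.finite(fit$log_likelihood))
})

test_that("Wald hazard ratios are exp(beta) with ordered bounds", {
  cfg <- simulation_config(n_drugs = 300, seed = 21)
  sim <- simulate_cohort(cfg)
  fit <- fit_msm(sim$panel, trial_model_spec("biomarker"))
  hr <- fit$hazard_ratios
  expect_equal(hr$hr, exp(unname(fit$estimate$beta[hr$param])))
  expect_true(all(hr$lower < hr$hr & hr$hr < hr$upper))
  one <- hazard_ratio(fit, "3-4", "biomarker")
  expect_equal(unname(one["hr"]),
               hr$hr[hr$param == "3-4:biomarker"])
  expect_error(hazard_ratio(fit, "1-5", "biomarker"), "not attached")
  # the exp(+/- 1.96 se) structure of the interval
  se <- hr$se_log[1]
  expect_equal(hr$upper[1] / hr$hr[1], exp(1.96 * se), tolerance = 1e-8)
})

test_that("likelihood-ratio tests count parameters and order invariantly", {
  cfg <- simulation_config(n_drugs = 300, seed = 5)
  sim <- simulate_cohort(cfg)
  spec0 <- trial_model_spec()
  spec1 <- trial_model_spec("biomarker")
  f0 <- fit_msm(sim$panel, spec0)
  f1 <- fit_msm(sim$panel, spec1)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_identical(lrt$df, 3L)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 3, lower.tail = FALSE))
  # identical fits: statistic 0, p = 1
  self <- likelihood_ratio_test(f0, f0)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # subject order must not matter
  perm <- sim$panel[order(rev(match(sim$panel$drug_id,
                                    unique(sim$panel$drug_id))),
                          sim$panel$time), ]
  f1p <- fit_msm(perm, spec1)
  expect_equal(f1p$log_likelihood, f1$log_likelihood, tolerance = 1e-6)
  lrtp <- likelihood_ratio_test(fit_msm(perm, spec0), f1p)
  expect_equal(lrtp$statistic, lrt$statistic, tolerance = 1e-4)
  # the shared-effect model nests in the per-transition model
  fsh <- fit_msm(sim$panel, trial_model_spec("biomarker",
                                             attachment = "shared"))
  lrt2 <- likelihood_ratio_test(fsh, f1)
  expect_identical(lrt2$df, 2L)
  expect_gte(lrt2$statistic, -1e-8)
  # non-nested structures are rejected
  expect_error(likelihood_ratio_test(f1, fsh), "not nested")
})
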