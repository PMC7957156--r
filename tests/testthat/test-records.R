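test_that("phase outcomes of the hand-traced programs classify exactly", {
  programs <- as_drug_programs(fixture_trials())
  expected <- fixture_expected_outcomes()
  for (pid in names(expected)) {
    pr <- programs[[grep(pid, names(programs))]]
    for (ph in names(expected[[pid]])) {
      out <- classify_phase_outcome(pr, ph, REF_DATE)
      expect_identical(out$status, unname(expected[[pid]][[ph]]),
                       label = paste(pid, "phase", ph))
    }
  }
})

test_that("outcome classification is exhaustive and errors on absent phases", {
  programs <- as_drug_programs(fixture_trials())
  for (pr in programs) {
    attempted <- unique(sub("I_II", "I", pr$trials$phase))
    for (ph in attempted) {
      st <- classify_phase_outcome(pr, ph, REF_DATE)$status
      expect_true(st %in% c("success", "failure", "ongoing"))
    }
  }
  p9 <- programs[[grep("P09", names(programs))]]
  expect_error(classify_phase_outcome(p9, "I", REF_DATE), "phase absent")
})

test_that("biomarker status respects the 2-year validation window", {
  reg <- fixture_registry()
  # never approved in the indication
  expect_identical(
    classify_biomarker_status("BRCA1", "breast", "2014-01-01", reg)$label,
    "exploratory")
  # approved in a different indication only
  expect_identical(
    classify_biomarker_status("ALK", "breast", "2014-01-01", reg)$label,
    "exploratory")
  # KRAS/colorectal approved 2009-07-01: the window closes 730 days later
  expect_identical(
    classify_biomarker_status("KRAS", "colorectal", "2008-01-01",
                              reg)$label, "exploratory")
  expect_identical(
    classify_biomarker_status("KRAS", "colorectal", "2010-07-01",
                              reg)$label, "exploratory")
  expect_identical(  # exactly 730 days: still inside the window
    classify_biomarker_status("KRAS", "colorectal", "2011-07-01",
                              reg)$label, "exploratory")
  expect_identical(  # 731 days: validated
    classify_biomarker_status("KRAS", "colorectal", "2011-07-02",
                              reg)$label, "validated")
  expect_identical(
    classify_biomarker_status("KRAS", "colorectal", "2014-07-01",
                              reg)$label, "validated")
  # no biomarker at all
  expect_identical(
    classify_biomarker_status(NA, "breast", "2014-01-01", reg)$label,
    "none")
  expect_error(
    classify_biomarker_status("KRAS", "pancreatic", "2014-01-01", reg),
    "unknown indication")
})

test_that("state histories end in the hand-derived terminal state", {
  programs <- as_drug_programs(fixture_trials())
  expected <- fixture_expected_terminal()
  for (pid in names(expected)) {
    pr <- programs[[grep(pid, names(programs))]]
    h <- build_state_history(pr, REF_DATE)
    expect_true(all(diff(h$time) > 0), label = paste(pid, "times"))
    expect_identical(h$time[1L], 0, label = paste(pid, "origin"))
    last <- h[nrow(h), ]
    if (!is.null(expected[[pid]]$state)) {
      expect_identical(last$state, expected[[pid]]$state,
                       label = paste(pid, "terminal state"))
      expect_identical(last$censor_set, "")
    } else {
      expect_true(is.na(last$state), label = paste(pid, "censored"))
      expect_identical(last$censor_set, expected[[pid]]$censor,
                       label = paste(pid, "censor set"))
    }
    # absorbing rows are terminal
    abs_rows <- which(!is.na(h$state) & h$state %in% c(4L, 5L))
    if (length(abs_rows)) expect_identical(abs_rows, nrow(h))
  }
})

test_that("history times are exact calendar differences in years", {
  programs <- as_drug_programs(fixture_trials())
  p1 <- programs[[grep("P01", names(programs))]]
  h <- build_state_history(p1, REF_DATE)
  d0 <- as.Date("2005-01-01")
  expect_equal(h$time, as.numeric(as.Date(c(
    "2005-01-01", "2006-06-01", "2009-01-01", "2012-03-01")) - d0) /
      365.25)
  expect_identical(h$state, c(1L, 2L, 3L, 4L))
})

test_that("later reference dates only resolve ongoing phases", {
  programs <- as_drug_programs(fixture_trials())
  # P03 ongoing at REF_DATE becomes a failure two years on
  p3 <- programs[[grep("P03", names(programs))]]
  expect_identical(classify_phase_outcome(p3, "I", REF_DATE)$status,
                   "ongoing")
  expect_identical(
    classify_phase_outcome(p3, "I", as.Date("2019-01-01"))$status,
    "failure")
  # successes and failures never flip with a later reference date
  for (pid in c("P01", "P02", "P05", "P07", "P08")) {
    pr <- programs[[grep(pid, names(programs))]]
    expected <- fixture_expected_outcomes()[[pid]]
    for (ph in names(expected)) {
      if (expected[[ph]] == "ongoing") next
      expect_identical(
        classify_phase_outcome(pr, ph, as.Date("2021-01-01"))$status,
        unname(expected[[ph]]), label = paste(pid, ph, "stable"))
    }
  }
})

test_that("histories agree with the per-phase classifications (round trip)", {
  programs <- as_drug_programs(fixture_trials())
  expected <- fixture_expected_outcomes()
  for (pid in names(expected)) {
    pr <- programs[[grep(pid, names(programs))]]
    h <- build_state_history(pr, REF_DATE)
    statuses <- expected[[pid]]
    last_phase_state <- max(h$state[!is.na(h$state) & h$state <= 3L])
    final <- statuses[[length(statuses)]]
    if (final == "success") {
      expect_identical(h$state[nrow(h)], 4L, label = pid)
    } else if (final == "failure") {
      expect_identical(h$state[nrow(h)], 5L, label = pid)
    } else {
      # censoring set starts at the last transient phase reached
      expect_match(h$censor_set[nrow(h)],
                   paste0("^", last_phase_state), label = pid)
    }
  }
})

test_that("drug-level biomarker covariates follow the any-trial rule", {
  programs <- as_drug_programs(fixture_trials())
  reg <- fixture_registry()
  st10 <- drug_biomarker_status(programs[[grep("P10", names(programs))]],
                                reg)
  expect_identical(st10$biomarker, 1L)
  expect_identical(st10$label, "validated")
  st12 <- drug_biomarker_status(programs[[grep("P12", names(programs))]],
                                reg)
  expect_identical(st12$label, "exploratory")
  expect_true(st12$mixed)  # only the first P12 trial used the biomarker
  st01 <- drug_biomarker_status(programs[[grep("P01", names(programs))]],
                                reg)
  expect_identical(st01$biomarker, 0L)
  expect_identical(st01$label, "none")
})

test_that("build_panel assembles covariates and valid panel structure", {
  panel <- build_panel(fixture_trials(), REF_DATE, fixture_registry())
  expect_identical(length(unique(panel$drug_id)), 12L)
  expect_setequal(unique(panel$biomarker), c(0L, 1L))
  expect_identical(
    sort(unique(panel$drug_id[panel$biomarker == 1L])), c("P10", "P12"))
  expect_identical(unique(panel$validated[panel$drug_id == "P10"]), 1L)
  expect_identical(unique(panel$exploratory[panel$drug_id == "P12"]), 1L)
  # the panel must satisfy the observation invariants the likelihood
  # enforces (no error on preparation)
  ll <- log_likelihood(panel, trial_model_spec(),
                       log(c(0.4, 0.2, 0.3, 0.2, 0.2, 0.2)))
  expect_true(is.finite(ll))
})
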