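---
title: "Modelling clinical-trial phase progression as a multi-state Markov process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical-trial phase progression as a multi-state Markov process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A drug's development in one indication is a path on five states:
Phase I (1), Phase II (2), Phase III (3), Approved (4) and Failed (5).
Approved and Failed are absorbing.  The allowed instantaneous
transitions are the three progressions 1→2, 2→3, 3→4 and the three
competing failures 1→5, 2→5, 3→5; the process is progressive (no
return to an earlier phase).  Time is continuous, measured in **years**
from the drug's first phase entry.  The transition intensities q_rs
form the generator Q (off-diagonals non-negative, rows summing to
zero), and the probability of occupying state s after an elapsed time
t, given state r now, is the (r, s) entry of P(t) = exp(Qt).

Covariates z (biomarker use; or indicators for exploratory and
validated biomarkers) act on the intensities proportionally,

$$ q_{rs}(z) = q^{(0)}_{rs}\, e^{\beta_{rs}^\top z}, $$

the standard proportional-intensities form for this model family;
exp(β) is the intensity ratio, reported as a hazard ratio.  Two
attachments are supported, because "the effect of a biomarker on
success" is genuinely ambiguous between them: a *per-transition*
attachment (one β per progression transition, needed for
hazard-by-phase summaries) and a *shared* attachment (a single β across
the progression transitions, reported as the phase-independent
"overall" HR).  The pipeline reports both.  By default covariates are
attached to progression transitions only — reported effects concern
advancement and approval — and attaching them to the failure
transitions as well is a configuration option (`on = "all"`).

Estimation is unconstrained quasi-Newton (BFGS) ascent on the log
baseline intensities and the β's, initialized at log crude rates
(observed transition counts over total time at risk, floored at 1e-6
per year) and zero β's, with convergence at relative log-likelihood
change below 1e-10 (at most 500 iterations).  The covariance is the
inverse of the numerically differentiated observed information at the
optimum; intervals are Wald on the log scale, exp-transformed.  Nested
models are compared by likelihood-ratio tests with degrees of freedom
equal to the free-parameter difference, where nesting is checked
structurally (the null's parameter grouping must be a coarsening of the
alternative's, with absent pairs read as β = 0).

## Observation semantics: what a panel row means

The likelihood is a product over consecutive observation pairs within a
drug, and each pair contributes one of four terms:

* **panel**: both states known, times uninformative — log P_rs(Δt; z);
* **censored terminal**: state known only to lie in a set C —
  log Σ_{s∈C} P_rs(Δt; z);
* **exact absorbing entry**: entry into Approved/Failed at a known date
  with a panel-observed history before it — the exact-event-time
  density log Σ_m P_rm(Δt) q_m,abs;
* **exactly-timed entry** (`obs_exact = 1`): the previous state was
  held over the whole interval and the jump happened at its end —
  log(e^{q_rr Δt} q_rs).

The fourth term deserves its rationale.  Phase-entry dates, approval
dates and failure dates are public events: a state history built from
trial records observes each transition at its true time.  Treating such
rows with the plain panel term makes the sampling times informative and
the likelihood degenerate — the Phase-I exit intensities drift to the
boundary (q_12 → ∞ with failures reattributed through Phase II),
because "being in Phase II exactly Δt after Phase I entry" is made most
likely by an instantaneous jump.  With the exactly-timed term the
likelihood on fully observed paths reduces to the classical
exposure-and-events form, and the ML intensities equal
(#transitions r→s)/(time at risk in r) — a property the test suite
checks against the analytic MLE.  Rows without the flag keep the panel
term, which is the correct choice for genuine snapshot schemes (the
generator's sparse check-up mode, below).

For administratively censored programs the censoring set depends on
what the observer could have seen.  Under the exact-entry scheme every
event is public, so "no event by the horizon" pins the current state:
the set is {current phase} and the term is the exponential survival
probability.  For real trial tables the failure rule involves a 2-year
discovery delay, so the terminal state is genuinely uncertain and the
set is {current phase, later transient phases, Approved} — a failure
would eventually have been declared, states behind the drug are
impossible, but it may have quietly advanced.

## Classification rules for trial records

Deterministic rules turn a trial table into state histories.  A phase
succeeds when a later-phase trial exists in the same indication (Phase
III: when the drug is FDA-approved).  It fails when the manufacturer
withdrew the drug, declared its primary endpoints missed, or more than
2 years (calendar-exact, 730 days; the boundary day counts as inside
the window) passed after the completion of the phase's latest trial
with no further development.  Otherwise the phase is ongoing: earlier
phases count as successes and the program is censored at the reference
date.  Phase I/II hybrid trials count as Phase I.  A drug first seen in
Phase II or III simply starts its history there; the clock always
starts at the first in-indication phase entry.  When several trials
share a phase, the phase enters at the earliest start and completes at
the latest completion.  The failure observation is timed at the failing
phase's last completion date: the 2-year rule is a discovery delay, not
an event time, and absorbing entries are conventionally treated as
exactly dated.

A drug is biomarker-based when **any** of its trials used a biomarker
for patient enrolment or exclusion (the permissive reading; an
every-trial rule is available, and mixed programs are flagged).  A
biomarker is *exploratory* in an indication until 2 years after its
first FDA approval there — use on the boundary day is still
exploratory — and *validated* afterwards; with no approval it stays
exploratory.  The three-level status is assigned at the drug's first
biomarker use (drug-level; a phase-level variant would re-classify per
trial and is deliberately not the default, since the sub-analysis
contrasts drugs).

## What the generator emulates — and what it does not

`simulation_config()` defines the study conditions the synthetic
cohorts emulate: 745 drugs split across breast / colorectal / melanoma
/ NSCLC in proportions 183:195:81:286; a biomarker-use probability of
381/745, with biomarker drugs split validated:exploratory ≈ 80:113;
program starts uniform over a 19-year enrolment window with
administrative censoring at its end; baseline intensities
(per year) of 0.40/0.27 out of Phase I, 0.12/0.28 out of Phase II and
0.17/0.17 out of Phase III.  Those baselines give mean phase sojourns
of roughly 1.5, 2.5 and 3 years, embedded-chain success probabilities
of about 0.60, 0.30 and 0.50 per phase, and so a ≈91% overall failure
rate among non-biomarker drugs that resolve — the qualitative regime of
large oncology development cohorts.  The default covariate effect is a
five-fold intensity ratio on each progression transition for biomarker
drugs.  These are fixture choices for validation, not estimates of any
real portfolio.

Each drug's random stream is derived from (seed, drug index), so
growing a cohort never reshuffles existing drugs.  The generator emits
the latent trajectory, the drug-level truth, and the observed panel
under either observation scheme (exact entries, or sparse fixed
check-ups that stress the interval-censored likelihood).

Deliberately not emulated: correlation between indication and
intensities (all indications share one truth, so per-indication fits
differ only by sampling noise); time-varying biomarker status within a
drug; trial-level structure inside a phase; calendar trends in
intensities; informative (non-administrative) censoring.  Passing
recovery tests on these cohorts therefore demonstrates correctness of
the estimator and pipeline under the model's own assumptions — it says
nothing about whether a real portfolio satisfies those assumptions.

## Numerical choices

* **Matrix exponential.**  The exported `transition_probability()` uses
  scaling-and-squaring Padé (`Matrix::expm`), with no diagonalizability
  assumption.  The likelihood's batched path computes P(t) for many t
  from one spectral decomposition of Q — valid here because a
  progressive Q is triangular up to relabelling — and accepts the
  decomposition only when it reconstructs Q to 1e-9 relative accuracy,
  falling back to Padé per distinct time otherwise (e.g. for defective
  generators with repeated eigenvalues).  Tiny negative round-off in
  P is clamped to zero.
* **Zero-probability observations** make the log-likelihood −∞ with a
  diagnostic attribute rather than throwing, so the optimizer treats
  impossible parameter regions as very bad instead of crashing.
* **Degenerate data** (a transition never observed) produce a warning
  and a boundary estimate with an honest `converged` flag; a singular
  information matrix yields absent (null-serialized) intervals, never
  fabricated numbers.
* **Determinism.**  Classification is rule-based with no randomness;
  fits are deterministic given data; all simulation randomness flows
  from the configured seed, and reports serialize with sorted keys and
  fixed precision so identical runs are byte-identical.

## Validation scale

The test suite validates the engine at sizes chosen to exercise the
asymptotics while staying desk-runnable: analytic closed forms to
1e-10; a 100,000-path Monte-Carlo occupancy oracle against P(t) for
five random generators; Chapman–Kolmogorov and row-normalization on
randomized models to 1e-8; parameter recovery on 100 replicate cohorts
of 1000 drugs (bias within three Monte-Carlo standard errors, CI
coverage in [0.90, 1.00]); and LRT size under the null on 200 replicate
cohorts (rejection in [0.02, 0.08] at α = 0.05).  `scripts/acceptance.R`
re-runs the pooled and sub-group analyses on the default 745-drug
cohort and the calibration experiments from a command-line seed.

## Known limitations

Intensities are time-homogeneous: no calendar trends, no phase-age
effects, no frailty.  Covariates are fixed per drug.  Wald intervals
can be poor for transitions with few events (the Phase III→Approved
cell is the sparsest; profile-likelihood intervals are out of scope).
The likelihood treats the classification rules' output as data:
misclassification (e.g. a failure not yet discoverable at the reference
date) propagates.  Absolute intensities depend on the chosen time unit
(years); intensity *ratios* are unit-free.  No multiplicity adjustment
is applied across the reported LRTs — raw p-values are reported and
labelled as such.
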