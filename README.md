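# trialpath

Multi-state Markov modelling of drug-development trajectories through
clinical trial phases.

## The problem

Most oncology drugs entering clinical testing never reach approval, and
a central question for trial design is whether biomarker-based patient
selection (enrolling or excluding patients by a predictive marker)
changes that risk.  `trialpath` treats the development of one drug in
one indication as a stochastic process on five states:

```
  1 Phase I --> 2 Phase II --> 3 Phase III --> 4 Approved
      |             |              |
      +-------------+--------------+--------->  5 Failed
```

and models it as a continuous-time Markov chain.  Each allowed
transition r→s has an intensity q_rs — the instantaneous rate of moving
from r to s — collected in a generator matrix Q whose rows sum to zero.
Covariates act proportionally on the intensities,

    q_rs(z) = q⁰_rs · exp(β_rs' z),

so exp(β) is the intensity ratio (reported as a hazard ratio, HR) of,
say, biomarker-selected versus unselected drugs on that transition.
Transition probabilities over an elapsed time t are P(t) = exp(Qt), and
programs still in testing at the analysis date are right-censored: the
likelihood sums P over the states they could occupy.  Models with and
without a covariate are compared by likelihood-ratio tests (LRT), with
degrees of freedom equal to the number of extra parameters.

The package is aimed at analysts of drug-development portfolios:
it takes a curated table of trials (one row per trial, with phases,
dates, outcome flags and biomarker usage), applies deterministic
classification rules (a phase succeeds when the drug advances; it fails
on >2 years of inactivity, manufacturer withdrawal, or missed primary
endpoints; otherwise it is ongoing and censored), and fits the model by
maximum likelihood.  A synthetic-cohort generator with known ground
truth makes every stage testable without access to any proprietary
dataset.

## Worked example

```r
library(trialpath)

# a small synthetic trial table shipped with the package
trials <- read_trials_csv(system.file(
  "extdata", "example_trials_synthetic.csv", package = "trialpath"))
registry <- read_biomarker_registry(system.file(
  "extdata", "example_registry_synthetic.csv", package = "trialpath"))

# classify outcomes and build the five-state panel dataset
panel <- build_panel(trials, as.Date("2017-01-02"), registry)
head(panel, 4)
#>   drug_id     time state censor_set obs_exact indication biomarker ...
#> 1     P01 0.000000     1                    0     breast         0
#> 2     P01 1.412731     2                    1     breast         0
#> 3     P01 4.000000     3                    1     breast         0
#> 4     P01 7.162218     4                    1     breast         0

# a cohort-sized analysis on simulated data with a known five-fold
# biomarker effect on every progression transition
sim <- simulate_cohort(simulation_config(n_drugs = 745, seed = 2021))
report <- run_pooled_analysis(sim$panel)
print(report)
#> Analysis report: pooled ( 745 drugs )
#>   drugs in Phase I/II/III: 745 / 530 / 277
#>   model comparison (biomarker): Likelihood ratio test:
#>     chi-square = 551.51 on 3 df, p = < 2.2e-16
#>   phase-independent HR: 4.88 [4.24, 5.61]
```

The phase-independent HR is the shared intensity ratio across the three
progression transitions (Phase I→II, II→III, III→Approved): here the
fitted 4.88 with 95% CI [4.24, 5.61] recovers the simulated five-fold
effect, and the LRT says biomarker status improves the model fit
decisively.  `report$per_phase_hazards` holds the fitted per-phase
transition intensities (per year) at each covariate level with Wald
intervals — the quantities usually drawn as hazard-by-phase figures —
and `write_report(report, "report.json")` serializes everything
deterministically.

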