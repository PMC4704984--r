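---
title: "Methods: a stepped-care cost-utility model for mild-to-moderate depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stepped-care cost-utility model for mild-to-moderate depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcea)
```

## The decision problem

`stepcea` evaluates three first-line strategies for an adult presenting to an
Australian GP with mild-to-moderate depression: antidepressant medication
with GP monitoring (TAU), a course of face-to-face CBT with a clinical
psychologist, and myCompass, an automated internet/mobile CBT-based self-help
program used as the low-intensity first step of a stepped-care pathway.
Benefits are quality-adjusted life years over a 28-week horizon; costs are
Australian-dollar outlays of the public provider (Medicare item fees, PBS
medication, program delivery), 2013/14 prices. No discounting is applied —
the horizon is under a year. The optimal strategy is the one with the highest
expected net monetary benefit `NMB = E·λ − C` at a willingness-to-pay of
λ = AUD 50,000 per QALY.

## Model structure

Patients occupy one of three mutually exclusive health states — depressive
*episode*, *remission*, and *maintenance* — over four 7-week cycles. The
model is an unrolled decision tree, evaluated by exhaustive path enumeration
(nine root-to-terminal paths per arm); there is no Markov generalisation
beyond the fixed four-cycle horizon.

* **Cycle 1 (acute phase).** Everyone starts in the episode state on their
  assigned treatment. A patient is first either adherent or non-adherent
  (arm-specific acute non-adherence probability), and adherent patients
  respond with the arm's initial effect size.
* **Step-up.** Acute non-adherers and adherent non-responders switch to
  second-line antidepressant TAU, per stepped-care protocol. The switch
  occupies cycle 2 (episode state, one cycle of medication plus GP
  monitoring); successful switchers remit and spend cycles 3–4 in
  maintenance on antidepressants, unsuccessful ones discontinue and remain
  in the episode state.
* **Maintenance phase (cycles 2–4).** Acute responders enter a 21-week
  maintenance phase. The arm's maintenance effect size and maintenance
  non-adherence each apply *once over the phase*, matching the single
  per-arm maintenance values in the parameter table rather than a per-cycle
  hazard. Non-adherers return to treatment with probability 0.4 and
  otherwise discontinue. Patients who maintain remission spend the phase in
  the maintenance state; relapse (including discontinuation) returns them to
  the episode state for the whole phase.

The topology is not hard-coded: it ships as a JSON document
(`inst/extdata/topology.json`, loaded by `read_topology()`) in which every
branch probability is a parameter reference or its complement, so the
reconstruction can be amended — and its consequences re-tested — without code
changes.

### Structural choices the published description leaves open

The source tree for this class of model is typically published only in part,
so several choices had to be fixed here. Each is a deliberate design
decision:

* **Remission after switching.** Two switch-remission probabilities are
  given: 0.306 for "second-line antidepressants" (a Beta(440, 999) from
  sequenced-treatment trial data) and 0.585 after CBT (a lognormal
  meta-analytic estimate). We read 0.306 as the remission rate on a *second
  antidepressant after a first antidepressant has failed* — the well-known
  drug-sequence penalty — and 0.585 as remission on antidepressants after
  failure of *CBT-based psychological therapy*. Patients failing CBT or the
  CBT-based myCompass program are pharmacologically naive, so both of those
  arms use 0.585 and only the TAU arm uses 0.306. This mapping is the only
  one under which the model reproduces the expected orderings (a small QALY
  advantage of myCompass over TAU, and the highest NMB for myCompass at the
  AUD 50,000 threshold); the opposite mapping makes every parameter favour
  TAU and the orderings unreachable for any shared-structure tree.
* **Relapse timing.** Because the maintenance effect applies once per phase,
  relapse is also resolved at phase level: a relapsing responder spends
  cycles 2–4 in the episode state. No half-cycle correction is applied;
  transitions occur at cycle boundaries.
* **Utilities for discontinued or relapsed patients.** Episode utility for
  the remaining weeks — conservative, and consistent with assigning
  utilities only to the three named states.
* **Costs for non-completers.** Treatment costs are adjusted pro rata:
  non-completers incur a configurable `completion_fraction` (default 0.5) of
  the phase's intervention cost. This is flagged as a reconstruction choice.
* **Second-line costs** accrue for the remaining cycles only: one episode
  cycle of medication, plus two maintenance cycles for successful switchers.
* **Severity mix.** Moderate cases present to services at roughly twice the
  rate of mild ones (68.8% vs 31.2%); the mix enters the QALY weights only,
  `u(episode) = 0.688·u_moderate + 0.312·u_mild`, not costs or transition
  probabilities.
* **Psychiatrist use** (0.056 consultations "per episode") is charged once
  per episode *spell*: once for the presenting episode, and again on
  relapse.
* **CBT maintenance boosters.** "Monthly booster sessions" over the 21-week
  phase are realised as 21 × 12/52 ≈ 4.85 expected sessions at the
  single-session psychologist fee.

## Parameters

All inputs live in a single table (`default_config()$parameters`): name,
role (probability, utility, unit cost, resource count, scaling constant),
point estimate, uncertainty distribution, bounds, and a source note. Two
conventions matter:

* **Point estimates vs distributions.** Deterministic (base-case) runs use
  the printed point estimates; probabilistic runs sample the printed
  distributions. For a few Beta rows the two disagree in the third decimal
  (e.g. 0.462 vs 121/261 = 0.4636), and the lognormal(−0.713, 0.188) row has
  mean ≈ 0.499 against a printed point of 0.585. Both are stored verbatim;
  neither is recomputed from the other.
* **Bounds.** Beta and uniform draws are bounded by construction; lognormal
  draws for a probability-role parameter are truncated at 1 by resampling,
  which preserves the low quantiles.

Sampling (`sample_parameters()`) gives each parameter a deterministic
substream derived from the root seed and the parameter's *name*, so adding a
parameter never reshuffles the draws of the others, and a seed fully
determines every downstream result.

**Medication cost placeholder.** The per-cycle antidepressant cost is not
part of the published unit-cost table (it was described only as an average of
the least and most costly commonly prescribed agents). The packaged default,
`cost_medication_per_cycle = 80` AUD per 7-week cycle (≈ AUD 51/month,
mid-range of 2013/14 PBS dispensed prices), was fixed once, a priori, and is
prominently flagged in the configuration. The acceptance checks were chosen
to be insensitive to it; any costing exercise that is not should replace it.

## Probabilistic sensitivity analysis

`run_psa()` propagates all distributions simultaneously: each of the 10,000
default iterations draws one parameter set and applies it to *all three*
strategies (common random numbers — the only coherent choice when utilities
and switch probabilities are shared across arms). Summaries use equal-tailed
empirical 2.5/97.5 percentiles with no smoothing. The CEAC reports, per λ on
a default grid of 0–100,000 in steps of 1,000, the fraction of iterations in
which each strategy attains the highest NMB; exact ties (probability zero
under continuous draws, but possible for degenerate configurations) break by
lowest cost, then declaration order, so results are deterministic. At λ = 0
the CEAC winner is the cost-minimising strategy by construction.

Because every unit cost is treated as fixed in the PSA (the published
uncertainty distributions cover probabilities and utilities only; costs are
varied in one-way analysis instead), the cost gap between CBT and the other
arms is essentially constant across iterations. A consequence worth noting:
each iteration's CBT-wins region in λ is an upper interval, so the empirical
CBT acceptability curve is exactly nondecreasing.

## One-way and threshold analysis

`one_way()` is a deterministic sweep: one parameter moves across a grid
(default 101 points), all others stay at their point estimates, and the
expected NMB of the optimal strategy is recorded — the standard tornado
construction. Published sweep ranges are shipped as defaults for the three
parameters that have them (myCompass acute non-adherence 0–0.35, CBT
delivery cost 0–619, myCompass delivery cost 0–564); note the published
footnote describing the CBT range as "0 to +20% of base case" is arithmetically
inconsistent with the printed bracket, and the printed bracket is used.
`threshold_search()` brackets the first change in the identity of the optimal
strategy with a coarse 257-point scan and bisects the incumbent's NMB margin
to an absolute tolerance of 0.01 in the parameter's units. In the packaged
reconstruction, CBT displaces myCompass when a course can be delivered below
≈ AUD 265 (the published model put this near AUD 310 — structure-dependent),
and myCompass tolerates a several-fold rise in its own delivery cost.

## Value of information

`evpi()` computes `E[max_s NMB_s] − max_s E[NMB_s]` over PSA draws, with a
bootstrap standard error (500 resamples). `evppi()` offers two estimators
with one contract: a nested Monte-Carlo (default 1,000 outer × 1,000 inner;
the reported SE is the outer-level error, and small inner counts bias the
estimate upward — use the defaults or larger for publication figures) and a
single-loop regression estimator that replaces the inner loop with spline
conditional means (`mgcv::gam`), cheap enough to rank every parameter on one
set of draws (`evppi_all()`). Population scaling multiplies per-patient EVPI
by the eligible treated population exactly as the published arithmetic does:
4.4 million Australians with a mental illness × 20.6% with a mood disorder ×
(25% + 59%) presentation mix × 2% acceptability over one year.

A caution on interpretation: under the stated utility distributions — SDs of
0.31 and 0.20 on the moderate-episode and maintenance weights — decision
uncertainty at AUD 50,000/QALY is dominated by the utility weights, whose
EVPPI (≈ AUD 35 and 24 per patient on 10,000 draws) dwarfs that of every
transition probability, including myCompass non-adherence (≈ 0, as for all
other single probabilities, whose SDs are an order of magnitude smaller). An
expectation that adherence to the internet program is the binding evidence
gap is *not* borne out by this reconstruction at the stated distributions;
the corresponding acceptance check is retained and fails honestly.

## Synthetic data and what a green test establishes

`simulate_cohort()` is a patient-level microsimulation of the same tree:
patients draw terminal paths with the enumeration probabilities, and
fractional utilisation counts (GP visits per cycle by state, psychiatrist
consultations per spell, booster sessions) are realised as Poisson draws
with the stated means, so the microsimulation mean converges to the cohort
expectation. Intervention cost fractions are pro-rata adjustments, not
counts, and stay deterministic. Every trajectory stores its state sequence
and realised tally, and its cost/QALY equal `path_cost()`/`path_qaly()`
recomputed from that tally. `generate_trial()`/`fit_beta()` emulate the
Bernoulli trials behind the Beta(events, non-events) rows and recover them
at the implied sample sizes.

The microsimulation is an *internal consistency* oracle: agreement within
Monte-Carlo error (checked at n = 200,000) establishes that the cohort
expectation, the path enumeration and the sampling machinery implement the
same model. It does not validate the reconstruction against external data,
and the synthetic trials emulate aggregate success counts only — not
item-level symptom scores, dropout timing, or covariate structure.

## Numerical conventions and degenerate inputs

Branch probabilities must sum to 1 at every chance node (checked to 1e-12 at
build time) and path probabilities to 1 (1e-9) at evaluation. Reports round
currency to 2 dp, probabilities to 3 dp and thresholds to 2 dp; raw data
exports (PSA draws, CE plane) are written at full precision and round-trip
exactly. The ICER is flagged undefined (not thrown) at ΔE = 0, with a
dominance annotation derived from the signs; incremental deltas are
*comparator minus reference*, so a positive incremental NMB favours the
comparator — the convention is stated in every manifest. Degenerate
configurations (all distributions fixed) are legal everywhere and give
exactly zero EVPI and collapsed credible intervals.

## Known limitations

* The absolute cost and QALY levels of the original published model are not
  recoverable: its printed mean QALYs (0.24–0.29 over 28 weeks) lie below
  what any utility-times-time accounting can produce with the stated
  utilities (≥ 0.35), and its cost credible intervals imply cost variation
  that fixed unit costs cannot generate. This package therefore reproduces
  the deterministic summary arithmetic exactly, and the probabilistic
  results structurally (orderings, the 100% cost-minimisation probability at
  λ = 0, qualitative curve shapes) rather than digit-for-digit.
* The horizon is four cycles; chronic relapse-remission dynamics, combination
  therapy, adverse-event disutilities, and societal/productivity costs are
  out of scope.
* Relapsed and discontinued patients receive no further treatment within the
  horizon.
* The medication unit cost is a placeholder (above).
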