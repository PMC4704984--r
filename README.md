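# stepcea

Cost-utility decision modelling for stepped-care depression treatment in the
Australian setting.

`stepcea` implements a 28-week decision-analytic cost-utility model comparing
three first-line strategies for mild-to-moderate depression:

* **TAU** — treatment as usual: antidepressant medication with GP monitoring;
* **CBT** — a course of face-to-face cognitive behaviour therapy with a
  clinical psychologist, with monthly booster sessions in maintenance;
* **myCompass** — a fully automated, internet/mobile-delivered CBT-based
  self-help program, offered as the low-intensity first step of a stepped-care
  pathway.

Patients move between mutually exclusive health states — depressive *episode*,
*remission*, and *maintenance* — over four 7-week cycles. Cycle 1 is the acute
phase; acute non-adherers and non-responders step up to second-line
antidepressants; responders enter a 21-week maintenance phase with its own
effect size and non-adherence. Costs are counted from the provider perspective
(Medicare/PBS unit costs, 2013/14); benefits are quality-adjusted life years,

```
QALY = Σ_states u(state) × weeks(state) / 52,
u(episode) = 0.688 · u_moderate + 0.312 · u_mild,   u(remission) = u_maintenance
```

Strategies are compared by net monetary benefit and the incremental
cost-effectiveness ratio,

```
NMB = E·λ − C          ICER = ΔC / ΔE
```

with a willingness-to-pay threshold of λ = AUD 50,000/QALY. All model inputs —
transition probabilities with Beta/lognormal uncertainty distributions,
utility weights, resource counts, and unit costs — ship as a structured
configuration ([`default_config()`], editable JSON via `write_config()` /
`read_config()`), and the tree topology itself is a JSON file
(`inst/extdata/topology.json`) that can be amended without touching code.

The package covers the full uncertainty workflow:

* `base_case()` — deterministic tree roll-back by exhaustive path enumeration;
* `run_psa()`, `summarize_psa()`, `ceac()`, `export_ce_plane()` — probabilistic
  sensitivity analysis (10,000 iterations by default) with credible intervals,
  cost-effectiveness acceptability curves and CE-plane exports;
* `one_way()`, `threshold_search()` — univariate and threshold sensitivity
  analysis;
* `evpi()`, `evppi()`, `population_evpi()` — value-of-information analysis
  (nested Monte-Carlo and single-loop regression EVPPI estimators);
* `simulate_cohort()`, `generate_trial()`, `fit_beta()` — a patient-level
  microsimulation that serves as a brute-force oracle for the cohort
  expectations, plus synthetic Bernoulli trials for the Beta parameters;
* `autoplot()` methods and broom-style `tidy()`/`glance()` for every result
  type, and a thin command-line wrapper (`cea_cli()`, `inst/cli/stepcea.R`).

## Worked example

```r
library(stepcea)
cfg <- default_config()

base_case(cfg)
#>   strategy  cost_aud  qaly    nmb
#> 1 TAU           721. 0.369 17729.
#> 2 CBT          1478. 0.387 17881.
#> 3 myCompass     644. 0.379 18301.

psa <- run_psa(cfg, n = 10000, seed = 42)
dplyr::filter(ceac(psa), wtp %in% c(0, 50000))
#>     wtp strategy  probability
#> 1     0 TAU             0
#> 2     0 CBT             0
#> 3     0 myCompass       1
#> 4 50000 TAU             0.100
#> 5 50000 CBT             0.24
#> 6 50000 myCompass       0.660

evpi(psa)
#>   kind  parameter   wtp value mc_se method     n
#> 1 EVPI  <NA>      50000  103.  2.08 psa    10000

threshold_search(cfg, "cost_cbt_course", 0, 737.72)
#>   parameter       found threshold strategy_below strategy_above   wtp
#> 1 cost_cbt_course TRUE       265. CBT            myCompass      50000
```

Reading: at the point estimates myCompass is the cheapest strategy
(AUD 644 per patient over 28 weeks) and carries the highest net monetary
benefit at AUD 50,000/QALY. Under full parameter uncertainty it is the
cost-minimising strategy in 100% of PSA iterations (the CEAC at λ = 0) and
the most likely optimal strategy at the threshold (66%); CBT's acceptability
rises with λ because it yields the most QALYs. Resolving all parameter
uncertainty before deciding would be worth about AUD 103 per patient; CBT
would displace myCompass as the optimal strategy only if a course could be
delivered for less than about AUD 265.

Figures: `autoplot(psa)` draws the cost-effectiveness plane,
`autoplot(ceac(psa))` the acceptability curves.

## Command line

```sh
Rscript inst/cli/stepcea.R base-case --out results/
Rscript inst/cli/stepcea.R psa --n 10000 --seed 7 --out results/ --plot
Rscript inst/cli/stepcea.R threshold --param cost_cbt_course --range 0:737.72 --out results/
```

Each subcommand writes CSV tables plus a JSON manifest (config hash, seed,
iteration counts) sufficient to reproduce its outputs bit-for-bit.

## Acceptance script

`scripts/acceptance.R` recomputes the headline probabilistic result from
scratch against the installed package — it runs a fresh 10,000-iteration PSA
on the packaged default configuration, evaluates the acceptability curve at a
willingness-to-pay of zero, and writes the myCompass probability (as a
percentage) to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Notes and caveats

* The antidepressant unit cost is not part of the published cost table; the
  packaged `cost_medication_per_cycle = 80` (AUD per 7-week cycle) is a
  documented placeholder — replace it for any costing exercise that depends
  on it.
* The published tree is only partially specified; the packaged topology is a
  documented reconstruction, and the methods vignette
  (`vignettes/stepped-care-cua.Rmd`) records every modelling choice, what the
  synthetic microsimulation does and does not establish, and known
  limitations.
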