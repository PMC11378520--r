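# screenflow

Capacity planning for cancer screening programs, built for the people who
have to staff them. A screening program — the packaged example is a Veterans
Affairs lung-cancer-screening program using low-dose CT (LDCT) — is modelled
as a **process map**: a directed acyclic graph of tasks in which each task
consumes a fixed number of minutes of named human resources (nurse
navigators, primary care providers, radiologists, ...) per patient who
reaches it, and routes patients to subsequent tasks with stated
probabilities. Given an initial population, `screenflow` answers:

* **How much staff does this population need?** Expected patient counts are
  propagated through the graph and per-resource minutes aggregated as

  &nbsp;&nbsp;&nbsp;&nbsp;Total requirement of resource *r* =
  Σ<sub>steps *i*</sub> (expected patients at step *i*) ×
  (minutes of *r* per patient at step *i*),

  then converted to full-time equivalents, FTE = minutes / 2,400 (one
  40-hour week), per planning-horizon week.
* **How do needs move when an input moves?** One-way sensitivity sweeps
  over the population, any branch probability (with proportional
  renormalisation of sibling branches), or any task duration. Because the
  flow is affine in each single parameter, the points where the resource
  ranking flips (**crossovers**) are solved in closed form.
* **How many patients can the staff I have actually screen?** A min-ratio
  inversion gives the maximum screenable population and names the
  **bottleneck** resource — the one whose minutes bind first.

A patient-level Monte Carlo simulator and an exhaustive path-enumeration
oracle independently verify the analytic engine.

## Worked example

The packaged demonstration model (`build_va_demo()`) sends 75,000 at-risk
Veterans through one screening cycle: a computer eligibility check routes
30% to shared decision making with the PCP; those who accept screening are
scheduled for an LDCT, followed up by a nurse navigator on a no-show, and
the scan's LungRADS score decides the follow-up work.

```r
library(screenflow)
m <- build_va_demo()
run_report(m)
#> <run_report> 13 tasks, 3 resources, population 75,000
#>   FTE ranking (basis 2400 min, horizon 1 week(s)):
#>     resource total_minutes     fte
#>           NN     199,216.9 83.0070
#>  Radiologist     132,283.1 55.1180
#>          PCP     131,400.0 54.7500
```

Reading: screening 75,000 Veterans in one week would take 83.0 nurse
navigators, 55.1 radiologists and 54.8 PCPs working full-time on the
program; spread over a year (`horizon_weeks = 52`) each figure divides by
52. Sweeping the probability that an eligible Veteran accepts screening
(task 2's edge to LDCT scheduling) from 0 to 1:

```r
sweep_parameter(m, param_spec("branch_probability", grid = seq(0, 1, 0.05),
                              task_id = 2, branch_next_id = 5))
#> <sweep_result> kind branch_probability, 21 grid points over [0, 1]
#>   crossovers:
#>      param overtaken  overtaking      fte
#>  0.2136410       PCP          NN 49.67904
#>  0.5953267       PCP Radiologist 54.68866
```

Below a 21.4% acceptance rate the PCPs are the scarcest resource; above it
the nurse navigators take over (and radiologists pass the PCPs at 59.5%).
Inverting the question — with 100 NN, 100 PCP and 50 radiologist FTEs
available, how many Veterans can be screened per week?

```r
max_population(m, staffing_scenario(NN = 100, PCP = 100, Radiologist = 50))
#> <capacity_result>
#>   max population: 68,035.89
#>   bottleneck:    Radiologist
#>     resource min_per_patient supported_pop slack_minutes
#>           NN         2.65623       90353.8      59281.37
#>          PCP         1.75200      136986.3     120801.12
#>  Radiologist         1.76377       68035.9          0.00
```

The radiologists run out first: at 68,036 patients their 120,000 available
minutes are fully consumed while the other resources have slack.

Model files are plain CSV (one row per task, resource columns in
minutes-per-patient, outcomes as `next_id:percent` pairs) or JSON — see
`?parse_model` and the packaged `inst/extdata/va_lcs_demo.csv`. A
command-line interface wraps everything:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/screenflow.R", package="screenflow"))')" \
  run inst/extdata/va_lcs_demo.csv --format json
```

## Further reading

The methods vignette (`vignettes/process-map-methods.Rmd`) documents the
model assumptions (single entry, acyclic step-wise progression, fixed task
times, 100% resource utilisation), the file formats, numerical choices and
known limitations.
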