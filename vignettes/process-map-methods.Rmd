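---
title: "Process-map resource modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-map resource modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenflow)
```

## The model

A screening program is represented as a **process map**: a directed
acyclic graph whose nodes are tasks and whose edges carry routing
probabilities. Task $i$ consumes a fixed $m_{i,r} \ge 0$ minutes of human
resource $r$ for every patient who reaches it, and sends a patient down
outcome edge $(i \to j)$ with probability $p_{ij}$, where
$\sum_j p_{ij} = 1$ at every non-terminal task. Patients enter at a single
root task and are absorbed at terminal tasks (no outgoing edges).

With initial population $N$ at the root, the expected number of patients
at task $i$ follows from one pass in topological order:

$$ n_{\text{root}} = N, \qquad n_j = \sum_{i \to j} n_i \, p_{ij}, $$

and the total requirement of resource $r$ is

$$ T_r = \sum_i n_i \, m_{i,r} \quad \text{minutes}, \qquad
   \text{FTE}_r = \frac{T_r}{2400 \cdot h}, $$

where 2,400 minutes is one person's 40-hour week and $h$ is the planning
horizon in weeks. Three modelling assumptions underpin this:

1. **Step-wise, acyclic progression** — a patient never repeats a task
   within one screening cycle. This is what makes the single-pass
   propagation exact and the topological order exist.
2. **Fixed task times** — each task takes the same average number of
   minutes for every patient; $T_r$ is an expectation over routing only.
3. **Full utilisation** — resources spend 100% of their paid time on
   program tasks; no idle time, queueing or scheduling friction.

Expected counts are kept **fractional**: a 0.5% branch routes 0.005 of a
patient. The computation is an expectation, and rounding would break the
exact linearity that the sensitivity machinery exploits.

### Consequences of linearity

$n_i$ is proportional to $N$, and $T_r$ is affine in any one task
duration (with slope $n_i$) and — after renormalisation — in any one
branch probability. Every one-way sensitivity curve is therefore exactly
a straight line, which has two practical payoffs:

* curve crossings (changes in the resource ranking) are solved **in closed
  form** from the affine segment between two grid points rather than
  bisected numerically, and each solution is confirmed by re-evaluating
  the flow at the solved parameter (agreement within $10^{-9}$);
* the capacity question inverts analytically: per-patient minutes
  $t_r = T_r(1)$ give a maximum population
  $N^\ast = \min_{r\,:\,t_r > 0} A_r / t_r$, where $A_r$ is the available
  minutes of resource $r$; the arg-min is the bottleneck and has zero
  slack at $N^\ast$ by construction.

## Tunable parameters

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| `population` | patients | model file value | overridable everywhere |
| `fte_basis_minutes` | min / FTE-week | 2400 | 40 h × 60; the FTE definition |
| `horizon_weeks` | weeks | 1 | divides FTEs; reported values are FTE-weeks at the default |
| branch probability tolerance | — | 1e-6 | outcome sums are checked, never silently renormalised |
| round-trip precision | significant digits | 15 | file serialisation; re-parse error ≪ 1e-12 |
| `max_paths` | paths | 10,000 | guard on the enumeration oracle |

The FTE basis deserves a note: an "FTE" is only meaningful relative to a
horizon. One FTE here means one 40-hour *week* of work; planners wanting
annual staffing divide by the horizon (`horizon_weeks = 52`) rather than
the package guessing a year. Both knobs are explicit on every interface.

## Sensitivity sweeps

`sweep_parameter()` supports three kinds. Population and duration sweeps
replace the single named quantity. Branch sweeps set the target edge to
$p$ and scale its sibling edges by $(1-p)/(1-p_0)$, preserving the
relative mix of the non-swept outcomes; when the siblings originally
carry zero mass the remainder is split equally. Proportional rescaling
was chosen because it reduces exactly to the natural two-outcome
accept/decline sweep and generalises to many-outcome tasks without
inventing structure. Sweeping the only outcome of a task is an error —
there is no sibling to absorb the complement.

Default grids package the three standard experiments on the demonstration
model: population 75,000–300,000 (step 25,000), acceptance probability
0–1 (step 0.05) on the screening-acceptance edge, and 0–3 minutes (step
0.5) on the eligibility-check duration.

## Verification strategy

Two independent oracles check the propagation engine:

* **Path enumeration** (`enumerate_paths()`): exhaustively lists
  root-to-terminal paths with their probabilities and accumulated
  minutes; $\sum_{\text{paths}} N \cdot P(\text{path}) \cdot
  \text{minutes}$ must match the propagated totals ($10^{-9}$ relative).
  The demonstration model has 15 paths; the test suite checks the
  equivalence on it and on 100 randomly generated 12-task models.
* **Monte Carlo simulation** (`simulate_cohort()`): each patient walks
  the graph sampling one branch per visited task. Totals are compared
  through $z = (\text{simulated} - \text{analytic}) / \widehat{SE}$ with
  $|z| \le 4$ required per resource; the packaged check simulates the
  full 75,000-patient cohort. Branch draws use cumulative-probability
  inversion in file order with boundary ties resolved toward the earlier
  branch, so runs are bit-reproducible for a given (model, n, seed) on
  any platform. Patients at the same task are advanced together in
  topological order — statistically identical to walking patients one by
  one, but vectorised.

## The random-model generator

`random_model()` draws layered DAGs for property-style testing: tasks in
a fixed topological sequence, edges only forward (acyclic by
construction), every non-root task wired to at least one predecessor
(connected, single root), uniform minutes on [0, 15], branch weights
normalised to sum to one. It emulates the *structural* variety of real
process maps — fan-out, reconvergence, multiple terminals — under which
conservation, oracle equivalence and round-trip identities must hold for
every seed. It does not emulate realistic probability magnitudes
(real screening models have rare branches like 0.5%), long chains of
near-deterministic hand-offs, or resource sparsity patterns; passing
tests on generated models therefore demonstrates correctness of the
algebra, not calibration of any real program, which is what the fixed
demonstration model is for.

## Numerical choices and degenerate inputs

* Probability sums are accepted within $10^{-6}$ and never repaired;
  a planning file that does not sum to one is an authoring error worth
  surfacing (`BAD_PROB_SUM`).
* Topological ties are broken by ascending task id (numeric when all ids
  are numbers), making orders, simulations and exports deterministic.
  Ids are otherwise opaque labels; no ordering is assumed from them.
* Exactly one entry task is required; merging flows from several entry
  points is modelled with an explicit zero-minute dispatcher task. In an
  acyclic model with one declared root, an unreachable task necessarily
  comes with a second zero-in-degree task or a cycle, so the
  `UNREACHABLE_TASK` warning always accompanies a `MULTIPLE_ROOTS` or
  `CYCLE` error; it is kept a warning so the message names the stranded
  tasks rather than just the symptom.
* Zero population yields exact zeros everywhere; an all-tie FTE ranking
  is flagged rather than arbitrarily ordered (lexicographic id breaks
  remaining ties, deterministically).
* Capacity with a zero-staffed, positively-consumed resource returns
  `max_population = 0` and lists the offending resources; resources
  omitted from a staffing scenario are unlimited unless `strict = TRUE`.
* Exact-tie detection on binding capacity ratios uses a $10^{-9}$
  relative band: ratios equal on paper can differ in the last
  floating-point ulp.
* Model files carry percentages as printed in program tables ("0.5"
  means 0.5%) and store fractions internally, keeping arithmetic in
  $[0,1]$ while files remain human-checkable against source tables.

## Problem sizes in the shipped checks

The test suite and the reproduction script use the 13-task demonstration
model, 100 random models of 12–50 tasks, and simulated cohorts of up to
100,000 patients; the whole suite runs in well under a minute on one core.
These sizes were chosen to exercise every code path with comfortable
statistical power, and scale linearly if enlarged.

## Known limitations

* No queueing, backlog or steady-state dynamics: the model prices one
  screening cycle for a population, not the calendar over which it is
  worked through.
* No repeat cycles (annual re-screening) and no within-cycle re-entry;
  the acyclicity assumption is structural.
* Fixed task durations and fixed branch probabilities: no patient-level
  variability beyond routing, and no parameter uncertainty — one-way
  sweeps, not probabilistic sensitivity analysis with distributions or
  confidence intervals.
* Human resources only; equipment (e.g. the CT scanner itself) and
  administrative staff are outside the model boundary.
* 100% utilisation means reported FTEs are lower bounds on real staffing.
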