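---
title: "Scheduling radiotherapy sessions around patient time-window preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling radiotherapy sessions around patient time-window preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

External-beam radiotherapy is delivered as a series of short irradiation
sessions ("fractions") on a linear accelerator (linac), usually one per
working day over one to seven weeks. A center books, every week, the
coming week's sessions for all patients: those already under treatment
and those due to start. Besides the hard operational rules — machines
have finite slot grids, a patient's sessions stay on one machine, spaced
(hypofractionated) schemes need rest days between sessions, waiting-time
targets impose a latest start day, at most a handful of new patients may
start per machine per day, and some patients may only be treated while a
specialist is in the department — many Dutch centers also ask patients
*when in the day* they would like to come, and try to honour it. That
last, soft requirement is what this package optimizes: it books every
session of every patient onto a machine, day and starting slot so that
the total deviation of session starts from the patients' preferred time
windows is minimal.

`rtsched` implements the whole decision pipeline: a validated data model
for instances, an exact mixed-integer formulation, a greedy
workload-balancing pre-assignment heuristic with a machine-cluster
decomposition for large centers, a calibrated synthetic instance
generator, an independent feasibility checker with schedule metrics, and
file formats plus a command-line interface around them.

## The model

Time is discretized into days $t = 1,\dots,|\mathcal T|$ (default 5, one
labour week) and, within each day, slots $s = 1,\dots,|\mathcal S|$ of
$l$ minutes (defaults 120 slots of 5 min: a 07h30–17h30 opening). Slot
$s$ starts $l(s-1)$ minutes after opening. For each patient $i$, machine
$k$, slot $s$ and day $t$, a binary $x_{iks}^t$ indicates a session of
$i$ starting at $(k,s,t)$. Continuous variables
$\Delta^-_{it}, \Delta^+_{it} \ge 0$ measure how many minutes the day-$t$
session start of patient $i$ falls before/after the preferred window
$[t_i^{\min}, t_i^{\max}]$, and auxiliary binaries $y_{ik}^t$ flag
treatment starts of new patients. The objective is

$$\min \sum_{i \in \mathcal P} \sum_{t \in \mathcal T}
  (\Delta^-_{it} + \Delta^+_{it}),$$

subject to, for every patient: session continuity (once a first session
is placed, sessions recur every $b_i$ days on the same machine until the
remaining count $I_i$ or the horizon is exhausted, and never on the off
days in between), at most one session per day and $I_i$ in total, a first
session no later than the due day $d_i$, machine-feasibility
($k \in \mathcal K^i$; ongoing patients are pinned to their current
machine), slot availability and non-overlap of multi-slot session
footprints, at most `max_new_starts` new patients starting per
machine-day, restricted start frames for specialist-presence patients,
and the linking rows

$$t_i^{\min} x_{iks}^t - \Delta^-_{it} \;\le\; l(s-1)\,x_{iks}^t
  \;\le\; t_i^{\max} x_{iks}^t + \Delta^+_{it}$$

that charge the objective for out-of-window starts. Because at most one
slot is selected per patient-day, these rows are linear without big-M
constants. On days without a session the minimization itself drives the
deviation variables to zero, so no extra fixing rows are needed; rows
whose start slot already lies on the compliant side of a bound are
dominated by the sign constraints and are not emitted. Machine
feasibility, end-of-day fits and frame restrictions are realized by not
creating the corresponding $x$ variables (equivalent to fixing them to
zero); the builder reports per-family counts of rows and eliminated
variables for auditing, and `write_lp()` dumps the model as LP text.

A deliberate literal reading: a session only has to *start* inside a
window or frame; it may run past the upper bound. Likewise blocked slots
forbid session *starts*, not spanning. Both choices follow the start-slot
semantics of the formulation; the independent checker mirrors them.

We include every patient in the objective. The non-overlap family is
emitted pairwise per (session-start, trailing-slot) combination — the
formulation's literal form — rather than aggregated into clique rows;
presolve consolidates the duplicates.

## Solving

`solve_milp()` hands the assembled sparse system to the HiGHS
branch-and-bound engine via `scipy.optimize.milp` in a short-lived
`python` subprocess (matrix as MatrixMarket, the rest as JSON). The
interface is the minimal solver contract — variables, linear rows,
objective, time limit, relative gap — so other backends can be dropped
in. Defaults: relative gap $10^{-4}$ and a 28 800 s total budget split
evenly over clusters, mirroring common planning practice of running the
optimization overnight on the last workday. HiGHS runs single-threaded,
which keeps repeated solves of the same model reproducible.

Exact optimality at full center scale under the tight 90-min windows is
expensive for any solver (hours of CPU in the original setting with a
commercial solver); the package's tests therefore certify correctness at
small scale and replicate the widened-window scenarios, where optima are
reached in seconds to minutes, rather than re-running the full-scale
week. The problem sizes used in the tests (up to 66 patients and 2
machines) are stated in the test suite itself.

## Pre-assignment and clustering

For centers with more than a few machines the monolithic model is
impractical, so `preassign()` implements the greedy balancing heuristic:
machine workloads $WL(k)$ start from the volume of ongoing patients
(volume = expected weekly session minutes, `patient_volume()`); each new
patient is then placed on the least-loaded feasible machine that still
has capacity for their volume, scanning machines in ascending workload.
Two unstated details are fixed for determinism: patients are processed
in input order (a largest-volume-first option exists but is off by
default), and workload ties break by machine id. `partition_clusters()`
then splits the instance along a user-chosen partition of the machines —
never mixing a satellite site with the main site, since the site choice
is made at referral and cannot be rebalanced — and each cluster is
solved independently and merged (`solve_sequential()`). Within a
cluster, new patients may still move to any feasible machine of that
cluster; decomposition therefore only restricts the solution space, and
the pooled optimum is a lower bound on any clustered objective (a
property the tests assert).

## The synthetic generator

Real booking data cannot ship with a package, so `default_nki_config()`
encodes the published weekly profile of a large 8-linac Dutch center
(about 260 patients/week, 33 per machine): session counts 1–35 by care
plan; durations 10–30 min in 5-min steps with 60.5% at 15 min and 19.9%
at ≥ 20 min; 34% urgent; 35% new patients with due days 1–5; 6% of
patients on every-other-day schemes; 21% restricted to the 08h30–17h00
staff-presence frame; and a 25/50/25 split over the morning [0, 90],
midday [90, 510] and late [510, 600] minute windows. Only the two
largest care plans are published with their shares ("Bone metastasis"
23.3%, "Breast" 16.5%); the generator ships those plus six synthetic
plans chosen to be clinically plausible (prostate with half the patients
at 35 fractions, long head-and-neck courses, a spaced
stereotactic/hypofractionated plan, ...), and the residual plan's
duration and urgency probabilities are *solved in code* so the aggregate
marginals above hold exactly. What matters to the optimization is the
aggregate load and flag mix, not the 56-way plan split.

Decisions where the source is silent, fixed once: due days of new
patients are uniform on 1–5 (the per-plan empirical waiting-time
distributions are not published; the field is a per-plan calibration
knob `due_probs`); ongoing patients' remaining sessions are uniform on
1..(their plan's course length), their current machine uniform over
their feasible set; the Monday-start share defaults to 0 (no published
rate) with a config hook; and by default every machine can treat every
patient, as in the published scaled experiments (pre-allocation can be
expressed through `feasible_linacs`). Generation is deterministic under
`seed` and restores the caller's RNG state.

What the generator does *not* emulate: arrival of urgent patients during
the week (the model is an offline weekly planner), per-plan waiting-time
empirics, machine breakdowns/maintenance, and correlations between
preference window and care plan. Tests passing on generated instances
therefore certify the optimization machinery and the published aggregate
mix, not those real-world effects.

## Numerical choices and edge cases

* Slots and days are 1-based everywhere, including files.
* Frames and windows are stored in minutes and converted to slot ranges
  with `frame_to_slot_range()` (smallest slot starting at or after the
  lower bound, largest starting at or before the upper bound); an empty
  range is a typed error.
* A start exactly on a window bound counts as in-window (zero
  deviation); "outside" means strictly positive minimal deviation. The
  reported average deviation is over out-of-window sessions only.
* Extraction refuses binaries further than $10^{-6}$ from integral; the
  checker re-verifies every extracted schedule and the metric total
  equals the solver objective to the same tolerance.
* The enumeration oracle `brute_force_optimal()` refuses search spaces
  beyond $10^7$ candidates; equal-objective ties anywhere are left to
  the solver, and tests assert objectives, never specific slots.
* Weekly machine capacity defaults to the full open grid
  ($5 \times 600 = 3000$ min) minus blocked slots; utilization is booked
  minutes over that capacity.

## Limitations

The planner is deterministic and offline: no-shows, duration overruns
and intra-week urgent arrivals are out of scope, as are doctor-consult
coordination, maintenance rescheduling and multi-week horizons (the
model accepts any horizon length; defaults and tests use 5 days).
Solution *times* are hardware- and solver-dependent and are never
asserted. At full center scale with tight windows the clustered
heuristic+MILP pipeline returns good feasible schedules long before
proving optimality; the published experience with a commercial solver is
consistent with that behaviour.
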