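---
title: "Methods: Monte Carlo beta-lactam dosing under kidney replacement therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo beta-lactam dosing under kidney replacement therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krtdose)
```

## The problem

Critically ill, anuric patients with acute kidney injury receive
extracorporeal kidney replacement therapy (KRT) in widely varying
combinations of session length, frequency, and dialysate/ultrafiltrate flow.
Because the study beta-lactams (cefepime, ceftazidime, imipenem, meropenem,
piperacillin/tazobactam) are small, poorly protein-bound and renally
cleared, they are readily removed across the dialyzer membrane, and the
on/off rhythm of KRT makes drug exposure strongly schedule-dependent.
Clinical PK trials cannot cover every KRT configuration, so dosing is
derived in silico: simulate a large virtual population under each schedule,
score each candidate regimen by its probability of attaining a
pharmacodynamic (PD) target on every day of the first treatment week, and
flag the accompanying risk of crossing neurotoxicity concentration
thresholds.

`krtdose` implements that pipeline end to end: a virtual-population
generator, an event-driven one-compartment PK engine with KRT-dependent
elimination, exact time-above-threshold PD metrics, and the optimal-regimen
selection rule.

## Model

### Pharmacokinetics

Each patient is a one-compartment, first-order system for **total** plasma
concentration $C$ (mg/L):

$$\frac{dC}{dt} = \frac{R(t)}{V_d} - k_e(t)\, C,$$

where $R(t)$ is the infusion rate (mg/h) and $V_d$ the apparent volume of
distribution. Elimination switches with the KRT schedule:

$$k_{e,\mathrm{on}} = \frac{CL_{NR} + CL_{EC}}{V_d}, \qquad
  k_{e,\mathrm{off}} = \frac{CL_{NR}}{V_d},$$

with extracorporeal clearance $CL_{EC} = S_A \cdot Q_d$ during hemodialysis
and $CL_{EC} = S_C \cdot Q_{uf}$ during ultrafiltration ($S_A$, $S_C$:
saturation/sieving coefficients; $Q_d$, $Q_{uf}$: effluent flow rates).
Patients are anuric with no residual renal function, so $CL_{NR}$ —
non-renal clearance — is the only route between sessions. Free concentration
is $f_u C$ with a patient-specific unbound fraction; PD targets are scored
on the free scale, toxicity thresholds on the total scale (the piperacillin
threshold can be switched to the free scale, since its literature source is
ambiguous on this point; the default total scale reproduces the published
day-wise exceedance tables closely, see below).

Because $R(t)$ and $k_e(t)$ are piecewise constant, the ODE is solved
*exactly*: breakpoints are placed at every dose start/stop, session
start/stop and day boundary, and within a segment

$$C(t_0 + \Delta t) = C_{ss} + (C(t_0) - C_{ss})e^{-k_e \Delta t}, \qquad
  C_{ss} = \frac{R}{k_e V_d},$$

with the linear limit when $k_e = 0$. There is no time grid and hence no
discretization error; the test suite verifies full-week profiles against a
dense Runge–Kutta integration to relative error $<10^{-5}$.

### Virtual population

All parameters are log-Gaussian. The published summaries are arithmetic
mean $\pm$ SD with an observed range, so the underlying normal is
moment-matched — $\sigma^2 = \ln(1 + (sd/m)^2)$, $\mu = \ln m - \sigma^2/2$
— and draws outside the range are rejected and redrawn. Resampling (rather
than clipping) avoids probability mass piling up at the bounds; the price is
that post-truncation moments deviate slightly from the nominal values (for
lightly truncated specs such as the saturation coefficients the shift is
well under 0.01, verified against numerical integration of the truncated
density). Parameters are sampled independently: no correlation structure is
published, and none is assumed. A range lower bound of 0 imposes no
constraint, since the log-normal support is positive. Body weight
(88 ± 26 kg, range 40–177) multiplies the per-kg volume of distribution.
Whether the source study truncated, clipped or resampled — and whether body
weight was itself log-Gaussian — is not stated; truncation-by-resampling and
a log-Gaussian weight with the published moments are this package's
choices.

What the generator deliberately does **not** emulate: residual/recovering
renal function, inter-occasion variability, parameter correlations (e.g.
weight–volume), interrupted or rescheduled KRT sessions, and saturable
protein binding. Passing tests therefore validate the simulator under the
stated population model, not the full heterogeneity of real ICU patients.

### KRT schedules

Five one-week schedules are built by `krt_schedule()`:

1. thrice-weekly (Mon/Wed/Fri) 4-h HD, Qd 300 mL/min;
2. daily 4-h HD, Qd 300;
3. daily 4-h HD (Qd 300) immediately followed by 20-h UF (Quf 5);
4. daily 9-h prolonged intermittent KRT (PIKRT), Qd 100, in two dose-timing
   variants — *early* (first dose at PIKRT start) and *late* (first dose
   15 h before PIKRT);
5. continuous 24-h extended PIKRT, Qd 50.

Clock convention: $t = 0$ is the start of the first session (settings 1–3,
4-early, 5) or the first dose (4-late). The first dose is anchored at the
end of the first HD session in settings 1–3 ("post-HD" dosing) and
subsequent doses follow at fixed clock times `anchor + k × interval`; on
non-HD days of setting 1 the q24h dose is given at the same clock time.
Day $d$ of therapy is the window $[24(d-1), 24d]$ hours **after the first
dose**, so the session timeline extends one dose-anchor beyond 168 h; for
setting 1 the day-7 window therefore contains the following Monday's HD
session, which is what produces the characteristic alternating day-wise
toxicity pattern (high on dialysis-gap days, low on post-HD days).

### PD metrics

`time_above()` computes time above a threshold exactly: each segment is
monotone (exponential approach to its steady state), so it crosses a
threshold at most once, at the closed-form time
$t^\* = \frac{1}{k_e}\ln\frac{C_0 - C_{ss}}{C_{th} - C_{ss}}$. Daily
attainment compares the fraction of the day above threshold with the
required fraction non-strictly (40% for carbapenems, 50% for
piperacillin/tazobactam, 60% for cephalosporins; thresholds are the
*P. aeruginosa* breakpoint MIC — 8, 8, 2, 2, 16 mg/L for
cefepime/ceftazidime/imipenem/meropenem/piperacillin — or 4× MIC for the
aggressive target; tazobactam uses a fixed 4 mg/L free threshold). The
end-of-day toxicity check is the instantaneous total concentration at
$t = 24d$ after the first dose, "at or above" the drug's threshold
(20/64/16/64/157 mg/L for cefepime/ceftazidime/imipenem/meropenem/
piperacillin).

### Regimen evaluation and selection

`evaluate_regimen()` runs a cohort through a regimen (both timing variants
for setting 4; the 8:1 piperacillin:tazobactam product split with joint
attainment for the combination) and `select_optimal()` applies the rule: the
smallest average daily dose whose PTA is $\ge 90\%$ on every day, ties
broken toward fewer administrations per day. Two documented concessions
follow the study's practice: when no candidate passes day 1, regimens with
days 2–7 at ~90% and day 1 at or above a relaxation floor (default 75%) are
accepted; and when even that is blocked by a conventional daily-dose cap
(cefepime 6 g/day; other drugs uncapped unless configured), the day-1
requirement is dropped entirely for candidates under the cap. The bands
(`approx_band` = 2.5 percentage points around "approximately 90%") and the
relaxation floor are configurable because the source criteria are
qualitative; the defaults were fixed once from the narrative description,
with the published 63% day-1 case reachable only through the dose-cap
branch.

## Worked example

```{r example}
lib <- krt_drug_library()
cohort <- sample_cohort(lib$cefepime, n = 1000, seed = 1)
prof <- simulate_cohort(cohort, krt_schedule(4, "early"),
                        regimen(1000, 6, loading_dose = 2000))
pta(daily_attainment(prof, efficacy_target(lib$cefepime, mic_multiplier = 4)))
toxicity_probability(prof, lib$cefepime$toxicity_threshold)
```

A full study (`run_study()`) loops drugs × settings × targets over the
candidate grids, writes per-day PTA and toxicity CSVs and an
optimal-regimen summary, and is byte-reproducible for a given seed: the
master seed spawns an independent substream per (drug, setting), so adding
one scenario never perturbs another's draws.

## Numerical choices and degenerate inputs

- Units: internal computation in litres and hours; mL/min inputs convert at
  0.06 L/h per mL/min.
- $k_e = 0$ (an anuric patient off KRT with zero non-renal clearance) uses
  the analytic linear limit everywhere (stepping, steady state, crossing
  times); concentration is then constant between infusions.
- A zero-variance parameter spec degenerates to its constant mean; a
  truncation window with acceptance probability below $10^{-6}$ under the
  moment-matched log-normal is rejected as internally inconsistent.
- Attainment and toxicity comparisons are non-strict ("at or above").
- Dose times are integer multiples of the interval from the anchor (every
  permitted interval divides 168 h), avoiding floating-point drift in event
  times.
- Simulation sizes: the published tables use cohorts of 5,000, which this
  package reproduces in seconds per scenario; the test suite uses 5,000 for
  the table-level reproduction checks and smaller cohorts (200–1,000) for
  property checks such as monotonicity, where the assertion does not depend
  on Monte Carlo precision.

## Known limitations

- One-compartment kinetics only: no distribution phase, no post-dialysis
  rebound, no saturable binding. Troughs right at the end of an HD session
  may be biased low relative to two-compartment reality.
- The candidate regimen grids are a reconstruction of typical clinical
  doses; the exhaustive grid behind the published tables is not available.
- PTA/toxicity percentages inherit the sampling decisions above; the
  package's stochastic reproduction checks allow for this (several
  percentage points at cohort size 5,000), and the binding validation is
  the analytic/oracle property suite.
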