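---
title: "Methods: variability and cost analysis of biotelemetry-enhanced CLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability and cost analysis of biotelemetry-enhanced CLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clptel)
```

## The problem

Cecal ligation and puncture (CLP) is the workhorse murine model of
polymicrobial sepsis, but the time at which an individual mouse becomes
acutely ill after surgery varies enormously — by a factor of nearly five
across genetically identical animals under one protocol. Interventions
tested at a fixed clock time after CLP therefore reach animals in very
different physiologic states, inflating variance and forcing larger group
sizes. Implanted biotelemetry (continuous heart rate, core temperature and
activity) lets an investigator *enroll each mouse at its own point of
acute physiologic deterioration* instead, the way human sepsis trials
enroll on physiologic criteria.

`clptel` implements the quantitative machinery of that design question:

1. a **detector** for the validated deterioration criterion,
2. a **capture-window analysis** quantifying how badly a fixed time point
   performs,
3. a **cost-equivalency model** for deciding when the biotelemetry
   equipment pays for itself in animals spared, and
4. a **synthetic telemetry generator** so that all of it is testable
   end-to-end without animal data.

## The deterioration criterion

A mouse meets criteria at the first sample $t$ at which **both** hold
simultaneously:

$$\mathrm{HR}(t) \le (1 - f_{hr}) \cdot \max_{s \le t}\mathrm{HR}(s),
\qquad
T(t) \le M_t - f_T\,(M_t - T_{\mathrm{floor}}), \quad
M_t = \max_{s \le t} T(s),$$

with defaults $f_{hr} = f_T = 0.10$ and $T_{\mathrm{floor}} = 25\,°C$:
a 10% heart-rate drop from peak together with a temperature drop of at
least 10% of the headroom between peak temperature and 25 °C. Mice not
meeting criteria within a 24-hour horizon are censored and excluded from
the variability analysis.

Design choices the criterion's prose leaves open, and how we resolved
them:

* **"Peak value" is the running maximum** up to the current sample, not a
  global or pre-specified peak. Detection must be causal — the model
  triages live animals in real time. A non-causal global-peak variant is
  available (`detect(..., peak = "global")`) for sensitivity analyses; it
  can only make the heart-rate criterion *easier*, since the global
  maximum is at least the running maximum.
* **Conjunction at a single timestamp.** Both criteria must hold at the
  same sample; a transient heart-rate dip that recovers before the
  temperature falls does not count.
* **No smoothing by default**; an optional centred moving average
  (`smooth_window`, odd number of samples) suppresses single-sample
  artifacts. Trace edges are left unsmoothed.
* **First qualifying sample wins** — no debounce, no tie-breaking beyond
  sample order.

## The synthetic trace generator

No raw per-mouse telemetry was ever published for this model, so the
generator is the package's substitute study population — its defaults
*are* the study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| cohort size | 115 | reported cohort size |
| non-deteriorator fraction | 0.07 | 8/115 mice never met criteria in 24 h |
| latent onset | log-normal, median 465 min, sdlog 0.16, truncated to [240, 1440] | reported median 465 min; sdlog 0.16 approximates the reported IQR 422–536 (a distribution symmetric on the log scale cannot match those skewed quartiles exactly — recovered quartiles are ≈ 418 and ≈ 519 min) |
| HR peak | uniform 650–750 bpm | septic tachycardia plateau in adult C57BL/6J |
| temperature peak | uniform 37–38.5 °C | febrile plateau |
| decline slopes | 2 bpm/min, 0.02 °C/min | place threshold crossings 35–65 min after onset, within the plateau-to-moribund decline seen in this model |
| noise | Gaussian, 10 bpm / 0.1 °C | device-scale measurement noise |
| sampling | 1 min over 1440 min | "continuous" monitoring with no stated rate |
| baseline | 500 bpm / 35 °C, 120-min ramp | post-anaesthesia depression and recovery |

The waveform is a **ramp–plateau–linear decline**, deliberately the
simplest shape whose threshold crossings have a closed form: with
noise off, heart rate crosses its threshold exactly
$f_{hr} \cdot \mathrm{peak} / \mathrm{slope}$ minutes after onset and
temperature $f_T (\mathrm{peak} - 25) / \mathrm{slope}_T$ minutes after
onset, so the conjunctive detection time is the later of the two
(`analytic_crossing_time()`). That closed form is the independent oracle
against which the sampled detector is tested — detection must land within
one sampling interval of it.

Non-deteriorators are simulated as plateau-only traces (their real
physiology was not described); every mouse's draws are a deterministic
function of `(seed, index)`, so cohorts are reproducible and individual
mice can be regenerated in isolation.

**What the generator does not emulate:** circadian modulation, ECG
morphology or arrhythmia, autocorrelated sensor noise, partial decliners
that meet one criterion only, and any covariance between onset time and
peak values. Tests passing on these traces therefore validate the
*analysis machinery* — thresholding, tabulation, statistics, costs — not
the biological realism of any waveform.

## The deterministic reference cohort

`reference_cohort()` reconstructs the 115-mouse cohort from its published
hourly capture distribution: 8 censored mice plus 107 deteriorating mice
placed inside hourly windows (window counts 2, 13, 26, 30, 11, 5, 4, 2,
3, 3, 1, 1, 1 at hours 5–17, plus 1 at 22 h and 2 at 23 h), evenly spaced
within each window at interior points. Whole-percent rounding of a
107-mouse denominator pins those counts uniquely — but only 105 of them.
The published columns are internally inconsistent (their cumulative
column is not the running sum of their window column, and the remaining
2 mice fit no populated window at the printed roundings), so the last
2 mice are placed late, evenly spaced in (1410, 1440] minutes. Two
residual discrepancies follow and are deliberate:

* the 24-hour row shows 2% where the published table prints 0%
  (hours 4–23 reproduce the published capture column exactly);
* the reconstruction's median is ≈ 475 min, near but not equal to the
  reported 465 min, because only rounded percentages were published.

## Capture-window analysis

Windows are **half-open**, $[60h - 30, 60h + 30)$ minutes, so consecutive
hourly windows partition the axis and every uncensored time falls in
exactly one window ("± 30 minutes" alone does not fix the boundary).
Proportions use the **deteriorating mice** (n = 107 in the reference
cohort) as denominator, for window, cumulative, past and not-yet columns
alike; the three state fractions then sum exactly to one at every hour.
Computation is carried at full precision; *reported* percentages are
rounded half-up to whole percent and p-values to two decimals.

Two windows are compared on the same animals, so the paired discordant
counts are just the two window counts (windows are disjoint). The exact
two-sided McNemar p-value is the binomial sign test

$$p = \min\!\left(1,\; 2\,P\!\left[X \le \min(b, c)\right]\right),
\qquad X \sim \mathrm{Binomial}(b + c, \tfrac12),$$

with $p = 1$ for $b = c = 0$ by convention; a continuity-corrected
$\chi^2$ variant is available. The 8 h window (30/107, 28%) beats 6 h
(13/107) at $p = 0.014 \to 0.01$; against 7 h (26/107) the exact value is
0.689, consistent with the published "not significant" comparison. The
binomial CI on the capture proportion is Wald by default with Wilson and
Clopper–Pearson options; all three give a 20% lower bound at 30/107.

Seasonal stratification (`seasonal_analysis()`) reports per-season
medians and IQRs, a Kruskal–Wallis test across seasons, Fisher's exact
test on per-season capture proportions (delegated to the exact network
algorithm in `stats::fisher.test`, guarded to totals ≤ 500), and the
Spearman correlation of ambient temperature with time-to-criteria. Only
the machinery is reproducible — the per-season raw data were never
published.

## The cost model

Equipment follows a stepped schedule: system ($24{,}336.50) plus an
initial set of four devices ($11{,}610), with a battery-replacement set
($2{,}405) after each block of 120 monitored single-day experiments (the
initial purchase covers the first block):

$$\mathrm{setup}(Q) = 24336.50 + 11610 + 2405\,(\lceil Q/120 \rceil - 1).$$

A fixed-time-point design capturing proportion $p$ needs $Q/p$ animals
for $Q$ at criteria. **Fractional $Q/p$ is kept inside the cost algebra**
(integer ceilings only for reporting); integer-only algebra fails to
reproduce the published \$235.27 and \$116.49. With $Q = 120$,
$c = \$25$, $p = 0.28$: incremental cost per quality mouse
$[\mathrm{setup}(Q) + Qc - (Q/p)c]/Q = \$235.27$; break-even cost-per-mouse
$\mathrm{setup}(Q)/(Q/p - Q) = \$116.49$ (then \$62.14 at 240 and \$44.03
at 360).

Solving the reverse question — how many quality mice make a given animal
cost break even — must respect the step function: for each battery tier
$k$, $Q_k = \mathrm{setup}_k / [c(1/p - 1)]$, accepting the tier whose
solution lies inside it, $Q_k \in (120k, 120(k+1)]$, and rounding to the
nearest mouse. This reproduces the published 317 mice at \$50 and the
full \$250 row (56 biotelemetry vs 200 standard, 144 spared). The
published rows at \$25, \$37.50, \$75, \$100, \$150 and \$200 deviate by
1–30 mice from every rounding/tier rule we reconstructed, and the
published \$91.54 cost-per-mouse-spared differs from the reconstruction's
\$91.49; these are reported by the model but never asserted in tests.
`capture_proportion` defaults to the printed 0.28, not 30/107.

The incremental cost difference at fixed $Q$ is exactly linear in $c$
with slope $Q - Q/p < 0$; the two-way sensitivity grid marks each
$(Q, c)$ cell's cheaper model, with the equivalency curve
$c = \mathrm{setup}(Q)/(Q/p - Q)$ as boundary — costs above the curve
favour biotelemetry.

## Numerical and degenerate-input choices

* Reported roundings are half-up (base `round()`'s banker's rounding
  would turn 2.5% into 2%); computations are never rounded internally.
* `ceiling()` on animal counts is applied after rounding at 1e-9 to
  absorb floating-point residue in $Q/p$.
* Traces must start at $t = 0$ with a strictly increasing, uniform time
  axis; heart rate positive; temperature within 20–42 °C. A trace whose
  peak temperature never exceeds the 25 °C floor makes the temperature
  criterion undefined and is a domain error, not a censored mouse.
* All-censored cohorts are an error for `capture_table()` (no analyzable
  denominator); `mcnemar_exact(0, 0)` returns 1; `equivalency_cost()` at
  $p = 1$ is an explicit error (no waste, no break-even).
* Best-window ties break to the earliest hour.

## Problem sizes

The test suite and acceptance script run the generator at the study's own
scale: full 115-mouse trace cohorts at 1-minute resolution for pipeline
checks, 10,000 latent draws for calibration recovery (median within
Monte-Carlo error of 465 min), 2,000 replicate cohorts for the censoring
expectation, and 500 replicates for the seasonal power check — sizes at
which every Monte-Carlo tolerance used is several standard errors wide.

## Known limitations

* The reference cohort is a *reconstruction* from rounded published
  percentages, not recovered raw data; quantities that depend on raw
  times (medians, cumulative proportions) carry that imprecision.
* The generator's waveform is schematic; it supports oracle testing, not
  physiologic inference.
* One severity, strain, sex and laboratory protocol stand behind the
  numbers the package reproduces; the 8-hour window is a property of that
  setting, not of CLP in general.
* No survival/hazard modelling and no stochastic cost modelling — the
  underlying analysis performs none.
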