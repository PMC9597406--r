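---
title: "Methods: activation costs, metabolic power and competing-cost pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation costs, metabolic power and competing-cost pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitccp)
```

## The scientific question

When people walk, they usually choose gaits that save whole-body metabolic
energy. But muscle-level objectives — in particular avoiding high activation
in any single muscle, a precursor of local fatigue — predict realistic gait
at least as well in simulation. The two objectives are normally coupled:
anything that lowers activation usually lowers energy use too. `gaitccp`
implements an analysis that *decouples* them, for an experiment in which
walkers repeatedly choose between two tasks at the same belt speed:

* **crouch walking** on a level treadmill (knee-flexed posture under a
  height constraint), which concentrates activation in the knee extensors at
  a moderate metabolic cost, and
* **upright incline walking** at grades of 0–24%, which raises metabolic
  power steeply while spreading activation evenly across muscles.

At some grade the incline becomes metabolically *more* expensive than the
crouch while still being *cheaper* in activation terms: a **competing-cost
pair (CCP)**. Which side of the pair a walker picks reveals which cost the
nervous system protects.

## Signal processing chain

**Stride segmentation.** Initial foot contacts are upward crossings of 2% of
the peak vertical ground reaction force (`detect_strides()`), with a 0.2 s
refractory guard after each contact. The 2% threshold is the only part of
the rule carried by convention from force-plate practice; the refractory
period and the "first sample at or above threshold after one below"
crossing direction are this package's own deterministic choices
(physiological stride times here exceed 0.8 s, so the guard cannot suppress
genuine contacts). Contacts are reported as 1-based sample indices; at
2000 Hz the 0.5 ms resolution is far below any tolerance used, so no
sub-sample interpolation is done.

**EMG linear envelope.** Per channel (`compute_envelope()`): subtract the
mean, zero-phase 4th-order Butterworth band-pass 20–350 Hz, full-wave
rectify, zero-phase 4th-order Butterworth low-pass 6 Hz, clip ringing below
zero. Zero-phase (forward–backward, `signal::filtfilt`) filtering is
standard EMG practice; it preserves burst timing relative to the force
record. The stated filter order is applied per design at each cut-off with
no cut-off correction. Every stage is positively homogeneous — the property
the normalization below relies on.

**Per-stride activation rate.** For muscle $i$ and stride $j$ of duration
$T_j$,

$$a_{ij} = \frac{1}{T_j}\int_0^{T_j} \mathrm{EMG}_{\mathrm{env},ij}(t)\,dt,$$

a trapezoidal integral on the uniform sample grid divided by the stride
time, so `a` carries both how much of the muscle is active and how often it
is recruited. Activations are normalized muscle-by-muscle to the
participant's level upright trial:

$$A_{ij} = a_{ij} \Big/ \tfrac{1}{5}\textstyle\sum_{j=1}^{5} a_{0,ij},$$

which makes the 0%-incline trial's per-muscle mean exactly 1. The five
analysed strides are the *first five artifact-free complete strides* of the
analysis window; which five strides of a longer recording are used is a
free choice, made configurable (`n_strides`, saturation bound) and logged
via the `strides_used` attribute. Channels excluded for signal quality
propagate as missing, and any cost computed over an incomplete table fails
loudly rather than silently renormalizing.

**Metabolic power.** Breath-by-breath gas exchange is averaged (unweighted,
closed window) over the final 60 s of each trial and converted with the
standard stoichiometric formula

$$C_{\mathrm{met},P} = \frac{1000\,(16.89\,\dot V_{O_2} + 4.82\,\dot V_{CO_2})}{M} \quad [\mathrm{W\,kg^{-1}}],$$

with gas rates in L s$^{-1}$ and body mass $M$ in kg. No
respiratory-exchange-ratio validity screen is applied; a warning is logged
when the window-mean RER exceeds 1.05. Speed is constant across trials, so
no conversion to cost per distance is made.

## Activation cost functionals

All three costs are instances of a weighted power mean per stride,
$\bar C_j = \sum_i w_i A_{ij}^{\,p} / \sum_i w_i$, averaged across the five
strides (per-stride first, then average — for the min–max cost the order
matters):

| cost | weights | exponent | character |
|---|---|---|---|
| `c_a2` | equal | 2 | fatigue-like: penalizes concentrated activation |
| `c_a_max` | — | $\infty$ (symbolic) | min–max limit: only the maximally activated muscle counts |
| `c_a_vol` | muscle volumes | 1 | effort-like: tracks active muscle volume, a proxy for energy use |

The volume weights (0.33, 0.08, 0.10, 0.17, 0.10, 0.17, 0.05 for Gmax, BF,
RF, VM, MG, SOL, TA) are fixed at the printed two-decimal proportions of
the seven-muscle total rather than recomputed from an anatomical atlas, so
the worked-example arithmetic is reproduced exactly. `p = Inf` is handled
symbolically, not as a large float. A note on the limit property: the
*unnormalized* p-norm $(\sum_i A^p)^{1/p}$ converges to the per-stride max
within 1% at $p = 64$ whenever the maximum is clearly separated; the
weight-normalized mean itself carries a persistent factor
$(1/7)^{1/p}$ (≈3% at $p=64$), which is why the tests compare the
compensated form.

## CCP rule, percentages and statistics

For each participant, crouch walking is the arithmetic mean of the initial
and final crouch trials (initial/final selectable for sensitivity checks),
and the comparison incline is the **pre-transition incline** — the steepest
grade chosen over crouch. Costs are expressed as percentages of the
0%-incline trial. A CCP is accepted per pairing when metabolic power
strictly decreased from incline to crouch *and* the activation cost
strictly increased; exact ties never accept.

Advantage and penalty percentages use the pre-transition incline value as
denominator:
$\mathrm{advantage}_X = 100\,(X_{\mathrm{crouch}} - X_{\mathrm{incline}})/X_{\mathrm{incline}}$,
$\mathrm{penalty}_{\mathrm{met}} = 100\,(C_{\mathrm{met,incline}} - C_{\mathrm{met,crouch}})/C_{\mathrm{met,incline}}$.
The denominator convention is not forced by the verbal definition; it was
fixed by an arithmetic cross-check against the worked example — only the
incline denominator reproduces all eight printed range endpoints and the
non-CCP participant's reported reductions — and is therefore the package's
committed choice. These ratios are invariant to any common positive
rescaling of one participant's costs.

Walkers whose choice sequence is not a single transition (an incline
selected above a crouch selection) are flagged non-monotone and excluded
from group summaries by default, since pre/post-transition grades presume
one switch; this is configurable.

`compare_conditions()` implements the decision tree for matched
crouch / pre- / post-transition triples: Shapiro–Wilk screen per condition
at 0.05; repeated-measures ANOVA with paired t post hocs on the parametric
branch, Friedman with Wilcoxon signed-rank post hocs (exact below n = 50
without ties, R's default) otherwise; pairwise decisions against the
Bonferroni-adjusted α = 0.017, post hocs run only after a significant
omnibus at α = 0.05. Degenerate inputs (constant values, constant paired
differences) short-circuit deterministically instead of erroring.

## The synthetic cohort: what it emulates, and what it does not

`sample_profiles()` + `generate_trial()` produce raw trials with the
statistical structure the analysis assumes, with the generator's ground
truth stored alongside:

* **EMG**: a band-limited Gaussian carrier (flat 20–350 Hz, unit RMS)
  amplitude-modulated by a raised-cosine burst spanning each stance phase.
  The envelope target is therefore analytically known:
  gain × burst, with gain$_i$ = baseline$_i(1 + s_i\,\mathrm{grade})$ on
  inclines and baseline$_i \times$ crouch-gain$_i$ in the crouch. Because
  the whole envelope chain is homogeneous, two trials generated with the
  same seed and different gains yield *exactly* the generator's gain ratio
  in the recovered activations; with independent seeds and default noise
  the 5-stride averages recover ratios to a few percent.
* **GRF**: per-stance half-sines with peak 1.2 × body weight and exactly
  zero swing force, with lognormal stride-time jitter (cv 3% by default) —
  so stride detection at any threshold in (0, 20%] recovers the scheduled
  contacts, up to the ~4–5 ms rise-time lag of a half-sine reaching 2% of
  its peak.
* **Gas exchange**: breaths every ~4 s with lognormal timing jitter; rates
  rise exponentially (τ = 30 s) to a condition-dependent target with 5%
  multiplicative noise per breath. A 15-breath final-minute window
  therefore has a ~1.3% standard error, which is why recovery is asserted
  on the average error (< 2%), not per breath.

Cohort defaults mirror the study conditions: ten walkers (mass
69.6 ± 11.1 kg, height 1.70 ± 0.07 m), five grades 0–24%, two crouch trials
plus one trial per grade (seven recordings each), 300 s trials, belt speed
1.15 m s⁻¹. Where the source experiment reports only a qualitative pattern,
defaults were chosen once to be physiologically plausible and are labelled
synthetic: crouch gains of ~3.2–4.2 (VM) and ~2.6–3.4 (RF) versus
~1.2–1.6 elsewhere reproduce the knee-extensor inflation pattern; incline
gain slopes of 0.045–0.055 per % give ~2.2× activation at 24%; oxygen
uptake is anchored at ~4.3 W kg⁻¹ level walking cost, ~1.7–1.9× that in
the crouch, and +7–8% of the level rate per % grade. Under these
conditions crouch walking is metabolically cheaper but activation-costlier
than steep inclines, so simulated choosers with default weights
(w_met = 1, w_act = 0.5 on costs rescaled to the level trial, ties to the
incline) transition to crouch at 18–24% and establish CCPs in the majority
— the qualitative behaviour the analysis is designed to detect.

What the generator does **not** emulate: electromechanical delay, motion
artefact and electrode noise floors, inter-muscle crosstalk, double-support
force sharing (the GRF is single-limb-like), RER drift, and fatigue over
the session. Passing recovery tests therefore validates the *pipeline
arithmetic* under the stated signal model, not robustness to real-world
artefact; the artefact path is exercised only through the explicit
exclusion mechanism.

**Seeds.** One cohort seed governs everything; per-trial seeds are derived
by a deterministic 31-polynomial string hash of (cohort seed, participant,
condition) modulo 2³¹−1, giving independent, individually regenerable
streams.

## Numerical choices and degenerate inputs

* Trapezoidal integration over the closed sample range of each stride;
  stride membership is half-open at the next contact.
* Strict floating-point inequalities in the CCP rule; no tolerance band —
  "decreased and increased" means strictly.
* Baselines with any zero per-muscle mean raise a degenerate-baseline
  error (division undefined); zero incline costs raise a
  degenerate-denominator error; all-zero force signals and records with
  fewer than two contacts raise an insufficient-strides error.
* The envelope clips low-pass ringing at zero, preserving positivity and
  homogeneity.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script cohort runs use ten participants,
seven 300 s trials each, with activation analysed over the first 30 s of
each record (~27 strides available, 5 used) and metabolic power over the
final 60 s — the same windows a 5-min treadmill protocol provides. The
worked-example analysis is pure arithmetic on the packaged
percent-of-baseline table and runs in milliseconds.

## Known limitations

* The statistical branch screens normality per condition rather than on
  ANOVA residuals; with n ≈ 10 the Shapiro–Wilk test has limited power
  either way, which mirrors common practice in this literature.
* The choice model is a deterministic threshold on a two-term composite;
  it contains no decision noise, exploration or hysteresis.
* `c_a2 ≤ c_a_max²` holds per stride but not necessarily after stride
  averaging, so it is not enforced as a runtime invariant; the orderings
  that are theorems (`c_a_vol ≤ c_a_max`, Jensen's bound against the
  squared p = 1 cost) are property-tested.
* Only the vertical GRF of one limb is modelled; toe-off and bilateral
  events are out of scope.
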