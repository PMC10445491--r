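---
title: "Characterizing neuraminidase inhibitors: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing neuraminidase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibkin)
```

## The assay and its models

A fluorometric neuraminidase assay reads the fluorescence of
4-methylumbelliferone released from the MUNANA substrate once per minute
over a 20-minute window. In the initial-rate regime the progress curve is
linear and its slope is a steady-state velocity $v$ (RFU/min). Everything
the package estimates derives from such velocities, measured under varied
substrate, inhibitor, enzyme, or preincubation conditions.

**Steady-state inhibition.** The four candidate rate laws are the textbook
forms:

$$
\begin{aligned}
\text{competitive:} \quad & v = \frac{V_{max} S}{K_m (1 + I/K_i) + S} \\
\text{non-competitive:} \quad & v = \frac{V_{max} S}{(K_m + S)(1 + I/K_i)} \\
\text{uncompetitive:} \quad & v = \frac{V_{max} S}{K_m + S (1 + I/K_i)} \\
\text{mixed:} \quad & v = \frac{V_{max} S}{K_m (1 + I/K_i) + S (1 + I/(\alpha K_i))}
\end{aligned}
$$

with $K_m$ and concentrations in µM and $V_{max}$ in RFU/min at the
reference enzyme level (0.02 unit/mL by default; velocity scales linearly
with enzyme).

**Dose-response.** The inhibition ratio
$(v_{ctrl} - v)/v_{ctrl}$ is already normalized to control, so the IC50
curve is the two-parameter logistic $f = c^h/(c^h + IC_{50}^h)$ with bottom
fixed at 0 and top at 1 — a 4PL would add parameters the ratio definition
has already eliminated. Note that when dose-response wells are *simulated
from a kinetic rate law*, the IC50 the traces actually encode follows the
Cheng-Prusoff relation ($IC_{50} = K_i(1 + S/K_m)$ for competitive,
$IC_{50} = K_i$ for pure non-competitive) rather than any nominal IC50
label.

**Slow binding.** Preincubating enzyme with inhibitor before adding
substrate reveals slow complex formation: residual activity decays as
$v/v_0 = e^{-K_{obs} t}$ with
$K_{obs} = k_4 (1 + [I]/K_i^{app}) = k_4 + k_3 [I]$ and
$K_i^{app} = k_4/k_3$. No steady-state plateau term is included — the decay
law is used exactly as written, which is appropriate over short
preincubation windows.

**Fluorescence quenching.** The enzyme's intrinsic tryptophan/tyrosine
fluorescence (scanned 300–400 nm, peak near 340 nm) is quenched by a bound
ligand. Two single-model descriptions are supported: Stern-Volmer,
$F_0/F = 1 + K_{SV}[Q]$, and the double-log binding isotherm,
$\log_{10}[(F_0-F)/F] = \log_{10} K_A + n \log_{10} [Q]_f$. Free quencher
$[Q]_f$ is approximated by total quencher because the enzyme is at trace
concentration (0.02 unit/mL); no inner-filter correction is applied.

## Estimators and numerical choices

**Velocity extraction** is an OLS slope over a linear window that shrinks
from the end of the trace until $r^2 \ge 0.98$ or only four points remain
(then flagged non-linear). A perfectly flat trace is velocity 0 with
$r^2 = 1$ by convention.

**IC50 fitting** works on the log-concentration scale
($f = 1/(1+e^{-h(\ell - \ell_{50})})$, $\ell = \log c$) via
Levenberg-Marquardt, started from linear interpolation of the 50% crossing.
Zero-concentration wells are controls, never fit points; replicates are
averaged first (`pool = TRUE` fits all points). Data whose inhibition never
crosses the 0.3–0.7 band do not bracket the midpoint and are rejected as
unreliable rather than extrapolated. The confidence interval propagates the
covariance of $\ell_{50}$; an exact zero-residual fit has zero propagated
variance and a degenerate interval.

**Mode classification** fits all four rate laws plus a no-inhibition model
to the full grid and selects by AICc. Near-ties (within 2 AICc units) go to
the fewest-assumption candidate, in the order none > competitive >
non-competitive > uncompetitive > mixed; this prefers the nested model, and
flags a grid with no inhibition signal as degenerate (Ki → ∞) rather than
returning an arbitrary huge Ki. The global fits are *unweighted* by
default: within one grid velocities span less than an order of magnitude, so
heteroscedasticity costs little, whereas weights estimated from the data —
observed $1/v^2$ or standard errors from three replicates — correlate with
the residuals and systematically inflate the apparent improvement of the
more flexible mixed model, biasing selection toward it (we measured the
non-competitive call rate at 2% CV dropping from ~97% unweighted to ~92%
with data-estimated weights). `weighting = "relative"` and `"se"` remain
available. Starting values come from the double-reciprocal line of the
uninhibited rows and a crude per-row Ki; lower bounds keep all constants
positive.

**Reciprocal-space diagnostics** (Lineweaver-Burk, Dixon) keep the classical
$1/v^2$ weights, because the reciprocal transform inflates the variance of
small velocities — there the correction matters and the regressions are
only cross-checks, not the primary verdict. Dixon's Ki is the negated
median abscissa of all pairwise line intersections; parallel lines (the
uncompetitive pattern, which has no Dixon intersection) raise an error that
points to the global fit.

**Reversibility** is judged by intercept z-scores of per-inhibitor
velocity-versus-enzyme lines (|z| < 2 for all levels ⇒ reversible). For
noiseless data the 0/0 z-score of an exactly-through-origin line is defined
as 0.

**Slow-binding constants** are deliberately estimated in the order slope →
intercept → ratio: $k_3$ is the slope and $k_4$ the intercept of the
$K_{obs}$ line, and $K_i^{app} = k_4/k_3$ is *derived*, so the three
reported numbers satisfy the defining identity to machine precision instead
of being three independent estimates. $K_{obs}$ fits use Levenberg-Marquardt
on the exponential directly (no log-linearization bias), with the log-slope
as start; an upward trend is flagged with $K_{obs} = 0$. All slow-binding
computation uses minutes; published tables sometimes print $k_3$ with an
s⁻¹ label while $k_4$ is min⁻¹, and the ratio identity only holds when both
share a time unit, so results carry an explicit unit note.

**Double-log fits** use base-10 logs (slope and intercept are only jointly
invariant to the base, so the base is fixed and documented). $K_A$'s formal
unit is µM⁻ⁿ; the conventional L·mol⁻¹ report applies the $10^6$ factor as
if $n = 1$ and is flagged as such.

## The synthetic-data generator

The generator emulates the published assay's study conditions: $K_m$ =
100 µM substrate at 0.5×/1×/2× $K_m$; inhibitor at 0 plus 0.5×/1×/2×
IC50; enzyme at 0.01/0.02/0.04 unit/mL; 1-min reads for 20 min;
preincubation 0–10 min in 2-min steps (and a 0–75 min profile series);
quencher at 0, 0.2, 0.4, 0.8, 1.6, 3.2 µM scanned 300–400 nm in 2-nm steps;
triplicates with multiplicative Gaussian noise at 2% CV by default. One seed
governs every draw, and identical (truth, noise, design) inputs are
bit-identical across runs.

What it does *not* emulate — and therefore what recovery tests cannot show
about real data: substrate depletion (progress curves are exactly linear),
inner-filter and quenching artifacts of the fluorophore itself,
plate-position and drift effects, correlated replicate errors, tight-binding
depletion of free inhibitor, and two-step induced-fit slow binding
(hyperbolic $K_{obs}$). Emission spectra are a single Gaussian peak at
340 nm (width 22 nm) — a smooth idealization of the real multi-residue
emission envelope; only its peak height carries signal.

Dose-response and quenching wells are generated from their response models
directly (one noise draw per observation), while trace-level stages apply
noise per time point, so a velocity estimated from a 21-point trace has an
effective CV well below the per-read CV — both routes are exercised in the
tests.

## Problem sizes and verification

The test-suite and acceptance runs use the designs above at their published
sizes: 200 seeded repetitions for each stochastic recovery (slow-binding
constants, IC50, mode-classification rate), 3×4 grids for mode work, and
6-point titrations for quenching. Noiseless recoveries are verified to
≤ 10⁻⁶ relative error; stochastic medians to within 5–10% of truth;
classification to ≥ 95% correct calls at 2% CV. Independent brute-force
grid-search oracles cross-check the slow-binding regression and the
double-log fit inside the test suite.

## Known limitations

Ki estimates assume free inhibitor ≈ total inhibitor (no Morrison
tight-binding correction), substrate kinetics are non-cooperative, and
partial/biphasic inhibition is out of scope. The Dixon estimator is
undefined for uncompetitive inhibitors by construction. The reversibility
verdict is a statistical statement about intercepts, not a mechanistic
proof — a slowly reversible inhibitor can appear irreversible-like on short
timescales.
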