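---
title: "Median-effect modelling and combination-index synergy analysis with chousyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-effect modelling and combination-index synergy analysis with chousyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chousyn)
```

## The model

chousyn quantifies enzyme inhibition and drug–drug interaction with the
mass-action median-effect model of Chou and Talalay. For a single agent at
dose $D$, the fraction of the system affected $f_a$ (here: fractional
inhibition of the enzyme) and the unaffected fraction $f_u = 1 - f_a$
satisfy

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

where $D_m$ is the median-effect dose (the dose producing 50% effect,
operationally an IC50) and $m$ a dimensionless sigmoidicity parameter
analogous to a Hill coefficient. Taking logarithms linearizes the law into
the *median-effect plot*

$$\log\frac{f_a}{f_u} = m \log D - m \log D_m,$$

a straight line in $(\log D, \log f_a/f_u)$ whose slope is $m$, whose
x-intercept antilog is $D_m$, and whose Pearson correlation $r$ measures
conformity to mass action ($r > 0.97$ is the conventional bar for in vitro
enzyme systems).

`fit_median_effect()` deliberately fits this *linearized* form by
unweighted ordinary least squares rather than doing nonlinear least
squares on $f_a$: the parameter set $(D_m, m, r)$ is *defined* through the
plot's slope, intercept and correlation, and the linear route is what the
established desktop tools for this analysis compute. The nonlinear route
is available separately: `fit_hill()` fits the four-parameter logistic
$\text{inh}\% = b + (t - b) / (1 + (IC_{50}/D)^{h})$ by multi-start
Levenberg–Marquardt, with the asymptotes fixed at $b = 0$, $t = 100$ by
default. Under those constraints the 4PL and the median-effect model are
the same curve, so $IC_{50} = D_m$ and $h = m$ on noiseless data — a
cross-check the test suite exercises to $10^{-6}$.

## From kinetic traces to dose–effect points

The supported assay readout is a DCIP-type declining absorbance trace:
enzyme activity is the velocity (slope) of $A_{600}$ versus time, and

$$\text{inhibition}(\%) = \frac{v_{\text{control}} - v_{\text{sample}}}
{v_{\text{control}}} \times 100, \qquad f_a = \text{inhibition}/100.$$

`fit_velocity()` takes the OLS slope over the full read by default
(`velocity_window = "full"`), reflecting a short pre-validated linear
window (default simulated design: 0–5 min at one-minute intervals). For
traces whose ends drift off the linear phase, `"auto"` scans every
contiguous window of length at least $\max(3, n/2)$ and keeps the one
with the highest $r^2$, breaking ties toward the earlier and then the
longer window; the test suite pins this policy to a brute-force
enumeration oracle. Replicates are aggregated by *averaging slopes before
computing inhibition* (equivalent to pooling the linear region), not by
averaging per-replicate inhibition percentages — the former is stable
under reordering and matches how a pooled velocity would be read.

Negative inhibition (apparent activation, a sample slope steeper than the
control) is reported as computed and flagged, never clamped: silently
clamping hides assay problems.

### Admissible effect range

The linearization is undefined at $f_a \in \{0, 1\}$ and dominated by
leverage next to those boundaries, so points are only *fittable* when
$f_a$ lies inside the clip bounds, default $(0.005, 0.995)$. Clipped
points are retained and flagged (`fittable = FALSE`), and reports keep
them; they simply never enter a regression.

## Combination analysis

For two agents combined at doses $(D_a, D_b)$ producing effect $f_a$, the
combination index in the two-term (mutually exclusive) form is

$$CI = \frac{D_a}{(D_x)_a} + \frac{D_b}{(D_x)_b},$$

with $(D_x)_a = D_{m,a} (f_a/f_u)^{1/m_a}$ the single-agent equipotent
dose (and likewise for $b$). $CI < 1$ is synergism, $CI = 1$ Loewe
additivity, $CI > 1$ antagonism. The dose-reduction index of each agent
is $DRI = D_x(\text{alone}) / D(\text{in combination})$, giving the exact
identity $CI = 1/DRI_a + 1/DRI_b$ (`ci_from_dri()`), which lets CI be
recomputed from published DRI tables whose dose columns are absent or
unreliable. CI is unitless — each dose is normalized by an equipotent
dose in its own unit — so an extract measured in µg/ml combines with an
inhibitor measured in nM without conversion; units are carried as opaque
labels and never converted (one unit per agent is enforced).

`fa_ci_profile()` builds the fa–CI curve the way fixed-ratio designs are
analysed in practice: the mixture itself is fitted as a single "agent" on
the total-dose axis; at each effect level the total dose
$D_c = D_x(\text{mixture}, f_a)$ is split into components by the fixed
ratio fractions, and CI/DRI follow. The published per-level dose columns
of combination tables are *not* used as inputs: in the benchmark tables
they drift in ratio across effect levels and are mutually inconsistent
with both the CI and DRI columns, so the mixture-fit construction and the
DRI identity are the reproducible routes. When ratio fractions are not
given they default to the agents' $D_m$ proportions — the
equipotency-anchored fixed ratio.

`isobologram_point()` produces the dose-normalized isobologram
coordinates $(D_a/(D_x)_a, D_b/(D_x)_b)$; the additivity line joins
$(1,0)$ and $(0,1)$ at every effect level, and the side-of-line call uses
the same additive band as `classify_interaction()`, so the two views can
never disagree (a property test enforces this).

### The additive band

Measured CI is never exactly 1, and the printed benchmark tables label
CI = 1.03 additive while calling 1.09 antagonism, so strict equality is
plainly not what is practised. `classify_interaction()` therefore uses a
configurable band, default $|CI - 1| \le 0.05$, with the band edges
inclusive (a $10^{-9}$ slack absorbs binary rounding at the edges).

### Loewe additivity as a constructive null

`solve_loewe_mixture()` inverts the additivity condition
$p D_c / D_{x,a}(f_a) + q D_c / D_{x,b}(f_a) = 1$ for $f_a$. The left
side is strictly decreasing in $f_a$ when both slopes are positive, so
the root is unique; it is found with `stats::uniroot()` (Brent
bracketing — robust on a monotone target, no derivatives) on
$f_a \in (10^{-9}, 1 - 10^{-9})$ at tolerance $10^{-12}$, and a missing
sign change is reported with the bracket endpoints rather than guessed
around.

One modelling fact matters when using this null end-to-end: a Loewe
mixture of two agents with *different* slopes $m$ is not itself a
median-effect curve, so refitting such a mixture and profiling CI shows
small model-family deviations (order $10^{-2}$), which are a property of
the model, not an error. With equal slopes the mixture is exactly
median-effect ($D_{m,\text{mix}} = 1/(p/D_{m,a} + q/D_{m,b})$, same
$m$), and the package's additivity-null tests use that construction, where
CI returns to 1 within $10^{-4}$ through the full simulate → kinetics →
fit → profile chain.

## The synthetic-data generator

`simulate_trace()` and the study-level wrappers generate the data the
pipeline assumes: a strictly linear absorbance decline whose velocity is
the control velocity scaled by $1 - f_a(D)$, with i.i.d. Gaussian noise
added to the *absorbance values* — the measured quantity — so noise
propagates through slope fitting exactly as in the assay. Defaults mirror
a standard plate protocol: reads at 0–5 min at one-minute intervals,
control velocity $-0.01\,\Delta A/\text{min}$, initial absorbance 1,
duplicate wells. Replicate-level variance of the real assay was never
published, so the default noise level used in the Monte-Carlo tests
(`noise_sd = 0.002`, i.e. a 3–4% velocity error per well after slope
fitting) is a nominal, realistic choice rather than a calibrated one.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real plates: substrate depletion and trace
curvature, DCIP re-oxidation, plate-position and edge effects, outliers
and pipetting failures, heteroscedastic reader noise. It is a generative
inverse of the analysis assumptions, which is precisely what makes
parameter-recovery and additivity-null tests meaningful.

All randomness flows from a single integer seed; identical seeds give
byte-identical bundles (a test asserts this on the serialized CSVs).

## Problem sizes and numerical choices

- Median-effect fits in the tests use 5–7 point designs spanning
  EC10–EC90, the canonical five-level layout of the benchmark table.
- The slope-bias Monte Carlo runs 500 seeded replicates of a duplicate
  five-dose design at `noise_sd = 0.002` and checks the median bias of
  $m$ stays below 0.05; this size gives a stable median in a few seconds.
- The Loewe grid-search oracle uses a $10^6$-point grid; the solver must
  match it to $10^{-6}$.
- Hill fitting starts from the median-effect guess plus dose quartiles
  (slopes 1 and 2), keeps the best residual sum of squares, reports the
  optimizer's own convergence flag, and refuses under-determined designs
  (fewer than 3 points constrained, fewer than 5 with free asymptotes).
- Reports store full-precision doubles plus a 2-decimal formatted mirror
  (the precision of the printed benchmark tables); the numeric payload is
  byte-deterministic for a fixed config and inputs.

## The screening statistic

The virtual-screening module aggregates per-compound docking scores
(kcal/mol; more negative is better) into a per-plant activity score:

$$\text{plant score} = \Big(\sum_{\text{hits}} \text{score}\Big) \times
\frac{n_{\text{hits}}}{n_{\text{total in database}}},$$

penalizing plants whose catalogued constituents are numerous but rarely
active. A hit is a compound scoring at or below a user-supplied cutoff;
no default cutoff is baked in because the choice is target- and
pipeline-specific (−10 kcal/mol is a common stringent example). Ranking
is most-negative-first with alphabetical tie-breaks, and is invariant to
positive rescaling of all scores.

## Known limitations

- Only the two-term (mutually exclusive) CI is implemented; the
  three-term mutually non-exclusive variant, Bliss independence, HSA, ZIP
  and response-surface models are out of scope, as are three-drug
  combinations.
- No confidence intervals on $D_m$ and $m$ are produced; the benchmark
  tables report none, and the linearized fit's error structure makes
  naive OLS intervals misleading near the clip bounds.
- The benchmark equi-effect dose table is internally consistent with the
  published $m$ and $r$ values but sits on a dose axis twice the
  published $D_m$ scale (a constant factor across agents and levels);
  because the fit is scale-equivariant this affects no slope or
  correlation benchmark, and $D_m$ is asserted only against synthetic
  ground truth.
- Two of the fifteen published DRI rows imply a CI (via the exact
  identity) that differs from the printed CI by slightly more than the
  printed tables' two-decimal precision would explain; the package
  reproduces 13/15 within ±0.02 and surfaces the two discrepant rows
  rather than smoothing them over.

## A worked example

```{r example, eval = FALSE}
library(chousyn)

# single-agent fits from the packaged benchmark dose table
de <- dhodh_dose_effect()
fits <- lapply(split(de, de$agent), fit_median_effect)
do.call(rbind, lapply(fits, glance))

# combination assessment from the published parameter table
ref <- dhodh_reference_fits()
mk <- function(a) with(ref[ref$agent == a, ],
                       medfit(a, Dm, m, r, dose_unit))
cb <- assess_combination(mk("allium_sativum"), mk("brequinar"),
                         mk("allium_sativum + brequinar"))
tidy(cb)
autoplot(cb, "fa_ci")
```
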