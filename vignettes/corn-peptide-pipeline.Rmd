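---
title: "Methods: hydrolysis assays, response-surface optimization and peptide screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrolysis assays, response-surface optimization and peptide screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptriact)
```

This vignette is the package's own account of the models it implements,
the defaults it chose where the methodology literature leaves choices
open, and what the synthetic-data tests do and do not establish.

## 1. pH-stat degree of hydrolysis

Proteolysis releases protons in proportion to the number of cleaved
peptide bonds; titrating them with base at constant pH gives the degree of
hydrolysis

$$DH\,(\%) = \frac{C \cdot V}{a \cdot m \cdot h_{tot}} \times 100,$$

with $C$ the titrant concentration (mol/L), $V$ the consumed volume (mL)
— so $C\,V$ is mmol of base, dimensionally consistent with $h_{tot}$ in
mmol of peptide bonds per g protein — $m$ the protein mass (g) and $a$
the fraction of liberated alpha-amino groups that are deprotonated at the
working pH,

$$a = \frac{10^{pH - pK_a}}{1 + 10^{pH - pK_a}}.$$

The alpha-amino $pK_a$ shifts with temperature. The default form used
here is

$$pK_a = 7.8 + \frac{(298 - T)}{298\,T}\,2400,$$

which equals 7.8 at 298 K and about 7.17 at 323 K, consistent with the
well-known drop of amine pKa values with temperature. A variant with the
sum $(298 + T)$ in the denominator appears in parts of the applied
literature, presumably as a typographical corruption of the product form:
at 323 K it yields a pKa near −89, outside any physically meaningful
range. It is retained behind `variant = "paper-literal"` strictly so the
two can be compared, and is not the default.

`h_tot` is substrate-specific and is treated as a user-supplied constant;
the default 7.35 mmol/g is the customary value for corn protein.

## 2. Initial rates from kinetic progress curves

Spectrophotometric enzyme assays (NADH formation at 340 nm for ADH, uric
acid at 290 nm for XOD) yield saturating progress curves. The initial
rate is defined as the analytic first derivative at $t = 0$ of a curve
fitted to the whole trace, which is far less noise-sensitive than a
two-point slope. Three families are available:

* **quadratic** (default): $A(t) = a_0 + a_1 t + a_2 t^2$, rate $a_1$.
  A quadratic captures the early-time curvature of a saturating trace
  over a 10-min window, has an exact least-squares solution and an exact
  derivative, and does not require the trace to reach its plateau.
* **linear**: for traces that stay in the linear regime.
* **exponential**: $A(t) = A_\infty - (A_\infty - a_0)e^{-kt}$, rate
  $k\,(A_\infty - a_0)$, fitted with `nls()` (log-linear starting values;
  `scaleOffset` keeps the iteration stable on noiseless traces). Use when
  the trace visibly plateaus inside the window.

Rates are always reported in AU/min; the trace declares its time unit
(`"s"` or `"min"`) at construction so unit errors cannot silently scale a
rate by 60. Activation and inhibition percentages
(`adh_activation_rate()`, `xod_inhibition_rate()`,
`dpph_scavenging_rate()`) may be negative; they are never clamped,
because sub-control activity is a real outcome (e.g. in stability
experiments) and clamping would bias averages of replicates.

## 3. Box–Behnken fitting and ANOVA

A 3-factor Box–Behnken design has 12 edge runs — every combination of two
factors at ±1 with the third at 0 — plus replicated center runs (default
5, giving 17 runs and 4 pure-error degrees of freedom). Factors are coded
as $x = (\text{actual} - \text{center})/((\text{high}-\text{low})/2)$; all
model arithmetic happens in coded units so coefficients are comparable
across factors.

The full 10-term second-order model is fitted by ordinary least squares.
On this design the linear columns are mutually orthogonal with
$\sum x_i^2 = 8$, which gives two useful identities asserted in the test
suite: each linear coefficient equals (sum of the response at +1 − sum at
−1)/8, and each linear term's partial sum of squares equals
$8\,\hat\beta^2$.

The ANOVA reports **partial** (drop-one-term, Type-III-like) sums of
squares: the increase in residual SS when the term is removed and the
model refitted. This matches the convention of the dedicated
response-surface packages practitioners compare against. Because the
three squared columns are correlated with the intercept and each other,
their partial SS are *not* additive — per-term SS need not sum to the
model SS, and the model row is therefore computed as corrected total
minus residual. The residual is split into pure error (squared deviations
of the center replicates about their mean, df = replicates − 1) and lack
of fit (the remainder); lack-of-fit F uses the pure-error mean square as
its denominator, all other F ratios the full-model residual mean square.
P-values come from the F distribution (`pf()`), displayed as `<0.0001`
below that threshold to match the conventional print format; full
precision is retained internally. Fit statistics: $R^2 = SS_{model} /
SS_{total}$, adjusted $R^2$, and $CV\% = 100\sqrt{MS_{resid}}/\bar{y}$.

With fewer than two center replicates the lack-of-fit split is undefined
and the report omits it with a warning rather than fabricating it.

## 4. Multi-response desirability optimization

Multiple fitted responses are combined by Derringer–Suich desirability:
each prediction is mapped to $d_i \in [0,1]$, linear between two anchors
(by default the response's observed minimum and maximum in the design),
rising for maximize goals; the overall objective is the weighted
geometric mean $D = (\prod d_i^{w_i})^{1/\sum w_i}$, maximized over the
coded cube $[-1,1]^3$.

Numerical choices: the search runs a bounded quasi-Newton (L-BFGS-B)
local optimization from each of the $3^3$ points of the corner/edge/center
grid and keeps the best solution — fully deterministic, no random
restarts. Individual desirabilities are floored at $10^{-12}$ inside the
geometric mean so a start in a $d = 0$ region still has a usable
gradient. $D$ is invariant under a common rescaling of the weights (this
is asserted as a property test).

Two caveats matter in practice. First, if a fitted surface's maximum
exceeds the observed response range, the default anchors clip $d_i$ at 1
over a whole region and the argmax becomes a plateau; supply wider
explicit `anchors` when a unique interior optimum is needed. Second, the
optimum can move substantially with the goal set, weights and anchors —
with four responses the desirability surface is typically flat near its
top, so differently configured optimizers can report points that are far
apart in factor space yet nearly equivalent in $D$. Reported optima from
closed-source design software whose desirability settings are not
disclosed should therefore be compared by predicted responses, not by
factor coordinates.

## 5. Peptide properties and the screening funnel

Masses are sums of residue masses plus one water, from the standard
average and monoisotopic tables. Net charge at a given pH is the
Henderson–Hasselbalch sum over ionizable groups — positive: N-terminus,
K, R, H; negative: C-terminus, D, E, C, Y. The default pKa set uses
Lehninger-style side-chain values with terminal pKas 9.0 (alpha-amino)
and 3.55 (alpha-carboxyl); every entry is overridable via
`default_pka_table()`. Published pKa sets differ by tenths of a unit, so
isoelectric points computed here agree with third-party calculators only
to a few tenths of a pH unit — comparisons should be tolerance-based.
The pI solves $z(pH) = 0$ by bisection on $[0,14]$ to $10^{-4}$ pH; the
charge function is continuous, strictly decreasing, positive at pH 0 and
negative at pH 14 for every sequence with both termini, so the root
exists and is unique.

The screening funnel applies strict-inequality filters in order: mass
< 1000 Da, ALC > 80 %, relative peak area > 10^5, bioactivity score
> 0.5, non-toxicity, good solubility. The bioactivity threshold is a
package default chosen so that scores just above 0.5 survive, consistent
with common PeptideRanker practice; it is configurable. External
predictors (bioactivity, toxicity, solubility) are third-party tools and
are deliberately not re-implemented: their outputs enter as columns or
through a user-supplied `score_provider` callable. The mass filter
prefers the observed MS mass when present (observed and sequence-computed
masses can legitimately differ, e.g. through modifications) and falls
back to the computed average mass. Because every stage is an independent
per-record predicate, the survivor set is invariant to both record order
and stage order; only the per-stage attrition counts depend on stage
order. Missing fields follow a strict policy by default (error naming the
record and field); a lenient policy passes the record through the
affected stage with a warning, for tables whose provenance lacks a
column (the bundled candidate-peptide table has no ALC column, for
example).

## 6. What the simulators emulate — and what they don't

The generators produce every input the pipeline consumes, with known
ground truth, under a fixed seed (byte-identical regeneration is
asserted):

* `sim_kinetic_trace()` — 61 points over 10 min (10 s cadence, the usual
  plate-reader setting), from a declared curve family plus i.i.d.
  Gaussian noise; default noise 0.002 AU, a typical absorbance
  read-to-read scatter.
* `sim_bbd_responses()` — responses from a known 10-coefficient coded
  surface plus Gaussian noise on the Box–Behnken runs. Gaussian noise
  mirrors the mean ± SD reporting convention of replicate assays;
  noise scales are chosen so the model CV lands in the range typical of
  enzyme bioassays (a few percent for titration up to ~25 % for
  activation assays).
* `sim_peptide_table()` — random sequences with planted funnel survivors;
  every non-survivor is given at least one disqualifying field.

Passing these tests shows the estimators are correct and calibrated under
the stated noise model. It does not show robustness to what real data
add: correlated drift and lamp noise in traces, heteroscedastic or
non-Gaussian assay error, run-order effects in the design, de-novo
sequencing errors, or modified/non-standard residues (sequences outside
the 20-letter alphabet are rejected, not modelled).

Problem sizes used by the test suite — 17-run designs, 61-point traces,
100-seed calibration loops, 100-record screening tables — match the scale
of the motivating laboratory workflow itself, and keep the whole suite
fast.

## 7. Known limitations

* Only the 3-factor Box–Behnken layout is supported: no central-composite
  or mixture designs, no response transformations, no stepwise term
  pruning.
* No correction for peptide-only absorbance interference in the kinetic
  assays, and no Michaelis–Menten parameter estimation ($K_m$, $V_{max}$)
  — initial rates only.
* Charge and pI assume free termini and no modifications; cysteine is
  treated as reduced.
* The desirability optimum is only as meaningful as its configuration;
  see the caveats in section 4.
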