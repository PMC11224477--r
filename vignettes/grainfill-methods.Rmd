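---
title: "Methods: logistic grain-filling analysis and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logistic grain-filling analysis and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainfill)
```

## The model and its assumptions

Grain dry-matter accumulation after pollination is treated as
logistic,

$$W(t) = \frac{A}{1 + B e^{-Ct}},$$

with $t$ in days after flowering (flowering day $t_0 = 0$), $A$ the
asymptotic 100-grain weight (g), $B$ a dimensionless shape parameter
and $C$ (d$^{-1}$) the rate parameter. The model assumes a single
smooth sigmoid per unit: no late-season weight loss, no bimodal
filling, kernels pooled over ear positions. The weight on flowering
day is $W_0 = A/(1+B)$; because sampling starts at 15 d
post-pollination, $W_0$ is always taken from the fitted model, never
from data. Days after pollination and days after flowering are treated
as the same axis, the convention in filling studies that sample from
pollination.

## Phase partition and the two constants

The instantaneous filling rate $W'(t) = ABCe^{-Ct}/(1+Be^{-Ct})^2$
peaks at $t_{max} = \ln B / C$ with value $AC/4$. The *fast* (peak)
period is delimited by the two concavity changes of the rate curve,
i.e. the roots of $W'''(t) = 0$. Writing $p = W/A$, one has
$W''' \propto p(1-p)(1-6p+6p^2)$, whose interior roots are
$p = (3 \mp \sqrt 3)/6$, giving

$$t_{1,2} = \frac{\ln B \mp k_1}{C}, \qquad k_1 = \ln(2+\sqrt 3)
= 1.3169578\ldots$$

The *effective filling period* ends when $W = 0.99A$:

$$t_3 = \frac{\ln B + k_3}{C}, \qquad k_3 = \ln 99 =
4.5951198\ldots$$

Printed phase tables in the agronomic literature use the rounded
constants 1.317 and 4.59512, and `partition_phases()` defaults to
them (`constants = "printed"`) so its output reproduces such tables
digit for digit; `constants = "exact"` uses full precision. The
difference in any boundary time is below $5\times10^{-5}/C$ d, far
beneath any biological signal, but the exact mode is what matches
independent numeric root-finding to $10^{-6}$ d (the rounded mode
differs from the true roots by about $3\times10^{-4}$ d at typical
$C$). `derive_phase_offsets()` recovers both constants numerically
from the model derivatives and serves as the package's internal
cross-check that the closed forms are right.

Durations, gains and mean rates are $T_1 = t_1$, $T_2 = t_2 - t_1$,
$T_3 = t_3 - t_2$, $w_i = W_i - W_{i-1}$, $V_i = w_i / T_i$. Since
$W_1/A$ and $W_2/A$ are fixed fractions ($0.2113$ and $0.7887$) and
$W_3/A = 0.99$, two ratios are *parameter-free*:

* $T_3 / T_2 = (k_3 - k_1)/(2k_1) \approx 1.2446$,
* $V_2 / V_3 \approx 3.5692$.

Consequences: (i) any treatment, year or variety shifts $V_2$ and
$V_3$ — and $T_2$ and $T_3$ — by *identical percentages* whenever the
phase parameters come from fitted logistic curves, which explains the
pairwise-identical percentage changes such tables often show; (ii)
$V_2$ and $V_3$ (and $T_2$, $T_3$) computed from fits are exactly
collinear, so stepwise selection over all three rates must and does
drop one member (with a warning). A published three-rate regression
can only arise from rates estimated some other way (e.g. empirical
secants) or from rounded inputs. Mass balance
$w_1 + w_2 + w_3 = 0.99A - W_0$ holds identically (it telescopes); in
rounded-constants mode $W_3$ differs from $0.99A$ by about $10^{-9}$
relative.

## Curve fitting

`fit_logistic()` uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with all parameters constrained positive,
`ftol = 1e-10` and at most 200 iterations (defaults exposed). The
start is deterministic: $A_0 = 1.05 \times \max W$, then OLS on the
linearization $\ln(A_0/W - 1) = \ln B - Ct$. The 5% inflation keeps
every observation strictly below the provisional asymptote; it also
biases the linearized $C_0$ and $\ln B_0$ low by up to ~25% on
typical 9-point series — acceptable for a starting value (the
optimizer then recovers noiseless truth to $10^{-4}$ relative and is
idempotent to $10^{-8}$ on its own predictions), and preferable to a
randomized start because repeated fits of the same data are
identical. No random restarts are used.

Failure handling: flat or otherwise degenerate series return
`converged = FALSE` with `NA` parameters rather than erroring, so a
trial-wide `fit_filling()` never dies on one bad unit. Both
per-replicate fitting (default) and treatment-mean fitting
(`mode = "treatment_mean"`) are provided: filling studies use both
conventions and rarely state which, so the choice is explicit here.

A design consideration behind the package's recovery benchmarks: for
9 samples (15–55 d) the Fisher information on $B$ is weak — a
Cramér–Rao calculation over the calibrated regime
($A \in [25,40]$, $\ln B \in [2.5,4.5]$, $C \in [0.10,0.20]$) shows
that with weighing noise at 1% of $A$ *no* estimator can recover all
three parameters within 10% more than about two-thirds of the time,
while at 0.25% of $A$ the bound allows essentially always. The
recovery study in the test suite therefore runs at 0.25% of $A$
(technical-replicate weighing scale, 300 series), while the trial
generator keeps field-level noise of 0.3 g for power and size
studies. Relative error on $A$ and on the derived phase *times* is
much less noise-sensitive than on $B$.

## Empirical rates and the quadratic peak

`filling_rates()` computes secant rates $(W_{curr}-W_{prev})/D$ per
sampling interval, placed at the interval midpoint — the midpoint
centres the secant estimate of the derivative. Intervals with
decreasing weight are flagged, never dropped. `quadratic_peak()` fits
$rate = a + bt + ct^2$ by OLS and reports the vertex, erroring when
the fit is not concave. The quadratic is an approximation: on a
noiseless logistic sampled 15–50 d its vertex sits about 3 d early
and 12% low relative to $(t_{max}, AC/4)$, because the sampling
window is asymmetric about the peak; the tests encode these measured
deviations rather than pretending the approximation is exact.

## Split-plot ANOVA, error strata and LSD

The design is the classical split plot: tillage on main plots within
replicate blocks, variety on subplots. Replicates are random blocks;
Error I is the block × tillage interaction with $(m-1)(r-1)$ df and
tests tillage; Error II is the residual with $m(v-1)(r-1)$ df and
tests variety and the interaction — exactly the two error strata that
variance-analysis tables for such trials print. Sums of squares are
closed-form for the balanced case and additive to machine precision;
unbalanced data are refused explicitly rather than approximated,
since the two-stratum decomposition is only clean when balanced. The
independent cross-check in the tests is `aov()` with an `Error()`
term, and a brute-force oracle from marginal means. Zero error
variance yields `NA` F-statistics plus a diagnostic note, not a
crash. Years are analysed separately (no pooled-year model), matching
how multi-year trait tables are reported.

LSD at level $\alpha$ is $t_{1-\alpha/2,df}\sqrt{2 MS_e/n}$ with
letters assigned by a descending-mean sweep; two levels share a
letter *iff* their means differ by at most the LSD (with a single LSD
this relation is an interval graph, so letters are the maximal runs
in sorted order). Comparing tillage levels at a fixed variety mixes
strata, so `lsd_tillage_within_variety()` defaults to the combined
error $[(v-1)MS_{II} + MS_I]/v$ with Satterthwaite df;
`method = "error2"` gives the simpler subplot-error convention for
compatibility with analyses that use it.

## Multivariate stages

Pearson p-values use the exact $t = r\sqrt{(n-2)/(1-r^2)}$ transform,
two-sided and unadjusted — trait-association studies of this kind
conventionally apply no multiplicity correction, and that choice is
surfaced rather than hidden. PCA is an eigendecomposition of the
correlation matrix (every variable standardized to unit variance);
explained fractions are $\lambda_i/\sum\lambda$, and each component
is sign-fixed so its largest-magnitude loading is positive — biplot
orientation is otherwise arbitrary and irreproducible.

Stepwise regression is the classical forward-entry /
backward-elimination scheme on partial-F p-values with entry and
stay thresholds `sle = sls = 0.15`, the long-standing default of the
major stepwise implementations; under it, terms with $p \approx 0.08$
are retained in final models, which matches how published stepwise
tables report moderately significant terms. Ties are broken by the
smallest entry p-value; exactly collinear candidates are skipped with
a warning; revisiting a previously seen model terminates the loop
with a diagnostic. With a single candidate and `sle = 1` the
procedure reduces to simple OLS, a reduction the tests verify.

## The synthetic generator: what it emulates and what it does not

`trial_config()` encodes a 9-tillage × 2-variety × 3-replicate
split-plot trial over two years, sampled every 5 d from 15 d
post-pollination (9 points). Defaults are calibrated to the effect
scale reported for tillage/straw-management trials on spring maize:
base asymptotes near 33–34 g (so maturity 100-grain weights at 14%
moisture land near 38–40 g), $\ln B \approx 3.7$–3.9,
$C \approx 0.15$ d$^{-1}$ (peak near 25 d, effective filling ~55 d);
tillage shifts on $A$ up to about +5.5% (largest for straw
incorporation with deep tillage, DPR, then subsoiling variant SSR)
and on $C$ up to +7%, giving peak-rate shifts in the low teens of
percent; replicate-level lognormal jitter of 1% on $A$ and $C$;
weighing noise 0.3 g. Quality traits are linear maps of the true
phase parameters plus noise, with signs chosen so grain weight
associates positively with starch and fat and negatively with protein
and soluble sugar; the starch and fat maps use published-scale
coefficients (starch $= 65.62 + 10.86\,V_1$; fat
$= 2.99 + 2.34\,V_1 - 4.21\,V_2 + 18.43\,V_3$) so trait values land
at realistic percentages.

What the generator does **not** emulate: weather-driven year effects
(years differ only by a 1% shift on $A$), spatial field structure and
block-by-treatment interaction beyond iid jitter, measurement error
in sampling *time*, kernel-position effects, non-logistic late-season
behaviour, and any soil-process mechanism linking tillage to filling.
Passing recovery and power tests on these data therefore demonstrates
correctness of the *statistical machinery* under the stated model,
not validity of the logistic model for any particular field data set.

Simulation study sizes, fixed as the package's own design: 1 000
parameter triples for the closed-form/numeric equivalence check; 300
series for parameter recovery; 3 000 null trials for ANOVA size
calibration (binomial SE ≈ 0.004 around 0.05); 200 trials for power
against a +5% DPR effect on $A$ and 1 000 null trials for the
false-positive rate of the same pipeline.

## Degenerate inputs and edge behaviour

* $A, B, C \le 0$: invalid-parameter error at every model entry
  point.
* $\ln B \le k_1$: "degenerate partition" error ($t_1 \le 0$, the
  gradual phase would start before flowering); the generator raises
  this at generation time rather than letting it surface downstream.
* Duplicate sampling dates: error naming the offending rows (reader)
  or series (rate computation).
* Constant series: initialization refuses (zero linearized slope);
  `fit_logistic()` converts that into `converged = FALSE`.
* Zero total variance: explicit error for $r^2$ and for correlation
  and PCA columns, naming the column.
* All-equal ANOVA input: all SS zero, F undefined, flagged via a
  note attribute.

## Known limitations

The partition inherits every limitation of the logistic form; growth
laws with asymmetric inflection (Richards, Weibull) are out of scope,
as are hierarchical/Bayesian curve fits, REML mixed models for the
split plot, heteroscedasticity corrections, and multiplicity
adjustment beyond LSD. The stepwise procedure is the classical one —
its selection inferences are conditional and should be read as
descriptive, which is how the linked literature uses them.
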