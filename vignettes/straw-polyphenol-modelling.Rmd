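---
title: "Modelling harvest effects on sugarcane straw polyphenols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling harvest effects on sugarcane straw polyphenols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawpoly)
```

## The problem

Sugarcane straw is a harvest by-product rich in polyphenols, but the
polyphenol content of any given straw batch depends strongly on how, where
and when it was harvested. `strawpoly` models five harvest factors —
collection date, sugarcane variety, geographic area, borer
(*Diatraea saccharalis*) infection level, and harvest (ratoon) number —
against five responses: the summed concentrations of the three polyphenol
classes in the extract (hydroxybenzoic acids, hydroxycinnamic acids,
flavones, in µg/g dry extract) and the antioxidant capacity measured as
ABTS and DPPH IC50 (mg/mL, lower = stronger).

Two model families are fitted and compared:

1. a **second-order response-surface model** (RSM) in coded factors, with a
   Derringer desirability search for the best harvest condition, and
2. a **single-hidden-layer perceptron** (MLP) trained by BFGS, with Garson
   connection-weight sensitivity analysis.

## The data

The package ships the study's printed tables as plain-text fixtures: a
compound-to-class listing (40 compounds in three classes), per-compound
concentrations for 14 samples per area (2 areas × 7 dates × high/low borer
infection), per-sample antioxidant IC50s, and the published coded-factor
coefficient table. `load_study_data()` reads, validates and aggregates all
of them:

```{r data}
d <- load_study_data()
head(d$responses)
```

Per-compound cells follow a `"value ± sd"` grammar; `"-"` means the
compound was not detected and contributes 0 to its class sum (the only
completion consistent with summing detected compounds), and `ND`
antioxidant cells become `NA` and are excluded from any model fitted to
that response.

One caveat is deliberate: the study reports only a high/low infection
*class* (4–11% vs 0–4%), never per-sample percentages. The conditions
fixture therefore carries a synthetic numeric stand-in at the class
midpoints (7.5 and 2.0%), and its filename says so. Everything downstream
treats infection like any other factor, but on the real fixtures the coded
infection column has just two values, so its quadratic term is constant
and the full 20-term design is rank-deficient (rank 19). `rsm_fit()`
detects this, warns, and returns a minimum-norm least-squares solution
with the aliased term flagged — predictions are unaffected, but
per-coefficient inference on the real data is not available. Synthetic
designs (below) spread infection across each class band and are full rank.

## The response-surface model

Raw factors are coded onto $[-1, +1]$: date affinely over the observed
span, variety by its ordinal position in the closed nine-variety list,
area as Guariba $= -1$ / Valparaiso $= +1$, infection and harvest affinely
over their observed ranges. Treating the nominal variety factor as one
ordinal axis is a modelling caveat inherited from the study design; the
coding is isolated in `factor_coding()` so an alternative is one function
away.

The model is the 20-term second-order polynomial

$$
Y = \beta_0 + \sum_i \beta_i X_i + \sum_{i \ne 3} \beta_{ii} X_i^2
  + \sum_{i<j} \beta_{ij} X_i X_j ,
$$

with the area quadratic excluded (a two-level factor coded to $\pm 1$ has
a constant square). Fitting is ordinary least squares; p-values are
two-sided t-tests with $n - \mathrm{rank}(X)$ degrees of freedom; $R^2$
uses mean-centred total sums of squares and is defined as 0 for a
zero-variance response (with a warning); RMSE is $\sqrt{SSE/n}$, matching
the comparison module's definition.

```{r rsm}
X <- code_factors(d$conditions)
fit <- suppressWarnings(rsm_fit(X, d$responses$hydroxybenzoic,
                                response = "hydroxybenzoic"))
fit
```

A model can also be seeded directly from the published coefficient table,
without refitting; its prediction at the coded origin is the published
intercept:

```{r seeded}
models <- read_coefficient_models()
predict(models$hydroxybenzoic, rep(0, 5))
```

## Desirability optimisation

Each response is transformed to a one-sided Derringer desirability
(maximise the three classes, minimise the two IC50s), with the observed
response range as the default desired range and unit weights. The
composite score is the weighted geometric mean — 1 only when every
response is fully desirable, 0 as soon as any is fully undesirable.

The optimiser is an exhaustive grid search over *realizable* conditions:
the observed dates, varieties, areas and harvests, with infection gridded
at 0.5% steps across its observed range. A continuous optimiser could
return a condition between varieties, which cannot be harvested. Ties
break to the lexicographically smallest coded point. When the optimum
predicts responses beyond their desired (observed) range the result is
flagged as extrapolation beyond the data hull — the published optimum has
the same character, predicting a flavone level far above any observed sum,
which is why no acceptance check is tied to those predicted values.

## The neural network

The network inputs are a one-hot expansion of the categorical factors
(7 dates + 9 varieties + 2 areas) plus the two standardized continuous
factors — 20 inputs, which reconciles every `MLP 20-h-5` network name in
the study's tables with its five outputs. Hidden sizes 3–5 and the four
activation functions (identity, logistic, tanh, exponential) span the
search space; training minimises the sum-of-squares error with BFGS using
analytic backpropagation gradients, from uniform $[-0.5, 0.5]$ seeded
initial weights, stopping at a gradient max-norm of $10^{-6}$ or 500
iterations. The data are split 70/15/15 (rounded to nearest, remainder to
training: 27 points split 19/4/4); the search trains 20 candidates and
retains the 5 with the highest mean validation Pearson correlation. Each
candidate derives its initialisation seed from its own description rather
than its position, so the ranking does not depend on the order candidates
are supplied. A single split is the study's published procedure;
leave-one-out validation would be preferable at these sample sizes and is
easy to script around `mlp_fit()`, but it is deliberately not the default.

Garson sensitivity partitions the absolute connection weights: input $x$'s
share through hidden neuron $b$ is $|W_{xb}| / \sum_a |W_{ab}|$, weighted
by $|V_b|$ and normalised over inputs (the normalisation index in the
source description is ambiguous; it is read here as the input count, the
standard Garson form). Indicator columns are summed back into their parent
factor, the importances are non-negative and sum to 1, and the result is
invariant to positive rescaling of the output weights and to hidden-neuron
permutation.

```{r pipeline}
man <- suppressWarnings(suppressMessages(run_pipeline(run_config(seed = 1))))
round(man$sensitivity, 3)
```

On the study fixtures, variety and collection date carry the largest
importances across all five responses, with harvest number next — in
qualitative agreement with the study's conclusion that season, variety and
region dominate, though the exact ordering of area versus harvest differs
under this package's coding and seeds.

## The synthetic generator

`simulation_spec()` / `simulate_design()` / `simulate_responses()`
generate datasets with the structure the analysis assumes: a deterministic
2-area × 7-date × 2-infection-class design (28 conditions, optionally
replicated), responses drawn from a known 20-term polynomial plus
homoscedastic Gaussian noise. Defaults are the study conditions — the
published coefficient columns as true coefficients and the published RMSE
row (7.455, 38.418, 8.948, 0.04, 0.12) as noise SDs. Numeric infection
levels cycle over four values in each class band (0.5–3.5 low, 5–11 high),
emulating the sampling plan's precise-level description and keeping the
quadratic infection term identifiable. A homoscedastic Gaussian noise
model is an assumption, not something inferred from the printed data; the
generator also cannot emulate per-compound variation (it synthesises at
the class level the models consume), analytical replicate structure, or
the correlated metadata quirks of the real tables, so passing synthetic
tests demonstrates correctness of the machinery, not field validity.

Two properties anchor the generator to the models. Noiseless
simulate → fit → predict is the identity on the coefficients (to $10^{-8}$),
and under study-level noise the 95% OLS confidence intervals cover each
true coefficient at close to nominal rate (≥ 90% over 200 seeded
replicates at $n = 56$).

The optional distortion term `amplitude * sigma_r * sin(pi X5) * X1` (in
noise-SD units per response) injects smooth curvature outside the
polynomial family. It operationalises the study's claim that the network
outperforms the polynomial only when such curvature exists: at three
design replicates ($n = 84$, enough that every condition is usually seen
in training), the polynomial's $R^2$ matches or beats the network's test
$R^2$ in the large majority of seeds when the amplitude is zero, and the
ordering reverses at amplitude 200. At $n = 56$ the network frequently
cannot generalise to conditions absent from its training split (a one-hot
encoding cannot extrapolate to unseen factor combinations), which is a
finding about the encoding, not a test failure — the test conditions use
the denser design.

## Numerical choices

* Concentration equality tolerance in tests: $10^{-6}$ µg/g (tables print
  one decimal). Response-table CSV round trips are exact to $10^{-9}$
  (full-precision formatting).
* Compound-name matching is exact after Unicode/whitespace normalisation;
  no fuzzy matching, so a typo fails loudly rather than silently
  misclassifying a compound.
* Rank-deficient designs: warning + minimum-norm SVD solution, aliased
  terms flagged, no coefficient inference.
* Saturated or coefficient-seeded models return point predictions with a
  warning instead of confidence intervals.
* Grid-search tie-break: lexicographic on coded coordinates.
* Desk-scale problem sizes throughout the test suite: 28–84 simulated
  conditions, 20-candidate searches with iteration caps of 60–400 —
  chosen to exercise every code path at the scale of the study itself.

## Known limitations

* Exact reproduction of the published fitted coefficients is out of reach:
  the original analysis used closed-source software whose factor coding
  (notably for the nominal variety) and network internals are
  undocumented. The package instead verifies everything that is checkable:
  printed table values, the published intercepts as origin predictions,
  procedural rules (split sizes, retain-5-of-20), and the statistical
  properties of its own estimators.
* The desirability optimum, like the published one, can extrapolate beyond
  the observed response range; it is reported with a hull-exit warning.
* IC50 responses are modelled on the 20 determined samples only; with 20
  observations and 20 terms those fits are saturated and serve prediction,
  not inference.
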