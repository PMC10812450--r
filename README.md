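# strawpoly

Response-surface and neural-network modelling of how harvest conditions
shape the polyphenol content of sugarcane straw.

Sugarcane straw is a large-volume harvest by-product and a usable source
of polyphenols, but the yield of a straw extract depends on biotic and
abiotic factors at harvest: collection date, sugarcane variety, geographic
area, borer (*Diatraea saccharalis*) infection level, and harvest (ratoon)
number. `strawpoly` is for chemometricians and agronomists who want to
model those five factors against five responses — the summed
concentrations of the three polyphenol classes in the extract
(hydroxybenzoic acids, hydroxycinnamic acids, flavones; µg/g dry extract)
and antioxidant capacity (ABTS and DPPH IC50, mg/mL) — and to find the
harvest condition that maximises them all at once.

## What it computes

**Response-surface model.** Factors are coded onto \[-1, +1\] and each
response is fitted by ordinary least squares to the 20-term second-order
polynomial

    Y = b0 + sum_i b_i X_i + sum_{i != 3} b_ii X_i^2 + sum_{i<j} b_ij X_i X_j

(the area quadratic is excluded: a two-level factor coded to ±1 has a
constant square). `rsm_fit()` returns a classed object with
`print`/`summary`/`coef`/`predict`/`residuals` methods, coefficient
t-tests, R², adjusted R² and RMSE.

**Derringer desirability.** Each predicted response maps to a one-sided
desirability d ∈ \[0, 1\] relative to its desired range (concentrations
maximised, IC50s minimised); the composite D is the weighted geometric
mean. `optimize_desirability()` searches exhaustively over realizable
harvest conditions and reports the best one.

**Neural network.** `mlp_fit()` trains a single-hidden-layer perceptron
(one-hot factor expansion to 20 inputs, 3–5 hidden neurons, sum-of-squares
loss, BFGS with analytic gradients, seeded). `mlp_search()` trains 20
candidates and retains the best 5 by validation Pearson correlation on a
seeded 70/15/15 split; `garson_importance()` partitions the connection
weights into per-factor relative importances that sum to 1.

**Comparison.** `comparison_report()` scores the polynomial and every
retained network by R² and RMSE, per response and per data partition.

**Synthetic surfaces.** `simulation_spec()` / `simulate_design()` /
`simulate_responses()` generate seeded datasets from a known polynomial
plus Gaussian noise (defaults: the published coefficient and RMSE values),
with an optional non-polynomial distortion for capacity comparisons.

The study's printed tables ship as plain-text fixtures under
`inst/extdata/` (the numeric infection column is a documented synthetic
stand-in at the printed class midpoints).

## Worked example

```r
library(strawpoly)

d <- load_study_data()                 # 28 samples, 5 responses
X <- code_factors(d$conditions)
fit <- rsm_fit(X, d$responses$hydroxybenzoic, response = "hydroxybenzoic")
fit
#> Second-order response-surface model for 'hydroxybenzoic'
#>   terms: 20  n: 28  rank: 19
#>   R2 = 0.9130  adj R2 = 0.7390  RMSE = 48.8801
```

The fit explains 91% of the hydroxybenzoic-acid variance across the 28
study samples; rank 19 (not 20) is expected on the shipped fixtures,
because the infection factor has only two printed levels so its quadratic
term is constant (the fit warns and uses a minimum-norm solution).

A model seeded from the published coefficient table predicts the printed
intercept at the coded design centre:

```r
models <- read_coefficient_models()
predict(models$hydroxybenzoic, rep(0, 5))
#> [1] 157.15
```

The full pipeline — ingest, aggregate, code, fit, optimise, search,
sensitivity, compare — is one call:

```r
man <- run_pipeline(run_config(seed = 1))
man$optimum
#> Optimum over 10584 candidate conditions: D = 1.0000
#> Decoded condition:
#>  collection_date  variety    area infection_level harvest_number
#>       2020-07-24 SP813250 Guariba               2              1
round(man$sensitivity[, 1:3], 3)
#>           hydroxybenzoic hydroxycinnamic flavones
#> date               0.249           0.243    0.245
#> variety            0.440           0.449    0.449
#> area               0.099           0.101    0.100
#> infection          0.074           0.063    0.064
#> harvest            0.138           0.144    0.143
```

`D = 1` means every response simultaneously reaches its most desirable
level at that condition (with an extrapolation warning, since the
predictions exceed the observed ranges). The Garson importances say
variety and collection date dominate polyphenol variability — the two
factors a grower choosing straw batches should look at first.

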