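# discardcast

Bayesian state-space hind-casting of the quantity and composition of fish
discarded by commercial fisheries, from research-vessel trawl-survey
length compositions and official landings.

## The problem

For most exploited fish stocks only the landed weight is recorded; the
portion of the catch thrown back at sea is seen only by observers aboard a
small sample of vessels. The traditional expansion from an observed
discard proportion *p*, `D = p L / (1 - p)`, blows up as *p* approaches 1
and is unusable for heavily discarded species. `discardcast` instead
estimates the *total catch* directly from a survey index of
biomass-at-length, and obtains discards by difference from the landings.

For species *k* in year *t*, with survey biomass index `u_t`, length
proportions `π_{i,t}`, catch ratio `Q_t` (survey catchability x harvest
rate), logistic capture selectivity `s'_i` (parameters SL50, SI) and
retention selectivity `r_i` (RL50, RI), and an annual bulk-discard
fraction `q_t`:

    C_t = u_t Q_t Σ_i s'_i π_{i,t}
    D_t = u_t Q_t ( Σ_i s'_i π_{i,t} + (q_t - 1) Σ_i r_i s'_i π_{i,t} )
    L_t = C_t - D_t

`log Q_t` and `log u_t` follow random walks; observed index, landings and
discards carry multiplicative lognormal measurement error. Discards split
into a *quantity-related* component `q_t C_t` (bulk rejection for quota or
market reasons) and a *size-related* component `D_t - q_t C_t` (fish below
the retention ogive).

Two fitting modes are provided (Gibbs sampling via JAGS/`rjags`):

* **full model** (`fit_full`) — joint fit to "reference" species with
  observed discard series, pooling capture SL50 hierarchically and
  estimating the retention-to-MLS ratio `h = Σ RL50_k / Σ MLS_k`;
* **reduced model** (`fit_reduced`) — landings-only species, with the
  catch ratio borrowed as a Dirichlet-weighted geometric mean of the
  reference species' posterior `log Q` series and RL50 fixed at
  `h × MLS`.

Supporting modules cover survey processing (swept areas with regression
imputation, taxon aggregation, allometric conversion of numbers to a
biomass index), retention estimation from observer length frequencies or
minimum landing sizes, a synthetic-data generator with exactly the model's
statistical structure, leave-discards-out cross-validation, knife-edge
estimation of `q` from age compositions, sensitivity analysis, and
draw-wise assemblage aggregation.

## Worked example

Generate a synthetic 5-reference + 3-landings-only scenario over 34 years,
fit the full model, and cross-validate the reduced model with discards
withheld:

```r
library(discardcast)

sc  <- reference_scenario(n_reference = 5, n_other = 3, n_years = 34, seed = 1)
obs <- lapply(sc$reference, function(s) sc$species[[s]]$obs)

fit <- fit_full(obs, mls = sc$mls, seed = 2)
fit
#> <discard_fit> full model: ref1, ref2, ref3, ref4, ref5; 34 years;
#>   4 chains x 2000 iterations; CONVERGENCE FLAGGED

fit$summary$median[fit$summary$variable == "h"]
#> 0.869        # retention/MLS ratio; the scenario was generated with 0.874

head(fit_series(fit, "D", "ref1"), 4)   # discard hind-cast vs truth below
#>  year  median   lower   upper      (true D: 6965, 10647, 5121, 4384)
#>  1978  7267.2  4919.0 10973.6
#>  1979  8808.2  5503.3 13153.3
#>  1980  5715.1  3748.5  9189.5
#>  1981  5019.7  3770.5  7078.2

cv <- cross_validate(obs, fit, mls = sc$mls, seed = 3)
round(cv$weights, 2)
#>      ref1 ref2 ref3 ref4 ref5
#> ref1 0.58 0.31 0.03 0.06 0.01
#> ref2 0.16 0.72 0.04 0.06 0.01
#> ref3 0.09 0.08 0.71 0.05 0.07
#> ref4 0.05 0.06 0.04 0.84 0.02
#> ref5 0.01 0.01 0.02 0.02 0.94
```

The true annual discards fall inside the 95% credible intervals, `h` is
recovered to within 1%, and each leave-discards-out refit puts its largest
Dirichlet weight on the species' own catch-ratio series (the diagonal).
The `CONVERGENCE FLAGGED` note reports slow mixing of the weakly
identified selectivity parameters — see the methods vignette
(`vignettes/discard-hindcasting.Rmd`) for why this is expected and how it
is diagnosed; the discard quantities themselves are well determined.

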