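---
title: "Hind-casting fishery discards from survey length compositions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hind-casting fishery discards from survey length compositions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by
`discardcast`, the choices made where the design was genuinely open, and
what the synthetic-data tests do and do not demonstrate about real survey
and landings data.

## The model

Commercial discarding is driven by two distinct processes: fish too small
to land (for legal or market reasons) and bulk rejection of
marketable-sized fish when quota is exhausted or the species has little
value. The model separates these by filtering a survey-derived
biomass-at-length composition through two logistic ogives.

For a species in year $t$, let $u_t$ be the latent survey biomass index
(kg km$^{-2}$), $\pi_{i,t}$ the proportion of survey biomass in 1-cm
length class $i$, $Q_t$ the catch ratio (the product of survey
catchability and the fleet's annual harvest rate — neither is separately
identifiable, and neither needs to be), $s'_i$ the capture selectivity of
the commercial fleet *relative to the survey's size perception*, $r_i$ the
retention selectivity applied during on-board sorting, and $q_t \in [0,1]$
the annual bulk-discard fraction. Then

$$C_t = u_t Q_t \sum_i s'_i \pi_{i,t}, \qquad
  D_t = u_t Q_t \Big( \sum_i s'_i \pi_{i,t} + (q_t - 1) \sum_i r_i s'_i \pi_{i,t} \Big),$$

with landings $L_t = C_t - D_t$. Both ogives are two-parameter logistics,
linear on the logit scale with slope $\log(9)/\mathrm{interval}$, so that
the selection interval is the distance between the 25% and 75% selection
lengths. It follows algebraically that $q_t C_t \le D_t \le C_t$ — an
invariant the test suite asserts over randomized inputs. Discards then
split exactly into a quantity-related component $q_t C_t$ and a
size-related component $D_t - q_t C_t$.

Latent states evolve as driftless random walks with multiplicative error,
$\log Q_t = \log Q_{t-1} + e_{Q,t}$ and likewise for $\log u_t$; observed
index, landings and discards are the latent quantities times lognormal
measurement error. The likelihood convention is pinned down for testing:
each non-missing datum contributes the normal density of the
*log-observation* (so a zero-residual datum at $\sigma = 1$ contributes
$-\tfrac12\log 2\pi$). Missing observations are skipped, never imputed;
zero observed values carry no information on the log scale and are
treated as missing.

## Priors and their interpretation

The full model (joint fit to the reference species $k$ with observed
discards) uses:

| parameter | prior | notes |
|---|---|---|
| SL50$^*$ (common capture midpoint, cm) | Uniform(5, 30) | lowest size class to above full retention |
| $\sigma_{SL50}$ (cm) | Uniform(0, 100) | hierarchical spread of SL50$_k$ |
| SL50$_k$ | Normal(SL50$^*$, $\sigma_{SL50}$) | species random effect |
| SI$_k$, RI$_k$ (cm) | Normal(6, 1.414) | truncated below at 0.5 cm |
| RL50$_k$ (cm) | Normal(MLS$_k$, 7.76) | centred on the minimum landing size |
| $q_t$ | Beta(0.5, 3) | mode at 0, long right tail |
| all precisions $1/\sigma^2$ | Gamma(0.1, 0.1) | observation and random-walk errors |
| $\log u_{1}$ | Normal(mean log index, 0.5) | initial index state |
| $\log Q_{1}$ | Uniform(2, 14) | natural-log scale, taken literally |

The reduced model (single landings-only species) replaces the capture
prior by Normal(15.25, 4.93) (the reference-case posterior), fixes RL50 at
$h \times$ MLS with $h = \sum_k \mathrm{RL50}_k / \sum_k \mathrm{MLS}_k$
from the full fit, and sets
$\log Q_t = \sum_k w_k \log Q_{k,t}$ with Dirichlet(1, …, 1) weights over
the reference series — a weighted geometric mean, chosen because the
reference catch ratios are strongly right-skewed (an arithmetic-mean
switch is exposed for sensitivity analysis). The bulk-discard prior is
Beta(1, 1) for low-value species (no presumption against bulk discarding)
or Beta(1.4, 12) for high-value species; `beta_from_moments()` reproduces
such a prior from the mean and variance of reference-case posterior $q$
values.

Three interpretive choices deserve record:

* **Scale parameters of Normal priors are standard deviations.** Models
  of this family are traditionally coded in the BUGS language, where
  `dnorm` takes a precision; the table values here read naturally as
  standard deviations and are converted to precisions internally.
  `normal_scale = "precision"` switches the reading for anyone porting a
  BUGS configuration.
* **The hierarchical SL50 block.** A flat Uniform(5, 30) on the
  species-level SL50 together with a hierarchical spread prior is only
  coherent if the uniform applies to the *common mean* SL50$^*$; that is
  how it is implemented.
* **The initial-index prior mean** is the mean of the *log* observed
  index, so the prior lives on the same scale as the parameter.

Normal priors on lengths and intervals are truncated below at 0.5 cm: a
non-positive selection interval is structurally impossible, and the
truncation point is far below any data-supported value.

## Fitting

Sampling is Gibbs/slice via JAGS (`rjags`); the model code is generated in
R (`full_model_code()`, `reduced_model_code()`). The default configuration
— 4 chains, 2,000 warm-up (adaptation + burn-in) and 2,000 retained
iterations each — is sized for the synthetic analyses in the test suite,
where a full five-species, 34-year fit takes well under a minute on one
CPU. `mcmc_config(mode = "production_full")` provides the single-chain
50,000-iteration / 15,000 burn-in configuration appropriate for a full
analysis of real survey archives. Historical descriptions of
reduced-model runs of this kind quote a burn-in of 50,000 with a chain
length of 15,000 — an inversion of the usual ordering that may or may not
be intended; both readings are available as presets
(`production_reduced`, `production_reduced_swapped`) and neither is
asserted as the correct one.

Every fit takes an explicit integer seed that drives all chains' RNG
streams; identical seed, data and configuration reproduce draws exactly
(this is what makes the null-perturbation sensitivity check exact).

Convergence is monitored by split-$\widehat R$ (each chain halved;
threshold 1.05) and effective sample size on the scalar parameters. A
failing diagnostic produces a *flagged* fit and a warning, never a silent
success. Users should expect the flag on selectivity parameters: SL50 and
RL50 trade off along a likelihood ridge (a shift in capture selectivity
can be compensated by retention and the catch-ratio level), so their
chains mix slowly and their marginal posteriors are wide. The quantities
the model exists for — $C_t$, $D_t$, $p_t$ and their intervals — are
functions of well-identified combinations and are stable across chains;
the parameter-recovery tests assert interval coverage for $D_t$ directly.

### A note on the noise-free limit

Two structural features bound how sharply the model can reproduce
noise-free data. First, a Gamma(0.1, 0.1) precision prior caps the
attainable posterior precision near $(0.1 + T/2)/0.1$, i.e. residual
standard deviations cannot fall much below 0.08 at $T = 34$ regardless of
the data. Second, the annual $q_t$ random effects give the model one free
state per discard observation, so the likelihood is saturated and the
posterior balances fit against the $q_t$ prior rather than interpolating.
The consistency-limit test therefore uses a diffuse precision prior and
pins the selectivity ogives, and asserts recovery of the discard series to
about a percent on average; users should not expect the default priors to
chase arbitrarily small observation error, nor need them to.

## Survey processing conventions

* **Length classes are labelled by their midpoints**: the class labelled
  20 cm spans 19.5–20.5 cm, and the allometric conversion
  $w = a\,l^b$ (grams) is evaluated at the label. Data recorded on the
  cm-below convention should have 0.5 added on ingestion.
* **Swept area** is tow distance × wing spread. Where geometry is
  unrecorded it is imputed from a log-linear regression of area on tow
  duration and seabed depth fitted to the hauls with complete geometry —
  a reproducible stand-in for external gear-relationship tables, not a
  reproduction of any published coefficients. Hauls with neither geometry
  nor covariates are excluded with a warning.
* **Zero survey indices are missing values**, not zeros: a year in which
  the survey caught nothing while the fishery landed something reflects
  failure to observe. Downstream, such years use the unweighted mean
  length composition over observed years, and the reduced model holds
  $q_t$ at its prior mean there (no index information reaches $q_t$ in
  those years).
* **Taxon aggregation** sums counts within user-supplied groups; taxa
  outside the mapping route to a catch-all "discard-only" group.
* **Era-varying minimum landing sizes**: the model assumes
  time-independent retention, so one MLS per species must be chosen.
  `read_mls_table()` picks the value in force for the longest stretch of
  the analysis window, overridable per species.

## The synthetic-data generator

`reference_scenario()` generates the study design the estimation machinery
is validated on: five reference species with observed discards plus three
landings-only species, 34 years, latent $\log Q$ and $\log u$ random walks
(process sd 0.15), $q_t \sim$ Beta(0.5, 3), capture midpoints scattered
around a common mean (15.25 cm, hierarchical sd 2 cm), retention midpoints
at $0.874 \times$ MLS, observation sds 0.2 (index), 0.1 (landings), 0.15
(discards), and length compositions that are discretised normal densities
with species mean length just above the MLS. Initial catch ratios are
spread across species so that their random-walk paths are distinguishable
— the property the cross-validation weight matrix probes. Haul-level
tables (`simulate_haul_table()`) draw Poisson counts against simulated tow
geometry, exercising the swept-area and density-estimation steps.

The generator reproduces the model's statistical structure *exactly*; that
is its purpose and its limitation. Passing recovery tests show the
estimation machinery is correct and well calibrated under the model's own
assumptions. They cannot show that real fisheries obey those assumptions —
in particular time-invariant selectivity, a single region-wide logistic
retention curve, lognormal index noise, and survey catchability absorbed
into a smoothly evolving $Q_t$ are idealisations, and quarter-1 survey
compositions are a biased snapshot of the sizes available to a year-round
fishery (a bias absorbed into the fitted capture selectivity, which is why
fitted RL50 tends to sit below the MLS).

## Validation and reporting machinery

* **Cross-validation** (`cross_validate`) refits each reference species
  with its discards withheld (leave-discards-out, not leave-species-out:
  the species' own $Q$ series stays among the candidates) and reports the
  Dirichlet weight matrix and coverage of the withheld observations.
* **Knife-edge $q$** (`q_from_age`) estimates the bulk-discard fraction
  from catch-at-age tables as the discarded share of weight in age
  classes whose mean body weight exceeds that of a fish at MLS + 1 cm.
* **Observed-rate comparison** (`compare_p`) averages sporadic observed
  discard proportions on the logit scale (their natural scale given the
  unit interval) but model proportions on the natural scale, over a
  2001–2010 window.
* **Sensitivity** (`sensitivity`) perturbs SL50, RL50 or the $q$-prior
  mean by ±10% (Beta shapes rescaled at constant concentration), or swaps
  the geometric for an arithmetic $Q$ mean, refitting with the baseline
  seed so the delta isolates the perturbation.
* **Assemblage aggregation** (`aggregate_assemblage`) is draw-wise
  throughout: totals, the overall discard rate $\sum D / \sum C$ and the
  size/quantity split are computed per retained draw and then summarised,
  so reported intervals are intervals of sums. Decades are calendar
  decades (1980s = 1980–1989). $r^2$ throughout is
  $1 - SS_{res}/SS_{tot}$ against the posterior median series and may be
  negative.

## Known limitations

* Capture and retention selectivity are time-invariant; regulatory changes
  in mesh size or MLS within an analysis window are not modelled.
* The selectivity ridge means SL50/RL50 posteriors should be read jointly,
  not marginally; single-parameter point estimates from a flagged fit are
  unreliable even when discard quantities are well determined.
* The reduced model inherits the reference fleet's selectivity; species
  caught mainly by gears unlike the reference fleet's (or sampled very
  inefficiently by the survey) will carry that bias — diffuse Dirichlet
  weights are the visible symptom.
* Posterior draws are held in memory as `coda::mcmc.list` objects;
  summaries are written as tidy CSV (`write_posterior_csv`). No NetCDF
  export is provided.
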