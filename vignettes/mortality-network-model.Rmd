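---
title: "Modelling regional all-cause mortality on a traveller-flux network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional all-cause mortality on a traveller-flux network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortnet)
```

## The problem

Monthly all-cause death counts of neighbouring administrative regions are
strongly correlated in time even in the absence of any declared epidemic.
`mortnet` implements a parsimonious generative model of such a panel — one
count $n_{im}$ per region $i$ and month $m$ — built from two ingredients
only: the well-known biphasic (U-shaped) effect of temperature on
mortality, and an infective component that spreads along the network of
traveller fluxes between regions. The package fits the model by stochastic
maximum likelihood and asks whether it can reproduce both the observed
counts and the observed *between-region correlation network*, the
second-order structure that single-region covariate models never touch.

## The biphasic temperature model

Counts are Poisson with a temperature-dependent mean per region,

$$\lambda_i^{\mathrm{biphasic}}(T) = e^{-a_{c,i} T + b_{c,i}} + e^{a_{h,i} T + b_{h,i}},
\qquad a_{c,i}, a_{h,i} > 0,$$

a cold arm falling with temperature plus a hot arm rising with it. The
curve is convex with a unique minimum at

$$T_{\min,i} = \frac{b_{c,i} - b_{h,i} + \log(a_{c,i}/a_{h,i})}{a_{c,i} + a_{h,i}},$$

the expression obtained by setting the derivative to zero; `biphasic_tmin()`
is verified against direct numerical minimisation in the test suite rather
than taken on faith. `fit_biphasic()` maximises the Poisson log-likelihood
$\sum_m n_m \log\lambda(T_m) - \lambda(T_m)$ with the slope positivity
enforced by optimising $\log a_c$ and $\log a_h$ (smooth and unconstrained,
rather than box bounds). Because the likelihood is bimodal in the
assignment of the two arms, the optimiser is restarted from eight
deterministic starting points whose slopes come from log-linear looks at
the coldest and hottest temperature terciles; the best optimum wins. A fit
requires at least 12 months and a temperature span of 10 °C — below that
the two arms are not separable and the function refuses rather than
returning nonsense.

`temperature_residuals()` subtracts the fitted curve from the raw counts
(additive residuals, not Pearson-scaled): what remains is the part of the
fluctuation that shared seasonality cannot explain.

## Regional temperatures from station data

`monthly_temperature()` assigns each regional capital its `k = 3` closest
weather stations (haversine distance, Earth radius 6371 km; ties broken by
station id for determinism) and averages their monthly mean daily
temperatures with weights proportional to inverse distance. A station day
uses TAVG when present, otherwise the TMAX/TMIN midpoint. No cutoff radius
is applied: exactly the three nearest stations enter, however far.

## The gravity models of traveller flux

With $c_{ij}$ the daily commuters from region $j$ to region $i$, $d_{ij}$
the distance between the capitals, $\mathrm{pop}_j$ and $\mathrm{GDP}_i$
the origin population and destination GDP, the package fits three forms:

* distance only: $c(d) = \kappa e^{-d/d_0} + b_0$;
* GDP only: total inflow $c_{i:} = \kappa\,\mathrm{GDP}_i$;
* combined: $c_{ij} = \kappa\, \mathrm{pop}_j \,\mathrm{GDP}_i\, e^{-d_{ij}/d_0}$.

All three minimise the squared *log* residual over the strictly positive
entries — a log-normal scatter model, under which empty origin-destination
cells carry no information and are excluded. For the GDP-only and combined
forms the objective is exactly linear in $(\log\kappa,\ 1/d_0)$, so the
package solves them in closed form (a geometric-mean ratio and an ordinary
least-squares regression respectively) instead of running an iterative
optimiser; the solutions are exact minimisers of the same objective, which
is why noiseless inputs are recovered to floating-point accuracy. The
distance-only form is genuinely nonlinear because of the offset $b_0 \ge 0$
and uses L-BFGS-B in log-parameter space, started from the OLS solution
that ignores $b_0$. $\kappa$ absorbs the population and GDP units and is
therefore dataset-scale-dependent; no normalisation is imposed.

The *episodic* flux — irregular longer-range travel invisible to commuter
statistics — takes the same gravity form with its own scale $\kappa_e$ and
a longer decay $d_{0e}$, and the total flux is
$f_{ij} = c_{ij} + e_{ij}$.

## The monthly-restarting network SIR

Each month a new infection appears: one patient zero in region $i_0$,
drawn with probability proportional to regional GDP (a proxy for external
traveller inflow). The population mixes during the day according to

$$\phi_{ij} = \begin{cases} f_{ij}/\mathrm{pop}_j & i \ne j\\
1 - \sum_k f_{kj}/\mathrm{pop}_j & i = j,\end{cases}$$

a column-stochastic matrix: column $j$ spreads region $j$'s residents over
their daytime locations. New infections arise in the daytime pools,

$$dI_l = \frac{\beta_l}{\mathrm{pop}_l}\Big(\sum_j \phi_{lj}S_j\Big)\Big(\sum_j \phi_{lj}I_j\Big),$$

and the evening reverse flux sends them home in proportion to the fraction
each origin contributed to the pool:

$$\hat\phi_{ij} = \phi_{ji} \Big/ \sum_k \phi_{jk}, \qquad
dI_i = \sum_l \hat\phi_{il}\, dI_l.$$

The printed form of the redistribution matrix is typographically ambiguous
in its usual presentation; the reading implemented here is the unique
nearby one that makes $\hat\phi$ column-stochastic, and therefore makes
the dynamics conserve the national population exactly — a requirement for
a closed country, and an invariant the test suite asserts to $10^{-9}$
over full trajectories. Recovery removes $\gamma I_i$ per day; transmission
is temperature-modulated per pool region,
$\beta_{im} = e^{-a_\beta T_{im} + b_\beta}$ (colder months are more
contagious), indexed by the pooling region as the incidence formula
dictates, and capped at $(1-10^{-9})/dt$: at $\beta = 1/dt$ a whole
population would be infected in a single Euler step and beyond it the
discretisation turns unphysical, so the strict inequality is realised as a
concrete ceiling just below it.

Integration is forward Euler with $dt = 1$ day for a fixed 30-day month
(calendar months of other lengths are an assembly concern, not a dynamics
one). Should a step overshoot a compartment below zero — possible only
with $\beta$ essentially at the cap — the state is clamped at zero and the
event is counted and reported in a warning, never silently. Susceptibility
resets every month: there is no carried immunity, each month's epidemic
starts afresh.

The expected deaths combine three terms,

$$\lambda_{im}^{i_0} = \mathrm{pop}_i\, e^{a_h T_{im} + b_h} + \rho_{0i}
+ \mu\, R_{im}^{i_0}(t = 30):$$

a warm-season arm shared by all regions (the parsimonious counterpart of
the per-region hot arm above), a region-specific baseline $\rho_{0i}$, and
a fraction $\mu$ of the month's recovered individuals. $\rho_{0i}$ enters
as an absolute monthly count, exactly as the expectation is written; a
per-capita convention would simply be absorbed by the fit.

## Stochastic maximum-likelihood training

The full model has $8 + n$ free parameters for $n$ regions
($a_h, b_h, \rho_{01..n}, \kappa_e, d_{0e}, \mu, a_\beta, b_\beta,
\gamma$). Training maximises the batch Poisson log-likelihood

$$\mathrm{LL}_{\mathrm{batch}} = \frac{1}{n\cdot n_{\mathrm{batch}}}
\sum_{i,m} n_{im}\log\lambda_{im}^{i_{0m}} - \lambda_{im}^{i_{0m}},$$

with `nbatch` months resampled with replacement from the training set at
every step and one GDP-distributed patient zero drawn per sampled month —
a Monte-Carlo approximation of the expectation over $i_0$. Two priors
constrain the flux: a soft flat prior that is zero while every region's
daily outflow fraction $\sum_k f_{ki}/\mathrm{pop}_i$ stays in $[0, 0.2]$
and quadratic outside it (stiffness $10^6$, large enough that a violation
of 0.05 costs 2500 nats and is effectively forbidden), and a quadratic
log-prior $-9.74\times10^{-7} d_{0e}^2$ on the episodic decay length.

The optimiser is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.99$) with the decaying
rate $\mathrm{lr}(s) = 10^{-3}(1 + s/10^4)^{-0.75}$. For the first
$10^4$ steps (`phase_switch_step`) the batch holds 10 months; afterwards it
grows to 100 and the objective gains a correlation regularizer

$$\mathrm{LL}_{\mathrm{corr}} = -\frac{\upsilon_{\mathrm{corr}}}{n(n-1)/2}
\sum_{i > j}\big(\mathrm{corr}_{ij} - \mathrm{corr}^0_{ij}\big)^2,
\qquad \upsilon_{\mathrm{corr}} = 8.76\times10^2,$$

comparing the Pearson correlations of the model's $\lambda$ series on the
specific batch against those of the observed counts on the same batch
months. Observed *counts* (not rates) enter $\mathrm{corr}^0$; Pearson
correlation is invariant to per-region scaling so the distinction is
immaterial, and a rates switch would change nothing. Zero-variance batch
series skip their pairs with a warning. The fixed pair normaliser
$n(n-1)/2$ equals 190 at $n = 20$.

Positivity is enforced by optimising logs ($\mu$ additionally through a
logistic squash to $[0,1]$), so Adam runs unconstrained. Initialisation is
deterministic and data-driven: $\rho_{0i}$ from 0.8 times the region mean
deaths, $(a_h, b_h)$ from a log-linear pre-fit on the hottest tercile of
cells, $d_{0e}$ at twice the commuter-fit $d_0$, $\kappa_e$ scaled so the
initial episodic outflow is 1% of each population, and small fixed defaults
for the epidemic scalars.

Gradients deserve a note. The objective passes through a 30-day epidemic
simulation, which rules out simple analytic gradients; the package
implements the batched objective in C++ and differentiates it by central
finite differences. Only five parameters
($\kappa_e, d_{0e}, a_\beta, b_\beta, \gamma$) actually influence the SIR
pass, so the epidemic is re-run for those alone (11 passes per step) while
the remaining $3 + n$ parameters reuse the cached recovered-compartment
matrix — an exact decomposition, not an approximation. The
finite-difference step is $10^{-5}\max(1, |\theta_k|)$ on the
log/logit scale; the test suite checks these gradients against dense
numerical differentiation of the scalar objective. All random draws
(batches, patient zeros, the train/test split) happen on the R side under
a single integer seed, making entire training runs bit-reproducible.

Training monitors the mean test log-likelihood on the held-out months,
evaluated with 5 Monte-Carlo patient-zero draws per test month — the exact
sum over $i_0$ would cost $n$ epidemics per month and sampling is already
the estimator used for the training objective itself. The evaluation
cadence and Monte-Carlo budget are configuration knobs with those defaults.

The train/test protocol reserves 12 of the 108 months as test data, one
exemplar of each calendar month; since the panel spans only 9 years,
exactly 3 randomly chosen years contribute two test months spaced 6
calendar months apart. `make_split()` implements this as: draw 3 of the 6
possible month pairs $(m, m+6)$, host them in 3 distinct random years, and
scatter the remaining 6 calendar months over the remaining 6 years. Month
lists that do not form 9 full years get a plain uniform holdout behind the
explicit `method = "uniform"` flag.

## The correlation network

`correlation_matrix()` computes Pearson correlations between regional
monthly series (rank correlation exists nowhere in the pipeline: the
quantities compared are means and linear fits, for which Pearson is the
coherent choice). `offdiag_summary()` reports the mean and population
standard deviation of the $n(n-1)/2$ distinct pairs plus each region's
*correlation degree*, its mean correlation with all others.
`model_data_agreement()` is the Pearson correlation between the two
vectorised upper triangles — the single number summarising how well a
fitted model reproduces the network — and `deaths_agreement()` its
analogue over all region-month cells.

As a minimal surveillance embodiment, `degree_anomaly()` compares each
region's current correlation degree against a baseline ensemble —
`rolling_correlations()` builds one from 36-month windows with stride 1 —
and returns z-scores; a region whose degree collapses (or jumps) relative
to its own history is flagged as an emerging systemic anomaly. Regions with
zero ensemble spread return `NA` with a warning rather than infinities.

## The synthetic study generator

Since the real inputs (registry death counts, commuter matrices, station
archives) cannot ship with a package, `synthetic_truth()` generates a
complete study with known ground truth, against which every stage has a
parameter-recovery surface:

* **regions**: log-uniform populations in $[10^5, 10^7]$ (two decades, so
  size heterogeneity is material), GDP proportional to population times a
  log-normal productivity factor (sd 0.3, per-capita scale 0.025),
  coordinates spread over roughly 1000 km of latitude;
* **temperatures**: per-region sinusoids peaking in July with amplitudes
  uniform in 8–12 °C, a latitude-linear baseline falling from 18 °C to
  10 °C across the extent, and 1 °C monthly noise;
* **commuters**: the combined gravity law with $\kappa = 4\times10^{-7}$,
  $d_0 = 150$ km, log-normal scatter (sd 0.3), and 10% of the
  longest-distance pairs zeroed exactly — the empty cells real
  origin-destination tables show;
* **mortality**: the full forward model above, Poisson-sampled, with the
  drawn patient-zero sequence and true Poisson means recorded for test
  introspection.

The default truth parameters ($a_h = 0.12$, $b_h = -11.3$,
$\rho_{0i} = 5\times10^{-4}\mathrm{pop}_i$, $\mu = 0.002$,
$a_\beta = 0.08$, $b_\beta = 0.35$, $\gamma = 0.3$,
$\kappa_e = 2\times10^{-7}$, $d_{0e} = 400$ km) were chosen once so that
the two mortality arms have comparable magnitude: baseline mortality of
$5\times10^{-4}$ per person per month, a summer warm-arm excess of about
half the baseline, and winter epidemics that reach attack fractions of
tens of percent — strong influenza seasons — killing 0.2% of those
infected. Winter transmission sits near the Euler cap, which exercises the
cap and clamp paths on purpose. One global seed streams to per-component
seeds by fixed offsets, so regions, temperatures, fluxes and counts are
independently reproducible.

What the generator does *not* emulate: real geography (regions are
scattered uniformly, not shaped like a country), age structure, harvesting
dynamics, lagged temperature effects, reporting artefacts, or
long-memory trends in mortality. Passing recovery tests therefore
demonstrate that the inference machinery is correct and well-calibrated on
data generated by its own model class — not that the model is true of any
country's registry data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run desk-scale versions of the
study: 6 regions × 108 months for the end-to-end fit with
$2\times10^4$ Adam steps (phase switch at $2\times10^3$), 10–20 regions
for the gravity and biphasic recovery harnesses, and 100 and 50 random
networks for the stochasticity and conservation properties. These sizes
were chosen so the whole pipeline — including two full training runs, with
and without the correlation regularizer — completes in a few minutes while
still recovering the generating $\lambda$ surface with correlation above
0.95. The default `fit_config()` keeps the full-scale settings
($10^6$ steps, phase switch at $10^4$) for real studies.

Other numerical choices collected in one place: haversine distances with
$R = 6371$ km; station ties broken lexically; Euler $dt = 1$ day, 30-day
dynamic months; $\beta$ cap $(1-10^{-9})/dt$; negative-state clamping with
a warning counter; $b_0 \ge 0$ in the distance-only fit (negative
asymptotic flux is unphysical and destabilises the log residual);
zero-inflow regions are an error in the GDP-only fit (its sum runs over
all regions, unlike the pairwise fits where zeros are excluded);
finite-difference step $10^{-5}$ relative; Adam $\epsilon = 10^{-8}$.

## Known limitations

* The Poisson likelihood has no overdispersion term; real registry counts
  are often overdispersed.
* The epidemic parameters are only partially identified: the data
  constrain the fitted $\lambda$ surface much more tightly than
  $(\mu, \gamma, b_\beta)$ individually, which trade off against each
  other. The package reports the surface agreement, not parameter
  confidence intervals (none are implemented, matching the method's
  scope).
* Euler with $dt = 1$ day is the method's own discretisation, kept for
  fidelity rather than accuracy; a stiff winter epidemic is resolved only
  approximately.
* The degree-anomaly baseline (rolling 36-month windows) is a minimal,
  package-defined embodiment of the surveillance idea, not a validated
  epidemiological alarm.
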