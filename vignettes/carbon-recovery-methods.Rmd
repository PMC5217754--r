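---
title: "Modelling post-logging carbon recovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-logging carbon recovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`acsrecovery` estimates how the aboveground carbon stock (ACS) of a
selectively logged tropical forest recovers, by decomposing stand dynamics
into demographic cohorts and fitting saturating flux curves in a hierarchical
Bayesian framework. This vignette explains the model, the assumptions behind
each component, the choices we made where the design was genuinely open, and
what the synthetic-data tests do and do not demonstrate.

## From tree inventories to carbon fluxes

Permanent-plot inventories record the diameter (DBH, cm) of every stem above
20 cm at a series of censuses. Each tree's carbon is computed from a
pantropical diameter–wood-density allometry,

$$AGB_i = \exp\!\big({-1.803} - 0.976E + 0.976\ln WD_i + 2.673\ln DBH_i -
0.0299[\ln DBH_i]^2\big),$$

in kg of biomass, with carbon taken as 50% of biomass. $E$ is a dimensionless
climatic water-stress index, constant within a site. Wood density is assigned
by a fallback protocol: the species value when the tree is identified to
species, else the genus average, else the average density of identified trees
at the site, so every tree receives a density. The genus average is computed
from the supplied density table, not from plot data, mirroring how global
wood-density compilations are used in practice. A per-site override of $E$ is
supported in the site table for sites where measured precipitation contradicts
gridded climatology; no site-specific logic is hard-coded.

The squared-log diameter term is read as $[\ln DBH]^2$; that is the form of
the underlying allometry family, and the $-0.0299$ coefficient belongs to it.
The 20 cm threshold is applied inclusively (a tree at exactly 20.0 cm counts):
recruits are defined by reaching $\ge$ 20 cm, and using the same closed
boundary everywhere keeps the cohort partition exhaustive.

**The recovery period.** Logging is followed by several years of elevated
mortality, so plot ACS keeps falling after the harvest. The recovery analysis
starts at the census of minimum ACS within 4 years of logging
(`detect_recovery_start()`); plots whose post-logging minimum falls after
that window are excluded — a late minimum signals a disturbance other than
the logging event (fire, roads, silviculture) and would contaminate the
recovery signal.

**Five fluxes.** From the recovery start $t_0$, each census interval is
decomposed into: survivors' growth ($Sg$) and mortality loss ($Sl$) — trees
already $\ge$ 20 cm and alive at $t_0$ — and new recruits' carbon ($Rr$),
recruits' growth ($Rg$) and recruits' mortality loss ($Rl$) for trees that
cross the threshold later. Gains are positive and losses negative; cohort
membership is fixed at first threshold crossing and kept until death. Dead
trees are valued at their last live census. Within each interval, a tree that
would have both recruited and died leaves no census record at or above the
threshold and is ignored — fluxes are defined on census states. The five
interval fluxes balance the plot's stock change exactly, which the tests
assert on synthetic inventories.

We model *cumulative* fluxes (running sums per plot, in Mg C ha$^{-1}$, zero
at $t_0$) rather than interval rates: mortality makes interval changes noisy,
while the cumulative trajectory carries the long-term signal. Interval values
are retained in the `flux_series` for diagnostics. A net-negative growth sum
in an interval (a measurement artifact, e.g. trees re-measured smaller) is
floored at zero with a warning, since the model defines gains as
non-negative.

## The recovery model

Survivors' cumulative growth and loss follow a saturating exponential in time
since $t_0$:

$$cS_{j,k} \sim \mathcal{N}\!\big(\alpha_j^S (1 - e^{-\beta_j^S t_k}),\;
(\sigma_E^S)^2\big),$$

so the flux in one interval is proportional to the previous one. The growth
asymptote $\alpha_j^{Sg}$ is plot-level and hierarchical,
$\alpha_j^{Sg} \sim \mathcal{N}(\alpha_0^{Sg}, (\sigma_\alpha^{Sg})^2)$
(truncated at zero — the package enforces positive growth asymptotes, a
mechanism the model statement leaves open). The loss asymptote is **not a
free parameter**: once every survivor has died, the cohort has lost its
initial stock plus everything it gained, so
$\alpha_j^{Sl} = -(\alpha_j^{Sg} + acs_{min,j})$ exactly. Implementing this
carbon-closure constraint by construction (rather than as a penalty)
guarantees a zero residual in every draw and removes a degenerate dimension.

Recruits reach a dynamic equilibrium: annual recruitment, recruit growth and
recruit mortality converge to constants that cancel. Annual changes are
$\alpha(1 - e^{-\beta t})$ for growth and loss (zero at $t_0$: there are no
recruits yet) and $\alpha(1 + \eta e^{-\beta t})$, $\eta > 0$, for newly
recruited carbon, which starts high after the competition release of logging
and decays. Cumulative curves are their exact time integrals,
$\alpha\,(t + \eta(1 - e^{-\beta t})/\beta)$ with $\eta = -1$ for
growth/loss. Recruit asymptotes are site-level
($\alpha_i^R \sim \mathcal{N}(\alpha_0^R, (\sigma_\alpha^R)^2)$, truncated
positive for gains), and the loss asymptote is again derived:
$\alpha_i^{Rl} = -(\alpha_i^{Rr} + \alpha_i^{Rg})$.

**Covariate-dependent rates.** The convergence rates carry the ecology. Six
plot covariates — disturbance intensity (`loss`, % of pre-logging ACS lost),
site mean pre-logging ACS (`acs0`), the plot's % deviation from it (`dacs`, a
maturity proxy), annual precipitation (`prec`), precipitation seasonality
(`seas`) and topsoil bulk density (`bd`) — are centred and standardized
(sample sd, $n-1$) over the calibration plots, and enter linearly:

$$\beta_j = \beta_0 + \textstyle\sum_{l=1}^{6} \lambda_l V_{j,l}.$$

Survivor rates are deterministic in the covariates; recruit rates get an
additional plot-level normal deviation with sd $\sigma_\beta^R$, truncated to
the prior support. This asymmetry is deliberate and preserved exactly:
survivors' curves are identified per plot (plot-level asymptotes), while
recruit asymptotes are site-level, so the plot-to-plot variability of
recruits is carried by their rates. Standardization moments (and ranges) are
stored with the covariate set and reused verbatim at prediction time —
re-centring on prediction inputs would silently rescale the disturbance
scenario. Moments are computed over plots (one row per plot), not
plot-by-census observations; covariates are constant within a plot, so the
alternative would only reweight plots by census count, which the observation
weights already govern.

**Priors** (`acs_priors()`) are uniform on ecologically justified supports:
the survivors' growth asymptote on [25, 250] Mg C ha$^{-1}$ (roughly 100
survivors/ha storing 0.25–2.5 Mg C each), and every rate on an interval
expressed through the 95%-convergence time $t_{0.95} = \ln(20)/\beta$ (e.g.
growth: 75–200 yr; recruitment: 5–500 yr). The survivors' loss rate support
is [0.006, $\beta_j^{Sg}$] *per plot* — loss converges more slowly than
growth — implemented as an ordered-rate constraint. Coefficients are bounded
relative to the baseline: $|\lambda_{loss}| \le \beta_0$ and
$|\lambda_l| \le \beta_0/4$ for the rest. The prior on $\eta$ is U[0, 3].
(The stated rationale for that bound — initial recruitment below three times
its equilibrium value — would actually imply $\eta < 2$ under the curve
family, since $Rr(0) = \alpha(1+\eta)$; we implement the stated support and
note the tension rather than resolving it.) Hyperpriors for the standard
deviations the model statement leaves open ($\sigma_E$, $\sigma_\alpha$,
$\sigma_\beta$) are weakly informative half-normals whose scales are
arguments of `acs_priors()`.

## Inference

`fit_survivors()` and `fit_recruits()` fit the two cohorts as separate joint
models (they share no parameters; $acs_{min}$ ties $Sg$ to $Sl$, the
equilibrium ties the three recruit fluxes). Sampling uses JAGS via `rjags` —
an adaptive MCMC backend — with the diagnostics contract (split-$\widehat R$,
effective sample size, a flagged-fit warning above the threshold) enforced in
the package; divergence counts are a Hamiltonian-specific notion and are
reported as `NA`. Each observation's log-density is multiplied by its plot
weight, proportional to plot area and normalised to mean one; implemented as
observation precision $w/\sigma_E^2$, which with mean-one weights is exactly
the intended power likelihood, keeping $\sigma_E$ interpretable.

Numerical choices that matter:

* **Reparameterized dependent priors.** $\lambda \mid \beta_0$ is sampled as
  $\lambda = u\,\beta_0$ (or $u\,\beta_0/4$) with $u \sim U[-1,1]$, and
  $\beta_0^{Sl}$ as a fraction of $[0.006, \beta_0^{Sg}]$. These are exact
  reparameterizations of the same joint prior that remove a funnel-shaped
  geometry and markedly improve mixing.
* **Hard support constraints.** Plot-level survivor rates are constrained to
  their supports (growth above its lower bound, loss positive and below the
  plot's growth rate) by a zero-likelihood rejection inside the sampler;
  recruit rates use truncated normals. Predicted rates outside the support
  are truncated to it.
* **Optimization-based starting values.** A weighted least-squares pre-fit
  supplies inits: given rates, every asymptote is a closed-form linear solve;
  the global rate parameters are optimized by BFGS on unconstrained
  transforms, and recruit plot rates are refined per site with the asymptotes
  profiled out. With noise-free data the pre-fit lands on the posterior point
  mass, which is what makes the noiseless identifiability check feasible at
  modest chain lengths.
* Observations at $t = 0$ are identically zero by construction and are
  excluded from the likelihood (they carry no information and would deflate
  $\sigma_E$).
* Defaults of 2 chains, 1000 retained iterations after 1000 warmup (plus 500
  adaptation) are configuration, not claims; the convergence flag threshold
  defaults to $\widehat R > 1.05$.

Posterior summaries are exported as the 2.5/10/50/90/97.5% quantile layout
(`summary()`, `write_quantiles()`), and fits are bit-reproducible given the
backend version, seed, chain count and iterations.

## The synthetic-data generator

`generate_flux_dataset()` forward-simulates the full statistical model with
known truth, emulating the study conditions: 12 sites of 5 plots by default,
plot areas 0.25–2.5 ha, series lengths 8–30 years with annual censuses for
the first four years then three-yearly, disturbance intensities 1–71% of
pre-logging stocks of 150–400 Mg C ha$^{-1}$, precipitation 1000–3500 mm,
and true hyperparameters placed mid-prior (residual sds of 3–4 Mg C
ha$^{-1}$ for survivors and 0.6–1 for recruits, chosen as plausible
census-level noise for these series). Configurations whose truth falls
outside the prior supports are refused — recovery tests would be vacuous.
Observation noise is drawn iid around the cumulative mean curves with sd
$\sigma_E/\sqrt{w_j}$, making the generator the *exact complement* of the
fitting likelihood (checked in the tests against an independent
per-observation loop). One consequence is worth stating plainly: interval
fluxes derived by differencing noisy cumulative series can transiently
violate the sign convention; the convention is guaranteed for the latent
mean increments and for noise-free data, exactly as for the fitted model,
whereas inventory-derived fluxes respect it by accounting identity.

`generate_inventory()` builds tree-level censuses (stand assembled to a
target stock, calibrated logging kill, growth, mortality, sub-threshold
recruitment) together with its own cohort tally, an independent oracle for
the decomposition pipeline. `generate_covariate_grid()` produces uniform,
gradient or random covariate grids for the mapping tests.

What passing these tests shows — and does not. Parameter recovery on
generator output demonstrates that the inference machinery is consistent
with the model's own assumptions at realistic sizes. It cannot demonstrate
robustness to what real inventories add: measurement error in DBH,
correlated census noise, missed censuses, taxonomic misidentification, or
sub-threshold dynamics (trees of 10–20 cm are not modelled at all).

## Prediction maps

`predict_recovery_map()` treats every pixel of a covariate grid as a
hypothetical plot logged at a prescribed intensity (default 40% of the
pixel's pre-disturbance carbon; `dacs` fixed at zero, i.e. pixels at their
regional maturity). Per Monte-Carlo replicate (default 200): one retained
posterior draw supplies the hyperparameters; pixel asymptotes are drawn from
their hierarchical normals to simulate random effects; loss asymptotes
follow from the constraints with $acs_{min} = 0.6 \times$ pixel carbon;
survivor rates come from the covariate linear predictor and recruit rates
get their plot-level noise redrawn per pixel and replicate (a pixel *is* a
hypothetical plot); the five cumulative fluxes are evaluated at the horizon
(default 10 years). Only the three free asymptotes are drawn; the loss-side
ones are derived, keeping the constraints exact in every replicate. The
carbon grid is taken to be in Mg C ha$^{-1}$; a configurable ingest factor
(e.g. 0.5) converts biomass products.

Per-pixel summaries are the median (mapped value), mean, sd and
CV = sd/|mean| of net recovery (the sum of the five fluxes), with the CV
flagged undefined near zero mean; map-wide area fractions by CV band
(< 40%, > 50%) summarize uncertainty. Regional aggregation reports net
recovery both as mean ± sd over pixels and across replicates (both are
meaningful and they answer different questions, so both are labelled and
returned), plus the survivors' share of gains
$cSg/(cSg + cRr + cRg)$ and flux trajectories flagged beyond the 30-year
calibration period. Pixel covariates outside the calibration range warn
(extrapolation) but do not fail. Results are seeded, bit-reproducible, and
invariant to pixel ordering (pixels are canonically ordered internally
before random-effect draws).

Grids are plain data.frames (`row`, `col`, covariates) with CSV round
tripping; the package deliberately ships no geospatial raster layer — the
mapping logic is the contribution, and co-registration of real rasters is
left to dedicated GIS tooling upstream.

## Problem sizes used by the test-suite

The automated checks run at desk scale, chosen to finish in minutes while
keeping every scientific property assertable: prior-bound and quadrature
checks are analytic; constraint exactness is checked on generated data, on
two short MCMC fits (3 sites × 3 plots, 2 × 400 iterations) and on 25
mapping replicates; parameter recovery uses the default 12 sites × 5 plots
with 2 chains × 1000 iterations over 10 seeded replicates (90% interval
coverage of $\alpha_0^{Sg}$, $\beta_0^{Sg}$, $\lambda_{loss}$, expecting at
least 8/10 each); noiseless identifiability uses 4 sites × 3 plots; mapping
sanity uses a uniform 20 × 20 grid with degenerate draws.
`scripts/acceptance.R` re-runs the same computations from scratch at these
sizes with 200 mapping replicates on a 20 × 20 gradient grid.

## Known limitations

* The exponential-kernel curve family is assumed, not selected; no
  alternative kernels (logistic, Gompertz), no time-varying covariates, no
  spatial random fields, and no model comparison.
* Allometric uncertainty is not propagated; carbon is a deterministic
  function of DBH, wood density and $E$.
* Survivor asymptote--rate pairs are weakly identified on short series
  (< 10 years); the priors then dominate, which is by design but should be
  kept in mind when reading plot-level posteriors.
* Recruit plot-level rates are weakly identified once their curves have
  saturated; their posteriors can mix slowly, and the fit flag reports it.
* Predictions beyond the 30-year calibration window and outside the
  calibration covariate ranges are extrapolation and are flagged as such.
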