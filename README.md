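# acsrecovery

Hierarchical Bayesian modelling of aboveground carbon stock (ACS) recovery in
tropical forests after selective logging.

Selective logging removes a few merchantable stems per hectare but, with
collateral damage and delayed mortality, can cost a stand tens of Mg C
ha⁻¹. The forest then recovers through two cohorts: **survivors** (trees
≥ 20 cm DBH alive when the stock bottoms out) and **recruits** (trees
crossing 20 cm afterwards). `acsrecovery` is for forest ecologists and
carbon scientists who want to quantify that recovery from permanent-plot
inventories: it turns tree-by-tree census tables into cohort carbon fluxes,
fits saturating recovery curves with covariate-dependent rates, and
propagates the posterior to gridded Monte-Carlo predictions of net recovery
under a prescribed disturbance intensity.

## The model in brief

Per-tree carbon comes from a pantropical allometry,
`AGB = exp(−1.803 − 0.976 E + 0.976 ln WD + 2.673 ln DBH − 0.0299 [ln DBH]²)`
(kg; carbon = 50% of biomass), with a species → genus → site fallback for
wood density. Each plot's dynamics from the post-logging ACS minimum
(`acs_min`, reached within 4 years of logging, else the plot is excluded)
are decomposed into five fluxes — survivors' growth `Sg` and loss `Sl`,
new-recruit carbon `Rr`, recruits' growth `Rg` and loss `Rl` — whose
cumulative series are modelled as

    cS_jk  ~ N( α_j (1 − exp(−β_j t_k)),  σ_E² )            survivors
    cR_ijk ~ N( α_i (t_k + η (1 − exp(−β_j t_k))/β_j), σ_E² )  recruits

with hierarchical asymptotes (plot-level for survivors, site-level for
recruits), rates linear in six standardized covariates (disturbance
intensity, site mean ACS, relative maturity, precipitation, seasonality,
bulk density), and two exact constraints: carbon closure
`α_Sl = −(α_Sg + acs_min)` and dynamic equilibrium
`α_Rl = −(α_Rr + α_Rg)`. Fitting is weighted MCMC (JAGS) under uniform,
ecologically justified priors; prediction draws posterior parameters and
per-pixel random effects to map net 10-year recovery under, e.g., a 40%
carbon loss.

## A worked example

Everything below runs on synthetic data with known truth — no downloads.

```r
library(acsrecovery)

cfg <- generator_config()                      # 12 sites x 5 plots, mid-prior truth
d   <- generate_flux_dataset(cfg, seed = 7)    # fluxes + covariates + truth

fit_s <- fit_survivors(d$flux, d$covariates, seed = 11)
fit_r <- fit_recruits(d$flux, d$covariates, seed = 11)
print(fit_s)
summary(fit_s, hyper_only = TRUE)[c("alpha0_Sg", "beta0_Sg", "lambda_Sg[1]"), ]

grid <- generate_covariate_grid(10, 10, cfg, type = "gradient")
pred <- predict_recovery_map(fit_s, fit_r, grid,
                             covariate_moments(d$covariates),
                             loss = 40, horizon = 10, n_rep = 200, seed = 2)
print(pred)
rs <- regional_summary(pred, list(all = rep(TRUE, 100)))
rs$summary[, c("net_mean_pixels", "net_sd_pixels", "survivors_share")]
```

which prints (elided):

```
Hierarchical Bayesian ACS flux model: survivors (Sg, Sl)
  60 plots, 12 sites, 580 observations
  2 chains x 1000 iterations (warmup 1000), seed 11
  max split-Rhat 1.498, min ESS 11

                     2.5%          10%          50%          90%        97.5%
alpha0_Sg    1.319977e+02 1.349688e+02 1.417221e+02 1.484133e+02 1.523830e+02
beta0_Sg     2.460522e-02 2.542556e-02 2.682575e-02 2.819523e-02 2.879340e-02
lambda_Sg[1] 1.816297e-03 2.137431e-03 2.911155e-03 3.629114e-03 3.918564e-03

Monte-Carlo ACS recovery prediction
  100 pixels, 200 replicates, 40% loss, 10-year horizon
  net recovery (per-pixel medians): mean 8.3, sd 8.21 Mg C/ha

  net_mean_pixels net_sd_pixels survivors_share
1        8.293444      8.211217       0.7143457
```

The survivors' growth asymptote (`alpha0_Sg`, posterior median ~142 Mg C
ha⁻¹ against a generating value of 137.5), baseline convergence rate
(`beta0_Sg`, ~0.027 yr⁻¹, i.e. 95% convergence in ~110 years; truth 0.0275)
and disturbance-intensity effect (`lambda_Sg[1]`, truth 0.003) are recovered
within their credible intervals. The fit warns that its worst split-Rhat
exceeds the 1.05 flag: a handful of weakly identified plot-level rates mix
slowly at the default chain lengths (see the vignette); the hyperparameters
above have materially lower Rhat. The gradient map also warns that some
pixels sit outside the calibration covariate range (deliberate here — the
grid spans wider physical ranges than the 12 calibration sites). The mapped
prediction says an average pixel on this synthetic gradient regains ~8 Mg C
ha⁻¹ in the decade after losing 40% of its carbon, with ~71% of the gains
contributed by surviving trees — the survivors, not the recruits, carry the
recovery.

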