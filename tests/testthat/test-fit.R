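test_that("every retained draw respects the prior supports", {
  sf <- shared_fits()
  dr <- posterior_draws(sf$survivors)
  pr <- acs_priors()
  expect_true(all(dr[, "alpha0_Sg"] >= pr$alpha_Sg[1] &
                    dr[, "alpha0_Sg"] <= pr$alpha_Sg[2]))
  expect_true(all(dr[, "beta0_Sg"] >= pr$beta_Sg[1] &
                    dr[, "beta0_Sg"] <= pr$beta_Sg[2]))
  expect_true(all(dr[, "beta0_Sl"] >= pr$beta_Sl[1] &
                    dr[, "beta0_Sl"] <= dr[, "beta0_Sg"]))
  # dependent coefficient priors: |lambda_loss| <= beta0, others <= beta0/4
  expect_true(all(abs(dr[, "lambda_Sg[1]"]) <= dr[, "beta0_Sg"]))
  for (l in 2:6)
    expect_true(all(abs(dr[, sprintf("lambda_Sg[%d]", l)]) <=
                      dr[, "beta0_Sg"] / 4))
  # plot-level rates: growth above its lower bound, loss ordered below growth
  J <- length(sf$survivors$plots)
  for (j in seq_len(J)) {
    bg <- dr[, sprintf("beta_Sg[%d]", j)]
    bl <- dr[, sprintf("beta_Sl[%d]", j)]
    expect_true(all(bg >= pr$beta_Sg[1]))
    expect_true(all(bl >= pr$beta_Sl[1] & bl <= bg))
  }
  drr <- posterior_draws(sf$recruits)
  expect_true(all(drr[, "eta"] >= 0 & drr[, "eta"] <= 3))
  expect_true(all(drr[, "alpha0_Rr"] >= pr$alpha_Rr[1] &
                    drr[, "alpha0_Rr"] <= pr$alpha_Rr[2]))
  for (j in seq_len(length(sf$recruits$plots))) {
    expect_true(all(drr[, sprintf("beta_Rr[%d]", j)] >= pr$beta_Rr[1] &
                      drr[, sprintf("beta_Rr[%d]", j)] <= pr$beta_Rr[2]))
    expect_true(all(drr[, sprintf("beta_Rl[%d]", j)] >= pr$beta_Rl[1] &
                      drr[, sprintf("beta_Rl[%d]", j)] <= pr$beta_Rl[2]))
  }
})

test_that("hard constraints hold in every posterior draw", {
  sf <- shared_fits()
  dr <- posterior_draws(sf$survivors)
  acs_min <- sf$survivors$meta$acs_min
  for (j in seq_along(sf$survivors$plots)) {
    resid <- dr[, sprintf("alpha_Sl[%d]", j)] +
      dr[, sprintf("alpha_Sg[%d]", j)] + acs_min[j]
    expect_lt(max(abs(resid)), 1e-8)
  }
  drr <- posterior_draws(sf$recruits)
  for (i in seq_along(sf$recruits$sites)) {
    resid <- drr[, sprintf("alpha_Rr[%d]", i)] +
      drr[, sprintf("alpha_Rg[%d]", i)] + drr[, sprintf("alpha_Rl[%d]", i)]
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("fits are reproducible given seed, chains and iterations", {
  sf <- shared_fits()
  again <- suppressWarnings(
    fit_survivors(sf$data$flux, sf$data$covariates, chains = 2,
                  iterations = 400, warmup = 400, seed = 7))
  expect_equal(posterior_draws(again), posterior_draws(sf$survivors))
})

test_that("zero-covariate plots recover the baseline recruit rate", {
  sf <- shared_fits()
  drr <- posterior_draws(sf$recruits)
  # E[beta_j | V = 0] = beta0 under the rate model: the posterior mean of the
  # plot rates should straddle the baseline, not drift systematically
  bs <- colMeans(drr[, sprintf("beta_Rg[%d]", seq_along(sf$recruits$plots))])
  b0 <- mean(drr[, "beta0_Rg"])
  expect_lt(abs(mean(bs) - b0), 0.02)
})

test_that("split-Rhat and effective sample size behave on reference chains", {
  sf <- shared_fits()
  fake <- sf$survivors
  # constant chains: Rhat exactly 1 by convention
  const <- coda::mcmc(matrix(1, 500, 2, dimnames = list(NULL, c("a", "b"))))
  fake$samples <- coda::mcmc.list(const, const)
  d <- diagnostics(fake, quiet = TRUE)
  expect_true(all(d$rhat == 1))
  # identical stationary chains: Rhat at 1 up to half-chain noise
  set.seed(1)
  m <- coda::mcmc(matrix(rnorm(2000), 1000, 2,
                         dimnames = list(NULL, c("a", "b"))))
  fake$samples <- coda::mcmc.list(m, m)
  d1 <- diagnostics(fake, quiet = TRUE)
  expect_true(all(d1$rhat < 1.02))
  # chains exploring different regions are flagged
  fake$samples <- coda::mcmc.list(m, m + 5)
  d_bad <- diagnostics(fake, quiet = TRUE)
  expect_true(all(d_bad$rhat > 1.5))
  expect_true(all(d_bad$flagged))
  # independent-draws fixture: ESS close to the number of draws
  iid <- matrix(rnorm(4000), 2000, 2,
                dimnames = list(NULL, c("a", "b")))
  fake$samples <- coda::mcmc.list(coda::mcmc(iid[1:1000, ]),
                                  coda::mcmc(iid[1001:2000, ]))
  d2 <- diagnostics(fake, quiet = TRUE)
  expect_true(all(d2$ess > 1000))
  expect_true(all(d2$rhat < 1.05))
  # a single chain warns
  fake$samples <- coda::mcmc.list(coda::mcmc(iid[1:1000, ]))
  expect_warning(diagnostics(fake), "single chain")
})

test_that("the fit object supports the standard modelling methods", {
  sf <- shared_fits()
  fs <- sf$survivors
  expect_output(print(fs), "survivors")
  q <- summary(fs, hyper_only = TRUE)
  expect_identical(colnames(q), c("2.5%", "10%", "50%", "90%", "97.5%"))
  expect_true(all(diff(t(unclass(q))) >= 0))  # quantiles are ordered
  expect_true("alpha0_Sg" %in% rownames(q))
  co <- coef(fs)
  expect_equal(unname(co["alpha0_Sg"]),
               unname(q["alpha0_Sg", "50%"]))
  # fitted + residuals reconstruct the observations
  fit_mu <- fitted(fs)
  res <- residuals(fs)
  expect_equal(fit_mu$cSg + res$cSg, fs$obs$cSg)
  # simulate returns replicate datasets of the right shape
  sims <- simulate(fs, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(fs$obs))
  # quantile export round trip
  path <- file.path(tempdir(), "quantiles.csv")
  write_quantiles(fs, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(names(back),
                   c("parameter", "2.5%", "10%", "50%", "90%", "97.5%"))
  unlink(path)
  # prediction for an average plot starts at zero and is monotone in t
  newdata <- data.frame(loss = 40, acs0 = 250, dacs = 0, prec = 2000,
                        seas = 60, bd = 1.2, acs_min = 150)
  mom <- covariate_moments(sf$data$covariates)
  pr <- predict(fs, newdata, mom, t = 0:15)
  sg <- pr[pr$flux == "cSg", ]
  expect_equal(sg$median[sg$t == 0], 0)
  expect_true(all(diff(sg$median) > 0))
  sl <- pr[pr$flux == "cSl", ]
  expect_true(all(diff(sl$median) < 0))
  # recruits fit: plot method runs
  pdf(NULL)
  expect_invisible(plot(sf$recruits, pch = "."))
  dev.off()
})
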