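test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(n_sites = 3, plots_per_site = 2)
  a <- generate_flux_dataset(cfg, seed = 123)
  b <- generate_flux_dataset(cfg, seed = 123)
  expect_identical(a$flux, b$flux)
  expect_identical(a$truth, b$truth)
  c <- generate_flux_dataset(cfg, seed = 124)
  expect_false(identical(as.data.frame(a$flux), as.data.frame(c$flux)))
})

test_that("configurations outside the prior supports are refused", {
  expect_error(generator_config(truth = list(alpha0_Sg = 500)),
               "outside prior support")
  expect_error(generator_config(truth = list(beta0_Rg = 0.5)),
               "outside prior support")
  expect_error(generator_config(truth = list(eta = 5)), "outside")
  # lambda_loss above its own baseline rate
  expect_error(generator_config(truth = list(
    lambda_Sg = c(0.05, 0, 0, 0, 0, 0))), "outside")
})

test_that("noise-free observations lie exactly on the mean curves and keep signs", {
  cfg <- generator_config(n_sites = 3, plots_per_site = 3)
  d <- generate_flux_dataset(cfg, seed = 4, sigma_scale = 0)
  tr <- d$truth
  obs <- as.data.frame(d$flux)
  j <- match(obs$plot_id, tr$plots$plot_id)
  sj <- match(obs$site_id, tr$sites$site_id)
  expect_equal(obs$cSg,
               survivor_cumulative_mean(tr$plots$alpha_Sg[j],
                                        tr$plots$beta_Sg[j], obs$t))
  expect_equal(obs$cSl,
               survivor_cumulative_mean(tr$plots$alpha_Sl[j],
                                        tr$plots$beta_Sl[j], obs$t))
  expect_equal(obs$cRr,
               recruit_cumulative_mean(tr$sites$alpha_Rr[sj],
                                       tr$plots$beta_Rr[j],
                                       tr$hyper$eta, obs$t))
  # sign conventions hold on every interval of the noise-free series
  expect_true(all(obs$Sg >= 0 & obs$Rr >= 0 & obs$Rg >= 0))
  expect_true(all(obs$Sl <= 0 & obs$Rl <= 0))
  # everything is zero at the start of the recovery period
  z <- obs[obs$t == 0, c("Rr", "Rg", "Rl", "Sg", "Sl",
                         "cRr", "cRg", "cRl", "cSg", "cSl")]
  expect_true(all(z == 0))
})

test_that("hierarchical draws average to their population means (law of large numbers)", {
  cfg <- generator_config(n_sites = 50, plots_per_site = 40,
                          duration_range = c(8, 9))
  d <- generate_flux_dataset(cfg, seed = 21)
  tr <- cfg$truth
  n <- nrow(d$truth$plots)
  se <- tr$sigma_a_Sg / sqrt(n)
  expect_lt(abs(mean(d$truth$plots$alpha_Sg) - tr$alpha0_Sg), 3 * se)
  se_r <- tr$sigma_a_Rr / sqrt(cfg$n_sites)
  expect_lt(abs(mean(d$truth$sites$alpha_Rr) - tr$alpha0_Rr), 4 * se_r)
})

test_that("generated covariates and latent rates respect the study conditions", {
  cfg <- generator_config()
  d <- generate_flux_dataset(cfg, seed = 31)
  m <- flux_meta(d$flux)
  expect_true(all(m$loss >= 1 & m$loss <= 71))
  expect_true(all(m$acs_min > 0))
  pr <- acs_priors()
  p <- d$truth$plots
  expect_true(all(p$beta_Sg >= pr$beta_Sg[1]))
  expect_true(all(p$beta_Sl >= pr$beta_Sl[1] & p$beta_Sl <= p$beta_Sg))
  expect_true(all(p$beta_Rr >= pr$beta_Rr[1] & p$beta_Rr <= pr$beta_Rr[2]))
  expect_true(all(p$beta_Rg >= pr$beta_Rg[1] & p$beta_Rg <= pr$beta_Rg[2]))
  expect_true(all(p$beta_Rl >= pr$beta_Rl[1] & p$beta_Rl <= pr$beta_Rl[2]))
  # series lengths between 8 and 30 years with annual censuses early on
  lens <- tapply(d$flux$t, d$flux$plot_id, max)
  expect_true(all(lens >= 8 & lens <= 30))
})

test_that("the generator is the exact complement of the weighted likelihood", {
  cfg <- generator_config(n_sites = 2, plots_per_site = 2)
  d <- generate_flux_dataset(cfg, seed = 77)
  got <- generator_logdensity(d)
  # independent recomputation: plain loop over rows and fluxes
  obs <- as.data.frame(d$flux)[d$flux$t > 0, ]
  m <- flux_meta(d$flux)
  tr <- d$truth
  want <- 0
  for (i in seq_len(nrow(obs))) {
    j <- match(obs$plot_id[i], tr$plots$plot_id)
    s <- match(obs$site_id[i], tr$sites$site_id)
    w <- m$weight[match(obs$plot_id[i], m$plot_id)]
    mus <- c(
      Sg = survivor_cumulative_mean(tr$plots$alpha_Sg[j],
                                    tr$plots$beta_Sg[j], obs$t[i]),
      Sl = survivor_cumulative_mean(tr$plots$alpha_Sl[j],
                                    tr$plots$beta_Sl[j], obs$t[i]),
      Rr = recruit_cumulative_mean(tr$sites$alpha_Rr[s],
                                   tr$plots$beta_Rr[j], tr$hyper$eta,
                                   obs$t[i]),
      Rg = recruit_cumulative_mean(tr$sites$alpha_Rg[s],
                                   tr$plots$beta_Rg[j], -1, obs$t[i]),
      Rl = recruit_cumulative_mean(tr$sites$alpha_Rl[s],
                                   tr$plots$beta_Rl[j], -1, obs$t[i]))
    sig <- c(Sg = tr$hyper$sigma_e_Sg, Sl = tr$hyper$sigma_e_Sl,
             Rr = tr$hyper$sigma_e_Rr, Rg = tr$hyper$sigma_e_Rg,
             Rl = tr$hyper$sigma_e_Rl)
    for (k in names(mus))
      want <- want + w * dnorm(obs[[paste0("c", k)]][i], mus[[k]], sig[[k]],
                               log = TRUE)
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the synthetic inventory reaches its target stocking", {
  gen <- generate_inventory(n_plots = 1, target_acs = 200, seed = 8)
  pre <- gen$inventory[gen$inventory$census_time == -1, ]
  acs <- plot_acs(pre, gen$wd, E = gen$sites$E, area = gen$plots$area[1],
                  site_id = "SYN")
  expect_lt(abs(acs - 200) / 200, 0.10)
  # the worked single-interval example reproduces under decomposition
  fx <- decompose_fluxes(gen$inventory, gen$wd, gen$sites, gen$plots)
  expect_equal(flux_meta(fx)$loss,
               disturbance_intensity(flux_meta(fx)$acs_prelogging,
                                     flux_meta(fx)$acs_min),
               tolerance = 1e-12)
})

test_that("covariate grids are uniform, monotone, or range-bounded as requested", {
  cfg <- generator_config()
  u <- generate_covariate_grid(4, 6, cfg, type = "uniform")
  expect_equal(nrow(u), 24)
  for (v in c("acs0", "prec", "seas", "bd"))
    expect_length(unique(u[[v]]), 1)
  g <- generate_covariate_grid(3, 8, cfg, type = "gradient")
  byrow <- g[g$row == 2, ]
  expect_true(all(diff(byrow$prec[order(byrow$col)]) > 0))
  r <- generate_covariate_grid(5, 5, cfg, type = "random", seed = 2)
  expect_true(all(r$prec >= 1000 & r$prec <= 3500))
  expect_true(all(r$bd >= 0.9 & r$bd <= 1.5))
  expect_identical(r, generate_covariate_grid(5, 5, cfg, "random", seed = 2))
})
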