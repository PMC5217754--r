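# Shared fixtures, generated in code and cached for the whole run.

.fixture_env <- new.env(parent = emptyenv())

# small noisy dataset + short fits, reused by several test files
shared_fits <- function() {
  if (!is.null(.fixture_env$fits)) return(.fixture_env$fits)
  cfg <- generator_config(n_sites = 3, plots_per_site = 3)
  d <- generate_flux_dataset(cfg, seed = 42)
  fs <- suppressWarnings(fit_survivors(d$flux, d$covariates, chains = 2,
                                       iterations = 400, warmup = 400,
                                       seed = 7))
  fr <- suppressWarnings(fit_recruits(d$flux, d$covariates, chains = 2,
                                      iterations = 400, warmup = 400,
                                      seed = 7))
  .fixture_env$fits <- list(cfg = cfg, data = d, survivors = fs,
                            recruits = fr)
  .fixture_env$fits
}

# degenerate (point-mass) posterior draw matrices for prediction tests:
# all hierarchical and rate sds zero, so every Monte-Carlo replicate is
# identical
degenerate_draws <- function(alpha0_Sg = 120, beta0_Sg = 0.03,
                             beta0_Sl = 0.012,
                             alpha0_Rr = 0.5, alpha0_Rg = 1.5, eta = 1.5,
                             beta0_Rr = 0.3, beta0_Rg = 0.08,
                             beta0_Rl = 0.03) {
  lam <- function(nm) {
    m <- matrix(0, 2, 6)
    colnames(m) <- sprintf("%s[%d]", nm, 1:6)
    m
  }
  s <- cbind(alpha0_Sg = rep(alpha0_Sg, 2), sigma_a_Sg = 0,
             beta0_Sg = beta0_Sg, beta0_Sl = beta0_Sl)
  s <- cbind(s, lam("lambda_Sg"), lam("lambda_Sl"))
  r <- cbind(alpha0_Rr = rep(alpha0_Rr, 2), sigma_a_Rr = 0,
             alpha0_Rg = alpha0_Rg, sigma_a_Rg = 0, eta = eta,
             beta0_Rr = beta0_Rr, beta0_Rg = beta0_Rg, beta0_Rl = beta0_Rl)
  sb <- matrix(0, 2, 3)
  colnames(sb) <- sprintf("sigma_b_R[%d]", 1:3)
  r <- cbind(r, lam("lambda_Rr"), lam("lambda_Rg"), lam("lambda_Rl"), sb)
  list(survivors = s, recruits = r)
}

# calibration moments spanning wide physical ranges, for prediction tests
wide_moments <- function() {
  data.frame(covariate = covariate_names(),
             mean = c(35, 275, 0, 2200, 60, 1.2),
             sd = c(20, 70, 10, 700, 25, 0.18),
             min = c(1, 150, -30, 1000, 20, 0.9),
             max = c(71, 400, 30, 3500, 100, 1.5))
}

# tiny two-census plot data for flux-accounting unit tests
toy_censuses <- function() {
  prev <- data.frame(
    tree_id = c("a", "b", "c", "d"),
    dbh = c(30, 25, 18, 15),
    status = c("alive", "alive", "alive", "alive"),
    acs = c(1.0, 0.8, 0.2, 0.1))
  curr <- data.frame(
    tree_id = c("a", "b", "c", "d"),
    dbh = c(32, 25, 21, 16),
    status = c("alive", "dead", "alive", "alive"),
    acs = c(1.2, NA, 0.3, 0.12))
  list(prev = prev, curr = curr)
}
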