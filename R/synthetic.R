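#' Configuration for the synthetic recovery-data generator
#'
#' Defines the study conditions emulated by [generate_flux_dataset()]: a
#' network of long-term experimental sites (default 12 sites of 5 plots,
#' censused 8--30 years with dense early censuses), disturbance intensities
#' spanning 1--71\% of pre-logging carbon, climate/soil covariates in
#' Amazonian ranges, and true model hyperparameters placed mid-prior. True
#' parameters must lie inside the prior supports of [acs_priors()]; the
#' constructor refuses configurations outside them, since parameter-recovery
#' runs would otherwise be vacuous.
#'
#' @param n_sites number of sites.
#' @param plots_per_site plots per site.
#' @param area_range plot area range, ha (uniform).
#' @param duration_range census-series length range after recovery start,
#'   years; censuses are annual for the first 4 years, then every 3 years.
#' @param acs_pre_range pre-logging plot ACS range, Mg C ha^-1.
#' @param loss_range disturbance-intensity range, \% of pre-logging ACS.
#' @param prec_range,seas_range,bd_range site covariate ranges (mm yr^-1,
#'   dimensionless, g cm^-3).
#' @param truth named list of true parameters; any subset of the defaults may
#'   be overridden.
#' @param priors the prior specification the truth must respect.
#' @return a list of class `acs_generator_config`.
#' @export
generator_config <- function(n_sites = 12, plots_per_site = 5,
                             area_range = c(0.25, 2.5),
                             duration_range = c(8, 30),
                             acs_pre_range = c(150, 400),
                             loss_range = c(1, 71),
                             prec_range = c(1000, 3500),
                             seas_range = c(20, 100),
                             bd_range = c(0.9, 1.5),
                             truth = list(),
                             priors = acs_priors()) {
  default_truth <- list(
    alpha0_Sg = 137.5, sigma_a_Sg = 20,
    beta0_Sg = 0.0275,
    lambda_Sg = c(0.003, 0.0008, -0.0008, 0.0008, -0.0008, 0.0008),
    beta0_Sl = 0.012,
    lambda_Sl = c(0.002, 0.0006, -0.0006, 0.0006, -0.0006, 0.0006),
    sigma_e_Sg = 3, sigma_e_Sl = 4,
    alpha0_Rr = 0.55, sigma_a_Rr = 0.10,
    alpha0_Rg = 1.75, sigma_a_Rg = 0.30,
    eta = 1.5,
    beta0_Rr = 0.30,
    lambda_Rr = c(0.03, 0.01, -0.01, 0.01, -0.01, 0.01),
    beta0_Rg = 0.078,
    lambda_Rg = c(0.008, 0.002, -0.002, 0.002, -0.002, 0.002),
    beta0_Rl = 0.0315,
    lambda_Rl = c(0.004, 0.001, -0.001, 0.001, -0.001, 0.001),
    sigma_b_Rr = 0.02, sigma_b_Rg = 0.008, sigma_b_Rl = 0.004,
    sigma_e_Rr = 0.8, sigma_e_Rg = 1.0, sigma_e_Rl = 0.6)
  truth <- utils::modifyList(default_truth, truth)
  inside <- function(x, b) x >= b[1] & x <= b[2]
  checks <- c(
    alpha0_Sg = inside(truth$alpha0_Sg, priors$alpha_Sg),
    beta0_Sg = inside(truth$beta0_Sg, priors$beta_Sg),
    beta0_Sl = truth$beta0_Sl >= priors$beta_Sl[1] &&
      truth$beta0_Sl <= truth$beta0_Sg,
    alpha0_Rr = inside(truth$alpha0_Rr, priors$alpha_Rr),
    alpha0_Rg = inside(truth$alpha0_Rg, priors$alpha_Rg),
    beta0_Rr = inside(truth$beta0_Rr, priors$beta_Rr),
    beta0_Rg = inside(truth$beta0_Rg, priors$beta_Rg),
    beta0_Rl = inside(truth$beta0_Rl, priors$beta_Rl),
    eta = inside(truth$eta, priors$eta),
    lambda_loss_Sg = abs(truth$lambda_Sg[1]) <= truth$beta0_Sg,
    lambda_other_Sg = all(abs(truth$lambda_Sg[-1]) <= truth$beta0_Sg / 4))
  if (!all(checks))
    stop("true parameters outside prior support: ",
         paste(names(checks)[!checks], collapse = ", "))
  structure(c(list(n_sites = n_sites, plots_per_site = plots_per_site,
                   area_range = area_range, duration_range = duration_range,
                   acs_pre_range = acs_pre_range, loss_range = loss_range,
                   prec_range = prec_range, seas_range = seas_range,
                   bd_range = bd_range, priors = priors),
              list(truth = truth)),
            class = "acs_generator_config")
}

# inverse-CDF truncated-normal draw (vectorised, seeded by the caller)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd == 0)) {
    out <- rep(mean, length.out = n)
    if (any(out < lower | out > upper))
      stop("degenerate truncated normal outside bounds")
    return(out)
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  out <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  # when the mean sits far outside the bounds the interval mass underflows
  # and qnorm degenerates; the truncated distribution then collapses onto the
  # nearest bound
  out <- pmin(pmax(out, lower), upper)
  bad <- !is.finite(out)
  if (any(bad))
    out[bad] <- pmin(pmax(rep(mean, length.out = n)[bad], lower), upper)
  out
}

#' Generate a synthetic flux dataset with known ground truth
#'
#' Forward-simulates the full statistical model: plot covariates are drawn
#' and standardized (moments stored as calibration moments); survivor rates
#' are the deterministic covariate linear predictors, recruit rates are drawn
#' around theirs (between-plot sd `sigma_b`), both kept inside the prior
#' supports; plot growth asymptotes and site recruit asymptotes are drawn
#' from their hierarchical normals; the loss-side asymptotes are derived
#' exactly from the carbon-closure and dynamic-equilibrium constraints; and
#' noisy cumulative observations are emitted at the census times with iid
#' Gaussian noise of sd `sigma_E / sqrt(weight)` -- the exact complement of
#' the weighted fitting likelihood. Interval fluxes are first differences of
#' the noisy cumulative series: their signs are guaranteed only for
#' `sigma_scale = 0` (the latent mean increments always respect the sign
#' convention).
#'
#' @param cfg an [generator_config()] object.
#' @param seed integer seed; runs are bit-reproducible.
#' @param sigma_scale multiplier on all residual sds (0 gives noiseless
#'   observations exactly on the mean curves).
#' @return list with `flux` (a `flux_series`), `covariates` (standardized
#'   `acs_covariates`) and `truth` (per-plot and per-site latent values plus
#'   the hyperparameters).
#' @export
generate_flux_dataset <- function(cfg = generator_config(), seed = 1,
                                  sigma_scale = 1) {
  stopifnot(inherits(cfg, "acs_generator_config"))
  set.seed(seed)
  tr <- cfg$truth
  pr <- cfg$priors
  J <- cfg$n_sites * cfg$plots_per_site
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(cfg$n_sites)),
    prec = stats::runif(cfg$n_sites, cfg$prec_range[1], cfg$prec_range[2]),
    seas = stats::runif(cfg$n_sites, cfg$seas_range[1], cfg$seas_range[2]),
    bd = stats::runif(cfg$n_sites, cfg$bd_range[1], cfg$bd_range[2]),
    acs_site = stats::runif(cfg$n_sites, cfg$acs_pre_range[1],
                            cfg$acs_pre_range[2]),
    duration = stats::runif(cfg$n_sites, cfg$duration_range[1],
                            cfg$duration_range[2]))
  si <- rep(seq_len(cfg$n_sites), each = cfg$plots_per_site)
  plots <- data.frame(
    plot_id = sprintf("%s-P%d", sites$site_id[si],
                      rep(seq_len(cfg$plots_per_site), cfg$n_sites)),
    site_id = sites$site_id[si],
    area = stats::runif(J, cfg$area_range[1], cfg$area_range[2]),
    acs_prelogging = sites$acs_site[si] * exp(stats::rnorm(J, 0, 0.10)),
    loss = stats::runif(J, cfg$loss_range[1], cfg$loss_range[2]))
  plots$acs_min <- plots$acs_prelogging * (1 - plots$loss / 100)
  plots$weight <- plots$area / mean(plots$area)

  meta <- data.frame(plot_id = plots$plot_id, site_id = plots$site_id,
                     area = plots$area, t0 = 0, acs_min = plots$acs_min,
                     acs_prelogging = plots$acs_prelogging,
                     loss = plots$loss, weight = plots$weight)
  cov <- standardize_covariates(build_covariates(
    meta, sites[, c("site_id", "prec", "seas", "bd")]))
  V <- as.matrix(as.data.frame(cov)[, paste0(covariate_names(), "_z")])

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  eps <- 1e-4
  beta_Sg <- clamp(survivor_rate(tr$beta0_Sg, tr$lambda_Sg, V),
                   pr$beta_Sg[1] + eps, pr$beta_Sg[2] * 2)
  beta_Sl <- clamp(survivor_rate(tr$beta0_Sl, tr$lambda_Sl, V),
                   pr$beta_Sl[1] + eps, beta_Sg - eps)
  alpha_Sg <- .rtnorm(J, tr$alpha0_Sg, tr$sigma_a_Sg, lower = 0)
  alpha_Sl <- survivor_loss_asymptote(alpha_Sg, plots$acs_min)
  alpha_Rr <- .rtnorm(cfg$n_sites, tr$alpha0_Rr, tr$sigma_a_Rr, lower = 0)
  alpha_Rg <- .rtnorm(cfg$n_sites, tr$alpha0_Rg, tr$sigma_a_Rg, lower = 0)
  alpha_Rl <- recruit_loss_asymptote(alpha_Rr, alpha_Rg)
  beta_Rr <- .rtnorm(J, survivor_rate(tr$beta0_Rr, tr$lambda_Rr, V),
                     tr$sigma_b_Rr, pr$beta_Rr[1], pr$beta_Rr[2])
  beta_Rg <- .rtnorm(J, survivor_rate(tr$beta0_Rg, tr$lambda_Rg, V),
                     tr$sigma_b_Rg, pr$beta_Rg[1], pr$beta_Rg[2])
  beta_Rl <- .rtnorm(J, survivor_rate(tr$beta0_Rl, tr$lambda_Rl, V),
                     tr$sigma_b_Rl, pr$beta_Rl[1], pr$beta_Rl[2])

  rows <- vector("list", J)
  for (j in seq_len(J)) {
    dur <- sites$duration[match(plots$site_id[j], sites$site_id)]
    t <- unique(c(0:min(4, floor(dur)), seq(4, floor(dur), by = 3), floor(dur)))
    t <- sort(t)
    n <- length(t)
    sj <- match(plots$site_id[j], sites$site_id)
    noise <- function(sig) {
      e <- stats::rnorm(n, 0, sigma_scale * sig / sqrt(plots$weight[j]))
      e[t == 0] <- 0
      e
    }
    cSg <- survivor_cumulative_mean(alpha_Sg[j], beta_Sg[j], t) + noise(tr$sigma_e_Sg)
    cSl <- survivor_cumulative_mean(alpha_Sl[j], beta_Sl[j], t) + noise(tr$sigma_e_Sl)
    cRr <- recruit_cumulative_mean(alpha_Rr[sj], beta_Rr[j], tr$eta, t) +
      noise(tr$sigma_e_Rr)
    cRg <- recruit_cumulative_mean(alpha_Rg[sj], beta_Rg[j], -1, t) +
      noise(tr$sigma_e_Rg)
    cRl <- recruit_cumulative_mean(alpha_Rl[sj], beta_Rl[j], -1, t) +
      noise(tr$sigma_e_Rl)
    rows[[j]] <- data.frame(
      plot_id = plots$plot_id[j], site_id = plots$site_id[j], t = t,
      Rr = c(0, diff(cRr)), Rg = c(0, diff(cRg)), Rl = c(0, diff(cRl)),
      Sg = c(0, diff(cSg)), Sl = c(0, diff(cSl)),
      cRr = cRr, cRg = cRg, cRl = cRl, cSg = cSg, cSl = cSl)
  }
  flux <- structure(do.call(rbind, rows), meta = meta,
                    excluded = character(),
                    class = c("flux_series", "data.frame"))
  rownames(flux) <- NULL
  truth <- list(
    hyper = tr,
    plots = data.frame(plots,
                       alpha_Sg = alpha_Sg, alpha_Sl = alpha_Sl,
                       beta_Sg = beta_Sg, beta_Sl = beta_Sl,
                       beta_Rr = beta_Rr, beta_Rg = beta_Rg,
                       beta_Rl = beta_Rl),
    sites = data.frame(sites, alpha_Rr = alpha_Rr, alpha_Rg = alpha_Rg,
                       alpha_Rl = alpha_Rl))
  list(flux = flux, covariates = cov, truth = truth)
}

#' Log-density of a generated dataset under the generator's own truth
#'
#' The generator and the fitting likelihood are exact complements: this
#' returns the weighted log-density of the cumulative observations around the
#' true mean curves, which equals [weighted_loglik()] summed over the five
#' fluxes (checkable on small fixtures).
#'
#' @param dataset result of [generate_flux_dataset()].
#' @return scalar log-density.
#' @export
generator_logdensity <- function(dataset) {
  flux <- dataset$flux; tr <- dataset$truth
  obs <- as.data.frame(flux)[flux$t > 0, ]
  meta <- flux_meta(flux)
  pid <- as.character(tr$plots$plot_id)
  w <- stats::setNames(meta$weight, as.character(meta$plot_id))
  sj <- match(tr$plots$site_id, tr$sites$site_id)
  ll <- 0
  specs <- list(
    Sg = list(a = tr$plots$alpha_Sg, b = tr$plots$beta_Sg, s = tr$hyper$sigma_e_Sg),
    Sl = list(a = tr$plots$alpha_Sl, b = tr$plots$beta_Sl, s = tr$hyper$sigma_e_Sl),
    Rr = list(a = tr$sites$alpha_Rr[sj], b = tr$plots$beta_Rr, s = tr$hyper$sigma_e_Rr),
    Rg = list(a = tr$sites$alpha_Rg[sj], b = tr$plots$beta_Rg, s = tr$hyper$sigma_e_Rg),
    Rl = list(a = tr$sites$alpha_Rl[sj], b = tr$plots$beta_Rl, s = tr$hyper$sigma_e_Rl))
  for (kind in names(specs)) {
    sp <- specs[[kind]]
    o <- data.frame(plot_id = obs$plot_id, t = obs$t,
                    y = obs[[paste0("c", kind)]],
                    weight = w[as.character(obs$plot_id)])
    ll <- ll + weighted_loglik(o, stats::setNames(sp$a, pid),
                               stats::setNames(sp$b, pid), sp$s, kind,
                               eta = tr$hyper$eta)
  }
  ll
}

#' Generate a synthetic tree inventory with known cohort bookkeeping
#'
#' Builds tree-by-tree census tables that exercise the allometry and flux
#' accounting end to end: a pre-logging stand assembled tree-by-tree until a
#' target plot ACS is reached, a logging kill calibrated to the target
#' disturbance intensity, post-logging survivor growth and mortality, and a
#' sub-threshold pool whose trees cross 20 cm DBH (recruits) and may die.
#' Because the generator knows every tree's cohort, it also returns its own
#' interval-flux tally, an independent oracle for [decompose_fluxes()].
#'
#' @param n_plots number of plots (one site).
#' @param target_acs pre-logging plot ACS target, Mg C ha^-1.
#' @param loss target disturbance intensity, \% (recycled over plots).
#' @param n_censuses number of post-logging censuses (annual).
#' @param area plot area, ha (recycled).
#' @param E climatic index of the site.
#' @param growth mean annual DBH increment of survivors, cm yr^-1.
#' @param mortality annual death probability after the logging kill.
#' @param seed integer seed.
#' @return list with `inventory` (long data.frame), `wd` (a `wd_table`
#'   covering all species), `sites`, `plots` (inputs for
#'   [decompose_fluxes()]), and `tally` (the generator's own per-interval
#'   fluxes in Mg C ha^-1, columns as in a `flux_series`).
#' @export
generate_inventory <- function(n_plots = 2, target_acs = 200, loss = 40,
                               n_censuses = 6, area = 1, E = 0.1,
                               growth = 0.4, mortality = 0.02, seed = 1) {
  set.seed(seed)
  loss <- rep_len(loss, n_plots)
  area <- rep_len(area, n_plots)
  species <- sprintf("Genus%d species%d", rep(1:5, each = 2), rep(1:2, 5))
  wd_vals <- seq(0.45, 0.85, length.out = length(species))
  wd <- wood_density_table(data.frame(level = "species", name = species,
                                      wd = wd_vals))
  wd$site["SYN"] <- mean(wd_vals)
  inv <- list(); tally <- list()
  for (p in seq_len(n_plots)) {
    pid <- sprintf("SYN-P%d", p)
    # assemble the pre-logging stand to the target ACS
    dbh <- c(); sp <- c()
    repeat {
      d <- 20 + stats::rexp(1, 1 / 15)
      s <- sample(species, 1)
      if (sum(tree_acs(c(dbh, d), wd$species[c(sp, s)], E)) / area[p] >=
          target_acs) break
      dbh <- c(dbh, d); sp <- c(sp, s)
    }
    n0 <- length(dbh)
    # sub-threshold pool: trees that may cross 20 cm during the series
    n_sub <- max(8, round(n0 / 3))
    dbh_sub <- stats::runif(n_sub, 14, 19.5)
    sp_sub <- sample(species, n_sub, replace = TRUE)
    ids <- c(sprintf("%s-T%03d", pid, seq_len(n0)),
             sprintf("%s-U%03d", pid, seq_len(n_sub)))
    all_dbh <- c(dbh, dbh_sub)
    all_sp <- c(sp, sp_sub)
    genus <- vapply(strsplit(all_sp, " "), `[`, "", 1)
    alive <- rep(TRUE, n0 + n_sub)

    census <- function(tt) data.frame(
      tree_id = ids, plot_id = pid, site_id = "SYN", census_time = tt,
      dbh = round(all_dbh, 1), taxon_species = all_sp, taxon_genus = genus,
      status = ifelse(alive, "alive", "dead"))
    cen <- list(census(-1))  # pre-logging census at t = -1, logging at t = 0

    # logging kill among the big trees until the ACS loss target is met
    acs_tree <- tree_acs(pmax(round(all_dbh, 1), 0.1), wd$species[all_sp], E)
    big <- which(all_dbh >= 20)
    target_kill <- sum(acs_tree[big]) * loss[p] / 100
    kill <- sample(big)
    cumk <- cumsum(acs_tree[kill])
    alive[kill[seq_len(which.min(abs(cumk - target_kill)))]] <- FALSE

    membership <- NULL
    for (k in seq_len(n_censuses)) {
      inc <- stats::rnorm(length(all_dbh), growth, growth / 4)
      all_dbh[alive] <- all_dbh[alive] + pmax(inc[alive], 0)
      if (k > 1) {  # deaths after the first post-logging census
        die <- alive & stats::runif(length(alive)) < mortality
        alive[die] <- FALSE
      }
      cen[[k + 1]] <- census(k)
    }
    inv[[p]] <- do.call(rbind, cen)

    # independent tally: cohort of each tree is known by construction
    post <- cen[-1]
    c0 <- post[[1]]
    surv <- c0$tree_id[c0$status == "alive" & c0$dbh >= 20]
    state <- stats::setNames(rep("survivor", length(surv)), surv)
    tl <- data.frame(plot_id = pid, t = 0, Rr = 0, Rg = 0, Rl = 0,
                     Sg = 0, Sl = 0)
    for (k in 2:length(post)) {
      prev <- post[[k - 1]]; curr <- post[[k]]
      a_prev <- tree_acs(pmax(prev$dbh, 0.1), wd$species[prev$taxon_species], E)
      a_curr <- tree_acs(pmax(curr$dbh, 0.1), wd$species[curr$taxon_species], E)
      names(a_prev) <- prev$tree_id; names(a_curr) <- curr$tree_id
      f <- c(Rr = 0, Rg = 0, Rl = 0, Sg = 0, Sl = 0)
      for (id in curr$tree_id) {
        al_prev <- prev$status[prev$tree_id == id] == "alive"
        al_curr <- curr$status[curr$tree_id == id] == "alive"
        m <- state[id]
        if (!is.na(m)) {
          if (al_prev && al_curr) {
            f[if (m == "survivor") "Sg" else "Rg"] <-
              f[if (m == "survivor") "Sg" else "Rg"] + a_curr[id] - a_prev[id]
          } else if (al_prev && !al_curr) {
            f[if (m == "survivor") "Sl" else "Rl"] <-
              f[if (m == "survivor") "Sl" else "Rl"] - a_prev[id]
          }
        } else if (al_curr && curr$dbh[curr$tree_id == id] >= 20) {
          f["Rr"] <- f["Rr"] + a_curr[id]
          state[id] <- "recruit"
        }
      }
      tl <- rbind(tl, data.frame(plot_id = pid, t = k - 1,
                                 Rr = f[["Rr"]], Rg = f[["Rg"]],
                                 Rl = f[["Rl"]], Sg = f[["Sg"]],
                                 Sl = f[["Sl"]]) )
      tl[nrow(tl), c("Rr", "Rg", "Rl", "Sg", "Sl")] <-
        tl[nrow(tl), c("Rr", "Rg", "Rl", "Sg", "Sl")] / area[p]
    }
    tally[[p]] <- tl
  }
  list(inventory = do.call(rbind, inv), wd = wd,
       sites = data.frame(site_id = "SYN", E = E),
       plots = data.frame(plot_id = sprintf("SYN-P%d", seq_len(n_plots)),
                          site_id = "SYN", area = area, logging_time = 0),
       tally = do.call(rbind, tally))
}

#' Generate a co-registered synthetic covariate grid
#'
#' Small raster-like grids (plain data.frames, one row per pixel) of the
#' prediction covariates: pre-disturbance carbon (`acs0`), annual
#' precipitation, seasonality and bulk density. `"uniform"` grids have all
#' pixels identical (constancy tests); `"gradient"` grids vary monotonically
#' left to right; `"random"` grids draw uniformly within the configured
#' physical ranges.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cfg a [generator_config()] (covariate ranges).
#' @param type grid pattern.
#' @param seed seed (used for `"random"`).
#' @return data.frame with columns `row`, `col`, `acs0`, `prec`, `seas`,
#'   `bd`.
#' @export
generate_covariate_grid <- function(n_rows = 10, n_cols = 10,
                                    cfg = generator_config(),
                                    type = c("uniform", "gradient", "random"),
                                    seed = 1) {
  type <- match.arg(type)
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  n <- nrow(g)
  rng <- list(acs0 = cfg$acs_pre_range, prec = cfg$prec_range,
              seas = cfg$seas_range, bd = cfg$bd_range)
  if (type == "uniform") {
    for (v in names(rng)) g[[v]] <- mean(rng[[v]])
  } else if (type == "gradient") {
    frac <- (g$col - 1) / max(1, n_cols - 1)
    for (v in names(rng))
      g[[v]] <- rng[[v]][1] + frac * diff(rng[[v]])
  } else {
    set.seed(seed)
    for (v in names(rng)) g[[v]] <- stats::runif(n, rng[[v]][1], rng[[v]][2])
  }
  g
}
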