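## Monte-Carlo spatial prediction of post-disturbance carbon recovery.
##
## Every pixel of a covariate grid is treated as a hypothetical plot logged at
## the prescribed disturbance intensity. Per replicate: one retained posterior
## draw supplies the hyperparameters; pixel-level asymptotes are drawn from
## their hierarchical normals (random effects); the loss-side asymptotes
## follow from the hard constraints with acs_min = (1 - loss/100) x pixel
## pre-disturbance carbon; rates come from the covariate linear predictors
## (survivors: deterministic, truncated to the prior support; recruits:
## normal noise redrawn per pixel and replicate, truncated likewise); the
## five cumulative fluxes are evaluated at the horizon.

.as_draws <- function(fit) {
  if (inherits(fit, "acs_fit")) posterior_draws(fit) else as.matrix(fit)
}

# canonical pixel order so results are invariant to input row ordering
.pixel_order <- function(grid) order(grid$row, grid$col)

.predict_replicates <- function(grid, draws_s, draws_r, moments,
                                loss, horizon, n_rep, seed,
                                priors = acs_priors(),
                                carbon_factor = 1) {
  ord <- .pixel_order(grid)
  g <- grid[ord, , drop = FALSE]
  P <- nrow(g)
  raw <- data.frame(loss = rep(loss, P),
                    acs0 = g$acs0 * carbon_factor,
                    dacs = rep(0, P),
                    prec = g$prec, seas = g$seas, bd = g$bd)
  # extrapolation check against the calibration range when available
  if (all(c("min", "max") %in% names(moments))) {
    for (i in seq_len(nrow(moments))) {
      v <- moments$covariate[i]
      if (any(raw[[v]] < moments$min[i] | raw[[v]] > moments$max[i]))
        warning("covariate '", v,
                "' outside the calibration range for some pixels ",
                "(extrapolation)", call. = FALSE)
    }
  }
  z <- apply_moments(raw, moments)
  V <- as.matrix(z[, paste0(covariate_names(), "_z")])
  acs_min <- (1 - loss / 100) * raw$acs0

  set.seed(seed)
  idx_s <- sample.int(nrow(draws_s), n_rep, replace = TRUE)
  idx_r <- sample.int(nrow(draws_r), n_rep, replace = TRUE)
  lam <- function(d, r, nm) as.numeric(d[r, sprintf("%s[%d]", nm, 1:6)])
  flux <- array(NA_real_, dim = c(P, 5, n_rep),
                dimnames = list(NULL, c("cSg", "cSl", "cRr", "cRg", "cRl"),
                                NULL))
  params <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    ds <- draws_s[idx_s[r], ]; dr <- draws_r[idx_r[r], ]
    a_sg <- .rtnorm(P, ds[["alpha0_Sg"]], ds[["sigma_a_Sg"]], lower = 0)
    a_sl <- survivor_loss_asymptote(a_sg, acs_min)
    b_sg <- pmax(survivor_rate(ds[["beta0_Sg"]], lam(draws_s, idx_s[r], "lambda_Sg"), V),
                 priors$beta_Sg[1])
    b_sl <- survivor_rate(ds[["beta0_Sl"]], lam(draws_s, idx_s[r], "lambda_Sl"), V)
    b_sl <- pmax(pmin(b_sl, b_sg), priors$beta_Sl[1])
    a_rr <- .rtnorm(P, dr[["alpha0_Rr"]], dr[["sigma_a_Rr"]], lower = 0)
    a_rg <- .rtnorm(P, dr[["alpha0_Rg"]], dr[["sigma_a_Rg"]], lower = 0)
    a_rl <- recruit_loss_asymptote(a_rr, a_rg)
    b_rr <- .rtnorm(P, survivor_rate(dr[["beta0_Rr"]],
                                     lam(draws_r, idx_r[r], "lambda_Rr"), V),
                    dr[["sigma_b_R[1]"]], priors$beta_Rr[1], priors$beta_Rr[2])
    b_rg <- .rtnorm(P, survivor_rate(dr[["beta0_Rg"]],
                                     lam(draws_r, idx_r[r], "lambda_Rg"), V),
                    dr[["sigma_b_R[2]"]], priors$beta_Rg[1], priors$beta_Rg[2])
    b_rl <- .rtnorm(P, survivor_rate(dr[["beta0_Rl"]],
                                     lam(draws_r, idx_r[r], "lambda_Rl"), V),
                    dr[["sigma_b_R[3]"]], priors$beta_Rl[1], priors$beta_Rl[2])
    eta <- dr[["eta"]]
    params[[r]] <- list(a_sg = a_sg, a_sl = a_sl, b_sg = b_sg, b_sl = b_sl,
                        a_rr = a_rr, a_rg = a_rg, a_rl = a_rl,
                        b_rr = b_rr, b_rg = b_rg, b_rl = b_rl, eta = eta)
    flux[, , r] <- .eval_fluxes(params[[r]], horizon)
  }
  list(flux = flux, params = params, order = ord, acs_min = acs_min)
}

.eval_fluxes <- function(p, t) {
  cbind(cSg = p$a_sg * (1 - exp(-p$b_sg * t)),
        cSl = p$a_sl * (1 - exp(-p$b_sl * t)),
        cRr = p$a_rr * (t + p$eta * (1 - exp(-p$b_rr * t)) / p$b_rr),
        cRg = p$a_rg * (t - (1 - exp(-p$b_rg * t)) / p$b_rg),
        cRl = p$a_rl * (t - (1 - exp(-p$b_rl * t)) / p$b_rl))
}

#' Monte-Carlo prediction of carbon recovery over a covariate grid
#'
#' Implements the full mapping procedure: pixel covariates standardized with
#' the calibration moments (`loss` fixed at the scenario intensity, forest
#' maturity `dacs` at zero), posterior parameter draws, per-pixel random
#' effects, hard-constraint loss asymptotes, and evaluation of the five
#' cumulative ACS changes at the horizon, repeated `n_rep` times.
#'
#' @param fit_s survivors fit (`acs_fit`) or a draws matrix with the
#'   survivors' hyperparameter columns.
#' @param fit_r recruits fit or draws matrix.
#' @param grid covariate grid ([generate_covariate_grid()] layout: `row`,
#'   `col`, `acs0`, `prec`, `seas`, `bd`), `acs0` in Mg C ha^-1 (use
#'   `carbon_factor = 0.5` when the grid carries biomass instead of carbon).
#' @param moments calibration moments ([covariate_moments()]).
#' @param loss disturbance intensity scenario, \% of pre-disturbance ACS;
#'   default 40.
#' @param horizon prediction horizon, years; default 10.
#' @param n_rep number of Monte-Carlo replicates; default 200.
#' @param seed integer seed; results are reproducible and invariant to pixel
#'   ordering.
#' @param priors prior supports used to truncate predicted rates.
#' @param carbon_factor multiplier applied to the grid's `acs0` at ingest.
#' @return object of class `acs_prediction`: list with the input `grid`
#'   (original order), the replicate flux array (`pixels x 5 fluxes x reps`),
#'   per-replicate parameter draws, and the scenario settings.
#' @export
predict_recovery_map <- function(fit_s, fit_r, grid, moments, loss = 40,
                                 horizon = 10, n_rep = 200, seed = 1,
                                 priors = acs_priors(), carbon_factor = 1) {
  stopifnot(all(c("row", "col", "acs0", "prec", "seas", "bd") %in%
                  names(grid)),
            all(grid$acs0 > 0), loss >= 0, loss < 100, horizon >= 0)
  if (missing(moments) && inherits(fit_s, "acs_fit") &&
      !is.null(fit_s$moments)) moments <- fit_s$moments
  res <- .predict_replicates(grid, .as_draws(fit_s), .as_draws(fit_r),
                             moments, loss, horizon, n_rep, seed, priors,
                             carbon_factor)
  # map back to the input pixel order
  inv <- order(res$order)
  structure(list(grid = grid, flux = res$flux[inv, , , drop = FALSE],
                 params = lapply(res$params, function(p)
                   lapply(p, function(x) if (length(x) > 1) x[inv] else x)),
                 acs_min = res$acs_min[inv],
                 loss = loss, horizon = horizon, n_rep = n_rep, seed = seed,
                 moments = moments),
            class = "acs_prediction")
}

#' Predict the five cumulative fluxes for a single pixel
#'
#' Single-pixel convenience wrapper around [predict_recovery_map()].
#'
#' @param pixel one-row data.frame with `acs0`, `prec`, `seas`, `bd`.
#' @inheritParams predict_recovery_map
#' @return matrix `n_rep x 5` of cumulative changes (Mg C ha^-1) at the
#'   horizon.
#' @export
pixel_predict <- function(pixel, fit_s, fit_r, moments, loss = 40,
                          horizon = 10, n_rep = 200, seed = 1,
                          priors = acs_priors()) {
  g <- data.frame(row = 1, col = 1, pixel[1, c("acs0", "prec", "seas", "bd")])
  pred <- predict_recovery_map(fit_s, fit_r, g, moments, loss, horizon,
                               n_rep, seed, priors)
  t(pred$flux[1, , ])
}

#' Net carbon recovery from the five cumulative fluxes
#'
#' The net ACS change is the sum of all five cumulative ACS changes
#' (gains are positive, losses negative).
#'
#' @param flux numeric vector of five changes, or a matrix/array whose last
#'   named dimension holds the five fluxes (`cSg`, `cSl`, `cRr`, `cRg`,
#'   `cRl`).
#' @return numeric: the sum over fluxes, preserving the remaining dimensions.
#' @export
net_recovery <- function(flux) {
  if (is.null(dim(flux))) return(sum(flux))
  d <- dim(flux)
  if (length(d) == 2) return(rowSums(flux))
  apply(flux, c(1, 3), sum)  # pixels x reps
}

#' Per-pixel summaries of a Monte-Carlo prediction
#'
#' Per pixel across replicates: median, mean, sd and coefficient of variation
#' (sd / |mean|) of net recovery, plus the median of each flux. The CV is
#' `NA` (flagged undefined) where the mean is within `tol` of zero. Map-wide
#' area fractions by CV band (share of pixels with CV < 0.4 and CV > 0.5)
#' summarize prediction uncertainty.
#'
#' @param pred an `acs_prediction`.
#' @param tol mean magnitude below which the CV is undefined.
#' @return data.frame, one row per pixel, with attribute `cv_bands`
#'   (`frac_below_40`, `frac_above_50`).
#' @export
summarize_grid <- function(pred, tol = 1e-8) {
  stopifnot(inherits(pred, "acs_prediction"), pred$n_rep >= 2)
  net <- net_recovery(pred$flux)            # pixels x reps
  out <- pred$grid[, c("row", "col")]
  out$net_median <- apply(net, 1, stats::median)
  out$net_mean <- rowMeans(net)
  out$net_sd <- apply(net, 1, stats::sd)
  out$cv <- ifelse(abs(out$net_mean) < tol, NA_real_,
                   out$net_sd / abs(out$net_mean))
  if (anyNA(out$cv))
    warning("CV undefined for ", sum(is.na(out$cv)),
            " pixel(s) with near-zero mean net recovery")
  for (v in dimnames(pred$flux)[[2]])
    out[[paste0(v, "_median")]] <- apply(pred$flux[, v, , drop = FALSE], 1,
                                         stats::median)
  ok <- !is.na(out$cv)
  attr(out, "cv_bands") <- c(frac_below_40 = mean(out$cv[ok] < 0.40),
                             frac_above_50 = mean(out$cv[ok] > 0.50))
  out
}

# evaluate regional flux trajectories for one replicate over a pixel mask
.region_trajectory <- function(params, mask, horizons) {
  sapply(horizons, function(tt) {
    f <- .eval_fluxes(lapply(params, function(x)
      if (length(x) > 1) x[mask] else x), tt)
    colMeans(f)
  })
}

#' Regional aggregation of a prediction
#'
#' For each region (a logical pixel mask or an index vector): net recovery at
#' the prediction horizon, both as mean +/- sd over pixels (of per-pixel
#' replicate medians) and as mean +/- sd across replicates (of regional
#' means); the survivors' contribution to the sum of ACS gains,
#' cSg / (cSg + cRr + cRg); and regional mean flux trajectories over a
#' horizon grid, flagged where they extend beyond the calibration period.
#'
#' @param pred an `acs_prediction`.
#' @param masks named list of logical vectors (length = pixels) or integer
#'   index vectors.
#' @param horizons trajectory evaluation times, years; default `0:30`.
#' @param calibration_limit years beyond which trajectories are flagged
#'   out-of-calibration; default 30.
#' @return list with `summary` (one row per region) and `trajectories`
#'   (long data.frame: region, t, flux, mean cumulative change,
#'   `out_of_calibration` flag).
#' @export
regional_summary <- function(pred, masks, horizons = 0:30,
                             calibration_limit = 30) {
  stopifnot(inherits(pred, "acs_prediction"))
  P <- dim(pred$flux)[1]
  net <- net_recovery(pred$flux)
  rows <- list(); traj <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (is.logical(m)) { stopifnot(length(m) == P); m <- which(m) }
    if (!length(m)) stop("empty mask for region '", nm, "'")
    if (any(m < 1 | m > P)) stop("mask outside grid extent for '", nm, "'")
    px_med <- apply(net[m, , drop = FALSE], 1, stats::median)
    rep_mean <- colMeans(net[m, , drop = FALSE])
    gains <- apply(pred$flux[m, c("cSg", "cRr", "cRg"), , drop = FALSE],
                   2, mean)  # regional+replicate mean per gain flux
    share <- gains[["cSg"]] / sum(gains)
    rows[[nm]] <- data.frame(
      region = nm, n_pixels = length(m),
      net_mean_pixels = mean(px_med), net_sd_pixels = stats::sd(px_med),
      net_mean_reps = mean(rep_mean), net_sd_reps = stats::sd(rep_mean),
      survivors_share = share)
    tr <- lapply(pred$params, .region_trajectory, mask = m,
                 horizons = horizons)
    tr_mean <- Reduce(`+`, tr) / length(tr)   # 5 fluxes x horizons
    traj[[nm]] <- data.frame(
      region = nm,
      t = rep(horizons, each = 5),
      flux = rep(rownames(tr_mean), length(horizons)),
      cumulative = as.numeric(tr_mean),
      out_of_calibration = rep(horizons > calibration_limit, each = 5))
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       trajectories = do.call(rbind, c(traj, make.row.names = FALSE)))
}

#' @export
print.acs_prediction <- function(x, ...) {
  cat("Monte-Carlo ACS recovery prediction\n")
  cat(sprintf("  %d pixels, %d replicates, %g%% loss, %g-year horizon\n",
              dim(x$flux)[1], x$n_rep, x$loss, x$horizon))
  net <- net_recovery(x$flux)
  med <- apply(net, 1, stats::median)
  cat(sprintf("  net recovery (per-pixel medians): mean %.1f, sd %.2f Mg C/ha\n",
              mean(med), stats::sd(med)))
  invisible(x)
}
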