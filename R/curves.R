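#' Survivors' cumulative flux mean curve
#'
#' The cumulative ACS change of the survivor cohort (growth or mortality loss)
#' follows a saturating exponential, \eqn{\alpha (1 - e^{-\beta t})}: change
#' is proportional to the change over the previous interval, so the cumulative
#' series converges monotonically to the finite limit \eqn{\alpha} (all
#' survivor carbon turned over) at rate \eqn{\beta} (yr^-1). The curve reaches
#' 95\% of its asymptote at \eqn{t_{0.95} = \ln(20)/\beta}.
#'
#' @param alpha asymptote, Mg C ha^-1 (positive for growth, negative for
#'   loss).
#' @param beta convergence rate, yr^-1 (> 0).
#' @param t years since the start of the recovery period (>= 0). Vectorised.
#' @return cumulative ACS change, Mg C ha^-1.
#' @export
survivor_cumulative_mean <- function(alpha, beta, t) {
  if (any(beta <= 0)) stop("'beta' must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  alpha * (1 - exp(-beta * t))
}

#' Covariate-dependent convergence rate
#'
#' The plot-level convergence rate is a deterministic linear function of the
#' six standardized covariates: \eqn{\beta_j = \beta_0 + \sum_l \lambda_l
#' V_{jl}}. At the calibration covariate means (all V = 0) the rate is the
#' baseline \eqn{\beta_0}; a negative coefficient slows convergence.
#'
#' @param beta0 baseline rate, yr^-1.
#' @param lambda numeric vector of six covariate coefficients (yr^-1 per sd).
#' @param V numeric vector of six standardized covariates, or a matrix with
#'   six columns (one row per plot).
#' @return rate(s), yr^-1. No positivity constraint is applied here; the
#'   samplers and predictors enforce the prior support.
#' @export
survivor_rate <- function(beta0, lambda, V) {
  if (is.matrix(V)) {
    stopifnot(ncol(V) == length(lambda))
    return(beta0 + drop(V %*% lambda))
  }
  stopifnot(length(V) == length(lambda))
  beta0 + sum(lambda * V)
}

#' Survivors' loss asymptote from the carbon-closure constraint
#'
#' Once every survivor has died, all the carbon the cohort gained by growth
#' (\eqn{\alpha_{Sg}}) plus its initial stock (`acs_min`) has been lost, so
#' the loss asymptote is fully determined:
#' \eqn{\alpha_{Sl} = -(\alpha_{Sg} + acs_{min})}. The constraint
#' \eqn{\alpha_{Sl} + \alpha_{Sg} + acs_{min} = 0} therefore holds exactly in
#' every parameter configuration the package emits.
#'
#' @param alpha_sg survivors' growth asymptote, Mg C ha^-1 (>= 0).
#' @param acs_min plot ACS at the start of the recovery period, Mg C ha^-1.
#' @return the (negative) loss asymptote, Mg C ha^-1.
#' @export
survivor_loss_asymptote <- function(alpha_sg, acs_min) {
  -(alpha_sg + acs_min)
}

#' Recruits' annual flux mean curve
#'
#' Annual ACS changes of the recruit cohort converge to a dynamic-equilibrium
#' value \eqn{\alpha} (Mg C ha^-1 yr^-1). Recruits' growth and mortality start
#' at zero (there are no recruits yet at t0) and rise as
#' \eqn{\alpha(1 - e^{-\beta t})}, i.e. `eta = -1`. Newly recruited carbon is
#' elevated at t0 by the post-logging competition drop and decays to its
#' asymptote as \eqn{\alpha(1 + \eta e^{-\beta t})} with `eta > 0`.
#'
#' @param alpha asymptotic annual change, Mg C ha^-1 yr^-1.
#' @param beta convergence rate, yr^-1 (> 0).
#' @param eta initial-recruitment multiplier: exactly -1 for growth/loss
#'   fluxes, > 0 for new-recruit carbon.
#' @param t years since the start of the recovery period. Vectorised.
#' @return annual ACS change, Mg C ha^-1 yr^-1.
#' @export
recruit_annual_mean <- function(alpha, beta, eta, t) {
  if (any(beta <= 0)) stop("'beta' must be positive")
  if (!(identical(all.equal(eta, -1), TRUE) || eta > 0))
    stop("'eta' must be -1 (growth/loss fluxes) or > 0 (new recruits)")
  alpha * (1 + eta * exp(-beta * t))
}

#' Recruits' cumulative flux mean curve
#'
#' Time-integral of [recruit_annual_mean()] from 0 to t:
#' \eqn{\alpha (t + \eta (1 - e^{-\beta t}) / \beta)}, in Mg C ha^-1. For
#' `eta = -1` the large-t slope is \eqn{\alpha}, the equilibrium annual
#' change.
#'
#' @inheritParams recruit_annual_mean
#' @return cumulative ACS change, Mg C ha^-1.
#' @export
recruit_cumulative_mean <- function(alpha, beta, eta, t) {
  if (any(beta <= 0)) stop("'beta' must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  if (!(identical(all.equal(eta, -1), TRUE) || eta > 0))
    stop("'eta' must be -1 (growth/loss fluxes) or > 0 (new recruits)")
  alpha * (t + eta * (1 - exp(-beta * t)) / beta)
}

#' Recruits' loss asymptote from the dynamic-equilibrium constraint
#'
#' At equilibrium the carbon gained annually by recruitment and recruits'
#' growth is exactly offset by recruits' mortality:
#' \eqn{\alpha_{Rr} + \alpha_{Rg} + \alpha_{Rl} = 0}, so
#' \eqn{\alpha_{Rl} = -(\alpha_{Rr} + \alpha_{Rg})}, holding exactly by
#' construction.
#'
#' @param alpha_rr new-recruit asymptote, Mg C ha^-1 yr^-1 (> 0).
#' @param alpha_rg recruits'-growth asymptote, Mg C ha^-1 yr^-1 (> 0).
#' @return the (negative) recruits'-loss asymptote, Mg C ha^-1 yr^-1.
#' @export
recruit_loss_asymptote <- function(alpha_rr, alpha_rg) {
  -(alpha_rr + alpha_rg)
}

#' Weighted Gaussian log-likelihood of a cumulative flux series
#'
#' Observations are cumulative ACS changes; each contributes its normal
#' log-density around the model mean curve multiplied by the plot weight
#' (a power likelihood; weights are proportional to plot area and normalised
#' to mean 1 upstream).
#'
#' @param obs data.frame with columns `plot_id`, `t`, `y` (observed cumulative
#'   change) and `weight`.
#' @param alpha named numeric vector of per-plot asymptotes (names = plot
#'   ids). For recruit fluxes, per-plot values of the site-level asymptote.
#' @param beta named numeric vector of per-plot rates.
#' @param sigma_e residual sd (> 0).
#' @param kind one of `"Sg"`, `"Sl"`, `"Rr"`, `"Rg"`, `"Rl"`.
#' @param eta initial-recruitment multiplier (used for recruit fluxes;
#'   `"Rg"`/`"Rl"` force -1).
#' @return the weighted log-likelihood (scalar).
#' @export
weighted_loglik <- function(obs, alpha, beta, sigma_e, kind, eta = -1) {
  kind <- match.arg(kind, c("Sg", "Sl", "Rr", "Rg", "Rl"))
  if (sigma_e <= 0) stop("'sigma_e' must be positive")
  id <- as.character(obs$plot_id)
  a <- alpha[id]; b <- beta[id]
  if (anyNA(a) || anyNA(b)) stop("missing parameters for some plots")
  mu <- if (kind %in% c("Sg", "Sl")) {
    survivor_cumulative_mean(a, b, obs$t)
  } else {
    e <- if (kind == "Rr") eta else -1
    recruit_cumulative_mean(a, b, e, obs$t)
  }
  sum(obs$weight * stats::dnorm(obs$y, mu, sigma_e, log = TRUE))
}
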