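#' Prior specification for the flux models
#'
#' Returns the uniform prior supports used by [fit_survivors()] and
#' [fit_recruits()], together with the justification each bound encodes in
#' terms of ecologically plausible quantities (asymptote ranges and the
#' 95\%-convergence time \eqn{t_{0.95} = \ln(20)/\beta}):
#'
#' * `alpha_Sg` U\[25, 250\]: about 100 survivors per ha storing 0.25--2.5
#'   Mg C each (upper bound 100 x 2.5 = 250).
#' * `beta_Sg` U\[0.015, 0.04\]: 75 < t0.95 < 200 yr.
#' * `beta_Sl` U\[0.006, beta_Sg\]: survivors' loss converges more slowly than
#'   their growth, t0.95 < 500 yr; the upper bound is the plot's own growth
#'   rate (ordered rates).
#' * `alpha_Rr` U\[0.1, 1\] and `alpha_Rg` U\[0.5, 3\]: ranges of observed
#'   annual changes in unlogged reference stands.
#' * `beta_Rr` U\[0.006, 0.6\]: 5 < t0.95 < 500 yr.
#' * `eta` U\[0, 3\]: initial recruitment bounded by a small multiple of its
#'   equilibrium value.
#' * `beta_Rg` U\[0.006, 0.15\]: 20 < t0.95 < 500 yr.
#' * `beta_Rl` U\[0.003, 0.06\]: 50 < t0.95 < 1000 yr.
#' * `lambda_loss` U\[-beta0, beta0\] and the five other coefficients
#'   U\[-beta0/4, beta0/4\] per sub-model, limiting collinearity artifacts.
#'
#' Hyperprior scales for the standard deviations the model statement leaves
#' open (`sigma_alpha`, `sigma_beta`, `sigma_E`: half-normal) are part of the
#' specification and can be overridden.
#'
#' @param sigma_alpha_sg,sigma_e_s half-normal scales for the survivors'
#'   between-plot asymptote sd and residual sd (Mg C ha^-1).
#' @param sigma_alpha_r,sigma_e_r half-normal scales for the recruits'
#'   between-site asymptote sd and residual sd.
#' @param sigma_beta_r half-normal scale for the recruits' between-plot rate
#'   sd (yr^-1).
#' @return a list of `c(lower, upper)` supports and hyperprior scales, class
#'   `acs_priors`.
#' @export
acs_priors <- function(sigma_alpha_sg = 50, sigma_e_s = 10,
                       sigma_alpha_r = 1, sigma_e_r = 5,
                       sigma_beta_r = 0.05) {
  structure(list(
    alpha_Sg = c(25, 250),
    beta_Sg  = c(0.015, 0.04),
    beta_Sl  = c(0.006, NA),   # upper bound: the plot's beta_Sg
    alpha_Rr = c(0.1, 1),
    beta_Rr  = c(0.006, 0.6),
    eta      = c(0, 3),
    alpha_Rg = c(0.5, 3),
    beta_Rg  = c(0.006, 0.15),
    beta_Rl  = c(0.003, 0.06),
    lambda_loss_factor = 1,    # |lambda_loss| <= beta0
    lambda_other_factor = 1/4, # |lambda_l| <= beta0/4, l != loss
    sigma_alpha_sg = sigma_alpha_sg,
    sigma_e_s = sigma_e_s,
    sigma_alpha_r = sigma_alpha_r,
    sigma_e_r = sigma_e_r,
    sigma_beta_r = sigma_beta_r
  ), class = "acs_priors")
}

#' 95\%-convergence time of a saturating flux
#'
#' Time at which \eqn{\alpha(1 - e^{-\beta t})} reaches 95\% of its asymptote:
#' \eqn{t_{0.95} = \ln(20)/\beta}.
#'
#' @param beta convergence rate, yr^-1 (> 0). Vectorised.
#' @return time in years.
#' @export
t095 <- function(beta) {
  if (any(beta <= 0)) stop("'beta' must be positive")
  log(20) / beta
}
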