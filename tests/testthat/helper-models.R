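## shared fixtures, all built in code

unit_square_of <- function(model, ...) {
  rp <- rescale_to_unit_diffusion(model)
  to_unit_time(transform_drift(rp, compute_time_warp(rp, ...)))
}

## constant boundaries 0 / width, constant drift
const_bounds_model <- function(mu0 = 0, width = 1, tau = 2, sigma = 1) {
  force(mu0); force(width)
  decision_model(
    sigma = sigma,
    mu = function(t, x) mu0 + 0 * t + 0 * x,
    mu_x = function(t, x) 0 * t + 0 * x,
    alpha = function(t) 0 * t, beta = function(t) width + 0 * t,
    dalpha = function(t) 0 * t, dbeta = function(t) 0 * t,
    tau = tau,
    mu_affine = function(t) list(m0 = mu0 + 0 * t, m1 = 0 * t),
    name = "const_bounds")
}

family_ctors <- list(
  hyperbolic = list(fn = hyperbolic_drift_family, N = 5L),
  linear_space = list(fn = linear_space_drift_family, N = 3L),
  collapsing = list(fn = collapsing_bounds_family, N = 4L))

corner_center_models <- function(fam) {
  info <- family_ctors[[fam]]
  lapply(list(rep(-1, info$N), rep(1, info$N), rep(0, info$N)), info$fn)
}
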