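#' Decision model in original coordinates
#'
#' A diffusion decision model: the SDE `dX_t = mu(t, X_t) dt + sigma dW_t`
#' started at `y`, absorbed at the lower boundary `alpha(t)` or the upper
#' boundary `beta(t)`, observed up to the horizon `tau`. The quantity of
#' interest is `F(tau, y)`, the probability that the lower boundary is hit
#' first, no later than `tau`.
#'
#' All functional fields must be vectorized over their arguments, and the
#' boundary derivatives and the spatial drift derivative are required in
#' closed form (no numeric differentiation is performed anywhere downstream).
#'
#' @param sigma diffusion coefficient, `sigma > 0`.
#' @param mu drift `function(t, x)`.
#' @param mu_x spatial derivative of the drift, `function(t, x)`.
#' @param alpha,beta lower/upper boundary `function(t)` with `alpha < beta`
#'   on `[0, tau]`.
#' @param dalpha,dbeta first derivatives of the boundaries, `function(t)`.
#' @param tau horizon, `tau > 0`.
#' @param y0 optional initial value in `[alpha(0), beta(0)]`.
#' @param mu_affine optional `function(t)` returning `list(m0, m1)` such that
#'   `mu(t, x) = m0 + m1 * x` (vectorized over `t`); enables the compiled
#'   Monte-Carlo path simulator.
#' @param name optional label.
#' @return an object of class `decision_model`.
#' @seealso [hyperbolic_drift_family()], [linear_space_drift_family()],
#'   [collapsing_bounds_family()], [rescale_to_unit_diffusion()]
#' @export
decision_model <- function(sigma, mu, mu_x, alpha, beta, dalpha, dbeta, tau,
                           y0 = NULL, mu_affine = NULL, name = "custom") {
  if (!is.numeric(sigma) || sigma <= 0) stop_domain("sigma must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop_domain("tau must be > 0")
  tchk <- seq(0, tau, length.out = 201L)
  if (!all(alpha(tchk) < beta(tchk)))
    stop_domain("invalid boundaries: alpha(t) >= beta(t) somewhere on [0, tau]")
  if (!is.null(y0) && (y0 < alpha(0) || y0 > beta(0)))
    stop_domain("y0 outside [alpha(0), beta(0)]")
  structure(list(sigma = sigma, mu = mu, mu_x = mu_x,
                 alpha = alpha, beta = beta, dalpha = dalpha, dbeta = dbeta,
                 tau = tau, y0 = y0, mu_affine = mu_affine, name = name),
            class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  cat("<decision_model>", x$name, "\n")
  cat("  sigma =", x$sigma, " tau =", x$tau, "\n")
  cat("  start interval [alpha(0), beta(0)] = [",
      x$alpha(0), ",", x$beta(0), "]\n")
  invisible(x)
}

#' Parameter box for a model family
#'
#' Holds the per-parameter ranges of a family and the affine bijection
#' between the physical box and the reference cube `[-1, 1]^N`.
#'
#' @param names character vector of parameter labels.
#' @param lo,hi numeric range endpoints, `lo < hi` componentwise.
#' @return an object of class `parameter_box`.
#' @export
parameter_box <- function(names, lo, hi) {
  stopifnot(length(names) == length(lo), length(lo) == length(hi))
  if (!all(lo < hi)) stop_domain("parameter box requires lo < hi componentwise")
  structure(list(names = names, lo = lo, hi = hi, N = length(names)),
            class = "parameter_box")
}

#' Map reference coordinates to physical parameters (and back)
#'
#' @param box a [parameter_box()].
#' @param rho point in `[-1, 1]^N`.
#' @return `box_map`: named numeric vector of physical parameters;
#'   `box_unmap`: point in `[-1, 1]^N`.
#' @export
box_map <- function(box, rho) {
  if (length(rho) != box$N) stop_domain("rho has wrong dimension")
  if (any(rho < -1 - 1e-12) || any(rho > 1 + 1e-12))
    stop_domain("rho outside [-1, 1]^N")
  setNames(box$lo + (rho + 1) / 2 * (box$hi - box$lo), box$names)
}

#' @rdname box_map
#' @param theta named or plain numeric vector of physical parameters.
#' @export
box_unmap <- function(box, theta) {
  if (length(theta) != box$N) stop_domain("theta has wrong dimension")
  2 * (unname(theta) - box$lo) / (box$hi - box$lo) - 1
}

#' Published model families
#'
#' Three parametric families of decision models from the neuroscience
#' literature, each defined on the reference cube `[-1, 1]^N` via its
#' parameter box (see `*_box()` companions):
#'
#' * `hyperbolic_drift_family()` (N = 5): time-dependent hyperbolic drift
#'   `mu(t, x) = mu0 + mu1 * t / (t + t0)`, constant boundaries `0` and
#'   `beta0`; ranges `mu0 in [-1.97, -1.64]`, `mu1 in [-2.31, -0.99]`,
#'   `t0 in [0.13, 0.40]`, `beta0 in [1.38, 2.26]`, `tau in [0.1, 2.5]`.
#' * `linear_space_family()` (N = 3): space-dependent linear drift
#'   `mu(t, x) = mu0 + mu1 * (beta0 - x)`, constant boundaries `0`, `beta0`,
#'   fixed `tau = 2.5`; ranges `mu0 in [-2, 2]`, `mu1 in [-4, 4]`,
#'   `beta0 in [0.5, 2]`.
#' * `collapsing_bounds_family()` (N = 4): constant drift `mu0` with linearly
#'   collapsing boundaries `alpha(t) = beta0 * t / (2 T0)`,
#'   `beta(t) = beta0 * (1 - t / (2 T0))`; ranges `mu0 in [-5.86, 0]`,
#'   `beta0 in [0.56, 3.93]`, `T0 in [3, 20]`, `tau in [0.1, 2.5]`;
#'   requires `tau < T0` (boundaries meet at `t = T0`).
#'
#' All families use `sigma = 1`. Parameter order inside `rho` is the order
#' listed above. Explicit-parameter constructors (`*_model()`) are also
#' provided.
#'
#' @param rho point in `[-1, 1]^N`.
#' @return a [decision_model()].
#' @name model_families
NULL

#' @rdname model_families
#' @export
hyperbolic_drift_box <- function() {
  parameter_box(c("mu0", "mu1", "t0", "beta0", "tau"),
                lo = c(-1.97, -2.31, 0.13, 1.38, 0.1),
                hi = c(-1.64, -0.99, 0.40, 2.26, 2.5))
}

#' @rdname model_families
#' @param mu0,mu1,t0,beta0,T0,tau explicit physical parameters.
#' @export
hyperbolic_drift_model <- function(mu0, mu1, t0, beta0, tau) {
  force(mu0); force(mu1); force(t0); force(beta0)
  decision_model(
    sigma = 1,
    mu = function(t, x) (mu0 + mu1 * t / (t + t0)) + 0 * x,
    mu_x = function(t, x) 0 * t + 0 * x,
    alpha = function(t) 0 * t, beta = function(t) beta0 + 0 * t,
    dalpha = function(t) 0 * t, dbeta = function(t) 0 * t,
    tau = tau,
    mu_affine = function(t) list(m0 = mu0 + mu1 * t / (t + t0), m1 = 0 * t),
    name = "hyperbolic_drift")
}

#' @rdname model_families
#' @export
hyperbolic_drift_family <- function(rho) {
  p <- box_map(hyperbolic_drift_box(), rho)
  hyperbolic_drift_model(p[["mu0"]], p[["mu1"]], p[["t0"]], p[["beta0"]],
                         p[["tau"]])
}

#' @rdname model_families
#' @export
linear_space_box <- function() {
  parameter_box(c("mu0", "mu1", "beta0"),
                lo = c(-2, -4, 0.5), hi = c(2, 4, 2))
}

#' @rdname model_families
#' @export
linear_space_model <- function(mu0, mu1, beta0, tau = 2.5) {
  force(mu0); force(mu1); force(beta0)
  decision_model(
    sigma = 1,
    mu = function(t, x) mu0 + mu1 * (beta0 - x) + 0 * t,
    mu_x = function(t, x) -mu1 + 0 * t + 0 * x,
    alpha = function(t) 0 * t, beta = function(t) beta0 + 0 * t,
    dalpha = function(t) 0 * t, dbeta = function(t) 0 * t,
    tau = tau,
    mu_affine = function(t) list(m0 = (mu0 + mu1 * beta0) + 0 * t,
                                 m1 = -mu1 + 0 * t),
    name = "linear_space_drift")
}

#' @rdname model_families
#' @export
linear_space_drift_family <- function(rho) {
  p <- box_map(linear_space_box(), rho)
  linear_space_model(p[["mu0"]], p[["mu1"]], p[["beta0"]])
}

#' @rdname model_families
#' @export
collapsing_bounds_box <- function() {
  parameter_box(c("mu0", "beta0", "T0", "tau"),
                lo = c(-5.86, 0.56, 3, 0.1), hi = c(0, 3.93, 20, 2.5))
}

#' @rdname model_families
#' @export
collapsing_bounds_model <- function(mu0, beta0, T0, tau, sigma = 1) {
  force(mu0); force(beta0); force(T0)
  if (tau >= T0)
    stop_domain("collapsing boundaries meet at t = T0; need tau < T0")
  decision_model(
    sigma = sigma,
    mu = function(t, x) mu0 + 0 * t + 0 * x,
    mu_x = function(t, x) 0 * t + 0 * x,
    alpha = function(t) beta0 * t / (2 * T0),
    beta = function(t) beta0 * (1 - t / (2 * T0)),
    dalpha = function(t) beta0 / (2 * T0) + 0 * t,
    dbeta = function(t) -beta0 / (2 * T0) + 0 * t,
    tau = tau,
    mu_affine = function(t) list(m0 = mu0 + 0 * t, m1 = 0 * t),
    name = "collapsing_bounds")
}

#' @rdname model_families
#' @export
collapsing_bounds_family <- function(rho) {
  p <- box_map(collapsing_bounds_box(), rho)
  collapsing_bounds_model(p[["mu0"]], p[["beta0"]], p[["T0"]], p[["tau"]])
}

#' Rescale a decision model to unit diffusion
#'
#' Substitutes `Ttilde = sigma^2 * tau / 2` and reverses time, so that the
#' hitting-probability PDE becomes a unit-diffusion advection-diffusion
#' problem on the strip between `a(ttilde) < b(ttilde)`:
#' `a(ttilde) = alpha((2/sigma^2) (Ttilde - ttilde))` (same for `b` from
#' `beta`) and `vtilde(ttilde, x) = (2/sigma^2) mu((2/sigma^2)(Ttilde -
#' ttilde), x)`. Boundary derivatives pick up the chain-rule factor
#' `-2/sigma^2`. All later stages work exclusively in rescaled time.
#'
#' @param model a [decision_model()].
#' @return an object of class `rescaled_problem` with fields `Ttilde`, `a`,
#'   `b`, `da`, `db`, `vtilde`, `vtilde_x` and the originating `model`.
#' @export
rescale_to_unit_diffusion <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  s2 <- model$sigma^2
  Ttilde <- s2 * model$tau / 2
  back <- function(tt) (2 / s2) * (Ttilde - tt)   # rescaled -> original time
  a <- function(tt) model$alpha(back(tt))
  b <- function(tt) model$beta(back(tt))
  da <- function(tt) -(2 / s2) * model$dalpha(back(tt))
  db <- function(tt) -(2 / s2) * model$dbeta(back(tt))
  vtilde <- function(tt, x) (2 / s2) * model$mu(back(tt), x)
  vtilde_x <- function(tt, x) (2 / s2) * model$mu_x(back(tt), x)
  tchk <- seq(0, Ttilde, length.out = 201L)
  if (!all(a(tchk) < b(tchk)))
    stop_domain("invalid boundaries: a(ttilde) >= b(ttilde) on [0, Ttilde]")
  structure(list(Ttilde = Ttilde, a = a, b = b, da = da, db = db,
                 vtilde = vtilde, vtilde_x = vtilde_x,
                 sigma = model$sigma, model = model),
            class = "rescaled_problem")
}

#' Reflect a decision model about x = 0
#'
#' The solver computes lower-boundary absorption probabilities. Upper-boundary
#' probabilities of `model` equal lower-boundary probabilities of the
#' reflected model returned here (`x -> -x`, so the roles of the boundaries
#' swap and the drift flips sign).
#'
#' @param model a [decision_model()].
#' @return the reflected [decision_model()].
#' @export
reflect_model <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  m <- model
  aff <- if (is.null(m$mu_affine)) NULL else function(t) {
    co <- m$mu_affine(t)
    list(m0 = -co$m0, m1 = co$m1)
  }
  decision_model(
    sigma = m$sigma,
    mu = function(t, x) -m$mu(t, -x),
    mu_x = function(t, x) m$mu_x(t, -x),
    alpha = function(t) -m$beta(t), beta = function(t) -m$alpha(t),
    dalpha = function(t) -m$dbeta(t), dbeta = function(t) -m$dalpha(t),
    tau = m$tau, y0 = if (is.null(m$y0)) NULL else -m$y0,
    mu_affine = aff, name = paste0(m$name, "_reflected"))
}
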