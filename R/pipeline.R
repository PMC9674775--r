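#' Solve a decision model end to end
#'
#' Runs the full deterministic pipeline: rescale to unit diffusion, compute
#' the time warp, transform the drift to the unit square, evaluate the
#' constant-drift reference series, assemble and solve the minimal-residual
#' system for the smooth remainder, and wire up evaluators for
#' `uhat = u(v0) + e` and the first-passage probability `F(tau, y)`.
#'
#' @param model a [decision_model()].
#' @param n mesh cells per direction (`h = 1/n`).
#' @param lambda `"auto"` or a numeric coercivity shift.
#' @param quad_order cell Gauss order.
#' @param series_tol truncation tolerance of the reference series.
#' @param warp_tol quadrature tolerance of the time warp.
#' @return an object of class `fpt_solution` with the intermediate objects,
#'   vectorized evaluators `uhat(t, x)`, `F(y)`, `utilde(ttilde, xtilde)`,
#'   and the discrete X-norm of the computed remainder (`xnorm_e`).
#' @examples
#' \donttest{
#' model <- collapsing_bounds_model(mu0 = 0, beta0 = 3.93, T0 = 3, tau = 2.5)
#' fit <- fpt_solve(model, n = 32)
#' fit$F(1.965)   # start midway between the boundaries
#' }
#' @export
fpt_solve <- function(model, n = 64L, lambda = "auto", quad_order = 4L,
                      series_tol = 1e-12, warp_tol = 1e-10) {
  stopifnot(inherits(model, "decision_model"))
  rp <- rescale_to_unit_diffusion(model)
  warp <- compute_time_warp(rp, tol = warp_tol)
  usp <- to_unit_time(transform_drift(rp, warp))
  sol <- solve_residual_problem(usp, n, lambda = lambda,
                                quad_order = quad_order,
                                series_tol = series_tol)
  field <- sol$field
  u0 <- sol$u0
  uhat <- function(t, x) eval_u0(u0, t, x) + eval_fem_field(field, t, x)
  pb <- pullback_first_passage(uhat, model, warp)
  structure(list(model = model, rescaled = rp, warp = warp, problem = usp,
                 field = field, system = sol$system, u0 = u0,
                 uhat = uhat, F = pb$F, utilde = pb$utilde,
                 n = as.integer(n), lambda = attr(field, "lambda"),
                 xnorm_e = xnorm(field, sol$system)),
            class = "fpt_solution")
}

#' @export
print.fpt_solution <- function(x, ...) {
  cat("<fpt_solution>", x$model$name, "\n")
  cat("  T =", signif(x$problem$T, 6), " v0 =", signif(x$problem$v0, 6),
      " lambda =", signif(x$lambda, 4), " n =", x$n, "\n")
  cat("  ||e_h||_X =", signif(x$xnorm_e, 6),
      " block residual =", signif(attr(x$field, "block_residual"), 3), "\n")
  invisible(x)
}

model_to_unit_square <- function(model, warp_tol = 1e-10) {
  rp <- rescale_to_unit_diffusion(model)
  to_unit_time(transform_drift(rp, compute_time_warp(rp, tol = warp_tol)))
}

#' Mesh-convergence study over a set of models
#'
#' Reproduces the error-versus-h protocol of the numerical experiments: for
#' each model, consecutive-mesh differences `||e_{h/2} - e_h||` in the
#' discrete X-norm; reported per `h` is the maximum over the models, with
#' the least-squares order fitted on the maxima.
#'
#' @param models list of [decision_model()]s (e.g. parameter-box corners and
#'   center of one family).
#' @param n_list dyadic mesh sizes.
#' @param ... passed to [convergence_study()].
#' @return `data.frame(n, h, err_X, rate)` of the per-`h` maxima; attribute
#'   `"slope"` carries the fitted order.
#' @export
fpt_convergence <- function(models, n_list = c(4L, 8L, 16L, 32L, 64L), ...) {
  errs <- vapply(models, function(m) {
    convergence_study(model_to_unit_square(m), n_list, ...)$err_X
  }, numeric(length(n_list)))
  err <- apply(matrix(errs, nrow = length(n_list)), 1L, max)
  rate <- c(NA, log2(err[-length(err)] / err[-1L]))
  out <- data.frame(n = n_list, h = 1 / n_list, err_X = err, rate = rate)
  ok <- err > 1e-13
  attr(out, "slope") <- if (sum(ok) >= 2L)
    unname(coef(lm(log(err[ok]) ~ log(1 / n_list[ok])))[2L]) else NA_real_
  out
}

#' Sparse-interpolation error study for a model family
#'
#' Convenience front end to [interp_error_study()] taking a family
#' constructor on `[-1, 1]^N`.
#'
#' @inheritParams interp_error_study
#' @export
fpt_interp <- function(family, N, q_list, n = 16L, test_set = NULL,
                       include_zero = FALSE) {
  interp_error_study(family, N, q_list, n, test_set = test_set,
                     include_zero = include_zero)
}

#' Validate the pipeline against the Monte-Carlo reference
#'
#' @param cases list of `list(model = <decision_model>, y = <start value>)`.
#' @param n mesh cells for the deterministic solves.
#' @param plan a [simulation_plan()]; its seed is advanced by the case index
#'   so the cases use independent streams but remain reproducible.
#' @param c_h discretization-allowance constant of the agreement band.
#' @return `data.frame` with one row per case (see
#'   [crosscheck_first_passage()]), plus the model name.
#' @export
fpt_validate <- function(cases, n = 64L, plan = simulation_plan(), c_h = 1) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    fit <- fpt_solve(cs$model, n = n)
    pl <- plan
    pl$seed <- plan$seed + i - 1L
    cbind(data.frame(model = cs$model$name),
          crosscheck_first_passage(cs$model, cs$y, fit$F, plan = pl,
                                   h = 1 / n, c_h = c_h))
  })
  do.call(rbind, rows)
}

#' Build a decision model from a configuration list or file
#'
#' Configuration is a named list (or a YAML file parsed into one) with a
#' `family` entry: one of `"hyperbolic"`, `"linear_space"`, `"collapsing"`,
#' or `"custom"`. Built-in families take either `rho` (reference cube
#' coordinates) or the explicit parameters of their constructors. A custom
#' family supplies `sigma`, `tau` and expression strings `mu`, `mu_x`,
#' `alpha`, `beta`, `dalpha`, `dbeta` in the variables `t` and `x`, parsed
#' by the safe arithmetic evaluator ([safe_function_tx()]), plus an optional
#' `params` table of named constants.
#'
#' @param config named list, or path to a YAML file (requires the `yaml`
#'   package).
#' @return a [decision_model()].
#' @export
model_from_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("reading config files requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  fam <- config$family
  if (is.null(fam)) stop_domain("config needs a 'family' entry")
  get_params <- function(ctor, box) {
    if (!is.null(config$rho)) return(ctor(as.numeric(config$rho)))
    args <- config[box$names[box$names %in% names(config)]]
    missing <- setdiff(box$names, names(args))
    if (fam == "linear_space") missing <- setdiff(missing, "tau")
    if (length(missing))
      stop_domain("config missing parameters: ", paste(missing, collapse = ", "))
    NULL
  }
  switch(fam,
    hyperbolic = {
      got <- get_params(hyperbolic_drift_family, hyperbolic_drift_box())
      if (!is.null(got)) got
      else hyperbolic_drift_model(config$mu0, config$mu1, config$t0,
                                  config$beta0, config$tau)
    },
    linear_space = {
      got <- get_params(linear_space_drift_family, linear_space_box())
      if (!is.null(got)) got
      else linear_space_model(config$mu0, config$mu1, config$beta0,
                              tau = if (is.null(config$tau)) 2.5 else config$tau)
    },
    collapsing = {
      got <- get_params(collapsing_bounds_family, collapsing_bounds_box())
      if (!is.null(got)) got
      else collapsing_bounds_model(config$mu0, config$beta0, config$T0,
                                   config$tau)
    },
    custom = {
      pars <- if (is.null(config$params)) list() else config$params
      fx <- function(key) safe_function_tx(config[[key]], pars)
      ft <- function(key) {
        g <- safe_function_tx(config[[key]], pars)
        function(t) g(t, 0 * t)
      }
      decision_model(sigma = config$sigma, mu = fx("mu"), mu_x = fx("mu_x"),
                     alpha = ft("alpha"), beta = ft("beta"),
                     dalpha = ft("dalpha"), dbeta = ft("dbeta"),
                     tau = config$tau, y0 = config$y0, name = "custom")
    },
    stop_domain("unknown family: ", fam))
}
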