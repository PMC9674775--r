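#' Compute the time warp flattening moving boundaries
#'
#' The substitution `theta' (t) = (b(theta(t)) - a(theta(t)))^2`, `theta(0) = 0`
#' maps the moving-boundary strip to a fixed-width strip. Its inverse is the
#' explicit integral `theta_inv(ttilde) = int_0^ttilde |b - a|^{-2}`, which is
#' evaluated here by adaptive quadrature accumulated over a reference grid;
#' `theta` itself is recovered by a monotone cubic interpolant of the sampled
#' inverse plus Newton refinement per query (the ODE form supplies the exact
#' Newton derivative). The warped horizon is `T = theta_inv(Ttilde)`.
#'
#' @param problem a `rescaled_problem` from [rescale_to_unit_diffusion()].
#' @param tol absolute quadrature tolerance; the round-trip error
#'   `|theta(theta_inv(ttilde)) - ttilde|` is kept below `10 * tol * (1 + Ttilde)`.
#' @param n_grid number of reference-grid nodes.
#' @return an object of class `time_warp` with fields `T`, `Ttilde`,
#'   `theta`, `theta_inv`, `dtheta` (all vectorized).
#' @export
compute_time_warp <- function(problem, tol = 1e-10, n_grid = 257L) {
  stopifnot(inherits(problem, "rescaled_problem"))
  a <- problem$a; b <- problem$b
  Ttilde <- problem$Ttilde
  gap <- function(tt) b(tt) - a(tt)
  tt_grid <- seq(0, Ttilde, length.out = n_grid)
  gmin <- min(gap(seq(0, Ttilde, length.out = 4L * n_grid)))
  if (gmin <= sqrt(.Machine$double.eps) * (1 + abs(Ttilde)))
    stop_domain("boundaries meet before Ttilde; time warp integral diverges")
  integrand <- function(s) gap(s)^-2

  piece <- vapply(seq_len(n_grid - 1L), function(i) {
    integrate(integrand, tt_grid[i], tt_grid[i + 1L],
              rel.tol = tol, abs.tol = tol)$value
  }, numeric(1))
  chi_grid <- c(0, cumsum(piece))           # theta_inv at the grid nodes
  Tw <- chi_grid[n_grid]

  theta_inv <- function(ttilde) {
    ttilde <- pmin(pmax(ttilde, 0), Ttilde)
    idx <- pmin(findInterval(ttilde, tt_grid), n_grid - 1L)
    base <- chi_grid[idx]
    corr <- vapply(seq_along(ttilde), function(k) {
      lo <- tt_grid[idx[k]]
      if (ttilde[k] <= lo) return(0)
      integrate(integrand, lo, ttilde[k], rel.tol = tol, abs.tol = tol)$value
    }, numeric(1))
    base + corr
  }

  ## monotone interpolant of the sampled inverse, used only as Newton seed
  theta_seed <- splinefun(chi_grid, tt_grid, method = "hyman")
  theta <- function(t) {
    t <- pmin(pmax(t, 0), Tw)
    y <- pmin(pmax(theta_seed(t), 0), Ttilde)
    for (it in 1:12) {
      r <- theta_inv(y) - t
      if (all(abs(r) <= tol * (1 + Ttilde))) break
      y <- pmin(pmax(y - r * gap(y)^2, 0), Ttilde)
    }
    y
  }
  dtheta <- function(t) gap(theta(t))^2

  structure(list(T = Tw, Ttilde = Ttilde, theta = theta,
                 theta_inv = theta_inv, dtheta = dtheta, tol = tol),
            class = "time_warp")
}

#' Closed-form warp for linearly collapsing boundaries
#'
#' For boundaries collapsing linearly toward each other
#' (`alpha(t) = beta0 t / (2 T0)`, `beta(t) = beta0 (1 - t / (2 T0))`) the
#' warp integral has the closed forms
#' `theta_inv(ttilde) = sigma^4 T0^2 ttilde / (beta0^2 (sigma^2 T0 - 2 Ttilde)
#' (sigma^2 T0 - 2 Ttilde + 2 ttilde))`,
#' `T = sigma^2 T0 Ttilde / (beta0^2 (sigma^2 T0 - 2 Ttilde))`, and
#' `theta(t) = beta0^2 (sigma^2 T0 - 2 Ttilde)^2 t /
#' (sigma^4 T0^2 - 2 beta0^2 (sigma^2 T0 - 2 Ttilde) t)`.
#' Valid for `Ttilde < sigma^2 T0 / 2`.
#'
#' @param beta0,T0 collapse parameters (`> 0`).
#' @param sigma diffusion coefficient of the original model.
#' @param Ttilde rescaled horizon `sigma^2 tau / 2`.
#' @return a `time_warp` object, interchangeable with [compute_time_warp()].
#' @export
closed_form_collapsing_warp <- function(beta0, T0, sigma = 1, Ttilde) {
  if (Ttilde >= sigma^2 * T0 / 2)
    stop_domain("horizon too large: need Ttilde < sigma^2 * T0 / 2")
  g <- sigma^2 * T0 - 2 * Ttilde                 # > 0
  A <- beta0^2 * g^2
  B <- sigma^4 * T0^2
  Cc <- 2 * beta0^2 * g
  Tw <- sigma^2 * T0 * Ttilde / (beta0^2 * g)
  theta_inv <- function(ttilde) B * ttilde / (beta0^2 * g * (g + 2 * ttilde))
  theta <- function(t) A * t / (B - Cc * t)
  dtheta <- function(t) A * B / (B - Cc * t)^2
  structure(list(T = Tw, Ttilde = Ttilde, theta = theta,
                 theta_inv = theta_inv, dtheta = dtheta, tol = 0),
            class = "time_warp")
}

#' @export
print.time_warp <- function(x, ...) {
  cat("<time_warp> Ttilde =", x$Ttilde, "-> T =", x$T, "\n")
  invisible(x)
}

#' Transform the drift to the fixed-width strip
#'
#' Composes the rescaled problem with a time warp, producing the drift of the
#' problem on `(0, T) x (0, 1)`:
#' `v(t, x) = (b - a)(theta(t)) * [vtilde(theta(t), xi) + (1 - x) a'(theta(t))
#' + x b'(theta(t))]` with `xi = (1 - x) a + x b`. The corner value
#' `v0 = v(0, 0)` is the constant drift whose reference solution is later
#' subtracted.
#'
#' @param problem a `rescaled_problem`.
#' @param warp a `time_warp` consistent with `problem`.
#' @return an object of class `transformed_problem` with vectorized fields
#'   `v`, `v_x`, the corner value `v0`, horizon `T`, the warp, and the affine
#'   space map `xi(ttilde, x)`.
#' @export
transform_drift <- function(problem, warp) {
  stopifnot(inherits(problem, "rescaled_problem"), inherits(warp, "time_warp"))
  a <- problem$a; b <- problem$b; da <- problem$da; db <- problem$db
  vt <- problem$vtilde; vtx <- problem$vtilde_x
  xi <- function(ttilde, x) (1 - x) * a(ttilde) + x * b(ttilde)
  v_at_theta <- function(th, x) {
    ba <- b(th) - a(th)
    ba * (vt(th, (1 - x) * a(th) + x * b(th)) +
            (1 - x) * da(th) + x * db(th))
  }
  vx_at_theta <- function(th, x) {
    ba <- b(th) - a(th)
    ba * (ba * vtx(th, (1 - x) * a(th) + x * b(th)) + (db(th) - da(th)))
  }
  v <- function(t, x) v_at_theta(warp$theta(t), x)
  v_x <- function(t, x) vx_at_theta(warp$theta(t), x)
  structure(list(T = warp$T, v = v, v_x = v_x,
                 v_at_theta = v_at_theta, vx_at_theta = vx_at_theta,
                 v0 = v_at_theta(warp$theta(0), 0),
                 warp = warp, xi = xi, rescaled = problem),
            class = "transformed_problem")
}

#' Rescale the warped problem to unit time
#'
#' Final substitution `t -> t T` putting the problem on the unit square
#' `(0, 1)^2`; the PDE becomes `du/dt = T [d2u/dx2 + vhat du/dx]` with
#' `vhat(t, x) = v(t T, x)`. Grid evaluation (`vhat_grid`) shares the warp
#' queries across a tensor grid, which the assembler exploits.
#'
#' @param problem a `transformed_problem`.
#' @return an object of class `unit_square_problem` with fields `T`, `v0`,
#'   `vhat(t, x)`, `vhat_x(t, x)`, and `vhat_grid(t, x)`/`vhat_x_grid(t, x)`
#'   returning `length(t) x length(x)` matrices.
#' @export
to_unit_time <- function(problem) {
  stopifnot(inherits(problem, "transformed_problem"))
  Tw <- problem$T
  warp <- problem$warp
  grid_of <- function(f_at_theta) {
    function(t, x) {
      th <- warp$theta(t * Tw)
      TH <- matrix(th, nrow = length(t), ncol = length(x))
      X <- matrix(x, nrow = length(t), ncol = length(x), byrow = TRUE)
      f_at_theta(TH, X)
    }
  }
  structure(list(
    T = Tw, v0 = problem$v0,
    vhat = function(t, x) problem$v(t * Tw, x),
    vhat_x = function(t, x) problem$v_x(t * Tw, x),
    vhat_grid = grid_of(problem$v_at_theta),
    vhat_x_grid = grid_of(problem$vx_at_theta),
    transformed = problem), class = "unit_square_problem")
}

#' @export
print.unit_square_problem <- function(x, ...) {
  cat("<unit_square_problem> T =", x$T, " v0 =", x$v0, "\n")
  invisible(x)
}

#' Pull a unit-square solution back to first-passage probabilities
#'
#' Given an evaluator of the unit-square solution `uhat(t, x)`, returns the
#' first-passage probability `F(tau, y) = uhat(1, (y - alpha(0)) /
#' (beta(0) - alpha(0)))` for starting values `y` in `[alpha(0), beta(0)]`,
#' together with a general interior evaluator
#' `utilde(ttilde, xtilde) = uhat(theta_inv(ttilde)/T,
#' (xtilde - a(ttilde))/(b(ttilde) - a(ttilde)))` in rescaled coordinates.
#'
#' @param uhat_eval vectorized `function(t, x)` on `[0, 1]^2`.
#' @param model the originating [decision_model()].
#' @param warp the `time_warp` used in the pipeline.
#' @return `list(F = function(y), utilde = function(ttilde, xtilde))`.
#' @export
pullback_first_passage <- function(uhat_eval, model, warp) {
  rp <- rescale_to_unit_diffusion(model)
  a0 <- model$alpha(0); b0 <- model$beta(0)
  F_fun <- function(y) {
    if (any(y < a0 - 1e-12) || any(y > b0 + 1e-12))
      stop_domain("y outside [alpha(0), beta(0)]")
    x <- pmin(pmax((y - a0) / (b0 - a0), 0), 1)
    uhat_eval(rep(1, length(x)), x)
  }
  utilde <- function(ttilde, xtilde) {
    t <- warp$theta_inv(ttilde) / warp$T
    lo <- rp$a(ttilde); hi <- rp$b(ttilde)
    if (any(xtilde < lo - 1e-12) || any(xtilde > hi + 1e-12))
      stop_domain("xtilde outside [a(ttilde), b(ttilde)]")
    x <- pmin(pmax((xtilde - lo) / (hi - lo), 0), 1)
    uhat_eval(t, x)
  }
  list(F = F_fun, utilde = utilde)
}
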