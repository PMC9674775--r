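#' Heat layer carrying the corner singularity
#'
#' `u_H(t, x) = Erfc(x / (2 sqrt(t)))`, the solution of the heat equation on
#' the half line that is 0 at `t = 0` and 1 at `x = 0`. It carries exactly
#' the discontinuity between initial and boundary data that makes the raw
#' hitting-probability PDE non-smooth at the corner `(0, 0)`.
#'
#' @param t,x vectors (recycled); `x >= 0`, with `t <= 0, x > 0` returning
#'   the limit value 0 and `t <= 0, x <= 0` an error.
#' @return values of `u_H`.
#' @export
heat_layer <- function(t, x) {
  n <- max(length(t), length(x))
  t <- rep_len(t, n); x <- rep_len(x, n)
  if (any(t <= 0 & x <= 0))
    stop_domain("heat layer undefined at t <= 0, x <= 0")
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- erfc_(x[pos] / (2 * sqrt(t[pos])))
  out[!pos] <- 0
  out
}

#' Stationary profile of the constant-drift problem
#'
#' The `t -> infinity` limit of the constant-drift absorption problem:
#' `(exp(-v0 x) - exp(-v0)) / (1 - exp(-v0))`, continuously extended to
#' `1 - x` at `v0 = 0`. This is also the classical probability that a
#' Brownian motion with drift exits `(0, 1)` through the lower endpoint.
#'
#' @param v0 constant drift.
#' @param x positions in `[0, 1]`.
#' @return profile values; 1 at `x = 0`, 0 at `x = 1`.
#' @export
steady_profile <- function(v0, x) {
  if (abs(v0) < 1e-300) return(1 - x)
  ## expm1 keeps this stable uniformly in v0, including |v0| << 1
  (expm1(-v0 * x) - expm1(-v0)) / (-expm1(-v0))
}

#' Constant-drift reference solution
#'
#' Evaluator of `uhat(v0, T)`, the solution on the unit square of
#' `du/dt = T [d2u/dx2 + v0 du/dx]` with `u(t,0) = 1`, `u(t,1) = 0`,
#' `u(0,x) = 0`. Two independent rapidly converging series are used:
#'
#' * a spectral (long-time) expansion
#'   `u = u_inf(x) - sum_n b_n e^{-v0 x / 2} sin(n pi x)
#'    e^{-(n^2 pi^2 + v0^2/4) s}` in physical time `s = T t`, whose
#'   coefficients collapse to the closed form
#'   `b_n = 2 n pi / (v0^2/4 + n^2 pi^2)`;
#' * an image (short-time) expansion obtained from the exponential tilt
#'   `u = u_inf + e^{-v0 x/2 - v0^2 s/4} psi(s, x)` with `psi` solving the
#'   pure heat equation, expanded over the Dirichlet images of `(0, 1)`;
#'   every term is a tilted Erfc/Gaussian layer in closed form.
#'
#' The evaluator switches between the two at `switch_t` (unit time); each
#' side then needs only a few dozen terms at `tol = 1e-12`, and the overlap
#' band provides a mutual cross-check used in the tests.
#'
#' @param v0 constant drift (the corner value of the transformed drift).
#' @param T time-scale factor of the unit-square problem.
#' @param tol absolute truncation tolerance.
#' @param switch_t series switchover point in unit time; default
#'   `0.05 / (T * pi^2)`, i.e. physical time `0.05 / pi^2`.
#' @return an object of class `constant_drift_solution`.
#' @export
constant_drift_solution <- function(v0, T, tol = 1e-12, switch_t = NULL) {
  stopifnot(T > 0, tol > 0)
  if (is.null(switch_t)) switch_t <- 0.05 / (T * pi^2)
  structure(list(v0 = v0, T = T, tol = tol, switch_t = switch_t),
            class = "constant_drift_solution")
}

#' @export
print.constant_drift_solution <- function(x, ...) {
  cat("<constant_drift_solution> v0 =", x$v0, " T =", x$T,
      " tol =", x$tol, "\n")
  invisible(x)
}

## long-time (spectral) branch, physical time s = T * t
u0_long <- function(v0, s, x, tol) {
  q <- v0^2 / 4
  smin <- min(s)
  nmax <- 2L
  while (nmax < 4000L &&
         (2 / (nmax * pi)) * exp(abs(v0) / 2 - (nmax^2 * pi^2 + q) * smin) >
           0.1 * tol) {
    nmax <- nmax + 1L
  }
  if (nmax >= 4000L)
    stop_domain("constant-drift series: tolerance not reachable (s too small ",
                "for the spectral branch; lower switch_t)")
  acc <- steady_profile(v0, x)
  tilt <- exp(-v0 * x / 2)
  for (n in seq_len(nmax)) {
    bn <- 2 * n * pi / (q + n^2 * pi^2)
    acc <- acc - bn * tilt * sin(n * pi * x) * exp(-(n^2 * pi^2 + q) * s)
  }
  acc
}

## 0.5*(erf((1-m)/(2 sqrt(s))) + erf(m/(2 sqrt(s)))) = int_0^1 K(s, y - m) dy
phi_window <- function(s, m) {
  rs <- 2 * sqrt(s)
  0.5 * (erf_((1 - m) / rs) + erf_(m / rs))
}

## short-time (image) branch, physical time s = T * t
u0_short <- function(v0, s, x, tol) {
  smax <- max(s)
  a2 <- abs(v0) / 2
  K <- ceiling(1 + sqrt(4 * smax * log(1 / tol)) / 2 + a2 * smax) + 1L
  K <- min(K, 40L)
  psi <- numeric(length(s))
  if (abs(v0) >= 1e-8) {
    Acoef <- c(-1, exp(-v0)) / (-expm1(-v0))
    acoef <- c(-v0 / 2, v0 / 2)
    for (k in -K:K) {
      z <- x - 2 * k
      for (j in 1:2) {
        aj <- acoef[j]
        psi <- psi + Acoef[j] *
          (exp(aj * z + aj^2 * s) * phi_window(s, z + 2 * aj * s) -
             exp(-aj * z + aj^2 * s) * phi_window(s, -z + 2 * aj * s))
      }
    }
  } else {
    ## v0 = 0: g(y) = y - 1, integrals against the heat kernel in closed form
    for (k in -K:K) {
      z <- x - 2 * k
      direct <- -sqrt(s / pi) * (exp(-(1 - z)^2 / (4 * s)) -
                                   exp(-z^2 / (4 * s))) +
        (z - 1) * phi_window(s, z)
      refl <- -sqrt(s / pi) * (exp(-(1 + z)^2 / (4 * s)) -
                                 exp(-z^2 / (4 * s))) -
        (z + 1) * phi_window(s, -z)
      psi <- psi + direct - refl
    }
  }
  steady_profile(v0, x) + exp(-v0 * x / 2 - v0^2 * s / 4) * psi
}

#' Evaluate the constant-drift reference solution
#'
#' @param sol a [constant_drift_solution()].
#' @param t,x coordinates in `[0, 1]` (vectors, recycled to a common length).
#' @param force_branch `NA` for the automatic switch, `"long"` or `"short"`
#'   to force one series (used for cross-validation).
#' @return values of `uhat(v0, T)(t, x)`.
#' @export
eval_u0 <- function(sol, t, x, force_branch = NA) {
  stopifnot(inherits(sol, "constant_drift_solution"))
  n <- max(length(t), length(x))
  t <- rep_len(t, n); x <- rep_len(x, n)
  out <- numeric(n)
  s <- sol$T * t
  corner <- s < 1e-14
  lo <- x <= 1e-14 & !corner
  hi <- x >= 1 - 1e-14 & !corner
  out[corner] <- ifelse(x[corner] <= 1e-14, 1, 0)
  out[lo] <- 1
  out[hi] <- 0
  inner <- !(corner | lo | hi)
  if (any(inner)) {
    use_long <- if (is.na(force_branch)) t >= sol$switch_t
                else rep(force_branch == "long", n)
    il <- inner & use_long
    is <- inner & !use_long
    if (any(il)) out[il] <- u0_long(sol$v0, s[il], x[il], sol$tol)
    if (any(is)) out[is] <- u0_short(sol$v0, s[is], x[is], sol$tol)
  }
  out
}

#' @rdname eval_u0
#' @return `eval_u0_grid`: a `length(t) x length(x)` matrix.
#' @export
eval_u0_grid <- function(sol, t, x, force_branch = NA) {
  tm <- rep(t, times = length(x))
  xm <- rep(x, each = length(t))
  matrix(eval_u0(sol, tm, xm, force_branch = force_branch),
         nrow = length(t), ncol = length(x))
}

#' Finite-difference residual of the reference series
#'
#' Verification helper: evaluates `|du/dt - T (d2u/dx2 + v0 du/dx)|` on an
#' interior grid, with derivatives taken by central differences of the
#' series itself. Small residuals confirm that the two series actually solve
#' the constant-drift PDE; used in the test-suite only.
#'
#' @param sol a [constant_drift_solution()].
#' @param t,x interior grid vectors (all points at distance `> step` from
#'   the boundary of the unit square).
#' @param step finite-difference step.
#' @return the maximal absolute residual over the grid.
#' @export
residual_check <- function(sol, t, x, step = 1e-4) {
  stopifnot(min(t) > step, min(x) > step, max(x) < 1 - step)
  tm <- rep(t, times = length(x))
  xm <- rep(x, each = length(t))
  u <- function(tt, xx) eval_u0(sol, tt, xx)
  ut <- (u(tm + step, xm) - u(tm - step, xm)) / (2 * step)
  uxx <- (u(tm, xm + step) - 2 * u(tm, xm) + u(tm, xm - step)) / step^2
  ux <- (u(tm, xm + step) - u(tm, xm - step)) / (2 * step)
  max(abs(ut - sol$T * (uxx + sol$v0 * ux)))
}
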