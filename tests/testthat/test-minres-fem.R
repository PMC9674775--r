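## dense reference assembly by straightforward per-cell Gauss quadrature,
## independent of the vectorized sparse assembler
dense_reference <- function(usp, n, quad_order = 5L) {
  h <- 1 / n
  gr <- firstpassage:::gauss_rule_01(quad_order)
  dimX <- (n + 1) * (n - 1); dimY <- 2 * n * (n - 1)
  hat_t <- function(i, t) pmax(0, 1 - abs(t * n - i))
  dhat_t <- function(i, t) ifelse(t * n >= i - 1 & t * n < i, n,
                                  ifelse(t * n >= i & t * n <= i + 1, -n, 0))
  Bd <- matrix(0, dimY, dimX); Ad <- matrix(0, dimY, dimY)
  for (k in 1:n) for (m in 1:n) {
    for (qa in seq_along(gr$nodes)) for (qb in seq_along(gr$nodes)) {
      t <- (k - 1 + gr$nodes[qa]) * h; x <- (m - 1 + gr$nodes[qb]) * h
      W <- gr$weights[qa] * gr$weights[qb] * h^2
      v <- usp$vhat(t, x)
      ## test functions supported here
      phi <- numeric(dimY); dphi_x <- numeric(dimY)
      for (a in 1:2) for (j in c(m - 1, m)) {
        if (j < 1 || j > n - 1) next
        row <- (k - 1) * 2 * (n - 1) + (a - 1) * (n - 1) + j
        tv <- if (a == 1) 1 - (t * n - (k - 1)) else t * n - (k - 1)
        phi[row] <- tv * pmax(0, 1 - abs(x * n - j))
        dphi_x[row] <- tv * ifelse(x * n < j, n, -n)
      }
      psi <- numeric(dimX); dpsi_t <- numeric(dimX); dpsi_x <- numeric(dimX)
      for (i in c(k - 1, k)) for (j in c(m - 1, m)) {
        if (j < 1 || j > n - 1) next
        col <- i * (n - 1) + j
        xs <- pmax(0, 1 - abs(x * n - j))
        dxs <- ifelse(x * n < j, n, -n)
        psi[col] <- hat_t(i, t) * xs
        dpsi_t[col] <- dhat_t(i, t) * xs
        dpsi_x[col] <- hat_t(i, t) * dxs
      }
      Bd <- Bd + W * (outer(phi, dpsi_t) + usp$T * outer(dphi_x, dpsi_x) -
                        usp$T * v * outer(phi, dpsi_x))
      Ad <- Ad + W * outer(dphi_x, dphi_x)
    }
  }
  list(Bd = Bd, Ad = Ad)
}

test_that("discrete X-norm matches a dense-quadrature reference", {
  usp <- unit_square_of(linear_space_model(-1, -2, 0.8))
  n <- 4L
  sys <- assemble_system(usp, n, lambda = 0)
  ref <- dense_reference(usp, n)
  set.seed(31)
  w <- rnorm(sys$dimX)
  r <- ref$Bd %*% w
  val_ref <- sqrt(drop(t(r) %*% solve(ref$Ad, r)) +
                    drop(t(w) %*% as.matrix(sys$C) %*% w))
  expect_equal(xnorm(w, sys), val_ref, tolerance = 1e-10)
  ## the form matrix itself agrees entrywise
  expect_lt(max(abs(as.matrix(sys$B0) - ref$Bd)), 1e-12)
})

test_that("Gauss quadrature is exact for the polynomial drifts used here", {
  usp <- unit_square_of(linear_space_model(1, 1.5, 1))
  s4 <- assemble_system(usp, 6, lambda = 0, quad_order = 4)
  s5 <- assemble_system(usp, 6, lambda = 0, quad_order = 5)
  expect_lt(max(abs(s4$B0 - s5$B0)), 1e-12)
  expect_lt(max(abs(s4$As - s5$As)), 1e-12)
  ## the forcing integrand contains the non-polynomial reference solution,
  ## so orders only agree up to the quadrature error of its smooth part
  expect_lt(max(abs(s4$f - s5$f)), 1e-3)
})

test_that("initial-trace matrix annihilates fields vanishing at t = 0", {
  usp <- unit_square_of(const_bounds_model(0.5, 1, 2))
  n <- 6L
  sys <- assemble_system(usp, n, lambda = 0)
  w <- c(numeric(n - 1), rnorm((n) * (n - 1)))
  expect_equal(max(abs(sys$C %*% w)), 0)
})

test_that("solver is exact for trial-space manufactured solutions", {
  usp <- unit_square_of(linear_space_model(-2, -4, 0.5))
  n <- 8L
  sys <- assemble_system(usp, n, lambda = 0)
  set.seed(32)
  wstar <- c(numeric(n - 1), rnorm(n * (n - 1)))
  f <- as.numeric(sys$B0 %*% wstar)
  wh <- solve_minres(sys, f = f)
  expect_lt(max(abs(wh$coef - wstar)), 1e-10)
  expect_lt(attr(wh, "block_residual"), 1e-10)
  ## zero forcing and linearity
  w0 <- solve_minres(sys, f = numeric(sys$dimY))
  expect_equal(max(abs(w0$coef)), 0)
  w2 <- solve_minres(sys, f = 2 * f)
  expect_equal(w2$coef, 2 * wh$coef, tolerance = 1e-10)
})

test_that("smooth manufactured solutions are quasi-optimally approximated", {
  usp <- unit_square_of(const_bounds_model(-0.4, 1, 2))
  wfun <- function(t, x) t * sin(pi * x)
  wt <- function(t, x) sin(pi * x) + 0 * t
  wx <- function(t, x) pi * t * cos(pi * x)
  for (n in c(8L, 16L, 32L)) {
    f <- manufactured_forcing(usp, n, wfun, wt, wx)
    sys <- assemble_system(usp, n, lambda = 0)
    wh <- solve_minres(sys, f = f)
    nf <- 2L * n
    sysf <- assemble_system(usp, nf, lambda = 0)
    wref <- nodal_interpolant(usp, nf, wfun)
    e_solve <- xnorm(prolong_field(wh, nf)$coef - wref$coef, sysf)
    e_interp <- xnorm(prolong_field(nodal_interpolant(usp, n, wfun), nf)$coef -
                        wref$coef, sysf)
    expect_lt(e_solve, 5 * e_interp)
  }
})

test_that("coercivity shift activates only for destabilizing drift gradients", {
  expect_equal(auto_shift(unit_square_of(const_bounds_model(-2, 1, 2))), 0)
  expect_equal(auto_shift(unit_square_of(linear_space_model(-2, -4, 0.5))), 0)
  usp <- unit_square_of(linear_space_model(2, 4, 2))   # dvhat/dx = -32
  lam <- auto_shift(usp)
  expect_equal(lam, usp$T * (32 - pi^2) / 2, tolerance = 1e-8)
  ## the shifted solve still meets its optimality system to round-off
  n <- 8L
  sys <- assemble_system(usp, n)
  expect_gt(sys$lambda, 0)
  fit <- solve_minres(sys)
  expect_lt(attr(fit, "block_residual"), 1e-10)
  ## without the shift the energy matrix is indefinite
  expect_error(solve_minres(assemble_system(usp, n, lambda = 0)),
               "positive definite")
})

test_that("zero-drift solutions inherit the symmetry of the forcing", {
  usp <- unit_square_of(const_bounds_model(0, 1, 2))
  n <- 8L
  f <- manufactured_forcing(usp, n,
                            function(t, x) t * x * (1 - x),
                            function(t, x) x * (1 - x) + 0 * t,
                            function(t, x) t * (1 - 2 * x))
  wh <- solve_minres(assemble_system(usp, n, lambda = 0), f = f)
  M <- matrix(wh$coef, nrow = n - 1)    # columns: time nodes
  expect_lt(max(abs(M - M[(n - 1):1, ])), 1e-12)
})

test_that("prolongation is exact nodal interpolation", {
  set.seed(33)
  fld <- fem_field(rnorm((5 + 1) * (5 - 1)), 5L)
  same <- prolong_field(fld, 5L)
  expect_equal(same$coef, fld$coef)
  fine <- prolong_field(fld, 20L)
  pts <- cbind(runif(50), runif(50))
  expect_equal(eval_fem_field(fine, pts[, 1], pts[, 2]),
               eval_fem_field(fld, pts[, 1], pts[, 2]), tolerance = 1e-13)
  fld2 <- fem_field(rnorm((5 + 1) * (5 - 1)), 5L)
  both <- prolong_field(fem_field(fld$coef + fld2$coef, 5L), 10L)
  expect_equal(both$coef,
               prolong_field(fld, 10L)$coef + prolong_field(fld2, 10L)$coef,
               tolerance = 1e-13)
  expect_error(prolong_field(fld, 12L), "multiple")
})

test_that("X-norm is a norm and errors decay under refinement", {
  usp <- unit_square_of(linear_space_model(-2, -4, 0.5))
  sys <- assemble_system(usp, 6, lambda = 0)
  expect_equal(xnorm(numeric(sys$dimX), sys), 0)
  set.seed(34)
  w <- rnorm(sys$dimX)
  expect_equal(xnorm(-2.5 * w, sys), 2.5 * xnorm(w, sys), tolerance = 1e-12)
  cs <- convergence_study(usp, c(8L, 16L, 32L))
  expect_true(all(diff(cs$err_X) < 0))
  ## constant drift equal to the corner value: e is identically zero
  cs0 <- convergence_study(unit_square_of(const_bounds_model(0.7, 1, 2)),
                           c(4L, 8L))
  expect_true(all(cs0$err_X <= 1e-12))
})
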