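test_that("time warp is the identity map for unit-width constant boundaries", {
  rp <- rescale_to_unit_diffusion(const_bounds_model(width = 1, tau = 2))
  w <- compute_time_warp(rp)
  expect_equal(w$T, rp$Ttilde, tolerance = 1e-12)
  t <- seq(0, w$T, length.out = 9)
  expect_equal(w$theta(t), t, tolerance = 1e-10)

  ## width 2: theta(t) = 4 t, T = Ttilde / 4
  rp2 <- rescale_to_unit_diffusion(const_bounds_model(width = 2, tau = 2))
  w2 <- compute_time_warp(rp2)
  expect_equal(w2$T, rp2$Ttilde / 4, tolerance = 1e-12)
  t2 <- seq(0, w2$T, length.out = 9)
  expect_equal(w2$theta(t2), 4 * t2, tolerance = 1e-10)
})

test_that("closed-form collapsing warp reproduces the worked-example values", {
  w <- closed_form_collapsing_warp(beta0 = 1, T0 = 1, sigma = 1, Ttilde = 0.25)
  expect_equal(w$T, 0.5, tolerance = 1e-14)
  expect_equal(w$theta_inv(0.25), 0.5, tolerance = 1e-14)
  expect_equal(w$theta(0), 0)
  expect_equal(w$theta(w$T), 0.25, tolerance = 1e-14)
  expect_error(closed_form_collapsing_warp(1, 1, 1, Ttilde = 0.6),
               "horizon too large")
})

test_that("quadrature warp agrees with the closed form on collapsing boundaries", {
  for (pars in list(c(2, 4, 1.5), c(0.56, 3, 2.4), c(3.93, 20, 0.1))) {
    m <- collapsing_bounds_model(0, pars[1], pars[2], pars[3])
    rp <- rescale_to_unit_diffusion(m)
    wq <- compute_time_warp(rp)
    wc <- closed_form_collapsing_warp(pars[1], pars[2], 1, rp$Ttilde)
    expect_equal(wq$T, wc$T, tolerance = 1e-10)
    tt <- seq(0, rp$Ttilde, length.out = 21)
    expect_equal(wq$theta_inv(tt), wc$theta_inv(tt), tolerance = 1e-10)
  }
})

test_that("warp round trip and monotonicity hold across the families", {
  set.seed(21)
  for (fam in names(family_ctors)) {
    info <- family_ctors[[fam]]
    for (k in 1:5) {
      rho <- runif(info$N, -1, 1)
      rp <- rescale_to_unit_diffusion(info$fn(rho))
      w <- compute_time_warp(rp)
      tt <- sort(runif(100, 0, rp$Ttilde))
      chi <- w$theta_inv(tt)
      expect_true(all(diff(chi) > 0))
      expect_lt(max(abs(w$theta(chi) - tt)), 1e-8 * (1 + rp$Ttilde))
    }
  }
})

test_that("drift transform has the stated closed forms", {
  ## constant unit boundaries, constant vtilde: identity transform
  m <- const_bounds_model(mu0 = 0.7, width = 1, tau = 2)
  rp <- rescale_to_unit_diffusion(m)
  tp <- transform_drift(rp, compute_time_warp(rp))
  expect_equal(tp$v0, 2 * 0.7, tolerance = 1e-12)   # vtilde = (2/sigma^2) mu
  expect_equal(tp$v(0.3, 0.6), 2 * 0.7, tolerance = 1e-12)

  ## constant boundaries of width 2, zero drift: no contribution at all
  m2 <- const_bounds_model(mu0 = 0, width = 2, tau = 2)
  rp2 <- rescale_to_unit_diffusion(m2)
  tp2 <- transform_drift(rp2, compute_time_warp(rp2))
  expect_equal(tp2$v(0.1, 0.8), 0, tolerance = 1e-13)

  ## collapsing boundaries: the boundary-motion part is (2x - 1) beta0 / T0
  m3 <- collapsing_bounds_model(0, 2, 5, 1.5)
  rp3 <- rescale_to_unit_diffusion(m3)
  w3 <- compute_time_warp(rp3)
  tp3 <- transform_drift(rp3, w3)
  for (pt in list(c(0.2, 0.3), c(0.6, 0.9))) {
    th <- w3$theta(pt[1])
    ba <- rp3$b(th) - rp3$a(th)
    expect_equal(tp3$v(pt[1], pt[2]) / ba, (2 * pt[2] - 1) * 2 / 5,
                 tolerance = 1e-10)
  }
})

test_that("unit-time rescaling substitutes t -> t T and keeps the corner value", {
  m <- hyperbolic_drift_family(rep(0.5, 5))
  rp <- rescale_to_unit_diffusion(m)
  tp <- transform_drift(rp, compute_time_warp(rp))
  usp <- to_unit_time(tp)
  expect_equal(usp$vhat(0.4, 0.3), tp$v(0.4 * tp$T, 0.3), tolerance = 1e-12)
  expect_equal(usp$vhat(0, 0), usp$v0, tolerance = 1e-12)
  g <- seq(0, 1, length.out = 64)
  V <- usp$vhat_grid(g, g)
  expect_true(all(is.finite(V)))
  ## grid evaluation consistent with pointwise evaluation
  expect_equal(V[5, 9], usp$vhat(g[5], g[9]), tolerance = 1e-12)
})

test_that("pull-back yields the boundary data of the hitting problem", {
  m <- const_bounds_model(mu0 = -0.5, width = 1.5, tau = 1)
  rp <- rescale_to_unit_diffusion(m)
  w <- compute_time_warp(rp)
  u0 <- constant_drift_solution(2 * (-0.5) * 1.5, w$T)
  uhat <- function(t, x) eval_u0(u0, t, x)
  pb <- pullback_first_passage(uhat, m, w)
  expect_equal(pb$F(0), 1)       # start on the lower boundary
  expect_equal(pb$F(1.5), 0)     # start on the upper boundary
  expect_error(pb$F(2), "outside")
  ## constant boundaries 0..1: F(tau, y) = uhat(1, y)
  m1 <- const_bounds_model(mu0 = 0.3, width = 1, tau = 1)
  w1 <- compute_time_warp(rescale_to_unit_diffusion(m1))
  u01 <- constant_drift_solution(0.6, w1$T)
  pb1 <- pullback_first_passage(function(t, x) eval_u0(u01, t, x), m1, w1)
  expect_equal(pb1$F(0.37), eval_u0(u01, 1, 0.37), tolerance = 1e-14)
})
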