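## Space-time minimal-residual Petrov-Galerkin solver on the unit square.
##
## Trial space X_h: continuous piecewise bilinears on a uniform n x n tensor
## mesh, zero at x = 0 and x = 1, free at t = 0 (the initial condition is
## imposed weakly through the trace mass matrix C).  dim = (n+1)(n-1),
## coefficient index = t_node * (n-1) + x_node, t_node = 0..n, x_node = 1..n-1.
##
## Test space Y_h: (discontinuous piecewise linear in time) x (same space
## hats).  dim = 2n(n-1), row index = (cell-1)*2(n-1) + (a-1)*(n-1) + x_node
## with a = 1, 2 the local linear time shape on the cell.  Y_h is block
## diagonal in time for every test-test operator, which the solver exploits:
## the saddle-point system is reduced to its Schur complement with per-cell
## dense factorizations.

trial_dim <- function(n) (n + 1L) * (n - 1L)
test_dim <- function(n) 2L * n * (n - 1L)

#' Coercivity shift for the minimal-residual solve
#'
#' The test-space energy form is coercive when the spatial advection term is
#' dominated; using the identity `int v w' w = -1/2 int (dv/dx) w^2` this
#' holds whenever `sup (-dvhat/dx)_+ < 2 pi^2`. When it fails, the solve is
#' performed on the exponentially shifted unknown `w exp(-lambda t)` with
#' `lambda = T * max(0, sup(-dvhat/dx)_+ - pi^2) / 2`, which restores
#' coercivity with constant 1/2; the public solution is transformed back.
#'
#' @param problem a `unit_square_problem`.
#' @param grid_n check-grid resolution per direction.
#' @return the shift `lambda >= 0`.
#' @export
auto_shift <- function(problem, grid_n = 33L) {
  g <- seq(0, 1, length.out = grid_n)
  vx <- problem$vhat_x_grid(g, g)
  m <- max(0, -min(vx))
  problem$T * max(0, m - pi^2) / 2
}

## local shape values at the tensor Gauss nodes of one reference cell
local_shapes <- function(n, quad_order) {
  gr <- gauss_rule_01(quad_order)
  q <- gr$nodes; nq <- length(q)
  h <- 1 / n
  ## index of quad combo: (qa - 1) * nq + qb  (time qa slower, space qb faster)
  qa <- rep(seq_len(nq), each = nq)
  qb <- rep(seq_len(nq), times = nq)
  W <- (gr$weights[qa] * gr$weights[qb]) * h^2
  P <- rbind(1 - q, q)              # local linear shapes at the nodes
  dP <- matrix(c(-n, n), 2, nq)     # their derivatives on a cell of width h
  list(nq = nq, qnodes = q, qa = qa, qb = qb, W = W, P = P, dP = dP, h = h)
}

## core assembler; returns the pieces requested in `want`
assemble_core <- function(problem, n, lambda, quad_order, u0, want_forcing) {
  stopifnot(inherits(problem, "unit_square_problem"), n >= 2L)
  Tw <- problem$T; v0 <- problem$v0
  ls <- local_shapes(n, quad_order)
  nq <- ls$nq; h <- ls$h
  tq <- as.vector(outer(ls$qnodes * h, (seq_len(n) - 1L) * h, "+")) # n*nq
  xq <- tq
  Vbig <- problem$vhat_grid(tq, xq)
  Vxbig <- problem$vhat_x_grid(tq, xq)

  ncell <- n * n
  cell_k <- rep(seq_len(n), each = n)
  cell_m <- rep(seq_len(n), times = n)
  nqq <- nq * nq
  Vc <- matrix(0, ncell, nqq)
  Vxc <- matrix(0, ncell, nqq)
  for (qi in seq_len(nqq)) {
    ridx <- (cell_k - 1L) * nq + ls$qa[qi]
    cidx <- (cell_m - 1L) * nq + ls$qb[qi]
    Vc[, qi] <- Vbig[cbind(ridx, cidx)]
    Vxc[, qi] <- Vxbig[cbind(ridx, cidx)]
  }

  ## per-quad-combo shape products for the 2 x 2 local bases
  Pt <- ls$P[, ls$qa, drop = FALSE]; dPt <- ls$dP[, ls$qa, drop = FALSE]
  Xs <- ls$P[, ls$qb, drop = FALSE]; dXs <- ls$dP[, ls$qb, drop = FALSE]

  node_x <- function(cloc) cell_m - 1L + (cloc - 1L)     # space node of local shape
  test_row <- function(a, cloc) {
    (cell_k - 1L) * 2L * (n - 1L) + (a - 1L) * (n - 1L) + node_x(cloc)
  }
  trial_col <- function(b, dloc) {
    (cell_k - 1L + (b - 1L)) * (n - 1L) + node_x(dloc)
  }
  xvalid <- function(cloc) {
    nx <- node_x(cloc); nx >= 1L & nx <= n - 1L
  }

  dimX <- trial_dim(n); dimY <- test_dim(n)
  ti_As <- tj_As <- tv_As <- vector("list", 16L)
  ti_B <- tj_B <- tv_B <- vector("list", 16L)
  tv_M <- vector("list", 16L)
  idx <- 0L
  for (a in 1:2) for (cc in 1:2) for (b in 1:2) for (d in 1:2) {
    idx <- idx + 1L
    ok <- xvalid(cc) & xvalid(d)
    if (!any(ok)) next
    PtPt <- Pt[a, ] * Pt[b, ]
    ## A_s (test x test): T dX dX - (T v/2)(dX X + X dX) + lambda X X
    cst_As <- sum(ls$W * (Tw * dXs[cc, ] * dXs[d, ] + lambda *
                            Xs[cc, ] * Xs[d, ]) * PtPt)
    cf_As <- -(Tw / 2) * ls$W * (dXs[d, ] * Xs[cc, ] + Xs[d, ] * dXs[cc, ]) * PtPt
    val_As <- cst_As + as.vector(Vc %*% cf_As)
    ## B (test a,cc x trial b,d): dt(w) z + T dx(w) dx(z) - T v dx(w) z
    cst_B <- sum(ls$W * (dPt[b, ] * Xs[d, ] * Pt[a, ] * Xs[cc, ] +
                           Tw * Pt[b, ] * dXs[d, ] * Pt[a, ] * dXs[cc, ]))
    cf_B <- -Tw * ls$W * Pt[b, ] * dXs[d, ] * Pt[a, ] * Xs[cc, ]
    val_B <- cst_B + as.vector(Vc %*% cf_B)
    cst_M <- sum(ls$W * Pt[b, ] * Xs[d, ] * Pt[a, ] * Xs[cc, ])

    ti_As[[idx]] <- test_row(a, cc)[ok]; tj_As[[idx]] <- test_row(b, d)[ok]
    tv_As[[idx]] <- val_As[ok]
    ti_B[[idx]] <- test_row(a, cc)[ok]; tj_B[[idx]] <- trial_col(b, d)[ok]
    tv_B[[idx]] <- val_B[ok]
    tv_M[[idx]] <- rep(cst_M, sum(ok))
  }
  As <- Matrix::sparseMatrix(i = unlist(ti_As), j = unlist(tj_As),
                             x = unlist(tv_As), dims = c(dimY, dimY))
  B0 <- Matrix::sparseMatrix(i = unlist(ti_B), j = unlist(tj_B),
                             x = unlist(tv_B), dims = c(dimY, dimX))
  Mmix <- if (lambda > 0) {
    Matrix::sparseMatrix(i = unlist(ti_B), j = unlist(tj_B),
                         x = unlist(tv_M), dims = c(dimY, dimX))
  } else NULL

  ## initial-trace mass: (t = 0 node selector) x 1D P1 mass in x
  jj <- seq_len(n - 1L)
  Ci <- c(jj, jj[-(n - 1L)], jj[-1L])
  Cj <- c(jj, jj[-1L], jj[-(n - 1L)])
  Cx <- c(rep(2 * h / 3, n - 1L), rep(h / 6, 2L * (n - 2L)))
  C <- Matrix::sparseMatrix(i = Ci, j = Cj, x = Cx, dims = c(dimX, dimX))

  f <- NULL
  if (want_forcing) {
    stopifnot(inherits(u0, "constant_drift_solution"))
    U0big <- eval_u0_grid(u0, tq, xq)
    U0c <- matrix(0, ncell, nqq)
    for (qi in seq_len(nqq)) {
      ridx <- (cell_k - 1L) * nq + ls$qa[qi]
      cidx <- (cell_m - 1L) * nq + ls$qb[qi]
      U0c[, qi] <- U0big[cbind(ridx, cidx)]
    }
    El <- if (lambda > 0) {
      Elm <- matrix(0, ncell, nqq)
      for (qi in seq_len(nqq)) {
        Elm[, qi] <- exp(-lambda * tq[(cell_k - 1L) * nq + ls$qa[qi]])
      }
      Elm
    } else 1
    M1 <- U0c * Vxc; M2 <- U0c * (Vc - v0)
    if (lambda > 0) { M1 <- M1 * El; M2 <- M2 * El }
    f <- numeric(dimY)
    for (a in 1:2) for (cc in 1:2) {
      ok <- xvalid(cc)
      w1 <- -Tw * ls$W * Pt[a, ] * Xs[cc, ]
      w2 <- -Tw * ls$W * Pt[a, ] * dXs[cc, ]
      vals <- as.vector(M1 %*% w1) + as.vector(M2 %*% w2)
      rows <- test_row(a, cc)
      f[rows[ok]] <- f[rows[ok]] + vals[ok]
    }
  }

  ## dense Cholesky of the interior 1D stiffness, for the X-norm evaluations
  Kx <- diag(2 * n, n - 1L)
  if (n > 2L) {
    Kx[cbind(1:(n - 2L), 2:(n - 1L))] <- -n
    Kx[cbind(2:(n - 1L), 1:(n - 2L))] <- -n
  }

  structure(list(n = n, h = h, T = Tw, v0 = v0, lambda = lambda,
                 quad_order = quad_order, As = As, B0 = B0, Mmix = Mmix,
                 C = C, f = f, Kx_chol = chol(Kx), dimX = dimX, dimY = dimY),
            class = "assembled_system")
}

#' Assemble the minimal-residual saddle-point system
#'
#' Builds the test-space energy matrix `As` (symmetric part of the spatial
#' operator, plus the `lambda` mass shift), the rectangular form matrix `B`,
#' the initial-trace mass `C`, and (when `u0` is supplied) the forcing vector
#' of the singular-reference residual problem. All drift-dependent entries
#' use per-cell tensor Gauss quadrature of order `quad_order` (exact for the
#' polynomial parts at the default 4); the forcing uses the
#' integrated-by-parts form containing only *values* of `u0`, and Gauss
#' nodes are interior to cells so the discontinuity corner `(0, 0)` is never
#' evaluated.
#'
#' @param problem a `unit_square_problem` from [to_unit_time()].
#' @param n cells per direction (`h = 1/n`).
#' @param lambda `"auto"` (default, via [auto_shift()]) or a number `>= 0`.
#' @param quad_order 1D Gauss order per cell (2 to 5).
#' @param u0 optional [constant_drift_solution()]; when given, the forcing
#'   vector `f` for the residual problem is assembled.
#' @param series_tol truncation tolerance for `u0` when it is built here.
#' @return an `assembled_system`.
#' @export
assemble_system <- function(problem, n, lambda = "auto", quad_order = 4L,
                            u0 = NULL, series_tol = 1e-12) {
  if (identical(lambda, "auto")) lambda <- auto_shift(problem)
  stopifnot(is.numeric(lambda), lambda >= 0)
  if (is.null(u0)) {
    u0 <- constant_drift_solution(problem$v0, problem$T, tol = series_tol)
  }
  assemble_core(problem, as.integer(n), lambda, as.integer(quad_order),
                u0, want_forcing = TRUE)
}

#' Assemble only the forcing vector
#'
#' @param problem a `unit_square_problem`.
#' @param u0 a [constant_drift_solution()] for the corner drift `v0`.
#' @param n cells per direction.
#' @param quad_order Gauss order.
#' @param lambda shift used (the forcing is damped by `exp(-lambda t)`).
#' @return the forcing vector (length `2n(n-1)`).
#' @export
assemble_forcing <- function(problem, u0, n, quad_order = 4L, lambda = 0) {
  sys <- assemble_core(problem, as.integer(n), lambda,
                       as.integer(quad_order), u0, want_forcing = TRUE)
  sys$f
}

as_blocks_chol <- function(system) {
  n <- system$n; bs <- 2L * (n - 1L)
  lapply(seq_len(n), function(k) {
    rows <- (k - 1L) * bs + seq_len(bs)
    blk <- as.matrix(system$As[rows, rows])
    tryCatch(chol(blk), error = function(e) {
      stop_domain("test-space energy matrix not positive definite; ",
                  "increase the shift lambda (currently ", system$lambda, ")")
    })
  })
}

apply_As_inv <- function(system, chols, r) {
  n <- system$n; bs <- 2L * (n - 1L)
  out <- numeric(length(r))
  for (k in seq_len(n)) {
    rows <- (k - 1L) * bs + seq_len(bs)
    out[rows] <- backsolve(chols[[k]], forwardsolve(t(chols[[k]]), r[rows]))
  }
  out
}

#' A finite element field on the tensor mesh
#'
#' Thin container for a trial-space coefficient vector; boundary coefficients
#' at `x = 0, 1` are implicit zeros.
#'
#' @param coef coefficient vector of length `(n+1)(n-1)`.
#' @param n mesh cells per direction.
#' @return an object of class `fem_field`.
#' @export
fem_field <- function(coef, n) {
  stopifnot(length(coef) == trial_dim(n))
  structure(list(coef = as.numeric(coef), n = as.integer(n)),
            class = "fem_field")
}

#' @export
print.fem_field <- function(x, ...) {
  cat("<fem_field> n =", x$n, " range [", min(x$coef), ",", max(x$coef), "]\n")
  invisible(x)
}

#' Evaluate a finite element field
#'
#' @param field a [fem_field()].
#' @param t,x coordinates in `[0, 1]` (vectors, recycled).
#' @return bilinear interpolated values.
#' @export
eval_fem_field <- function(field, t, x) {
  n <- field$n
  m <- max(length(t), length(x))
  t <- pmin(pmax(rep_len(t, m), 0), 1)
  x <- pmin(pmax(rep_len(x, m), 0), 1)
  it <- pmin(floor(t * n), n - 1L); q <- t * n - it
  jx <- pmin(floor(x * n), n - 1L); r <- x * n - jx
  cf <- function(i, j) {
    v <- numeric(length(i))
    ok <- j >= 1L & j <= n - 1L
    v[ok] <- field$coef[i[ok] * (n - 1L) + j[ok]]
    v
  }
  (1 - q) * (1 - r) * cf(it, jx) + (1 - q) * r * cf(it, jx + 1L) +
    q * (1 - r) * cf(it + 1L, jx) + q * r * cf(it + 1L, jx + 1L)
}

#' Solve the assembled saddle-point system
#'
#' Computes the minimal-residual approximation as the second component of the
#' block system `[As B; B' C] [mu; w] = [f; 0]`, via per-time-cell dense
#' Cholesky factorizations of the block-diagonal `As` and a sparse Cholesky
#' of the Schur complement `S = B' As^-1 B + C`. If a shift `lambda > 0` was
#' used, the returned field is the back-transformed solution (nodal values
#' multiplied by `exp(lambda t)`).
#'
#' @param system an `assembled_system` with forcing.
#' @param f optional forcing vector overriding `system$f` (e.g. manufactured).
#' @return a [fem_field()]; attribute `"block_residual"` carries the relative
#'   residual of the full block system and `"lambda"` the shift used.
#' @export
solve_minres <- function(system, f = NULL) {
  stopifnot(inherits(system, "assembled_system"))
  if (is.null(f)) f <- system$f
  if (is.null(f)) stop_domain("system has no forcing vector; supply f")
  n <- system$n
  B <- if (system$lambda > 0) system$B0 + system$lambda * system$Mmix
       else system$B0
  chols <- as_blocks_chol(system)
  bs <- 2L * (n - 1L)
  Sf <- apply_As_inv(system, chols, f)
  rhs <- as.numeric(Matrix::crossprod(B, Sf))
  trip_i <- trip_j <- trip_v <- vector("list", n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * bs + seq_len(bs)
    cols <- (k - 1L) * (n - 1L) + seq_len(2L * (n - 1L))
    Bk <- as.matrix(B[rows, cols])
    Zk <- backsolve(chols[[k]], forwardsolve(t(chols[[k]]), Bk))
    Sk <- crossprod(Bk, Zk)
    trip_i[[k]] <- rep(cols, times = length(cols))
    trip_j[[k]] <- rep(cols, each = length(cols))
    trip_v[[k]] <- as.vector(Sk)
  }
  S <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_v),
                            dims = c(system$dimX, system$dimX)) + system$C
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(S), LDL = FALSE),
                 error = function(e) {
                   stop_domain("Schur complement singular ",
                               "(discrete inf-sup failure)")
                 })
  w <- as.numeric(Matrix::solve(ch, rhs))
  ## a few steps of iterative refinement on the Schur equation keep the
  ## block-system residual at round-off even on the finer meshes
  for (it in 1:3) {
    rs <- rhs - as.numeric(S %*% w)
    if (sqrt(sum(rs^2)) <= 1e-14 * max(sqrt(sum(rhs^2)), 1e-300)) break
    w <- w + as.numeric(Matrix::solve(ch, rs))
  }
  mu <- apply_As_inv(system, chols, f - as.numeric(B %*% w))
  r1 <- as.numeric(system$As %*% mu) + as.numeric(B %*% w) - f
  ## optimality system is [[As, B], [B', -C]] [mu; w] = [f; 0] for
  ## mu = As^-1 (f - B w); its Schur complement is (B' As^-1 B + C) w = B' mu_f
  r2 <- as.numeric(Matrix::crossprod(B, mu)) - as.numeric(system$C %*% w)
  denom <- max(sqrt(sum(f^2)), 1e-300)
  resid <- sqrt(sum(r1^2) + sum(r2^2)) / denom
  if (system$lambda > 0) {
    tnode <- rep(0:n, each = n - 1L) / n
    w <- w * exp(system$lambda * tnode)
  }
  out <- fem_field(w, n)
  attr(out, "block_residual") <- resid
  attr(out, "lambda") <- system$lambda
  out
}

## (Mt kron Kx)^{-1} r per time cell: Mt is the 2x2 local P1 time mass
apply_Agram_inv <- function(system, r) {
  n <- system$n; h <- system$h; bs <- 2L * (n - 1L)
  Mti <- matrix(c(4, -2, -2, 4), 2, 2) / h
  out <- numeric(length(r))
  for (k in seq_len(n)) {
    rows <- (k - 1L) * bs + seq_len(bs)
    Rm <- matrix(r[rows], n - 1L, 2L)
    Xs <- backsolve(system$Kx_chol,
                    forwardsolve(t(system$Kx_chol), Rm)) %*% Mti
    out[rows] <- as.vector(Xs)
  }
  out
}

#' Discrete X-norm of a trial-space field
#'
#' Computes the computable equivalent of the natural parabolic norm
#' (`L2(H1_0)` intersect `H1(H^-1)`):
#' `||w||^2 = w' B' (A)^-1 B w + w' C w`, where `B` is the *unshifted* form
#' matrix and `A` is the pure `dx`-Gram matrix on the test space. Used for
#' all error reporting.
#'
#' @param field a [fem_field()] (or plain coefficient vector) on the mesh of
#'   `system`.
#' @param system the `assembled_system` of the matching mesh.
#' @return the norm value.
#' @export
xnorm <- function(field, system) {
  w <- if (inherits(field, "fem_field")) field$coef else as.numeric(field)
  stopifnot(length(w) == system$dimX)
  r <- as.numeric(system$B0 %*% w)
  q <- apply_Agram_inv(system, r)
  sqrt(sum(r * q) + sum(w * as.numeric(system$C %*% w)))
}

#' Prolong a field to a finer nested mesh
#'
#' Exact nodal interpolation onto a mesh with `n2` a multiple of `n`
#' (bilinears are preserved).
#'
#' @param field a [fem_field()].
#' @param n2 target cells per direction.
#' @return a [fem_field()] on the finer mesh.
#' @export
prolong_field <- function(field, n2) {
  n2 <- as.integer(n2)
  if (n2 %% field$n != 0L) stop_domain("n2 must be a multiple of n")
  tn <- rep(0:n2, each = n2 - 1L) / n2
  xn <- rep(seq_len(n2 - 1L), times = n2 + 1L) / n2
  fem_field(eval_fem_field(field, tn, xn), n2)
}

#' Solve the residual problem for one model
#'
#' Convenience wrapper: builds the constant-drift reference, assembles and
#' solves at resolution `n`.
#'
#' @param problem a `unit_square_problem`.
#' @param n cells per direction.
#' @inheritParams assemble_system
#' @return `list(field, system, u0)`.
#' @export
solve_residual_problem <- function(problem, n, lambda = "auto",
                                   quad_order = 4L, series_tol = 1e-12) {
  u0 <- constant_drift_solution(problem$v0, problem$T, tol = series_tol)
  sys <- assemble_system(problem, n, lambda = lambda,
                         quad_order = quad_order, u0 = u0)
  list(field = solve_minres(sys), system = sys, u0 = u0)
}

#' Mesh-refinement error study
#'
#' For each `n` in `n_list`, solves at `n` and `2n` and measures
#' `||e_{h/2} - e_h||` in the discrete X-norm of the finer mesh (the
#' standard consecutive-mesh surrogate for `||e - e_h||`). Solutions are
#' cached across the list.
#'
#' @param problem a `unit_square_problem`.
#' @param n_list increasing dyadic mesh sizes.
#' @inheritParams assemble_system
#' @return a `data.frame` with columns `n`, `h`, `err_X`, `rate`
#'   (`log2(err[i-1]/err[i])`); attribute `"slope"` holds the least-squares
#'   slope of `log(err)` against `log(h)`.
#' @export
convergence_study <- function(problem, n_list, lambda = "auto",
                              quad_order = 4L, series_tol = 1e-12) {
  ns <- sort(unique(c(n_list, 2L * n_list)))
  sols <- lapply(ns, function(n)
    solve_residual_problem(problem, n, lambda = lambda,
                           quad_order = quad_order, series_tol = series_tol))
  names(sols) <- as.character(ns)
  err <- vapply(n_list, function(n) {
    co <- sols[[as.character(n)]]
    fi <- sols[[as.character(2L * n)]]
    d <- prolong_field(co$field, 2L * n)$coef - fi$field$coef
    xnorm(d, fi$system)
  }, numeric(1))
  rate <- c(NA, log2(err[-length(err)] / err[-1L]))
  out <- data.frame(n = n_list, h = 1 / n_list, err_X = err, rate = rate)
  ## a slope is only meaningful away from round-off (err == 0 when vhat == v0)
  ok <- err > 1e-13
  attr(out, "slope") <- if (sum(ok) >= 2L) {
    unname(coef(lm(log(err[ok]) ~ log(1 / n_list[ok])))[2L])
  } else NA_real_
  out
}

#' Forcing vector for a manufactured solution
#'
#' Builds `f(z) = int dt(w*) z + T dx(w*) dx(z) - T vhat dx(w*) z` by the
#' same cell quadrature as the assembler, for a smooth `w*` given with its
#' analytic derivatives. With `f := B w*` for `w*` in the trial space the
#' minimal-residual solution recovers `w*` exactly; for smooth `w*` outside
#' the trial space it provides a quasi-optimality check.
#'
#' @param problem a `unit_square_problem`.
#' @param n cells per direction.
#' @param w,wt,wx vectorized `function(t, x)` giving `w*` and its `t`/`x`
#'   derivatives; `w*` must vanish at `x = 0, 1` and at `t = 0`.
#' @param quad_order Gauss order.
#' @return a forcing vector usable with [solve_minres()] on a `lambda = 0`
#'   system.
#' @export
manufactured_forcing <- function(problem, n, w, wt, wx, quad_order = 4L) {
  n <- as.integer(n)
  Tw <- problem$T
  ls <- local_shapes(n, quad_order)
  nq <- ls$nq; h <- ls$h
  tq <- as.vector(outer(ls$qnodes * h, (seq_len(n) - 1L) * h, "+"))
  xq <- tq
  Vbig <- problem$vhat_grid(tq, xq)
  TQ <- matrix(tq, length(tq), length(xq))
  XQ <- matrix(xq, length(tq), length(xq), byrow = TRUE)
  WTb <- wt(TQ, XQ); WXb <- wx(TQ, XQ)
  ncell <- n * n
  cell_k <- rep(seq_len(n), each = n)
  cell_m <- rep(seq_len(n), times = n)
  nqq <- nq * nq
  G1 <- matrix(0, ncell, nqq)  # dt(w*) - T vhat dx(w*)   (multiplies z)
  G2 <- matrix(0, ncell, nqq)  # T dx(w*)                 (multiplies dx z)
  for (qi in seq_len(nqq)) {
    ridx <- (cell_k - 1L) * nq + ls$qa[qi]
    cidx <- (cell_m - 1L) * nq + ls$qb[qi]
    ij <- cbind(ridx, cidx)
    G1[, qi] <- WTb[ij] - Tw * Vbig[ij] * WXb[ij]
    G2[, qi] <- Tw * WXb[ij]
  }
  Pt <- ls$P[, ls$qa, drop = FALSE]
  Xs <- ls$P[, ls$qb, drop = FALSE]
  dXs <- ls$dP[, ls$qb, drop = FALSE]
  f <- numeric(test_dim(n))
  for (a in 1:2) for (cc in 1:2) {
    nxv <- cell_m - 1L + (cc - 1L)
    ok <- nxv >= 1L & nxv <= n - 1L
    rows <- (cell_k - 1L) * 2L * (n - 1L) + (a - 1L) * (n - 1L) + nxv
    vals <- as.vector(G1 %*% (ls$W * Pt[a, ] * Xs[cc, ])) +
      as.vector(G2 %*% (ls$W * Pt[a, ] * dXs[cc, ]))
    f[rows[ok]] <- f[rows[ok]] + vals[ok]
  }
  f
}

#' Nodal interpolant of a smooth function into the trial space
#'
#' @param problem unused except for interface symmetry; may be `NULL`.
#' @param n cells per direction.
#' @param w vectorized `function(t, x)`.
#' @return a [fem_field()] with `w` sampled at the trial nodes.
#' @export
nodal_interpolant <- function(problem, n, w) {
  n <- as.integer(n)
  tn <- rep(0:n, each = n - 1L) / n
  xn <- rep(seq_len(n - 1L), times = n + 1L) / n
  fem_field(w(tn, xn), n)
}
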