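## brute-force Smolyak evaluation straight from the telescoped definition
## sum_{|i| <= q} prod_n (I_{i_n} - I_{i_n - 1}), with each univariate
## interpolant evaluated through plain Lagrange products (no barycentric
## shortcuts, no combination coefficients)
smolyak_brute <- function(N, q, f, rho) {
  lag_interp <- function(level, g) {
    ## g: function of the remaining coordinates evaluated at each 1D node
    if (level == 0L) return(function(r) 0)
    nodes <- cc_nodes(level)
    function(r) {
      tot <- 0
      for (j in seq_along(nodes)) {
        lj <- 1
        for (k in seq_along(nodes)) {
          if (k != j) lj <- lj * (r - nodes[k]) / (nodes[j] - nodes[k])
        }
        tot <- tot + lj * g(nodes[j])
      }
      tot
    }
  }
  tensor_eval <- function(levels, f, rho) {
    if (length(levels) == 0L) return(f(numeric(0)))
    if (any(levels == 0L)) return(0)
    op <- lag_interp(levels[1L],
                     function(v) tensor_eval(levels[-1L],
                                             function(rest) f(c(v, rest)),
                                             rho[-1L]))
    op(rho[1L])
  }
  idx <- firstpassage:::multi_indices(N, q)
  tot <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    for (kbits in 0:(2^N - 1)) {
      k <- as.integer(intToBits(kbits))[seq_len(N)]
      tot <- tot + (-1)^sum(k) * tensor_eval(i - k, f, rho)
    }
  }
  tot
}

test_that("Clenshaw-Curtis levels are the nested cosine sets", {
  expect_equal(cc_nodes(0), numeric(0))
  expect_equal(cc_nodes(1), 0)
  expect_equal(cc_nodes(2), c(-1, 0, 1))
  expect_equal(cc_nodes(3), c(-1, -sqrt(2) / 2, 0, sqrt(2) / 2, 1))
  for (lev in 1:6) {
    expect_true(all(cc_nodes(lev) %in% cc_nodes(lev + 1)))  # bitwise nesting
    expect_equal(cc_nodes(lev), -rev(cc_nodes(lev)))        # exact symmetry
  }
  expect_length(cc_nodes(6), 2^5 + 1)
})

test_that("small sparse grids have the expected node sets", {
  g <- sparse_grid(2, 3)
  expect_equal(nrow(g$nodes), 5L)   # the axis cross {(0,0), (+-1,0), (0,+-1)}
  sorted <- g$nodes[order(g$nodes[, 1], g$nodes[, 2]), ]
  expect_equal(unname(sorted),
               rbind(c(-1, 0), c(0, -1), c(0, 0), c(0, 1), c(1, 0)))
  expect_error(sparse_grid(2, 1), "q >= N")
})

test_that("combination coefficients form a partition of unity", {
  set.seed(41)
  for (N in 1:3) for (q in N:(N + 2)) {
    g <- sparse_grid(N, q)
    rho <- runif(N, -1, 1)
    expect_equal(sum(sparse_weights(g, rho)), 1, tolerance = 1e-12)
  }
})

test_that("combination-technique evaluation equals the telescoped definition", {
  set.seed(42)
  f <- function(rho) exp(rho[1]) * cos(rho[2]) + rho[1] * rho[2]^3
  for (q in 2:4) {
    ip <- build_interpolant(2, q, f)
    for (k in 1:5) {
      rho <- runif(2, -1, 1)
      expect_equal(evaluate_interpolant(ip, rho), smolyak_brute(2, q, f, rho),
                   tolerance = 1e-11)
    }
  }
})

test_that("interpolation is exact at sparse nodes, for constants, and for N = 1", {
  f <- function(rho) sin(sum(rho)) + prod(rho)
  ip <- build_interpolant(3, 6, f)
  for (k in seq_len(nrow(ip$grid$nodes))) {
    rho <- ip$grid$nodes[k, ]
    expect_equal(evaluate_interpolant(ip, rho), f(rho), tolerance = 1e-12)
  }
  ## constant payloads are reproduced exactly everywhere
  ipc <- build_interpolant(2, 4, function(rho) 3.25)
  expect_equal(evaluate_interpolant(ipc, c(0.3, -0.77)), 3.25,
               tolerance = 1e-13)
  ## N = 1 telescopes to the plain univariate interpolant of level q
  ip1 <- build_interpolant(1, 4, function(rho) exp(rho[1]))
  uni <- function(r) sum(firstpassage:::cc_lagrange(4, r) * exp(cc_nodes(4)))
  set.seed(43)
  for (r in runif(10, -1, 1)) {
    expect_equal(evaluate_interpolant(ip1, r), uni(r), tolerance = 1e-12)
  }
  ## low-degree monomials lie in the exactness set
  ipm <- build_interpolant(2, 4, function(rho) rho[1] * rho[2])
  for (k in 1:10) {
    rho <- runif(2, -1, 1)
    expect_equal(evaluate_interpolant(ipm, rho), rho[1] * rho[2],
                 tolerance = 1e-12)
  }
  expect_error(evaluate_interpolant(ip1, 1.5), "outside")
})

test_that("the printed Lebesgue bound dominates sampled estimates", {
  expect_equal(lebesgue_upper_bound(2, 1), 9)
  expect_equal(lebesgue_upper_bound(2, 2), 36)
  set.seed(44)
  for (N in 1:2) for (q in N:5) {
    g <- sparse_grid(N, q)
    emp <- max(vapply(seq_len(1000), function(i)
      sum(abs(sparse_weights(g, runif(N, -1, 1)))), numeric(1)))
    expect_lt(emp, lebesgue_upper_bound(q, N))
  }
})

test_that("interpolation of an analytic function converges in q", {
  N <- 3
  f <- function(rho) exp(sum(rho) / (2 * N))
  set.seed(45)
  pts <- matrix(runif(300 * N, -1, 1), 300, N)
  errs <- vapply(c(N + 2, N + 4, N + 6), function(q) {
    ip <- build_interpolant(N, q, f)
    max(abs(apply(pts, 1, function(r) evaluate_interpolant(ip, r) - f(r))))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("payload caching reuses nested evaluations across levels", {
  calls <- new.env(); calls$n <- 0L
  cache <- new.env(parent = emptyenv())
  f <- function(rho) { calls$n <- calls$n + 1L; sum(rho^2) }
  ip4 <- build_interpolant(2, 4, f, cache = cache)
  after4 <- calls$n
  ip5 <- build_interpolant(2, 5, f, cache = cache)
  expect_equal(after4, nrow(ip4$grid$nodes))
  ## only the genuinely new nodes were evaluated for q = 5
  expect_equal(calls$n, nrow(ip5$grid$nodes))
})
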