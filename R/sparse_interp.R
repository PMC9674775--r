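## Smolyak sparse tensor-product interpolation on [-1, 1]^N with nested
## Clenshaw-Curtis abscissae.  Level 1 is the single node {0}; level i + 1
## uses the 2^(i-1) + 1 cosine nodes, so nodes(i) is contained in nodes(i+1)
## exactly.  The operator is realized through the combination technique:
## I_q = sum over j in N^N of c_j (tensor I_{j_1} x ... x I_{j_N}), with
## c_j = sum_{k in {0,1}^N, |j + k| <= q} (-1)^|k|  (terms with a zero index
## vanish because the empty operator is defined as 0).

#' Clenshaw-Curtis abscissae of one nesting level
#'
#' Level 0 has no nodes (the associated interpolation operator is zero),
#' level 1 is `{0}`, and level `i + 1` consists of the `2^(i-1) + 1` points
#' `cos(j pi / 2^(i-1))`. The cosine values are symmetrized so plus/minus
#' pairs are exact negatives, keeping the nesting bitwise exact.
#'
#' @param level integer `>= 0`.
#' @return sorted ascending numeric vector of nodes.
#' @export
cc_nodes <- function(level) {
  level <- as.integer(level)
  if (level < 0L) stop_domain("level must be >= 0")
  if (level == 0L) return(numeric(0))
  if (level == 1L) return(0)
  m <- 2L^(level - 1L)
  x <- cos(seq(0L, m) * pi / m)
  x <- (x - rev(x)) / 2          # exact symmetry about 0
  sort(x)
}

## barycentric weights for the Chebyshev-extrema nodes (ascending order)
cc_bary_weights <- function(level) {
  n <- length(cc_nodes(level))
  if (n == 1L) return(1)
  w <- rep_len(c(1, -1), n)
  w[1L] <- w[1L] / 2
  w[n] <- w[n] / 2
  w
}

## values of all Lagrange basis polynomials of one level at a point
cc_lagrange <- function(level, rho) {
  nodes <- cc_nodes(level)
  n <- length(nodes)
  if (n == 1L) return(1)
  d <- rho - nodes
  hit <- which(abs(d) < 1e-14)
  if (length(hit)) {
    out <- numeric(n); out[hit[1L]] <- 1
    return(out)
  }
  w <- cc_bary_weights(level) / d
  w / sum(w)
}

#' Printed upper bound for the Smolyak Lebesgue constant
#'
#' `(# {i in N_0^N : sum i_n <= q})^2 = choose(q + N, N)^2`, the operator
#' norm bound of the sparse interpolator on continuous functions.
#'
#' @param q level parameter (`q >= N`).
#' @param N dimension.
#' @return the bound.
#' @export
lebesgue_upper_bound <- function(q, N) {
  if (q < N) stop_domain("need q >= N")
  choose(q + N, N)^2
}

## multi-indices i in N^N (componentwise >= 1) with sum <= q
multi_indices <- function(N, q) {
  if (q < N) stop_domain("need q >= N (index set has no full-dimensional term)")
  grow <- function(prefix, rem_dims, budget) {
    if (rem_dims == 0L) return(list(prefix))
    out <- list()
    for (i in seq_len(budget - (rem_dims - 1L))) {
      out <- c(out, grow(c(prefix, i), rem_dims - 1L, budget - i))
    }
    out
  }
  do.call(rbind, grow(integer(0), N, q))
}

#' Build the sparse grid of the Smolyak interpolator
#'
#' Enumerates the index set, computes the combination coefficients, and
#' collects the union of tensor-product node sets.
#'
#' @param N dimension of the parameter cube.
#' @param q level parameter, `q >= N`.
#' @return an object of class `sparse_grid`: combination terms (`indices`
#'   rows with nonzero `coef`), the distinct `nodes` matrix (rows are points
#'   in `[-1, 1]^N`), and per-term maps from tensor positions to node rows.
#' @export
sparse_grid <- function(N, q) {
  N <- as.integer(N); q <- as.integer(q)
  idx <- multi_indices(N, q)
  coefs <- apply(idx, 1L, function(j) {
    s <- 0L
    for (kbits in 0:(2L^N - 1L)) {
      k <- as.integer(intToBits(kbits))[seq_len(N)]
      if (sum(j + k) <= q) s <- s + (1L - 2L * (sum(k) %% 2L))
    }
    s
  })
  keep <- coefs != 0L
  idx <- idx[keep, , drop = FALSE]
  coefs <- coefs[keep]

  node_key <- function(p) paste(sprintf("%.15g", p), collapse = ",")
  node_env <- new.env(parent = emptyenv())
  nodes_list <- list()
  term_maps <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    pts_1d <- lapply(idx[r, ], cc_nodes)
    grid <- as.matrix(expand.grid(pts_1d, KEEP.OUT.ATTRS = FALSE))
    colnames(grid) <- NULL
    map <- integer(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      key <- node_key(grid[g, ])
      id <- node_env[[key]]
      if (is.null(id)) {
        id <- length(nodes_list) + 1L
        nodes_list[[id]] <- grid[g, ]
        node_env[[key]] <- id
      }
      map[g] <- id
    }
    term_maps[[r]] <- map
  }
  structure(list(N = N, q = q, indices = idx, coef = coefs,
                 nodes = do.call(rbind, nodes_list), term_maps = term_maps),
            class = "sparse_grid")
}

#' @export
print.sparse_grid <- function(x, ...) {
  cat("<sparse_grid> N =", x$N, " q =", x$q, " terms =", nrow(x$indices),
      " nodes =", nrow(x$nodes), "\n")
  invisible(x)
}

#' Per-node weights of the sparse interpolant at a query point
#'
#' Returns `w(rho)` with `(I_q f)(rho) = sum_k w_k(rho) f(node_k)`; the
#' basis for both evaluation and empirical Lebesgue-constant estimates
#' (`sum |w_k|`).
#'
#' @param grid a [sparse_grid()].
#' @param rho point in `[-1, 1]^N`.
#' @return numeric weight vector over `grid$nodes` rows.
#' @export
sparse_weights <- function(grid, rho) {
  if (length(rho) != grid$N) stop_domain("rho has wrong dimension")
  if (any(rho < -1 - 1e-12) || any(rho > 1 + 1e-12))
    stop_domain("rho outside [-1, 1]^N; no extrapolation")
  w <- numeric(nrow(grid$nodes))
  for (r in seq_len(nrow(grid$indices))) {
    lag <- lapply(seq_len(grid$N),
                  function(d) cc_lagrange(grid$indices[r, d], rho[d]))
    tens <- Reduce(function(u, v) as.vector(outer(u, v)), lag)
    map <- grid$term_maps[[r]]
    w[map] <- w[map] + grid$coef[r] * tens
  }
  w
}

#' Build a Smolyak sparse interpolant of a vector-valued map
#'
#' Evaluates `evaluator` once per distinct sparse-grid node (payloads must
#' all have a common length, e.g. coefficient vectors of [fem_field()]s on
#' one shared mesh — interpolating coefficients then interpolates the
#' fields exactly, because the basis is fixed) and stores them for
#' barycentric evaluation at arbitrary `rho`.
#'
#' @param N,q dimension and level (`q >= N`).
#' @param evaluator `function(rho)` returning a numeric payload.
#' @param cache optional environment memoizing evaluator calls across builds
#'   (keyed by the node coordinates); nested grids then reuse payloads.
#' @return an object of class `sparse_interpolant`.
#' @export
build_interpolant <- function(N, q, evaluator, cache = NULL) {
  grid <- sparse_grid(N, q)
  key_of <- function(p) paste(sprintf("%.15g", p), collapse = ",")
  payload_at <- function(p) {
    if (is.null(cache)) return(evaluator(p))
    key <- key_of(p)
    got <- cache[[key]]
    if (is.null(got)) {
      got <- evaluator(p)
      cache[[key]] <- got
    }
    got
  }
  pls <- lapply(seq_len(nrow(grid$nodes)),
                function(k) as.numeric(payload_at(grid$nodes[k, ])))
  len <- unique(vapply(pls, length, integer(1)))
  if (length(len) != 1L)
    stop_domain("evaluator returned payloads of differing lengths")
  structure(list(grid = grid, payloads = do.call(rbind, pls)),
            class = "sparse_interpolant")
}

#' @export
print.sparse_interpolant <- function(x, ...) {
  cat("<sparse_interpolant> N =", x$grid$N, " q =", x$grid$q,
      " nodes =", nrow(x$grid$nodes),
      " payload length =", ncol(x$payloads), "\n")
  invisible(x)
}

#' Evaluate a sparse interpolant
#'
#' @param interp a [build_interpolant()] result.
#' @param rho point in `[-1, 1]^N`.
#' @return interpolated payload vector.
#' @export
evaluate_interpolant <- function(interp, rho) {
  w <- sparse_weights(interp$grid, rho)
  as.numeric(crossprod(interp$payloads, w))
}

#' Interpolation-error study over a parameter test set
#'
#' For each `q`, builds the sparse interpolant of `rho -> e_h(rho)` (the
#' minimal-residual solution of the residual problem at mesh size `h = 1/n`)
#' and reports the maximal discrete X-norm of `e_h(rho) - (I_q e_h)(rho)`
#' over the test set; the norm is evaluated with the system assembled at the
#' same `rho`.
#'
#' @param family `function(rho)` returning a [decision_model()].
#' @param N parameter dimension of the family.
#' @param q_list increasing levels (`>= N`).
#' @param n mesh cells per direction for the payload solves.
#' @param test_set matrix of query points (rows); default the tensor set
#'   `{-1, -0.5, 0.5, 1}^N`, optionally with 0 included via
#'   `include_zero = TRUE`.
#' @param include_zero include 0 in the per-axis test values.
#' @return `data.frame(q, n_nodes, max_err_X)`.
#' @export
interp_error_study <- function(family, N, q_list, n, test_set = NULL,
                               include_zero = FALSE) {
  vals <- if (include_zero) c(-1, -0.5, 0, 0.5, 1) else c(-1, -0.5, 0.5, 1)
  if (is.null(test_set)) {
    test_set <- as.matrix(expand.grid(rep(list(vals), N),
                                      KEEP.OUT.ATTRS = FALSE))
    colnames(test_set) <- NULL
  }
  solve_cache <- new.env(parent = emptyenv())
  sys_cache <- new.env(parent = emptyenv())
  key_of <- function(p) paste(sprintf("%.15g", p), collapse = ",")
  pipe_at <- function(rho) {
    key <- key_of(rho)
    got <- solve_cache[[key]]
    if (is.null(got)) {
      rp <- rescale_to_unit_diffusion(family(rho))
      usp <- to_unit_time(transform_drift(rp, compute_time_warp(rp)))
      sol <- solve_residual_problem(usp, n)
      got <- list(coef = sol$field$coef, system = sol$system)
      solve_cache[[key]] <- got
    }
    got
  }
  rows <- lapply(q_list, function(q) {
    interp <- build_interpolant(N, q, function(rho) pipe_at(rho)$coef,
                                cache = sys_cache)
    errs <- vapply(seq_len(nrow(test_set)), function(i) {
      rho <- test_set[i, ]
      ref <- pipe_at(rho)
      xnorm(evaluate_interpolant(interp, rho) - ref$coef, ref$system)
    }, numeric(1))
    data.frame(q = q, n_nodes = nrow(interp$grid$nodes), max_err_X = max(errs))
  })
  do.call(rbind, rows)
}
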