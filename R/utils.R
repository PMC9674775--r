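#' @useDynLib firstpassage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats integrate splinefun pnorm runif setNames lm coef
#' @importFrom methods as
NULL

## complementary error function; pnorm gives full double accuracy in both tails
erfc_ <- function(x) 2 * pnorm(-sqrt(2) * x)

erf_ <- function(x) 1 - erfc_(x)

## 4-point Gauss-Legendre rule on [0, 1]
gauss_rule_01 <- function(order = 4L) {
  if (order == 4L) {
    x <- c(-0.8611363115940526, -0.3399810435848563,
           0.3399810435848563, 0.8611363115940526)
    w <- c(0.3478548451374538, 0.6521451548625461,
           0.6521451548625461, 0.3478548451374538)
  } else if (order == 2L) {
    x <- c(-1, 1) / sqrt(3)
    w <- c(1, 1)
  } else if (order == 3L) {
    x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    w <- c(5, 8, 5) / 9
  } else if (order == 5L) {
    x <- c(-0.9061798459386640, -0.5384693101056831, 0,
           0.5384693101056831, 0.9061798459386640)
    w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
           0.4786286704993665, 0.2369268850561891)
  } else {
    stop("unsupported quadrature order: ", order)
  }
  list(nodes = (x + 1) / 2, weights = w / 2)
}

stop_domain <- function(...) stop(..., call. = FALSE)

#' Build a function of (t, x) from an arithmetic expression string
#'
#' Used by the model-configuration reader for "custom" families. Only plain
#' arithmetic, a whitelist of elementary functions, the variables `t` and `x`,
#' and the names in `params` are allowed; anything else is rejected, so
#' configuration files cannot execute arbitrary code.
#'
#' @param text expression string, e.g. `"mu0 + mu1 * t / (t + t0)"`.
#' @param params named list of numeric parameter values substituted as constants.
#' @return a vectorized `function(t, x)`.
#' @export
safe_function_tx <- function(text, params = list()) {
  allowed_funs <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
                    "sin", "cos", "tan", "tanh", "abs", "pmin", "pmax")
  allowed_syms <- c("t", "x", names(params))
  expr <- str2lang(text)
  check <- function(e) {
    if (is.numeric(e) || is.integer(e)) return(invisible())
    if (is.symbol(e)) {
      if (!(as.character(e) %in% allowed_syms))
        stop_domain("symbol not allowed in model expression: ", as.character(e))
      return(invisible())
    }
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!(fn %in% allowed_funs))
        stop_domain("function not allowed in model expression: ", fn)
      for (i in seq_along(e)[-1L]) check(e[[i]])
      return(invisible())
    }
    stop_domain("unsupported element in model expression")
  }
  check(expr)
  env <- list2env(params, parent = baseenv())
  function(t, x) {
    out <- eval(expr, envir = list(t = t, x = x), enclos = env)
    if (length(out) == 1L) out <- rep(out, max(length(t), length(x)))
    out
  }
}
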