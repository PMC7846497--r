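#' Construct a coefficient set
#'
#' The per-topic interaction-coefficient functions `g_i(t)` (units: per
#' week) of the nonautonomous Lotka-Volterra system. Each element may be a
#' `utility_function` (typically the [derivative()] of a fitted utility) or
#' a plain R function of time.
#'
#' @param funs named list of `utility_function`s or functions of `t`.
#' @param provenance `"fitted"` or `"specified"`.
#' @param topics topic labels; default `names(funs)`.
#' @return an object of class `coefficient_set`.
#' @export
coefficient_set <- function(funs, provenance = c("fitted", "specified"),
                            topics = names(funs)) {
  provenance <- match.arg(provenance)
  if (is.null(topics)) topics <- paste0("topic", seq_along(funs))
  ok <- vapply(funs, function(f)
    is.function(f) || inherits(f, "utility_function"), TRUE)
  if (!all(ok))
    stop("coefficient_set: elements must be functions or utility_functions")
  structure(list(topics = topics, funs = funs, provenance = provenance),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set>", length(x$topics), "topics (", x$provenance,
      ")\n")
  invisible(x)
}

#' Evaluate a coefficient set on a time grid
#'
#' @param coeffs a [coefficient_set].
#' @param times numeric time grid.
#' @return numeric matrix, `length(times)` rows by one column per topic.
#' @export
eval_coefficients <- function(coeffs, times) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  G <- vapply(coeffs$funs, function(f) {
    v <- if (inherits(f, "utility_function")) predict(f, times) else f(times)
    as.numeric(v)
  }, numeric(length(times)))
  G <- matrix(G, nrow = length(times))
  if (any(!is.finite(G)))
    stop("eval_coefficients: non-finite coefficient values on the grid")
  colnames(G) <- coeffs$topics
  G
}

#' Closed-form share trajectories from utility functions
#'
#' Evaluates the logit share map at every grid point. By the integrability
#' of the system, this closed form is the unique global solution of the
#' Lotka-Volterra initial-value problem with coefficients `g_i = df_i/dt`,
#' so no numerical integration is needed in the analysis pipeline.
#'
#' @param utilities named list of `utility_function`s (or functions of `t`),
#'   one per topic.
#' @param times numeric grid.
#' @return a [share_system].
#' @export
solve_shares <- function(utilities, times) {
  F <- vapply(utilities, function(u) {
    v <- if (inherits(u, "utility_function")) predict(u, times) else u(times)
    as.numeric(v)
  }, numeric(length(times)))
  F <- matrix(F, nrow = length(times))
  sh <- logit_shares(F)
  topics <- names(utilities)
  if (is.null(topics)) topics <- paste0("topic", seq_len(ncol(F)))
  share_system(times, sh$S, sh$S0, topics = topics)
}

#' Lotka-Volterra right-hand side
#'
#' The share velocity decomposed into logistic growth and competition:
#' `dS_i/dt = g_i S_i (1 - S_i) - sum_{j != i} g_j S_j S_i`.
#'
#' @param S numeric vector of topic shares at one time (outside share
#'   excluded).
#' @param g numeric vector of coefficient values at the same time.
#' @return numeric vector of share time-derivatives.
#' @export
lv_rhs <- function(S, g) {
  if (length(S) != length(g)) stop("lv_rhs: S and g lengths differ")
  g * S * (1 - S) - S * (sum(g * S) - g * S)
}

#' Residual of a share system against the Lotka-Volterra ODE
#'
#' Compares a numerical time derivative of the shares (centered differences,
#' one-sided at the boundaries) with the analytic right-hand side evaluated
#' from the coefficient set. For shares produced by [solve_shares()] from
#' utilities whose derivatives are the coefficients, the residual is zero up
#' to finite-difference error (O(h^2) in the grid step).
#'
#' @param shares a [share_system].
#' @param coeffs a [coefficient_set] evaluable on the same grid.
#' @return residual matrix (time points x topics).
#' @export
ode_residual <- function(shares, coeffs) {
  stopifnot(inherits(shares, "share_system"))
  G <- eval_coefficients(coeffs, shares$times)
  if (ncol(G) != ncol(shares$S))
    stop("ode_residual: coefficient set and share system topic counts differ")
  t <- shares$times
  n <- length(t)
  if (n < 3L) stop("ode_residual: need at least 3 grid points")
  dS <- shares$S
  dS[1L, ] <- (shares$S[2L, ] - shares$S[1L, ]) / (t[2L] - t[1L])
  dS[n, ] <- (shares$S[n, ] - shares$S[n - 1L, ]) / (t[n] - t[n - 1L])
  inner <- 2:(n - 1L)
  dS[inner, ] <- (shares$S[inner + 1L, ] - shares$S[inner - 1L, ]) /
    (t[inner + 1L] - t[inner - 1L])
  rhs <- t(vapply(seq_len(n), function(k) lv_rhs(shares$S[k, ], G[k, ]),
                  numeric(ncol(G))))
  dS - rhs
}

## One Dormand-Prince 5(4) step: returns 5th-order solution and error estimate
dopri_step <- function(fun, t, y, h) {
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  cc <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  k <- matrix(0, 7, length(y))
  k[1L, ] <- fun(t, y)
  for (s in 1:6) {
    ys <- y + h * drop(a[[s]] %*% k[seq_len(s), , drop = FALSE])
    k[s + 1L, ] <- fun(t + cc[s] * h, ys)
  }
  y5 <- y + h * drop(b5 %*% k)
  y4 <- y + h * drop(b4 %*% k)
  list(y = y5, err = y5 - y4)
}

#' Numerical integration of the Lotka-Volterra system
#'
#' Adaptive Dormand-Prince Runge-Kutta 5(4) integration of the share ODE
#' from an initial share vector. Used as an independent oracle against the
#' closed-form solution; the analysis pipeline itself never integrates
#' (the closed form is exact and cheap).
#'
#' @param coeffs a [coefficient_set].
#' @param S0 initial topic shares (outside share excluded) at `times[1]`.
#' @param times output grid (the integrator substeps adaptively between
#'   output points).
#' @param rtol,atol relative/absolute error tolerances (defaults 1e-9 /
#'   1e-12).
#' @return a [share_system] on `times`.
#' @export
integrate_forward <- function(coeffs, S0, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (any(S0 <= 0) || sum(S0) >= 1)
    stop("integrate_forward: initial shares must be positive with sum < 1")
  gfun <- function(t) eval_coefficients(coeffs, t)[1L, ]
  fun <- function(t, y) lv_rhs(y, gfun(t))
  n <- length(times)
  out <- matrix(NA_real_, n, length(S0))
  out[1L, ] <- S0
  y <- S0
  h <- diff(times[1:2]) / 10
  for (k in 2:n) {
    t <- times[k - 1L]
    tend <- times[k]
    while (t < tend) {
      h <- min(h, tend - t)
      st <- dopri_step(fun, t, y, h)
      sc <- atol + rtol * pmax(abs(y), abs(st$y))
      errn <- sqrt(mean((st$err / sc)^2))
      if (!is.finite(errn)) stop("integrate_forward: integrator diverged at t = ",
                                 format(t))
      if (errn <= 1) {
        t <- t + h
        y <- st$y
      }
      fac <- if (errn > 0) 0.9 * errn^(-1 / 5) else 5
      h <- h * min(5, max(0.2, fac))
      if (h < 1e-12)
        stop("integrate_forward: step size underflow at t = ", format(t))
    }
    out[k, ] <- y
  }
  share_system(times, out, 1 - rowSums(out), topics = coeffs$topics)
}
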