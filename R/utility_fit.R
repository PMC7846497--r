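#' Parametric utility functions
#'
#' Two smooth families, both evaluable and twice continuously differentiable
#' everywhere (the smoothness the Lotka-Volterra decomposition assumes), and
#' both closed under analytic differentiation:
#'
#' * **Fourier series of order n**:
#'   `f(t) = a0 + sum_r a_r cos(r pi t / tau) + b_r sin(r pi t / tau)`,
#'   with half-period `tau > 0` in weeks;
#' * **polynomial of degree d**: `f(t) = c0 + c1 t + ... + cd t^d`.
#'
#' @param a0,a,b Fourier coefficients: intercept and length-`n` cosine/sine
#'   coefficient vectors.
#' @param tau half-period in weeks (`tau > 0`).
#' @param coef polynomial coefficients `c(c0, c1, ..., cd)`.
#' @return an object of class `c("fourier_utility", "utility_function")` or
#'   `c("polynomial_utility", "utility_function")`.
#' @name utility_function
NULL

#' @rdname utility_function
#' @export
fourier_utility <- function(a0, a, b, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("fourier_utility: tau must be a positive scalar")
  if (length(a) != length(b) || length(a) < 1L)
    stop("fourier_utility: 'a' and 'b' must have equal length >= 1")
  structure(list(a0 = as.numeric(a0), a = as.numeric(a), b = as.numeric(b),
                 order = length(a), tau = tau),
            class = c("fourier_utility", "utility_function"))
}

#' @rdname utility_function
#' @export
polynomial_utility <- function(coef) {
  if (length(coef) < 1L) stop("polynomial_utility: empty coefficient vector")
  structure(list(coef = as.numeric(coef), degree = length(coef) - 1L),
            class = c("polynomial_utility", "utility_function"))
}

#' @export
predict.fourier_utility <- function(object, t, ...) {
  t <- as.numeric(t)
  v <- rep(object$a0, length(t))
  for (r in seq_len(object$order)) {
    w <- r * pi * t / object$tau
    v <- v + object$a[r] * cos(w) + object$b[r] * sin(w)
  }
  v
}

#' @export
predict.polynomial_utility <- function(object, t, ...) {
  t <- as.numeric(t)
  v <- rep(0, length(t))
  for (k in rev(seq_along(object$coef))) v <- v * t + object$coef[k]
  v
}

#' @export
print.fourier_utility <- function(x, ...) {
  cat("<fourier_utility> order", x$order, "tau", format(x$tau),
      "a0", format(x$a0, digits = 4), "\n")
  invisible(x)
}

#' @export
print.polynomial_utility <- function(x, ...) {
  cat("<polynomial_utility> degree", x$degree, "\n")
  invisible(x)
}

#' Analytic derivative of a utility function
#'
#' Exact term-by-term differentiation. For the Fourier family,
#' `d/dt [a_r cos(r pi t/tau)] = -(a_r r pi/tau) sin(r pi t/tau)` and
#' symmetrically for the sine terms, so the derivative is again an order-`n`
#' Fourier series (zero intercept). For polynomials, the power rule. The
#' derivative of a fitted utility is the interaction coefficient function
#' `g(t)` of the Lotka-Volterra system.
#'
#' @param x a `utility_function`.
#' @param ... unused.
#' @return a `utility_function` of the same family.
#' @export
derivative <- function(x, ...) UseMethod("derivative")

#' @rdname derivative
#' @export
derivative.fourier_utility <- function(x, ...) {
  r <- seq_len(x$order)
  fourier_utility(a0 = 0,
                  a = r * pi / x$tau * x$b,
                  b = -(r * pi / x$tau) * x$a,
                  tau = x$tau)
}

#' @rdname derivative
#' @export
derivative.polynomial_utility <- function(x, ...) {
  if (x$degree == 0L) return(polynomial_utility(0))
  k <- seq_len(x$degree)
  polynomial_utility(x$coef[k + 1L] * k)
}

## Fourier design matrix on times t: [1 | cos(r pi t/tau), sin(r pi t/tau)]
fourier_design <- function(t, order, tau) {
  cols <- lapply(seq_len(order), function(r) {
    w <- r * pi * t / tau
    cbind(cos(w), sin(w))
  })
  cbind(1, do.call(cbind, cols))
}

ls_solve <- function(X, y, what) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop(what, ": rank-deficient design (rank ", qx$rank, " < ", ncol(X),
         " coefficients); too few or degenerate sample times")
  qr.coef(qx, y)
}

#' Least-squares Fourier fit of utility samples
#'
#' Fits an order-`n` Fourier series to one topic's utility samples by linear
#' least squares on the basis `1, cos(r pi t/tau), sin(r pi t/tau)`, solved
#' by QR decomposition. If the samples were generated exactly by a series of
#' order `m <= n` with the same `tau`, the generating coefficients are
#' recovered (up to numerical precision).
#'
#' @param times numeric sample times (week indices).
#' @param values numeric utility samples, same length.
#' @param order Fourier order `n >= 1`; needs `length(times) >= 2n + 1`.
#' @param tau half-period in weeks; default `diff(range(times))`, i.e. the
#'   full observation span (the series is not assumed periodic within the
#'   window).
#' @return a `fourier_utility` with diagnostic attributes `"fitted"` and
#'   `"residuals"`.
#' @export
fit_fourier <- function(times, values, order, tau = NULL) {
  if (length(times) != length(values))
    stop("fit_fourier: times and values lengths differ")
  if (order < 1L) stop("fit_fourier: order must be >= 1")
  if (is.null(tau)) tau <- diff(range(times))
  if (tau <= 0) stop("fit_fourier: tau must be positive")
  if (length(times) < 2L * order + 1L)
    stop("fit_fourier: ", length(times), " samples cannot identify ",
         2L * order + 1L, " coefficients (order ", order, ")")
  X <- fourier_design(times, order, tau)
  cf <- ls_solve(X, values, "fit_fourier")
  u <- fourier_utility(a0 = cf[1L],
                       a = cf[seq.int(2L, by = 2L, length.out = order)],
                       b = cf[seq.int(3L, by = 2L, length.out = order)],
                       tau = tau)
  fit <- as.numeric(X %*% cf)
  attr(u, "fitted") <- fit
  attr(u, "residuals") <- values - fit
  u
}

#' Least-squares polynomial fit of utility samples
#'
#' @param times,values numeric sample vectors of equal length.
#' @param degree polynomial degree (default 4, the alternative smoother to
#'   the Fourier family); needs `length(times) >= degree + 1`.
#' @return a `polynomial_utility` with attributes `"fitted"` and
#'   `"residuals"`.
#' @export
fit_polynomial <- function(times, values, degree = 4L) {
  if (length(times) != length(values))
    stop("fit_polynomial: times and values lengths differ")
  if (degree < 0L) stop("fit_polynomial: degree must be >= 0")
  if (length(times) < degree + 1L)
    stop("fit_polynomial: ", length(times), " samples cannot identify ",
         degree + 1L, " coefficients (degree ", degree, ")")
  X <- outer(as.numeric(times), 0:degree, `^`)
  cf <- ls_solve(X, values, "fit_polynomial")
  u <- polynomial_utility(cf)
  fit <- as.numeric(X %*% cf)
  attr(u, "fitted") <- fit
  attr(u, "residuals") <- values - fit
  u
}

#' Mean squared error between historical and predicted values
#'
#' `MSE = (1/n) sum_i (h_i - p_i)^2`.
#'
#' @param historical,predicted numeric vectors of equal length `n >= 1`.
#' @return non-negative scalar; zero iff the series are identical.
#' @export
mse <- function(historical, predicted) {
  if (length(historical) != length(predicted))
    stop("mse: length mismatch (", length(historical), " vs ",
         length(predicted), ")")
  if (length(historical) == 0L) stop("mse: empty series")
  mean((historical - predicted)^2)
}

#' Automatic Fourier order selection
#'
#' Fits all topics jointly at orders `1..cap` and picks the smallest order
#' whose pooled utility-scale residual MSE is within `factor` of the
#' cap-order MSE. The rule is relative rather than an absolute threshold so
#' it is invariant to the coverage constant `alpha` (utility residuals shift
#' by an exact constant under `alpha` changes, leaving the selection
#' untouched) and to rescaling the inputs. The cap (default 6 for ~52 weekly
#' points) guards against interpolating observation noise.
#'
#' @param times sample times.
#' @param f utility sample matrix (time points x topics).
#' @param cap maximum order (default 6).
#' @param factor slack relative to the cap-order MSE (default 2).
#' @param tau half-period; default the observation span.
#' @return selected order (integer scalar) with attribute `"mse"`, the
#'   per-order pooled MSE vector.
#' @export
choose_fourier_order <- function(times, f, cap = 6L, factor = 2,
                                 tau = NULL) {
  f <- as.matrix(f)
  if (is.null(tau)) tau <- diff(range(times))
  cap <- min(cap, (length(times) - 1L) %/% 2L)
  if (cap < 1L) stop("choose_fourier_order: too few samples")
  msen <- vapply(seq_len(cap), function(n) {
    X <- fourier_design(times, n, tau)
    mean((f - X %*% qr.coef(qr(X), f))^2)
  }, 0)
  # near-zero residuals mean the order already represents the data exactly;
  # comparing round-off magnitudes would make the relative rule unstable
  pick <- which(msen <= factor * msen[cap] | msen < 1e-20)[1L]
  structure(as.integer(pick), mse = msen)
}

#' Fit utility functions for every topic of a sample set
#'
#' @param samples a `utility_samples` object (see
#'   [utilities_from_shares()]).
#' @param kind `"fourier"` or `"polynomial"`.
#' @param order Fourier order or polynomial degree; `NULL` (default) selects
#'   the Fourier order automatically via [choose_fourier_order()]
#'   (polynomials default to degree 4).
#' @param tau_multiple half-period as a multiple of the observation span
#'   (default 1).
#' @param cap order cap for automatic selection.
#' @return a named list of `utility_function`s, one per topic, with
#'   attribute `"order"`.
#' @export
fit_utilities <- function(samples, kind = c("fourier", "polynomial"),
                          order = NULL, tau_multiple = 1, cap = 6L) {
  kind <- match.arg(kind)
  stopifnot(inherits(samples, "utility_samples"))
  tms <- samples$times
  if (kind == "polynomial") {
    if (is.null(order)) order <- 4L
    fits <- lapply(seq_along(samples$topics), function(i)
      fit_polynomial(tms, samples$f[, i], degree = order))
  } else {
    tau <- tau_multiple * diff(range(tms))
    if (is.null(order))
      order <- choose_fourier_order(tms, samples$f, cap = cap, tau = tau)
    fits <- lapply(seq_along(samples$topics), function(i)
      fit_fourier(tms, samples$f[, i], order = order, tau = tau))
  }
  names(fits) <- samples$topics
  structure(fits, order = as.integer(order))
}

#' Fit diagnostics for a fitted share system
#'
#' Per-topic mean squared error on the share scale, with residual and
#' fitted-value series.
#'
#' @param observed,fitted two [share_system]s on the same grid.
#' @return an object of class `fit_diagnostics`: list with `topics`, `mse`
#'   (named per-topic vector, share^2 scale), `residuals` and `fitted`
#'   matrices.
#' @export
fit_diagnostics <- function(observed, fitted) {
  stopifnot(inherits(observed, "share_system"),
            inherits(fitted, "share_system"))
  if (length(observed$times) != length(fitted$times) ||
      any(observed$times != fitted$times))
    stop("fit_diagnostics: share systems are on different grids")
  res <- observed$S - fitted$S
  m <- colMeans(res^2)
  names(m) <- observed$topics
  structure(list(topics = observed$topics, mse = m, residuals = res,
                 fitted = fitted$S),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat("<fit_diagnostics> per-topic share-scale MSE:\n")
  print(signif(x$mse, 4))
  invisible(x)
}
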