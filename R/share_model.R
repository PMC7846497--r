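#' Construct a share system
#'
#' The joint state of the logit attention-share model: for each week-index
#' time point, the `N` topic shares `S_i(t)` plus the outside share `S_0(t)`
#' absorbing all untracked searches. Shares are strictly inside `(0, 1)` and
#' sum to one at every time point.
#'
#' @param times numeric week indices (0, 1, 2, ...).
#' @param S numeric matrix, `length(times)` rows, one column per topic.
#' @param S0 numeric outside-share vector, one value per time point.
#' @param topics topic labels; default taken from `colnames(S)`.
#' @return an object of class `share_system`.
#' @export
share_system <- function(times, S, S0, topics = colnames(S)) {
  S <- as.matrix(S)
  if (is.null(topics)) topics <- paste0("topic", seq_len(ncol(S)))
  topics <- unname(topics)
  if (length(times) != nrow(S) || length(S0) != nrow(S))
    stop("share_system: times, S, S0 sizes disagree")
  if (any(S <= 0) || any(S >= 1) || any(S0 <= 0) || any(S0 >= 1))
    stop("share_system: all shares must lie strictly in (0, 1)")
  tot <- rowSums(S) + S0
  if (any(abs(tot - 1) > 1e-12))
    stop("share_system: shares do not sum to 1 (max deviation ",
         format(max(abs(tot - 1))), ")")
  colnames(S) <- topics
  structure(list(times = as.numeric(times), topics = topics, S = S,
                 S0 = as.numeric(S0)),
            class = "share_system")
}

#' @export
print.share_system <- function(x, ...) {
  cat("<share_system>", length(x$topics), "topics x", length(x$times),
      "time points; outside share in [",
      format(min(x$S0), digits = 4), ",", format(max(x$S0), digits = 4),
      "]\n")
  invisible(x)
}

#' Convert an attention panel to shares with a constant outside share
#'
#' Relative-interest values are proportional, within a time point, to the
#' fraction of all searches each topic received; the panel is renormalized
#' per week and scaled by a constant coverage `alpha`, the combined share of
#' all tracked topics, so that the outside share is `1 - alpha` at every
#' time. The coverage constant is arbitrary, and provably irrelevant: it
#' shifts every recovered utility by the constant `log(alpha/(1-alpha))`,
#' which the derivative kills, so interaction coefficients and role labels
#' do not depend on it.
#'
#' @param series named list of [attention_series] on a common weekly axis,
#'   all values strictly positive (see [floor_values()]).
#' @param coverage scalar `alpha` in `(0, 1)`; default 0.5.
#' @return a [share_system]; week indices start at 0 and the original dates
#'   are kept in attribute `"dates"`.
#' @export
to_shares <- function(series, coverage = 0.5) {
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage >= 1)
    stop("to_shares: coverage must be a scalar in (0, 1)")
  v <- panel_values(series)
  if (any(v <= 0))
    stop("to_shares: all values must be strictly positive; apply ",
         "floor_values() first")
  S <- coverage * v / rowSums(v)
  out <- share_system(times = seq_len(nrow(v)) - 1, S = S,
                      S0 = rep(1 - coverage, nrow(v)))
  attr(out, "dates") <- panel_dates(series)
  out
}

#' Logit map from utilities to shares
#'
#' The discrete-choice share of topic `i` given utilities `f`:
#' `S_i = exp(f_i) / (1 + sum_j exp(f_j))`, with the outside share
#' `S_0 = 1 / (1 + sum_j exp(f_j))`. Output sums to one exactly (up to
#' floating point).
#'
#' @param f numeric vector of utilities (one time point), or a matrix with
#'   one row per time point and one column per topic.
#' @return for a vector: a named share vector with the outside share last
#'   (`"outside"`); for a matrix: a list with elements `S` (matrix) and `S0`
#'   (vector).
#' @export
logit_shares <- function(f) {
  if (!all(is.finite(f))) stop("logit_shares: utilities must be finite")
  if (is.matrix(f)) {
    E <- exp(f)
    den <- 1 + rowSums(E)
    return(list(S = E / den, S0 = 1 / den))
  }
  E <- exp(f)
  den <- 1 + sum(E)
  out <- c(E / den, 1 / den)
  names(out) <- c(if (is.null(names(f))) paste0("topic", seq_along(f))
                  else names(f), "outside")
  out
}

#' Recover utility samples from shares
#'
#' Inverts the logit map pointwise: `f_i(t) = ln S_i(t) - ln S_0(t)`, the
#' log-odds of topic `i` against the outside search. Exact inverse of
#' [logit_shares()] on valid shares.
#'
#' @param shares a [share_system].
#' @return an object of class `utility_samples`: list with `times`, `topics`
#'   and the `f` matrix (time points x topics).
#' @export
utilities_from_shares <- function(shares) {
  stopifnot(inherits(shares, "share_system"))
  f <- log(shares$S) - log(shares$S0)
  structure(list(times = shares$times, topics = shares$topics, f = f),
            class = "utility_samples")
}

#' @export
print.utility_samples <- function(x, ...) {
  cat("<utility_samples>", length(x$topics), "topics x", length(x$times),
      "time points\n")
  invisible(x)
}
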