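#' Role labels of the pairwise interaction taxonomy
#' @keywords internal
ROLE_LEVELS <- c("competition", "predator-prey", "mutualism", "commensalism",
                 "amensalism", "neutralism")

new_interaction_report <- function(df) {
  stopifnot(all(c("time", "topic_a", "topic_b", "role", "predator", "g_a",
                  "g_b", "intensity") %in% names(df)))
  if (!all(df$role %in% ROLE_LEVELS))
    stop("interaction_report: unknown role label(s): ",
         paste(setdiff(unique(df$role), ROLE_LEVELS), collapse = ", "))
  bad <- xor(df$role == "predator-prey", !is.na(df$predator))
  if (any(bad))
    stop("interaction_report: predator identity must be present iff the ",
         "role is predator-prey")
  if (any(df$intensity < 0))
    stop("interaction_report: negative intensity")
  class(df) <- c("interaction_report", "data.frame")
  df
}

sign_band <- function(g, eps) {
  ifelse(g > eps, 1L, ifelse(g < -eps, -1L, 0L))
}

#' Classify the competitive role of one topic pair
#'
#' Signs of the two interaction coefficients, banded by a zero-threshold
#' `eps`, determine the ecological role:
#'
#' | sign A | sign B | role |
#' |--------|--------|------|
#' | + | + | competition |
#' | + | - (either order) | predator-prey, predator = positive topic |
#' | - | - | mutualism |
#' | - | 0 (either order) | commensalism (the negative topic benefits the other) |
#' | + | 0 (either order) | amensalism |
#' | 0 | 0 | neutralism |
#'
#' The predator convention follows the system algebra: in the LV right-hand
#' side the term `-g_j S_j S_i` makes a positive-coefficient topic depress
#' every other share while a negative-coefficient topic boosts them.
#'
#' @param g_a,g_b coefficient values of topics A and B at one time.
#' @param eps zero-threshold (`eps >= 0`); values with `|g| <= eps` count as
#'   zero.
#' @return list with `role` (one of the six labels) and `predator` (`"A"`,
#'   `"B"`, or `NA` when the role is not predator-prey).
#' @export
classify_pair <- function(g_a, g_b, eps) {
  stopifnot(length(g_a) == 1L, length(g_b) == 1L, eps >= 0)
  sa <- sign_band(g_a, eps)
  sb <- sign_band(g_b, eps)
  key <- paste(sa, sb)
  role <- switch(key,
    "1 1"   = "competition",
    "1 -1"  = "predator-prey",
    "-1 1"  = "predator-prey",
    "-1 -1" = "mutualism",
    "-1 0"  = "commensalism",
    "0 -1"  = "commensalism",
    "1 0"   = "amensalism",
    "0 1"   = "amensalism",
    "0 0"   = "neutralism")
  predator <- if (role == "predator-prey") {
    if (sa > 0L) "A" else "B"
  } else NA_character_
  list(role = role, predator = predator)
}

#' Classify all topic pairs over a time grid
#'
#' Applies [classify_pair()] to every unordered topic pair at every grid
#' point and attaches the system-wide interaction intensity
#' `sum_i |g_i(t)|`.
#'
#' @param coeffs a [coefficient_set].
#' @param times non-empty numeric grid.
#' @param eps zero-threshold; `NULL` (default) uses 10% of the maximum
#'   absolute coefficient over the run, a scale-adaptive choice: the
#'   strongest interaction observed sets the magnitude against which "no
#'   interaction" is judged.
#' @param smooth_weeks odd window length (in grid points) for an optional
#'   majority-vote smoothing of role labels, suppressing flicker near sign
#'   crossings; 0 (default) disables it.
#' @return an `interaction_report` data frame: one row per (time, pair) with
#'   columns `time`, `topic_a`, `topic_b`, `role`, `predator`, `g_a`, `g_b`,
#'   `intensity`. The `eps` used is stored in attribute `"eps"`.
#' @export
classify_system <- function(coeffs, times, eps = NULL, smooth_weeks = 0L) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (length(times) == 0L) stop("classify_system: empty time grid")
  G <- eval_coefficients(coeffs, times)
  if (ncol(G) < 2L) stop("classify_system: need at least two topics")
  if (is.null(eps)) eps <- 0.1 * max(abs(G))
  intensity <- rowSums(abs(G))
  pairs <- utils::combn(ncol(G), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cl <- lapply(seq_along(times), function(m)
      classify_pair(G[m, i], G[m, j], eps))
    role <- vapply(cl, `[[`, "", "role")
    pred <- vapply(cl, `[[`, "", "predator")
    if (smooth_weeks >= 3L) {
      role <- majority_smooth(role, smooth_weeks)
      pred <- ifelse(role == "predator-prey",
                     ifelse(G[, i] >= G[, j], "A", "B"), NA_character_)
    }
    data.frame(time = unname(as.numeric(times)),
               topic_a = coeffs$topics[i], topic_b = coeffs$topics[j],
               role = unname(role),
               predator = unname(ifelse(pred == "A", coeffs$topics[i],
                                        ifelse(pred == "B", coeffs$topics[j],
                                               NA_character_))),
               g_a = unname(G[, i]), g_b = unname(G[, j]),
               intensity = unname(intensity),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- new_interaction_report(do.call(rbind, rows))
  attr(out, "eps") <- eps
  out
}

## majority vote over a centered odd window; ties keep the original label
majority_smooth <- function(labels, window) {
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(labels)
  out <- labels
  for (k in seq_len(n)) {
    idx <- max(1L, k - half):min(n, k + half)
    tab <- table(labels[idx])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) out[k] <- top
  }
  out
}

#' @export
print.interaction_report <- function(x, ...) {
  eps <- attr(x, "eps")
  cat("<interaction_report>", length(unique(paste(x$topic_a, x$topic_b))),
      "pairs x", length(unique(x$time)), "time points",
      if (!is.null(eps)) paste("; eps =", format(eps, digits = 4)) else "",
      "\n")
  tab <- table(x$role)
  print(tab[order(-tab)])
  invisible(x)
}

#' Interaction intensity profile
#'
#' The scalar intensity of interaction at each time point: the sum of the
#' absolute interaction coefficients over all topics.
#'
#' @param coeffs a [coefficient_set].
#' @param times numeric grid.
#' @return non-negative numeric vector, one value per grid point.
#' @export
intensity_profile <- function(coeffs, times) {
  rowSums(abs(eval_coefficients(coeffs, times)))
}

#' Detect the onset of interaction intensification
#'
#' Scans all candidate changepoints and returns the index maximizing the
#' ratio of the trailing-window mean intensity to the leading-window mean;
#' ties are broken by the earliest index. On a flat profile every ratio is 1
#' and the earliest candidate (`window + 1`) is returned (degenerate case,
#' documented). A zero leading mean with a positive trailing mean yields an
#' infinite ratio and wins; 0/0 counts as 1.
#'
#' @param intensity numeric intensity series (length `> 2 * window`).
#' @param window window length in grid points (default 6).
#' @return integer index into `intensity` at which the new (intense) regime
#'   starts, with attribute `"ratio"` (the winning ratio).
#' @export
detect_intensification <- function(intensity, window = 6L) {
  n <- length(intensity)
  if (n <= 2L * window)
    stop("detect_intensification: series length ", n,
         " must exceed 2 * window = ", 2L * window)
  if (any(intensity < 0)) stop("detect_intensification: negative intensity")
  best <- -Inf
  best_k <- NA_integer_
  for (k in (window + 1L):(n - window + 1L)) {
    lead <- mean(intensity[(k - window):(k - 1L)])
    trail <- mean(intensity[k:(k + window - 1L)])
    ratio <- if (lead == 0 && trail == 0) 1 else trail / lead
    if (ratio > best) {
      best <- ratio
      best_k <- k
    }
  }
  structure(best_k, ratio = best)
}
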