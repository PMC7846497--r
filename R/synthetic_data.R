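#' Define a synthetic attention scenario
#'
#' A scenario fixes everything needed to generate a Trends-like weekly panel
#' with known ground truth: topic labels, per-regime Fourier utility
#' coefficients, the regime changepoints, observation noise, and the seed.
#'
#' @param topics character vector of `N >= 2` topic labels.
#' @param regimes list of regimes, each a list with `start` (week index in
#'   `[0, span)`, strictly increasing, first must be 0) and `coef`, a list
#'   of per-topic Fourier coefficient sets `list(a0, a, b)`.
#' @param span total number of weekly points (default 52).
#' @param tau Fourier half-period of the regime utilities (default
#'   `span - 1`, the observation span).
#' @param noise_sd sd of additive observation noise on the 0-100 scale
#'   (default 0).
#' @param round_to_int round observations to integers as Trends does
#'   (default `FALSE`).
#' @param seed integer RNG seed (default 1).
#' @param coverage the coverage constant `alpha` recorded for downstream
#'   analysis of the generated panel (default 0.5).
#' @param start_date first week-start date of the panel (cosmetic).
#' @param area area label attached to the generated series.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(topics, regimes, span = 52L, tau = NULL,
                               noise_sd = 0, round_to_int = FALSE, seed = 1L,
                               coverage = 0.5,
                               start_date = as.Date("2019-05-05"),
                               area = "synthetic") {
  if (length(topics) < 2L) stop("synthetic_scenario: need at least 2 topics")
  if (noise_sd < 0) stop("synthetic_scenario: noise_sd must be >= 0")
  if (is.null(tau)) tau <- span - 1
  starts <- vapply(regimes, `[[`, 0, "start")
  if (starts[1L] != 0)
    stop("synthetic_scenario: first regime must start at week 0")
  if (any(diff(starts) <= 0) || any(starts < 0) || any(starts >= span))
    stop("synthetic_scenario: regime starts must be strictly increasing ",
         "within [0, span)")
  for (rg in regimes) {
    if (length(rg$coef) != length(topics))
      stop("synthetic_scenario: each regime needs one coefficient set per ",
           "topic")
  }
  structure(list(topics = topics, regimes = regimes, span = as.integer(span),
                 tau = tau, noise_sd = noise_sd,
                 round_to_int = isTRUE(round_to_int), seed = as.integer(seed),
                 coverage = coverage, start_date = as.Date(start_date),
                 area = area),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario>", length(x$topics), "topics,", x$span, "weeks,",
      length(x$regimes), "regime(s), noise sd", x$noise_sd, "\n")
  invisible(x)
}

## C2 blending ramp: quintic smoothstep and its derivative on [0, 1]
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 + x * (-15 + 6 * x))
}
smoothstep_deriv <- function(x) {
  inside <- x > 0 & x < 1
  x <- pmin(pmax(x, 0), 1)
  ifelse(inside, 30 * x^2 * (1 - x)^2, 0)
}

## per-topic truth utility f(t) and coefficient g(t) closures: regimes
## blended over a 2-week C2 ramp centered on each regime start, keeping the
## utilities twice continuously differentiable
scenario_truth_funs <- function(scenario, topic_idx, ramp = 2) {
  regs <- scenario$regimes
  tau <- scenario$tau
  us <- lapply(regs, function(rg) {
    cf <- rg$coef[[topic_idx]]
    if (is.null(cf$a) || length(cf$a) == 0L)
      polynomial_utility(cf$a0)
    else
      fourier_utility(cf$a0, cf$a, cf$b, tau)
  })
  starts <- vapply(regs, `[[`, 0, "start")
  f <- function(t) {
    v <- predict(us[[1L]], t)
    for (k in seq_along(regs)[-1L]) {
      w <- smoothstep((t - (starts[k] - ramp / 2)) / ramp)
      v <- (1 - w) * v + w * predict(us[[k]], t)
    }
    v
  }
  g <- function(t) {
    v <- predict(us[[1L]], t)
    d <- predict(derivative(us[[1L]]), t)
    for (k in seq_along(regs)[-1L]) {
      x <- (t - (starts[k] - ramp / 2)) / ramp
      w <- smoothstep(x)
      wd <- smoothstep_deriv(x) / ramp
      vk <- predict(us[[k]], t)
      dk <- predict(derivative(us[[k]]), t)
      d <- (1 - w) * d + w * dk + wd * (vk - v)
      v <- (1 - w) * v + w * vk
    }
    d
  }
  list(f = f, g = g)
}

#' Rescale a share system to the Trends 0-100 dialect
#'
#' Joint (not per-topic) normalization: `v_i(t) = 100 S_i(t) / max S`, the
#' maximum taken over all topics and weeks, so exactly one cell of the panel
#' equals 100 - mirroring a Trends multi-topic comparison. Share *ratios*
#' between topics are preserved exactly.
#'
#' @param shares a [share_system].
#' @param dates optional `Date` vector for the output series; default a
#'   weekly axis from `start_date`.
#' @param start_date first week when `dates` is `NULL`.
#' @param area area label for the output series.
#' @return named list of [attention_series].
#' @export
trendsify <- function(shares, dates = NULL,
                      start_date = as.Date("2019-05-05"),
                      area = "synthetic") {
  stopifnot(inherits(shares, "share_system"))
  mx <- max(shares$S)
  if (mx <= 0) stop("trendsify: all-zero shares")
  v <- 100 * shares$S / mx
  if (is.null(dates)) dates <- start_date + 7 * (seq_along(shares$times) - 1)
  out <- lapply(seq_along(shares$topics), function(i)
    attention_series(shares$topics[i], dates, v[, i], area = area))
  names(out) <- shares$topics
  out
}

#' Generate a synthetic Trends-like panel with known ground truth
#'
#' Builds per-topic truth utilities from the scenario's regimes (blended
#' over a 2-week C2 ramp at each regime boundary), derives truth shares
#' through the closed-form logit map and truth coefficients by analytic
#' differentiation, rescales to the 0-100 dialect, then adds iid Gaussian
#' observation noise on the observation scale (clamped to `[0, 100]`) and
#' optionally rounds to integers. Identical seeds give identical output.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with `series` (named list of [attention_series], the
#'   observable panel) and `truth`: `utilities` (list of functions),
#'   `coefficients` (a [coefficient_set], provenance `"specified"`),
#'   `shares` (the noise-free [share_system]) and `changepoints` (week
#'   indices of regime starts after the first).
#' @export
generate_trends <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  times <- seq_len(scenario$span) - 1
  funs <- lapply(seq_along(scenario$topics), function(i)
    scenario_truth_funs(scenario, i))
  f_list <- lapply(funs, `[[`, "f")
  g_list <- lapply(funs, `[[`, "g")
  names(f_list) <- names(g_list) <- scenario$topics
  truth_shares <- solve_shares(f_list, times)
  series <- trendsify(truth_shares, start_date = scenario$start_date,
                      area = scenario$area)
  if (scenario$noise_sd > 0 || scenario$round_to_int) {
    set.seed(scenario$seed)
    series <- lapply(series, function(s) {
      v <- s$values
      if (scenario$noise_sd > 0)
        v <- v + stats::rnorm(length(v), 0, scenario$noise_sd)
      v <- pmin(pmax(v, 0), 100)
      if (scenario$round_to_int) v <- round(v)
      s$values <- v
      s
    })
  }
  starts <- vapply(scenario$regimes, `[[`, 0, "start")
  list(series = series,
       truth = list(
         utilities = f_list,
         coefficients = coefficient_set(g_list, provenance = "specified",
                                        topics = scenario$topics),
         shares = truth_shares,
         changepoints = starts[-1L]))
}

#' Pandemic-like four-topic preset scenario
#'
#' A 52-week, four-topic scenario emulating the qualitative attention
#' dynamics around an epidemic outbreak: 44 quiet weeks in which utilities
#' carry only small seasonal terms (all interaction coefficients near zero,
#' so pairs sit in neutralism), then from week 44 a regime in which topic 1
#' ("unemployment") gains utility at about +0.28 per week while the other
#' three lose at -0.10, -0.08 and -0.12 per week: topic 1 predates every
#' other topic and topics 2-4 proceed in pairwise mutualism, and the
#' interaction intensity jumps by more than an order of magnitude.
#'
#' @param noise_sd observation noise sd on the 0-100 scale (default 2,
#'   a small Trends-like sampling error).
#' @param seed RNG seed.
#' @param round_to_int integer observations (default `TRUE`).
#' @param coverage coverage constant recorded for analysis (default 0.5).
#' @return a [synthetic_scenario] with attribute `"changepoint"` (44).
#' @export
pandemic_preset <- function(noise_sd = 2, seed = 1L, round_to_int = TRUE,
                            coverage = 0.5) {
  topics <- c("unemployment", "symptoms", "news", "porn")
  span <- 52L
  tau <- span - 1
  cp <- 44
  base <- c(-2.2, -1.3, -0.6, -1.1)   # quiet-period log-odds vs outside
  wig_a2 <- 0.05 * c(1, -1, 1, -1)    # small seasonal terms, |g| << eps
  wig_b1 <- 0.04 * c(-1, 1, 1, -1)
  reg1 <- lapply(1:4, function(i)
    list(a0 = base[i], a = c(0, wig_a2[i]), b = c(wig_b1[i], 0)))
  slopes <- c(0.28, -0.10, -0.08, -0.12)  # late-regime du/dt per week
  ## realize a near-constant slope s on [cp, span) with a single sine term:
  ## d/dt [b1 sin(pi t/tau)] = b1 pi/tau cos(pi t/tau) ~= -0.93 b1 pi/tau
  b1 <- -slopes * tau / pi / 0.93
  reg2 <- lapply(1:4, function(i) {
    u1 <- fourier_utility(reg1[[i]]$a0, reg1[[i]]$a, reg1[[i]]$b, tau)
    a0 <- predict(u1, cp) - b1[i] * sin(pi * cp / tau)  # value-matched at cp
    list(a0 = a0, a = c(0, 0), b = c(b1[i], 0))
  })
  sc <- synthetic_scenario(
    topics = topics,
    regimes = list(list(start = 0, coef = reg1),
                   list(start = cp, coef = reg2)),
    span = span, tau = tau, noise_sd = noise_sd,
    round_to_int = round_to_int, seed = seed, coverage = coverage)
  attr(sc, "changepoint") <- cp
  sc
}

#' Write / read a scenario as JSON
#'
#' @param scenario a [synthetic_scenario].
#' @param path JSON file path.
#' @return `read_scenario_json()` returns a [synthetic_scenario].
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  x <- unclass(scenario)
  x$start_date <- format(x$start_date)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @param path JSON file path.
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  regimes <- lapply(x$regimes, function(rg)
    list(start = rg$start,
         coef = lapply(rg$coef, function(cf)
           list(a0 = cf$a0, a = unlist(cf$a), b = unlist(cf$b)))))
  synthetic_scenario(topics = unlist(x$topics), regimes = regimes,
                     span = x$span, tau = x$tau, noise_sd = x$noise_sd,
                     round_to_int = x$round_to_int, seed = x$seed,
                     coverage = x$coverage,
                     start_date = as.Date(x$start_date), area = x$area)
}
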