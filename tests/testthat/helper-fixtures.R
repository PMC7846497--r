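# shared fixture builders; all randomness is under the calling test's seed

# random strictly-valid share matrix (rows sum with S0 to 1)
random_share_system <- function(n_times, n_topics) {
  w <- matrix(stats::rexp(n_times * (n_topics + 1L)) + 0.05,
              nrow = n_times)
  w <- w / rowSums(w)
  share_system(times = seq_len(n_times) - 1,
               S = w[, seq_len(n_topics), drop = FALSE],
               S0 = w[, n_topics + 1L])
}

# random Fourier utility system with moderate coefficients
random_fourier_system <- function(n_topics = 4L, order = 4L, tau = 51) {
  us <- lapply(seq_len(n_topics), function(i) {
    r <- seq_len(order)
    fourier_utility(a0 = stats::runif(1, -2, 0),
                    a = stats::rnorm(order, 0, 0.3 / r),
                    b = stats::rnorm(order, 0, 0.3 / r),
                    tau = tau)
  })
  names(us) <- paste0("topic", seq_len(n_topics))
  us
}

# minimal single-regime synthetic scenario with known Fourier truth
simple_scenario <- function(order = 2L, n_topics = 4L, span = 52L,
                            noise_sd = 0, seed = 1L,
                            round_to_int = FALSE) {
  set.seed(seed + 1000L)
  coefs <- lapply(seq_len(n_topics), function(i) {
    r <- seq_len(order)
    list(a0 = stats::runif(1, -2, -0.3),
         a = stats::rnorm(order, 0, 0.25 / r),
         b = stats::rnorm(order, 0, 0.25 / r))
  })
  synthetic_scenario(topics = paste0("topic", seq_len(n_topics)),
                     regimes = list(list(start = 0, coef = coefs)),
                     span = span, noise_sd = noise_sd, seed = seed,
                     round_to_int = round_to_int)
}

# Trends-dialect CSV text with preamble; values: matrix or data.frame
trends_csv_lines <- function(dates, values, topics,
                             area = "United States") {
  header <- paste(c("Week", sprintf("%s: (%s)", topics, area)),
                  collapse = ",")
  rows <- vapply(seq_along(dates), function(k)
    paste(c(format(dates[k]), as.character(unlist(values[k, ]))),
          collapse = ","), "")
  c("Category: All categories", "", header, rows)
}

weekly_dates <- function(n, start = as.Date("2019-05-05")) start + 7 * (0:(n - 1))
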