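test_that("classify_pair reproduces the six-way sign taxonomy exactly", {
  eps <- 0.01
  val <- c(`1` = 0.4, `0` = 0.004, `-1` = -0.4)  # representative magnitudes
  expected <- rbind(
    c("1", "1", "competition", NA),
    c("1", "-1", "predator-prey", "A"),
    c("-1", "1", "predator-prey", "B"),
    c("-1", "-1", "mutualism", NA),
    c("-1", "0", "commensalism", NA),
    c("0", "-1", "commensalism", NA),
    c("1", "0", "amensalism", NA),
    c("0", "1", "amensalism", NA),
    c("0", "0", "neutralism", NA))
  for (k in seq_len(nrow(expected))) {
    got <- classify_pair(val[[expected[k, 1]]], val[[expected[k, 2]]], eps)
    expect_identical(got$role, expected[k, 3])
    expect_identical(got$predator,
                     if (is.na(expected[k, 4])) NA_character_
                     else expected[k, 4])
  }
  # spec'd spot checks
  expect_identical(classify_pair(0.4, 0.2, 0.01)$role, "competition")
  expect_identical(classify_pair(-0.3, -0.1, 0.01)$role, "mutualism")
  expect_identical(classify_pair(0.005, -0.002, 0.01)$role, "neutralism")
  pp <- classify_pair(0.4, -0.2, 0.01)
  expect_identical(pp$role, "predator-prey")
  expect_identical(pp$predator, "A")
})

test_that("the positive-coefficient topic is the predator in the dynamics", {
  # constant g = (+0.4, -0.2): integrating the system, A's share must grow
  # and B's must shrink - A preys on B
  cs <- coefficient_set(list(A = function(t) rep(0.4, length(t)),
                             B = function(t) rep(-0.2, length(t))),
                        "specified")
  out <- integrate_forward(cs, c(0.2, 0.2), 0:10)
  expect_true(all(diff(out$S[, "A"]) > 0))
  expect_true(all(diff(out$S[, "B"]) < 0))
})

test_that("classify_system maps a (+,-,-,-) system to predator + mutualism", {
  cs <- coefficient_set(list(u = function(t) rep(0.3, length(t)),
                             s = function(t) rep(-0.1, length(t)),
                             n = function(t) rep(-0.15, length(t)),
                             p = function(t) rep(-0.2, length(t))),
                        "specified")
  rep_ <- classify_system(cs, 0:51)
  with_u <- rep_[rep_$topic_a == "u", ]
  expect_true(all(with_u$role == "predator-prey"))
  expect_true(all(with_u$predator == "u"))
  others <- rep_[rep_$topic_a != "u", ]
  expect_true(all(others$role == "mutualism"))
  expect_equal(rep_$intensity, rep(0.75, nrow(rep_)))
})

test_that("all-zero coefficients give neutralism with zero intensity", {
  cs <- coefficient_set(list(a = function(t) rep(0, length(t)),
                             b = function(t) rep(0, length(t))),
                        "specified")
  rep_ <- classify_system(cs, 0:20)
  expect_true(all(rep_$role == "neutralism"))
  expect_true(all(rep_$intensity == 0))
  expect_true(all(is.na(rep_$predator)))
})

test_that("labels change category exactly at the eps band crossings", {
  eps <- 0.5
  cs <- coefficient_set(list(a = function(t) t - 5,
                             b = function(t) rep(-1, length(t))),
                        "specified")
  t <- seq(0, 10, by = 0.25)
  rep_ <- classify_system(cs, t, eps = eps)
  g1 <- t - 5
  want <- ifelse(g1 < -eps, "mutualism",
                 ifelse(g1 <= eps, "commensalism", "predator-prey"))
  expect_identical(rep_$role, unname(want))
})

test_that("classification is invariant to coverage and input rescaling", {
  gen <- generate_trends(pandemic_preset(noise_sd = 2, seed = 5))
  res1 <- run_analysis(gen$series, coverage = 0.3)
  res2 <- run_analysis(gen$series, coverage = 0.7)
  scaled <- lapply(gen$series, function(s) { s$values <- s$values / 4; s })
  res3 <- run_analysis(scaled, coverage = 0.3, value_floor = 0.125)
  expect_identical(res1$report$role, res2$report$role)
  expect_identical(res1$report$role, res3$report$role)
  G1 <- eval_coefficients(res1$coefficients, res1$times)
  G3 <- eval_coefficients(res3$coefficients, res3$times)
  expect_lt(max(abs(G1 - G3)), 1e-9)
})

test_that("intensity_profile sums absolute coefficients", {
  cs <- coefficient_set(list(a = function(t) rep(0.2, length(t)),
                             b = function(t) rep(-0.3, length(t))),
                        "specified")
  expect_equal(intensity_profile(cs, 0:10), rep(0.5, 11))
  cs0 <- coefficient_set(list(a = function(t) rep(0, length(t)),
                              b = function(t) rep(0, length(t))),
                         "specified")
  expect_equal(intensity_profile(cs0, 0:10), rep(0, 11))
  # invariant under topic relabeling
  cs_swap <- coefficient_set(list(b = function(t) rep(-0.3, length(t)),
                                  a = function(t) rep(0.2, length(t))),
                             "specified")
  expect_equal(intensity_profile(cs_swap, 0:10),
               intensity_profile(cs, 0:10))
})

test_that("detect_intensification agrees with an exhaustive-scan oracle", {
  brute <- function(x, w) {
    ratios <- sapply((w + 1):(length(x) - w + 1), function(k) {
      l <- mean(x[(k - w):(k - 1)]); tr <- mean(x[k:(k + w - 1)])
      if (l == 0 && tr == 0) 1 else tr / l
    })
    (w + 1):(length(x) - w + 1)
  }
  # step x10 at index 41 (week 40 on a 0-indexed axis)
  x <- c(rep(0.05, 40), rep(0.5, 12))
  idx <- detect_intensification(x, window = 6)
  expect_identical(as.integer(idx), 41L)
  # independent exhaustive scan confirms the maximizing index
  cand <- brute(x, 6)
  ratios <- sapply(cand, function(k)
    mean(x[k:(k + 5)]) / mean(x[(k - 6):(k - 1)]))
  expect_identical(cand[which.max(ratios)], 41L)

  # flat profile: ratio 1 everywhere, earliest index returned
  flat <- detect_intensification(rep(0.2, 30), window = 5)
  expect_identical(as.integer(flat), 6L)
  expect_equal(attr(flat, "ratio"), 1)

  # monotone ramp from zero: the ratio is maximized where the leading
  # window hugs the near-zero start, so the earliest candidate wins
  # (frozen from the exhaustive scan; documented degenerate behavior)
  ramp <- seq(0, 1, length.out = 41)
  mid <- detect_intensification(ramp, window = 8)
  rat <- sapply(9:33, function(k)
    mean(ramp[k:(k + 7)]) / mean(ramp[(k - 8):(k - 1)]))
  expect_identical(as.integer(mid), (9:33)[which.max(rat)])
  expect_identical(as.integer(mid), 9L)

  expect_error(detect_intensification(rep(1, 12), window = 6),
               "must exceed")
})

test_that("majority-vote smoothing suppresses single-point flicker", {
  g1 <- c(rep(0.3, 10), -0.3, rep(0.3, 10))  # one-point sign flicker
  cs <- coefficient_set(list(a = function(t) g1[t + 1],
                             b = function(t) rep(-0.2, length(t))),
                        "specified")
  raw <- classify_system(cs, 0:20, eps = 0.05)
  sm <- classify_system(cs, 0:20, eps = 0.05, smooth_weeks = 5)
  expect_identical(unique(sm$role), "predator-prey")
  expect_true("mutualism" %in% raw$role)
})
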