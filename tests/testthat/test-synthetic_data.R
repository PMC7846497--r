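test_that("generation is deterministic under a fixed seed", {
  g1 <- generate_trends(pandemic_preset(noise_sd = 2, seed = 42))
  g2 <- generate_trends(pandemic_preset(noise_sd = 2, seed = 42))
  expect_identical(g1$series, g2$series)
  g3 <- generate_trends(pandemic_preset(noise_sd = 2, seed = 43))
  expect_false(identical(g1$series, g3$series))
})

test_that("trendsify normalizes jointly to a single 100 cell", {
  sh <- share_system(0:9, matrix(0.2, 10, 2), rep(0.6, 10),
                     topics = c("a", "b"))
  v <- trendsify(sh)
  expect_true(all(v$a$values == 100 & v$b$values == 100))

  sh2 <- share_system(0:9, cbind(a = rep(0.2, 10), b = rep(0.1, 10)),
                      rep(0.7, 10))
  v2 <- trendsify(sh2)
  expect_equal(v2$a$values, 2 * v2$b$values)     # ratios preserved
  expect_identical(max(c(v2$a$values, v2$b$values)), 100)

  # to_shares o trendsify preserves share ratios exactly
  back <- to_shares(v2, coverage = 0.42)
  expect_equal(back$S[, "a"] / back$S[, "b"], sh2$S[, "a"] / sh2$S[, "b"])
})

test_that("generated panels satisfy the attention-series invariants", {
  gen <- generate_trends(pandemic_preset(noise_sd = 2, seed = 9))
  expect_named(gen$series, c("unemployment", "symptoms", "news", "porn"))
  for (s in gen$series) {
    expect_s3_class(s, "attention_series")   # constructor validates
    expect_true(all(s$values >= 0 & s$values <= 100))
    expect_true(all(s$values == round(s$values)))
  }
  # pre-noise the joint maximum is exactly 100
  clean <- generate_trends(pandemic_preset(noise_sd = 0,
                                           round_to_int = FALSE))
  expect_identical(max(vapply(clean$series, function(s) max(s$values), 0)),
                   100)
})

test_that("noise-free truth shares yield exact coefficient recovery", {
  sc <- simple_scenario(order = 2L, seed = 4)
  gen <- generate_trends(sc)
  samples <- utilities_from_shares(gen$truth$shares)
  fits <- fit_utilities(samples, order = 3L)
  G_hat <- eval_coefficients(
    coefficient_set(lapply(fits, derivative), "fitted"), samples$times)
  G_true <- eval_coefficients(gen$truth$coefficients, samples$times)
  expect_lt(max(abs(G_hat - G_true)), 1e-6)
  expect_lt(max(fit_diagnostics(gen$truth$shares,
                                solve_shares(fits, samples$times))$mse),
            1e-10)
})

test_that("CSV-path recovery is exact for pairwise coefficient differences", {
  # the per-week panel renormalization adds a common term to every
  # recovered utility; it cancels in differences between topics
  sc <- simple_scenario(order = 2L, seed = 6)
  gen <- generate_trends(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trends_csv(gen$series, path)
  res <- run_analysis(path, order = 6L)
  G_hat <- eval_coefficients(res$coefficients, res$times)
  G_true <- eval_coefficients(gen$truth$coefficients, res$times)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(max(abs((G_hat[, i] - G_hat[, j]) -
                      (G_true[, i] - G_true[, j]))), 1e-6)
  }
})

test_that("pandemic_preset realizes its stated regime structure", {
  gen <- generate_trends(pandemic_preset(noise_sd = 0,
                                         round_to_int = FALSE))
  times <- gen$truth$shares$times
  G <- eval_coefficients(gen$truth$coefficients, times)
  early <- times < 41
  late <- times > 47
  expect_lt(max(abs(G[early, ])), 0.01)            # weak interactions
  expect_true(all(G[late, 1] > 0.2))               # topic 1 surges
  expect_true(all(G[late, 2:4] < -0.05))
  # intensity explodes across the changepoint (frozen regression bound)
  inten <- intensity_profile(gen$truth$coefficients, times)
  expect_gt(mean(inten[late]) / mean(inten[early]), 5)

  rep_ <- classify_system(gen$truth$coefficients, times)
  early_r <- rep_[rep_$time < 41, ]
  expect_true(all(early_r$role == "neutralism"))
  late_r <- rep_[rep_$time > 47, ]
  u <- late_r[late_r$topic_a == "unemployment", ]
  expect_true(all(u$role == "predator-prey" & u$predator == "unemployment"))
  expect_true(all(late_r$role[late_r$topic_a != "unemployment"] ==
                  "mutualism"))

  cp <- detect_intensification(inten, window = 6)
  expect_lte(abs(times[cp] - 44), 2)
})

test_that("scenario JSON round trip preserves the generated world", {
  sc <- pandemic_preset(noise_sd = 1.5, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  back <- read_scenario_json(path)
  expect_identical(generate_trends(back)$series,
                   generate_trends(sc)$series)
})

test_that("scenario validation rejects bad regime orderings", {
  cf <- list(list(a0 = 0, a = 0.1, b = 0.1), list(a0 = 0, a = 0.1, b = 0.1))
  expect_error(synthetic_scenario(
    c("a", "b"),
    list(list(start = 0, coef = cf), list(start = 60, coef = cf)),
    span = 52), "regime starts")
  expect_error(synthetic_scenario(
    c("a", "b"), list(list(start = 5, coef = cf)), span = 52),
    "start at week 0")
  expect_error(synthetic_scenario("a", list(list(start = 0, coef = cf[1]))),
               "at least 2 topics")
})
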