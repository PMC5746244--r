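test_that("normal_from_uniform matches the closed-form uniform moments", {
  expect_equal(normal_from_uniform(0, 1),
               c(mean = 0.5, sd = 1 / sqrt(12)))
  expect_equal(normal_from_uniform(0, 1)[["sd"]], 0.28868, tolerance = 1e-4)
  expect_equal(normal_from_uniform(9.4, 15.6),
               c(mean = 12.5, sd = 6.2 / sqrt(12)))
  expect_equal(normal_from_uniform(9.4, 15.6)[["sd"]], 1.7898, tolerance = 1e-4)
  expect_equal(normal_from_uniform(0.3, 0.3), c(mean = 0.3, sd = 0))
  expect_error(normal_from_uniform(1, 0), "exceed")
})

test_that("uniform draws respect bounds and the law of large numbers", {
  ranges <- parameter_set(
    parameter_range("efficacy", 0.35, 0.55),
    parameter_range("const", 0.5, 0.5)
  )
  draws <- withr::with_seed(1, sample_draws(ranges, 1e5))
  expect_true(all(draws[, "efficacy"] >= 0.35 & draws[, "efficacy"] <= 0.55))
  expect_true(all(draws[, "const"] == 0.5))
  # mean within 3 MC standard errors of the uniform mean
  se <- (0.55 - 0.35) / sqrt(12 * 1e5)
  expect_lt(abs(mean(draws[, "efficacy"]) - 0.45), 3 * se)
})

test_that("normal_matched draws are clamped to the physical domain", {
  ranges <- parameter_set(parameter_range("p", 0, 0.06, kind = "probability"))
  draws <- withr::with_seed(2, sample_draws(ranges, 1e4, "normal_matched"))
  expect_true(all(draws >= 0 & draws <= 1))
  # the matched normal puts ~4% of mass below zero, so clamping must bite
  expect_true(any(draws == 0))
})

test_that("simulations are bit-identical under a fixed seed", {
  flu <- make_influenza_like()
  cfg <- sim_config(n_iterations = 500, seed = 99)
  expect_identical(run_simulation(flu$model, flu$ranges, cfg),
                   run_simulation(flu$model, flu$ranges, cfg))
  cfg_n <- sim_config(n_iterations = 500, seed = 99,
                      input_distribution = "normal_matched")
  expect_identical(run_simulation(flu$model, flu$ranges, cfg_n),
                   run_simulation(flu$model, flu$ranges, cfg_n))
})

test_that("a point-mass parameter set yields a constant sample", {
  m <- toy_mortality_model()
  ranges <- parameter_set(
    parameter_range("mortality_rate", 12.5, 12.5, kind = "rate_per_100k"),
    parameter_range("coverage", 0.575, 0.575),
    parameter_range("efficacy_mortality", 0.45, 0.45),
    parameter_range("adherence", 0.85, 0.85)
  )
  s <- run_simulation(m, ranges, sim_config(1000, seed = 1))
  point <- run_cpb(m, midpoint_draw(ranges))$qalys_per_1e3
  expect_equal(unique(s), point)
  one <- run_simulation(m, ranges, sim_config(1, seed = 1))
  expect_equal(one, point)
})

test_that("product-chain sample moments match the closed-form oracle", {
  fx <- make_product_chain(2)
  expect_equal(fx$mean, 0.25)
  expect_equal(fx$sd, sqrt(1 / 9 - 1 / 16))
  s <- run_simulation(fx$model, fx$ranges, sim_config(1e5, seed = 4))
  se_mean <- fx$sd / sqrt(1e5)
  expect_lt(abs(mean(s) - fx$mean), 3 * se_mean)
  expect_equal(sd(s), fx$sd, tolerance = 0.02)
})

test_that("summaries use the n-1 sd and interpolated quantiles", {
  est <- summarize_sample(rep(3.3, 50))
  expect_equal(est$mean, 3.3)
  expect_equal(est$sd, 0)
  expect_equal(c(est$qi_low, est$qi_high), c(3.3, 3.3))

  # order-statistics: the 0.025/0.975 interpolated quantiles of 1..1000
  est <- summarize_sample(1:1000)
  expect_equal(c(est$qi_low, est$qi_high), c(25.975, 975.025))
  expect_equal(est$mean, 500.5)
  expect_equal(est$sd, sqrt(1000 * 1001 / 12))  # closed-form sd of 1..n

  expect_error(summarize_sample(numeric(0)), "empty")
})

test_that("the 95% quantile interval covers ~95% of the sample", {
  flu <- make_influenza_like()
  s <- run_simulation(flu$model, flu$ranges, sim_config(1e4, seed = 8))
  est <- summarize_sample(s)
  covered <- mean(s >= est$qi_low & s <= est$qi_high)
  expect_gte(covered, 0.94)
  expect_lte(covered, 0.96)
  expect_lte(est$qi_low, est$mean)
  expect_lte(est$mean, est$qi_high)
})

test_that("monotone-model samples stay inside the corner-point envelope", {
  fx <- make_product_chain(4, seed = 31)
  lows <- vapply(unclass(fx$ranges), `[[`, numeric(1), "low")
  highs <- vapply(unclass(fx$ranges), `[[`, numeric(1), "high")
  s <- run_simulation(fx$model, fx$ranges, sim_config(2e4, seed = 32))
  expect_gte(min(s), prod(lows))
  expect_lte(max(s), prod(highs))
})

test_that("uniform and variance-matched normal inputs agree on the mean", {
  flu <- make_influenza_like()
  n <- 2e4
  su <- run_simulation(flu$model, flu$ranges, sim_config(n, seed = 10))
  sn <- run_simulation(flu$model, flu$ranges,
                       sim_config(n, seed = 10,
                                  input_distribution = "normal_matched"))
  se <- sqrt(var(su) / n + var(sn) / n)
  expect_lt(abs(mean(su) - mean(sn)), 3 * se)
})

test_that("convergence traces tighten as iterations accumulate", {
  flu <- make_influenza_like()
  # single checkpoint equals the summary of the full run
  cfg <- sim_config(5000, seed = 21)
  tr <- convergence_trace(flu$model, flu$ranges, cfg, checkpoints = 5000)
  full <- summarize_sample(run_simulation(flu$model, flu$ranges, cfg))
  expect_equal(tr$mean, full$mean)
  expect_equal(tr$sd, full$sd)

  # point-mass parameters give a flat trace
  m <- toy_mortality_model()
  pm <- parameter_set(
    parameter_range("mortality_rate", 12.5, 12.5, kind = "rate_per_100k"),
    parameter_range("coverage", 0.5, 0.5),
    parameter_range("efficacy_mortality", 0.45, 0.45),
    parameter_range("adherence", 0.85, 0.85)
  )
  tr <- convergence_trace(m, pm, sim_config(1000, seed = 1),
                          checkpoints = c(10, 100, 1000))
  expect_equal(length(unique(tr$mean)), 1L)
  expect_equal(tr$sd, rep(0, 3))

  expect_error(convergence_trace(flu$model, flu$ranges, cfg,
                                 checkpoints = c(100, 100)),
               "increasing")

  # the 1e4-iteration mean is closer to the full-run mean than the
  # 1e2-iteration mean for (almost) every seed; check a fixed panel
  hits <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(1e5, seed = seed)
    s <- run_simulation(flu$model, flu$ranges, cfg)
    full_mean <- mean(s)
    if (abs(mean(s[1:1e4]) - full_mean) < abs(mean(s[1:100]) - full_mean)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})
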