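test_that("attributable_events scales rates to person-years", {
  expect_equal(attributable_events(12.5, 5e7), 6250)
  expect_equal(attributable_events(15.6, 5e7), 7800)
  expect_equal(attributable_events(0, 1e12), 0)
  expect_error(attributable_events(-1, 10), "non-negative")
})

test_that("counterfactual back-calculation inverts the covered burden", {
  # midpoints of the published coverage (0.43-0.72) and mortality-efficacy
  # (0.35-0.55) ranges applied to the ~85,000 current-death scale
  cf <- counterfactual_burden(85000, 0.575, 0.45)
  expect_equal(cf, 85000 / (1 - 0.575 * 0.45))
  expect_equal(cf, 114671.16, tolerance = 1e-6)

  expect_equal(counterfactual_burden(85000, 0, 0.9), 85000)
  expect_equal(counterfactual_burden(0, 0.5, 0.5), 0)
  expect_error(counterfactual_burden(10, 1, 1), "diverges")
  expect_error(counterfactual_burden(-5, 0.5, 0.5), "non-negative")

  # counterfactual >= current, equality iff coverage * efficacy = 0
  withr::with_seed(11, {
    for (i in 1:50) {
      c0 <- runif(1, 0, 1e5); p <- runif(1); e <- runif(1, 0, 0.99)
      expect_gte(counterfactual_burden(c0, p, e), c0)
    }
  })
})

test_that("effectiveness and prevented events behave as products", {
  expect_equal(effectiveness(0.85, 0.45), 0.3825)
  expect_equal(effectiveness(1, 0.3), 0.3)
  expect_equal(effectiveness(0, 0.3), 0)
  expect_error(effectiveness(1.2, 0.5), "\\[0, 1\\]")

  cf <- counterfactual_burden(85000, 0.575, 0.45)
  expect_equal(prevented_events(cf, 0.3825), cf * 0.3825)
  expect_equal(prevented_events(cf, 0.3825), 43861.72, tolerance = 1e-6)
  expect_equal(prevented_events(123, 0), 0)
  expect_equal(prevented_events(123, 1), 123)
  expect_error(prevented_events(10, 1.5), "<= 1")
})

test_that("QALY accounting weights channels and fixes mortality at 1", {
  expect_equal(qalys_saved(c(mortality = 41000), c(mortality = 1)), 41000)
  expect_equal(qalys_saved(c(hospitalization = 180000),
                           c(hospitalization = 0.30)), 54000)
  expect_equal(qalys_saved(c(mortality = 0, hospitalization = 0, illness = 0),
                           c(mortality = 1, hospitalization = 0.3,
                             illness = 0.01)), 0)
  expect_error(qalys_saved(c(mortality = 10), c(mortality = 0.5)),
               "exactly 1")
  expect_error(event_channel("mortality", "r", "e", qaly_weight = 0.5),
               "weight 1")
})

test_that("qalys_per_1e3 normalises to the per-thousand reporting scale", {
  expect_equal(qalys_per_1e3(300000, 1e8), 3.0)
  expect_equal(qalys_per_1e3(0, 5), 0)
  expect_equal(qalys_per_1e3(7.7, 1000), 7.7)
  expect_error(qalys_per_1e3(1, 0), "positive")
})

test_that("run_cpb equals the hand-composed chain of elementary operations", {
  flu <- make_influenza_like(seniors_only = TRUE)
  draw <- midpoint_draw(flu$ranges)
  res <- run_cpb(flu$model, draw)

  # hand-compose per channel, then normalise by delivered interventions
  hand_channel <- function(rate, efficacy, weight) {
    current <- attributable_events(rate, 5e7)
    cf <- counterfactual_burden(current, draw[["coverage_65plus"]], efficacy)
    prev <- prevented_events(cf, effectiveness(draw[["adherence"]], efficacy))
    list(current = current, cf = cf, prev = prev, qalys = prev * weight)
  }
  mort <- hand_channel(draw[["mortality_rate_65plus"]],
                       draw[["efficacy_mortality"]], 1)
  hosp <- hand_channel(draw[["hospitalization_rate_65plus"]],
                       draw[["efficacy_hospitalization"]],
                       draw[["qaly_weight_sickness"]])
  ill <- hand_channel(draw[["illness_rate_65plus"]],
                      draw[["efficacy_illness"]],
                      draw[["qaly_weight_illness"]])
  total <- mort$qalys + hosp$qalys + ill$qalys
  expect_equal(res$total_qalys, total)
  expect_equal(res$n_interventions, 5e7 * draw[["adherence"]])
  expect_equal(res$qalys_per_1e3,
               qalys_per_1e3(total, 5e7 * draw[["adherence"]]))
  expect_equal(res$events$current,
               c(mort$current, hosp$current, ill$current))
  expect_equal(res$events$counterfactual, c(mort$cf, hosp$cf, ill$cf))
  expect_equal(res$events$prevented, c(mort$prev, hosp$prev, ill$prev))

  # mortality chain at midpoints matches the elementary-op values
  expect_equal(res$events$current[1], 6250)
  expect_equal(res$events$counterfactual[1], 6250 / (1 - 0.575 * 0.45))

  # determinism
  expect_identical(res, run_cpb(flu$model, draw))
})

test_that("run_cpb reports which parameter is missing", {
  m <- toy_mortality_model()
  expect_error(run_cpb(m, c(coverage = 0.5, efficacy_mortality = 0.4,
                            adherence = 0.8)),
               "mortality_rate")
})

test_that("zero coverage and zero adherence degenerate correctly", {
  m <- toy_mortality_model()
  res <- run_cpb(m, c(mortality_rate = 12.5, coverage = 0,
                      efficacy_mortality = 0.45, adherence = 0))
  expect_equal(res$events$counterfactual, res$events$current)
  expect_equal(res$total_qalys, 0)
  expect_equal(res$qalys_per_1e3, 0)
})

test_that("the QALY rate is monotone in efficacy, adherence, rate, and weight", {
  flu <- make_influenza_like(seniors_only = TRUE)
  base <- midpoint_draw(flu$ranges)
  out_base <- run_cpb(flu$model, base)$qalys_per_1e3
  bump <- function(name, delta) {
    d <- base; d[[name]] <- d[[name]] + delta
    run_cpb(flu$model, d)$qalys_per_1e3
  }
  expect_gte(bump("efficacy_mortality", 0.05), out_base)
  expect_gte(bump("efficacy_illness", 0.05), out_base)
  expect_gte(bump("mortality_rate_65plus", 1), out_base)
  expect_gte(bump("qaly_weight_sickness", 0.05), out_base)
  # adherence raises cohort QALYs proportionally; with the delivered-
  # intervention denominator the per-intervention rate is unchanged
  expect_equal(bump("adherence", 0.05), out_base)

  withr::with_seed(23, {
    for (i in 1:20) {
      d <- sample_draw(flu$ranges)
      for (p in c("efficacy_mortality", "illness_rate_65plus",
                  "qaly_weight_illness")) {
        d2 <- d; d2[[p]] <- d2[[p]] * 1.1
        expect_gte(run_cpb(flu$model, d2)$qalys_per_1e3,
                   run_cpb(flu$model, d)$qalys_per_1e3)
      }
    }
  })
})

test_that("vectorised model evaluation agrees with per-draw run_cpb", {
  flu <- make_influenza_like()
  draws <- withr::with_seed(5, sample_draws(flu$ranges, 25))
  vec <- model_evaluate(flu$model, draws)
  row_by_row <- vapply(seq_len(nrow(draws)), function(i) {
    run_cpb(flu$model, draws[i, ])$qalys_per_1e3
  }, numeric(1))
  expect_equal(vec, row_by_row)
})

test_that("cohort models round-trip through YAML", {
  flu <- make_influenza_like()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_model(flu$model, path)
  back <- read_cohort_model(path)
  expect_equal(back, flu$model, ignore_attr = FALSE)

  bundled <- read_cohort_model(system.file("extdata", "influenza_model.yaml",
                                           package = "cpbsim"))
  expect_equal(bundled, flu$model)
})
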