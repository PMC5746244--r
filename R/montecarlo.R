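#' Mean and standard deviation of a matched normal
#'
#' Given uniform bounds, return the mean and standard deviation of the normal
#' distribution with the same first two moments: `mean = (low + high) / 2`,
#' `sd = (high - low) / sqrt(12)`. Used for the distributional sensitivity
#' analysis in which every uniform input is replaced by a variance-matched
#' normal.
#'
#' @param low,high Uniform bounds, `low <= high`.
#' @return Named numeric vector `c(mean, sd)`.
#' @examples
#' normal_from_uniform(0, 1)      # mean 0.5, sd 0.28868
#' normal_from_uniform(9.4, 15.6) # mean 12.5, sd 1.7898
#' @export
normal_from_uniform <- function(low, high) {
  if (any(low > high)) stop("low must not exceed high", call. = FALSE)
  c(mean = (low + high) / 2, sd = (high - low) / sqrt(12))
}

kind_domain <- function(kind) {
  switch(kind,
         probability = c(0, 1),
         rate_per_100k = c(0, Inf),
         count = c(0, Inf),
         qaly_weight = c(0, Inf),
         c(-Inf, Inf))
}

#' Sample parameter draws
#'
#' Draws `n` values for every parameter in the set, in the set's parameter
#' order (which fixes the RNG stream and makes results reproducible given a
#' seed). Uniform mode samples `U(low, high)`; `normal_matched` mode samples
#' the variance-matched normal of [normal_from_uniform()] and clamps each
#' value to the parameter kind's physical domain (probabilities to `[0, 1]`,
#' rates, counts and QALY weights to `>= 0`). Clamping rather than rejection
#' keeps the draw count and RNG stream fixed.
#'
#' @param ranges A [parameter_set()].
#' @param n Number of draws.
#' @param kind `"uniform"` or `"normal_matched"`.
#' @return An `n x p` numeric matrix with one named column per parameter.
#'   With `n = 1` this is a one-row matrix usable as a draw for [run_cpb()]
#'   via `drop()`.
#' @export
sample_draws <- function(ranges, n, kind = c("uniform", "normal_matched")) {
  stopifnot(inherits(ranges, "parameter_set"), n >= 1)
  kind <- match.arg(kind)
  n <- as.integer(n)
  cols <- lapply(unclass(ranges), function(r) {
    if (r$low == r$high) return(rep(r$low, n))
    if (kind == "uniform") {
      stats::runif(n, r$low, r$high)
    } else {
      ms <- normal_from_uniform(r$low, r$high)
      dom <- kind_domain(r$kind)
      pmin(pmax(stats::rnorm(n, ms[["mean"]], ms[["sd"]]), dom[1]), dom[2])
    }
  })
  matrix(unlist(cols), nrow = n, dimnames = list(NULL, names(ranges)))
}

#' One parameter draw as a named vector
#'
#' Convenience wrapper around [sample_draws()] with `n = 1`.
#'
#' @inheritParams sample_draws
#' @return Named numeric vector.
#' @export
sample_draw <- function(ranges, kind = c("uniform", "normal_matched")) {
  drop(sample_draws(ranges, 1L, kind))
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Run a Monte Carlo CPB simulation
#'
#' Samples `config$n_iterations` independent parameter draws and evaluates the
#' model on each, yielding that many estimates of QALYs saved per thousand
#' interventions. Fully reproducible given `config$seed`; the estimates are
#' effectively converged by about `1e4` iterations, with `1e6` the
#' conventional reporting scale.
#'
#' @param model A [cohort_model()] (or any object with a [model_evaluate()]
#'   method, e.g. a synthetic [make_product_chain()] model).
#' @param ranges A [parameter_set()] covering the model's parameters.
#' @param config A [sim_config()].
#' @return Numeric vector of length `n_iterations`.
#' @seealso [summarize_sample()], [convergence_trace()], [simulate_rate()]
#' @export
run_simulation <- function(model, ranges, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  missing <- if (inherits(model, "cohort_model")) {
    setdiff(model_parameters(model), names(ranges))
  } else character()
  if (length(missing)) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with_optional_seed(config$seed, {
    draws <- sample_draws(ranges, config$n_iterations,
                          config$input_distribution)
    unname(model_evaluate(model, draws))
  })
}

#' Per-intervention QALY-rate estimate
#'
#' The summary object reported per intervention: mean, standard deviation and
#' a central quantile interval of QALYs saved per thousand interventions,
#' either simulated or taken from the literature.
#'
#' @param intervention Intervention name.
#' @param mean,sd Mean and standard deviation (QALYs / 10^3 interventions).
#' @param qi_low,qi_high Quantile-interval bounds (may be `NA` for
#'   literature-derived estimates, which carry no distribution).
#' @param n_iterations Number of Monte Carlo iterations behind the estimate
#'   (`NA` for literature values).
#' @param source `"simulated"` or `"literature"`.
#' @return An object of class `qaly_rate_estimate`.
#' @export
qaly_rate_estimate <- function(intervention, mean, sd,
                               qi_low = NA_real_, qi_high = NA_real_,
                               n_iterations = NA_integer_,
                               source = c("simulated", "literature")) {
  source <- match.arg(source)
  stopifnot(sd >= 0)
  if (!is.na(qi_low) && !is.na(qi_high) && qi_low > qi_high) {
    stop("quantile interval bounds are inverted", call. = FALSE)
  }
  structure(
    list(intervention = intervention, mean = as.numeric(mean),
         sd = as.numeric(sd), qi_low = as.numeric(qi_low),
         qi_high = as.numeric(qi_high),
         n_iterations = n_iterations, source = source),
    class = "qaly_rate_estimate"
  )
}

#' @export
print.qaly_rate_estimate <- function(x, ...) {
  cat(sprintf("<qaly_rate_estimate> %s: %s QALYs/10^3 interventions [%s]\n",
              x$intervention, render_estimate(x), x$source))
  invisible(x)
}

#' Summarise a simulated sample into a rate estimate
#'
#' Mean, sample standard deviation (`n - 1` denominator) and empirical
#' quantiles at the requested levels. Quantiles use the standard
#' linear-interpolation rule (R type 7), so results are reproducible
#' bit-for-bit.
#'
#' @param sample Non-empty numeric vector of simulated rates.
#' @param levels Two quantile levels (default `c(0.025, 0.975)`).
#' @param intervention Name recorded in the estimate.
#' @return A [qaly_rate_estimate()] with `source = "simulated"`.
#' @export
summarize_sample <- function(sample, levels = c(0.025, 0.975),
                             intervention = "simulated") {
  if (length(sample) == 0L) stop("sample is empty", call. = FALSE)
  q <- stats::quantile(sample, probs = levels, names = FALSE, type = 7)
  qaly_rate_estimate(
    intervention = intervention,
    mean = mean(sample),
    sd = if (length(sample) > 1L) stats::sd(sample) else 0,
    qi_low = q[1], qi_high = q[2],
    n_iterations = length(sample), source = "simulated"
  )
}

#' Simulate and summarise in one call
#'
#' @inheritParams run_simulation
#' @param intervention Name recorded in the estimate.
#' @return A [qaly_rate_estimate()].
#' @export
simulate_rate <- function(model, ranges, config = sim_config(),
                          intervention = if (inherits(model, "cohort_model"))
                            model$name else "simulated") {
  summarize_sample(run_simulation(model, ranges, config),
                   levels = config$quantile_levels,
                   intervention = intervention)
}

#' Convergence trace of a Monte Carlo simulation
#'
#' Runs a single simulation stream of `max(checkpoints)` iterations and
#' summarises the first `k` values at each checkpoint `k`, showing how the
#' mean and standard deviation stabilise as iterations accumulate.
#'
#' @inheritParams run_simulation
#' @param checkpoints Increasing vector of iteration counts.
#' @return Data frame with columns `n`, `mean`, `sd`, `qi_low`, `qi_high`.
#' @export
convergence_trace <- function(model, ranges, config = sim_config(),
                              checkpoints = 10^(2:4)) {
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop("checkpoints must be strictly increasing", call. = FALSE)
  }
  full <- run_simulation(model, ranges,
                         sim_config(n_iterations = max(checkpoints),
                                    seed = config$seed,
                                    input_distribution = config$input_distribution,
                                    quantile_levels = config$quantile_levels))
  rows <- lapply(checkpoints, function(k) {
    est <- summarize_sample(full[seq_len(k)], config$quantile_levels)
    data.frame(n = k, mean = est$mean, sd = est$sd,
               qi_low = est$qi_low, qi_high = est$qi_high)
  })
  do.call(rbind, rows)
}
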