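#' Synthetic product-chain fixtures with closed-form oracles
#'
#' A product-chain model multiplies `n` independent uniform parameters; its
#' output mean and standard deviation have closed forms, making it an exact
#' oracle for the Monte Carlo machinery. For `U(a, b)`,
#' `E[X] = (a + b) / 2` and `E[X^2] = (a^2 + ab + b^2) / 3`; for a product of
#' independent factors the mean is the product of means and
#' `Var = prod(E[X_i^2]) - prod(E[X_i])^2`.
#'
#' @param n Number of factors, `n >= 1`.
#' @param seed Optional seed; when given, the factor ranges are themselves
#'   randomised (low in `[0, 0.5]`, high in `(low, 1]`), giving a family of
#'   distinct fixtures. Without a seed every factor is `U(0, 1)`.
#' @param bounds Optional `n x 2` matrix of explicit `(low, high)` bounds,
#'   overriding both defaults.
#' @return List with `model` (class `product_chain_model`, usable with
#'   [run_simulation()]), `ranges` (a [parameter_set()]), and the analytic
#'   `mean` and `sd` of the model output.
#' @examples
#' fx <- make_product_chain(2)
#' fx$mean  # 0.25
#' fx$sd    # sqrt((1/3)^2 - (1/4)^2) = 0.2485
#' @export
make_product_chain <- function(n, seed = NULL, bounds = NULL) {
  stopifnot(n >= 1)
  if (is.null(bounds)) {
    bounds <- if (is.null(seed)) {
      cbind(rep(0, n), rep(1, n))
    } else {
      withr::with_seed(seed, {
        lo <- stats::runif(n, 0, 0.5)
        hi <- lo + stats::runif(n, 0.05, 1 - lo)
        cbind(lo, pmin(hi, 1))
      })
    }
  }
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  stopifnot(nrow(bounds) == n)
  nm <- sprintf("factor_%02d", seq_len(n))
  ranges <- parameter_set(lapply(seq_len(n), function(i) {
    parameter_range(nm[i], bounds[i, 1], bounds[i, 2],
                    units = "dimensionless", kind = "probability")
  }))
  m <- (bounds[, 1] + bounds[, 2]) / 2
  m2 <- (bounds[, 1]^2 + bounds[, 1] * bounds[, 2] + bounds[, 2]^2) / 3
  model <- structure(list(name = sprintf("product_chain_%d", n), params = nm),
                     class = "product_chain_model")
  list(model = model, ranges = ranges,
       mean = prod(m), sd = sqrt(max(prod(m2) - prod(m)^2, 0)))
}

#' @rdname model_evaluate
#' @export
model_evaluate.product_chain_model <- function(model, draws) {
  out <- rep(1, nrow(draws))
  for (p in model$params) {
    if (!p %in% colnames(draws)) {
      stop("draws are missing required parameter '", p, "'", call. = FALSE)
    }
    out <- out * draws[, p]
  }
  out
}

#' Influenza-vaccination cohort model and parameter ranges
#'
#' Builds the bundled two-stratum (ages 50–64 and 65+), three-channel
#' (mortality, hospitalization, influenza-like illness) birth-cohort model
#' for annual influenza vaccination, together with its parameter ranges.
#' Ranges for the senior mortality rate (9.4–15.6 per 100,000/yr), mortality
#' efficacy (0.35–0.55), senior coverage (0.43–0.72), adherence (0.75–0.95),
#' illness efficacy (0.10–0.30) and the sick-time QALY weight (0.20–0.40) are
#' literature values; the remaining ranges (50–64 stratum, hospitalization
#' and illness incidence, hospitalization efficacy, per-illness weight) are
#' plausibility placeholders, flagged as such in their `note` field, because
#' no published range is available for them. Quantities that depend on the
#' placeholders are therefore illustrative, not literature estimates.
#'
#' @param seniors_only If `TRUE`, keep only the 65+ stratum.
#' @return List with `model` (a [cohort_model()]) and `ranges`
#'   (a [parameter_set()]).
#' @export
make_influenza_like <- function(seniors_only = FALSE) {
  ph <- "placeholder range, not literature-sourced"
  ranges <- parameter_set(
    parameter_range("adherence", 0.75, 0.95, "probability/yr", "probability"),
    parameter_range("coverage_65plus", 0.43, 0.72, "fraction", "probability"),
    parameter_range("coverage_50_64", 0.30, 0.50, "fraction", "probability",
                    note = ph),
    parameter_range("mortality_rate_65plus", 9.4, 15.6, "per 100,000/yr",
                    "rate_per_100k"),
    parameter_range("mortality_rate_50_64", 0.8, 2.2, "per 100,000/yr",
                    "rate_per_100k", note = ph),
    parameter_range("hospitalization_rate_65plus", 200, 400, "per 100,000/yr",
                    "rate_per_100k", note = ph),
    parameter_range("hospitalization_rate_50_64", 40, 100, "per 100,000/yr",
                    "rate_per_100k", note = ph),
    parameter_range("illness_rate_65plus", 4000, 8000, "per 100,000/yr",
                    "rate_per_100k", note = ph),
    parameter_range("illness_rate_50_64", 3000, 7000, "per 100,000/yr",
                    "rate_per_100k", note = ph),
    parameter_range("efficacy_mortality", 0.35, 0.55, "fraction", "probability"),
    parameter_range("efficacy_hospitalization", 0.25, 0.45, "fraction",
                    "probability", note = ph),
    parameter_range("efficacy_illness", 0.10, 0.30, "fraction", "probability"),
    parameter_range("qaly_weight_sickness", 0.20, 0.40, "QALY/event",
                    "qaly_weight"),
    parameter_range("qaly_weight_illness", 0.004, 0.012, "QALY/event",
                    "qaly_weight",
                    note = paste(ph, "- sick-time utility decrement times",
                                 "an illness duration of one to two weeks"))
  )
  stratum <- function(label, py, coverage, suffix) {
    age_stratum(label, py, coverage, list(
      event_channel("mortality",
                    paste0("mortality_rate_", suffix), "efficacy_mortality"),
      event_channel("hospitalization",
                    paste0("hospitalization_rate_", suffix),
                    "efficacy_hospitalization",
                    qaly_weight_param = "qaly_weight_sickness"),
      event_channel("illness",
                    paste0("illness_rate_", suffix), "efficacy_illness",
                    qaly_weight_param = "qaly_weight_illness")
    ))
  }
  strata <- list(stratum("65+", 5e7, "coverage_65plus", "65plus"))
  if (!seniors_only) {
    strata <- c(list(stratum("50-64", 6e7, "coverage_50_64", "50_64")), strata)
  }
  model <- cohort_model(
    if (seniors_only) "influenza_seniors" else "influenza_50plus",
    strata, "adherence", birth_cohort_size = 4e6
  )
  list(model = model, ranges = ranges)
}

#' Collapse every range to its midpoint
#'
#' @param ranges A [parameter_set()].
#' @return Named numeric vector of midpoints, usable as a [run_cpb()] draw.
#' @export
midpoint_draw <- function(ranges) {
  stopifnot(inherits(ranges, "parameter_set"))
  vapply(unclass(ranges), function(r) (r$low + r$high) / 2, numeric(1))
}

#' Write fixture files with oracle sidecars
#'
#' Materialises seeded product-chain fixtures and the influenza model as
#' files: parameter YAMLs, model YAMLs, and JSON sidecars holding the
#' closed-form oracle mean/sd and the generating seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base seed; fixture `i` uses `seed + i`.
#' @param n_chains Number of product-chain fixtures.
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixture_files <- function(dir, seed = 1L, n_chains = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (i in seq_len(n_chains)) {
    fx <- make_product_chain(n = 1L + i, seed = seed + i)
    pf <- file.path(dir, sprintf("product_chain_%d_params.yaml", i))
    of <- file.path(dir, sprintf("product_chain_%d_oracle.json", i))
    write_parameter_set(fx$ranges, pf)
    jsonlite::write_json(
      list(mean = fx$mean, sd = fx$sd, seed = seed + i,
           n_parameters = length(fx$ranges)),
      of, auto_unbox = TRUE, digits = NA)
    written <- c(written, pf, of)
  }
  flu <- make_influenza_like()
  pf <- file.path(dir, "influenza_params.yaml")
  mf <- file.path(dir, "influenza_model.yaml")
  write_parameter_set(flu$ranges, pf)
  write_cohort_model(flu$model, mf)
  invisible(c(written, pf, mf))
}
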