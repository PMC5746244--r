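#' Literature-derived QALY rates and the fixed coefficient of variation
#'
#' For interventions whose published burden calculations are not detailed
#' enough to parametrize a simulation, only a mean QALY rate is available.
#' The standard deviation is then approximated by a fixed coefficient of
#' variation of one third — a value inside the 15–40% band of CVs observed
#' across the simulated interventions — so that these services can still enter
#' the clinic-impact variance propagation.
#'
#' @param mean Mean QALYs per thousand interventions, non-negative.
#' @return `cv_estimate()`: `mean / 3`.
#' @examples
#' cv_estimate(33)   # 11, colonoscopy
#' cv_estimate(6.0)  # 2.0, adult obesity screening
#' @export
cv_estimate <- function(mean) {
  if (any(mean < 0)) stop("mean must be non-negative", call. = FALSE)
  mean / 3
}

#' @rdname cv_estimate
#' @param intervention Intervention name.
#' @param citation Free-text citation tag for the source of the mean.
#' @return `literature_rate()`: an object of class `literature_rate`.
#' @export
literature_rate <- function(intervention, mean, citation = "") {
  if (mean < 0) stop("mean must be non-negative", call. = FALSE)
  structure(
    list(intervention = intervention, mean = as.numeric(mean),
         citation = as.character(citation)),
    class = "literature_rate"
  )
}

#' @rdname cv_estimate
#' @param lit A `literature_rate`.
#' @return `to_rate_estimate()`: a [qaly_rate_estimate()] with
#'   `sd = cv_estimate(mean)`, `source = "literature"`, and no quantile
#'   interval (none exists without a simulated distribution). The stored sd is
#'   unrounded; rendered output truncates to two significant figures (see
#'   [format_sig()] with `floor = TRUE`), which is how `17/3 = 5.667` prints
#'   as `5.6`.
#' @export
to_rate_estimate <- function(lit) {
  stopifnot(inherits(lit, "literature_rate"))
  qaly_rate_estimate(
    intervention = lit$intervention,
    mean = lit$mean, sd = cv_estimate(lit$mean),
    source = "literature"
  )
}

#' Bundled per-intervention QALY-rate table
#'
#' Returns the bundled table of QALYs saved per thousand interventions:
#' six simulated rows (mean, SD and 95% quantile interval from 1e6-iteration
#' Monte Carlo runs over literature parameter ranges) and nine
#' literature-derived rows (published means with the fixed CV = 1/3 SD).
#' These printed summary values are the inputs of the clinic-impact layer.
#'
#' @param path Optional path to an alternative rates CSV with columns
#'   `intervention,label,mean,sd,qi_low,qi_high,source`.
#' @return Data frame, one row per intervention.
#' @seealso [scenario_impact()], [ucc_service_menu()]
#' @export
ucc_rate_table <- function(path = system.file("extdata", "ucc_rates.csv",
                                              package = "cpbsim")) {
  rates <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("intervention", "label", "mean", "sd", "qi_low", "qi_high",
                "source")
  missing <- setdiff(required, names(rates))
  if (length(missing)) {
    stop("rates table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(rates$mean < 0) || any(rates$sd < 0, na.rm = TRUE)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  rates
}

#' Look up one intervention's rate estimate from a rates table
#'
#' @param rates Data frame as returned by [ucc_rate_table()].
#' @param intervention Intervention key.
#' @return A [qaly_rate_estimate()].
#' @export
rate_from_table <- function(rates, intervention) {
  i <- match(intervention, rates$intervention)
  if (is.na(i)) {
    stop("unknown intervention '", intervention, "' (have: ",
         paste(rates$intervention, collapse = ", "), ")", call. = FALSE)
  }
  qaly_rate_estimate(
    intervention = if ("label" %in% names(rates)) rates$label[i] else intervention,
    mean = rates$mean[i], sd = rates$sd[i],
    qi_low = rates$qi_low[i], qi_high = rates$qi_high[i],
    source = rates$source[i]
  )
}
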