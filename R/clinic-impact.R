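#' Economic assumptions for the clinic-impact layer
#'
#' @param cost_per_qaly Dollar value of one QALY saved (default 132,200:
#'   a conservative 2003 estimate of $100,000/QALY adjusted for inflation to
#'   2017, combining healthcare costs, lost wages, and societal willingness to
#'   pay).
#' @param cost_cv Year-to-year fractional fluctuation of the QALY value
#'   (default 0.20), used only in the `with_cost_variance` dollar mode.
#' @param annual_budget Clinic annual operating budget in dollars (default
#'   50,000).
#' @param exam_cost Out-of-pocket cost of a physical exam for an uninsured
#'   patient (default $230).
#' @param uninsured_fraction Fraction of exams assumed to go to uninsured
#'   patients (default 0.5).
#' @return An object of class `economic_assumptions`.
#' @export
economic_assumptions <- function(cost_per_qaly = 132200, cost_cv = 0.20,
                                 annual_budget = 50000, exam_cost = 230,
                                 uninsured_fraction = 0.5) {
  vals <- c(cost_per_qaly, cost_cv, annual_budget, exam_cost,
            uninsured_fraction)
  if (any(vals < 0)) stop("economic assumptions must be non-negative", call. = FALSE)
  if (uninsured_fraction > 1) stop("uninsured_fraction must be <= 1", call. = FALSE)
  structure(
    list(cost_per_qaly = cost_per_qaly, cost_cv = cost_cv,
         annual_budget = annual_budget, exam_cost = exam_cost,
         uninsured_fraction = uninsured_fraction),
    class = "economic_assumptions"
  )
}

#' A clinic service: an intervention at an annual volume
#'
#' @param intervention Intervention key (must match a rates-table row when
#'   used via [scenario_impact()] with a table).
#' @param rate A [qaly_rate_estimate()] giving QALYs per thousand
#'   interventions.
#' @param annual_volume Interventions delivered per year.
#' @param volume_cv Fractional year-to-year fluctuation in volume, interpreted
#'   as the standard deviation of the annual volume divided by its mean
#'   (default 0.20).
#' @return An object of class `clinic_service`.
#' @export
clinic_service <- function(intervention, rate, annual_volume,
                           volume_cv = 0.20) {
  stopifnot(inherits(rate, "qaly_rate_estimate"))
  if (annual_volume < 0) stop("annual_volume must be non-negative", call. = FALSE)
  if (volume_cv < 0 || volume_cv >= 1) {
    stop("volume_cv must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(intervention = intervention, rate = rate,
         annual_volume = as.numeric(annual_volume),
         volume_cv = as.numeric(volume_cv)),
    class = "clinic_service"
  )
}

#' Annual QALYs saved by one service
#'
#' Multiplies the per-thousand-interventions QALY rate by the annual volume.
#' Rate and volume are treated as independent random variables (rate
#' uncertainty from the Monte Carlo or CV estimate; volume fluctuating
#' year-to-year with standard deviation `volume_cv * volume`), so the variance
#' of their product is the exact product-variance formula
#' `m_r^2 s_v^2 + v^2 s_r^2 + s_r^2 s_v^2`.
#'
#' @param rate A [qaly_rate_estimate()].
#' @param volume Annual interventions.
#' @param volume_cv Fractional volume fluctuation (standard deviation / mean).
#' @return Named numeric `c(mean, sd)` in QALYs per year.
#' @examples
#' obesity <- qaly_rate_estimate("obesity", 6.0, 2.0, source = "literature")
#' annual_qalys(obesity, 500)  # 3.0 (1.18) QALYs/year
#' @export
annual_qalys <- function(rate, volume, volume_cv = 0.20) {
  stopifnot(inherits(rate, "qaly_rate_estimate"), volume >= 0,
            volume_cv >= 0, volume_cv < 1)
  s_v <- volume_cv * volume
  s_r <- rate$sd
  mean <- rate$mean * volume / 1000
  var <- (rate$mean^2 * s_v^2 + volume^2 * s_r^2 + s_r^2 * s_v^2) / 1e6
  c(mean = mean, sd = sqrt(var))
}

#' Annual dollars saved by one service
#'
#' Converts annual QALYs into thousands of dollars per year at the assumed
#' dollar value of a QALY. In `"row"` mode (the default, and the convention
#' of the per-service impact tables) the dollar SD is the QALY SD scaled by
#' the cost mean; `"with_cost_variance"` additionally folds the cost
#' fluctuation `cost_cv * cost_per_qaly` into the product-variance formula.
#'
#' @param qalys Named numeric `c(mean, sd)` from [annual_qalys()].
#' @param econ An [economic_assumptions()].
#' @param mode `"row"` or `"with_cost_variance"`.
#' @return Named numeric `c(mean, sd)` in thousands of dollars per year.
#' @export
annual_dollars <- function(qalys, econ = economic_assumptions(),
                           mode = c("row", "with_cost_variance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(econ, "economic_assumptions"))
  c_k <- econ$cost_per_qaly / 1000  # thousands of dollars per QALY
  mean <- qalys[["mean"]] * c_k
  sd <- if (mode == "row") {
    qalys[["sd"]] * c_k
  } else {
    s_c <- econ$cost_cv * c_k
    sqrt(qalys[["mean"]]^2 * s_c^2 + c_k^2 * qalys[["sd"]]^2 +
           qalys[["sd"]]^2 * s_c^2)
  }
  c(mean = mean, sd = sd)
}

impact_row <- function(intervention, label, qalys, dollars) {
  data.frame(intervention = intervention, label = label,
             qalys_mean = qalys[["mean"]], qalys_sd = qalys[["sd"]],
             dollars_mean = dollars[["mean"]], dollars_sd = dollars[["sd"]],
             stringsAsFactors = FALSE)
}

#' Aggregate per-service impact rows into a total
#'
#' Under the independence assumption, total means are column sums and total
#' variances are sums of row variances (so the total SD is the root of the
#' sum of squared row SDs).
#'
#' @param rows Data frame of impact rows (columns `qalys_mean`, `qalys_sd`,
#'   `dollars_mean`, `dollars_sd`).
#' @return One-row data frame of the same shape, labelled `"Total"`.
#' @export
aggregate_impact <- function(rows) {
  if (is.null(nrow(rows)) || nrow(rows) == 0L) {
    stop("cannot aggregate an empty set of impact rows", call. = FALSE)
  }
  data.frame(
    intervention = "total", label = "Total",
    qalys_mean = sum(rows$qalys_mean),
    qalys_sd = sqrt(sum(rows$qalys_sd^2)),
    dollars_mean = sum(rows$dollars_mean),
    dollars_sd = sqrt(sum(rows$dollars_sd^2)),
    stringsAsFactors = FALSE
  )
}

#' Annual impact of a clinic service menu
#'
#' For each service, composes [annual_qalys()] and [annual_dollars()] and
#' aggregates the rows into a total. This is the machinery behind the annual
#' health-and-economic impact tables: QALYs/year and thousands of dollars per
#' year, each with a standard deviation from the independence-based variance
#' propagation.
#'
#' @param services List of [clinic_service()] objects.
#' @param econ An [economic_assumptions()].
#' @param mode Dollar-SD mode, see [annual_dollars()].
#' @return An object of class `impact_table`: list with `rows` (data frame,
#'   one per service) and `total` (one-row data frame).
#' @examples
#' rates <- ucc_rate_table()
#' menu <- ucc_service_menu("current")
#' impact <- scenario_impact(services_from_menu(menu, rates))
#' impact$total
#' @export
scenario_impact <- function(services, econ = economic_assumptions(),
                            mode = c("row", "with_cost_variance")) {
  mode <- match.arg(mode)
  ok <- vapply(services, inherits, logical(1), "clinic_service")
  if (!length(services) || !all(ok)) {
    stop("services must be a non-empty list of clinic_service objects",
         call. = FALSE)
  }
  rows <- do.call(rbind, lapply(services, function(s) {
    q <- annual_qalys(s$rate, s$annual_volume, s$volume_cv)
    d <- annual_dollars(q, econ, mode)
    impact_row(s$intervention, s$rate$intervention, q, d)
  }))
  structure(list(rows = rows, total = aggregate_impact(rows), econ = econ),
            class = "impact_table")
}

#' @export
print.impact_table <- function(x, ...) {
  cat(render_impact_table(x), sep = "\n")
  invisible(x)
}

#' Annual return on investment
#'
#' @param total_dollars Total thousands of dollars saved per year.
#' @param budget Annual operating budget in dollars.
#' @return `total_dollars * 1000 / budget`, the fold-return on the budget.
#' @examples
#' roi(858, 50000)  # > 17
#' @export
roi <- function(total_dollars, budget) {
  if (budget <= 0) stop("budget must be positive", call. = FALSE)
  total_dollars * 1000 / budget
}

#' Costs waived for uninsured patients
#'
#' Free exams are themselves a saving to patients that the QALY accounting
#' does not capture: `n_patients * uninsured_fraction * exam_cost` dollars
#' per year.
#'
#' @param n_patients Annual exams given.
#' @param uninsured_fraction Fraction of exams going to uninsured patients.
#' @param exam_cost Out-of-pocket cost of one exam, dollars.
#' @return Dollars saved per year.
#' @examples
#' uninsured_exam_savings(500, 0.5, 230)  # 57,500
#' @export
uninsured_exam_savings <- function(n_patients, uninsured_fraction, exam_cost) {
  if (any(c(n_patients, uninsured_fraction, exam_cost) < 0) ||
      uninsured_fraction > 1) {
    stop("inputs must be non-negative with uninsured_fraction <= 1", call. = FALSE)
  }
  n_patients * uninsured_fraction * exam_cost
}

#' Bundled clinic service menus
#'
#' `"current"` is the menu of services delivered at the studied clinic
#' (universal screenings at the full 500-patient annual load; 100 diabetes
#' screenings; 10 mammography referrals; 50 adult and 5 senior influenza
#' vaccinations). `"prospective"` is the what-if menu of candidate additions
#' (universal depression screening, 50 cholesterol screenings, 10 colonoscopy
#' referrals). Both assume a 20% year-to-year volume fluctuation.
#'
#' @param which `"current"` or `"prospective"`, or ignored when `path` is
#'   given.
#' @param path Optional path to a menu CSV with columns
#'   `intervention,annual_volume,volume_cv`.
#' @return Data frame with columns `intervention`, `annual_volume`,
#'   `volume_cv`.
#' @export
ucc_service_menu <- function(which = c("current", "prospective"),
                             path = NULL) {
  if (is.null(path)) {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("menu_ucc_", which, ".csv"),
                        package = "cpbsim")
  }
  menu <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("intervention", "annual_volume", "volume_cv")
  missing <- setdiff(required, names(menu))
  if (length(missing)) {
    stop("menu is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  menu
}

#' Build clinic services from a menu and a rates table
#'
#' @param menu Data frame as from [ucc_service_menu()].
#' @param rates Data frame as from [ucc_rate_table()].
#' @return List of [clinic_service()] objects, in menu order.
#' @export
services_from_menu <- function(menu, rates = ucc_rate_table()) {
  lapply(seq_len(nrow(menu)), function(i) {
    clinic_service(
      intervention = menu$intervention[i],
      rate = rate_from_table(rates, menu$intervention[i]),
      annual_volume = menu$annual_volume[i],
      volume_cv = menu$volume_cv[i]
    )
  })
}
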