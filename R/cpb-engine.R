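#' Elementary operations of the clinically-preventable-burden chain
#'
#' The CPB of a preventive intervention is computed by comparing the current
#' (partially-covered) disease burden with the counterfactual burden that would
#' occur if no one received the intervention, and then asking how much of that
#' counterfactual burden an offer of the intervention to the whole birth cohort
#' would avert. These five functions are the elementary steps; [run_cpb()]
#' chains them across age strata and event channels. All are vectorised over
#' their numeric arguments.
#'
#' @param rate_per_100k Annual event rate per 100,000 person-years.
#' @param person_years Person-years of exposure in the stratum.
#' @return `attributable_events()`: the expected number of events,
#'   `rate_per_100k / 1e5 * person_years`.
#' @examples
#' attributable_events(12.5, 5e7)  # 6250 influenza deaths at the midpoint rate
#' @name cpb-ops
#' @export
attributable_events <- function(rate_per_100k, person_years) {
  if (any(rate_per_100k < 0) || any(person_years < 0)) {
    stop("rates and person-years must be non-negative", call. = FALSE)
  }
  rate_per_100k / 1e5 * person_years
}

#' @rdname cpb-ops
#' @param current_events Observed events under present coverage.
#' @param coverage Fraction of the population currently receiving the
#'   intervention (pre-existing uptake, not the program under study).
#' @param efficacy Per-recipient probability that the intervention prevents
#'   the event.
#' @return `counterfactual_burden()`: events expected with zero coverage,
#'   `current_events / (1 - coverage * efficacy)`. The observed burden is what
#'   remains after `coverage * efficacy` of the counterfactual burden has
#'   already been averted, hence the back-calculation by division.
#' @export
counterfactual_burden <- function(current_events, coverage, efficacy) {
  if (any(current_events < 0)) stop("current_events must be non-negative", call. = FALSE)
  if (any(coverage < 0) || any(efficacy < 0)) {
    stop("coverage and efficacy must be non-negative", call. = FALSE)
  }
  ce <- coverage * efficacy
  if (any(ce >= 1)) {
    stop("coverage * efficacy must be < 1 (counterfactual diverges)", call. = FALSE)
  }
  current_events / (1 - ce)
}

#' @rdname cpb-ops
#' @param adherence Probability that an offered intervention is accepted.
#' @return `effectiveness()`: `adherence * efficacy`, the realised fraction of
#'   preventable events averted when the intervention is offered to everyone.
#' @export
effectiveness <- function(adherence, efficacy) {
  if (any(adherence < 0 | adherence > 1) || any(efficacy < 0 | efficacy > 1)) {
    stop("adherence and efficacy must lie in [0, 1]", call. = FALSE)
  }
  adherence * efficacy
}

#' @rdname cpb-ops
#' @param counterfactual Counterfactual event count.
#' @return `prevented_events()`: `counterfactual * effectiveness`.
#' @export
prevented_events <- function(counterfactual, effectiveness) {
  if (any(counterfactual < 0) || any(effectiveness < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  if (any(effectiveness > 1)) stop("effectiveness must be <= 1", call. = FALSE)
  counterfactual * effectiveness
}

#' @rdname cpb-ops
#' @param prevented Named list (or vector) of prevented event counts per
#'   channel.
#' @param weights Named list (or vector) of per-event QALY decrements, aligned
#'   with `prevented`. A prevented death contributes a full weight of 1 QALY;
#'   morbidity channels carry fractional weights.
#' @return `qalys_saved()`: `sum(prevented * weights)`.
#' @export
qalys_saved <- function(prevented, weights) {
  prevented <- unlist(prevented)
  weights <- unlist(weights)
  if (!is.null(names(prevented)) && !is.null(names(weights))) {
    weights <- weights[names(prevented)]
  }
  stopifnot(length(prevented) == length(weights))
  if (any(weights < 0)) stop("QALY weights must be non-negative", call. = FALSE)
  if ("mortality" %in% names(weights) && any(weights[["mortality"]] != 1)) {
    stop("mortality channel must carry a QALY weight of exactly 1", call. = FALSE)
  }
  sum(prevented * weights)
}

#' @rdname cpb-ops
#' @param total_qalys Total QALYs saved in the cohort.
#' @param n_interventions Number of interventions delivered.
#' @return `qalys_per_1e3()`: `total_qalys / n_interventions * 1000`, the
#'   reporting scale used throughout (QALYs per thousand interventions).
#' @export
qalys_per_1e3 <- function(total_qalys, n_interventions) {
  if (any(n_interventions <= 0)) {
    stop("n_interventions must be positive", call. = FALSE)
  }
  total_qalys / n_interventions * 1000
}

#' Define an event channel of a cohort model
#'
#' A channel is one kind of preventable event (mortality, hospitalization, or
#' illness) within an age stratum. It names the parameters that supply its
#' incidence rate and intervention efficacy, and either names a QALY-weight
#' parameter or fixes a constant weight. The mortality channel always has
#' weight 1.
#'
#' @param name `"mortality"`, `"hospitalization"`, or `"illness"`.
#' @param incidence_param Name of the rate-per-100k parameter.
#' @param efficacy_param Name of the efficacy parameter for this channel.
#' @param qaly_weight_param Name of the QALY-weight parameter (morbidity
#'   channels), or `NULL` to use `qaly_weight`.
#' @param qaly_weight Constant weight; must be 1 for mortality.
#' @export
event_channel <- function(name = c("mortality", "hospitalization", "illness"),
                          incidence_param, efficacy_param,
                          qaly_weight_param = NULL, qaly_weight = NULL) {
  name <- match.arg(name)
  if (name == "mortality") {
    if (!is.null(qaly_weight_param) || (!is.null(qaly_weight) && qaly_weight != 1)) {
      stop("mortality channel must have constant QALY weight 1", call. = FALSE)
    }
    qaly_weight <- 1
  } else if (is.null(qaly_weight_param) && is.null(qaly_weight)) {
    stop("channel '", name, "' needs qaly_weight_param or qaly_weight",
         call. = FALSE)
  }
  structure(
    list(name = name, incidence_param = incidence_param,
         efficacy_param = efficacy_param,
         qaly_weight_param = qaly_weight_param,
         qaly_weight = if (is.null(qaly_weight)) NULL else as.numeric(qaly_weight)),
    class = "event_channel"
  )
}

#' Define an age stratum of a cohort model
#'
#' @param label Stratum label, e.g. `"65+"`.
#' @param person_years Person-years the birth cohort spends in the stratum
#'   (about 5e7 for ages 65+ in a cohort of four million).
#' @param coverage_param Name of the pre-existing coverage parameter for the
#'   stratum.
#' @param channels List of [event_channel()] objects.
#' @export
age_stratum <- function(label, person_years, coverage_param, channels) {
  person_years <- as.numeric(person_years)
  stopifnot(length(person_years) == 1L, person_years > 0)
  ok <- vapply(channels, inherits, logical(1), "event_channel")
  if (!all(ok)) stop("channels must be event_channel objects", call. = FALSE)
  structure(
    list(label = label, person_years = person_years,
         coverage_param = coverage_param, channels = channels),
    class = "age_stratum"
  )
}

#' Define a birth-cohort CPB model
#'
#' A cohort model describes how one draw of the input parameters is turned
#' into QALYs saved per thousand interventions: per stratum and channel,
#' attributable events are scaled up to the no-intervention counterfactual,
#' multiplied by the realised effectiveness (adherence x efficacy) to give
#' prevented events, weighted into QALYs, summed, and normalised by the number
#' of interventions delivered.
#'
#' The intervention denominator is `sum(person_years) * adherence` —
#' interventions actually delivered when the service is offered to the whole
#' cohort — by default; set `denominator = "person_years"` to count offers
#' instead, or `"cohort"` to normalise by the birth-cohort size.
#'
#' @param name Model name.
#' @param strata List of [age_stratum()] objects (non-overlapping ages;
#'   computed independently and summed — no transmission effects between
#'   strata).
#' @param adherence_param Name of the adherence parameter shared by all
#'   strata.
#' @param birth_cohort_size Cohort size in persons (default 4e6).
#' @param denominator `"delivered"` (default), `"person_years"`, or
#'   `"cohort"`.
#' @return An object of class `cohort_model`.
#' @seealso [run_cpb()], [read_cohort_model()]
#' @export
cohort_model <- function(name, strata, adherence_param,
                         birth_cohort_size = 4e6,
                         denominator = c("delivered", "person_years", "cohort")) {
  stopifnot(birth_cohort_size > 0)
  ok <- vapply(strata, inherits, logical(1), "age_stratum")
  if (!all(ok)) stop("strata must be age_stratum objects", call. = FALSE)
  labels <- vapply(strata, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("strata labels must be unique", call. = FALSE)
  structure(
    list(name = name, strata = strata, adherence_param = adherence_param,
         birth_cohort_size = as.numeric(birth_cohort_size),
         denominator = match.arg(denominator)),
    class = "cohort_model"
  )
}

#' @export
print.cohort_model <- function(x, ...) {
  n_chan <- sum(vapply(x$strata, function(s) length(s$channels), integer(1)))
  cat(sprintf("<cohort_model> %s: %d strata, %d channels, cohort %g\n",
              x$name, length(x$strata), n_chan, x$birth_cohort_size))
  invisible(x)
}

#' Parameter names a cohort model consumes
#'
#' @param model A [cohort_model()].
#' @return Character vector of required parameter names.
#' @export
model_parameters <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  nm <- model$adherence_param
  for (s in model$strata) {
    nm <- c(nm, s$coverage_param)
    for (ch in s$channels) {
      nm <- c(nm, ch$incidence_param, ch$efficacy_param, ch$qaly_weight_param)
    }
  }
  unique(nm)
}

draw_value <- function(draw, name) {
  if (!name %in% names(draw)) {
    stop("draw is missing required parameter '", name, "'", call. = FALSE)
  }
  draw[[name]]
}

#' Run the CPB chain for one parameter draw
#'
#' Deterministically chains [attributable_events()], [counterfactual_burden()],
#' [effectiveness()], [prevented_events()], [qalys_saved()] and
#' [qalys_per_1e3()] across the model's strata and channels.
#'
#' @param model A [cohort_model()].
#' @param draw Named numeric vector (or list) holding one sampled value per
#'   parameter named by the model.
#' @return An object of class `cpb_result` with elements `events` (data frame
#'   of current / counterfactual / prevented counts and QALYs per stratum and
#'   channel), `total_qalys`, `n_interventions`, and `qalys_per_1e3`.
#' @examples
#' m <- cohort_model("toy",
#'   strata = list(age_stratum("65+", 5e7, "coverage",
#'     list(event_channel("mortality", "mort_rate", "efficacy")))),
#'   adherence_param = "adherence")
#' run_cpb(m, c(mort_rate = 12.5, coverage = 0.575,
#'              efficacy = 0.45, adherence = 0.85))
#' @export
run_cpb <- function(model, draw) {
  stopifnot(inherits(model, "cohort_model"))
  draw <- as.list(draw)
  adherence <- draw_value(draw, model$adherence_param)
  rows <- list()
  for (s in model$strata) {
    coverage <- draw_value(draw, s$coverage_param)
    for (ch in s$channels) {
      rate <- draw_value(draw, ch$incidence_param)
      efficacy <- draw_value(draw, ch$efficacy_param)
      weight <- if (is.null(ch$qaly_weight_param)) ch$qaly_weight
                else draw_value(draw, ch$qaly_weight_param)
      current <- attributable_events(rate, s$person_years)
      counterfactual <- counterfactual_burden(current, coverage, efficacy)
      eff <- effectiveness(adherence, efficacy)
      prevented <- prevented_events(counterfactual, eff)
      qalys <- qalys_saved(stats::setNames(list(prevented), ch$name),
                           stats::setNames(list(weight), ch$name))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s$label, channel = ch$name,
        current = current, counterfactual = counterfactual,
        prevented = prevented, qalys = qalys,
        stringsAsFactors = FALSE
      )
    }
  }
  events <- do.call(rbind, rows)
  total_qalys <- sum(events$qalys)
  py <- sum(vapply(model$strata, `[[`, numeric(1), "person_years"))
  n_int <- switch(model$denominator,
                  delivered = py * adherence,
                  person_years = py,
                  cohort = model$birth_cohort_size)
  # degenerate but well-defined: nothing delivered, nothing saved
  qp <- if (n_int > 0) qalys_per_1e3(total_qalys, n_int)
        else if (total_qalys == 0) 0
        else qalys_per_1e3(total_qalys, n_int)  # error: saved QALYs without interventions
  structure(
    list(events = events, total_qalys = total_qalys,
         n_interventions = n_int, qalys_per_1e3 = qp),
    class = "cpb_result"
  )
}

#' @export
print.cpb_result <- function(x, ...) {
  cat(sprintf("<cpb_result> %.4g QALYs / 10^3 interventions (%.4g QALYs, %.4g interventions)\n",
              x$qalys_per_1e3, x$total_qalys, x$n_interventions))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Evaluate a model on a matrix of parameter draws
#'
#' Generic used by the Monte Carlo layer: given an `n x p` matrix of draws
#' (columns named after parameters), return the `n` model outputs. For
#' `cohort_model` the output is QALYs per thousand interventions; the chain is
#' evaluated in vectorised arithmetic, and agrees element-wise with
#' [run_cpb()] applied row by row.
#'
#' @param model A model object.
#' @param draws Numeric matrix with one column per parameter.
#' @return Numeric vector of length `nrow(draws)`.
#' @export
model_evaluate <- function(model, draws) UseMethod("model_evaluate")

#' @rdname model_evaluate
#' @export
model_evaluate.cohort_model <- function(model, draws) {
  col <- function(name) {
    if (!name %in% colnames(draws)) {
      stop("draws are missing required parameter '", name, "'", call. = FALSE)
    }
    draws[, name]
  }
  adherence <- col(model$adherence_param)
  total <- 0
  for (s in model$strata) {
    coverage <- col(s$coverage_param)
    for (ch in s$channels) {
      efficacy <- col(ch$efficacy_param)
      weight <- if (is.null(ch$qaly_weight_param)) ch$qaly_weight
                else col(ch$qaly_weight_param)
      current <- attributable_events(col(ch$incidence_param), s$person_years)
      counterfactual <- counterfactual_burden(current, coverage, efficacy)
      prevented <- prevented_events(counterfactual,
                                    effectiveness(adherence, efficacy))
      total <- total + prevented * weight
    }
  }
  py <- sum(vapply(model$strata, `[[`, numeric(1), "person_years"))
  n_int <- switch(model$denominator,
                  delivered = py * adherence,
                  person_years = py,
                  cohort = model$birth_cohort_size)
  if (length(n_int) == 1L) n_int <- rep(n_int, length(total))
  zero <- n_int == 0 & total == 0
  if (any(zero)) {
    out <- rep(0, length(total))
    out[!zero] <- qalys_per_1e3(total[!zero], n_int[!zero])
    out
  } else {
    qalys_per_1e3(total, n_int)
  }
}

#' Read / write a cohort model definition (YAML)
#'
#' The file names the strata, their person-years and coverage parameters, the
#' event channels with the parameter names each consumes, and the adherence
#' parameter and denominator convention.
#'
#' @param path Path to a YAML model file.
#' @return `read_cohort_model()`: a [cohort_model()].
#' @export
read_cohort_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  strata <- lapply(doc$strata, function(s) {
    channels <- lapply(s$channels, function(ch) {
      event_channel(ch[["name"]], ch[["incidence_param"]],
                    ch[["efficacy_param"]],
                    qaly_weight_param = ch[["qaly_weight_param"]],
                    qaly_weight = ch[["qaly_weight"]])
    })
    age_stratum(s[["label"]], s[["person_years"]], s[["coverage_param"]],
                channels)
  })
  cohort_model(doc$name, strata, doc$adherence_param,
               birth_cohort_size = if (is.null(doc$birth_cohort_size)) 4e6
                                   else doc$birth_cohort_size,
               denominator = if (is.null(doc$denominator)) "delivered"
                             else doc$denominator)
}

#' @rdname read_cohort_model
#' @param model A [cohort_model()].
#' @return `write_cohort_model()`: `path`, invisibly.
#' @export
write_cohort_model <- function(model, path) {
  stopifnot(inherits(model, "cohort_model"))
  doc <- list(
    name = model$name,
    birth_cohort_size = model$birth_cohort_size,
    adherence_param = model$adherence_param,
    denominator = model$denominator,
    strata = lapply(model$strata, function(s) {
      list(label = s$label, person_years = s$person_years,
           coverage_param = s$coverage_param,
           channels = lapply(s$channels, function(ch) {
             out <- list(name = ch$name,
                         incidence_param = ch$incidence_param,
                         efficacy_param = ch$efficacy_param)
             if (!is.null(ch$qaly_weight_param)) {
               out$qaly_weight_param <- ch$qaly_weight_param
             } else {
               out$qaly_weight <- ch$qaly_weight
             }
             out
           }))
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
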