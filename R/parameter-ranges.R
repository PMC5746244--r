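#' Parameter ranges and parameter sets
#'
#' A `parameter_range` is one named model input with `[low, high]` bounds, a
#' unit string, and a `kind` that fixes its physical domain. Parameter ranges
#' are the elementary inputs of the clinically-preventable-burden (CPB)
#' machinery: the literature typically reports only a minimum and maximum for
#' each quantity (mortality rate, vaccine efficacy, adherence, ...), which is
#' sufficient to parametrize a uniform sampling distribution.
#'
#' Recognised kinds and their domains:
#' * `probability` — both bounds in `[0, 1]`
#' * `rate_per_100k` — annual event rate per 100,000 person-years, non-negative
#' * `count` — non-negative count (e.g. person-years, cohort size)
#' * `qaly_weight` — per-event QALY decrement, non-negative
#'
#' Degenerate ranges with `low == high` are legal and encode fixed constants.
#'
#' @param name Parameter identifier (unique within a set).
#' @param low,high Numeric bounds, `low <= high`.
#' @param units Free-text unit annotation.
#' @param kind One of `"probability"`, `"rate_per_100k"`, `"count"`,
#'   `"qaly_weight"`.
#' @param note Optional free-text annotation; used to flag placeholder ranges
#'   that are not literature-sourced.
#' @return An object of class `parameter_range`.
#' @examples
#' parameter_range("mortality_rate_65plus", 9.4, 15.6,
#'                 units = "per 100,000/yr", kind = "rate_per_100k")
#' @export
parameter_range <- function(name, low, high, units = "", kind = "probability",
                            note = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (length(low) != 1L || length(high) != 1L || is.na(low) || is.na(high)) {
    stop("parameter '", name, "': bounds must be single finite numbers",
         call. = FALSE)
  }
  kind <- match.arg(kind, parameter_kinds())
  if (low > high) {
    stop("parameter '", name, "': low (", low, ") exceeds high (", high, ")",
         call. = FALSE)
  }
  if (kind == "probability" && (low < 0 || high > 1)) {
    stop("parameter '", name, "': probability bounds must lie in [0, 1]",
         call. = FALSE)
  }
  if (kind %in% c("rate_per_100k", "count", "qaly_weight") && low < 0) {
    stop("parameter '", name, "': kind '", kind, "' must be non-negative",
         call. = FALSE)
  }
  structure(
    list(name = name, low = low, high = high,
         units = as.character(units), kind = kind,
         note = if (is.null(note)) NULL else as.character(note)),
    class = "parameter_range"
  )
}

parameter_kinds <- function() {
  c("probability", "rate_per_100k", "count", "qaly_weight")
}

#' @export
print.parameter_range <- function(x, ...) {
  cat(sprintf("<parameter_range> %s [%g, %g] %s (%s)%s\n",
              x$name, x$low, x$high, x$units, x$kind,
              if (!is.null(x$note)) paste0(" -- ", x$note) else ""))
  invisible(x)
}

#' Bundle parameter ranges into a named set
#'
#' @param ... `parameter_range` objects, or a single list of them.
#' @return An object of class `parameter_set`: a list of ranges keyed by
#'   parameter name.
#' @examples
#' ps <- parameter_set(
#'   parameter_range("adherence", 0.75, 0.95, kind = "probability"),
#'   parameter_range("efficacy", 0.35, 0.55, kind = "probability")
#' )
#' @export
parameter_set <- function(...) {
  ranges <- list(...)
  if (length(ranges) == 1L && is.list(ranges[[1L]]) &&
      !inherits(ranges[[1L]], "parameter_range")) {
    ranges <- ranges[[1L]]
  }
  ok <- vapply(ranges, inherits, logical(1), "parameter_range")
  if (!all(ok)) stop("all elements must be parameter_range objects", call. = FALSE)
  nm <- vapply(ranges, `[[`, character(1), "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate parameter names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(ranges) <- nm
  structure(ranges, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' @export
`[.parameter_set` <- function(x, i) {
  parameter_set(unclass(x)[i])
}

#' Read a parameter set from a YAML file
#'
#' The on-disk dialect is one YAML document per intervention: a top-level
#' `parameters:` sequence whose entries carry `name`, `low`, `high`, `units`,
#' `kind`, and optionally `note`. [write_parameter_set()] emits the same
#' dialect, and `read_parameter_set(write_parameter_set(ps, f))` is the
#' identity on any valid set.
#'
#' @param path Path to a YAML parameter file.
#' @return A [parameter_set()].
#' @seealso [write_parameter_set()], [validate_parameter_set()]
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  entries <- doc[["parameters"]]
  if (is.null(entries)) {
    stop("malformed parameter file '", path, "': missing 'parameters' block",
         call. = FALSE)
  }
  ranges <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    for (field in c("name", "low", "high", "kind")) {
      if (is.null(e[[field]])) {
        stop("malformed parameter entry ", i, " in '", path,
             "': missing field '", field, "'", call. = FALSE)
      }
    }
    parameter_range(e$name, e$low, e$high,
                    units = if (is.null(e$units)) "" else e$units,
                    kind = e$kind, note = e$note)
  })
  parameter_set(ranges)
}

#' Write a parameter set to a YAML file
#'
#' @param ranges A [parameter_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ranges, path) {
  stopifnot(inherits(ranges, "parameter_set"))
  entries <- lapply(unclass(ranges), function(r) {
    e <- list(name = r$name, low = r$low, high = r$high,
              units = r$units, kind = r$kind)
    if (!is.null(r$note)) e$note <- r$note
    e
  })
  yaml::write_yaml(list(parameters = unname(entries)), path, precision = 15)
  invisible(path)
}

#' Validate a parameter set against a list of required names
#'
#' Checks that every required parameter name appears exactly once and that all
#' range invariants hold (they are enforced at construction, so an object that
#' exists is internally valid; this re-checks defensively for lists assembled
#' by hand). Validation is order-independent.
#'
#' @param ranges A [parameter_set()] (or plain list of `parameter_range`).
#' @param required Character vector of parameter names that must be present.
#' @return `TRUE` if valid; `FALSE` (with a `missing` attribute naming absent
#'   parameters) if required names are missing. Structural violations
#'   (duplicates, inverted bounds, out-of-domain probabilities) are errors.
#' @export
validate_parameter_set <- function(ranges, required = character()) {
  if (!inherits(ranges, "parameter_set")) ranges <- parameter_set(ranges)
  for (r in ranges) {
    # re-run constructor checks so hand-edited objects cannot slip through
    parameter_range(r$name, r$low, r$high, units = r$units, kind = r$kind,
                    note = r$note)
  }
  missing <- setdiff(required, names(ranges))
  if (length(missing)) {
    return(structure(FALSE, missing = missing))
  }
  TRUE
}

#' Simulation configuration
#'
#' @param n_iterations Number of Monte Carlo iterations (default `1e6`, the
#'   scale at which the per-intervention estimates are fully converged; `1e4`
#'   already gives near-converged means).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param input_distribution `"uniform"` to sample each parameter from
#'   `U(low, high)`, or `"normal_matched"` for a normal with the same mean and
#'   variance (see [normal_from_uniform()]), clamped to the parameter's domain.
#' @param quantile_levels Two quantile levels for the reported quantile
#'   interval (default `c(0.025, 0.975)`, the central 95% interval).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_iterations = 1e6, seed = NULL,
                       input_distribution = c("uniform", "normal_matched"),
                       quantile_levels = c(0.025, 0.975)) {
  n_iterations <- as.numeric(n_iterations)
  stopifnot(length(n_iterations) == 1L, n_iterations >= 1,
            n_iterations == floor(n_iterations))
  input_distribution <- match.arg(input_distribution)
  stopifnot(length(quantile_levels) == 2L)
  if (!(0 < quantile_levels[1] && quantile_levels[1] < quantile_levels[2] &&
        quantile_levels[2] < 1)) {
    stop("quantile_levels must satisfy 0 < lo < hi < 1", call. = FALSE)
  }
  structure(
    list(n_iterations = as.integer(n_iterations),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         input_distribution = input_distribution,
         quantile_levels = as.numeric(quantile_levels)),
    class = "sim_config"
  )
}
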