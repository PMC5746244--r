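#' Format a number at a fixed count of significant figures
#'
#' Renders `x` at `digits` significant figures, preserving trailing zeros
#' ("0.030", "1.0") and never using scientific notation. With `floor = TRUE`
#' the value is truncated toward zero instead of rounded — the convention
#' used when rendering literature-derived standard deviations, where
#' `17/3 = 5.667` prints as `5.6` and `0.50/3 = 0.1667` as `0.16`.
#'
#' @param x Numeric scalar or vector.
#' @param digits Significant figures (default 2).
#' @param floor Truncate toward zero instead of rounding.
#' @return Character vector.
#' @export
format_sig <- function(x, digits = 2, floor = FALSE) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return(paste0("0.", strrep("0", digits - 1)))
    s <- if (floor) signif_floor(v, digits) else signif_half_away(v, digits)
    decimals <- max(0L, digits - 1L - floor(log10(abs(s))))
    formatC(s, format = "f", digits = decimals)
  }, character(1))
}

#' @rdname format_sig
#' @return `signif_half_away()`: numeric, `x` rounded at `digits` significant
#'   figures with ties going away from zero (the usual print convention,
#'   unlike the round-half-even rule of [signif()]).
#' @export
signif_half_away <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v) || v == 0) return(v)
    scale <- 10^(digits - 1 - floor(log10(abs(v))))
    floor(abs(v) * scale + 0.5 + 1e-9) / scale * sign(v)
  }, numeric(1))
}

#' @rdname format_sig
#' @return `signif_floor()`: numeric, `x` truncated toward zero at `digits`
#'   significant figures.
#' @export
signif_floor <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v) || v == 0) return(v)
    scale <- 10^(digits - 1 - floor(log10(abs(v))))
    # nudge before truncating so exactly-representable values are not
    # dragged down by floating-point representation error
    trunc(abs(v) * scale + 1e-9) / scale * sign(v)
  }, numeric(1))
}

render_thousands <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (abs(v) >= 10) {
      formatC(floor(abs(v) + 0.5) * sign(v), format = "d")
    } else {
      format_sig(v, 2)
    }
  }, character(1))
}

#' Render a QALY-rate estimate in table style
#'
#' Produces the `"mean (sd)  [lo, hi]"` style used in the per-intervention
#' summary tables, at two significant figures; the quantile interval is
#' omitted when absent (literature-derived rates).
#'
#' @param est A [qaly_rate_estimate()].
#' @return Character scalar, e.g. `"2.9 (1.0)  [1.4, 5.2]"`.
#' @export
render_estimate <- function(est) {
  stopifnot(inherits(est, "qaly_rate_estimate"))
  sd_txt <- if (est$source == "literature") {
    format_sig(est$sd, 2, floor = TRUE)
  } else {
    format_sig(est$sd, 2)
  }
  out <- sprintf("%s (%s)", format_sig(est$mean, 2), sd_txt)
  if (!is.na(est$qi_low) && !is.na(est$qi_high)) {
    out <- sprintf("%s  [%s, %s]", out,
                   format_sig(est$qi_low, 2), format_sig(est$qi_high, 2))
  }
  out
}

#' Render an impact table at paper precision
#'
#' QALY columns are shown at two significant figures; dollar columns
#' (thousands per year) as integers at or above 10 and at two significant
#' figures below.
#'
#' @param x An `impact_table` from [scenario_impact()].
#' @return Character vector of lines (header, one line per service, total).
#' @export
render_impact_table <- function(x) {
  stopifnot(inherits(x, "impact_table"))
  all_rows <- rbind(x$rows, x$total)
  lines <- sprintf("%-55s %s (%s)\t%s (%s)",
                   all_rows$label,
                   format_sig(all_rows$qalys_mean, 2),
                   format_sig(all_rows$qalys_sd, 2),
                   render_thousands(all_rows$dollars_mean),
                   render_thousands(all_rows$dollars_sd))
  c(sprintf("%-55s %s\t%s", "Intervention", "QALYs/year (SD)",
            "Thousands of Dollars (SD)"),
    lines)
}

#' Impact table as a plain data frame for delimited export
#'
#' @param x An `impact_table`.
#' @return Data frame of rows plus the total row.
#' @export
impact_as_data_frame <- function(x) {
  stopifnot(inherits(x, "impact_table"))
  rbind(x$rows, x$total)
}

#' Gaussian kernel-density export of a simulated sample
#'
#' Evaluates a Gaussian-kernel density estimate on an evenly spaced grid
#' covering the sample (extended by three bandwidths so the curve integrates
#' to one), for plotting the distribution of simulated QALY rates. The
#' default bandwidth is Scott's rule; the trapezoid integral of the exported
#' curve is 1 within 1%.
#'
#' @param sample Numeric vector, at least two distinct values.
#' @param n_grid Number of grid points (default 512).
#' @param bandwidth Optional bandwidth override.
#' @return Data frame with columns `x` and `density`.
#' @export
kde_export <- function(sample, n_grid = 512, bandwidth = NULL) {
  if (length(sample) < 2) {
    stop("need at least two observations for a density estimate", call. = FALSE)
  }
  if (stats::sd(sample) == 0) {
    stop("sample is constant; a density estimate is degenerate - use a histogram",
         call. = FALSE)
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd(sample) else bandwidth
  d <- stats::density(sample, bw = bw, kernel = "gaussian", n = n_grid)
  data.frame(x = d$x, density = d$y)
}

#' Write a run manifest next to an output file
#'
#' Every file produced by the command-line interface is accompanied by a
#' small JSON manifest (same path plus `.manifest.json`) echoing the command,
#' its arguments, the seed and the package version — enough to reproduce the
#' output exactly.
#'
#' @param out_path Path of the output file the manifest describes.
#' @param command Command or function name.
#' @param args Named list of arguments to echo.
#' @param seed Seed used (or `NULL`).
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(out_path, command, args = list(), seed = NULL) {
  manifest <- list(
    command = command,
    args = args,
    seed = seed,
    output = basename(out_path),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "cpbsim",
    version = as.character(utils::packageVersion("cpbsim"))
  )
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
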