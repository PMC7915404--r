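#' Polarizability of an attitude profile
#'
#' Fraction of agents holding an extreme opinion: `|x|` strictly greater
#' than the cutoff (default 0.8). Only agents that hold an attitude should
#' be passed in; an empty input returns 0 by convention.
#'
#' @param x Attitude vector in \[-1, 1\] (`NA`s, i.e. agents with no
#'   attitude, are dropped).
#' @param threshold Extremity cutoff (default 0.8).
#' @return Fraction in \[0, 1\].
#' @export
polarizability <- function(x, threshold = 0.8) {
  x <- x[!is.na(x)]
  if (!length(x)) return(0)
  if (any(abs(x) > 1 + 1e-12))
    stop("attitudes must lie in [-1, 1]", call. = FALSE)
  mean(abs(x) > threshold)
}

#' Peak compartment count
#'
#' Maximum over time of one compartment's count series in a simulation or
#' ensemble result (for ensembles, the pointwise-mean series).
#'
#' @param result A `seirja_result` or `ensemble_result`.
#' @param compartment One of `"S"`, `"E"`, `"I"`, `"R"`.
#' @return The peak count.
#' @export
peak_count <- function(result, compartment = c("S", "E", "I", "R")) {
  compartment <- match.arg(compartment)
  counts <- if (inherits(result, "ensemble_result")) result$mean_counts
            else result$counts
  max(counts[[compartment]])
}

#' Daily comment-proportion curve
#'
#' Aggregates a simulation into days of `steps_per_day` steps and reports,
#' for each day, the number of distinct agents that were in the
#' communication state at any step of that day, divided by the number of
#' distinct agents ever in the communication state during the run. An agent
#' commenting on several days is counted once per day (so the series can sum
#' to more than 1); set `first_day_only = TRUE` to attribute each agent to
#' its first active day instead (the series then sums to exactly 1).
#'
#' Day `d` covers the post-step snapshots of steps `(d-1)*steps_per_day + 1`
#' through `d*steps_per_day`; the initial communicators are folded into
#' day 1.
#'
#' @param result A `seirja_result` (or classic-baseline result) carrying
#'   per-step communicator sets.
#' @param steps_per_day Steps per calendar day (>= 1).
#' @param first_day_only Attribute each commenter only to its first day.
#' @return A `curve_series` data frame with columns `t` (day index, from 1)
#'   and `value`.
#' @export
comment_proportion_series <- function(result, steps_per_day = 5,
                                      first_day_only = FALSE) {
  if (steps_per_day < 1) stop("steps_per_day must be >= 1", call. = FALSE)
  sets <- result$comm_sets
  total <- unique(unlist(sets))
  step_sets <- sets[-1]
  n_days <- max(1L, ceiling(length(step_sets) / steps_per_day))
  seen <- integer(0)
  vals <- vapply(seq_len(n_days), function(d) {
    idx <- ((d - 1) * steps_per_day + 1):min(d * steps_per_day,
                                             length(step_sets))
    day_users <- unique(unlist(step_sets[idx]))
    if (d == 1L) day_users <- unique(c(day_users, sets[[1]]))
    if (first_day_only) {
      day_users <- setdiff(day_users, seen)
      seen <<- c(seen, day_users)
    }
    if (length(total) == 0) 0 else length(day_users) / length(total)
  }, numeric(1))
  curve_series(seq_len(n_days), vals, label = "comment_proportion")
}

#' Curve container
#'
#' A labeled time/value series; the common currency of the comparison
#' metrics. Serializes to CSV with header `t,value`.
#'
#' @param t Time axis (steps or days).
#' @param value Values, same length as `t`.
#' @param label Optional label.
#' @return A data frame of class `curve_series`.
#' @export
curve_series <- function(t, value, label = NULL) {
  if (length(t) != length(value))
    stop("t and value must have equal length", call. = FALSE)
  structure(data.frame(t = t, value = value),
            label = label, class = c("curve_series", "data.frame"))
}

#' @rdname curve_series
#' @param curve A `curve_series`.
#' @param path Output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("t", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname curve_series
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  curve_series(df$t, df$value)
}

#' Root-mean-square error between two curves
#'
#' `sqrt(mean((a - b)^2))` over two equal-length series. Proportion curves
#' are compared on the percentage-point scale, so pass `percent = TRUE`
#' (default) when the inputs are fractions in \[0, 1\].
#'
#' @param curve_a,curve_b `curve_series` objects or plain numeric vectors of
#'   equal length.
#' @param percent Multiply fractional inputs by 100 before comparing.
#' @return The RMSE (in percentage points when `percent = TRUE`).
#' @export
curve_rmse <- function(curve_a, curve_b, percent = TRUE) {
  a <- if (is.data.frame(curve_a)) curve_a$value else curve_a
  b <- if (is.data.frame(curve_b)) curve_b$value else curve_b
  if (length(a) != length(b))
    stop("curves must have equal length", call. = FALSE)
  if (percent) { a <- 100 * a; b <- 100 * b }
  sqrt(mean((a - b)^2))
}

#' Relative standard deviation
#'
#' `100 * sd / mean` of a sample; 0 when the mean is 0 or fewer than two
#' values are supplied. Used pointwise across ensemble runs and averaged
#' over time as the reproducibility index of an ensemble.
#'
#' @param values Numeric vector.
#' @return RSD in percent.
#' @export
relative_sd <- function(values) {
  if (!length(values)) stop("values must be nonempty", call. = FALSE)
  if (length(values) < 2) return(0)
  mu <- mean(values)
  if (mu == 0) return(0)
  100 * sd(values) / mu
}
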