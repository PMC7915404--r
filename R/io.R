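#' Synthetic comment stream
#'
#' Generates a timestamped sentiment-comment stream with the shape of a
#' crawled social-media comment table: one record per comment with a user
#' id, an hour-resolution timestamp and a sentiment score in \[-1, 1\]. The
#' stream is synthetic throughout — no real platform data is involved.
#'
#' The mechanism runs a coupled dissemination/polarization simulation at the
#' requested scale: every agent in the communication state at a step emits a
#' comment whose sentiment is its current attitude plus Gaussian noise
#' (sd 0.1), clipped to \[-1, 1\]. The emission pool is then calibrated to
#' the requested totals: exactly `round(first3h_share * n_comments)`
#' comments are placed in the first three hours (drawn from the earliest
#' emissions and recentered to `first3h_mean_sentiment`), the remainder are
#' resampled from the later emissions and spread uniformly within their
#' mapped day, and emitting agents are split or merged onto exactly
#' `n_users` user ids.
#'
#' @param n_comments Total number of comments.
#' @param n_users Number of distinct users (`<= n_comments`).
#' @param duration_days Period length in days (>= 1).
#' @param first3h_mean_sentiment Target mean sentiment of the first three
#'   hours.
#' @param first3h_share Share of all comments posted in the first three
#'   hours (default 0.05).
#' @param gamma Mainstream step of the underlying simulation; larger values
#'   yield more extreme late-period sentiments, `gamma = 0` freezes all
#'   sentiments near the initial mean. Default `0.025`.
#' @param N Agent count of the underlying simulation (default 500).
#' @param steps_per_day Simulation steps mapped onto one day (default 5).
#' @param start_date Period start (`Date` or string, hour 0).
#' @param seed Optional integer seed; fixed seed reproduces the stream.
#' @return A data frame of class `comment_stream` with columns `user_id`,
#'   `timestamp` (POSIXct, UTC) and `sentiment`, plus attributes
#'   `start_date` and `duration_days`.
#' @export
generate_comment_stream <- function(n_comments, n_users, duration_days,
                                    first3h_mean_sentiment = 0,
                                    first3h_share = 0.05,
                                    gamma = 0.025,
                                    N = 500L, steps_per_day = 5L,
                                    start_date = "2020-01-01",
                                    seed = NULL) {
  if (n_users > n_comments)
    stop("n_users must not exceed n_comments", call. = FALSE)
  if (duration_days < 1) stop("duration_days must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  horizon <- as.integer(duration_days * steps_per_day)
  pars <- seirja_params(
    N = N, d1 = 0.3, d2 = 0.7, p = 0.5, T0 = 0.8, gamma = gamma,
    z0 = max(1L, as.integer(round(0.75 * horizon))),
    init_comm_frac = max(1 / N, first3h_share),
    attitude_mean = first3h_mean_sentiment, attitude_sd = 0.4,
    max_steps = horizon
  )
  net <- default_network(pars)
  state <- init_state(pars, net)

  emit <- function(st) {
    who <- which(st$state == .I)
    if (!length(who)) return(NULL)
    data.frame(agent = who, step = st$t,
               sentiment = pmin(1, pmax(-1, st$x[who] + rnorm(length(who),
                                                              0, 0.1))))
  }
  events <- list(emit(state))
  while (state$t < horizon) {
    state <- sim_step(state, pars)
    events[[state$t + 1L]] <- emit(state)
  }
  pool <- do.call(rbind, events)
  if (is.null(pool) || !nrow(pool))
    stop("simulation produced no comments; increase first3h_share or N",
         call. = FALSE)

  n_first <- round(first3h_share * n_comments)
  n_rest <- n_comments - n_first

  # first-3h block: earliest emissions, recentered to the requested mean
  early <- pool[pool$step <= 1L, , drop = FALSE]
  if (!nrow(early)) early <- pool[pool$step == min(pool$step), , drop = FALSE]
  fi <- early[sample.int(nrow(early), n_first, replace = TRUE), , drop = FALSE]
  fi$sentiment <- pmin(1, pmax(-1, fi$sentiment +
                                 (first3h_mean_sentiment -
                                    mean(fi$sentiment))))
  fi$hour <- runif(n_first, 0, 3)

  # remainder: resample later emissions, uniform hour within the mapped day
  late <- pool[pool$step > 1L, , drop = FALSE]
  if (!nrow(late)) late <- pool
  re <- late[sample.int(nrow(late), n_rest, replace = TRUE), , drop = FALSE]
  day_of <- pmin(duration_days, ceiling(pmax(1L, re$step) / steps_per_day))
  lo <- ifelse(day_of == 1, 3, 0)  # keep day-1 stragglers out of the 3h window
  re$hour <- (day_of - 1) * 24 + lo + runif(n_rest) * (24 - lo)

  stream <- rbind(fi[, c("agent", "hour", "sentiment")],
                  re[, c("agent", "hour", "sentiment")])

  # map emitting agents onto exactly n_users synthetic user ids
  ids <- match(stream$agent, unique(stream$agent))
  k <- length(unique(ids))
  if (k > n_users) {
    ids[ids > n_users] <- sample.int(n_users, sum(ids > n_users),
                                     replace = TRUE)
  } else if (k < n_users) {
    # split events off multi-comment users until the target count is reached
    need <- n_users - k
    counts <- tabulate(ids)
    donors <- which(!seq_along(ids) %in% match(seq_len(k), ids) &
                      counts[ids] > 1)
    donors <- head(donors, need)
    ids[donors] <- k + seq_along(donors)
    if (length(donors) < need)
      stop("cannot realize n_users distinct users from this stream",
           call. = FALSE)
  }
  stream$user_id <- ids

  origin <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  stream$timestamp <- origin + floor(stream$hour) * 3600
  stream <- stream[order(stream$timestamp), c("user_id", "timestamp",
                                              "sentiment")]
  rownames(stream) <- NULL
  structure(stream, start_date = as.Date(start_date),
            duration_days = as.integer(duration_days),
            class = c("comment_stream", "data.frame"))
}

#' Summarize a comment stream
#'
#' Recomputes the period-level summary from the records: total comments,
#' distinct users, duration, and the share and mean sentiment of the
#' comments posted in the first three hours.
#'
#' @param stream A `comment_stream`.
#' @return A list with `n_comments`, `n_users`, `duration_days`,
#'   `first3h_share`, `first3h_mean`.
#' @export
stream_summary <- function(stream) {
  stopifnot(inherits(stream, "comment_stream"))
  t0 <- min(stream$timestamp)
  in3h <- as.numeric(stream$timestamp - t0, units = "hours") < 3
  list(
    n_comments = nrow(stream),
    n_users = length(unique(stream$user_id)),
    duration_days = attr(stream, "duration_days") %||%
      as.integer(ceiling(as.numeric(max(stream$timestamp) - t0,
                                    units = "days"))),
    first3h_share = mean(in3h),
    first3h_mean = if (any(in3h)) mean(stream$sentiment[in3h]) else 0
  )
}

stream_day <- function(stream) {
  t0 <- as.POSIXct(paste(attr(stream, "start_date") %||%
                           as.Date(min(stream$timestamp)), "00:00:00"),
                   tz = "UTC")
  pmax(1L, ceiling(as.numeric(stream$timestamp - t0, units = "days") + 1e-9))
}

#' Daily curves of a comment stream
#'
#' `stream_comment_curve()` is the daily distinct-commenter proportion (the
#' number of distinct users commenting each day over the distinct users of
#' the whole period); `stream_polarizability_curve()` is the daily fraction
#' of comments with `|sentiment|` above the extremity cutoff.
#'
#' @param stream A `comment_stream`.
#' @param threshold Extremity cutoff (default 0.8).
#' @return A `curve_series` with one row per day.
#' @export
stream_comment_curve <- function(stream) {
  stopifnot(inherits(stream, "comment_stream"))
  day <- stream_day(stream)
  n_days <- attr(stream, "duration_days") %||% max(day)
  total <- length(unique(stream$user_id))
  vals <- vapply(seq_len(n_days), function(d)
    length(unique(stream$user_id[day == d])) / total, numeric(1))
  curve_series(seq_len(n_days), vals, label = "actual_comment_proportion")
}

#' @rdname stream_comment_curve
#' @export
stream_polarizability_curve <- function(stream, threshold = 0.8) {
  stopifnot(inherits(stream, "comment_stream"))
  day <- stream_day(stream)
  n_days <- attr(stream, "duration_days") %||% max(day)
  vals <- vapply(seq_len(n_days), function(d) {
    s <- stream$sentiment[day == d]
    if (!length(s)) 0 else mean(abs(s) > threshold)
  }, numeric(1))
  curve_series(seq_len(n_days), vals, label = "actual_polarizability")
}

#' Comment-stream CSV input/output
#'
#' Header `user_id,timestamp,sentiment` with ISO-8601 UTC timestamps.
#'
#' @param stream A `comment_stream`.
#' @param path File path.
#' @param duration_days Optional period length when reading (inferred from
#'   the timestamp span otherwise).
#' @return `read_comment_stream()` returns a `comment_stream`;
#'   `write_comment_stream()` invisibly returns `path`.
#' @export
write_comment_stream <- function(stream, path) {
  stopifnot(inherits(stream, "comment_stream"))
  out <- data.frame(
    user_id = stream$user_id,
    timestamp = format(stream$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    sentiment = stream$sentiment
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_comment_stream
#' @export
read_comment_stream <- function(path, duration_days = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("user_id", "timestamp", "sentiment") %in% names(df)))
    stop("malformed comment stream: expected user_id,timestamp,sentiment",
         call. = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts)) stop("malformed timestamps in comment stream", call. = FALSE)
  if (any(abs(df$sentiment) > 1))
    stop("sentiment scores must lie in [-1, 1]", call. = FALSE)
  start <- as.Date(min(ts))
  if (is.null(duration_days))
    duration_days <- as.integer(ceiling(
      as.numeric(max(ts) - as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
                 units = "days")))
  structure(
    data.frame(user_id = df$user_id, timestamp = ts,
               sentiment = df$sentiment),
    start_date = start, duration_days = max(1L, duration_days),
    class = c("comment_stream", "data.frame")
  )
}

run_config_defaults <- function() {
  c(as.list(seirja_params()),
    list(n_runs = 10L, base_seed = 1L, steps_per_day = 5L, omega = 40))
}

#' Read and validate a run configuration
#'
#' A flat YAML (or JSON) key-value document whose keys are the
#' [seirja_params()] field names plus `n_runs`, `base_seed`,
#' `steps_per_day` and `omega`. Every key is defaulted; unknown keys and
#' out-of-range values are rejected with named errors
#' (`seirja_unknown_key`, `seirja_bad_value`).
#'
#' @param path Path to the config file; `NULL` yields the full default
#'   configuration.
#' @return A list of class `run_config` with elements `params`
#'   (a [seirja_params()]), `n_runs`, `base_seed`, `steps_per_day`,
#'   `omega`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    # YAML 1.1 reads a bare `N:` key as boolean FALSE; map it back to the
    # population-size key
    names(user)[names(user) == "FALSE"] <- "N"
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop(errorCondition(
        sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
        class = c("seirja_unknown_key", "error")
      ))
  }
  merged <- utils::modifyList(defaults, user)
  par_names <- names(formals(seirja_params))
  pars <- tryCatch(
    do.call(seirja_params, merged[intersect(names(merged), par_names)]),
    error = function(e) stop(errorCondition(
      conditionMessage(e), class = c("seirja_bad_value", "error")
    ))
  )
  structure(
    list(params = pars, n_runs = as.integer(merged$n_runs),
         base_seed = as.integer(merged$base_seed),
         steps_per_day = as.integer(merged$steps_per_day),
         omega = merged$omega),
    class = "run_config"
  )
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- c(unclass(config$params),
            list(n_runs = config$n_runs, base_seed = config$base_seed,
                 steps_per_day = config$steps_per_day, omega = config$omega))
  flat <- flat[!vapply(flat, is.null, logical(1))]
  flat$update_partner_mainstream <- as.logical(flat$update_partner_mainstream)
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' Write simulation outputs
#'
#' Serializes a single-run or ensemble result to a directory: compartment
#' counts and polarizability as CSV, plus a JSON manifest recording the
#' parameters, seeds and (for ensembles) the average relative standard
#' deviations, so any output can be regenerated from the manifest alone.
#'
#' @param result A `seirja_result` or `ensemble_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(result, "ensemble_result")) {
    utils::write.csv(result$mean_counts, file.path(dir, "mean_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    write_curve_csv(
      curve_series(result$mean_counts$t, result$mean_polarizability),
      file.path(dir, "mean_polarizability.csv")
    )
    pars <- result$runs[[1]]$params
    manifest <- list(kind = "ensemble", n_runs = result$n_runs,
                     base_seed = result$base_seed,
                     seeds = result$base_seed + seq_len(result$n_runs) - 1L,
                     avg_rsd = as.list(result$avg_rsd),
                     params = unclass(pars))
  } else {
    utils::write.csv(result$counts, file.path(dir, "counts.csv"),
                     row.names = FALSE, quote = FALSE)
    write_curve_csv(curve_series(result$counts$t, result$polarizability),
                    file.path(dir, "polarizability.csv"))
    manifest <- list(kind = "run", t_end = result$t_end,
                     reason = result$reason, params = unclass(result$params))
  }
  manifest$params <- manifest$params[!vapply(manifest$params, is.null,
                                             logical(1))]
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
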