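#' Parameter sweep over seeded ensembles
#'
#' Runs one Monte-Carlo ensemble per value of a single model parameter,
#' holding everything else at the supplied baseline. Ensemble `k` uses
#' seeds `base_seed + (k-1) * n_runs + (0:(n_runs-1))`, so all ensembles
#' are disjointly seeded and the whole sweep is reproducible from
#' `base_seed`.
#'
#' @param param Name of the swept [seirja_params()] field (e.g.
#'   `"init_comm_frac"`, `"z0"`, `"p"`, `"T0"`, `"gamma"`).
#' @param values Vector of values to sweep.
#' @param params Baseline parameters.
#' @param n_runs Runs per ensemble (default 10).
#' @param base_seed Base seed.
#' @return A `sweep_result` list: `param`, `values`, `ensembles` (one
#'   `ensemble_result` per value).
#' @export
run_sweep <- function(param, values, params = seirja_params(),
                      n_runs = 10, base_seed = 1) {
  stopifnot(inherits(params, "seirja_params"))
  if (!param %in% names(params))
    stop(sprintf("unknown parameter '%s'", param), call. = FALSE)
  ensembles <- lapply(seq_along(values), function(k) {
    pk <- unclass(params)
    pk[[param]] <- if (param %in% c("N", "z0", "max_steps", "ba_m", "ws_k"))
      as.integer(values[k]) else values[k]
    pk <- structure(pk, class = "seirja_params")
    validate_seirja_params(pk)
    run_ensemble(pk, n_runs = n_runs,
                 base_seed = base_seed + (k - 1L) * n_runs)
  })
  structure(list(param = param, values = values, ensembles = ensembles),
            class = "sweep_result")
}

#' Summarize a sweep
#'
#' One row per swept value: peak mean silent (E) and communication (I)
#' counts, the final mean polarizability, and the first time at which the
#' mean uninformed count falls below half the population (`NA` if it never
#' does).
#'
#' @param sweep A `sweep_result`.
#' @return A data frame.
#' @export
sweep_summary <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  rows <- lapply(seq_along(sweep$values), function(k) {
    ens <- sweep$ensembles[[k]]
    mc <- ens$mean_counts
    half <- which(mc$S < mc$S[1] / 2)
    data.frame(
      value = sweep$values[k],
      peak_E = max(mc$E),
      peak_I = max(mc$I),
      final_polarizability =
        ens$mean_polarizability[length(ens$mean_polarizability)],
      t_half_S = if (length(half)) mc$t[half[1]] else NA_integer_,
      avg_rsd_polar = unname(ens$avg_rsd["polarizability"])
    )
  })
  do.call(rbind, rows)
}

#' Polarizability at time checkpoints across a two-parameter grid
#'
#' Runs one ensemble per `(T0, gamma)` combination and reports the
#' ensemble-mean polarizability at each requested checkpoint (series are
#' carried forward at their final value when a run converges earlier).
#'
#' @param T0_values,gamma_values Grid axes.
#' @param checkpoints Time steps at which polarizability is read off.
#' @param params Baseline parameters.
#' @param n_runs Runs per ensemble.
#' @param base_seed Base seed.
#' @return A long data frame with columns `T0`, `gamma`, `t`,
#'   `polarizability`.
#' @export
run_polarization_grid <- function(T0_values = c(0.2, 0.4, 0.6, 0.8),
                                  gamma_values = c(0.05, 0.1, 0.15, 0.2),
                                  checkpoints = c(10, 20, 40, 70),
                                  params = seirja_params(),
                                  n_runs = 10, base_seed = 1) {
  grid <- expand.grid(T0 = T0_values, gamma = gamma_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pk <- unclass(params)
    pk$T0 <- grid$T0[k]; pk$gamma <- grid$gamma[k]
    pk <- structure(pk, class = "seirja_params")
    ens <- run_ensemble(pk, n_runs = n_runs,
                        base_seed = base_seed + (k - 1L) * n_runs)
    mp <- pad_forward(ens$mean_polarizability, max(checkpoints) + 1L)
    data.frame(T0 = grid$T0[k], gamma = grid$gamma[k], t = checkpoints,
               polarizability = mp[checkpoints + 1L])
  })
  do.call(rbind, rows)
}

#' Cross-network polarization comparison
#'
#' Runs matched ensembles on the scale-free, small-world and random
#' substrates at equal size and (approximately) equal mean degree, and
#' reports the ensemble polarizability curves, the final values, and the
#' realized scale statistics of each substrate.
#'
#' @param params Baseline parameters; the `network` field is overridden.
#' @param n_runs Runs per ensemble.
#' @param base_seed Base seed.
#' @return A `network_comparison` list: `networks` (character), `ensembles`,
#'   `final_polarizability` (named), `scale` (data frame of clustering and
#'   mean degree per family, one seeded instance each).
#' @export
run_network_comparison <- function(params = seirja_params(),
                                   n_runs = 10, base_seed = 1) {
  stopifnot(inherits(params, "seirja_params"))
  fams <- c("ba", "ws", "er")
  ensembles <- lapply(seq_along(fams), function(k) {
    pk <- unclass(params)
    pk$network <- fams[k]
    pk <- structure(pk, class = "seirja_params")
    run_ensemble(pk, n_runs = n_runs,
                 base_seed = base_seed + (k - 1L) * n_runs)
  })
  names(ensembles) <- fams
  finals <- vapply(ensembles, function(e)
    e$mean_polarizability[length(e$mean_polarizability)], numeric(1))
  nets <- list(ba = make_ba_network(params$N, params$ba_m, seed = base_seed),
               ws = make_ws_network(params$N, params$ws_k, params$ws_p,
                                    seed = base_seed),
               er = make_er_network(params$N, params$er_p, seed = base_seed))
  scale <- data.frame(
    network = fams,
    clustering = vapply(nets, network_clustering, numeric(1)),
    mean_degree = vapply(nets, average_degree, numeric(1))
  )
  structure(list(networks = fams, ensembles = ensembles,
                 final_polarizability = finals, scale = scale),
            class = "network_comparison")
}

#' Model configurations for an empirical-style period
#'
#' Translates the summary of a comment stream into the three model
#' configurations used in the empirical scenario: the initial communicator
#' fraction equals the share of comments posted in the first three hours,
#' the attention span is three quarters of the period horizon, the initial
#' attitude distribution is centered on the first-three-hour mean sentiment
#' with spread 0.4, and the mainstream step is `1 / omega`.
#'
#' @param summary A list/row with `duration_days`, `first3h_share`,
#'   `first3h_mean` (as produced by [stream_summary()]).
#' @param N Population size (default 500).
#' @param omega Inverse mainstream step (default 40, so `gamma = 0.025`).
#' @param steps_per_day Simulation steps per calendar day (default 5).
#' @return A list with elements `seirja` ([seirja_params()]),
#'   `classic_seir` ([classic_seir_params()]), `classic_ja`
#'   ([classic_ja_params()]) and `steps_per_day`.
#' @export
period_configs <- function(summary, N = 500L, omega = 40,
                           steps_per_day = 5L) {
  horizon <- as.integer(summary$duration_days * steps_per_day)
  list(
    seirja = seirja_params(
      N = N, d1 = 0.3, d2 = 0.7, p = 0.5, T0 = 0.8,
      gamma = 1 / omega,
      z0 = max(1L, as.integer(round(0.75 * horizon))),
      init_comm_frac = summary$first3h_share,
      attitude_mean = summary$first3h_mean, attitude_sd = 0.4,
      max_steps = horizon
    ),
    classic_seir = classic_seir_params(
      N = N, acceptance_coef = 1, dissemination_coef = 0.3,
      immune_coef = 0.2, init_comm_frac = summary$first3h_share,
      max_steps = horizon
    ),
    classic_ja = classic_ja_params(
      N = N, d1 = 0.3, d2 = 0.7, mu = 0.5,
      attitude_mean = summary$first3h_mean, attitude_sd = 0.4,
      max_steps = horizon
    ),
    steps_per_day = steps_per_day
  )
}

day_end_polarizability <- function(result, steps_per_day, n_days) {
  mp <- pad_forward(result$polarizability, n_days * steps_per_day + 1L)
  mp[pmin(length(mp), seq_len(n_days) * steps_per_day + 1L)]
}

#' Empirical-style scenario: three models against a comment stream
#'
#' Configures the coupled model and the two classic baselines from the
#' stream's summary ([period_configs()]), runs a seeded ensemble of each,
#' and compares the resulting daily comment-proportion and polarizability
#' curves with the curves computed from the stream itself, reporting the
#' root-mean-square error (percentage points) of each model curve.
#'
#' @param stream A `comment_stream` (see [generate_comment_stream()]).
#' @param N Population size.
#' @param omega Inverse mainstream step for the coupled model.
#' @param steps_per_day Steps per calendar day.
#' @param n_runs Runs per ensemble.
#' @param base_seed Base seed.
#' @return An `empirical_scenario` list: `summary`, `configs`, `curves`
#'   (named list of `curve_series`), `rmse` (data frame), `ensembles`.
#' @export
run_empirical_scenario <- function(stream, N = 500L, omega = 40,
                                   steps_per_day = 5L, n_runs = 10,
                                   base_seed = 1) {
  smry <- stream_summary(stream)
  cfg <- period_configs(smry, N = N, omega = omega,
                        steps_per_day = steps_per_day)
  n_days <- smry$duration_days

  ens_sj <- run_ensemble(cfg$seirja, n_runs = n_runs, base_seed = base_seed)
  ens_cs <- run_ensemble(cfg$classic_seir, n_runs = n_runs,
                         base_seed = base_seed + n_runs,
                         runner = run_classic_seir)
  ens_ja <- run_ensemble(cfg$classic_ja, n_runs = n_runs,
                         base_seed = base_seed + 2L * n_runs,
                         runner = run_classic_ja)

  mean_curve <- function(ens, fun) {
    vals <- vapply(ens$runs, function(r) fun(r)$value, numeric(n_days))
    curve_series(seq_len(n_days), rowMeans(vals))
  }
  comment_fun <- function(r) {
    # carry the final communicator set forward when a run converged early,
    # so every run spans the full period
    need <- n_days * steps_per_day + 1L
    if (length(r$comm_sets) < need)
      r$comm_sets <- c(r$comm_sets,
                       rep(r$comm_sets[length(r$comm_sets)],
                           need - length(r$comm_sets)))
    comment_proportion_series(r, steps_per_day = steps_per_day)
  }
  polar_fun <- function(r)
    curve_series(seq_len(n_days),
                 day_end_polarizability(r, steps_per_day, n_days))

  curves <- list(
    actual_comments = stream_comment_curve(stream),
    actual_polarizability = stream_polarizability_curve(stream),
    seirja_comments = mean_curve(ens_sj, comment_fun),
    classic_seir_comments = mean_curve(ens_cs, comment_fun),
    seirja_polarizability = mean_curve(ens_sj, polar_fun),
    classic_ja_polarizability = mean_curve(ens_ja, polar_fun)
  )
  rmse <- data.frame(
    model = c("seirja", "classic_seir", "seirja", "classic_ja"),
    metric = c("comment_proportion", "comment_proportion",
               "polarizability", "polarizability"),
    rmse = c(
      curve_rmse(curves$seirja_comments, curves$actual_comments),
      curve_rmse(curves$classic_seir_comments, curves$actual_comments),
      curve_rmse(curves$seirja_polarizability, curves$actual_polarizability),
      curve_rmse(curves$classic_ja_polarizability,
                 curves$actual_polarizability)
    )
  )
  structure(
    list(summary = smry, configs = cfg, curves = curves, rmse = rmse,
         ensembles = list(seirja = ens_sj, classic_seir = ens_cs,
                          classic_ja = ens_ja)),
    class = "empirical_scenario"
  )
}
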