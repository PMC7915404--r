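# Compartment codes used throughout the engine. S = uninformed, E = silent,
# I = communication (actively spreading), R = immune (disengaged for good).
.S <- 1L
.E <- 2L
.I <- 3L
.R <- 4L
.state_names <- c("S", "E", "I", "R")

#' Model parameters for the coupled dissemination/polarization simulator
#'
#' Collects every scalar of the coupled model, validated and fully
#' defaulted. The defaults are the baseline study conditions used by all
#' parameter sweeps: thresholds `d1 = 0.3`, `d2 = 0.7`, communication
#' threshold `p = 0.5` and mean conservatism `T0 = 0.8` from the empirical
#' scenario, mainstream step `gamma = 0.1` and attention span `z0 = 70`
#' (the midpoints of their respective sweeps), a 10% initial communicator
#' fraction, and 300 agents on a scale-free network with mean degree near
#' 49.
#'
#' @param N Population size.
#' @param d1 Assimilation threshold in \[0, 1\].
#' @param d2 Rejection threshold in \[0, 1\]; must exceed `d1`.
#' @param p Communication threshold: minimum willingness at which a silent
#'   agent starts spreading.
#' @param gamma Mainstream-degree step per interaction, in (0, 0.5\].
#' @param T0 Mean conservatism in \[0, 1\].
#' @param z0 Attention span in steps; an agent whose receipt clock exceeds
#'   `z0` becomes immune.
#' @param init_comm_frac Initial fraction of communicating agents.
#' @param attitude_mean,attitude_sd Mean and standard deviation of the
#'   initial attitude distribution (a normal clipped to \[-1, 1\]).
#' @param stop_tol Convergence tolerance for the summed squared one-step
#'   attitude change.
#' @param max_steps Hard cap on the number of steps.
#' @param polar_threshold Extremity cutoff for the polarizability metric.
#' @param network One of `"ba"`, `"ws"`, `"er"`: the substrate generated
#'   when no network is supplied to [run_seirja()].
#' @param ba_m,ws_k,ws_p,er_p Generator parameters for the three families;
#'   defaults match the three substrates at mean degree near 48-50.
#' @param recognition_floor Optional lower bound on the recognition degree
#'   `m` (see [update_recognition()]). The default (none) keeps the
#'   rejection-driven immune transition reachable.
#' @param update_partner_mainstream Should an interaction update the
#'   mainstream degrees of both parties (default) or only the initiator's?
#' @param clip_coefficients Clip conformity and the opinion-change
#'   coefficient to \[0, 1\] (default); `FALSE` leaves them on \[-1, 1\] and
#'   \[-2, 2\].
#' @return A validated list of class `seirja_params`.
#' @export
seirja_params <- function(N = 300L,
                          d1 = 0.3, d2 = 0.7, p = 0.5,
                          gamma = 0.1, T0 = 0.8, z0 = 70L,
                          init_comm_frac = 0.1,
                          attitude_mean = 0, attitude_sd = 0.3876,
                          stop_tol = 0.1, max_steps = 200L,
                          polar_threshold = 0.8,
                          network = c("ba", "ws", "er"),
                          ba_m = 25L, ws_k = 48L, ws_p = 0.1,
                          er_p = 49.61 / 299,
                          recognition_floor = NULL,
                          update_partner_mainstream = TRUE,
                          clip_coefficients = TRUE) {
  network <- match.arg(network)
  pars <- list(
    N = as.integer(N), d1 = d1, d2 = d2, p = p, gamma = gamma, T0 = T0,
    z0 = as.integer(z0), init_comm_frac = init_comm_frac,
    attitude_mean = attitude_mean, attitude_sd = attitude_sd,
    stop_tol = stop_tol, max_steps = as.integer(max_steps),
    polar_threshold = polar_threshold, network = network,
    ba_m = as.integer(ba_m), ws_k = as.integer(ws_k), ws_p = ws_p,
    er_p = er_p, recognition_floor = recognition_floor,
    update_partner_mainstream = isTRUE(update_partner_mainstream),
    clip_coefficients = isTRUE(clip_coefficients)
  )
  validate_seirja_params(pars)
  structure(pars, class = "seirja_params")
}

validate_seirja_params <- function(pars) {
  with(pars, {
    if (N < 1) stop("N must be positive", call. = FALSE)
    for (nm in c("d1", "d2", "p", "T0"))
      if (pars[[nm]] < 0 || pars[[nm]] > 1)
        stop(sprintf("%s must lie in [0, 1]", nm), call. = FALSE)
    if (d1 >= d2) stop("require d1 < d2", call. = FALSE)
    if (gamma < 0 || gamma > 0.5)
      stop("gamma must lie in (0, 0.5] (0 allowed for frozen-opinion runs)",
           call. = FALSE)
    if (z0 < 1) stop("z0 must be a positive integer", call. = FALSE)
    if (init_comm_frac < 0 || init_comm_frac >= 1)
      stop("init_comm_frac must lie in [0, 1)", call. = FALSE)
    if (attitude_sd < 0) stop("attitude_sd must be nonnegative", call. = FALSE)
    if (stop_tol < 0) stop("stop_tol must be nonnegative", call. = FALSE)
    if (max_steps < 0) stop("max_steps must be nonnegative", call. = FALSE)
  })
  invisible(pars)
}

#' @export
print.seirja_params <- function(x, ...) {
  cat("<seirja_params>\n")
  cat(sprintf("  N=%d  d1=%.3g d2=%.3g p=%.3g  gamma=%.3g T0=%.3g z0=%d\n",
              x$N, x$d1, x$d2, x$p, x$gamma, x$T0, x$z0))
  cat(sprintf("  init_comm_frac=%.3g  attitudes ~ N(%.3g, %.3g) clipped\n",
              x$init_comm_frac, x$attitude_mean, x$attitude_sd))
  cat(sprintf("  network=%s  stop_tol=%.3g max_steps=%d\n",
              x$network, x$stop_tol, x$max_steps))
  invisible(x)
}

# Draw n initial attitudes: normal clipped (not resampled) to [-1, 1].
draw_attitudes <- function(n, mean, sd) {
  pmin(1, pmax(-1, rnorm(n, mean, sd)))
}

default_network <- function(params) {
  switch(params$network,
    ba = make_ba_network(params$N, params$ba_m),
    ws = make_ws_network(params$N, params$ws_k, params$ws_p),
    er = make_er_network(params$N, params$er_p)
  )
}

#' Initialize a simulation state
#'
#' Selects `round(init_comm_frac * N)` agents uniformly at random as the
#' seed communicators. Each seed draws an attitude from the clipped initial
#' normal distribution, starts with recognition `m = 1`, receipt clock
#' `z = 1` and balanced mainstream degrees `w+ = w- = 0.5`; everyone else is
#' uninformed with no attitude. Conservatism is assigned from the degree
#' profile ([conservatism_profile()]).
#'
#' @param params A [seirja_params()] object.
#' @param net An `opinion_network` with `params$N` nodes.
#' @param seed Optional integer seed.
#' @return A `seirja_state` list with per-agent vectors `state`, `x`, `m`,
#'   `z`, `wp` (positive mainstream degree) and `tcons`, plus the network
#'   and the step counter `t = 0`.
#' @export
init_state <- function(params, net, seed = NULL) {
  stopifnot(inherits(params, "seirja_params"), inherits(net, "opinion_network"))
  if (net$n != params$N)
    stop("network size must equal params$N", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  n_seed <- round(params$init_comm_frac * N)
  st <- rep(.S, N)
  x <- rep(NA_real_, N)
  m <- rep(NA_real_, N)
  z <- rep(NA_integer_, N)
  wp <- rep(NA_real_, N)
  if (n_seed > 0) {
    seeds <- sample.int(N, n_seed)
    st[seeds] <- .I
    x[seeds] <- draw_attitudes(n_seed, params$attitude_mean,
                               params$attitude_sd)
    m[seeds] <- 1
    z[seeds] <- 1L
    wp[seeds] <- 0.5
  }
  structure(
    list(t = 0L, state = st, x = x, m = m, z = z, wp = wp,
         tcons = conservatism_profile(net, params$T0), net = net),
    class = "seirja_state"
  )
}

#' Advance the coupled simulation by one step
#'
#' One unit of model time:
#' 1. Every agent that was communicating at the start of the step, in a
#'    fresh random order, picks one uniformly random neighbor. An uninformed
#'    partner first forms an attitude and a willingness and enters the
#'    communication or silent state accordingly; immune partners ignore the
#'    contact; everyone else interacts through the bounded-confidence kernel
#'    with per-agent coefficients built from embeddedness, conservatism and
#'    conformity. Attitude changes are visible to later interactions within
#'    the same step; each interaction also steps both parties' mainstream
#'    degrees and recognition.
#' 2. After all interactions, every informed agent's willingness is
#'    recomputed and the compartment transitions are applied synchronously:
#'    silent agents with willingness at or above `p` start communicating,
#'    communicating agents below `p` fall silent, and any informed agent
#'    with negative willingness or a receipt clock past `z0` becomes
#'    immune.
#' 3. Receipt clocks of the remaining informed agents advance by one.
#'
#' @param state A `seirja_state`.
#' @param params The matching [seirja_params()].
#' @return The updated `seirja_state`.
#' @export
sim_step <- function(state, params) {
  st <- state$state; x <- state$x; m <- state$m; z <- state$z
  wp <- state$wp; tcons <- state$tcons
  adj <- state$net$adj; deg <- state$net$deg
  d1 <- params$d1; d2 <- params$d2; gamma <- params$gamma
  clip <- params$clip_coefficients
  floor_m <- params$recognition_floor
  both_w <- params$update_partner_mainstream

  comm <- which(st == .I)
  if (length(comm) > 1L) comm <- sample(comm)
  for (i in comm) {
    ki <- deg[i]
    if (ki == 0L) next
    ai <- adj[[i]]
    j <- ai[sample.int(ki, 1L)]
    sj <- st[j]
    if (sj == .R) next
    if (sj == .S) {
      # first receipt: form attitude and willingness, choose E or I
      x[j] <- draw_attitudes(1L, params$attitude_mean, params$attitude_sd)
      m[j] <- 1; z[j] <- 1L; wp[j] <- 0.5
      st[j] <- if (abs(x[j]) >= params$p) .I else .E
    }
    # pairwise interaction with per-agent coefficients
    kj <- deg[j]
    emb <- if (ki == 1L && kj == 1L) 1
           else sum(ai %in% adj[[j]]) / ((ki - 1L) + (kj - 1L))
    xi0 <- x[i]; xj0 <- x[j]
    ci <- if (xj0 >= 0) 2 * wp[i] - 1 else 1 - 2 * wp[i]
    cj <- if (xi0 >= 0) 2 * wp[j] - 1 else 1 - 2 * wp[j]
    if (clip) { ci <- max(0, ci); cj <- max(0, cj) }
    mu_i <- (1 + emb) * (1 - tcons[i]) * ci
    mu_j <- (1 + emb) * (1 - tcons[j]) * cj
    if (clip) { mu_i <- min(1, max(0, mu_i)); mu_j <- min(1, max(0, mu_j)) }
    gap <- abs(xi0 - xj0)
    if (gap < d1) {
      x[i] <- min(1, max(-1, xi0 + mu_i * (xj0 - xi0)))
      x[j] <- min(1, max(-1, xj0 + mu_j * (xi0 - xj0)))
      m[i] <- m[i] + 1; m[j] <- m[j] + 1
    } else if (gap > d2) {
      x[i] <- min(1, max(-1, xi0 - mu_i * (xj0 - xi0)))
      x[j] <- min(1, max(-1, xj0 - mu_j * (xi0 - xj0)))
      m[i] <- m[i] - 1; m[j] <- m[j] - 1
    }
    if (!is.null(floor_m)) { m[i] <- max(floor_m, m[i]); m[j] <- max(floor_m, m[j]) }
    # mainstream degrees step toward the partner's camp (0 counts positive)
    wp[i] <- min(1, max(0, wp[i] + (if (xj0 >= 0) gamma else -gamma)))
    if (both_w)
      wp[j] <- min(1, max(0, wp[j] + (if (xi0 >= 0) gamma else -gamma)))
  }

  # synchronous compartment transitions from recomputed willingness
  informed <- which(st == .E | st == .I)
  if (length(informed)) {
    P <- (abs(x[informed]) - 1) * exp(1 - m[informed]) + 1
    to_R <- P < 0 | z[informed] > params$z0
    to_I <- !to_R & st[informed] == .E & P >= params$p
    to_E <- !to_R & st[informed] == .I & P < params$p
    st[informed[to_R]] <- .R
    st[informed[to_I]] <- .I
    st[informed[to_E]] <- .E
    still <- informed[!to_R]
    z[still] <- z[still] + 1L
  }

  state$t <- state$t + 1L
  state$state <- st; state$x <- x; state$m <- m; state$z <- z; state$wp <- wp
  state
}

snapshot_counts <- function(st) {
  tabulate(st, nbins = 4L)
}

#' Run one coupled dissemination/polarization simulation
#'
#' Iterates [sim_step()] from a fresh initial state until the opinion
#' profile converges ([has_converged()], evaluated from the second step
#' onward, with attitudes of still-uninformed agents taken as 0) or
#' `max_steps` is reached. Records the compartment counts, the
#' polarizability of the informed population and the set of communicating
#' agents after every step.
#'
#' @param params A [seirja_params()] object.
#' @param net Optional `opinion_network`; generated from `params$network`
#'   when omitted.
#' @param seed Optional integer seed controlling network generation (when
#'   `net` is omitted), initialization and the whole trajectory.
#' @return A `seirja_result` list: `counts` (data frame `t`, `S`, `E`, `I`,
#'   `R`, one row per snapshot starting at `t = 0`), `polarizability`
#'   (per-snapshot fraction of informed agents with `|x| >` the extremity
#'   cutoff), `comm_sets` (per-snapshot integer vectors of communicating
#'   agents), `x` (final attitudes, `NA` when never informed), `state`
#'   (final compartments), `t_end` and `reason` (`"converged"` or
#'   `"max_steps"`).
#' @export
run_seirja <- function(params, net = NULL, seed = NULL) {
  stopifnot(inherits(params, "seirja_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- default_network(params)
  state <- init_state(params, net)

  counts <- list(snapshot_counts(state$state))
  polar <- informed_polarizability(state$x, params$polar_threshold)
  comm_sets <- list(which(state$state == .I))
  x_prev <- ifelse(is.na(state$x), 0, state$x)
  reason <- "max_steps"
  while (state$t < params$max_steps) {
    state <- sim_step(state, params)
    counts[[state$t + 1L]] <- snapshot_counts(state$state)
    polar <- c(polar, informed_polarizability(state$x, params$polar_threshold))
    comm_sets[[state$t + 1L]] <- which(state$state == .I)
    x_curr <- ifelse(is.na(state$x), 0, state$x)
    if (state$t >= 2L && has_converged(x_prev, x_curr, params$stop_tol)) {
      reason <- "converged"
      break
    }
    x_prev <- x_curr
    if (all(state$state == .S | state$state == .R)) {
      # nothing left that can interact
      reason <- "converged"
      break
    }
  }
  cmat <- do.call(rbind, counts)
  colnames(cmat) <- .state_names
  structure(
    list(
      counts = data.frame(t = 0:state$t, cmat),
      polarizability = polar,
      comm_sets = comm_sets,
      x = state$x,
      state = state$state,
      t_end = state$t,
      reason = reason,
      params = params
    ),
    class = "seirja_result"
  )
}

informed_polarizability <- function(x, threshold) {
  inf <- !is.na(x)
  if (!any(inf)) return(0)
  mean(abs(x[inf]) > threshold)
}

#' @export
print.seirja_result <- function(x, ...) {
  fin <- x$counts[nrow(x$counts), ]
  cat(sprintf(
    "<seirja_result> %d steps (%s); final S/E/I/R = %d/%d/%d/%d; final polarizability %.3f\n",
    x$t_end, x$reason, fin$S, fin$E, fin$I, fin$R,
    x$polarizability[length(x$polarizability)]
  ))
  invisible(x)
}

pad_forward <- function(v, len) {
  if (length(v) >= len) v else c(v, rep(v[length(v)], len - length(v)))
}

#' Seeded Monte-Carlo ensemble
#'
#' Runs `n_runs` independent simulations (run `r` uses seed
#' `base_seed + r - 1`), each on a freshly generated network unless a fixed
#' network is supplied. Shorter runs are carried forward at their final
#' value so series can be averaged pointwise; the per-time relative
#' standard deviation across runs (skipping times with zero mean) is
#' averaged over time as a reproducibility index.
#'
#' @param params A [seirja_params()] object.
#' @param n_runs Number of runs (default 10).
#' @param base_seed Integer seed of the first run.
#' @param net Optional fixed `opinion_network` shared by all runs.
#' @param runner Function `(params, net, seed) -> result` used for each run;
#'   defaults to [run_seirja()] and accepts the baseline runners as drop-in
#'   replacements.
#' @return An `ensemble_result` list: `runs`, `mean_counts` (data frame of
#'   pointwise-mean compartment counts), `mean_polarizability`, and
#'   `avg_rsd` (named vector of time-averaged RSDs, in percent, for each
#'   series).
#' @export
run_ensemble <- function(params, n_runs = 10, base_seed = 1,
                         net = NULL, runner = run_seirja) {
  if (n_runs < 1) stop("n_runs must be at least 1", call. = FALSE)
  runs <- lapply(seq_len(n_runs), function(r) {
    runner(params, net = net, seed = base_seed + r - 1L)
  })
  len <- max(vapply(runs, function(r) nrow(r$counts), 1L))
  series <- c(.state_names, "polarizability")
  mats <- lapply(series, function(s) {
    do.call(rbind, lapply(runs, function(r) {
      v <- if (s == "polarizability") r$polarizability else r$counts[[s]]
      pad_forward(v, len)
    }))
  })
  names(mats) <- series
  means <- lapply(mats, colMeans)
  avg_rsd <- vapply(mats, function(mm) {
    rsd_t <- apply(mm, 2, relative_sd)
    keep <- colMeans(mm) != 0
    if (!any(keep)) 0 else mean(rsd_t[keep])
  }, numeric(1))
  structure(
    list(
      runs = runs,
      mean_counts = data.frame(t = 0:(len - 1L),
                               S = means$S, E = means$E,
                               I = means$I, R = means$R),
      mean_polarizability = means$polarizability,
      avg_rsd = avg_rsd,
      n_runs = n_runs,
      base_seed = base_seed
    ),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %d runs; peak mean E %.1f, peak mean I %.1f; final mean polarizability %.3f\n",
    x$n_runs, max(x$mean_counts$E), max(x$mean_counts$I),
    x$mean_polarizability[length(x$mean_polarizability)]
  ))
  invisible(x)
}
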