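#' Parameters for the classic probabilistic SEIR baseline
#'
#' The comparison dissemination model with fixed transition probabilities
#' and no opinion dynamics: a contacted uninformed agent accepts the
#' information with probability `acceptance_coef`, a silent agent starts
#' spreading with probability `dissemination_coef` per step, and a
#' spreading agent disengages with probability `immune_coef` per step. The
#' defaults (1 / 0.3 / 0.2) are the empirical-scenario coefficients.
#'
#' @param N Population size.
#' @param acceptance_coef,dissemination_coef,immune_coef Probabilities in
#'   \[0, 1\].
#' @param init_comm_frac Initial fraction of spreading agents.
#' @param max_steps Step cap (the model also halts at absorption, when no
#'   silent or spreading agents remain).
#' @param network,ba_m,ws_k,ws_p,er_p Substrate specification as in
#'   [seirja_params()].
#' @return A validated list of class `classic_seir_params`.
#' @export
classic_seir_params <- function(N = 500L,
                                acceptance_coef = 1,
                                dissemination_coef = 0.3,
                                immune_coef = 0.2,
                                init_comm_frac = 0.05,
                                max_steps = 200L,
                                network = c("ba", "ws", "er"),
                                ba_m = 25L, ws_k = 48L, ws_p = 0.1,
                                er_p = 49.61 / 299) {
  network <- match.arg(network)
  for (v in c(acceptance_coef, dissemination_coef, immune_coef))
    if (v < 0 || v > 1)
      stop("all coefficients must lie in [0, 1]", call. = FALSE)
  if (init_comm_frac < 0 || init_comm_frac >= 1)
    stop("init_comm_frac must lie in [0, 1)", call. = FALSE)
  structure(
    list(N = as.integer(N), acceptance_coef = acceptance_coef,
         dissemination_coef = dissemination_coef, immune_coef = immune_coef,
         init_comm_frac = init_comm_frac, max_steps = as.integer(max_steps),
         network = network, ba_m = as.integer(ba_m), ws_k = as.integer(ws_k),
         ws_p = ws_p, er_p = er_p),
    class = "classic_seir_params"
  )
}

classic_default_network <- function(params) {
  switch(params$network,
    ba = make_ba_network(params$N, params$ba_m),
    ws = make_ws_network(params$N, params$ws_k, params$ws_p),
    er = make_er_network(params$N, params$er_p)
  )
}

#' One synchronous step of the classic SEIR baseline
#'
#' Contact process: every spreading (I) agent contacts one uniformly random
#' neighbor; an uninformed (S) neighbor accepts — becomes silent (E) — with
#' probability `acceptance_coef` per contact. Bookkeeping is synchronous on
#' the step-start compartments: step-start E agents each become I with
#' probability `dissemination_coef`, and step-start I agents each become R
#' with probability `immune_coef`. Newly accepted agents become eligible
#' from the next step.
#'
#' @param st Integer compartment vector (1 = S, 2 = E, 3 = I, 4 = R).
#' @param net An `opinion_network`.
#' @param params A [classic_seir_params()] object.
#' @return The updated compartment vector.
#' @export
classic_seir_step <- function(st, net, params) {
  infectious <- which(st == 3L)
  start_E <- which(st == 2L)
  contacts <- integer(0)
  for (i in infectious) {
    ki <- net$deg[i]
    if (ki == 0L) next
    contacts <- c(contacts, net$adj[[i]][sample.int(ki, 1L)])
  }
  contacts <- contacts[st[contacts] == 1L]
  if (length(contacts)) {
    accepted <- contacts[runif(length(contacts)) < params$acceptance_coef]
    st[accepted] <- 2L   # duplicates collapse: any successful contact converts
  }
  if (length(start_E)) {
    go_I <- start_E[runif(length(start_E)) < params$dissemination_coef]
    st[go_I] <- 3L
  }
  if (length(infectious)) {
    go_R <- infectious[runif(length(infectious)) < params$immune_coef]
    st[go_R] <- 4L
  }
  st
}

#' Run the classic SEIR baseline
#'
#' Iterates [classic_seir_step()] from a random initial seeding until
#' absorption (no silent or spreading agents) or `max_steps`. Emits the same
#' result shape as [run_seirja()] so the ensemble and comment-curve
#' machinery apply unchanged; the model has no attitudes, so the
#' polarizability series is identically zero.
#'
#' @param params A [classic_seir_params()] object.
#' @param net Optional `opinion_network`; generated from the params when
#'   omitted.
#' @param seed Optional integer seed.
#' @return A `seirja_result`-shaped list (see [run_seirja()]).
#' @export
run_classic_seir <- function(params, net = NULL, seed = NULL) {
  stopifnot(inherits(params, "classic_seir_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- classic_default_network(params)
  if (net$n != params$N) stop("network size must equal params$N", call. = FALSE)
  N <- params$N
  st <- rep(1L, N)
  n_seed <- round(params$init_comm_frac * N)
  if (n_seed > 0) st[sample.int(N, n_seed)] <- 3L

  counts <- list(snapshot_counts(st))
  comm_sets <- list(which(st == 3L))
  t <- 0L
  reason <- "max_steps"
  while (t < params$max_steps) {
    st <- classic_seir_step(st, net, params)
    t <- t + 1L
    counts[[t + 1L]] <- snapshot_counts(st)
    comm_sets[[t + 1L]] <- which(st == 3L)
    if (!any(st == 2L | st == 3L)) {
      reason <- "absorbed"
      break
    }
  }
  cmat <- do.call(rbind, counts)
  colnames(cmat) <- .state_names
  structure(
    list(counts = data.frame(t = 0:t, cmat),
         polarizability = rep(0, t + 1L),
         comm_sets = comm_sets,
         x = rep(NA_real_, N),
         state = st, t_end = t, reason = reason, params = params),
    class = "seirja_result"
  )
}

#' Parameters for the classic Jager-Amblard baseline
#'
#' The comparison polarization model: every agent holds an attitude from
#' step 0 (no compartments) and interacts with one random neighbor per step
#' through the homogeneous kernel [classic_ja_interact()] with a single
#' shared coefficient `mu`. The defaults (`d1 = 0.3`, `d2 = 0.7`,
#' `mu = 0.5`) are the empirical-scenario parameterization.
#'
#' @param N Population size.
#' @param d1,d2 Assimilation and rejection thresholds.
#' @param mu Shared opinion-change coefficient.
#' @param attitude_mean,attitude_sd Initial attitude distribution (normal
#'   clipped to \[-1, 1\]).
#' @param stop_tol Convergence tolerance on the summed squared one-step
#'   change.
#' @param max_steps Step cap.
#' @param polar_threshold Extremity cutoff for the recorded polarizability.
#' @param network,ba_m,ws_k,ws_p,er_p Substrate specification as in
#'   [seirja_params()].
#' @return A validated list of class `classic_ja_params`.
#' @export
classic_ja_params <- function(N = 500L, d1 = 0.3, d2 = 0.7, mu = 0.5,
                              attitude_mean = 0, attitude_sd = 0.4,
                              stop_tol = 0.1, max_steps = 500L,
                              polar_threshold = 0.8,
                              network = c("ba", "ws", "er"),
                              ba_m = 25L, ws_k = 48L, ws_p = 0.1,
                              er_p = 49.61 / 299) {
  network <- match.arg(network)
  if (d1 >= d2) stop("require d1 < d2", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  structure(
    list(N = as.integer(N), d1 = d1, d2 = d2, mu = mu,
         attitude_mean = attitude_mean, attitude_sd = attitude_sd,
         stop_tol = stop_tol, max_steps = as.integer(max_steps),
         polar_threshold = polar_threshold, network = network,
         ba_m = as.integer(ba_m), ws_k = as.integer(ws_k), ws_p = ws_p,
         er_p = er_p),
    class = "classic_ja_params"
  )
}

#' Run the classic Jager-Amblard baseline
#'
#' Per step, every agent in a fresh random order interacts with one
#' uniformly random neighbor; updates are sequential, so changes are
#' visible to later interactions within the step. Halts when the summed
#' squared one-step attitude change falls to `stop_tol` (checked from the
#' second step) or at `max_steps`. The result mirrors [run_seirja()]; all
#' agents count as communicating at every step.
#'
#' @param params A [classic_ja_params()] object.
#' @param net Optional `opinion_network`.
#' @param seed Optional integer seed.
#' @return A `seirja_result`-shaped list (see [run_seirja()]).
#' @export
run_classic_ja <- function(params, net = NULL, seed = NULL) {
  stopifnot(inherits(params, "classic_ja_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- classic_default_network(params)
  if (net$n != params$N) stop("network size must equal params$N", call. = FALSE)
  N <- params$N
  adj <- net$adj; deg <- net$deg
  d1 <- params$d1; d2 <- params$d2; mu <- params$mu
  x <- draw_attitudes(N, params$attitude_mean, params$attitude_sd)

  polar <- polarizability(x, params$polar_threshold)
  t <- 0L
  x_prev <- x
  reason <- "max_steps"
  while (t < params$max_steps) {
    for (i in sample.int(N)) {
      ki <- deg[i]
      if (ki == 0L) next
      j <- adj[[i]][sample.int(ki, 1L)]
      xi0 <- x[i]; xj0 <- x[j]
      gap <- abs(xi0 - xj0)
      if (gap < d1) {
        x[i] <- min(1, max(-1, xi0 + mu * (xj0 - xi0)))
        x[j] <- min(1, max(-1, xj0 + mu * (xi0 - xj0)))
      } else if (gap > d2) {
        x[i] <- min(1, max(-1, xi0 - mu * (xj0 - xi0)))
        x[j] <- min(1, max(-1, xj0 - mu * (xi0 - xj0)))
      }
    }
    t <- t + 1L
    polar <- c(polar, polarizability(x, params$polar_threshold))
    if (t >= 2L && has_converged(x_prev, x, params$stop_tol)) {
      reason <- "converged"
      break
    }
    x_prev <- x
  }
  all_agents <- seq_len(N)
  structure(
    list(counts = data.frame(t = 0:t, S = 0L, E = 0L, I = N, R = 0L),
         polarizability = polar,
         comm_sets = rep(list(all_agents), t + 1L),
         x = x, state = rep(.I, N), t_end = t, reason = reason,
         params = params),
    class = "seirja_result"
  )
}
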