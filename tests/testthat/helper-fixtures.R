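# Small graphs built in code, used across the suite.

path_graph <- function(n) {
  as_opinion_network(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), n_nodes = n)
}

star_graph <- function(n_leaves) {
  as_opinion_network(cbind(1L, seq_len(n_leaves) + 1L),
                     n_nodes = n_leaves + 1L)
}

complete_graph <- function(n) {
  as_opinion_network(t(utils::combn(n, 2)), n_nodes = n)
}

triangle_graph <- function() complete_graph(3)

# Step a coupled simulation manually, collecting per-step snapshots so
# invariants can be asserted along the whole trajectory.
trace_seirja <- function(params, net, seed, n_steps) {
  set.seed(seed)
  state <- init_state(params, net)
  snaps <- list(state)
  for (k in seq_len(n_steps)) {
    state <- sim_step(state, params)
    snaps[[k + 1L]] <- state
  }
  snaps
}

# Assert the compartment/attitude invariants on a trajectory of snapshots.
expect_valid_trajectory <- function(snaps) {
  N <- length(snaps[[1]]$state)
  # S may reach R within a single step (receipt followed by a rejection
  # that drives willingness negative at the transition pass); immunity is
  # absorbing and no one returns to uninformed
  allowed <- list(`1` = 1:4, `2` = c(2L, 3L, 4L),
                  `3` = c(2L, 3L, 4L), `4` = 4L)
  for (k in seq_along(snaps)) {
    s <- snaps[[k]]
    expect_length(s$state, N)
    expect_true(all(s$state %in% 1:4))
    informed <- !is.na(s$x)
    expect_true(all(abs(s$x[informed]) <= 1))
    expect_true(all(s$wp[informed] >= 0 & s$wp[informed] <= 1))
    expect_true(all(s$z[informed] >= 1L))
    expect_identical(informed, s$state != 1L)
    if (k > 1) {
      prev <- snaps[[k - 1]]
      expect_lte(sum(s$state == 1L), sum(prev$state == 1L))
      expect_gte(sum(s$state == 4L), sum(prev$state == 4L))
      for (i in seq_len(N))
        expect_true(s$state[i] %in% allowed[[as.character(prev$state[i])]])
    }
  }
  invisible(snaps)
}

# Exhaustive one-step transition distribution of the classic SEIR baseline
# on a small graph: returns a named probability vector over next-state
# strings (states pasted with "").  Contacted uninformed nodes accept with
# probability 1 - (1 - a)^c for c contacts, silent nodes start spreading
# with the dissemination probability, spreading nodes retire with the
# immune probability, all independently.
enumerate_classic_step <- function(st, net, params) {
  probs <- list()
  add <- function(key, p) probs[[key]] <<- (probs[[key]] %||% 0) + p
  `%||%` <- function(a, b) if (is.null(a)) b else a
  infectious <- which(st == 3L)
  start_E <- which(st == 2L)
  choice_sets <- lapply(infectious, function(i) net$adj[[i]])
  combos <- if (length(infectious))
    expand.grid(lapply(choice_sets, seq_along)) else data.frame(row = 1)
  for (ci in seq_len(nrow(combos))) {
    p_choice <- 1
    contacts <- integer(0)
    for (q in seq_along(infectious)) {
      opts <- choice_sets[[q]]
      contacts <- c(contacts, opts[combos[ci, q]])
      p_choice <- p_choice / length(opts)
    }
    s_contacted <- contacts[st[contacts] == 1L]
    cnt <- table(s_contacted)
    s_nodes <- as.integer(names(cnt))
    p_accept <- 1 - (1 - params$acceptance_coef)^as.integer(cnt)
    bern_nodes <- c(s_nodes, start_E, infectious)
    bern_p <- c(p_accept,
                rep(params$dissemination_coef, length(start_E)),
                rep(params$immune_coef, length(infectious)))
    bern_to <- c(rep(2L, length(s_nodes)),
                 rep(3L, length(start_E)),
                 rep(4L, length(infectious)))
    n_b <- length(bern_nodes)
    outcomes <- if (n_b) expand.grid(rep(list(c(FALSE, TRUE)), n_b))
                else data.frame(row = 1)
    for (oi in seq_len(nrow(outcomes))) {
      st2 <- st
      p_o <- p_choice
      for (b in seq_len(n_b)) {
        hit <- isTRUE(outcomes[oi, b])
        p_o <- p_o * if (hit) bern_p[b] else 1 - bern_p[b]
        if (hit) st2[bern_nodes[b]] <- bern_to[b]
      }
      add(paste(st2, collapse = ""), p_o)
    }
  }
  unlist(probs)
}
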