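small_params <- function(...) {
  args <- utils::modifyList(list(N = 60L, ba_m = 4L, max_steps = 60L),
                            list(...))
  do.call(seirja_params, args)
}

test_that("initialization seeds the requested communicator fraction", {
  p <- seirja_params(N = 300L, init_comm_frac = 0.1)
  net <- make_ba_network(300, 25, seed = 3)
  st <- init_state(p, net, seed = 5)
  expect_equal(sum(st$state == 3L), 30)
  expect_equal(sum(st$state == 1L), 270)
  seeds <- st$state == 3L
  expect_true(all(abs(st$x[seeds]) <= 1))
  expect_true(all(st$m[seeds] == 1))
  expect_true(all(st$z[seeds] == 1L))
  expect_true(all(st$wp[seeds] == 0.5))
  expect_true(all(is.na(st$x[!seeds])))
  # fixed seed reproduces the initial state
  st2 <- init_state(p, net, seed = 5)
  expect_identical(st$x, st2$x)
  expect_identical(st$state, st2$state)
})

test_that("a zero-communicator start terminates immediately, all uninformed", {
  p <- small_params(init_comm_frac = 0)
  r <- run_seirja(p, seed = 1)
  expect_equal(r$counts$S[nrow(r$counts)], 60)
  expect_lte(r$t_end, 2)
})

test_that("trajectories satisfy conservation, monotonicity, legal moves", {
  p <- small_params()
  net <- make_ba_network(60, 4, seed = 2)
  snaps <- trace_seirja(p, net, seed = 10, n_steps = 40)
  expect_valid_trajectory(snaps)
  counts <- t(vapply(snaps, function(s) tabulate(s$state, 4), integer(4)))
  expect_true(all(rowSums(counts) == 60))
})

test_that("runs are deterministic under a fixed seed", {
  p <- small_params()
  a <- run_seirja(p, seed = 33)
  b <- run_seirja(p, seed = 33)
  expect_identical(a$counts, b$counts)
  expect_identical(a$x, b$x)
  expect_identical(a$polarizability, b$polarizability)
})

test_that("attention span 1 forces immunity within two steps of receipt", {
  p <- small_params(z0 = 1L, max_steps = 30L)
  net <- make_ba_network(60, 4, seed = 6)
  snaps <- trace_seirja(p, net, seed = 7, n_steps = 30)
  first_informed <- rep(NA_integer_, 60)
  for (k in seq_along(snaps)) {
    inf <- which(snaps[[k]]$state %in% 2:3)
    first_informed[inf[is.na(first_informed[inf])]] <- k
    # nobody may stay informed-but-not-immune longer than two steps
    if (any(!is.na(first_informed)))
      expect_true(all(k - first_informed[inf] <= 2, na.rm = TRUE))
  }
})

test_that("a frozen mainstream step keeps every attitude at its first draw", {
  p <- small_params(gamma = 0)
  net <- make_ba_network(60, 4, seed = 11)
  snaps <- trace_seirja(p, net, seed = 12, n_steps = 40)
  first_x <- rep(NA_real_, 60)
  for (s in snaps) {
    inf <- which(!is.na(s$x))
    new <- inf[is.na(first_x[inf])]
    first_x[new] <- s$x[new]
    expect_equal(s$x[inf], first_x[inf])
  }
  # hence the extremity of the informed pool is that of the raw draws
  last <- snaps[[length(snaps)]]
  expect_equal(polarizability(last$x, p$polar_threshold),
               polarizability(first_x, p$polar_threshold))
})

test_that("forgetting clock advances and triggers immunity past z0", {
  p <- small_params(z0 = 5L)
  net <- make_ba_network(60, 4, seed = 13)
  snaps <- trace_seirja(p, net, seed = 14, n_steps = 20)
  for (k in 2:length(snaps)) {
    s <- snaps[[k]]
    live <- which(s$state %in% 2:3)
    expect_true(all(s$z[live] <= p$z0 + 1L))
  }
})

test_that("ensembles average runs and carry short runs forward", {
  p <- small_params()
  ens <- run_ensemble(p, n_runs = 3, base_seed = 50)
  expect_length(ens$runs, 3)
  len <- nrow(ens$mean_counts)
  expect_equal(len, max(vapply(ens$runs, function(r) nrow(r$counts), 1L)))
  # padded mean at the last time equals the mean of final values
  finals <- vapply(ens$runs, function(r) r$counts$R[nrow(r$counts)],
                   numeric(1))
  expect_equal(ens$mean_counts$R[len], mean(finals))
  expect_equal(rowSums(ens$mean_counts[, c("S", "E", "I", "R")]),
               rep(60, len), ignore_attr = TRUE)
})

test_that("ensemble RSD follows the sample-SD/mean convention", {
  p <- small_params()
  # identical seeds: zero spread
  runs_same <- run_ensemble(p, n_runs = 1, base_seed = 9)
  expect_true(all(runs_same$avg_rsd == 0))
  # hand-checked two-run pointwise RSD (worked through relative_sd below)
  expect_equal(relative_sd(c(0.4, 0.6)), 100 * sd(c(0.4, 0.6)) / 0.5)
  expect_equal(relative_sd(c(0.4, 0.6)), 28.28427, tolerance = 1e-6)
})
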