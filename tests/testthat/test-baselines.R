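test_that("classic SEIR degenerate coefficients behave as expected", {
  net <- path_graph(6)
  # dissemination 0, immunity 1: seeds retire after one step, spread freezes
  p <- classic_seir_params(N = 6L, acceptance_coef = 1,
                           dissemination_coef = 0, immune_coef = 1,
                           init_comm_frac = 0.34, max_steps = 20L)
  r <- run_classic_seir(p, net, seed = 1)
  expect_equal(r$counts$I[1], 2)
  # all spreaders retire after one step and the E/S split stays frozen
  expect_true(all(r$counts$I[-1] == 0))
  expect_true(all(r$counts$E[-1] == r$counts$E[2]))
  expect_true(all(r$counts$S[-1] == r$counts$S[2]))
  # acceptance 0: the uninformed count never moves
  p0 <- classic_seir_params(N = 6L, acceptance_coef = 0,
                            dissemination_coef = 0.3, immune_coef = 0.2,
                            init_comm_frac = 0.34, max_steps = 30L)
  r0 <- run_classic_seir(p0, net, seed = 2)
  expect_true(all(r0$counts$S == r0$counts$S[1]))
})

test_that("classic SEIR trajectories conserve and respect monotonicity", {
  p <- classic_seir_params(N = 80L, init_comm_frac = 0.05, max_steps = 60L,
                           ba_m = 5L)
  r <- run_classic_seir(p, seed = 3)
  expect_true(all(rowSums(r$counts[, c("S", "E", "I", "R")]) == 80))
  expect_true(all(diff(r$counts$S) <= 0))
  expect_true(all(diff(r$counts$R) >= 0))
})

test_that("classic SEIR one-step law matches exhaustive enumeration", {
  # 5-node path, middle spreader plus one silent node: covers contact,
  # acceptance, dissemination and immunity branches at once
  net <- path_graph(5)
  st0 <- c(1L, 2L, 3L, 1L, 1L)
  p <- classic_seir_params(N = 5L, acceptance_coef = 0.6,
                           dissemination_coef = 0.3, immune_coef = 0.2)
  expected <- enumerate_classic_step(st0, net, p)
  expect_equal(sum(expected), 1, tolerance = 1e-12)

  set.seed(77)
  n_samp <- 10000
  keys <- vapply(seq_len(n_samp), function(k)
    paste(classic_seir_step(st0, net, p), collapse = ""), character(1))
  obs <- table(factor(keys, levels = names(expected)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.001)
})

test_that("classic J-A settles identical attitudes immediately", {
  p <- classic_ja_params(N = 20L, attitude_mean = 0.4, attitude_sd = 0,
                         ba_m = 3L, max_steps = 50L)
  r <- run_classic_ja(p, seed = 5)
  expect_equal(r$reason, "converged")
  expect_lte(r$t_end, 2)
  expect_true(all(r$x == 0.4))
  expect_true(all(r$polarizability == 0))
})

test_that("classic J-A rejection drives a polarized pair to the bounds", {
  out <- classic_ja_interact(-0.9, 0.9, 0.5, 0.3, 0.7)
  expect_equal(out$x_i, -1); expect_equal(out$x_j, 1)
})

test_that("classic J-A with a wide-open bound conserves the mean attitude", {
  # d1 = 2 makes every encounter assimilative; with no clipping possible
  # (attitudes stay inside [-1,1] under assimilation) the population mean
  # is invariant, the averaging-dynamics oracle
  p <- classic_ja_params(N = 30L, d1 = 1.99, d2 = 2, mu = 0.5,
                         attitude_mean = 0.1, attitude_sd = 0.3,
                         ba_m = 3L, max_steps = 40L)
  set.seed(9)
  net <- make_ba_network(30, 3)
  r <- run_classic_ja(p, net, seed = 9)
  set.seed(9)
  x0 <- pmin(1, pmax(-1, rnorm(30, 0.1, 0.3)))
  expect_equal(mean(r$x), mean(x0), tolerance = 1e-10)
})

test_that("baseline runners slot into the ensemble machinery", {
  p <- classic_seir_params(N = 40L, init_comm_frac = 0.1, max_steps = 30L,
                           ba_m = 4L)
  ens <- run_ensemble(p, n_runs = 3, base_seed = 2, runner = run_classic_seir)
  expect_length(ens$runs, 3)
  expect_true(all(rowSums(ens$mean_counts[, c("S", "E", "I", "R")]) == 40))
})
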