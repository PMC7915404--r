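test_that("communicating willingness matches closed-form cases", {
  # extreme opinion saturates at 1 regardless of recognition
  expect_equal(communicating_willingness(1, 1), 1)
  expect_equal(communicating_willingness(-1, 7), 1)
  # at the initial recognition m = 1 willingness equals |x|
  expect_equal(communicating_willingness(0.5, 1), 0.5)
  expect_equal(communicating_willingness(0, 3), 1 - exp(-2))
  # recognition below 1 can push willingness negative
  expect_lt(communicating_willingness(0.5, 0), 0)
  expect_equal(communicating_willingness(0.5, 0), -0.5 * exp(1) + 1)
})

test_that("willingness is monotone in recognition and extremity", {
  xs <- seq(-0.9, 0.9, by = 0.3)
  for (x in xs) {
    p <- communicating_willingness(x, c(1, 2, 4, 8))
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= abs(x) & p <= 1))
  }
  p_ext <- communicating_willingness(c(0, 0.4, 0.8), 2)
  expect_true(all(diff(p_ext) > 0))
})

test_that("conservatism profile has mean T0 and hand-checked values", {
  # regular graph: everyone at the mean
  expect_equal(conservatism_profile(complete_graph(5), 0.3), rep(0.3, 5))
  # star on 4 nodes: hub least conservative, leaves most
  star <- star_graph(3)
  expect_equal(conservatism_profile(star, 0.5), c(0.2, 0.6, 0.6, 0.6))
  # leaves clip at 1 when the raw profile overshoots
  expect_equal(conservatism_profile(star, 0.9), c(0.36, 1, 1, 1))
  expect_equal(conservatism_profile(star, 0.9, clip = FALSE),
               c(0.36, 1.08, 1.08, 1.08))
})

test_that("pre-clipping conservatism mean is exact on random graphs", {
  for (s in 1:10) {
    net <- make_er_network(60, 0.1, seed = s)
    con <- net$deg > 0
    tc <- conservatism_profile(net, 0.7, clip = FALSE)
    expect_equal(mean(tc[con]), 0.7, tolerance = 1e-12)
    # monotone nonincreasing in degree
    ord <- order(net$deg[con])
    expect_true(all(diff(tc[con][ord]) <= 1e-12))
  }
})

test_that("mainstream update steps by gamma and preserves the sum", {
  expect_equal(update_mainstream(0.5, 0.5, +1, 0.1), c(0.6, 0.4))
  expect_equal(update_mainstream(0.6, 0.4, -1, 0.1), c(0.5, 0.5))
  # joint clipping keeps both components in [0, 1] and the sum at 1
  expect_equal(update_mainstream(0.95, 0.05, +1, 0.1), c(1, 0))
  set.seed(4)
  w <- c(0.5, 0.5)
  for (k in 1:200) {
    w <- update_mainstream(w[1], w[2], sample(c(-1, 1), 1), 0.07)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("conformity is the clipped linear transform of mainstream degree", {
  expect_equal(conformity(0.5), 0)
  expect_equal(conformity(0.75), 0.5)
  expect_equal(conformity(0.3), 0)   # raw -0.4, minority camp exerts no pull
  expect_equal(conformity(1), 1)
})

test_that("opinion-change coefficient multiplies tie, openness, conformity", {
  expect_equal(opinion_change_coefficient(0.3, 0.4, 0, 0.8, x_partner = 0.5), 0)
  expect_equal(opinion_change_coefficient(0.5, 0.2, 0.5, 0.1, x_partner = 0.5),
               0.6)
  # negative partner selects the negative-camp conformity
  expect_equal(opinion_change_coefficient(0.5, 0.2, 0.5, 0.1, x_partner = -0.5),
               1.5 * 0.8 * 0.1)
  # attitude 0 counts as positive
  expect_equal(opinion_change_coefficient(0.5, 0.2, 0.5, 0.1, x_partner = 0),
               0.6)
  # raw value 2 clips to the declared range
  expect_equal(opinion_change_coefficient(1, 0, 1, 1, x_partner = 1), 1)
})

test_that("coefficient is monotone in embeddedness, conformity, openness", {
  base <- function(e, t, c) opinion_change_coefficient(e, t, c, c, 0.1)
  expect_true(all(diff(sapply(c(0, 0.4, 0.9), base, t = 0.5, c = 0.4)) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.4, 0.7), function(c)
    base(0.3, 0.5, c))) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.5, 0.9), function(t)
    base(0.3, t, 0.4))) < 0))
})

test_that("recognition update follows interaction outcomes", {
  expect_equal(update_recognition(1, "assimilated"), 2)
  expect_equal(update_recognition(1, "neutral"), 1)
  expect_equal(update_recognition(1, "rejected"), 0)
  # unbounded below by default, which enables the rejection-driven exit
  m <- 1
  for (k in 1:3) m <- update_recognition(m, "rejected")
  expect_equal(m, -2)
  expect_lt(communicating_willingness(0.5, 0), 0)
  expect_equal(update_recognition(1, "rejected", floor = 1), 1)
})
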