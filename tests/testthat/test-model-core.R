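test_that("hill functions match their closed forms and reject bad input", {
  expect_equal(hill_act(2, 1, 4), 16 / 17)
  expect_equal(hill_act(0, 3, 2), 0)
  for (K in c(0.3, 1, 5)) expect_equal(hill_act(K, K, 4), 0.5)
  expect_equal(hill_inh(0, 2, 4), 1)
  expect_equal(hill_inh(1.7, 1.7, 3), 0.5)
  expect_error(hill_act(-1, 1, 4), "non-negative")
  expect_error(hill_act(1, 0, 4), "positive")
  expect_error(hill_act(1, 1, 0.5), ">= 1")
})

test_that("activation and inhibition are complementary and monotone", {
  set.seed(42)
  x <- runif(1000, 0, 10)
  K <- runif(1000, 0.05, 5)
  n <- runif(1000, 1, 8)
  expect_equal(hill_act(x, K, n) + hill_inh(x, K, n), rep(1, 1000))
  xs <- sort(runif(200, 0, 4))
  expect_true(all(diff(hill_act(xs, 0.7, 4)) >= 0))
  expect_true(all(diff(hill_inh(xs, 0.7, 4)) <= 0))
})

test_that("perceived signal is a windowed mean respecting topology", {
  st <- embryo_state(B = c(3, 0, 0, 0, 0), V = rep(1, 5))
  expect_equal(perceived_signal(st, "B", r = 1), c(1, 1, 0, 0, 1))
  expect_equal(perceived_signal(st, "B", r = 0), st$cells[, "B"])
  # uniform field: mean of constants for any radius and topology
  u <- embryo_state(B = rep(2.5, 9), V = rep(0.3, 9), cuts = c(0L, 4L))
  for (r in 0:3) expect_equal(perceived_signal(u, "B", r = r), rep(2.5, 9))
  # truncation at a sealed arc end averages over available cells only
  st2 <- random_state(n = 12, seed = 7, cuts = c(0L, 6L))
  for (r in c(1, 3)) {
    expect_equal(perceived_signal(st2, "B", r = r),
                 oracle_window_mean(st2$cells[, "B"], r, st2$cuts))
    expect_equal(perceived_signal(st2, "V", r = r),
                 oracle_window_mean(st2$cells[, "V"], r, st2$cuts))
  }
  end_window <- perceived_signal(st2, "B", r = 1)[7]  # cell after the cut at 6
  expect_equal(end_window, mean(st2$cells[7:8, "B"]))
})

test_that("rhs matches an independent scalar evaluation on a 5-cell ring", {
  p <- tiny_params(n_cells = 5, r = 1)
  for (seed in 1:5) {
    st <- random_state(n = 5, seed = seed)
    expect_equal(model_rhs(st, p), oracle_rhs(st, p), tolerance = 1e-14)
  }
  # with sources and cuts
  st <- random_state(n = 5, seed = 9, cuts = c(1L, 3L))
  src <- c(0, 1, 0, 0.5, 0)
  expect_equal(model_rhs(st, p, src_B = src, src_V = rev(src)),
               oracle_rhs(st, p, src_B = src, src_V = rev(src)),
               tolerance = 1e-14)
})

test_that("the all-off state is an exact fixed point", {
  p <- tiny_params(n_cells = 6, r = 1)
  st <- embryo_state(rep(0, 6), rep(0, 6))
  expect_equal(max(abs(model_rhs(st, p))), 0)
})

test_that("rhs production terms are bounded", {
  p <- default_parameters()
  capFB <- p$alpha_B
  capFV <- p$alpha_V * (1 + p$c_BV)
  set.seed(3)
  st <- embryo_state(runif(p$n_cells, 0, 50), runif(p$n_cells, 0, 50),
                     rep(0, p$n_cells), rep(0, p$n_cells))
  d <- model_rhs(st, p)
  expect_true(all(d[, "FB"] <= capFB + 1e-12))
  expect_true(all(d[, "FV"] <= capFV + 1e-12))
})

test_that("rhs is equivariant under rotation and reflection of a ring", {
  p <- tiny_params(n_cells = 8, r = 2)
  st <- random_state(n = 8, seed = 11)
  base <- model_rhs(st, p)
  for (k in c(1, 3, 5)) {
    rot <- model_rhs(rotate_state(st, k), p)
    idx <- ((seq_len(8) - 1 - k) %% 8) + 1
    expect_equal(rot, base[idx, ], tolerance = 1e-14)
  }
  refl <- st
  refl$cells <- refl$cells[8:1, ]
  expect_equal(model_rhs(refl, p), base[8:1, ], tolerance = 1e-14)
})

test_that("homogeneous steady states are genuine fixed points", {
  p <- default_parameters()
  ss <- steady_states(p)
  expect_true(any(ss$B == 0 & ss$V == 0))      # all-off is always present
  expect_true(all(ss$residual < 1e-8))          # verified against the full rhs
  expect_true(any(ss$B > 0 & ss$V > 0))         # a doubly-active state exists
  # re-check each root against the lattice rhs independently of the search
  for (i in seq_len(nrow(ss))) {
    st <- axisbreak:::uniform_state(ss$B[i], ss$V[i], p)
    expect_lt(max(abs(model_rhs(st, p))), 1e-8)
  }
  # and the launch state must be one of them
  ls <- launch_state(p)
  expect_lt(max(abs(model_rhs(ls, p))), 1e-8)
})

test_that("uniform fixed points do not depend on the coupling radius", {
  p1 <- model_parameters(coupling_radius = 1L)
  p2 <- model_parameters(coupling_radius = 10L)
  s1 <- steady_states(p1)
  s2 <- steady_states(p2)
  expect_equal(s1$B, s2$B, tolerance = 1e-9)
  expect_equal(s1$V, s2$V, tolerance = 1e-9)
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(model_parameters(K_lo = 2, K_hi = 1), "K_lo")
  expect_error(model_parameters(n_cells = 10L, coupling_radius = 5L), "window")
  expect_error(model_parameters(alpha_B = -1), "alpha_B")
  expect_error(model_parameters(sigma_init = -0.1), "sigma_init")
  expect_error(model_parameters(frobnicate = 1), "unknown")
  expect_error(model_parameters(n_cells = 2L), "n_cells")
})
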