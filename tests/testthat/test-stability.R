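test_that("window transfer factor has the right structure", {
  N <- 100
  for (r in c(0, 1, 4, 9)) {
    g <- coupling_gain(0:(N / 2), r, N)
    expect_equal(g[1], 1)                       # g(0) = 1
    expect_true(all(g <= 1 + 1e-12))
    expect_true(all(g >= -1))
    # even in k
    expect_equal(coupling_gain(3, r, N), coupling_gain(N - 3, r, N))
  }
  expect_equal(coupling_gain(5, 0, 60), 1)      # r = 0: no coupling filter
})

test_that("the all-off state is linearly stable at every wavenumber", {
  p <- default_parameters()
  st <- embryo_state(rep(0, p$n_cells), rep(0, p$n_cells))
  sp <- mode_spectrum(p, st)
  expect_true(all(sp$growth_rate < 0))
  # analytic check: Hill derivatives vanish at 0 for n > 1, so the Jacobian
  # is triangular with the decay rates on the diagonal
  J <- uniform_jacobian(p, st, g = 1)
  expect_equal(sort(Re(eigen(J)$values)),
               sort(-c(p$delta_B, p$delta_V, p$delta_F, p$delta_F)))
})

test_that("k = 0 growth rates equal the uncoupled single-cell Jacobian", {
  p <- default_parameters()
  st <- launch_state(p)
  sp <- mode_spectrum(p, st)
  J <- uniform_jacobian(p, st, g = 1)
  expect_equal(sp$growth_rate[sp$k == 0],
               max(Re(eigen(J, only.values = TRUE)$values)), tolerance = 1e-12)
})

test_that("per-mode eigenvalues reproduce the full lattice Jacobian", {
  # circulant block-diagonalisation: the union over k of the 4x4 per-mode
  # spectra equals the spectrum of the full 4N x 4N Jacobian obtained by
  # finite differences on the rhs
  for (N in c(8, 12)) {
    p <- model_parameters(n_cells = as.integer(N), coupling_radius = 2L,
                          sigma_init = 0)
    st <- launch_state(p)
    h <- 1e-6
    full <- matrix(0, 4 * N, 4 * N)
    y0 <- as.vector(st$cells)
    f <- function(y) {
      s <- embryo_state(y[1:N], y[N + 1:N], y[2 * N + 1:N], y[3 * N + 1:N])
      as.vector(model_rhs(s, p))
    }
    for (j in seq_len(4 * N)) {
      yp <- y0; ym <- y0
      yp[j] <- yp[j] + h; ym[j] <- max(ym[j] - h, 0)
      full[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
    }
    ev_full <- eigen(full, only.values = TRUE)$values
    ev_modes <- unlist(lapply(0:(N - 1), function(k) {
      g <- coupling_gain(k, p$coupling_radius, N)
      eigen(uniform_jacobian(p, st, g), only.values = TRUE)$values
    }))
    key <- function(z) {  # canonicalise: flush signed zeros before ordering
      re <- round(Re(z), 9); im <- round(Im(z), 9)
      complex(real = re, imaginary = im)[order(re, im)]
    }
    expect_equal(key(ev_modes), key(ev_full), tolerance = 1e-5)
  }
})

test_that("seeded single-harmonic perturbations grow at the predicted rate", {
  p <- model_parameters(sigma_init = 0)
  st <- launch_state(p)
  sp <- mode_spectrum(p, st)
  N <- p$n_cells
  th <- 2 * pi * (seq_len(N) - 1) / N
  for (k in c(1, 3)) {
    lam <- sp$growth_rate[sp$k == k]
    g <- coupling_gain(k, p$coupling_radius, N)
    J <- uniform_jacobian(p, st, g)
    es <- eigen(J)
    lead <- which.max(Re(es$values))
    vec <- Re(es$vectors[, lead])
    vec <- vec / max(abs(vec))
    pert <- st
    eps <- 1e-4
    for (f in 1:4) pert$cells[, f] <- pert$cells[, f] + eps * vec[f] * cos(k * th)
    pert$cells[pert$cells < 0] <- 0
    # amplitude of the k-th harmonic of B over one predicted e-folding
    t_fold <- 1 / abs(lam)
    tr <- integrate_state(pert, p, t_end = 1.5 * t_fold, dt = 0.01,
                          record_every = t_fold / 8, conv_tol = 1e-16)
    amp <- apply(tr$snapshots[, 1, ], 2, function(x)
      Mod(sum(x * exp(-1i * k * th))) * 2 / N)
    sel <- tr$times <= t_fold + 1e-9 & tr$times >= t_fold / 8
    fit <- stats::lm(log(amp[sel]) ~ tr$times[sel])
    expect_equal(unname(stats::coef(fit)[2]), lam, tolerance = 0.05)
  }
})

test_that("mode_spectrum rejects non-fixed-point input", {
  p <- default_parameters()
  st <- embryo_state(rep(0.5, p$n_cells), rep(0.5, p$n_cells),
                     rep(0.5, p$n_cells), rep(0.5, p$n_cells))
  expect_error(mode_spectrum(p, st), "fixed point")
  ru <- random_state(n = p$n_cells, seed = 1)
  expect_error(mode_spectrum(p, ru), "homogeneous")
})
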