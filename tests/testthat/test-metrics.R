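test_that("call_domains handles flat, block and antipodal profiles", {
  expect_equal(nrow(call_domains(rep(2, 50))), 0)          # uniform: flat rule
  expect_equal(nrow(call_domains(rep(0, 50))), 0)          # all-zero
  x <- rep(0, 40); x[11:20] <- 1
  d <- call_domains(x)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end, d$width), c(11, 20, 10))
  # two antipodal blocks: two domains with centroids pi apart
  y <- rep(0, 60); y[5:10] <- 1; y[35:40] <- 1
  d2 <- call_domains(y)
  expect_equal(nrow(d2), 2)
  expect_equal(angle_separation(d2$centroid[1], d2$centroid[2]), pi,
               tolerance = 1e-9)
})

test_that("call_domains wraps, merges and filters on the circle", {
  # a domain crossing the index origin
  x <- rep(0, 30); x[c(28, 29, 30, 1, 2, 3)] <- 1
  d <- call_domains(x)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end, d$width), c(28, 3, 6))
  # merging across the origin gap
  y <- rep(0, 24); y[c(21, 22, 23)] <- 1; y[c(2, 3, 4)] <- 1; y[24] <- 0; y[1] <- 0
  d2 <- call_domains(y, merge_gap = 2)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$width, 8)
  # min_width drops narrow blips
  z <- rep(0, 30); z[5:6] <- 1; z[15:25] <- 1
  d3 <- call_domains(z, min_width = 3)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$start, 15)
  expect_error(call_domains(numeric(0)), "empty")
})

test_that("call_domains never merges across a sealed cut", {
  x <- rep(0, 20); x[9:12] <- 1          # block straddling a cut at boundary 10
  d <- call_domains(x, cuts = c(0L, 10L))
  expect_equal(nrow(d), 0)               # split into 9:10 and 11:12, both < 3
  d <- call_domains(x, cuts = c(0L, 10L), min_width = 2)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$start), c(9, 11))
})

test_that("call_domains agrees with exhaustive enumeration on binary rings", {
  for (n in c(8, 10, 12)) {
    for (case in 1:400) {
      set.seed(n * 1000 + case)
      x <- rbinom(n, 1, runif(1, 0.2, 0.8))
      expect_equal(nrow(call_domains(x)), oracle_domains_binary(x),
                   info = sprintf("n=%d case=%d x=%s", n, case,
                                  paste(x, collapse = "")))
    }
  }
})

test_that("polarity index matches closed forms", {
  th <- 2 * pi * (0:99) / 100
  expect_equal(polarity_index(rep(3, 100)), 0)
  expect_equal(polarity_index(1 + cos(th)), 0.5)
  point <- rep(0, 100); point[37] <- 5
  expect_equal(polarity_index(point), 1)
  expect_error(polarity_index(rep(0, 10)), "all-zero")
  # rotation and scale invariance
  x <- 1 + cos(th - 1.2)^2
  for (k in c(5, 50)) {
    xr <- x[((seq_along(x) - 1 + k) %% 100) + 1]
    expect_equal(polarity_index(xr), polarity_index(x), tolerance = 1e-12)
  }
  expect_equal(polarity_index(7.3 * x), polarity_index(x), tolerance = 1e-12)
})

test_that("bv correlation reads antiphase patterns as mutual exclusion", {
  th <- 2 * pi * (0:49) / 50
  st <- embryo_state(1 + cos(th), 1 - cos(th))
  expect_equal(bv_correlation(st), -1, tolerance = 1e-12)
  st2 <- embryo_state(1 + cos(th), 1 + cos(th))
  expect_equal(bv_correlation(st2), 1, tolerance = 1e-12)
  expect_error(bv_correlation(embryo_state(rep(1, 50), 1 + cos(th))),
               "zero variance")
})

test_that("pattern metrics are rotation invariant and scale invariant", {
  st <- state_fixture(list(kind = "unimodal", center = 0.5),
                      list(kind = "unimodal", center = 0.5 + pi), n_cells = 80)
  ps <- pattern_summary(st, v_threshold = 0.4)
  for (k in c(7, 31)) {
    str <- rotate_state(st, k)
    pr <- pattern_summary(str, v_threshold = 0.4)
    expect_equal(pr$classification, ps$classification)
    expect_equal(pr$bv_correlation, ps$bv_correlation, tolerance = 1e-12)
    expect_equal(pr$polarity_index_V, ps$polarity_index_V, tolerance = 1e-12)
    expect_equal(pr$centroid_separation, ps$centroid_separation, tolerance = 1e-9)
  }
  sc <- st; sc$cells <- sc$cells * 3.7
  d1 <- call_domains(st$cells[, "V"])
  d2 <- call_domains(sc$cells[, "V"])
  expect_equal(d1$start, d2$start)
  expect_equal(d1$width, d2$width)
})

test_that("streak prediction thresholds on absolute Vg1 level", {
  st <- state_fixture(list(kind = "uniform", baseline = 0.1),
                      list(kind = "unimodal", center = pi), n_cells = 60)
  expect_equal(predict_streaks(st, v_threshold = 0.5)$count, 1)
  expect_equal(predict_streaks(st, v_threshold = 2)$count, 0)   # peak too low
  zero <- embryo_state(rep(0.2, 60), rep(0, 60))
  expect_equal(predict_streaks(zero, v_threshold = 0.5)$count, 0)
  four <- state_fixture(list(kind = "uniform", baseline = 0.1),
                        list(kind = "k_modal", k = 4, kappa = 30), n_cells = 100)
  stk <- predict_streaks(four, v_threshold = 0.5)
  expect_equal(stk$count, 4)
})
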