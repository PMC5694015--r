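# Shared fixtures for the test suite. Everything is generated in code.

# A small, fast parameter set for structural tests (not the calibrated
# defaults): same rate structure, tiny lattice.
tiny_params <- function(n_cells = 5, r = 1, ...) {
  model_parameters(n_cells = as.integer(n_cells), coupling_radius = as.integer(r),
                   ...)
}

# Random valid state on n cells, reproducible.
random_state <- function(n = 5, seed = 1, scale = 2, cuts = integer(0)) {
  set.seed(seed)
  embryo_state(runif(n) * scale, runif(n) * scale, runif(n) * scale,
               runif(n) * scale, cuts = cuts)
}

# Independent scalar evaluation of the model equations, written directly from
# their definition, loop-based and free of the package's C++ path. Used as the
# oracle for model_rhs.
oracle_rhs <- function(state, params, src_B = rep(0, nrow(state$cells)),
                       src_V = rep(0, nrow(state$cells))) {
  p <- params
  n <- nrow(state$cells)
  hA <- function(x, K) x^p$hill_exponent / (K^p$hill_exponent + x^p$hill_exponent)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("B", "V", "FB", "FV")))
  SB <- oracle_window_mean(state$cells[, "B"], p$coupling_radius, state$cuts)
  SV <- oracle_window_mean(state$cells[, "V"], p$coupling_radius, state$cuts)
  for (i in seq_len(n)) {
    B <- state$cells[i, "B"]; V <- state$cells[i, "V"]
    FB <- state$cells[i, "FB"]; FV <- state$cells[i, "FV"]
    prodFB <- p$alpha_B * hA(SB[i], p$K_BB) * (1 - hA(SV[i], p$K_VB))
    prodFV <- p$alpha_V * (1 - hA(SB[i], p$K_hi)) *
      (hA(SV[i], p$K_VV) + p$c_BV * hA(SB[i], p$K_lo))
    out[i, ] <- c(p$beta_B * FB - p$delta_B * B + src_B[i],
                  p$beta_V * FV - p$delta_V * V + src_V[i],
                  prodFB - p$delta_F * FB,
                  prodFV - p$delta_F * FV)
  }
  out
}

# Independent windowed mean respecting cuts, by explicit walking.
oracle_window_mean <- function(x, r, cuts = integer(0)) {
  n <- length(x)
  cutbefore <- rep(FALSE, n)
  cutbefore[cuts + 1] <- TRUE  # cut b severs edge between cells b and b+1 (1-based)
  vapply(seq_len(n), function(i) {
    acc <- x[i]; cnt <- 1
    pos <- i
    for (s in seq_len(r)) {
      if (cutbefore[pos]) break
      pos <- if (pos == 1) n else pos - 1
      acc <- acc + x[pos]; cnt <- cnt + 1
    }
    pos <- i
    for (s in seq_len(r)) {
      nxt <- if (pos == n) 1 else pos + 1
      if (cutbefore[nxt]) break
      pos <- nxt
      acc <- acc + x[pos]; cnt <- cnt + 1
    }
    acc / cnt
  }, numeric(1))
}

# Brute-force domain count for binary circular profiles, by exhaustive
# pairwise merging: above-threshold cells are vertices; two cells are joined
# when one of the two circular paths between them runs through at most
# merge_gap consecutive sub-threshold cells and no intervening above cell.
# Connected components are candidate domains; a component counts when its
# minimal covering arc spans at least min_width cells.
oracle_domains_binary <- function(x, min_width = 3, merge_gap = 2) {
  n <- length(x)
  if (all(x == x[1])) return(0L)  # flat profiles call no domains
  above <- which(x == 1)
  m <- length(above)
  if (!m) return(0L)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m)) {
    nxt <- if (i == m) 1L else i + 1L
    gap <- (above[nxt] - above[i] - 1) %% n
    if (gap <= merge_gap) {
      ri <- find(i); rj <- find(nxt)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comps <- split(above, vapply(seq_len(m), find, integer(1)))
  spans <- vapply(comps, function(cells) {
    # minimal covering circular arc: n minus the largest gap between
    # consecutive member cells
    cells <- sort(cells)
    gaps <- diff(c(cells, cells[1] + n)) - 1
    as.integer(n - max(gaps))
  }, integer(1))
  sum(spans >= min_width)
}
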