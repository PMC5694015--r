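#' Synthetic circular expression profiles
#'
#' Generates idealised per-cell expression profiles with known ground truth,
#' emulating the in-situ patterns the metrics layer has to quantify: `uniform`
#' (ubiquitous expression), `unimodal` (a single polarised domain), `bipolar`
#' (two bumps a set angle apart — returned as a pair, see [state_fixture()]),
#' `k_modal` (`k` equispaced bumps, as after multiple ectopic grafts) and
#' `step_block` (an exact rectangular block for exact-arithmetic tests).
#' Smooth bumps are von-Mises shaped: `baseline + amplitude *
#' exp(kappa * (cos(theta - mu) - 1))`, circular-native with width set by
#' `kappa`.
#'
#' @param kind one of `"uniform"`, `"unimodal"`, `"k_modal"`, `"step_block"`.
#' @param n_cells lattice size.
#' @param amplitude bump height above baseline (>= 0).
#' @param baseline constant floor (>= 0).
#' @param kappa von-Mises concentration (bump sharpness).
#' @param k number of equispaced bumps for `k_modal`.
#' @param center centre angle of the (first) bump, radians.
#' @param half_width half-width in cells for `step_block`.
#' @param noise_sd additive Gaussian noise standard deviation (clamped at 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A list with `values` (length `n_cells`), `truth_centers` (angles of
#'   the generating bumps) and `truth_domains` (their count).
#' @export
profile_fixture <- function(kind = c("uniform", "unimodal", "k_modal", "step_block"),
                            n_cells = 100, amplitude = 1, baseline = 0,
                            kappa = 8, k = 1, center = pi, half_width = 5,
                            noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  if (amplitude < 0 || baseline < 0) stop("amplitude and baseline must be >= 0")
  if (k < 1) stop("k must be >= 1")
  th <- 2 * pi * (seq_len(n_cells) - 1) / n_cells
  centers <- switch(kind,
    uniform = numeric(0),
    unimodal = center,
    k_modal = (center + 2 * pi * (seq_len(k) - 1) / k) %% (2 * pi),
    step_block = center)
  vals <- rep(baseline, n_cells)
  if (kind == "step_block") {
    cells <- footprint_cells(center, half_width, n_cells)
    vals[cells] <- vals[cells] + amplitude
  } else {
    for (mu in centers) vals <- vals + amplitude * exp(kappa * (cos(th - mu) - 1))
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vals <- pmax(vals + rnorm(n_cells, sd = noise_sd), 0)
  }
  list(values = vals, truth_centers = centers, truth_domains = length(centers))
}

#' Build a full embryo state from profile fixtures
#'
#' Assembles an `mz_state` from a B profile and a V profile, with the
#' intracellular factors set proportional to their ligand (`FB = factor_rule *
#' B`, `FV = factor_rule * V`), so battery predicates can be exercised on
#' states of known structure without running the simulator. The classic
#' anti-phase pair uses two unimodal fixtures `separation` radians apart.
#'
#' @param spec_B,spec_V lists of arguments for [profile_fixture()] (each may
#'   omit `n_cells`, filled from `n_cells`).
#' @param n_cells lattice size for both profiles.
#' @param factor_rule proportionality of intracellular factors to ligands.
#' @return An `mz_state` with attributes `truth_B` and `truth_V` (the fixture
#'   ground truths).
#' @export
state_fixture <- function(spec_B, spec_V, n_cells = 100, factor_rule = 1) {
  fb <- do.call(profile_fixture, modifyList(list(n_cells = n_cells), spec_B))
  fv <- do.call(profile_fixture, modifyList(list(n_cells = n_cells), spec_V))
  if (length(fb$values) != length(fv$values)) stop("profile lengths differ")
  st <- embryo_state(fb$values, fv$values,
                     factor_rule * fb$values, factor_rule * fv$values)
  attr(st, "truth_B") <- fb
  attr(st, "truth_V") <- fv
  st
}
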