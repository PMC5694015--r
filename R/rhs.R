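#' Model right-hand side
#'
#' Evaluates the time derivatives of all four species in every cell. Each cell
#' responds to its perceived (neighbourhood-averaged) signals `S_B` and `S_V`:
#'
#' \deqn{dF_B/dt = \alpha_B\, h^+(S_B, K_{BB})\, h^-(S_V, K_{VB}) - \delta_F F_B}
#' \deqn{dF_V/dt = \alpha_V\, h^-(S_B, K_{hi})\,[h^+(S_V, K_{VV}) + c_{BV} h^+(S_B, K_{lo})] - \delta_F F_V}
#' \deqn{dB/dt = \beta_B F_B - \delta_B B + src_B}
#' \deqn{dV/dt = \beta_V F_V - \delta_V V + src_V}
#'
#' where \eqn{h^+}/\eqn{h^-} are [hill_act()]/[hill_inh()] with exponent
#' `hill_exponent`. Perceived BMP4 activates its own factor `F_B` and, through
#' the band-pass pair (`K_lo`, `K_hi`), has a biphasic effect on `F_V`:
#' intermediate levels induce it (weight `c_BV`), high levels shut it down.
#' Perceived Vg1 inhibits `F_B` and sustains its own factor `F_V`.
#'
#' @param state an `mz_state`.
#' @param params an `mz_params` with `n_cells` matching the state.
#' @param src_B,src_V per-cell source rates (scalar or length `n_cells`),
#'   non-negative; used by perturbations.
#' @param mult_FB,mult_FV per-cell multipliers on the production terms of the
#'   intracellular factors (knockdowns use `1 - efficiency`).
#' @return An `n_cells x 4` matrix of derivatives with columns B, V, FB, FV.
#' @export
model_rhs <- function(state, params, src_B = 0, src_V = 0,
                      mult_FB = 1, mult_FV = 1) {
  stopifnot(inherits(state, "mz_state"), inherits(params, "mz_params"))
  n <- n_cells(state)
  expand <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, n)
    if (length(x) != n) stop(nm, " must have length 1 or n_cells")
    as.numeric(x)
  }
  src_B <- expand(src_B, "src_B"); src_V <- expand(src_V, "src_V")
  if (any(src_B < 0) || any(src_V < 0)) stop("source rates must be non-negative")
  .rhs_core(state$cells, params, state$cuts, src_B, src_V,
            expand(mult_FB, "mult_FB"), expand(mult_FV, "mult_FV"))
}

# Uniform fixed points satisfy B = A_B h+(B,K_BB) h-(V,K_VB) and
# V = A_V h-(B,K_hi) [h+(V,K_VV) + c h+(B,K_lo)] with
# A_B = alpha_B beta_B / (delta_F delta_B), A_V likewise; FB, FV follow.
uniform_residual <- function(bv, p) {
  AB <- p$alpha_B * p$beta_B / (p$delta_F * p$delta_B)
  AV <- p$alpha_V * p$beta_V / (p$delta_F * p$delta_V)
  B <- bv[1]; V <- bv[2]; n <- p$hill_exponent
  c(AB * hill_act(B, p$K_BB, n) * hill_inh(V, p$K_VB, n) - B,
    AV * hill_inh(B, p$K_hi, n) * (hill_act(V, p$K_VV, n) +
                                     p$c_BV * hill_act(B, p$K_lo, n)) - V)
}

#' Homogeneous steady states of the model
#'
#' Finds all non-negative uniform fixed points of the dynamics (states in which
#' every cell is identical, so perceived signals equal local concentrations and
#' the coupling radius drops out). The search reduces the four equations per
#' cell to two unknowns (B, V), runs a multistart root search from a log-spaced
#' grid plus the origin, merges duplicates, and verifies every root against the
#' full lattice right-hand side.
#'
#' The trivial all-off state is always included. At the calibrated defaults the
#' nontrivial state of interest is the doubly-active "launch" state in which
#' both ligands are expressed everywhere, as in the embryo before stage X.
#'
#' @param params an `mz_params`.
#' @param grid_points number of grid points along the B axis for the
#'   continuation seeding.
#' @return A data.frame with columns `B`, `V`, `FB`, `FV`, `residual` (max
#'   absolute RHS over the full system) and `stable_k0` (stability against
#'   uniform perturbations), sorted by ascending `B`.
#' @export
steady_states <- function(params, grid_points = 120) {
  stopifnot(inherits(params, "mz_params"))
  p <- params
  roots <- c(list(c(0, 0)), steady_state_seeds(p, grid_points))
  roots <- lapply(roots, function(z) newton_uniform(z, p))
  roots <- Filter(function(z) !is.null(z) &&
                    max(abs(uniform_residual(z, p))) < 1e-10, roots)
  roots <- c(list(c(0, 0)), roots)
  # merge duplicates at relative tolerance 1e-6
  uniq <- list()
  for (z in roots) {
    dup <- any(vapply(uniq, function(u)
      max(abs(u - z)) <= 1e-6 * max(1, max(abs(u))), logical(1)))
    if (!dup) uniq <- c(uniq, list(z))
  }
  res <- lapply(uniq, function(z) {
    st <- uniform_state(z[1], z[2], p)
    resid <- max(abs(model_rhs(st, p)))
    J <- uniform_jacobian(p, st, g = 1)
    data.frame(B = z[1], V = z[2],
               FB = st$cells[1, "FB"], FV = st$cells[1, "FV"],
               residual = resid,
               stable_k0 = max(Re(eigen(J, only.values = TRUE)$values)) < 0)
  })
  out <- do.call(rbind, res)
  out <- out[out$residual < 1e-8, , drop = FALSE]
  out <- out[order(out$B), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Seeds for the root search: walk a B grid over the attainable range
# [0, A_B]; for each B, locate every V root of the second equation by a dense
# sign-change scan (the V equation is one-dimensional and at most cubic-like
# in behaviour, so bracketing finds all roots).
steady_state_seeds <- function(p, grid_points) {
  AB <- p$alpha_B * p$beta_B / (p$delta_F * p$delta_B)
  AV <- p$alpha_V * p$beta_V / (p$delta_F * p$delta_V)
  Vcap <- AV * (1 + p$c_BV) * 1.001
  Bgrid <- c(0, exp(seq(log(1e-3), log(AB * 1.001), length.out = grid_points)))
  Vgrid <- seq(0, Vcap, length.out = 400)
  n <- p$hill_exponent
  hVV <- hill_act(Vgrid, p$K_VV, n)
  seeds <- list()
  for (B in Bgrid) {
    base <- AV * hill_inh(B, p$K_hi, n)
    band <- p$c_BV * hill_act(B, p$K_lo, n)
    vals <- base * (hVV + band) - Vgrid
    if (abs(vals[1]) < 1e-14) seeds <- c(seeds, list(c(B, 0)))
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      # linear interpolation of the bracket; the Newton polish does the rest
      w <- vals[i] / (vals[i] - vals[i + 1])
      seeds <- c(seeds, list(c(B, Vgrid[i] + w * (Vgrid[i + 1] - Vgrid[i]))))
    }
  }
  seeds
}

# Damped Newton on the reduced 2-equation system with the analytic Jacobian.
newton_uniform <- function(z, p, max_iter = 60) {
  n <- p$hill_exponent
  AB <- p$alpha_B * p$beta_B / (p$delta_F * p$delta_B)
  AV <- p$alpha_V * p$beta_V / (p$delta_F * p$delta_V)
  for (it in seq_len(max_iter)) {
    f <- uniform_residual(z, p)
    if (max(abs(f)) < 1e-13) return(z)
    B <- z[1]; V <- z[2]
    J <- matrix(c(
      AB * hill_act_deriv(B, p$K_BB, n) * hill_inh(V, p$K_VB, n) - 1,
      -AB * hill_act(B, p$K_BB, n) * hill_act_deriv(V, p$K_VB, n),
      AV * (-hill_act_deriv(B, p$K_hi, n) *
              (hill_act(V, p$K_VV, n) + p$c_BV * hill_act(B, p$K_lo, n)) +
              hill_inh(B, p$K_hi, n) * p$c_BV * hill_act_deriv(B, p$K_lo, n)),
      AV * hill_inh(B, p$K_hi, n) * hill_act_deriv(V, p$K_VV, n) - 1),
      2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    znew <- z - step
    znew[znew < 0 & znew > -1e-9] <- 0
    if (any(znew < 0) || any(!is.finite(znew))) return(NULL)
    if (max(abs(znew - z)) < 1e-14 * max(1, max(abs(z)))) { z <- znew; break }
    z <- znew
  }
  if (max(abs(uniform_residual(z, p))) < 1e-12) z else NULL
}

# Build the exact uniform state implied by ligand levels (B, V): the factor
# levels are the corresponding production/decay balance.
uniform_state <- function(B, V, params) {
  p <- params
  n <- p$hill_exponent
  FB <- p$alpha_B / p$delta_F * hill_act(B, p$K_BB, n) * hill_inh(V, p$K_VB, n)
  FV <- p$alpha_V / p$delta_F * hill_inh(B, p$K_hi, n) *
    (hill_act(V, p$K_VV, n) + p$c_BV * hill_act(B, p$K_lo, n))
  N <- p$n_cells
  embryo_state(rep(B, N), rep(V, N), rep(FB, N), rep(FV, N))
}

#' The doubly-active launch state
#'
#' Returns the homogeneous fixed point with both ligands expressed — the
#' model's representation of the pre-stage-X embryo, from which the simulated
#' symmetry breaking starts. Chosen as the steady state maximising
#' `min(B, V)`.
#'
#' @param params an `mz_params`.
#' @return An `mz_state`; errors if no doubly-active state exists.
#' @export
launch_state <- function(params) {
  ss <- steady_states(params)
  cand <- ss[ss$B > 1e-6 & ss$V > 1e-6, , drop = FALSE]
  if (!nrow(cand))
    stop("no doubly-active homogeneous steady state exists at these parameters")
  pick <- cand[which.max(pmin(cand$B, cand$V)), ]
  uniform_state(pick$B, pick$V, params)
}
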