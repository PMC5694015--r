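#' Per-mode Jacobian of a homogeneous state
#'
#' The coupling through perceived signals is circulant on the ring, so linear
#' perturbations decompose into discrete Fourier modes. For wavenumber `k`
#' every coupled derivative is multiplied by the window transfer factor
#' \deqn{g(k) = \frac{1}{2r+1}\sum_{|m| \le r} \cos(2\pi k m / N),}
#' and the mode evolves under a 4x4 matrix: intracellular terms unchanged,
#' signal-mediated terms scaled by `g`. Derivatives of the Hill terms are
#' closed-form.
#'
#' @param params an `mz_params`.
#' @param state a homogeneous `mz_state` (all cells identical).
#' @param g window transfer factor (1 for uniform perturbations).
#' @return A 4x4 numeric matrix in the variable order B, V, FB, FV.
#' @export
uniform_jacobian <- function(params, state, g = 1) {
  p <- params
  n <- p$hill_exponent
  B <- state$cells[1, "B"]; V <- state$cells[1, "V"]
  hBB <- hill_act(B, p$K_BB, n);  dBB <- hill_act_deriv(B, p$K_BB, n)
  hVBi <- hill_inh(V, p$K_VB, n); dVB <- hill_act_deriv(V, p$K_VB, n)
  hVV <- hill_act(V, p$K_VV, n);  dVV <- hill_act_deriv(V, p$K_VV, n)
  hHii <- hill_inh(B, p$K_hi, n); dHi <- hill_act_deriv(B, p$K_hi, n)
  hLo <- hill_act(B, p$K_lo, n);  dLo <- hill_act_deriv(B, p$K_lo, n)
  J <- matrix(0, 4, 4, dimnames = rep(list(c("B", "V", "FB", "FV")), 2))
  J["B", "B"] <- -p$delta_B;  J["B", "FB"] <- p$beta_B
  J["V", "V"] <- -p$delta_V;  J["V", "FV"] <- p$beta_V
  J["FB", "B"] <- g * p$alpha_B * dBB * hVBi
  J["FB", "V"] <- -g * p$alpha_B * hBB * dVB
  J["FB", "FB"] <- -p$delta_F
  J["FV", "B"] <- g * p$alpha_V * (-dHi * (hVV + p$c_BV * hLo) + hHii * p$c_BV * dLo)
  J["FV", "V"] <- g * p$alpha_V * hHii * dVV
  J["FV", "FV"] <- -p$delta_F
  J
}

#' Window transfer factor
#'
#' Fourier multiplier of the mean-over-window coupling on a ring of `N` cells
#' with radius `r`: `g(0) = 1`, `g` is even in `k`.
#' @param k wavenumber(s), `0..floor(N/2)`.
#' @param r coupling radius.
#' @param N ring size.
#' @return Numeric vector of transfer factors.
#' @export
coupling_gain <- function(k, r, N) {
  vapply(k, function(kk) {
    m <- seq_len(r)
    (1 + if (r > 0) 2 * sum(cos(2 * pi * kk * m / N)) else 0) / (2 * r + 1)
  }, numeric(1))
}

#' Linear stability spectrum of a homogeneous state
#'
#' Growth rate of every spatial Fourier mode of the ring around a verified
#' homogeneous fixed point: for each wavenumber `k` the leading eigenvalue
#' real part of the per-mode Jacobian. A positive growth rate at some `k >= 1`
#' with a non-positive rate at `k = 0` is the signature of spontaneous,
#' finite-wavelength symmetry breaking — the pattern is an emergent property
#' of the coupled dynamics, not of any pre-imposed bias.
#'
#' @param params an `mz_params`.
#' @param state a homogeneous `mz_state`; must satisfy `max|rhs| < 1e-8`.
#' @return An object of class `mz_spectrum`: data.frame with columns `k`,
#'   `gain`, `growth_rate`, plus attributes `most_unstable_k` and
#'   `steady_state`.
#' @export
mode_spectrum <- function(params, state) {
  stopifnot(inherits(params, "mz_params"), inherits(state, "mz_state"))
  if (max(abs(apply(state$cells, 2, function(x) diff(range(x))))) > 1e-10)
    stop("state must be homogeneous")
  if (max(abs(model_rhs(state, params))) >= 1e-8)
    stop("state is not a fixed point (residual >= 1e-8)")
  N <- params$n_cells
  r <- params$coupling_radius
  ks <- 0:floor(N / 2)
  g <- coupling_gain(ks, r, N)
  growth <- vapply(seq_along(ks), function(i) {
    J <- uniform_jacobian(params, state, g[i])
    max(Re(eigen(J, only.values = TRUE)$values))
  }, numeric(1))
  out <- data.frame(k = ks, gain = g, growth_rate = growth)
  structure(out, class = c("mz_spectrum", "data.frame"),
            most_unstable_k = ks[which.max(growth)],
            steady_state = state$cells[1, ])
}

#' @export
print.mz_spectrum <- function(x, ...) {
  kstar <- attr(x, "most_unstable_k")
  cat(sprintf("Mode spectrum over k = 0..%d; most unstable k = %d (growth %.4g)\n",
              max(x$k), kstar, x$growth_rate[x$k == kstar]))
  pos <- x$k[x$growth_rate > 0]
  cat(if (length(pos)) paste0("  unstable modes: k = ", paste(pos, collapse = ", "), "\n")
      else "  no unstable modes\n")
  invisible(x)
}

#' @export
plot.mz_spectrum <- function(x, ...) {
  plot(x$k, x$growth_rate, type = "b", pch = 16, xlab = "wavenumber k",
       ylab = "growth rate Re(lambda)", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
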