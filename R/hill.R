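#' Hill activation and inhibition
#'
#' Sigmoidal response functions used for every pairwise gene-regulatory
#' interaction in the model. `hill_act(x, K, n)` is the activating form
#' \eqn{x^n / (K^n + x^n)}; `hill_inh(x, K, n)` is its complement
#' \eqn{K^n / (K^n + x^n)}, so the two always sum to one.
#'
#' @param x non-negative signal concentration (vectorised).
#' @param K half-saturation constant, strictly positive.
#' @param n Hill exponent, at least 1.
#' @return A numeric vector of fractions in `[0, 1]`.
#' @examples
#' hill_act(1, 1, 4)   # 0.5 at the half-saturation point
#' hill_inh(0, 2, 4)   # 1: no inhibitor present
#' @export
hill_act <- function(x, K, n) {
  if (any(!is.finite(x)) || any(x < 0)) stop("'x' must be finite and non-negative")
  if (any(K <= 0)) stop("'K' must be strictly positive")
  if (any(n < 1)) stop("'n' must be >= 1")
  xn <- x^n
  out <- xn / (K^n + xn)
  out[x == 0] <- 0  # guard 0^n/0^n for pathological n
  out
}

#' @rdname hill_act
#' @export
hill_inh <- function(x, K, n) 1 - hill_act(x, K, n)

# d/dx of hill_act, closed form: n K^n x^(n-1) / (K^n + x^n)^2
hill_act_deriv <- function(x, K, n) {
  Kn <- K^n
  ifelse(x > 0, n * Kn * x^(n - 1) / (Kn + x^n)^2, if (n > 1) 0 else n / Kn)
}
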