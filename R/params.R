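#' Model parameters
#'
#' Constructs and validates the full parameter set of the marginal-zone model:
#' lattice size, paracrine coupling radius, Hill constants and exponent,
#' production/secretion/decay rates, the band-pass constants of the biphasic
#' BMP4 -> F_V response, and noise amplitudes. All quantities are dimensionless;
#' time is measured in units of the intracellular factor lifetime (1/`delta_F`)
#' and concentrations are scaled to the model's Hill constants.
#'
#' Unnamed fields fall back to the committed calibrated defaults (see
#' [default_parameters()]).
#'
#' @param ... named parameter values overriding the defaults; unknown names are
#'   an error.
#' @return An object of class `mz_params` (a validated named list).
#' @seealso [default_parameters()], [read_parameters()], [steady_states()]
#' @export
model_parameters <- function(...) {
  override <- list(...)
  if (length(override) == 1 && is.null(names(override)) && is.list(override[[1]]))
    override <- override[[1]]
  defs <- .default_parameter_list()
  unknown <- setdiff(names(override), names(defs))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(defs, override)
  p$n_cells <- as.integer(p$n_cells)
  p$coupling_radius <- as.integer(p$coupling_radius)
  validate_parameters(p)
  structure(p, class = "mz_params")
}

# Committed calibrated defaults (see the methods vignette for the staged
# search that fixed them). The geometry they realise: a BMP4-dominant
# attractor below the rising flank of the band-pass BMP4 -> F_V response
# (so an ectopic anterior source has induction headroom), a Vg1-dominant
# attractor, a doubly-active saddle with a difference-type instability, and
# a band weight c_BV tuned near the front's Maxwell point so that domain
# walls coarsen and then pin.
.default_parameter_list <- function() {
  list(
    n_cells = 100L,
    coupling_radius = 3L,
    hill_exponent = 4,
    alpha_B = 1.90,
    alpha_V = 1.83,
    beta_B = 1,
    beta_V = 1,
    delta_F = 1,
    delta_B = 1,
    delta_V = 1,
    K_BB = 0.41,
    K_VB = 1.58,
    K_VV = 0.95,
    K_lo = 2.90,
    K_hi = 6.69,
    c_BV = 0.69,
    sigma_init = 0.02,
    sigma_dyn = 0
  )
}

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

validate_parameters <- function(p) {
  need <- names(.default_parameter_list())
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid parameters: ", msg)
  chk(p$n_cells >= 3, "n_cells must be at least 3")
  chk(p$coupling_radius >= 0, "coupling_radius must be non-negative")
  chk(2 * p$coupling_radius + 1 <= p$n_cells,
      "coupling window (2*coupling_radius + 1) exceeds n_cells")
  chk(p$hill_exponent >= 1, "hill_exponent must be >= 1")
  pos <- c("alpha_B", "alpha_V", "beta_B", "beta_V", "delta_F", "delta_B",
           "delta_V", "K_BB", "K_VB", "K_VV", "K_lo", "K_hi")
  for (nm in pos) chk(is.numeric(p[[nm]]) && p[[nm]] > 0, paste(nm, "must be > 0"))
  chk(p$K_lo < p$K_hi, "K_lo/K_hi: band-pass requires K_lo < K_hi")
  chk(p$c_BV >= 0, "c_BV must be >= 0")
  chk(p$sigma_init >= 0, "sigma_init must be >= 0")
  chk(p$sigma_dyn >= 0, "sigma_dyn must be >= 0")
  invisible(p)
}

#' @export
print.mz_params <- function(x, ...) {
  cat("Marginal-zone model parameters\n")
  cat(sprintf("  lattice: %d cells, coupling radius %d (window of %d), Hill n = %g\n",
              x$n_cells, x$coupling_radius, 2 * x$coupling_radius + 1, x$hill_exponent))
  cat(sprintf("  F_B branch: alpha_B = %.4g, K_BB = %.3g (act by S_B), K_VB = %.3g (inh by S_V)\n",
              x$alpha_B, x$K_BB, x$K_VB))
  cat(sprintf("  F_V branch: alpha_V = %.4g, K_VV = %.3g (self-act), band %.3g..%.3g, c_BV = %.3g\n",
              x$alpha_V, x$K_VV, x$K_lo, x$K_hi, x$c_BV))
  cat(sprintf("  secretion beta = (%.3g, %.3g), decay delta = (F %.3g, B %.3g, V %.3g)\n",
              x$beta_B, x$beta_V, x$delta_F, x$delta_B, x$delta_V))
  cat(sprintf("  noise: sigma_init = %.3g, sigma_dyn = %.3g\n", x$sigma_init, x$sigma_dyn))
  invisible(x)
}

#' Read or write parameters as flat JSON
#'
#' Parameters serialise to a flat key-value JSON object. On reading, unknown
#' keys are an error; missing keys are filled from the committed defaults with
#' a notice via `message()`.
#'
#' @param path file path.
#' @param params an `mz_params` object.
#' @return `read_parameters()` returns an `mz_params`; `write_parameters()`
#'   returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- .default_parameter_list()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop("configuration error in ", path, ": unknown key(s) ",
         paste(unknown, collapse = ", "))
  miss <- setdiff(names(defs), names(raw))
  if (length(miss))
    message("filling missing parameter(s) from defaults: ", paste(miss, collapse = ", "))
  model_parameters(raw)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "mz_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
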