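#' In-silico experimental manipulations
#'
#' Constructors for the manipulations used in the experiment battery, mirroring
#' the wet-lab protocols on the lattice:
#' * `bead()` — a ligand-soaked bead: a constant source of `B` or `V` added to
#'   all cells within `radius` of `center` during `[t_on, t_off)`;
#' * `pellet()` — a graft of ligand-secreting cells, identical to a bead with
#'   the ligand fixed to Vg1;
#' * `knockdown()` — an antisense-style knockdown: the production term of the
#'   named intracellular factor is multiplied by `1 - efficiency` in the
#'   covered cells during the window.
#'
#' A bead is modelled as a constant-rate source rather than a concentration
#' clamp, matching a reservoir that releases ligand and keeping the dynamics
#' smooth.
#'
#' @param center cell index (1-based) or angular position in radians (reals in
#'   `[0, 2*pi)` are interpreted as angles when not a whole cell index).
#' @param ligand `"B"` or `"V"`.
#' @param strength source rate (concentration/time), non-negative.
#' @param radius extent in cells on each side of the centre.
#' @param t_on,t_off activity window, `t_on < t_off`.
#' @param factor `"FB"` or `"FV"` (knockdown target).
#' @param efficiency knockdown efficiency in `[0, 1]`.
#' @return An object of class `mz_perturbation`.
#' @export
bead <- function(center, ligand = c("B", "V"), strength = 6, radius = 5,
                 t_on = 0, t_off = Inf) {
  ligand <- match.arg(ligand)
  new_perturbation("bead", ligand, center, radius, strength, t_on, t_off)
}

#' @rdname bead
#' @export
pellet <- function(center, strength = 6, radius = 5, t_on = 0, t_off = Inf) {
  p <- new_perturbation("pellet", "V", center, radius, strength, t_on, t_off)
  p
}

#' @rdname bead
#' @export
knockdown <- function(factor = c("FB", "FV"), center, radius, efficiency,
                      t_on = 0, t_off = Inf) {
  factor <- match.arg(factor)
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop("knockdown efficiency must lie in [0, 1]")
  new_perturbation("knockdown", factor, center, radius, efficiency, t_on, t_off)
}

new_perturbation <- function(kind, target, center, radius, strength, t_on, t_off) {
  if (!is.numeric(strength) || strength < 0) stop("strength must be non-negative")
  if (!is.numeric(radius) || radius < 0) stop("radius must be non-negative")
  if (!(t_on < t_off)) stop("t_on must be earlier than t_off")
  structure(list(kind = kind, target = target, center = center,
                 radius = as.integer(radius), strength = strength,
                 t_on = t_on, t_off = t_off),
            class = "mz_perturbation")
}

#' @export
print.mz_perturbation <- function(x, ...) {
  cat(sprintf("%s on %s: center %s, radius %d cells, %s %.3g, window [%g, %g)\n",
              x$kind, x$target, format(x$center), x$radius,
              if (x$kind == "knockdown") "efficiency" else "strength",
              x$strength, x$t_on, x$t_off))
  invisible(x)
}

# Resolve a centre given as angle or cell index to a 1-based cell index.
resolve_center <- function(center, n) {
  if (center %% 1 == 0 && center >= 1 && center <= n) return(as.integer(center))
  if (center >= 0 && center < 2 * pi) return((round(center / (2 * pi) * n) %% n) + 1L)
  stop("center must be a cell index in 1..n_cells or an angle in [0, 2*pi)")
}

#' Cells covered by a circular footprint
#'
#' @param center cell index or angle (see [bead()]).
#' @param radius extent in cells on each side.
#' @param n ring size.
#' @return 1-based cell indices within `radius` of the centre.
#' @export
footprint_cells <- function(center, radius, n) {
  c0 <- resolve_center(center, n)
  if (2 * radius + 1 > n) stop("footprint exceeds the lattice")
  (((c0 - 1) + seq(-radius, radius)) %% n) + 1L
}

# Lower the perturbation list to the event table consumed by the C++ core.
compile_events <- function(perturbations, params) {
  if (inherits(perturbations, "mz_perturbation"))
    perturbations <- list(perturbations)
  n <- params$n_cells
  tab <- matrix(numeric(0), ncol = 4)
  cells <- list()
  for (p in perturbations) {
    if (!inherits(p, "mz_perturbation")) stop("perturbations must be mz_perturbation objects")
    type <- switch(p$target, B = 0, V = 1, FB = 2, FV = 3)
    tab <- rbind(tab, c(type, p$t_on, p$t_off, p$strength))
    cells <- c(cells, list(footprint_cells(p$center, p$radius, n) - 1L))
  }
  list(table = tab, cells = cells)
}
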