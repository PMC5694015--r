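#' Embryo state on a ring of marginal-zone cells
#'
#' An `mz_state` holds, for each of the `n_cells` lattice sites, the four
#' species of the model: extracellular BMP4 (`B`) and Vg1 (`V`) and the
#' intracellular factors `FB` and `FV`. Cell `i` sits at angular position
#' `theta_i = 2*pi*(i-1)/n_cells`. The topology is a closed ring unless cut
#' positions are supplied, in which case the lattice is a set of sealed arcs.
#'
#' Cuts are 0-based boundary indices in `0..n_cells-1`: a cut at `b` severs the
#' edge between cell `b` and cell `b+1` in 1-based cell numbering (a cut at 0
#' separates cell `n_cells` from cell 1).
#'
#' @param B,V,FB,FV numeric vectors of equal length (>= 3), all non-negative.
#' @param cuts integer vector of cut boundaries (empty for a closed ring).
#' @param time non-negative simulation time attached to the snapshot.
#' @return An object of class `mz_state`.
#' @export
embryo_state <- function(B, V, FB = rep(0, length(B)), FV = rep(0, length(B)),
                         cuts = integer(0), time = 0) {
  n <- length(B)
  if (n < 3) stop("an embryo state needs at least 3 cells")
  if (length(V) != n || length(FB) != n || length(FV) != n)
    stop("B, V, FB, FV must have equal length")
  m <- cbind(B = as.numeric(B), V = as.numeric(V),
             FB = as.numeric(FB), FV = as.numeric(FV))
  if (any(!is.finite(m)) || any(m < 0))
    stop("all state fields must be finite and non-negative")
  cuts <- check_cuts(cuts, n)
  structure(list(cells = m, cuts = cuts, time = as.numeric(time)),
            class = "mz_state")
}

check_cuts <- function(cuts, n) {
  if (!length(cuts)) return(integer(0))
  cuts <- as.integer(cuts)
  if (anyDuplicated(cuts)) stop("duplicate cut positions")
  if (any(cuts < 0 | cuts >= n)) stop("cut positions must lie in 0..n_cells-1")
  sort(cuts)
}

n_cells <- function(state) nrow(state$cells)

#' @export
print.mz_state <- function(x, ...) {
  n <- n_cells(x)
  topo <- if (length(x$cuts)) sprintf("%d sealed arcs", length(x$cuts)) else "closed ring"
  cat(sprintf("Embryo state: %d cells (%s), t = %.3g\n", n, topo, x$time))
  rng <- apply(x$cells, 2, range)
  for (s in colnames(x$cells))
    cat(sprintf("  %-2s in [%.4g, %.4g], mean %.4g\n",
                s, rng[1, s], rng[2, s], mean(x$cells[, s])))
  invisible(x)
}

#' @export
as.data.frame.mz_state <- function(x, ...) {
  data.frame(time = x$time, cell_index = seq_len(n_cells(x)),
             B = x$cells[, "B"], V = x$cells[, "V"],
             FB = x$cells[, "FB"], FV = x$cells[, "FV"])
}

#' Perceived paracrine signal
#'
#' The signal a cell actually responds to is the mean of a species over all
#' cells within graph distance `r` on the lattice. On a ring the window wraps;
#' on sealed arcs it is truncated at cut boundaries, and the mean is taken
#' over the cells available (so a uniform field is perceived uniformly
#' regardless of topology).
#'
#' @param state an `mz_state`.
#' @param species `"B"` or `"V"` (intracellular factors are not secreted).
#' @param r coupling radius in cells; defaults to the calibrated radius.
#' @return Numeric vector of per-cell perceived concentrations.
#' @export
perceived_signal <- function(state, species = c("B", "V"),
                             r = default_parameters()$coupling_radius) {
  species <- match.arg(species)
  stopifnot(inherits(state, "mz_state"), r >= 0)
  .perceived_core(state$cells[, species], as.integer(r), state$cuts)
}

#' Fragment the ring into sealed arcs
#'
#' Implements the embryo fragmentation experiment: cutting the blastodisc into
#' pieces, each of which can organise its own axis. Cell states are unchanged
#' at the instant of cutting; only the topology (and hence all subsequent
#' perceived-signal windows) changes.
#'
#' @param state an `mz_state` on a closed ring.
#' @param cuts integer vector of cut boundaries (see [embryo_state()]); a
#'   single cut opens the ring into one arc.
#' @return The state with arc topology.
#' @export
apply_fragmentation <- function(state, cuts) {
  stopifnot(inherits(state, "mz_state"))
  if (!length(cuts)) stop("at least one cut position is required")
  state$cuts <- check_cuts(cuts, n_cells(state))
  state
}

#' Arc membership of each cell
#'
#' @param state an `mz_state`.
#' @return Integer vector assigning each cell to an arc (all 1 on a ring).
#' @export
arc_membership <- function(state) {
  n <- n_cells(state)
  if (!length(state$cuts)) return(rep(1L, n))
  # cells 0..n-1; arc starts at each cut boundary b (cell index b, 1-based b+1)
  starts <- sort(state$cuts)
  id <- integer(n)
  lab <- 0L
  # walk from the first cut
  ord <- ((starts[1] + seq_len(n) - 1) %% n) + 1L  # 1-based cell sequence
  cutset <- starts
  for (cell in ord) {
    if ((cell - 1L) %in% cutset) lab <- lab + 1L
    id[cell] <- lab
  }
  if (any(id == 0L)) id[id == 0L] <- lab  # only when walk started mid-arc
  id
}

#' Rotate a ring state by k cells
#'
#' Utility used for the model's rotational-equivariance properties. Only valid
#' on a closed ring.
#' @param state an `mz_state` with no cuts.
#' @param k integer shift (cell `i` moves to `i + k`).
#' @return The rotated state.
#' @export
rotate_state <- function(state, k) {
  stopifnot(inherits(state, "mz_state"))
  if (length(state$cuts)) stop("rotation is only defined on a closed ring")
  n <- n_cells(state)
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  state$cells <- state$cells[idx, , drop = FALSE]
  state
}
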