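#' Call expression domains on a circular profile
#'
#' Turns a per-cell expression profile into discrete high-expression domains.
#' Flat profiles (relative range below `flat_frac`, or maximum below 1e-6)
#' yield no domains. Otherwise cells above
#' `min + threshold_frac * (max - min)` form candidate arcs; arcs separated by
#' at most `merge_gap` sub-threshold cells are merged; merged arcs narrower
#' than `min_width` (span, in cells) are dropped. On a ring the arcs wrap; with
#' cuts, arcs never cross a cut boundary. The threshold is computed over the
#' whole profile supplied.
#'
#' @param profile non-negative per-cell values (length >= 3).
#' @param threshold_frac relative threshold in (0, 1).
#' @param min_width minimum domain span in cells.
#' @param merge_gap largest sub-threshold gap merged into a domain.
#' @param flat_frac relative range below which the profile counts as flat.
#' @param cuts cut boundaries (see [embryo_state()]); `integer(0)` for a ring.
#' @return A data.frame with one row per domain: `start`, `end` (1-based cell
#'   indices, inclusive; `end < start` indicates wrap-around), `width`, `peak`,
#'   and `centroid` (angle in radians, the circular mean of cell angles
#'   weighted by value minus threshold).
#' @export
call_domains <- function(profile, threshold_frac = 0.5, min_width = 3,
                         merge_gap = 2, flat_frac = 0.05, cuts = integer(0)) {
  if (!length(profile)) stop("empty profile")
  if (length(profile) < 3) stop("profile must have length >= 3")
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("profile must be finite and non-negative")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  n <- length(profile)
  cuts <- check_cuts(cuts, n)
  lo <- min(profile); hi <- max(profile)
  empty <- data.frame(start = integer(0), end = integer(0), width = integer(0),
                      peak = numeric(0), centroid = numeric(0))
  if (hi < 1e-6 || (hi - lo) < flat_frac * hi) return(empty)
  thr <- lo + threshold_frac * (hi - lo)
  above <- profile > thr

  # Treat every cut as a hard break. On an uncut ring, unroll inside the
  # longest sub-threshold gap, so that merging across every other gap (and
  # across the index origin) follows circular semantics. If even the longest
  # gap is mergeable, all above-threshold cells form one domain.
  breaks <- cuts  # 0-based boundary before cell (boundary b precedes cell b+1)
  if (!length(breaks)) {
    if (all(above)) {
      dom <- data.frame(start = 1L, end = n, width = n, peak = hi,
                        centroid = domain_centroid(profile, seq_len(n), thr, n))
      return(dom)
    }
    gap <- longest_circular_run(!above)
    if (gap$len <= merge_gap) {
      # every gap merges: a single domain spanning all but the longest gap
      start <- (gap$start + gap$len - 1L) %% n + 1L
      end <- (gap$start - 2L) %% n + 1L
      span <- n - gap$len
      if (span < min_width) return(empty)
      cells <- ((start - 1L + seq_len(span) - 1L) %% n) + 1L
      return(data.frame(start = start, end = end, width = span,
                        peak = max(profile[cells[above[cells]]]),
                        centroid = domain_centroid(profile, cells[above[cells]],
                                                   thr, n)))
    }
    breaks <- (gap$start - 1L) %% n  # boundary before the longest gap
  }
  # unroll the circle starting at the first break
  b0 <- sort(breaks)[1]
  ord <- ((b0 + seq_len(n) - 1) %% n) + 1L          # 1-based cells in walk order
  hard <- c(TRUE, ((ord[-1] - 1L) %in% breaks))     # break before this position?

  runs <- list()
  cur <- integer(0)
  gap <- Inf
  flush <- function(runs, cur) if (length(cur)) c(runs, list(cur)) else runs
  for (j in seq_len(n)) {
    if (hard[j] && j > 1) { runs <- flush(runs, cur); cur <- integer(0); gap <- Inf }
    if (above[ord[j]]) {
      if (length(cur) && gap > merge_gap) { runs <- flush(runs, cur); cur <- integer(0) }
      cur <- c(cur, j)
      gap <- 0
    } else if (length(cur)) gap <- gap + 1
  }
  runs <- flush(runs, cur)
  if (!length(runs)) return(empty)

  rows <- lapply(runs, function(jj) {
    span <- jj[1]:jj[length(jj)]
    cells <- ord[span]
    if (length(span) < min_width) return(NULL)
    data.frame(start = cells[1], end = cells[length(cells)],
               width = length(span), peak = max(profile[cells[above[cells]]]),
               centroid = domain_centroid(profile, cells[above[cells]], thr, n))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# longest circular run of TRUE values: list(start = 1-based first cell, len)
longest_circular_run <- function(flag) {
  n <- length(flag)
  r <- rle(rep(flag, 2))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & starts <= n
  len <- pmin(r$lengths[ok], n)
  best <- which.max(len)
  list(start = starts[ok][best], len = len[best])
}

# circular mean of cell angles weighted by (value - thr), clamped at 0
domain_centroid <- function(profile, cells, thr, n) {
  th <- 2 * pi * (cells - 1) / n
  w <- pmax(profile[cells] - thr, 0)
  if (sum(w) == 0) w <- rep(1, length(cells))
  Arg(sum(w * exp(1i * th))) %% (2 * pi)
}

#' Polarity index of a circular profile
#'
#' Magnitude of the first circular harmonic of the mass distribution,
#' `|sum(p_i exp(i theta_i))| / sum(p_i)`: 0 for a uniform profile, 1 for a
#' point mass; invariant to rotation and positive scaling.
#'
#' @param profile non-negative per-cell values, not all zero.
#' @return A number in `[0, 1]`.
#' @export
polarity_index <- function(profile) {
  if (any(profile < 0)) stop("profile must be non-negative")
  s <- sum(profile)
  if (s == 0) stop("polarity index is undefined for an all-zero profile")
  th <- 2 * pi * (seq_along(profile) - 1) / length(profile)
  Mod(sum(profile * exp(1i * th))) / s
}

#' BMP4-Vg1 anticorrelation
#'
#' Pearson correlation of per-cell B against V; strongly negative once the two
#' ligands have segregated to opposite poles.
#'
#' @param state an `mz_state`.
#' @return Correlation in `[-1, 1]`; errors if either profile has zero
#'   variance.
#' @export
bv_correlation <- function(state) {
  stopifnot(inherits(state, "mz_state"))
  B <- state$cells[, "B"]; V <- state$cells[, "V"]
  if (sd(B) == 0 || sd(V) == 0)
    stop("correlation undefined: a profile has zero variance")
  cor(B, V)
}

#' Predict primitive-streak initiation sites
#'
#' Streaks are predicted wherever a called Vg1 domain's peak exceeds an
#' absolute threshold tied to the model's own scale: half the Vg1 level of the
#' doubly-active homogeneous state (so calls do not depend on a run's
#' particular maximum).
#'
#' @param state an `mz_state`.
#' @param params an `mz_params` (used to derive the default threshold).
#' @param v_threshold absolute Vg1 peak threshold; derived from `params` when
#'   `NULL`.
#' @param ... passed to [call_domains()].
#' @return A list with `count` and `centroids` (radians).
#' @export
predict_streaks <- function(state, params = default_parameters(),
                            v_threshold = NULL, ...) {
  stopifnot(inherits(state, "mz_state"))
  if (is.null(v_threshold)) v_threshold <- streak_threshold(params)
  dom <- call_domains(state$cells[, "V"], cuts = state$cuts, ...)
  dom <- dom[dom$peak > v_threshold, , drop = FALSE]
  list(count = nrow(dom), centroids = dom$centroid)
}

streak_threshold <- function(params) {
  ss <- steady_states(params)
  von <- ss[ss$V > 1e-6, , drop = FALSE]
  if (!nrow(von)) return(0.5)  # degenerate parameter sets: fixed fallback
  0.5 * max(von$V)
}

#' Summarise a pattern
#'
#' Full quantitative readout of a final state: called B and V domains,
#' polarity indices, B-V correlation, centroid separation, predicted streaks,
#' and a classification into `uniform`, `unipolar`, `bipolar` (exactly one
#' domain of each ligand with centroids more than 2*pi/3 apart) or
#' `multipolar`.
#'
#' @inheritParams predict_streaks
#' @return An object of class `mz_pattern`.
#' @export
pattern_summary <- function(state, params = default_parameters(),
                            v_threshold = NULL, ...) {
  stopifnot(inherits(state, "mz_state"))
  B <- state$cells[, "B"]; V <- state$cells[, "V"]
  dB <- call_domains(B, cuts = state$cuts, ...)
  dV <- call_domains(V, cuts = state$cuts, ...)
  sep <- if (nrow(dB) == 1 && nrow(dV) == 1)
    angle_separation(dB$centroid, dV$centroid) else NA_real_
  cls <- if (nrow(dB) + nrow(dV) == 0) "uniform"
  else if (nrow(dB) == 1 && nrow(dV) == 1 && isTRUE(sep > 2 * pi / 3)) "bipolar"
  else if (nrow(dB) + nrow(dV) == 1) "unipolar"
  else "multipolar"
  structure(list(
    domains_B = dB, domains_V = dV,
    polarity_index_B = if (sum(B) > 0) polarity_index(B) else 0,
    polarity_index_V = if (sum(V) > 0) polarity_index(V) else 0,
    bv_correlation = if (sd(B) > 0 && sd(V) > 0) cor(B, V) else NA_real_,
    centroid_separation = sep,
    streaks = predict_streaks(state, params, v_threshold, ...),
    classification = cls), class = "mz_pattern")
}

#' Angular separation mapped to `[0, pi]`
#' @param a,b angles in radians.
#' @return The separation between the two angles.
#' @export
angle_separation <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' @export
print.mz_pattern <- function(x, ...) {
  cat(sprintf("Pattern: %s | %d B domain(s), %d V domain(s)\n",
              x$classification, nrow(x$domains_B), nrow(x$domains_V)))
  cat(sprintf("  polarity B %.3f, V %.3f; B-V correlation %s\n",
              x$polarity_index_B, x$polarity_index_V,
              ifelse(is.na(x$bv_correlation), "NA", sprintf("%.3f", x$bv_correlation))))
  if (!is.na(x$centroid_separation))
    cat(sprintf("  centroid separation %.3f rad\n", x$centroid_separation))
  cat(sprintf("  predicted streaks: %d\n", x$streaks$count))
  invisible(x)
}
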