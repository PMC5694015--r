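#' Export a trajectory to CSV with a JSON sidecar
#'
#' Writes the long-format table (`time`, `cell_index`, `B`, `V`, `FB`, `FV`)
#' and a JSON sidecar with the run metadata (parameters, seed, events,
#' convergence). Reruns with identical inputs reproduce identical bytes.
#'
#' @param traj an `mz_trajectory`.
#' @param dir output directory (created if needed).
#' @param stem file stem; produces `<stem>.csv` and `<stem>.json`.
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
write_trajectory <- function(traj, dir, stem = "trajectory") {
  stopifnot(inherits(traj, "mz_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, ".json"))
  df <- as.data.frame(traj)
  write.csv(df, csv, row.names = FALSE)
  meta <- list(params = unclass(traj$params), seed = traj$seed,
               cuts = traj$cuts,
               events = lapply(traj$events, unclass),
               converged = traj$converged,
               final_residual = traj$final_residual,
               n_snapshots = length(traj$times))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(write_manifest(dir, c(csv, js)))
}

#' Write an analysis report with a file manifest
#'
#' Serialises any list-like report to JSON in `dir` and returns a manifest of
#' the files written with their MD5 content hashes, so a rerun can be checked
#' for byte-reproducibility.
#'
#' @param report a list (e.g. battery output or a pattern summary).
#' @param dir output directory.
#' @param stem file stem for `<stem>.json`.
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(strip_classes(report), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(write_manifest(dir, js))
}

strip_classes <- function(x) {
  if (inherits(x, "mz_state")) x <- list(cells = x$cells, cuts = x$cuts, time = x$time)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

write_manifest <- function(dir, files) {
  man <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  man
}
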