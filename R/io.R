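#' Export a trajectory to CSV with a JSON metadata sidecar
#'
#' Writes the trajectory in long format (`time_s, species, concentration_M`)
#' and wide format (one column per species), plus a JSON sidecar recording
#' solver tolerances, horizon and the parameter-file hash.
#'
#' @param trajectory A `coag_trajectory`.
#' @param prefix Output path prefix; files are `<prefix>_long.csv`,
#'   `<prefix>_wide.csv` and `<prefix>_meta.json`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_trajectory <- function(trajectory, prefix) {
  wide <- data.frame(time_s = trajectory$time,
                     trajectory$conc, check.names = FALSE)
  long <- data.frame(
    time_s = rep(trajectory$time, times = ncol(trajectory$conc)),
    species = rep(colnames(trajectory$conc), each = length(trajectory$time)),
    concentration_M = as.vector(trajectory$conc),
    stringsAsFactors = FALSE)
  paths <- paste0(prefix, c("_long.csv", "_wide.csv", "_meta.json"))
  utils::write.csv(long, paths[1], row.names = FALSE)
  utils::write.csv(wide, paths[2], row.names = FALSE)
  jsonlite::write_json(trajectory$meta, paths[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back a wide-format trajectory CSV
#'
#' @param path Path to a `*_wide.csv` written by [write_trajectory()].
#' @return A `coag_trajectory` (metadata read from the sidecar when
#'   present).
#' @export
read_trajectory <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  meta_path <- sub("_wide\\.csv$", "_meta.json", path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(list(time = wide$time_s,
                 conc = as.matrix(wide[, -1, drop = FALSE]),
                 meta = meta),
            class = "coag_trajectory")
}
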