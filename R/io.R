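#' Read and write trajectory tables
#'
#' Trajectory tables are delimited text with a mandatory header and columns
#' `track_id, frame, theta_mrad, chi_mrad[, population]`; `frame` is 0-based.
#'
#' @param trajs Trajectory tibble.
#' @param path File path (CSV).
#' @return `read_trajectories()` returns a tibble; `write_trajectories()`
#'   returns `path` invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  assert_cols(trajs, c("track_id", "frame", "theta_mrad", "chi_mrad"), "`trajs`")
  cols <- intersect(c("track_id", "frame", "theta_mrad", "chi_mrad",
                      "population"), names(trajs))
  readr::write_csv(trajs[cols], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("track_id", "frame", "theta_mrad", "chi_mrad"),
              sprintf("'%s'", path))
  out
}

#' Write a map as delimited text with edge headers
#'
#' The matrix (tilt bins as rows, twist bins as columns) is preceded by two
#' comment lines giving the extended bin edges.
#'
#' @param map A `two_axis_map` or `subtraction_map`.
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  m <- if (inherits(map, "two_axis_map")) map$density else map$difference
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# chi_edges:", paste(map$chi_edges, collapse = " ")),
    paste("# theta_edges:", paste(map$theta_edges, collapse = " "))), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write run configuration files
#'
#' Run configurations are YAML files mirroring [default_run_config()]; values
#' present in the file override the defaults.
#'
#' @param path YAML file path.
#' @param config A run-config list.
#' @return `read_run_config()` returns a complete run-config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  modifyList(cfg, user)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
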