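#' Read and write fiducial series as CSV
#'
#' The on-disk format is a two-column CSV with columns `type` (one of `P`,
#' `QRSon`, `R`, `QRSoff`, `Tend`) and `time_s`, one fiducial per row.
#'
#' @param f A \code{\link{fiducial_series}}.
#' @param path File path.
#' @param species,duration Metadata applied on read (see
#'   \code{\link{fiducial_series}}).
#' @return `read_fiducials` returns a `fiducial_series`;
#'   `write_fiducials` returns `path` invisibly.
#' @export
write_fiducials <- function(f, path) {
  stopifnot(inherits(f, "fiducial_series"))
  rows <- rbind(
    data.frame(type = rep("P", length(f$p_times)), time_s = f$p_times),
    data.frame(type = rep("QRSon", length(f$qrs_onsets)), time_s = f$qrs_onsets %||% numeric()),
    data.frame(type = rep("R", length(f$r_times)), time_s = f$r_times),
    data.frame(type = rep("QRSoff", length(f$qrs_offsets)), time_s = f$qrs_offsets %||% numeric()),
    data.frame(type = rep("Tend", length(f$t_ends)), time_s = f$t_ends %||% numeric()))
  utils::write.csv(rows[order(rows$time_s), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path, species = "zebrafish", duration = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("type", "time_s") %in% names(d))) {
    stop("fiducial CSV needs columns 'type' and 'time_s'")
  }
  grab <- function(ty) {
    x <- sort(d$time_s[d$type == ty])
    if (length(x)) x else NULL
  }
  fiducial_series(p_times = grab("P") %||% numeric(),
                  r_times = grab("R") %||% numeric(),
                  qrs_onsets = grab("QRSon"), qrs_offsets = grab("QRSoff"),
                  t_ends = grab("Tend"), species = species, duration = duration)
}

#' Export a simulated membrane-potential trace
#'
#' Writes the two-column trace CSV (`time_s`, `em_mV`); beats go to a
#' one-column CSV (`beat_time_s`).
#'
#' @param sim A `san_sim` result from \code{\link{simulate_pacemaker}}.
#' @param trace_path,beats_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_sim_csv <- function(sim, trace_path = NULL, beats_path = NULL) {
  stopifnot(inherits(sim, "san_sim"))
  if (!is.null(trace_path)) {
    utils::write.csv(data.frame(time_s = sim$time, em_mV = sim$em_trace),
                     trace_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(beats_path)) {
    utils::write.csv(data.frame(beat_time_s = sim$beat_times),
                     beats_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(trace_path, beats_path))
}

#' Write population results and a run manifest
#'
#' The population table (one row per variant: id, scalings, rates, responses,
#' status, label) and the group-comparison table are plain CSVs; the manifest
#' is a small JSON file recording the seed, population settings and model
#' provenance so a run can be reproduced.
#'
#' @param records Population data frame.
#' @param comparison Comparison data frame from \code{\link{compare_groups}}
#'   (optional).
#' @param config The \code{\link{population_config}} used.
#' @param model The \code{\link{pacemaker_model}} used (or `NULL` for the
#'   surrogate engine).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_population <- function(records, comparison = NULL, config = NULL,
                             model = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(records, file.path(dir, "population.csv"), row.names = FALSE)
  if (!is.null(comparison)) {
    utils::write.csv(comparison, file.path(dir, "comparison.csv"), row.names = FALSE)
  }
  manifest <- list(
    seed = if (!is.null(config)) config$seed else NA,
    n_variants = if (!is.null(config)) config$n_variants else nrow(records),
    sigma = if (!is.null(config)) config$sigma else NA,
    varied_params = if (!is.null(config)) config$varied_params else attr(records, "varied_params"),
    model = if (!is.null(model)) model$metadata else "analytic surrogate")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write episode calls as CSV
#'
#' @param episodes Episode data frame from \code{\link{detect_sa_episodes}} or
#'   \code{\link{detect_avb_episodes}} (or both, row-bound).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_episodes <- function(episodes, path) {
  cols <- intersect(c("kind", "onset", "offset", "evidence"), names(episodes))
  utils::write.csv(episodes[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
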