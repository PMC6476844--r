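# File formats: time-series / endpoint CSVs, run manifests, state snapshots.
# CSV dialect is fixed (comma-separated, header row, UTF-8, '.' decimal, no
# row index) for cross-tool stability.

#' Write a time-series or endpoint table as CSV
#'
#' @param x A tibble/data.frame (e.g. `sim$records` or a [run_grid()]
#'   endpoint table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_time_series
#' @export
write_endpoint_table <- write_time_series

#' Save a population-state snapshot
#'
#' Serializes the full evolving state together with the generation counter
#' and a hash of the scenario configuration, so that long runs can be
#' checkpointed and resumed (see `initial_state` in [run_simulation()]) and
#' so a resume against a different configuration is detectable.
#'
#' @param state A `population_state`.
#' @param path Output path (RDS container).
#' @param config Optional `scenario_config` whose hash is stored.
#' @return `path`, invisibly.
#' @export
write_population_snapshot <- function(state, path, config = NULL) {
  stopifnot(inherits(state, "population_state"))
  saveRDS(list(
    format = "ecodiverge_snapshot_v1",
    state = state,
    generation = state$generation,
    config_hash = if (is.null(config)) NA_character_ else config_hash(config)
  ), path)
  invisible(path)
}

#' Load a population-state snapshot
#'
#' @param path Path written by [write_population_snapshot()].
#' @param config Optional `scenario_config`; if given, its hash must match
#'   the one stored in the snapshot.
#' @return The `population_state`.
#' @export
read_population_snapshot <- function(path, config = NULL) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  snap <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt snapshot: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(snap) || !identical(snap$format, "ecodiverge_snapshot_v1") ||
      !inherits(snap$state, "population_state")) {
    stop("corrupt snapshot: not an ecodiverge snapshot", call. = FALSE)
  }
  if (!is.null(config) && !is.na(snap$config_hash) &&
      !identical(config_hash(config), snap$config_hash)) {
    stop("snapshot/config mismatch: configuration hash differs", call. = FALSE)
  }
  snap$state
}

#' Hash of a scenario configuration
#'
#' @param config A `scenario_config`.
#' @return A short stable hash string.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a run's outputs
#' exactly: the configuration hash of every scenario, the base seed, the
#' software version, a timestamp, and the output paths.
#'
#' @param grid A [build_grid()] tibble (or one-scenario equivalent).
#' @param base_seed Base seed of the run.
#' @param replicates Replicates per scenario.
#' @param outputs Named character vector/list of output file paths.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(grid, base_seed, replicates, outputs = list()) {
  structure(list(
    package = "ecodiverge",
    version = as.character(utils::packageVersion("ecodiverge")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = base_seed,
    replicates = replicates,
    scenarios = lapply(seq_len(nrow(grid)), function(i) {
      list(scenario_id = grid$scenario_id[i],
           config_hash = config_hash(grid$config[[i]]))
    }),
    outputs = as.list(outputs)
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
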