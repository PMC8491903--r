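#' Read a model configuration file
#'
#' Loads a flat YAML configuration whose keys mirror the model's parameter
#' table (`mu0, alpha, b_S, d_S, r_S, b_R, d_R, r_R, d_max, u_max, k, h, T,
#' K, S0, R0, theta_S, theta_R`, plus `growth_kind` and `u_MTD`). Missing
#' keys fall back to the packaged defaults; each fallback is logged as a
#' message. Cross-field invariants are enforced and violations are rejected
#' naming the rule (e.g. an `r_S` inconsistent with `b_S - d_S`).
#'
#' The packaged default configuration is
#' `system.file("extdata", "default_params.yaml", package = "evorescue")`.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress fallback messages.
#' @return A validated [rescue_params()] object.
#' @export
read_params <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- rescue_params()
  known <- setdiff(names(unclass(defaults)), character())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(defaults)
  for (key in known) {
    if (!is.null(raw[[key]])) {
      p[[key]] <- if (key == "growth_kind") as.character(raw[[key]]) else
        as.numeric(raw[[key]])
    } else if (!quiet) {
      message("read_params: key '", key, "' missing, using default ",
              format(defaults[[key]]))
    }
  }
  class(p) <- "rescue_params"
  validate_params(p)
}

#' Write a model configuration file
#'
#' Serialises a parameter set to flat YAML at full precision, so that
#' `read_params(write_params(p, path))` round-trips exactly.
#'
#' @param p A [rescue_params()] object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "rescue_params"))
  yaml::write_yaml(unclass(p), path, precision = 15)
  invisible(path)
}

#' Write result objects to disk
#'
#' Serialises the package's result types to plain-text artifacts: CSV for
#' tabular objects (trajectories, cohort replicate and summary tables,
#' contour grids, schedules) and JSON for scalar summaries. Numeric CSV
#' output is written at full precision so re-runs are diffable. Returns a
#' file inventory with checksums, suitable for a run manifest.
#'
#' @param x A result object (`rescue_trajectory`, `cohort_result`,
#'   `dose_sweep`, `control_solution`, `control_map`, `contour_result`, or
#'   a plain data frame).
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_<part>.<ext>`.
#' @return A tibble `file, md5` of everything written.
#' @export
write_results <- function(x, prefix) {
  UseMethod("write_results")
}

write_csv_full <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- dplyr::mutate(as.data.frame(df), dplyr::across(
    dplyr::where(is.numeric), ~ format(.x, digits = 17, trim = TRUE,
                                       scientific = NA)))
  tryCatch(
    write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed writing ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  path
}

write_json_full <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

inventory <- function(paths) {
  tibble::tibble(file = paths,
                 md5 = unname(tools::md5sum(paths)))
}

#' @export
write_results.data.frame <- function(x, prefix) {
  inventory(write_csv_full(x, paste0(prefix, ".csv")))
}

#' @export
write_results.rescue_trajectory <- function(x, prefix) {
  inventory(write_csv_full(
    dplyr::select(tibble::as_tibble(x), t = "time", "S", "R", "u"),
    paste0(prefix, "_trajectory.csv")))
}

#' @export
write_results.cohort_result <- function(x, prefix) {
  inventory(c(
    write_csv_full(x$replicates, paste0(prefix, "_replicates.csv")),
    write_csv_full(x$summary, paste0(prefix, "_summary.csv")),
    write_json_full(list(params = unclass(x$params), seed = x$seed),
                    paste0(prefix, "_meta.json"))))
}

#' @export
write_results.dose_sweep <- function(x, prefix) {
  inventory(c(
    write_csv_full(x$cohort$replicates, paste0(prefix, "_replicates.csv")),
    write_csv_full(x$summary, paste0(prefix, "_summary.csv")),
    write_csv_full(x$establishment, paste0(prefix, "_establishment.csv")),
    write_json_full(list(params = unclass(x$params), seed = x$seed),
                    paste0(prefix, "_meta.json"))))
}

#' @export
write_results.control_solution <- function(x, prefix) {
  paths <- character(0)
  if (!is.null(x$schedule)) {
    paths <- write_csv_full(x$schedule, paste0(prefix, "_schedule.csv"))
  }
  paths <- c(paths, write_json_full(glance(x), paste0(prefix, "_summary.json")))
  inventory(paths)
}

#' @export
write_results.control_map <- function(x, prefix) {
  inventory(c(
    write_csv_full(tidy(x), paste0(prefix, "_map.csv")),
    write_json_full(list(objective = x$objective, V0 = x$V0,
                         dt = x$diagnostics$dt, n_t = x$diagnostics$n_t),
                    paste0(prefix, "_summary.json"))))
}

#' @export
write_results.contour_result <- function(x, prefix) {
  inventory(c(
    write_csv_full(x$grid, paste0(prefix, "_grid.csv")),
    write_csv_full(x$optimal, paste0(prefix, "_optimal.csv"))))
}

#' Build and write a run manifest
#'
#' Records everything needed to re-run an analysis bit-identically with the
#' same package version: the resolved parameters, command and arguments,
#' seeds, package version, timestamp, and the output file inventory with
#' checksums.
#'
#' @param command Name of the command or experiment.
#' @param p The resolved [rescue_params()].
#' @param args Named list of grids, seeds and options.
#' @param files Inventory tibble from [write_results()].
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, p, args, files, path) {
  write_json_full(list(
    command = command,
    params = unclass(p),
    args = args,
    files = files,
    version = as.character(utils::packageVersion("evorescue")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), path)
  invisible(path)
}
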