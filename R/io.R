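# CSV readers/writers for the two data shapes, plus JSON run configuration.
# Readers validate and reject malformed rows rather than coercing silently.

#' Read and write caliper measurement tables
#'
#' CSV with header `mouse_id,day,site,volume_mm3` (UTF-8, `.` decimal).
#' Reading validates the schema ([measurement_series()]); writing is the
#' exact inverse so `read_measurements(write_measurements(x))` is the
#' identity.
#'
#' @param path file path.
#' @param x a [measurement_series()] table.
#' @return the measurement table / invisibly the path.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "day", "site", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " is missing columns: ", paste(miss, collapse = ", "))
  for (cl in c("day", "volume_mm3")) {
    if (nrow(df) == 0) df[[cl]] <- numeric(0)
    if (!is.numeric(df[[cl]]))
      stop("column ", cl, " is not numeric in ", path)
  }
  if (nrow(df) == 0)
    for (cl in c("mouse_id", "site")) df[[cl]] <- character(0)
  measurement_series(df)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  x <- measurement_series(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write endpoint nodule tables
#'
#' CSV with header `mouse_id,nodule_id,area_mm2,volume_mm3,endpoint_day`.
#' A missing volume is derived from the area through the spherical formula
#' (and vice versa); a row with neither is rejected, as is an inconsistent
#' pair.
#'
#' @param path file path.
#' @param x a [nodule_table()].
#' @return the nodule table / invisibly the path.
#' @export
read_nodules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nodule_table(df)
}

#' @rdname read_nodules
#' @export
write_nodules <- function(x, path) {
  x <- nodule_table(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_schema <- list(
  model = c("two_tumor", "metastatic", "single"),
  fields = c("model", "law", "capacity_mode", "rate_mode", "pooling",
             "mask_group", "data", "nodules", "out", "seed", "swarm_size",
             "max_iterations", "restarts", "X0", "cells_per_mm3",
             "relevance_threshold_cells", "weights", "t_end", "surgery_day",
             "surgery_mode", "no_seeding", "params", "n_mice", "sigma",
             "preset"))

#' Load a run configuration
#'
#' JSON only (no YAML parser is available in this stack). Unknown keys are
#' rejected with their names; defaults are filled for the optimizer and unit
#' convention.
#'
#' @param path path to a JSON file.
#' @return named list of class `run_config` with defaults applied.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .config_schema$fields)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model) || !cfg$model %in% .config_schema$model)
    stop("config needs a `model` of: ",
         paste(.config_schema$model, collapse = ", "))
  defaults <- list(seed = 1L, swarm_size = 50L, max_iterations = 300L,
                   restarts = 3L, cells_per_mm3 = 1e6,
                   relevance_threshold_cells = 3500, law = "gompertz",
                   capacity_mode = "shared", rate_mode = "equal")
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

# write a fit result to JSON (parameters, objective, BIC, RSE, seed)
.write_fit_json <- function(fit, path) {
  out <- list(kind = fit$kind,
              variant = if (!is.null(fit$variant)) format(fit$variant),
              mask = if (!is.null(fit$mask)) fit$mask[c("group", "subject")],
              parameters = fit$parameters,
              group_parameters = as.list(fit$group_parameters),
              objective_value = fit$objective_value,
              n_observations = fit$n_observations,
              k_free_parameters = fit$k_free_parameters, bic = fit$bic,
              rse = fit$rse_percent, seed = fit$seed,
              converged = fit$converged,
              package_version = as.character(utils::packageVersion("sharedcap")))
  writeLines(jsonlite::toJSON(out, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}
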