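# Tidy containers for the two experimental data shapes: longitudinal caliper
# volumes and endpoint nodule tables.

#' Longitudinal caliper measurements
#'
#' Validates a tidy table of caliper measurements: one row per
#' (mouse, day, site) with the site one of `"T1"`, `"T2"` (two-tumor
#' experiments) or `"PT"` (single primary tumor).
#'
#' @param x data.frame with columns `mouse_id`, `day`, `site`, `volume_mm3`.
#' @return the validated data.frame with class `measurement_series`.
#' @export
measurement_series <- function(x) {
  need <- c("mouse_id", "day", "site", "volume_mm3")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$mouse_id <- as.character(x$mouse_id)
  x$site <- as.character(x$site)
  bad <- !x$site %in% c("T1", "T2", "PT")
  if (any(bad)) stop("invalid site in rows: ", paste(which(bad), collapse = ", "))
  bad <- !is.finite(x$volume_mm3) | x$volume_mm3 < 0
  if (any(bad)) stop("negative or non-finite volumes in rows: ",
                     paste(which(bad), collapse = ", "))
  key <- paste(x$mouse_id, x$day, x$site)
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, day, site) in rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  x <- x[order(x$mouse_id, x$day, x$site), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("measurement_series", "data.frame")
  x
}

#' Endpoint metastatic nodule table
#'
#' One row per nodule; at least one of `area_mm2` and `volume_mm3` must be
#' present, and when only the area is given the volume is derived through the
#' spherical formula ([area_to_volume()]). When both are present they must be
#' consistent to a relative tolerance of 1e-6.
#'
#' @param x data.frame with columns `mouse_id`, `nodule_id`, `area_mm2`,
#'   `volume_mm3`, `endpoint_day` (missing value columns allowed).
#' @return validated data.frame with class `nodule_table`.
#' @export
nodule_table <- function(x) {
  need <- c("mouse_id", "nodule_id", "area_mm2", "volume_mm3", "endpoint_day")
  x <- as.data.frame(x)
  for (cl in c("area_mm2", "volume_mm3"))
    if (is.null(x[[cl]])) x[[cl]] <- NA_real_
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- x[need]
  x$mouse_id <- as.character(x$mouse_id)
  x$nodule_id <- as.character(x$nodule_id)
  both_na <- is.na(x$area_mm2) & is.na(x$volume_mm3)
  if (any(both_na))
    stop("rows with neither area nor volume: ",
         paste(which(both_na), collapse = ", "))
  derive <- is.na(x$volume_mm3)
  x$volume_mm3[derive] <- area_to_volume(x$area_mm2[derive])
  derive_a <- is.na(x$area_mm2)
  x$area_mm2[derive_a] <- volume_to_area(x$volume_mm3[derive_a])
  both <- !derive & !derive_a
  if (any(both)) {
    rel <- abs(x$volume_mm3[both] - area_to_volume(x$area_mm2[both])) /
      pmax(x$volume_mm3[both], .Machine$double.eps)
    if (any(rel > 1e-6))
      stop("inconsistent area/volume pairs in rows: ",
           paste(which(both)[rel > 1e-6], collapse = ", "))
  }
  if (any(x$area_mm2 <= 0) || any(x$volume_mm3 <= 0))
    stop("areas and volumes must be positive")
  rownames(x) <- NULL
  class(x) <- c("nodule_table", "data.frame")
  x
}

# split a measurement_series into per-mouse lists with per-site day/volume
.split_mice <- function(data) {
  stopifnot(is.data.frame(data))
  lapply(split(data, data$mouse_id), function(d) {
    sites <- split(d, d$site)
    lapply(sites, function(s) s[order(s$day), c("day", "volume_mm3")])
  })
}
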