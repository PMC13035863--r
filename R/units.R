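#' Unit conventions for cell counts and volumes
#'
#' The metastasis model works internally in cells; experimental data are
#' volumes (mm^3) or H&E section areas (mm^2). A unit convention fixes the
#' cell density (default: 1 mm^3 corresponds to one million cells) and the
#' clinical relevance threshold below which a metastasis counts as a
#' micro-metastasis (default 3500 cells).
#'
#' @param cells_per_mm3 cell density used for all conversions, cells per mm^3.
#' @param relevance_threshold_cells clinical relevance threshold in cells.
#' @return an object of class `unit_convention`.
#' @export
unit_convention <- function(cells_per_mm3 = 1e6, relevance_threshold_cells = 3500) {
  if (!is.numeric(cells_per_mm3) || cells_per_mm3 <= 0)
    stop("`cells_per_mm3` must be a positive number")
  if (!is.numeric(relevance_threshold_cells) || relevance_threshold_cells <= 0)
    stop("`relevance_threshold_cells` must be a positive number")
  structure(list(cells_per_mm3 = cells_per_mm3,
                 relevance_threshold_cells = relevance_threshold_cells),
            class = "unit_convention")
}

#' Convert between cell counts, volumes and diameters
#'
#' `cells_to_volume()` and `volume_to_cells()` are exact inverses under the
#' convention's cell density. `diameter_from_cells()` gives the diameter of a
#' sphere with the corresponding volume.
#'
#' @param n cell count(s), non-negative.
#' @param v volume(s) in mm^3, non-negative.
#' @param units a [unit_convention()].
#' @return numeric vector (mm^3, cells, or mm respectively).
#' @examples
#' cells_to_volume(1e6)            # 1 mm^3
#' diameter_from_cells(3500)       # diameter of a 3500-cell sphere, mm
#' @export
cells_to_volume <- function(n, units = unit_convention()) {
  stopifnot(inherits(units, "unit_convention"))
  if (any(n < 0)) stop("cell counts must be non-negative")
  n / units$cells_per_mm3
}

#' @rdname cells_to_volume
#' @export
volume_to_cells <- function(v, units = unit_convention()) {
  stopifnot(inherits(units, "unit_convention"))
  if (any(v < 0)) stop("volumes must be non-negative")
  v * units$cells_per_mm3
}

#' @rdname cells_to_volume
#' @export
diameter_from_cells <- function(n, units = unit_convention()) {
  v <- cells_to_volume(n, units)
  2 * (3 * v / (4 * pi))^(1 / 3)
}

#' Convert between H&E section areas and spherical volumes
#'
#' Metastatic nodules are measured as 2-D areas on a section; assuming a
#' spherical nodule whose great circle has that area, the radius is
#' `r = sqrt(area / pi)` and the volume `4/3 * pi * r^3`. The two functions
#' are mutual inverses.
#'
#' @param area area(s) in mm^2, non-negative.
#' @param volume volume(s) in mm^3, non-negative.
#' @return numeric vector (mm^3 or mm^2).
#' @examples
#' area_to_volume(pi)    # unit radius -> 4*pi/3
#' volume_to_area(area_to_volume(1))
#' @export
area_to_volume <- function(area) {
  if (any(area < 0)) stop("areas must be non-negative")
  r <- sqrt(area / pi)
  4 / 3 * pi * r^3
}

#' @rdname area_to_volume
#' @export
volume_to_area <- function(volume) {
  if (any(volume < 0)) stop("volumes must be non-negative")
  r <- (3 * volume / (4 * pi))^(1 / 3)
  pi * r^2
}
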