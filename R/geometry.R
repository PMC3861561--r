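#' Calibrated microscope field geometry
#'
#' Describes the physical extent of one digital field (one x40 capture in
#' the reference protocol: 310.3 um x 232.72 um, i.e. 0.072213 mm^2).
#' Marker coordinates are validated against, and densities computed from,
#' this geometry.
#'
#' @param width_um field width in micrometres (> 0).
#' @param height_um field height in micrometres (> 0).
#' @param um_per_px optional micrometres per pixel; required to interpret
#'   or emit pixel-unit annotations.
#' @param objective_label optional free-text objective description
#'   (e.g. `"x40"`).
#' @return An object of class `field_geometry`.
#' @examples
#' field_geometry()                   # the default x40 field
#' field_geometry(1000, 1000)        # a 1 mm^2 field
#' @export
field_geometry <- function(width_um = 310.3, height_um = 232.72,
                           um_per_px = NULL, objective_label = NULL) {
  if (!is_scalar_number(width_um) || width_um <= 0 ||
      !is_scalar_number(height_um) || height_um <= 0) {
    abort_validation("Field dimensions `width_um` and `height_um` must be strictly positive.")
  }
  if (!is.null(um_per_px) && (!is_scalar_number(um_per_px) || um_per_px <= 0)) {
    abort_validation("`um_per_px` must be a strictly positive scale if supplied.")
  }
  structure(
    list(width_um = as.numeric(width_um), height_um = as.numeric(height_um),
         um_per_px = if (!is.null(um_per_px)) as.numeric(um_per_px),
         objective_label = objective_label),
    class = "field_geometry"
  )
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %.4g x %.4g um (%.6f mm^2)",
              x$width_um, x$height_um, field_area_mm2(x)))
  if (!is.null(x$um_per_px)) cat(sprintf(", %.4g um/px", x$um_per_px))
  if (!is.null(x$objective_label)) cat(", objective", x$objective_label)
  cat("\n")
  invisible(x)
}

as_field_geometry <- function(x) {
  if (inherits(x, "field_geometry")) return(x)
  if (is.list(x) && all(c("width_um", "height_um") %in% names(x))) {
    return(field_geometry(x$width_um, x$height_um,
                          um_per_px = x$um_per_px,
                          objective_label = x$objective_label))
  }
  abort_validation("Cannot interpret `geometry`: expected a field_geometry or a list with width_um and height_um.")
}

#' Field area in square millimetres
#'
#' Exact product conversion um^2 -> mm^2. The reference x40 field of
#' 310.3 um x 232.72 um gives 0.072213 mm^2.
#'
#' @param geometry a [field_geometry()].
#' @return Area in mm^2 (a single number).
#' @examples
#' field_area_mm2(field_geometry(310.3, 232.72))
#' @export
field_area_mm2 <- function(geometry = field_geometry()) {
  geometry <- as_field_geometry(geometry)
  geometry$width_um * geometry$height_um / 1e6
}

#' Nuclear density in nuclei per mm^2
#'
#' @param n_nuclei non-negative nucleus count(s).
#' @param area_mm2 field area in mm^2 (> 0), or a [field_geometry()].
#' @param rounded report as integer nuclei/mm^2 (the conventional table
#'   presentation)? Default `TRUE`; set `FALSE` for full precision.
#' @return Density in nuclei/mm^2, vectorised over `n_nuclei`.
#' @examples
#' nuclear_density(c(83, 151, 585), field_geometry())
#' @export
nuclear_density <- function(n_nuclei, area_mm2 = field_area_mm2(),
                            rounded = TRUE) {
  if (inherits(area_mm2, "field_geometry")) area_mm2 <- field_area_mm2(area_mm2)
  if (!is_scalar_number(area_mm2) || area_mm2 <= 0) {
    abort_validation("`area_mm2` must be a single strictly positive area.")
  }
  if (!is.numeric(n_nuclei) || any(!is.finite(n_nuclei)) || any(n_nuclei < 0)) {
    abort_validation("`n_nuclei` must be non-negative counts.")
  }
  d <- n_nuclei / area_mm2
  if (rounded) round(d) else d
}
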