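MARKER_LABELS <- c("positive", "negative")

#' A single annotated microscope field
#'
#' One field's worth of clicked nucleus markers plus the calibration
#' geometry they live in. Each marker is one human click on a tumor
#' nucleus, labelled positive (immunostained) or negative. Coordinates are
#' stored in micrometres with the origin at the field's top-left corner,
#' x rightward and y downward; markers exactly on the field border are
#' in-bounds (clicked nuclei may straddle edges).
#'
#' @param case_id,field_id identifiers (coerced to character).
#' @param markers a data frame with columns `x`, `y` (micrometres) and
#'   `label` (`"positive"` or `"negative"`). Row order is preserved: the
#'   click sequence is part of the record.
#' @param geometry a [field_geometry()].
#' @return An object of class `field_annotation`.
#' @examples
#' field_annotation("case1", "f1",
#'                  data.frame(x = c(10, 20), y = c(5, 5),
#'                             label = c("positive", "negative")))
#' @export
field_annotation <- function(case_id, field_id, markers,
                             geometry = field_geometry()) {
  geometry <- as_field_geometry(geometry)
  markers <- tibble::as_tibble(markers)
  if (nrow(markers) > 0) {
    res <- validate_marker_rows(markers, geometry)
    if (nrow(res$rejected) > 0) {
      bad <- res$rejected[1, ]
      abort_validation(sprintf(
        "Invalid marker in case '%s' field '%s' (row %d): %s",
        case_id, field_id, bad$row, bad$reason))
    }
    markers <- res$accepted
  } else {
    markers <- tibble::tibble(x = numeric(), y = numeric(),
                              label = character())
  }
  structure(
    list(case_id = as.character(case_id), field_id = as.character(field_id),
         geometry = geometry, markers = markers),
    class = "field_annotation"
  )
}

#' @export
print.field_annotation <- function(x, ...) {
  n_pos <- sum(x$markers$label == "positive")
  cat(sprintf("<field_annotation> case %s, field %s: %d markers (%d positive, %d negative)\n",
              x$case_id, x$field_id, nrow(x$markers), n_pos,
              nrow(x$markers) - n_pos))
  invisible(x)
}

#' Validate marker rows against a field geometry
#'
#' Splits marker rows into accepted and rejected sets. A row is rejected
#' iff its label is not `positive`/`negative`, a coordinate is missing or
#' non-finite, or it falls outside the closed interval
#' `[0, width] x [0, height]` in micrometres. Accepted + rejected always
#' partition the input.
#'
#' @param markers data frame with columns `x`, `y` (micrometres), `label`.
#' @param geometry a [field_geometry()].
#' @return A list with `accepted` (tibble of valid rows) and `rejected`
#'   (tibble with columns `row`, `reason`).
#' @export
validate_marker_rows <- function(markers, geometry = field_geometry()) {
  geometry <- as_field_geometry(geometry)
  markers <- tibble::as_tibble(markers)
  for (col in c("x", "y", "label")) {
    if (!col %in% names(markers)) {
      abort_validation(sprintf("Marker table is missing required column '%s'.", col))
    }
  }
  n <- nrow(markers)
  reason <- rep(NA_character_, n)
  lab <- as.character(markers$label)
  x <- suppressWarnings(as.numeric(markers$x))
  y <- suppressWarnings(as.numeric(markers$y))
  bad_lab <- !(lab %in% MARKER_LABELS)
  reason[bad_lab] <- sprintf("unknown label '%s' (expected 'positive' or 'negative')",
                             lab[bad_lab])
  bad_xy <- is.na(reason) & (!is.finite(x) | !is.finite(y))
  reason[bad_xy] <- "missing or non-numeric coordinate"
  oob <- is.na(reason) &
    (x < 0 | x > geometry$width_um | y < 0 | y > geometry$height_um)
  reason[oob] <- sprintf(
    "marker at (%.4g, %.4g) um outside field %.4g x %.4g um",
    x[oob], y[oob], geometry$width_um, geometry$height_um)
  keep <- is.na(reason)
  list(
    accepted = tibble::tibble(x = x[keep], y = y[keep], label = lab[keep]),
    rejected = tibble::tibble(row = which(!keep), reason = reason[!keep])
  )
}

#' Read a calibration sidecar
#'
#' Reads field calibration metadata (width_um, height_um, optional
#' um_per_px, objective_label) from a YAML or JSON sidecar file.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [field_geometry()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Calibration file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  if (!all(c("width_um", "height_um") %in% names(raw))) {
    abort_validation(sprintf(
      "Calibration file %s must define width_um and height_um.", path))
  }
  field_geometry(raw$width_um, raw$height_um,
                 um_per_px = raw$um_per_px,
                 objective_label = raw$objective_label)
}

resolve_geometry <- function(calibration) {
  if (is.null(calibration)) return(field_geometry())
  if (inherits(calibration, "field_geometry")) return(calibration)
  if (is.character(calibration) && length(calibration) == 1L) {
    return(read_calibration(calibration))
  }
  as_field_geometry(calibration)
}

to_um <- function(x, unit, geometry) {
  if (unit == "um") return(as.numeric(x))
  if (is.null(geometry$um_per_px)) {
    abort_validation("Markers are in pixels but the calibration has no `um_per_px` scale.")
  }
  as.numeric(x) * geometry$um_per_px
}

from_um <- function(x, unit, geometry) {
  if (unit == "um") return(x)
  if (is.null(geometry$um_per_px)) {
    abort_validation("Cannot emit pixel coordinates: calibration has no `um_per_px` scale.")
  }
  x / geometry$um_per_px
}

group_annotation_rows <- function(df, geometry) {
  key <- paste(df$case_id, df$field_id, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    field_annotation(rows$case_id[1], rows$field_id[1],
                     rows[, c("x", "y", "label")], geometry)
  })
  names(out) <- vapply(out, function(f) paste(f$case_id, f$field_id, sep = "/"),
                       character(1))
  out
}

#' Read per-field point annotations
#'
#' Reads clicked-nucleus annotations from CSV (columns `case_id`,
#' `field_id`, `x`, `y`, `label`) or GeoJSON (Point features with those
#' properties), validates every marker against the field geometry, and
#' groups markers by case and field with click order preserved.
#'
#' The coordinate unit is taken from, in order of precedence: the `unit`
#' argument; a `# unit: um` (or `px`) comment line at the top of the CSV /
#' a top-level `"unit"` member of the GeoJSON; else pixels. Pixel input
#' requires a calibration with `um_per_px`.
#'
#' @param path path to a `.csv` or `.geojson`/`.json` file.
#' @param unit `"px"` or `"um"`, overriding any unit declared in the file.
#' @param calibration a [field_geometry()], a calibration list, or a path
#'   to a YAML/JSON sidecar (see [read_calibration()]). Defaults to the
#'   reference x40 field. A calibration embedded in a GeoJSON file takes
#'   precedence over this default but not over an explicit argument.
#' @return A named list of [field_annotation()] objects
#'   (`"<case_id>/<field_id>"`), in first-appearance order.
#' @export
read_field_annotations <- function(path, unit = NULL, calibration = NULL) {
  if (!file.exists(path)) abort_io(sprintf("Annotation file not found: %s", path))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_annotations_geojson(path, unit, calibration)
  } else {
    read_annotations_csv(path, unit, calibration)
  }
}

read_annotations_csv <- function(path, unit, calibration) {
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  file_unit <- NULL
  m <- regmatches(head_lines, regexpr("^#\\s*unit:\\s*(px|um)\\s*$", head_lines))
  if (length(m) > 0) file_unit <- sub("^#\\s*unit:\\s*", "", trimws(m[[1]]))
  unit <- match.arg(unit %||% file_unit %||% "px", c("px", "um"))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("case_id", "field_id", "x", "y", "label")) {
    if (!col %in% names(df)) {
      abort_validation(sprintf(
        "Annotation CSV %s is missing required column '%s'.", path, col))
    }
  }
  geometry <- resolve_geometry(calibration)
  if (nrow(df) == 0) return(structure(list(), names = character()))
  df$x <- to_um(df$x, unit, geometry)
  df$y <- to_um(df$y, unit, geometry)
  group_annotation_rows(df, geometry)
}

read_annotations_geojson <- function(path, unit, calibration) {
  gj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort_validation(sprintf("%s is not a GeoJSON FeatureCollection.", path))
  }
  if (is.null(calibration) && !is.null(gj$calibration)) {
    calibration <- gj$calibration
  }
  geometry <- resolve_geometry(calibration)
  unit <- match.arg(unit %||% gj$unit %||% "px", c("px", "um"))
  feats <- gj$features
  if (is.null(feats) || NROW(feats) == 0) {
    return(structure(list(), names = character()))
  }
  types <- feats$geometry$type
  if (any(types != "Point")) {
    abort_validation("All GeoJSON features must have Point geometry.")
  }
  coords <- do.call(rbind, feats$geometry$coordinates)
  props <- feats$properties
  for (col in c("case_id", "field_id", "label")) {
    if (!col %in% names(props)) {
      abort_validation(sprintf(
        "GeoJSON features are missing required property '%s'.", col))
    }
  }
  df <- data.frame(case_id = as.character(props$case_id),
                   field_id = as.character(props$field_id),
                   x = to_um(coords[, 1], unit, geometry),
                   y = to_um(coords[, 2], unit, geometry),
                   label = as.character(props$label),
                   stringsAsFactors = FALSE)
  group_annotation_rows(df, geometry)
}

#' Write per-field point annotations
#'
#' Writes a collection of [field_annotation()]s to CSV or GeoJSON in a
#' form [read_field_annotations()] reads back to an equivalent structure
#' (marker counts, labels and coordinates preserved to formatting
#' precision).
#'
#' @param fields a [field_annotation()] or list of them.
#' @param path output path; format chosen by extension (`.csv` vs
#'   `.geojson`/`.json`).
#' @param unit coordinate unit to emit, `"um"` (default) or `"px"`
#'   (requires `um_per_px` in every field's calibration).
#' @return `path`, invisibly.
#' @export
write_field_annotations <- function(fields, path, unit = c("um", "px")) {
  unit <- match.arg(unit)
  if (inherits(fields, "field_annotation")) fields <- list(fields)
  ok <- vapply(fields, inherits, logical(1), "field_annotation")
  if (!all(ok)) abort_validation("`fields` must be field_annotation objects.")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort_io(sprintf("Cannot write to %s: directory does not exist.", path))
  rows <- lapply(fields, function(f) {
    m <- f$markers
    tibble::tibble(case_id = f$case_id, field_id = f$field_id,
                   x = from_um(m$x, unit, f$geometry),
                   y = from_um(m$y, unit, f$geometry),
                   label = m$label)
  })
  df <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    tibble::tibble(case_id = character(), field_id = character(),
                   x = numeric(), y = numeric(), label = character())
  }
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    geometry <- if (length(fields) > 0) fields[[1]]$geometry else field_geometry()
    features <- if (nrow(df) == 0) list() else lapply(seq_len(nrow(df)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$x[i], df$y[i])),
           properties = list(case_id = df$case_id[i],
                             field_id = df$field_id[i],
                             label = df$label[i]))
    })
    gj <- list(type = "FeatureCollection", unit = unit,
               calibration = list(width_um = geometry$width_um,
                                  height_um = geometry$height_um,
                                  um_per_px = geometry$um_per_px),
               features = features)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# unit: %s", unit), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Flag pairs of markers closer than a separation threshold
#'
#' Guards against double-clicked nuclei: returns every unordered marker
#' pair strictly closer than `min_separation_um`. Pairs are flagged, never
#' merged — the human click is ground truth in this protocol, so cleanup
#' is left to the annotator.
#'
#' @param field a [field_annotation()].
#' @param min_separation_um non-negative separation threshold in
#'   micrometres. With threshold 0 nothing can be strictly closer, so the
#'   result is empty.
#' @return A tibble with columns `i`, `j` (1-based marker indices, i < j)
#'   and `distance_um`.
#' @export
flag_near_duplicates <- function(field, min_separation_um) {
  if (!inherits(field, "field_annotation")) {
    abort_validation("`field` must be a field_annotation.")
  }
  if (!is_scalar_number(min_separation_um) || min_separation_um < 0) {
    abort_validation("`min_separation_um` must be a non-negative length.")
  }
  m <- field$markers
  empty <- tibble::tibble(i = integer(), j = integer(), distance_um = numeric())
  n <- nrow(m)
  if (n < 2 || min_separation_um == 0) return(empty)
  d <- as.matrix(stats::dist(cbind(m$x, m$y)))
  idx <- which(upper.tri(d) & d < min_separation_um, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ord <- order(idx[, 1], idx[, 2])
  tibble::tibble(i = as.integer(idx[ord, 1]), j = as.integer(idx[ord, 2]),
                 distance_um = d[idx[ord, , drop = FALSE]])
}
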