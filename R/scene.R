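# Domain types for one bitewing scene: frame, tooth detections with FDI
# numbers, caries detections with ICCMS severity (RA/RB/RC), polygon
# outline and derived box.

#' ICCMS radiographic severity classes
#'
#' The three severity stages used throughout the package, with their fixed
#' integer class IDs: RA (initial) = 0, RB (moderate) = 1, RC (extensive) = 2.
#'
#' @format A named integer vector.
#' @export
SEVERITY_CLASSES <- c(RA = 0L, RB = 1L, RC = 2L)

#' Map severity label to class ID and back
#'
#' @param label One of `"RA"`, `"RB"`, `"RC"`.
#' @param id Integer class ID 0, 1 or 2.
#' @return `severity_id()` returns the integer ID; `severity_label()` the label.
#' @export
severity_id <- function(label) {
  if (!all(label %in% names(SEVERITY_CLASSES))) {
    stop_format(sprintf("unknown severity label(s): %s",
                        paste(setdiff(label, names(SEVERITY_CLASSES)), collapse = ", ")))
  }
  unname(SEVERITY_CLASSES[label])
}

#' @rdname severity_id
#' @export
severity_label <- function(id) {
  m <- match(as.integer(id), SEVERITY_CLASSES)
  if (anyNA(m)) {
    stop_format(sprintf("unknown severity class id(s): %s",
                        paste(id[is.na(m)], collapse = ", ")))
  }
  names(SEVERITY_CLASSES)[m]
}

VALID_FDI <- as.integer(outer(1:8, c(10L, 20L, 30L, 40L), `+`))

#' Image frame of a bitewing radiograph
#'
#' @param width,height Positive integer pixel dimensions.
#' @param side Which side of the mouth the bitewing shows: `"left"`,
#'   `"right"` or `"unknown"`.
#' @return A list of class `"frame_spec"`.
#' @export
frame_spec <- function(width, height, side = "unknown") {
  if (!is_scalar_number(width) || !is_scalar_number(height) ||
      width <= 0 || height <= 0) {
    stop_invalid_geometry("frame width and height must be positive")
  }
  side <- match.arg(side, c("left", "right", "unknown"))
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 side = side),
            class = "frame_spec")
}

#' A tooth bounding box with its FDI number
#'
#' @param fdi FDI two-digit tooth number (permanent dentition: 11-18, 21-28,
#'   31-38, 41-48).
#' @param box The tooth's bounding box ([bbox()]).
#' @param confidence Detector score in `[0, 1]`.
#' @return A list of class `"tooth_detection"`.
#' @export
tooth_detection <- function(fdi, box, confidence = 1) {
  fdi <- as.integer(fdi)
  if (length(fdi) != 1L || !fdi %in% VALID_FDI) {
    stop_format(sprintf("invalid FDI tooth number: %s", fdi))
  }
  if (!is_scalar_number(confidence) || confidence < 0 || confidence > 1) {
    stop_format("tooth confidence must be in [0, 1]")
  }
  structure(list(fdi = fdi, box = as_bbox(box), confidence = as.numeric(confidence)),
            class = "tooth_detection")
}

#' A carious lesion detection
#'
#' The bounding box is derived from the polygon outline; if `box` is
#' supplied it must agree with the polygon's tight bounds within 1e-6 px.
#'
#' @param severity Severity label (`"RA"`, `"RB"`, `"RC"`).
#' @param polygon Lesion outline ([polygon_outline()]).
#' @param box Optional precomputed bounding box; checked against the polygon.
#' @param confidence Detector score in `[0, 1]`.
#' @return A list of class `"caries_detection"`.
#' @export
caries_detection <- function(severity, polygon, box = NULL, confidence = 1) {
  severity <- match.arg(severity, names(SEVERITY_CLASSES))
  polygon <- as_polygon(polygon)
  derived <- polygon_to_box(polygon)
  if (!is.null(box)) {
    box <- as_bbox(box)
    if (max(abs(unclass(box) - unclass(derived))) > 1e-6) {
      stop_invalid_geometry(
        "caries box does not match the polygon's bounding box (tolerance 1e-6 px)")
    }
  }
  if (!is_scalar_number(confidence) || confidence < 0 || confidence > 1) {
    stop_format("caries confidence must be in [0, 1]")
  }
  structure(list(severity = severity, polygon = polygon, box = derived,
                 confidence = as.numeric(confidence)),
            class = "caries_detection")
}

#' A bitewing scene: frame plus tooth and caries detections
#'
#' @param image_id Unique identifier (character).
#' @param frame A [frame_spec()].
#' @param teeth List of [tooth_detection()] objects.
#' @param caries List of [caries_detection()] objects.
#' @return A list of class `"scene"`. All boxes and polygon vertices must lie
#'   within the frame.
#' @export
scene <- function(image_id, frame, teeth = list(), caries = list()) {
  if (!inherits(frame, "frame_spec")) stop_format("frame must be a frame_spec")
  image_id <- as.character(image_id)
  if (length(image_id) != 1L || !nzchar(image_id)) {
    stop_format("image_id must be a non-empty string")
  }
  in_frame <- function(b) {
    b[["x_min"]] >= 0 && b[["y_min"]] >= 0 &&
      b[["x_max"]] <= frame$width && b[["y_max"]] <= frame$height
  }
  for (t in teeth) {
    if (!inherits(t, "tooth_detection")) stop_format("teeth must be tooth_detection objects")
    if (!in_frame(t$box)) {
      stop_invalid_geometry(sprintf("tooth %d box lies outside the frame", t$fdi))
    }
  }
  for (cd in caries) {
    if (!inherits(cd, "caries_detection")) stop_format("caries must be caries_detection objects")
    if (!in_frame(cd$box)) {
      stop_invalid_geometry("caries polygon lies outside the frame")
    }
  }
  structure(list(image_id = image_id, frame = frame, teeth = teeth,
                 caries = caries),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s> %gx%g side=%s | %d teeth, %d caries\n",
              x$image_id, x$frame$width, x$frame$height, x$frame$side,
              length(x$teeth), length(x$caries)))
  invisible(x)
}

flip_box <- function(b, extent, axis) {
  if (axis == "horizontal") {
    bbox(extent - b[["x_max"]], b[["y_min"]], extent - b[["x_min"]], b[["y_max"]])
  } else {
    bbox(b[["x_min"]], extent - b[["y_max"]], b[["x_max"]], extent - b[["y_min"]])
  }
}

#' Mirror a scene horizontally or vertically
#'
#' Maps every x (horizontal) or y (vertical) coordinate `c` to `extent - c`.
#' A horizontal flip toggles the frame side left/right (the mirrored image
#' shows the opposite laterality); a vertical flip leaves it unchanged.
#' Severity labels, FDI numbers and confidences are untouched.
#'
#' @param s A [scene()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return The mirrored scene.
#' @export
flip_scene <- function(s, axis = c("horizontal", "vertical")) {
  if (!inherits(s, "scene")) stop_format("s must be a scene")
  axis <- match.arg(axis)
  extent <- if (axis == "horizontal") s$frame$width else s$frame$height
  new_side <- s$frame$side
  if (axis == "horizontal" && new_side != "unknown") {
    new_side <- if (new_side == "left") "right" else "left"
  }
  teeth <- lapply(s$teeth, function(t) {
    tooth_detection(t$fdi, flip_box(t$box, extent, axis), t$confidence)
  })
  caries <- lapply(s$caries, function(cd) {
    v <- unclass(cd$polygon)
    if (axis == "horizontal") v[, 1L] <- extent - v[, 1L] else v[, 2L] <- extent - v[, 2L]
    caries_detection(cd$severity, polygon_outline(v), confidence = cd$confidence)
  })
  scene(s$image_id, frame_spec(s$frame$width, s$frame$height, new_side),
        teeth = teeth, caries = caries)
}
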