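# Planar geometry on image coordinates: origin top-left, x rightward,
# y downward, continuous pixel units. Boxes are stored corner-form
# (x_min, y_min, x_max, y_max); center-form appears only at YOLO I/O.

#' Construct an axis-aligned bounding box
#'
#' Boxes are closed real intervals in image coordinates (origin top-left,
#' x rightward, y downward), stored as corners `(x_min, y_min, x_max, y_max)`.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates in pixels; `x_min < x_max`
#'   and `y_min < y_max` are required (zero-area boxes are rejected).
#' @return A named numeric vector of class `"bbox"`.
#' @examples
#' bbox(0, 0, 10, 10)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (anyNA(b) || any(!is.finite(b))) {
    stop_invalid_geometry("box coordinates must be finite numbers")
  }
  if (b[["x_min"]] >= b[["x_max"]] || b[["y_min"]] >= b[["y_max"]]) {
    stop_invalid_geometry(sprintf(
      "degenerate box: need x_min < x_max and y_min < y_max, got (%g, %g, %g, %g)",
      b[["x_min"]], b[["y_min"]], b[["x_max"]], b[["y_max"]]))
  }
  structure(b, class = "bbox")
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  if (is.numeric(b) && length(b) == 4L) {
    return(bbox(b[[1L]], b[[2L]], b[[3L]], b[[4L]]))
  }
  stop_invalid_geometry("expected a bbox or a length-4 numeric (x_min, y_min, x_max, y_max)")
}

#' Box area in square pixels
#' @param b A [bbox()].
#' @return Positive area in px^2.
#' @export
box_area <- function(b) {
  b <- as_bbox(b)
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' Intersection area of two boxes
#'
#' @param a,b Boxes ([bbox()] or length-4 numerics).
#' @return Non-negative overlap area in px^2; 0 when disjoint; when one box
#'   contains the other, the area of the smaller box.
#' @export
intersection_area <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes ([bbox()] or length-4 numerics).
#' @return Symmetric overlap ratio in `[0, 1]`.
#' @examples
#' box_iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Construct a polygon outline
#'
#' Polygons are ordered vertex lists in pixel coordinates, implicitly closed
#' (the last vertex connects back to the first). At least three vertices and
#' nonzero shoelace area are required.
#'
#' @param vertices A numeric matrix with one `(x, y)` row per vertex, or a
#'   flat numeric vector `x1, y1, x2, y2, ...`.
#' @return A numeric matrix of class `"caries_polygon"` with columns `x`, `y`.
#' @export
polygon_outline <- function(vertices) {
  if (is.numeric(vertices) && is.null(dim(vertices))) {
    if (length(vertices) %% 2L != 0L) {
      stop_invalid_geometry("flat vertex vector must have even length")
    }
    vertices <- matrix(vertices, ncol = 2L, byrow = TRUE)
  }
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop_invalid_geometry("polygon vertices must be (x, y) pairs")
  if (nrow(vertices) < 3L) stop_invalid_geometry("polygon needs at least 3 vertices")
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop_invalid_geometry("polygon vertices must be finite")
  }
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (shoelace_area(vertices) == 0) {
    stop_invalid_geometry("polygon has zero area (degenerate outline)")
  }
  structure(vertices, class = c("caries_polygon", "matrix", "array"))
}

as_polygon <- function(p) {
  if (inherits(p, "caries_polygon")) return(p)
  polygon_outline(p)
}

shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param p A polygon ([polygon_outline()]).
#' @return Absolute area in px^2, independent of vertex orientation.
#' @export
polygon_area <- function(p) {
  shoelace_area(as_polygon(p))
}

#' Tight axis-aligned bounding box of a polygon
#'
#' @param p A polygon.
#' @return A [bbox()] covering all vertices.
#' @export
polygon_to_box <- function(p) {
  p <- as_polygon(p)
  bbox(min(p[, "x"]), min(p[, "y"]), max(p[, "x"]), max(p[, "y"]))
}

# Winding number of point grid (px, py vectors of equal length) w.r.t.
# polygon v; nonzero winding => inside. Vectorised over points.
winding_number <- function(px, py, v) {
  wn <- integer(length(px))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1L]; y1 <- v[i, 2L]
    x2 <- v[j, 1L]; y2 <- v[j, 2L]
    # cross > 0: point left of edge (in y-down coords this flips sign, but
    # only consistency matters for the nonzero rule)
    cross <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- (y1 <= py) & (y2 > py) & (cross > 0)
    down <- (y2 <= py) & (y1 > py) & (cross < 0)
    wn <- wn + up - down
  }
  wn
}

# Rasterize a polygon on the pixel grid of `frame`: pixel (i, j) (0-based
# column i, row j) belongs to the mask iff its center (i + 0.5, j + 0.5)
# lies inside the polygon under the nonzero winding rule. Returns an
# integer matrix of pixel indices (col i, row j), restricted to the
# polygon's bounding box clipped to the frame.
rasterize_polygon <- function(p, frame) {
  p <- as_polygon(p)
  b <- polygon_to_box(p)
  i0 <- max(0L, floor(b[["x_min"]] - 0.5))
  i1 <- min(frame$width - 1L, ceiling(b[["x_max"]]))
  j0 <- max(0L, floor(b[["y_min"]] - 0.5))
  j1 <- min(frame$height - 1L, ceiling(b[["y_max"]]))
  if (i1 < i0 || j1 < j0) return(matrix(integer(0), ncol = 2L))
  is <- seq.int(i0, i1); js <- seq.int(j0, j1)
  grid <- expand.grid(i = is, j = js)
  inside <- winding_number(grid$i + 0.5, grid$j + 0.5, p) != 0L
  as.matrix(grid[inside, , drop = FALSE])
}

#' Mask IoU of two polygons on a pixel grid
#'
#' Both polygons are rasterized on the frame's pixel grid (a pixel belongs
#' to a mask iff its center lies inside the polygon, nonzero winding rule)
#' and the IoU of the two binary masks is returned.
#'
#' @param p,q Polygons ([polygon_outline()]).
#' @param frame A [frame_spec()] giving the raster extent.
#' @return Symmetric ratio in `[0, 1]`.
#' @export
mask_iou <- function(p, q, frame) {
  rp <- rasterize_polygon(p, frame)
  rq <- rasterize_polygon(q, frame)
  if (nrow(rp) == 0L && nrow(rq) == 0L) {
    stop_invalid_geometry("both masks rasterize to zero pixels; IoU undefined")
  }
  if (nrow(rp) == 0L || nrow(rq) == 0L) return(0)
  kp <- rp[, 1L] * frame$height + rp[, 2L]
  kq <- rq[, 1L] * frame$height + rq[, 2L]
  inter <- length(intersect(kp, kq))
  inter / (length(kp) + length(kq) - inter)
}
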