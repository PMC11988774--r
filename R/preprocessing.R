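# Image enhancement and geometry-preserving dataset transforms. Images are
# plain R matrices (rows = y, columns = x) of 8-bit gray values 0..255, the
# orientation png::readPNG returns; EBImage does the heavy lifting behind
# this surface.

#' Preprocessing configuration
#'
#' @param clip_limit CLAHE contrast clip factor (> 0). Default 1.4.
#' @param tile_grid Integer `(rows, cols)` CLAHE tile grid. Default `(8, 8)`.
#' @param target_size Integer `(width, height)` resize target in px.
#'   Default `(1024, 768)`, the working scale for 3300x2550 bitewings.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(clip_limit = 1.4, tile_grid = c(8L, 8L),
                              target_size = c(1024L, 768L)) {
  if (!is_scalar_number(clip_limit) || clip_limit <= 0) {
    stop_usage("clip_limit must be a positive number")
  }
  if (length(tile_grid) != 2L || any(tile_grid < 1)) {
    stop_usage("tile_grid must be two integers >= 1")
  }
  if (length(target_size) != 2L || any(target_size < 1)) {
    stop_usage("target_size must be two positive integers")
  }
  structure(list(clip_limit = clip_limit,
                 tile_grid = as.integer(tile_grid),
                 target_size = as.integer(target_size)),
            class = "preprocess_config")
}

assert_gray8 <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_usage("image must be a single-channel numeric matrix (rows = y)")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop_usage("image values must lie in [0, 255]")
  }
  invisible(image)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipped-histogram redistribution
#' and bilinear inter-tile interpolation, the standard enhancement for
#' low-contrast radiographs. Deterministic; preserves shape and the 8-bit
#' value range.
#'
#' @param image Single-channel matrix of gray values in `[0, 255]`
#'   (rows = y, columns = x).
#' @param cfg A [preprocess_config()].
#' @return Matrix of the same dimensions, integer gray values in `[0, 255]`.
#' @export
clahe_enhance <- function(image, cfg = preprocess_config()) {
  if (length(dim(image)) > 2L) stop_usage("clahe_enhance expects a single-channel image")
  assert_gray8(image)
  img <- EBImage::Image(t(image) / 255)          # EBImage is (x, y)
  out <- EBImage::clahe(img, nx = cfg$tile_grid[2L], ny = cfg$tile_grid[1L],
                        limit = cfg$clip_limit)
  res <- t(EBImage::imageData(out)) * 255
  res <- pmin(pmax(round(res), 0), 255)
  storage.mode(res) <- "integer"
  res
}

scale_box <- function(b, sx, sy) {
  bbox(b[["x_min"]] * sx, b[["y_min"]] * sy, b[["x_max"]] * sx, b[["y_max"]] * sy)
}

#' Rescale a scene's coordinates to a new frame size
#'
#' Every x coordinate is scaled by `target_w / orig_w` and every y by
#' `target_h / orig_h`; the two axes scale independently (no letterboxing),
#' matching a plain 3300x2550 to 1024x768 resize.
#'
#' @param s A [scene()].
#' @param target_size Integer `(width, height)`.
#' @return The rescaled scene.
#' @export
scale_scene <- function(s, target_size) {
  sx <- target_size[1L] / s$frame$width
  sy <- target_size[2L] / s$frame$height
  teeth <- lapply(s$teeth, function(t) {
    tooth_detection(t$fdi, scale_box(t$box, sx, sy), t$confidence)
  })
  caries <- lapply(s$caries, function(cd) {
    v <- unclass(cd$polygon)
    v[, 1L] <- v[, 1L] * sx; v[, 2L] <- v[, 2L] * sy
    caries_detection(cd$severity, polygon_outline(v), confidence = cd$confidence)
  })
  scene(s$image_id, frame_spec(target_size[1L], target_size[2L], s$frame$side),
        teeth = teeth, caries = caries)
}

#' Resize an image together with its scene annotations
#'
#' The raster is resampled bilinearly to `cfg$target_size`; annotation
#' coordinates are scaled per axis via [scale_scene()].
#'
#' @param image Gray matrix as in [clahe_enhance()], or `NULL` to transform
#'   coordinates only.
#' @param s The matching [scene()] (frame must equal the image dimensions).
#' @param cfg A [preprocess_config()].
#' @return A list with elements `image` and `scene`.
#' @export
resize_scene <- function(image, s, cfg = preprocess_config()) {
  if (!is.null(image)) {
    assert_gray8(image)
    if (nrow(image) != s$frame$height || ncol(image) != s$frame$width) {
      stop_usage("image dimensions do not match the scene frame")
    }
    img <- EBImage::Image(t(image) / 255)
    out <- EBImage::resize(img, w = cfg$target_size[1L], h = cfg$target_size[2L])
    image <- pmin(pmax(round(t(EBImage::imageData(out)) * 255), 0), 255)
    storage.mode(image) <- "integer"
  }
  list(image = image, scene = scale_scene(s, cfg$target_size))
}

#' Expand a dataset with horizontal and vertical flips
#'
#' Each selected scene is emitted three times: original, horizontal flip
#' (`<id>__hflip`) and vertical flip (`<id>__vflip`), with split tags
#' preserved. The test split is never augmented, so held-out evaluation
#' images stay untouched.
#'
#' @param set An [annotation_set()].
#' @param splits Split tags eligible for augmentation.
#' @return The augmented [annotation_set()].
#' @export
augment_flips <- function(set, splits = c("train", "val", "unsplit")) {
  splits <- setdiff(splits, "test")
  scenes <- list(); tags <- character(0)
  for (k in seq_along(set$scenes)) {
    s <- set$scenes[[k]]; tag <- set$splits[[k]]
    scenes <- c(scenes, list(s)); tags <- c(tags, tag)
    if (tag %in% splits) {
      h <- flip_scene(s, "horizontal"); h$image_id <- paste0(s$image_id, "__hflip")
      v <- flip_scene(s, "vertical"); v$image_id <- paste0(s$image_id, "__vflip")
      scenes <- c(scenes, list(h, v)); tags <- c(tags, tag, tag)
    }
  }
  annotation_set(scenes, tags)
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers over the png package that convert between files and the
#' `[0, 255]` gray matrices used by [clahe_enhance()].
#'
#' @param path PNG file path.
#' @param image Gray matrix in `[0, 255]`.
#' @return `read_gray_png()` returns the matrix; `write_gray_png()` the
#'   path, invisibly.
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  res <- round(arr * 255)
  storage.mode(res) <- "integer"
  res
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(image, path) {
  assert_gray8(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
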