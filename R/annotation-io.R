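# Annotation interchange: COCO JSON, YOLO-segmentation and YOLO-detection
# text dialects, dataset splits and per-class counts. Tooth detections
# travel in a separate sidecar TSV because the tooth-numbering model is an
# external component; COCO files carry caries annotations only.

#' A set of annotated scenes with split tags
#'
#' @param scenes List of [scene()] objects with unique image ids.
#' @param splits Character vector (one per scene) of split tags:
#'   `"train"`, `"val"`, `"test"` or `"unsplit"`.
#' @return A list of class `"annotation_set"`.
#' @export
annotation_set <- function(scenes, splits = rep("unsplit", length(scenes))) {
  ids <- vapply(scenes, function(s) s$image_id, character(1))
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate image ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  splits <- as.character(splits)
  if (length(splits) != length(scenes)) {
    stop_format("splits must have one tag per scene")
  }
  bad <- setdiff(unique(splits), c("train", "val", "test", "unsplit"))
  if (length(bad)) stop_format(sprintf("unknown split tag(s): %s", paste(bad, collapse = ", ")))
  names(scenes) <- ids
  names(splits) <- ids
  structure(list(scenes = scenes, splits = splits), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d scenes (%s)\n", length(x$scenes),
              paste(sprintf("%s=%d", names(table(x$splits)), table(x$splits)),
                    collapse = ", ")))
  invisible(x)
}

set_image_ids <- function(set) names(set$scenes)

coco_category_table <- function() {
  data.frame(id = seq_along(SEVERITY_CLASSES),
             name = names(SEVERITY_CLASSES),
             class_id = unname(SEVERITY_CLASSES))
}

#' Write an annotation set as a COCO JSON file
#'
#' Emits `images` (with frame dimensions plus `side` and `split` extension
#' fields), `annotations` (polygon segmentation, corner-derived `bbox` in
#' COCO `[x, y, w, h]` form, `score` when confidences are informative) and
#' `categories` (RA/RB/RC).
#'
#' @param set An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(set, path) {
  cats <- coco_category_table()
  images <- list(); annotations <- list()
  ann_id <- 0L
  for (k in seq_along(set$scenes)) {
    s <- set$scenes[[k]]
    images[[k]] <- list(id = k, file_name = paste0(s$image_id, ".png"),
                        width = s$frame$width, height = s$frame$height,
                        side = s$frame$side, split = unname(set$splits[[k]]))
    for (cd in s$caries) {
      ann_id <- ann_id + 1L
      b <- cd$box
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = k,
        category_id = cats$id[match(cd$severity, cats$name)],
        segmentation = list(as.numeric(t(unclass(cd$polygon)))),
        bbox = c(b[["x_min"]], b[["y_min"]],
                 b[["x_max"]] - b[["x_min"]], b[["y_max"]] - b[["y_min"]]),
        area = polygon_area(cd$polygon),
        score = cd$confidence, iscrowd = 0L)
    }
  }
  obj <- list(images = images, annotations = annotations,
              categories = lapply(seq_len(nrow(cats)), function(i) {
                list(id = cats$id[i], name = cats$name[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO annotation file into an annotation set
#'
#' One scene is built per `images` entry; every annotation becomes a
#' [caries_detection()] whose bounding box is recomputed from the polygon
#' (the file's own `bbox` field is ignored). Category names must map onto
#' RA/RB/RC.
#'
#' @param path Path to a COCO-structured JSON file.
#' @return An [annotation_set()] (scenes carry no teeth; see
#'   [read_tooth_table()]).
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("COCO file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (fld in c("images", "annotations", "categories")) {
    if (is.null(obj[[fld]])) stop_format(sprintf("COCO file lacks '%s'", fld))
  }
  cat_name <- vapply(obj$categories, function(ct) as.character(ct$name), character(1))
  names(cat_name) <- vapply(obj$categories, function(ct) as.character(ct$id), character(1))
  unknown <- setdiff(cat_name, names(SEVERITY_CLASSES))
  if (length(unknown)) {
    stop_format(sprintf("unknown categories: %s", paste(unknown, collapse = ", ")))
  }
  img_key <- vapply(obj$images, function(im) as.character(im$id), character(1))
  caries_by_img <- setNames(vector("list", length(obj$images)), img_key)
  for (an in obj$annotations) {
    key <- as.character(an$image_id)
    if (!key %in% img_key) {
      stop_format(sprintf("annotation %s references missing image id %s",
                          an$id, an$image_id))
    }
    cid <- as.character(an$category_id)
    if (!cid %in% names(cat_name)) {
      stop_format(sprintf("annotation %s has unknown category id %s", an$id, cid))
    }
    seg <- an$segmentation
    if (is.list(seg)) seg <- seg[[1L]]
    cd <- caries_detection(cat_name[[cid]], polygon_outline(as.numeric(seg)),
                           confidence = if (is.null(an$score)) 1 else an$score)
    caries_by_img[[key]] <- c(caries_by_img[[key]], list(cd))
  }
  scenes <- vector("list", length(obj$images))
  splits <- character(length(obj$images))
  for (k in seq_along(obj$images)) {
    im <- obj$images[[k]]
    image_id <- tools::file_path_sans_ext(as.character(im$file_name))
    side <- if (is.null(im$side)) "unknown" else im$side
    splits[k] <- if (is.null(im$split)) "unsplit" else im$split
    scenes[[k]] <- scene(image_id,
                         frame_spec(im$width, im$height, side),
                         caries = caries_by_img[[as.character(im$id)]] %||% list())
  }
  annotation_set(scenes, splits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt6 <- function(x) sprintf("%.6f", x)

check_in_frame_norm <- function(xs, ys, frame, image_id) {
  if (any(xs < 0 | xs > frame$width) || any(ys < 0 | ys > frame$height)) {
    stop_format(sprintf(
      "image %s: coordinates outside the frame; refusing to clip", image_id))
  }
}

#' Write YOLO-segmentation label files
#'
#' One text file per image, named `<image_id>.txt`: each lesion is a line
#' `class_id x1 y1 x2 y2 ...` with coordinates normalized to `[0, 1]` by the
#' frame width/height, six decimal places, space-separated. Images without
#' lesions yield an empty file. Out-of-frame vertices are an error, never
#' clipped.
#'
#' @param set An [annotation_set()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_yolo_seg <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in set$scenes) {
    lines <- vapply(s$caries, function(cd) {
      v <- unclass(cd$polygon)
      check_in_frame_norm(v[, 1L], v[, 2L], s$frame, s$image_id)
      coords <- as.numeric(t(cbind(v[, 1L] / s$frame$width, v[, 2L] / s$frame$height)))
      paste(c(severity_id(cd$severity), fmt6(coords)), collapse = " ")
    }, character(1))
    writeLines(lines, file.path(dir, paste0(s$image_id, ".txt")))
  }
  invisible(dir)
}

#' Write YOLO-detection label files
#'
#' Same dialect as [write_yolo_seg()] but each line is
#' `class_id x_center y_center width height` (normalized center form).
#'
#' @inheritParams write_yolo_seg
#' @return The directory path, invisibly.
#' @export
write_yolo_det <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in set$scenes) {
    lines <- vapply(s$caries, function(cd) {
      b <- cd$box
      check_in_frame_norm(c(b[["x_min"]], b[["x_max"]]),
                          c(b[["y_min"]], b[["y_max"]]), s$frame, s$image_id)
      w <- s$frame$width; h <- s$frame$height
      vals <- c((b[["x_min"]] + b[["x_max"]]) / 2 / w,
                (b[["y_min"]] + b[["y_max"]]) / 2 / h,
                (b[["x_max"]] - b[["x_min"]]) / w,
                (b[["y_max"]] - b[["y_min"]]) / h)
      paste(c(severity_id(cd$severity), fmt6(vals)), collapse = " ")
    }, character(1))
    writeLines(lines, file.path(dir, paste0(s$image_id, ".txt")))
  }
  invisible(dir)
}

#' Read YOLO-segmentation label files back into an annotation set
#'
#' Inverse of [write_yolo_seg()] up to the 6-decimal normalization rounding.
#'
#' @param dir Directory of `<image_id>.txt` label files.
#' @param frames Frame lookup: a named list of [frame_spec()] keyed by
#'   image id, or a data frame with columns `image_id`, `width`, `height`
#'   and optionally `side`.
#' @return An [annotation_set()].
#' @export
read_yolo_seg <- function(dir, frames) {
  if (is.data.frame(frames)) {
    fr <- lapply(seq_len(nrow(frames)), function(i) {
      frame_spec(frames$width[i], frames$height[i],
                 if ("side" %in% names(frames)) frames$side[i] else "unknown")
    })
    names(fr) <- frames$image_id
    frames <- fr
  }
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  scenes <- vector("list", length(files))
  for (k in seq_along(files)) {
    image_id <- tools::file_path_sans_ext(basename(files[k]))
    fr <- frames[[image_id]]
    if (is.null(fr)) stop_format(sprintf("no frame registered for image %s", image_id))
    lines <- readLines(files[k])
    lines <- lines[nzchar(trimws(lines))]
    caries <- vector("list", length(lines))
    for (li in seq_along(lines)) {
      tok <- as.numeric(strsplit(trimws(lines[li]), "\\s+")[[1L]])
      if (anyNA(tok)) {
        stop_format(sprintf("%s line %d: non-numeric token", basename(files[k]), li))
      }
      coords <- tok[-1L]
      if (length(coords) %% 2L != 0L || length(coords) < 6L) {
        stop_format(sprintf("%s line %d: odd or short coordinate list",
                            basename(files[k]), li))
      }
      v <- matrix(coords, ncol = 2L, byrow = TRUE)
      v[, 1L] <- v[, 1L] * fr$width
      v[, 2L] <- v[, 2L] * fr$height
      caries[[li]] <- caries_detection(severity_label(tok[1L]), polygon_outline(v))
    }
    scenes[[k]] <- scene(image_id, fr, caries = caries)
  }
  annotation_set(scenes)
}

#' Split a dataset into train/val/test by deterministic shuffle
#'
#' Scenes are shuffled under `seed`; validation and test sizes are
#' `floor(n * ratio)` and the remainder goes to training (so 1354 scenes at
#' 80/10/10 give 1084/135/135).
#'
#' @param set An [annotation_set()].
#' @param ratios Numeric `(train, val, test)` summing to 1.
#' @param seed Integer RNG seed.
#' @return The set with split tags assigned.
#' @export
split_dataset <- function(set, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
    stop_usage("ratios must be three numbers summing to 1")
  }
  n <- length(set$scenes)
  if (n < sum(ratios > 0)) stop_usage("fewer scenes than nonzero splits")
  n_val <- floor(n * ratios[2L]); n_test <- floor(n * ratios[3L])
  perm <- with_seed(seed, sample.int(n))
  tags <- rep("train", n)
  tags[perm[seq_len(n_val)]] <- "val"
  if (n_test > 0) tags[perm[n_val + seq_len(n_test)]] <- "test"
  annotation_set(set$scenes, tags)
}

#' Per-split image and lesion class counts
#'
#' @param set An [annotation_set()].
#' @return A data frame with one row per split present plus a `total` row;
#'   columns `split`, `images`, `RA`, `RB`, `RC`, `total` (= RA+RB+RC).
#' @export
class_counts <- function(set) {
  splits_present <- intersect(c("train", "val", "test", "unsplit"),
                              unique(set$splits))
  if (!length(splits_present)) splits_present <- character(0)
  row_for <- function(ids) {
    sev <- unlist(lapply(set$scenes[ids], function(s) {
      vapply(s$caries, function(cd) cd$severity, character(1))
    }))
    counts <- vapply(names(SEVERITY_CLASSES), function(lb) sum(sev == lb), integer(1))
    c(images = length(ids), counts, total = sum(counts))
  }
  rows <- lapply(splits_present, function(sp) row_for(which(set$splits == sp)))
  tab <- as.data.frame(do.call(rbind, c(rows, list(row_for(seq_along(set$scenes))))))
  tab <- cbind(split = c(splits_present, "total"), tab)
  rownames(tab) <- NULL
  tab
}

#' Write / read the sidecar tooth-detection table
#'
#' Tooth boxes come from an external tooth-numbering model and are
#' interchanged as a TSV with columns `image_id`, `fdi`, `x_min`, `y_min`,
#' `x_max`, `y_max`, `confidence`.
#'
#' @param set An [annotation_set()] whose scenes carry teeth.
#' @param path TSV file path.
#' @return `write_tooth_table()` returns `path` invisibly;
#'   `read_tooth_table()` the data frame; `attach_teeth()` the set with
#'   teeth filled in from the table.
#' @export
write_tooth_table <- function(set, path) {
  rows <- do.call(rbind, lapply(set$scenes, function(s) {
    if (!length(s$teeth)) return(NULL)
    do.call(rbind, lapply(s$teeth, function(t) {
      data.frame(image_id = s$image_id, fdi = t$fdi,
                 x_min = t$box[["x_min"]], y_min = t$box[["y_min"]],
                 x_max = t$box[["x_max"]], y_max = t$box[["y_max"]],
                 confidence = t$confidence)
    }))
  }))
  if (is.null(rows)) {
    rows <- data.frame(image_id = character(0), fdi = integer(0),
                       x_min = numeric(0), y_min = numeric(0),
                       x_max = numeric(0), y_max = numeric(0),
                       confidence = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tooth_table
#' @export
read_tooth_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("tooth table not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_tooth_table
#' @param table A data frame as returned by [read_tooth_table()].
#' @export
attach_teeth <- function(set, table) {
  scenes <- lapply(set$scenes, function(s) {
    rows <- table[table$image_id == s$image_id, , drop = FALSE]
    teeth <- lapply(seq_len(nrow(rows)), function(i) {
      tooth_detection(rows$fdi[i],
                      bbox(rows$x_min[i], rows$y_min[i], rows$x_max[i], rows$y_max[i]),
                      rows$confidence[i])
    })
    scene(s$image_id, s$frame, teeth = teeth, caries = s$caries)
  })
  annotation_set(unname(scenes), unname(set$splits))
}

#' Write / read a dataset manifest (YAML)
#'
#' The manifest lists every image with its frame dimensions, bitewing side
#' and split tag, plus the companion annotation files, and is the entry
#' point consumed by the command-line interface.
#'
#' @param set An [annotation_set()].
#' @param path Manifest file path.
#' @param files Optional named list of companion file paths (e.g.
#'   `coco`, `teeth`, `truth`, `image_dir`), stored verbatim.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   a list with elements `images` (data frame) and `files`.
#' @export
write_manifest <- function(set, path, files = list()) {
  images <- lapply(seq_along(set$scenes), function(k) {
    s <- set$scenes[[k]]
    list(image_id = s$image_id, width = s$frame$width, height = s$frame$height,
         side = s$frame$side, split = unname(set$splits[[k]]))
  })
  yaml::write_yaml(list(images = images, files = files), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("manifest not found: %s", path))
  obj <- yaml::read_yaml(path)
  images <- do.call(rbind, lapply(obj$images, function(im) {
    data.frame(image_id = as.character(im$image_id), width = im$width,
               height = im$height, side = im$side %||% "unknown",
               split = im$split %||% "unsplit", stringsAsFactors = FALSE)
  }))
  list(images = images, files = obj$files %||% list())
}
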