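# Synthetic bitewing scenes: two rows of axis-aligned tooth boxes with
# FDI numbering for the chosen side, proximal gaps, and lesions placed
# straddling proximal surfaces so that all three assignment scenarios
# occur. Ground-truth tooth and surface are recorded at placement time.
# A perturbation-based mock detector stands in for a trained network so
# threshold studies run without one.

#' Synthetic scene generator configuration
#'
#' Defaults emulate the working bitewing geometry (1024x768 frame, four
#' teeth per row at FDI positions 4-7) with a lesion rate of 0.15 per
#' proximal surface site and severity proportions matching the clinical
#' class mix RA:RB:RC = 1371:3275:542.
#'
#' @param side `"left"`, `"right"` or `"random"` (sampled per scene).
#' @param teeth_per_row Teeth per row (2-5; FDI positions 4 onward).
#' @param frame_size Integer `(width, height)` px.
#' @param lesion_rate Probability of a lesion at each proximal surface site.
#' @param class_mix Probabilities over `(RA, RB, RC)`, summing to 1.
#' @param proximal_gap Nominal gap (px) between adjacent tooth boxes.
#' @param overlap_junction_rate Probability a junction has overlapping
#'   tooth boxes instead of a gap (produces complete-overlap geometry).
#' @param overlap_depth Horizontal overlap (px) at overlapping junctions.
#' @param edge_truncation Probability that a terminal tooth is dropped from
#'   the detected teeth (emulating a tooth-numbering model that misses
#'   partially visible teeth at the image edge); its lesions keep their
#'   ground truth.
#' @param seed Integer base seed; scenes are deterministic under
#'   `(seed, index)`.
#' @return A list of class `"scene_gen_config"`.
#' @export
scene_gen_config <- function(side = "random", teeth_per_row = 4L,
                             frame_size = c(1024L, 768L), lesion_rate = 0.15,
                             class_mix = c(RA = 1371, RB = 3275, RC = 542) / 5188,
                             proximal_gap = 6, overlap_junction_rate = 0.25,
                             overlap_depth = 8, edge_truncation = 0,
                             seed = 0L) {
  side <- match.arg(side, c("left", "right", "random"))
  if (teeth_per_row < 2L || teeth_per_row > 5L) {
    stop_usage("teeth_per_row must be between 2 and 5")
  }
  if (abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop_usage("class_mix must be nonnegative and sum to 1")
  }
  for (p in c(lesion_rate, overlap_junction_rate, edge_truncation)) {
    if (p < 0 || p > 1) stop_usage("probabilities must be in [0, 1]")
  }
  structure(list(side = side, teeth_per_row = as.integer(teeth_per_row),
                 frame_size = as.integer(frame_size), lesion_rate = lesion_rate,
                 class_mix = class_mix, proximal_gap = proximal_gap,
                 overlap_junction_rate = overlap_junction_rate,
                 overlap_depth = overlap_depth, edge_truncation = edge_truncation,
                 seed = as.integer(seed)),
            class = "scene_gen_config")
}

# Diamond-shaped lesion outline whose tight bounds equal the given box.
lesion_polygon <- function(x0, y0, x1, y1) {
  w <- x1 - x0; h <- y1 - y0
  polygon_outline(rbind(
    c(x0, y0 + stats::runif(1, 0.3, 0.7) * h),
    c(x0 + stats::runif(1, 0.3, 0.7) * w, y0),
    c(x1, y0 + stats::runif(1, 0.3, 0.7) * h),
    c(x0 + stats::runif(1, 0.3, 0.7) * w, y1)))
}

fdi_row <- function(side, row, n) {
  pos <- seq.int(4L, 3L + n)
  if (side == "left") {
    # midline at the left image edge: most mesial tooth leftmost
    if (row == "upper") 20L + pos else 30L + pos
  } else {
    # midline at the right image edge: positions decrease left to right
    if (row == "upper") 10L + rev(pos) else 40L + rev(pos)
  }
}

#' Generate one synthetic bitewing scene with ground truth
#'
#' Deterministic under `(cfg$seed, index)`. Lesions are placed at proximal
#' surface sites; at gap junctions they straddle the owner tooth's edge
#' (single-tooth or unequal two-tooth overlap geometry), at overlapping
#' junctions they sit fully inside both tooth boxes, offset toward the
#' owner's edge (complete-overlap geometry). Ground-truth diagnosis rows
#' record the owning tooth and surface at placement time.
#'
#' @param cfg A [scene_gen_config()].
#' @param index Scene index (also drives the RNG stream and the image id).
#' @return A list with `scene` (a [scene()]) and `truth` (data frame with
#'   `image_id`, `caries_index`, `severity`, `tooth`, `surface`).
#' @export
generate_scene <- function(cfg, index = 1L) {
  with_seed(derive_seed(cfg$seed, index), {
    W <- cfg$frame_size[1L]; H <- cfg$frame_size[2L]
    side <- if (cfg$side == "random") sample(c("left", "right"), 1L) else cfg$side
    n <- cfg$teeth_per_row
    margin <- 0.03 * W
    rows <- list(upper = c(0.08, 0.45) * H, lower = c(0.55, 0.92) * H)
    teeth <- list(); truth_rows <- list(); caries <- list()
    truncated_fdi <- integer(0)

    for (row_name in names(rows)) {
      yr <- rows[[row_name]]
      fdis <- fdi_row(side, row_name, n)
      offsets <- vapply(seq_len(n - 1L), function(j) {
        if (stats::runif(1) < cfg$overlap_junction_rate) -cfg$overlap_depth
        else cfg$proximal_gap * stats::runif(1, 0.8, 1.3)
      }, numeric(1))
      avail <- W - 2 * margin - sum(offsets)
      # each tooth must be wide enough to host proximal lesions on both sides
      if (avail / n < max(60, 6 * cfg$overlap_depth)) {
        stop_usage("frame too small to fit teeth_per_row teeth")
      }
      widths <- stats::runif(n, 0.92, 1.08)
      widths <- widths / sum(widths) * avail
      x0 <- margin + c(0, cumsum(widths[-n] + offsets))
      boxes <- lapply(seq_len(n), function(k) bbox(x0[k], yr[1L], x0[k] + widths[k], yr[2L]))

      for (k in seq_len(n)) {
        teeth <- c(teeth, list(tooth_detection(fdis[k], boxes[[k]],
                                               stats::runif(1, 0.88, 0.995))))
      }
      # terminal teeth may be dropped from detections (edge failure mode)
      for (k in c(1L, n)) {
        if (stats::runif(1) < cfg$edge_truncation) {
          truncated_fdi <- c(truncated_fdi, fdis[k])
        }
      }

      mesial_sign <- if (side == "right") 1 else -1
      for (j in seq_len(n - 1L)) {
        bl <- boxes[[j]]; br <- boxes[[j + 1L]]
        for (owner_left in c(TRUE, FALSE)) {
          if (stats::runif(1) >= cfg$lesion_rate) next
          facing <- if (owner_left) 1 else -1
          surface <- if (facing == mesial_sign) "mesial" else "distal"
          owner_fdi <- if (owner_left) fdis[j] else fdis[j + 1L]
          h_l <- stats::runif(1, 14, 34)
          cy <- stats::runif(1, yr[1L] + 0.15 * diff(yr), yr[1L] + 0.6 * diff(yr))
          ly0 <- cy - h_l / 2; ly1 <- cy + h_l / 2
          if (offsets[j] < 0) {
            # overlapping junction: lesion fully inside both tooth boxes,
            # centred nearer the owner's edge so the nearest-edge rule
            # recovers the owner
            d <- -offsets[j]
            xr0 <- br[["x_min"]]; xl1 <- bl[["x_max"]]
            w_l <- stats::runif(1, max(2, 0.3 * d), 0.65 * d)
            shift <- 0.16 * d
            cx <- (xr0 + xl1) / 2 + facing * shift
            lx0 <- cx - w_l / 2; lx1 <- cx + w_l / 2
          } else {
            g <- offsets[j]
            e <- if (owner_left) bl[["x_max"]] else br[["x_min"]]
            depth_in <- stats::runif(1, 8, 20)
            if (stats::runif(1) < 0.5) {
              # unequal two-tooth overlap: small incursion into the neighbour
              depth_nb <- stats::runif(1, 1.5, min(6, 0.55 * depth_in))
              ext <- g + depth_nb
            } else {
              # single-tooth overlap: lesion reaches into the gap only
              ext <- stats::runif(1, 0.2, 0.7) * g
            }
            lx0 <- if (owner_left) e - depth_in else e - ext
            lx1 <- if (owner_left) e + ext else e + depth_in
          }
          cd <- caries_detection(
            sample(names(cfg$class_mix), 1L, prob = cfg$class_mix),
            lesion_polygon(lx0, ly0, lx1, ly1), confidence = 1)
          caries <- c(caries, list(cd))
          truth_rows <- c(truth_rows, list(data.frame(
            caries_index = length(caries), severity = cd$severity,
            tooth = owner_fdi, surface = surface, stringsAsFactors = FALSE)))
        }
      }
    }

    teeth <- Filter(function(t) !t$fdi %in% truncated_fdi, teeth)
    image_id <- sprintf("synth_%06d", index)
    s <- scene(image_id, frame_spec(W, H, side), teeth = teeth, caries = caries)
    truth <- if (length(truth_rows)) {
      cbind(image_id = image_id, do.call(rbind, truth_rows))
    } else {
      data.frame(image_id = character(0), caries_index = integer(0),
                 severity = character(0), tooth = integer(0),
                 surface = character(0))
    }
    list(scene = s, truth = truth)
  })
}

#' Render a synthetic scene as a crude grayscale raster
#'
#' Uniform dark background, brighter tooth rectangles, darker lesion
#' blobs — sufficient for enhancement and file-I/O tests; image realism is
#' a non-goal.
#'
#' @param s A [scene()].
#' @return An integer gray matrix (rows = y) in `[0, 255]`.
#' @export
render_scene <- function(s) {
  W <- s$frame$width; H <- s$frame$height
  img <- matrix(40L, nrow = H, ncol = W)
  clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  for (t in s$teeth) {
    b <- t$box
    img[clip(ceiling(b[["y_min"]]), 1, H):clip(floor(b[["y_max"]]), 1, H),
        clip(ceiling(b[["x_min"]]), 1, W):clip(floor(b[["x_max"]]), 1, W)] <- 165L
  }
  for (cd in s$caries) {
    b <- cd$box
    img[clip(ceiling(b[["y_min"]]), 1, H):clip(floor(b[["y_max"]]), 1, H),
        clip(ceiling(b[["x_min"]]), 1, W):clip(floor(b[["x_max"]]), 1, W)] <- 70L
  }
  img
}

#' Generate a dataset on disk in all interchange formats
#'
#' Writes the COCO file, YOLO-segmentation and YOLO-detection label
#' directories, the sidecar tooth table, the ground-truth diagnosis table
#' and a manifest; optionally rendered PNG images.
#'
#' @param cfg A [scene_gen_config()].
#' @param n_images Number of scenes (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param render Write rendered PNGs under `images/`.
#' @return Invisibly, a list with `set` (the [annotation_set()]), `truth`
#'   (diagnosis table) and `paths`.
#' @export
generate_dataset <- function(cfg, n_images, out_dir, render = FALSE) {
  if (!is_scalar_number(n_images) || n_images < 1) {
    stop_usage("n_images must be >= 1")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- lapply(seq_len(n_images), function(i) generate_scene(cfg, i))
  set <- annotation_set(lapply(gen, `[[`, "scene"))
  truth <- do.call(rbind, lapply(gen, `[[`, "truth"))
  paths <- list(coco = file.path(out_dir, "annotations.json"),
                yolo_seg = file.path(out_dir, "labels_seg"),
                yolo_det = file.path(out_dir, "labels_det"),
                teeth = file.path(out_dir, "teeth.tsv"),
                truth = file.path(out_dir, "truth.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_coco(set, paths$coco)
  write_yolo_seg(set, paths$yolo_seg)
  write_yolo_det(set, paths$yolo_det)
  write_tooth_table(set, paths$teeth)
  utils::write.table(truth, paths$truth, sep = "\t", row.names = FALSE, quote = FALSE)
  if (render) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (s in set$scenes) {
      write_gray_png(render_scene(s), file.path(img_dir, paste0(s$image_id, ".png")))
    }
    paths$image_dir <- img_dir
  }
  write_manifest(set, paths$manifest,
                 files = lapply(paths[names(paths) != "manifest"], basename))
  invisible(list(set = set, truth = truth, paths = paths))
}

#' Mock detector perturbation configuration
#'
#' @param box_jitter_sd SD (px) of a common translation applied to each
#'   detected lesion.
#' @param vertex_jitter_sd SD (px) of independent per-vertex jitter.
#' @param miss_rate Probability a ground-truth lesion is dropped.
#' @param spurious_rate Expected number of false lesions per image
#'   (Poisson).
#' @param class_confusion Row-stochastic 3x3 matrix; row = true class,
#'   column = reported class (RA, RB, RC order).
#' @param conf_model Confidence distributions: list with `true_mean`,
#'   `true_sd`, `spurious_mean`, `spurious_sd` (Gaussian, clamped to
#'   `[0.05, 1]`).
#' @param seed Integer base seed.
#' @return A list of class `"perturbation_config"`.
#' @export
perturbation_config <- function(box_jitter_sd = 1.0, vertex_jitter_sd = 1.5,
                                miss_rate = 0.12, spurious_rate = 0.6,
                                class_confusion = rbind(c(0.85, 0.13, 0.02),
                                                        c(0.08, 0.86, 0.06),
                                                        c(0.03, 0.17, 0.80)),
                                conf_model = list(true_mean = 0.85, true_sd = 0.08,
                                                  spurious_mean = 0.30,
                                                  spurious_sd = 0.12),
                                seed = 0L) {
  if (miss_rate < 0 || miss_rate > 1) stop_usage("miss_rate must be in [0, 1]")
  if (spurious_rate < 0) stop_usage("spurious_rate must be >= 0")
  if (!is.matrix(class_confusion) || any(dim(class_confusion) != 3L) ||
      any(abs(rowSums(class_confusion) - 1) > 1e-9) || any(class_confusion < 0)) {
    stop_usage("class_confusion must be a 3x3 row-stochastic matrix")
  }
  structure(list(box_jitter_sd = box_jitter_sd, vertex_jitter_sd = vertex_jitter_sd,
                 miss_rate = miss_rate, spurious_rate = spurious_rate,
                 class_confusion = class_confusion, conf_model = conf_model,
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Perturbation-based mock detector
#'
#' Emulates detector error on a scene's ground-truth lesions: each lesion
#' is independently dropped with `miss_rate`, otherwise translated and
#' vertex-jittered (Gaussian), its class resampled through the confusion
#' matrix and a confidence drawn from the true-detection distribution;
#' spurious lesions are added at random locations with the spurious
#' distribution. Deterministic under the config seed and the image id.
#'
#' @param s A [scene()] whose caries list is the ground truth.
#' @param p A [perturbation_config()].
#' @param rng_seed Optional explicit seed; by default derived from
#'   `p$seed` and the image id.
#' @return A list of [caries_detection()] predictions with confidences.
#' @export
mock_detect <- function(s, p = perturbation_config(), rng_seed = NULL) {
  if (is.null(rng_seed)) {
    rng_seed <- derive_seed(p$seed, sum(utf8ToInt(s$image_id)))
  }
  W <- s$frame$width; H <- s$frame$height
  with_seed(rng_seed, {
    preds <- list()
    for (cd in s$caries) {
      if (stats::runif(1) < p$miss_rate) next
      v <- unclass(cd$polygon)
      v[, 1L] <- v[, 1L] + stats::rnorm(1, 0, p$box_jitter_sd) +
        stats::rnorm(nrow(v), 0, p$vertex_jitter_sd)
      v[, 2L] <- v[, 2L] + stats::rnorm(1, 0, p$box_jitter_sd) +
        stats::rnorm(nrow(v), 0, p$vertex_jitter_sd)
      v[, 1L] <- clamp01(v[, 1L], 0, W); v[, 2L] <- clamp01(v[, 2L], 0, H)
      cls <- sample(names(SEVERITY_CLASSES), 1L,
                    prob = p$class_confusion[severity_id(cd$severity) + 1L, ])
      conf <- clamp01(stats::rnorm(1, p$conf_model$true_mean, p$conf_model$true_sd),
                      0.05, 1)
      pred <- tryCatch(caries_detection(cls, polygon_outline(v), confidence = conf),
                       proxcaries_invalid_geometry = function(e) NULL)
      if (!is.null(pred)) preds <- c(preds, list(pred))
    }
    n_spur <- stats::rpois(1, p$spurious_rate)
    for (k in seq_len(n_spur)) {
      w_l <- stats::runif(1, 8, 22); h_l <- stats::runif(1, 12, 30)
      x0 <- stats::runif(1, 1, W - w_l - 1); y0 <- stats::runif(1, 1, H - h_l - 1)
      cls <- sample(names(SEVERITY_CLASSES), 1L)
      conf <- clamp01(stats::rnorm(1, p$conf_model$spurious_mean,
                                   p$conf_model$spurious_sd), 0.05, 1)
      preds <- c(preds, list(caries_detection(
        cls, lesion_polygon(x0, y0, x0 + w_l, y0 + h_l), confidence = conf)))
    }
    preds
  })
}

#' Run the mock detector over a whole set
#'
#' @param set An [annotation_set()] of ground-truth scenes.
#' @param p A [perturbation_config()].
#' @return An [annotation_set()] of prediction scenes (same ids/frames).
#' @export
mock_detect_set <- function(set, p = perturbation_config()) {
  scenes <- lapply(set$scenes, function(s) {
    scene(s$image_id, s$frame, teeth = s$teeth, caries = mock_detect(s, p))
  })
  annotation_set(unname(scenes), unname(set$splits))
}
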