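# Fixture builders and independent oracles used across test files.

rect_poly <- function(x0, y0, x1, y1) {
  polygon_outline(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

rect_caries <- function(severity, x0, y0, x1, y1, confidence = 1) {
  caries_detection(severity, rect_poly(x0, y0, x1, y1), confidence = confidence)
}

# A hand-built scene with one lesion of every severity class, fully inside
# known teeth, on a right bitewing.
three_class_scene <- function(id = "fix1") {
  teeth <- list(
    tooth_detection(17, bbox(10, 50, 240, 350)),
    tooth_detection(16, bbox(250, 50, 480, 350)),
    tooth_detection(15, bbox(490, 50, 720, 350)))
  caries <- list(
    rect_caries("RA", 200, 100, 220, 130),   # mesial-facing (+x) edge of 17
    rect_caries("RB", 260, 150, 280, 180),   # distal-facing (-x) edge of 16
    rect_caries("RC", 500, 120, 520, 150))   # distal-facing (-x) edge of 15
  scene(id, frame_spec(1024, 768, "right"), teeth = teeth, caries = caries)
}

shift_scene <- function(s, dx, dy) {
  teeth <- lapply(s$teeth, function(t) {
    tooth_detection(t$fdi, bbox(t$box[["x_min"]] + dx, t$box[["y_min"]] + dy,
                                t$box[["x_max"]] + dx, t$box[["y_max"]] + dy),
                    t$confidence)
  })
  caries <- lapply(s$caries, function(cd) {
    v <- unclass(cd$polygon); v[, 1] <- v[, 1] + dx; v[, 2] <- v[, 2] + dy
    caries_detection(cd$severity, polygon_outline(v), confidence = cd$confidence)
  })
  scene(s$image_id, s$frame, teeth = teeth, caries = caries)
}

# Exhaustive maximum-matching oracle: largest number of prediction/ground
# truth pairs with same class and IoU >= thr, by brute-force enumeration.
oracle_max_matching <- function(preds, gts, thr) {
  if (!length(preds) || !length(gts)) return(0L)
  iou <- outer(seq_along(preds), seq_along(gts), Vectorize(function(i, j) {
    if (preds[[i]]$severity != gts[[j]]$severity) return(0)
    box_iou(preds[[i]]$box, gts[[j]]$box)
  }))
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(preds)) { best <<- max(best, sum(used)); return() }
    recurse(i + 1L, used)                      # leave prediction i unmatched
    for (j in seq_along(gts)) {
      if (!used[j] && iou[i, j] >= thr && iou[i, j] > 0) {
        used[j] <- TRUE; recurse(i + 1L, used); used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(gts)))
  best
}

# Independent re-derivation of the three-scenario tooth assignment for the
# exhaustive small-instance check.
oracle_assign <- function(cd, teeth, tol = 1e-6) {
  area <- vapply(teeth, function(t) intersection_area(cd$box, t$box), numeric(1))
  fdi <- vapply(teeth, function(t) t$fdi, integer(1))
  keep <- area > 0
  area <- area[keep]; fdi <- fdi[keep]; kept <- which(keep)
  if (!length(area)) return(NA_integer_)
  if (length(area) == 1L) return(fdi)
  ca <- box_area(cd$box)
  covered <- area >= (1 - tol) * ca
  max_a <- max(area)
  tied <- area == max_a
  if (sum(covered) >= 2L || sum(tied) >= 2L) {
    cand <- if (sum(covered) >= 2L) which(covered) else which(tied)
    cx <- (cd$box[["x_min"]] + cd$box[["x_max"]]) / 2
    d <- vapply(cand, function(k) {
      b <- teeth[[kept[k]]]$box
      min(abs(cx - b[["x_min"]]), abs(cx - b[["x_max"]]))
    }, numeric(1))
    ord <- order(d, fdi[cand])
    return(fdi[cand][ord[1L]])
  }
  fdi[which.max(area)]
}

# Ground-truth-recovery rate of diagnose_scene over generated scenes.
assignment_accuracy <- function(cfg, n_scenes) {
  n <- 0L; ok <- 0L
  for (i in seq_len(n_scenes)) {
    g <- generate_scene(cfg, i)
    if (!nrow(g$truth)) next
    d <- diagnose_scene(g$scene)
    m <- merge(d, g$truth, by = c("image_id", "caries_index"))
    n <- n + nrow(m)
    ok <- ok + sum(!is.na(m$tooth.x) & m$tooth.x == m$tooth.y &
                     m$surface.x == m$surface.y)
  }
  list(n = n, ok = ok, pct = 100 * ok / n)
}
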