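# Detection scoring: confidence filtering, per-class greedy IoU matching,
# precision/recall/F1, all-point-interpolated average precision and the
# macro mAP (unweighted class mean), plus the five-row diagnosis tally
# used to compare full diagnoses.

check_ratio <- function(x, what) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    stop_usage(sprintf("%s must be a number in [0, 1]", what))
  }
}

pair_iou <- function(p, g, iou_kind, frame) {
  if (iou_kind == "box") box_iou(p$box, g$box) else mask_iou(p$polygon, g$polygon, frame)
}

#' Match predicted to ground-truth caries detections
#'
#' Predictions below `conf_thr` are discarded. Within each severity class,
#' surviving predictions are processed in descending confidence; each is
#' matched greedily to the unmatched same-class ground truth with the
#' highest IoU and accepted as a true positive iff that IoU reaches
#' `iou_thr`, otherwise it is a false positive. Unmatched ground truths are
#' false negatives. Matching is class-exclusive: a wrong-class overlap is a
#' false positive for its predicted class and leaves the ground truth
#' unmatched.
#'
#' @param preds,gts Lists of [caries_detection()] (predictions carry
#'   confidences).
#' @param iou_thr,conf_thr Thresholds in `[0, 1]`.
#' @param iou_kind `"box"` (bounding-box IoU) or `"mask"` (rasterized
#'   polygon IoU; requires `frame`).
#' @param frame A [frame_spec()], needed when `iou_kind = "mask"`.
#' @return A list of class `"match_result"`: `per_class` (data frame with
#'   `class`, `tp`, `fp`, `fn`), `pairs` (matched prediction/gt indices and
#'   IoU), and `pred_flags` (per retained prediction: class, confidence,
#'   tp flag) for precision-recall curves.
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5, conf_thr = 0.25,
                             iou_kind = c("box", "mask"), frame = NULL) {
  check_ratio(iou_thr, "iou_thr"); check_ratio(conf_thr, "conf_thr")
  iou_kind <- match.arg(iou_kind)
  if (iou_kind == "mask" && is.null(frame)) {
    stop_usage("mask IoU needs the scene frame")
  }
  classes <- names(SEVERITY_CLASSES)
  conf <- vapply(preds, function(p) p$confidence, numeric(1))
  keep <- which(conf >= conf_thr)
  per_class <- data.frame(class = classes, tp = 0L, fp = 0L, fn = 0L)
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0),
                      class = character(0))
  flags <- data.frame(class = character(0), confidence = numeric(0),
                      tp = logical(0), pred = integer(0))
  for (cls in classes) {
    gt_idx <- which(vapply(gts, function(g) g$severity, character(1)) == cls)
    pr_idx <- keep[vapply(preds[keep], function(p) p$severity, character(1)) == cls]
    pr_idx <- pr_idx[order(-conf[pr_idx], pr_idx)]   # desc confidence, stable
    gt_used <- logical(length(gt_idx))
    for (pi in pr_idx) {
      best <- 0; best_j <- 0L
      for (j in seq_along(gt_idx)) {
        if (gt_used[j]) next
        v <- pair_iou(preds[[pi]], gts[[gt_idx[j]]], iou_kind, frame)
        if (v > best) { best <- v; best_j <- j }
      }
      is_tp <- best_j > 0L && best >= iou_thr && best > 0
      if (is_tp) {
        gt_used[best_j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = pi, gt = gt_idx[best_j],
                                         iou = best, class = cls))
      }
      flags <- rbind(flags, data.frame(class = cls, confidence = conf[pi],
                                       tp = is_tp, pred = pi))
    }
    row <- per_class$class == cls
    per_class$tp[row] <- sum(gt_used)
    per_class$fp[row] <- length(pr_idx) - sum(gt_used)
    per_class$fn[row] <- length(gt_idx) - sum(gt_used)
  }
  structure(list(per_class = per_class, pairs = pairs, pred_flags = flags,
                 iou_thr = iou_thr, conf_thr = conf_thr, iou_kind = iou_kind),
            class = "match_result")
}

#' Precision, recall and F1 from match counts
#'
#' Conventions: any 0/0 ratio is 0 (with a warning), so empty-prediction
#' edge cases are total.
#'
#' @param m A `"match_result"` from [match_detections()], or a class row is
#'   selected with `class`.
#' @param class Severity label; if `NULL`, counts are summed over classes.
#' @return Named numeric `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(m, class = NULL) {
  pc <- m$per_class
  if (!is.null(class)) pc <- pc[pc$class == class, , drop = FALSE]
  tp <- sum(pc$tp); fp <- sum(pc$fp); fn <- sum(pc$fn)
  if (tp + fp == 0 || tp + fn == 0) warning("0/0 metric defined as 0")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' F1 score from precision and recall
#'
#' `f1 = 2pr / (p + r)`, with `0` when `p + r = 0`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The harmonic mean.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

# AP from pooled prediction flags: confidences, tp logical, number of gts.
# All-point interpolation: precision envelope made monotone non-increasing,
# area accumulated over recall increments.
ap_from_flags <- function(confidence, tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(confidence)) return(0)
  ord <- order(-confidence, seq_along(confidence))
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  penv <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * penv)
}

#' Average precision for one class on one scene
#'
#' All predictions are ranked by confidence (no confidence filtering), the
#' precision-recall curve is swept, the precision envelope is made monotone
#' non-increasing (all-point interpolation) and the area under it returned.
#'
#' @inheritParams match_detections
#' @param class Severity label to score.
#' @return AP in `[0, 1]`, or `NA` (with a warning) when the class has no
#'   ground truths.
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5,
                              iou_kind = c("box", "mask"), frame = NULL,
                              class = NULL) {
  iou_kind <- match.arg(iou_kind)
  m <- match_detections(preds, gts, iou_thr = iou_thr, conf_thr = 0,
                        iou_kind = iou_kind, frame = frame)
  classes <- if (is.null(class)) names(SEVERITY_CLASSES) else class
  aps <- vapply(classes, function(cls) {
    fl <- m$pred_flags[m$pred_flags$class == cls, , drop = FALSE]
    n_gt <- sum(vapply(gts, function(g) g$severity, character(1)) == cls)
    if (n_gt == 0L) {
      warning(sprintf("class %s has no ground truths; AP undefined", cls))
      return(NA_real_)
    }
    ap_from_flags(fl$confidence, fl$tp, n_gt)
  }, numeric(1))
  if (length(classes) == 1L) unname(aps) else aps
}

match_set_ids <- function(pred_set, gt_set) {
  pid <- set_image_ids(pred_set); gid <- set_image_ids(gt_set)
  if (!setequal(pid, gid)) {
    stop_format(sprintf("image ids differ between prediction and reference sets (%s)",
                        paste(union(setdiff(pid, gid), setdiff(gid, pid)), collapse = ", ")))
  }
  gid
}

#' Evaluate a prediction set against a reference set
#'
#' Matching runs per image; counts and ranked prediction flags are pooled
#' over all images into a single per-class confusion (not averaged per
#' image). AP is computed on the pooled ranking with no confidence filter;
#' precision/recall/F1 use `conf_thr`. Macro ("overall") values are
#' unweighted class means; in particular `mAP = (1/C) * sum(AP_c)`.
#'
#' @param pred_set,gt_set [annotation_set()] objects with matching image ids.
#' @param iou_thr,conf_thr Thresholds; defaults 0.5 and 0.25, the operating
#'   point used for the headline metrics.
#' @param iou_kind `"box"` or `"mask"`.
#' @return A list of class `"metrics_report"`: `per_class` data frame
#'   (`class`, `tp`, `fp`, `fn`, `n_gt`, `precision`, `recall`, `f1`, `ap`),
#'   `macro` named numeric (`precision`, `recall`, `f1`, `mAP`), and the
#'   thresholds used.
#' @export
evaluate <- function(pred_set, gt_set, iou_thr = 0.5, conf_thr = 0.25,
                     iou_kind = c("box", "mask")) {
  iou_kind <- match.arg(iou_kind)
  ids <- match_set_ids(pred_set, gt_set)
  classes <- names(SEVERITY_CLASSES)
  acc <- data.frame(class = classes, tp = 0L, fp = 0L, fn = 0L, n_gt = 0L)
  flags <- list()
  for (id in ids) {
    preds <- pred_set$scenes[[id]]$caries
    gts <- gt_set$scenes[[id]]$caries
    frame <- gt_set$scenes[[id]]$frame
    m_conf <- match_detections(preds, gts, iou_thr, conf_thr, iou_kind, frame)
    m_all <- match_detections(preds, gts, iou_thr, 0, iou_kind, frame)
    acc$tp <- acc$tp + m_conf$per_class$tp
    acc$fp <- acc$fp + m_conf$per_class$fp
    acc$fn <- acc$fn + m_conf$per_class$fn
    acc$n_gt <- acc$n_gt + m_conf$per_class$tp + m_conf$per_class$fn
    flags[[id]] <- m_all$pred_flags
  }
  flags <- do.call(rbind, c(flags, list(data.frame(class = character(0),
                                                   confidence = numeric(0),
                                                   tp = logical(0),
                                                   pred = integer(0)))))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  acc$precision <- safe_div(acc$tp, acc$tp + acc$fp)
  acc$recall <- safe_div(acc$tp, acc$tp + acc$fn)
  acc$f1 <- f1_score(acc$precision, acc$recall)
  acc$ap <- vapply(classes, function(cls) {
    if (acc$n_gt[acc$class == cls] == 0L) {
      warning(sprintf("class %s has no ground truths; AP excluded from mAP", cls))
      return(NA_real_)
    }
    fl <- flags[flags$class == cls, , drop = FALSE]
    ap_from_flags(fl$confidence, fl$tp, acc$n_gt[acc$class == cls])
  }, numeric(1))
  macro <- c(precision = mean(acc$precision), recall = mean(acc$recall),
             f1 = mean(acc$f1), mAP = mean(acc$ap, na.rm = TRUE))
  structure(list(per_class = acc, macro = macro,
                 thresholds = list(iou_thr = iou_thr, conf_thr = conf_thr,
                                   iou_kind = iou_kind)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics at IoU %.2f, confidence %.3g (%s IoU)\n",
              x$thresholds$iou_thr, x$thresholds$conf_thr, x$thresholds$iou_kind))
  tab <- x$per_class
  tab[c("precision", "recall", "f1", "ap")] <-
    round(tab[c("precision", "recall", "f1", "ap")], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall: precision %.3f, recall %.3f, F1 %.3f, mAP %.3f\n",
              x$macro[["precision"]], x$macro[["recall"]],
              x$macro[["f1"]], x$macro[["mAP"]]))
  invisible(x)
}

#' Evaluate over a grid of IoU and confidence thresholds
#'
#' @inheritParams evaluate
#' @param iou_list,conf_list Non-empty threshold vectors; the defaults are
#'   the standard operating grid `{0.5, 0.75} x {0.001, 0.25, 0.5}`.
#' @return A long-format data frame: one row per (iou, conf, class) plus
#'   `macro` rows, with precision, recall, f1 and ap columns.
#' @export
threshold_sweep <- function(pred_set, gt_set, iou_list = c(0.5, 0.75),
                            conf_list = c(0.001, 0.25, 0.5),
                            iou_kind = c("box", "mask")) {
  if (!length(iou_list) || !length(conf_list)) {
    stop_usage("threshold lists must be non-empty")
  }
  iou_kind <- match.arg(iou_kind)
  out <- list()
  for (iou in iou_list) for (conf in conf_list) {
    rep <- evaluate(pred_set, gt_set, iou, conf, iou_kind)
    pc <- rep$per_class[c("class", "precision", "recall", "f1", "ap")]
    pc <- rbind(pc, data.frame(class = "macro",
                               precision = rep$macro[["precision"]],
                               recall = rep$macro[["recall"]],
                               f1 = rep$macro[["f1"]],
                               ap = rep$macro[["mAP"]]))
    pc$iou_thr <- iou; pc$conf_thr <- conf
    out[[length(out) + 1L]] <- pc
  }
  do.call(rbind, out)
}

#' Tally full-diagnosis agreement between two diagnosed sets
#'
#' Lesions are put in correspondence per image by greedy box-IoU matching
#' (class-agnostic, descending prediction confidence) at `iou_thr`; the
#' five tallies mirror a reader-study scoreboard: detected instances, fully
#' correct (severity AND tooth AND surface), severity-correct,
#' tooth-correct and surface-correct.
#'
#' @param pred_set,gt_set [annotation_set()] objects carrying the lesion
#'   geometry.
#' @param pred_diag,gt_diag Diagnosis data frames from [diagnose_set()]
#'   (or the generator's ground-truth table), keyed by `image_id` and
#'   `caries_index`.
#' @param iou_thr Box IoU needed for two lesions to correspond.
#' @return Named integer vector: `total_gt`, `detected`, `fully_correct`,
#'   `severity_correct`, `tooth_correct`, `surface_correct`.
#' @export
compare_diagnoses <- function(pred_set, pred_diag, gt_set, gt_diag,
                              iou_thr = 0.5) {
  ids <- match_set_ids(pred_set, gt_set)
  tally <- c(total_gt = 0L, detected = 0L, fully_correct = 0L,
             severity_correct = 0L, tooth_correct = 0L, surface_correct = 0L)
  lookup <- function(diag, id, idx, col) {
    v <- diag[diag$image_id == id & diag$caries_index == idx, col]
    if (length(v) != 1L) stop_format(sprintf(
      "diagnosis table lacks a unique row for image %s lesion %d", id, idx))
    v
  }
  for (id in ids) {
    preds <- pred_set$scenes[[id]]$caries
    gts <- gt_set$scenes[[id]]$caries
    tally[["total_gt"]] <- tally[["total_gt"]] + length(gts)
    if (!length(preds) || !length(gts)) next
    conf <- vapply(preds, function(p) p$confidence, numeric(1))
    order_p <- order(-conf, seq_along(preds))
    gt_used <- logical(length(gts))
    for (pi in order_p) {
      iou <- vapply(seq_along(gts), function(j) {
        if (gt_used[j]) return(-1)
        box_iou(preds[[pi]]$box, gts[[j]]$box)
      }, numeric(1))
      j <- which.max(iou)
      if (iou[j] < iou_thr || iou[j] <= 0) next
      gt_used[j] <- TRUE
      tally[["detected"]] <- tally[["detected"]] + 1L
      sev_ok <- identical(lookup(pred_diag, id, pi, "severity"),
                          lookup(gt_diag, id, j, "severity"))
      tooth_ok <- identical(as.integer(lookup(pred_diag, id, pi, "tooth")),
                            as.integer(lookup(gt_diag, id, j, "tooth")))
      surf_ok <- identical(lookup(pred_diag, id, pi, "surface"),
                           lookup(gt_diag, id, j, "surface"))
      tally[["severity_correct"]] <- tally[["severity_correct"]] + sev_ok
      tally[["tooth_correct"]] <- tally[["tooth_correct"]] + (tooth_ok && !is.na(tooth_ok))
      tally[["surface_correct"]] <- tally[["surface_correct"]] + surf_ok
      tally[["fully_correct"]] <- tally[["fully_correct"]] +
        (sev_ok && tooth_ok && !is.na(tooth_ok) && surf_ok)
    }
  }
  tally
}
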