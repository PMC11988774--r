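test_that("greedy matching applies confidence and IoU thresholds", {
  gts <- list(rect_caries("RA", 0, 0, 20, 20), rect_caries("RB", 50, 0, 70, 20))
  # identical predictions -> all TP at any thresholds <= 1
  m <- match_detections(gts, gts, iou_thr = 0.99, conf_thr = 0.5)
  expect_equal(sum(m$per_class$tp), 2)
  expect_equal(sum(m$per_class$fp) + sum(m$per_class$fn), 0)
  # no predictions -> all FN
  m0 <- match_detections(list(), gts, 0.5, 0.25)
  expect_equal(sum(m0$per_class$fn), 2)
  # IoU 0.4 below threshold 0.5 -> FP and FN
  pred <- list(rect_caries("RA", 0, 0, 20, 11.2, confidence = 0.9))  # IoU = 0.56/1 ... below
  iou <- box_iou(pred[[1]]$box, gts[[1]]$box)
  expect_lt(iou, 0.6); expect_gt(iou, 0.4)
  m1 <- match_detections(pred, gts[1], iou_thr = 0.6, conf_thr = 0.25)
  expect_equal(m1$per_class$fp[m1$per_class$class == "RA"], 1L)
  expect_equal(m1$per_class$fn[m1$per_class$class == "RA"], 1L)
  # below-confidence predictions are discarded before matching
  low <- list(rect_caries("RA", 0, 0, 20, 20, confidence = 0.1))
  m2 <- match_detections(low, gts[1], 0.5, 0.25)
  expect_equal(m2$per_class$tp[1], 0L)
  expect_equal(m2$per_class$fn[1], 1L)
  # wrong-class overlap is FP for its class, FN for the gt class
  wrong <- list(rect_caries("RB", 0, 0, 20, 20, confidence = 0.9))
  m3 <- match_detections(wrong, gts[1], 0.5, 0.25)
  expect_equal(m3$per_class$fp[m3$per_class$class == "RB"], 1L)
  expect_equal(m3$per_class$fn[m3$per_class$class == "RA"], 1L)
  expect_error(match_detections(gts, gts, 1.5, 0.25), class = "proxcaries_usage_error")
})

test_that("precision/recall/F1 reproduce the published per-class arithmetic", {
  expect_equal(round(f1_score(0.796, 0.882), 3), 0.837)
  expect_equal(round(f1_score(0.928, 0.816), 3), 0.868)
  expect_equal(round(f1_score(0.808, 0.894), 3), 0.849)
  m <- list(per_class = data.frame(class = "RA", tp = 0L, fp = 0L, fn = 0L))
  expect_warning(v <- precision_recall_f1(m, "RA"))
  expect_equal(unname(v), c(0, 0, 0))
  # f1 bounds: 0 <= f1 <= (p + r) / 2, zero iff p * r = 0
  set.seed(3)
  for (k in 1:50) {
    p <- runif(1); r <- runif(1)
    f <- f1_score(p, r)
    expect_gte(f, 0); expect_lte(f, (p + r) / 2 + 1e-12)
  }
  expect_equal(f1_score(0, 0.7), 0)
})

test_that("average precision uses the monotone precision envelope", {
  gt <- list(rect_caries("RA", 0, 0, 20, 20))
  expect_equal(average_precision(list(rect_caries("RA", 0, 0, 20, 20, confidence = 0.9)),
                                 gt, class = "RA"), 1)
  # higher-confidence FP then TP: PR points (0,0), (1,0.5) -> AP 0.5
  preds <- list(rect_caries("RA", 200, 200, 220, 220, confidence = 0.9),
                rect_caries("RA", 0, 0, 20, 20, confidence = 0.6))
  expect_equal(average_precision(preds, gt, class = "RA"), 0.5)
  # all predictions FP -> 0
  expect_equal(average_precision(preds[1], gt, class = "RA"), 0)
  # no ground truths of the class -> NA with warning
  expect_warning(v <- average_precision(preds, gt, class = "RB"))
  expect_true(is.na(v))
  # rank-only dependence: uniform confidence rescaling leaves AP unchanged
  scaled <- lapply(preds, function(p) {
    caries_detection(p$severity, p$polygon, confidence = p$confidence * 0.5)
  })
  expect_equal(average_precision(scaled, gt, class = "RA"),
               average_precision(preds, gt, class = "RA"))
})

test_that("evaluate pools over images and macro-averages per class", {
  set <- annotation_set(list(three_class_scene("e1"),
                             three_class_scene("e2")))
  rep <- evaluate(set, set, 0.5, 0.25, "box")
  expect_equal(rep$per_class$precision, c(1, 1, 1))
  expect_equal(rep$per_class$recall, c(1, 1, 1))
  expect_equal(rep$per_class$ap, c(1, 1, 1))
  expect_equal(unname(rep$macro), c(1, 1, 1, 1))
  # mAP is exactly the unweighted mean of per-class APs
  expect_identical(rep$macro[["mAP"]], mean(rep$per_class$ap))
  # mask IoU route gives the same perfect result on identical sets
  repm <- evaluate(set, set, 0.5, 0.25, "mask")
  expect_equal(unname(repm$macro), c(1, 1, 1, 1))
  # mismatched ids -> pairing error
  other <- annotation_set(list(three_class_scene("zz")))
  expect_error(evaluate(other, set), class = "proxcaries_format_error")
})

test_that("macro mAP equals the class mean on mock-detector output", {
  cfg <- scene_gen_config(seed = 41, lesion_rate = 0.35)
  gset <- annotation_set(lapply(1:12, function(i) generate_scene(cfg, i)$scene))
  pset <- mock_detect_set(gset, perturbation_config(seed = 2))
  rep <- suppressWarnings(evaluate(pset, gset))
  expect_identical(rep$macro[["mAP"]], mean(rep$per_class$ap, na.rm = TRUE))
  expect_identical(rep$macro[["f1"]], mean(rep$per_class$f1))
  expect_true(all(rep$per_class$tp + rep$per_class$fn == rep$per_class$n_gt))
})

test_that("recall is monotone in confidence and AP in IoU threshold", {
  for (seed in 0:9) {
    cfg <- scene_gen_config(seed = seed, lesion_rate = 0.35)
    gset <- annotation_set(lapply(1:4, function(i) generate_scene(cfg, i)$scene))
    pset <- mock_detect_set(gset, perturbation_config(seed = seed))
    sw <- suppressWarnings(threshold_sweep(pset, gset, c(0.5, 0.75), c(0.001, 0.25, 0.5)))
    for (cls in unique(sw$class)) for (iou in c(0.5, 0.75)) {
      rec <- sw$recall[sw$class == cls & sw$iou_thr == iou]
      expect_true(all(diff(rec) <= 1e-12))      # conf 0.001 -> 0.25 -> 0.5
    }
    for (cls in setdiff(unique(sw$class), "macro")) for (conf in c(0.001, 0.25, 0.5)) {
      ap <- sw$ap[sw$class == cls & sw$conf_thr == conf]
      expect_true(is.na(ap[2]) || is.na(ap[1]) || ap[2] <= ap[1] + 1e-12)
    }
  }
})

test_that("default sweep grid yields six reports", {
  set <- annotation_set(list(three_class_scene()))
  sw <- threshold_sweep(set, set)
  expect_equal(nrow(sw), 6 * 4)   # 6 grid points x (3 classes + macro)
  expect_equal(nrow(unique(sw[c("iou_thr", "conf_thr")])), 6)
  expect_error(threshold_sweep(set, set, numeric(0), 0.25),
               class = "proxcaries_usage_error")
})

test_that("greedy matching attains the exhaustive maximum in the generator regime", {
  # gts on well-separated grid cells; predictions are jittered copies
  # (IoU >> thr) or placed in empty cells (IoU 0)
  for (seed in 1:10) {
    set.seed(seed)
    cells <- expand.grid(x = c(0, 60, 120, 180), y = c(0, 60))
    gi <- sample(nrow(cells), sample(0:4, 1))
    gts <- lapply(gi, function(k) {
      rect_caries(sample(c("RA", "RB", "RC"), 1),
                  cells$x[k] + 5, cells$y[k] + 5, cells$x[k] + 45, cells$y[k] + 45)
    })
    preds <- list()
    for (k in gi) {
      if (runif(1) < 0.7) {
        j <- runif(2, -2, 2)
        cls <- if (runif(1) < 0.8 && length(gts)) gts[[match(k, gi)]]$severity
               else sample(c("RA", "RB", "RC"), 1)
        preds <- c(preds, list(rect_caries(cls, cells$x[k] + 5 + j[1], cells$y[k] + 5 + j[2],
                                           cells$x[k] + 45 + j[1], cells$y[k] + 45 + j[2],
                                           confidence = runif(1, 0.3, 1))))
      }
    }
    for (k in sample(setdiff(seq_len(nrow(cells)), gi), sample(0:2, 1))) {
      preds <- c(preds, list(rect_caries(sample(c("RA", "RB", "RC"), 1),
                                         cells$x[k] + 5, cells$y[k] + 5,
                                         cells$x[k] + 45, cells$y[k] + 45,
                                         confidence = runif(1, 0.3, 1))))
    }
    m <- match_detections(preds, gts, iou_thr = 0.5, conf_thr = 0)
    expect_equal(sum(m$per_class$tp), oracle_max_matching(preds, gts, 0.5))
  }
})

test_that("diagnosis comparison tallies the five scoreboard rows", {
  gset <- annotation_set(list(three_class_scene("t1")))
  gdiag <- diagnose_set(gset)
  tal <- compare_diagnoses(gset, gdiag, gset, gdiag)
  expect_equal(unname(tal[c("detected", "fully_correct", "severity_correct",
                            "tooth_correct", "surface_correct")]),
               rep(3L, 5))
  # one lesion with wrong severity only
  s <- gset$scenes[["t1"]]
  caries2 <- s$caries
  caries2[[2]] <- caries_detection("RC", caries2[[2]]$polygon,
                                   confidence = caries2[[2]]$confidence)
  pset <- annotation_set(list(scene("t1", s$frame, teeth = s$teeth, caries = caries2)))
  pdiag <- diagnose_set(pset)
  tal2 <- compare_diagnoses(pset, pdiag, gset, gdiag)
  expect_equal(unname(tal2["detected"]), 3L)
  expect_equal(unname(tal2["fully_correct"]), 2L)
  expect_equal(unname(tal2["severity_correct"]), 2L)
  expect_equal(unname(tal2["tooth_correct"]), 3L)
  expect_equal(unname(tal2["surface_correct"]), 3L)
  # empty predictions -> all zero except the gt total
  eset <- annotation_set(list(scene("t1", s$frame, teeth = s$teeth)))
  tal3 <- compare_diagnoses(eset, diagnose_set(eset), gset, gdiag)
  expect_equal(unname(tal3["detected"]), 0L)
  expect_equal(unname(tal3["total_gt"]), 3L)
})
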