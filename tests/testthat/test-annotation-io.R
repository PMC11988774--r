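test_that("a minimal COCO file reads into one scene with recomputed box", {
  dir <- withr::local_tempdir()
  coco <- list(
    images = list(list(id = 1, file_name = "bw1.png", width = 1024, height = 768)),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            segmentation = list(c(100, 100, 200, 100, 200, 200)),
                            bbox = c(0, 0, 1, 1))),   # bbox field is ignored
    categories = list(list(id = 1, name = "RA"), list(id = 2, name = "RB"),
                      list(id = 3, name = "RC")))
  path <- file.path(dir, "mini.json")
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  set <- read_coco(path)
  expect_length(set$scenes, 1)
  cd <- set$scenes[["bw1"]]$caries[[1]]
  expect_identical(cd$severity, "RA")
  expect_equal(unclass(cd$box), c(x_min = 100, y_min = 100, x_max = 200, y_max = 200))

  # zero annotations -> empty caries lists
  coco$annotations <- list()
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  expect_length(read_coco(path)$scenes[["bw1"]]$caries, 0)

  # annotation referencing a missing image id -> format error naming it
  coco$annotations <- list(list(id = 1, image_id = 99, category_id = 1,
                                segmentation = list(c(0, 0, 5, 0, 5, 5))))
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_coco(path), "99", class = "proxcaries_format_error")

  # unknown category name -> format error
  coco$annotations <- list()
  coco$categories <- list(list(id = 1, name = "sound"))
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_coco(path), class = "proxcaries_format_error")
})

test_that("YOLO dialects emit the fixed 6-decimal line format", {
  s <- scene("img1", frame_spec(1024, 768),
             caries = list(caries_detection("RA",
               polygon_outline(c(100, 100, 200, 100, 200, 200)))))
  set <- annotation_set(list(s))
  d <- withr::local_tempdir()
  write_yolo_seg(set, file.path(d, "seg"))
  expect_identical(readLines(file.path(d, "seg", "img1.txt")),
                   "0 0.097656 0.130208 0.195312 0.130208 0.195312 0.260417")
  write_yolo_det(set, file.path(d, "det"))
  expect_identical(readLines(file.path(d, "det", "img1.txt")),
                   "0 0.146484 0.195312 0.097656 0.130208")

  # RC lesions start with class id 2; full-frame box maps to 0.5 0.5 1 1
  s2 <- scene("img2", frame_spec(100, 100),
              caries = list(rect_caries("RC", 0, 0, 100, 100)))
  write_yolo_det(annotation_set(list(s2)), file.path(d, "det2"))
  expect_identical(readLines(file.path(d, "det2", "img2.txt")),
                   "2 0.500000 0.500000 1.000000 1.000000")

  # lesion-free image -> empty file
  s3 <- scene("img3", frame_spec(100, 100))
  write_yolo_seg(annotation_set(list(s3)), file.path(d, "seg3"))
  expect_identical(readLines(file.path(d, "seg3", "img3.txt")), character(0))
})

test_that("YOLO-seg round trip preserves labels and coordinates", {
  cfg <- scene_gen_config(seed = 21)
  set <- annotation_set(lapply(1:6, function(i) generate_scene(cfg, i)$scene))
  d <- withr::local_tempdir()
  write_yolo_seg(set, d)
  frames <- data.frame(image_id = set_ids <- names(set$scenes),
                       width = 1024, height = 768)
  back <- read_yolo_seg(d, frames)
  expect_setequal(names(back$scenes), set_ids)
  for (id in set_ids) {
    orig <- set$scenes[[id]]$caries; got <- back$scenes[[id]]$caries
    expect_length(got, length(orig))
    for (i in seq_along(orig)) {
      expect_identical(got[[i]]$severity, orig[[i]]$severity)
      dx <- abs(unclass(got[[i]]$polygon) - unclass(orig[[i]]$polygon))
      dx[, 1] <- dx[, 1] / 1024; dx[, 2] <- dx[, 2] / 768
      expect_lt(max(dx), 1e-4)   # normalized units
    }
  }
})

test_that("malformed YOLO label lines are rejected with line numbers", {
  d <- withr::local_tempdir()
  frames <- data.frame(image_id = "x", width = 100, height = 100)
  writeLines("0 0.1 0.1 0.2 0.1 0.2", file.path(d, "x.txt"))   # odd count
  expect_error(read_yolo_seg(d, frames), "line 1", class = "proxcaries_format_error")
  writeLines("3 0.1 0.1 0.2 0.1 0.2 0.2", file.path(d, "x.txt"))
  expect_error(read_yolo_seg(d, frames), class = "proxcaries_format_error")
  writeLines(character(0), file.path(d, "x.txt"))
  expect_length(read_yolo_seg(d, frames)$scenes[["x"]]$caries, 0)
})

test_that("out-of-frame vertices are an error, never clipped", {
  s <- scene("big", frame_spec(1000, 1000),
             caries = list(rect_caries("RA", 900, 900, 990, 990)))
  set <- annotation_set(list(s))
  set$scenes[["big"]]$frame$width <- 950   # frame shrunk after construction
  expect_error(write_yolo_seg(set, withr::local_tempdir()),
               class = "proxcaries_format_error")
})

test_that("split_dataset uses floor sizes with the remainder to train", {
  scenes <- lapply(seq_len(1354), function(i) scene(paste0("s", i), frame_spec(10, 10)))
  set <- annotation_set(scenes)
  sp <- split_dataset(set, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(as.vector(table(sp$splits)[c("train", "val", "test")]),
                   c(1084L, 135L, 135L))
  sp2 <- split_dataset(set, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(sp$splits, sp2$splits)
  small <- annotation_set(scenes[1:10])
  sp10 <- split_dataset(small, c(0.8, 0.1, 0.1), seed = 0)
  expect_identical(as.vector(table(sp10$splits)[c("train", "val", "test")]),
                   c(8L, 1L, 1L))
  expect_error(split_dataset(annotation_set(scenes[1:2]), c(0.8, 0.1, 0.1), 0),
               class = "proxcaries_usage_error")
  expect_error(split_dataset(small, c(0.8, 0.1, 0.2), 0),
               class = "proxcaries_usage_error")
})

test_that("class_counts rows always satisfy total = RA + RB + RC", {
  s1 <- scene("a", frame_spec(100, 100),
              caries = list(rect_caries("RA", 1, 1, 5, 5),
                            rect_caries("RA", 10, 1, 15, 5),
                            rect_caries("RA", 20, 1, 25, 5)))
  s2 <- scene("b", frame_spec(100, 100),
              caries = list(rect_caries("RB", 1, 1, 5, 5),
                            rect_caries("RC", 10, 1, 15, 5)))
  tab <- class_counts(annotation_set(list(s1, s2)))
  tot <- tab[tab$split == "total", ]
  expect_equal(c(tot$RA, tot$RB, tot$RC, tot$total), c(3, 1, 1, 5))
  expect_equal(tab$total, tab$RA + tab$RB + tab$RC)

  empty <- class_counts(annotation_set(list()))
  expect_equal(empty$total, 0)

  # property against an independent tally on generated data
  cfg <- scene_gen_config(seed = 33)
  gen <- lapply(1:10, function(i) generate_scene(cfg, i))
  set <- annotation_set(lapply(gen, `[[`, "scene"))
  tab <- class_counts(set)
  truth <- do.call(rbind, lapply(gen, `[[`, "truth"))
  for (lb in c("RA", "RB", "RC")) {
    expect_equal(tab[tab$split == "total", lb], sum(truth$severity == lb))
  }
})

test_that("tooth sidecar table and manifest round-trip", {
  cfg <- scene_gen_config(seed = 9)
  set <- annotation_set(lapply(1:3, function(i) generate_scene(cfg, i)$scene))
  d <- withr::local_tempdir()
  write_tooth_table(set, file.path(d, "teeth.tsv"))
  bare <- annotation_set(lapply(set$scenes, function(s) scene(s$image_id, s$frame, caries = s$caries)))
  filled <- attach_teeth(bare, read_tooth_table(file.path(d, "teeth.tsv")))
  for (id in names(set$scenes)) {
    expect_equal(vapply(filled$scenes[[id]]$teeth, `[[`, integer(1), "fdi"),
                 vapply(set$scenes[[id]]$teeth, `[[`, integer(1), "fdi"))
  }
  write_manifest(set, file.path(d, "m.yaml"), files = list(teeth = "teeth.tsv"))
  man <- read_manifest(file.path(d, "m.yaml"))
  expect_setequal(man$images$image_id, names(set$scenes))
  expect_identical(man$files$teeth, "teeth.tsv")
})
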