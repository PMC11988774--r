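# Lesion-to-anatomy assignment. For each caries detection the intersecting
# tooth boxes are found and one of three scenarios applies:
#   1. exactly one tooth overlaps -> that tooth;
#   2. several teeth overlap with strictly different overlap areas -> the
#      tooth with the greatest overlap;
#   3. the caries box is completely covered by two or more teeth (or the
#      top overlap areas tie) -> the tooth whose nearest vertical box edge
#      is horizontally closest to the caries box center.
# The affected surface then follows from comparing x-midpoints of the
# caries and tooth boxes, oriented by the bitewing side.

#' Assignment configuration
#'
#' @param complete_overlap_tol Relative tolerance for treating a caries box
#'   as fully covered by a tooth box (scenario 3): covered means overlap
#'   area >= `(1 - tol) *` caries box area. Default 1e-6.
#' @param min_overlap_area Intersection areas (px^2) at or below this value
#'   are treated as no overlap. Default 0.
#' @param mesial_positive_side Which bitewing side has the mesial direction
#'   pointing toward +x. Default `"right"` (so on a left bitewing mesial is
#'   -x); the opposite display convention is this one-line change.
#' @return A list of class `"assignment_config"`.
#' @export
assignment_config <- function(complete_overlap_tol = 1e-6,
                              min_overlap_area = 0,
                              mesial_positive_side = c("right", "left")) {
  if (complete_overlap_tol < 0 || min_overlap_area < 0) {
    stop_usage("tolerances must be >= 0")
  }
  structure(list(complete_overlap_tol = complete_overlap_tol,
                 min_overlap_area = min_overlap_area,
                 mesial_positive_side = match.arg(mesial_positive_side)),
            class = "assignment_config")
}

#' Teeth overlapping a caries detection
#'
#' @param cd A [caries_detection()].
#' @param teeth List of [tooth_detection()] objects.
#' @param min_overlap_area Overlap areas at or below this are dropped.
#' @return A data frame with columns `fdi`, `area` (overlap px^2) and
#'   `index` (position in `teeth`), sorted by decreasing area with ties
#'   broken by ascending FDI.
#' @export
overlapping_teeth <- function(cd, teeth, min_overlap_area = 0) {
  if (!length(teeth)) {
    return(data.frame(fdi = integer(0), area = numeric(0), index = integer(0)))
  }
  area <- vapply(teeth, function(t) intersection_area(cd$box, t$box), numeric(1))
  fdi <- vapply(teeth, function(t) t$fdi, integer(1))
  keep <- area > min_overlap_area
  out <- data.frame(fdi = fdi[keep], area = area[keep],
                    index = which(keep))
  out[order(-out$area, out$fdi), , drop = FALSE]
}

# Horizontal distance from x to the nearest vertical edge of box b.
nearest_edge_distance <- function(x, b) {
  min(abs(x - b[["x_min"]]), abs(x - b[["x_max"]]))
}

#' Assign a caries detection to its affected tooth
#'
#' Applies the three overlap scenarios described above. A lesion that
#' overlaps no tooth box is undetermined (`NA` tooth), which is a value,
#' not an error: it is the expected outcome for lesions at the image edge
#' where the tooth-numbering model detected nothing.
#'
#' @param cd A [caries_detection()].
#' @param teeth List of [tooth_detection()] objects.
#' @param cfg An [assignment_config()].
#' @return A list with `fdi` (integer or `NA`), `scenario` (0 = no overlap,
#'   1, 2 or 3) and `reason` (character).
#' @export
assign_tooth <- function(cd, teeth, cfg = assignment_config()) {
  ov <- overlapping_teeth(cd, teeth, cfg$min_overlap_area)
  if (nrow(ov) == 0L) {
    return(list(fdi = NA_integer_, scenario = 0L, reason = "no overlapping tooth"))
  }
  if (nrow(ov) == 1L) {
    return(list(fdi = ov$fdi[1L], scenario = 1L, reason = "single overlapping tooth"))
  }
  c_area <- box_area(cd$box)
  covered <- ov[ov$area >= (1 - cfg$complete_overlap_tol) * c_area, , drop = FALSE]
  tied <- ov[ov$area == ov$area[1L], , drop = FALSE]
  if (nrow(covered) >= 2L || nrow(tied) >= 2L) {
    cands <- if (nrow(covered) >= 2L) covered else tied
    cx <- (cd$box[["x_min"]] + cd$box[["x_max"]]) / 2
    d <- vapply(cands$index, function(i) nearest_edge_distance(cx, teeth[[i]]$box),
                numeric(1))
    pick <- cands[order(d, cands$fdi), , drop = FALSE][1L, ]
    return(list(fdi = pick$fdi, scenario = 3L,
                reason = "complete/tied overlap resolved by nearest vertical edge"))
  }
  list(fdi = ov$fdi[1L], scenario = 2L, reason = "greatest overlap area")
}

#' Infer the bitewing side from FDI quadrants
#'
#' Quadrants 1 (upper right) and 4 (lower right) vote right; quadrants 2
#' and 3 vote left; a tie or an empty list is unknown.
#'
#' @param teeth List of [tooth_detection()] objects.
#' @return `"left"`, `"right"` or `"unknown"`.
#' @export
infer_side <- function(teeth) {
  if (!length(teeth)) return("unknown")
  q <- vapply(teeth, function(t) t$fdi %/% 10L, integer(1))
  right <- sum(q %in% c(1L, 4L)); left <- sum(q %in% c(2L, 3L))
  if (right > left) "right" else if (left > right) "left" else "unknown"
}

#' Determine the affected surface (mesial or distal)
#'
#' Compares the x-midpoint of the caries box with the x-midpoint of the
#' assigned tooth's box, oriented by the bitewing side: with the default
#' convention, mesial (toward the dental midline) is the +x direction on a
#' right bitewing and the -x direction on a left one.
#'
#' @param cd A [caries_detection()].
#' @param tooth The assigned [tooth_detection()].
#' @param side Bitewing side: `"left"`, `"right"` or `"unknown"`.
#' @param cfg An [assignment_config()].
#' @return `"mesial"`, `"distal"` or `"undetermined"` (unknown side, or
#'   midpoints coincide within 1e-9 px).
#' @export
determine_surface <- function(cd, tooth, side, cfg = assignment_config()) {
  if (side == "unknown") return("undetermined")
  cx <- (cd$box[["x_min"]] + cd$box[["x_max"]]) / 2
  tx <- (tooth$box[["x_min"]] + tooth$box[["x_max"]]) / 2
  if (abs(cx - tx) <= 1e-9) return("undetermined")
  mesial_sign <- if (side == cfg$mesial_positive_side) 1 else -1
  if (sign(cx - tx) == mesial_sign) "mesial" else "distal"
}

#' Diagnose every lesion in a scene
#'
#' Runs [assign_tooth()] and [determine_surface()] over each caries
#' detection. The side is taken from the frame; when the frame side is
#' unknown it is inferred from the tooth FDI quadrants via [infer_side()].
#'
#' @param s A [scene()].
#' @param cfg An [assignment_config()].
#' @return A data frame with one row per lesion, in input order: `image_id`,
#'   `caries_index`, `severity`, `tooth` (FDI or `NA` = undetermined),
#'   `surface` (`mesial`/`distal`/`undetermined`), `scenario`, `reason`.
#'   The surface is always undetermined when the tooth is.
#' @export
diagnose_scene <- function(s, cfg = assignment_config()) {
  side <- s$frame$side
  if (side == "unknown") side <- infer_side(s$teeth)
  n <- length(s$caries)
  out <- data.frame(image_id = rep(s$image_id, n),
                    caries_index = seq_len(n),
                    severity = character(n), tooth = rep(NA_integer_, n),
                    surface = character(n), scenario = integer(n),
                    reason = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cd <- s$caries[[i]]
    asg <- assign_tooth(cd, s$teeth, cfg)
    out$severity[i] <- cd$severity
    out$tooth[i] <- asg$fdi
    out$scenario[i] <- asg$scenario
    out$reason[i] <- asg$reason
    out$surface[i] <- if (is.na(asg$fdi)) {
      "undetermined"
    } else {
      idx <- which(vapply(s$teeth, function(t) t$fdi, integer(1)) == asg$fdi)[1L]
      determine_surface(cd, s$teeth[[idx]], side, cfg)
    }
  }
  out
}

#' Diagnose every scene in an annotation set
#'
#' @param set An [annotation_set()] whose scenes carry tooth detections.
#' @param cfg An [assignment_config()].
#' @return A data frame stacking [diagnose_scene()] over all scenes.
#' @export
diagnose_set <- function(set, cfg = assignment_config()) {
  do.call(rbind, lapply(set$scenes, diagnose_scene, cfg = cfg))
}

#' Human-readable per-image diagnosis report
#'
#' @param diag A diagnosis data frame from [diagnose_scene()].
#' @return A character vector of report lines, one per lesion.
#' @export
format_diagnosis <- function(diag) {
  vapply(seq_len(nrow(diag)), function(i) {
    r <- diag[i, ]
    if (is.na(r$tooth)) {
      sprintf("%s lesion %d: severity %s, tooth undetermined (%s)",
              r$image_id, r$caries_index, r$severity, r$reason)
    } else {
      sprintf("%s lesion %d: severity %s on the %s surface of tooth %d",
              r$image_id, r$caries_index, r$severity, r$surface, r$tooth)
    }
  }, character(1))
}
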