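# Quality control and exam-level aggregation: collapse per-image counts into
# the feature vector the CAPI-score rules consume.

#' Quality-control filter for NVC exams
#'
#' Exams are excluded before analysis when they consist of fewer than
#' `min_images` images (default 8, the standard exclusion threshold for
#' software-analysed capillaroscopies), when they were not calibrated, or
#' when no capillary at all was detected (density and percentages would be
#' undefined). Checks run in that order and the first failure is reported,
#' so each excluded exam carries a single deterministic reason.
#'
#' @param images per-image measurement table (see [read_image_table()]).
#' @param min_images minimum number of images per exam; exams with fewer are
#'   excluded. Configurable for sensitivity analyses; default 8.
#' @return data frame with one row per exam: `exam_id`, `passed` (logical),
#'   `reason` (`"OK"`, `"TOO_FEW_IMAGES"`, `"NOT_CALIBRATED"`,
#'   `"NO_CAPILLARIES"`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_exams = 5, seed = 1))
#' qc_filter(cohort$images)
#' @export
qc_filter <- function(images, min_images = 8) {
  stopifnot(is.numeric(min_images), length(min_images) == 1, min_images >= 1)
  validate_image_table(images)
  ids <- unique(images$exam_id)
  n_img <- tapply(images$image_id, images$exam_id, length)[ids]
  calibrated <- tapply(images$calibrated, images$exam_id, function(x) x[1])[ids]
  total_caps <- tapply(images$n_capillaries, images$exam_id, sum)[ids]
  reason <- rep("OK", length(ids))
  reason[total_caps == 0] <- "NO_CAPILLARIES"
  reason[!calibrated] <- "NOT_CALIBRATED"
  reason[n_img < min_images] <- "TOO_FEW_IMAGES"
  data.frame(
    exam_id = ids,
    passed = reason == "OK",
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-image measurements into exam-level features
#'
#' Produces the feature vector the rule engine consumes, one row per exam:
#'
#' * `density` — capillaries per millimetre. Pooled by default: total
#'   capillaries over total measured width, which weights each image by the
#'   nailfold width it covers. `method = "image_mean"` instead averages the
#'   per-image densities, for sensitivity analyses.
#' * `pct_giant`, `pct_abnormal`, `pct_tortuous` — percentages of the pooled
#'   exam-wide capillary count (never per-image percentages averaged, which
#'   would be unstable for images with few capillaries).
#' * `haemorrhages_present` — `TRUE` when at least one haemorrhage was seen
#'   anywhere in the exam.
#' * `total_capillaries`, `total_width_mm` — the pooled denominators.
#'
#' Exams must have passed QC: at least one capillary and positive total
#' width. Run [qc_filter()] first and subset; an exam violating the
#' precondition raises an error naming it.
#'
#' @inheritParams qc_filter
#' @param method density aggregate: `"pooled"` (default) or `"image_mean"`.
#' @return data frame of exam-level features, one row per exam, in first-
#'   appearance order of `exam_id`.
#' @examples
#' imgs <- data.frame(
#'   exam_id = "E1", image_id = c("i1", "i2"), calibrated = TRUE,
#'   n_capillaries = c(10L, 8L), width_mm = c(1.5, 1.5),
#'   n_giant = 0L, n_abnormal = 0L, n_tortuous = 0L, n_haemorrhages = 0L
#' )
#' aggregate_exams(imgs)$density  # 18 capillaries / 3 mm = 6
#' @export
aggregate_exams <- function(images, method = c("pooled", "image_mean")) {
  method <- match.arg(method)
  validate_image_table(images)
  ids <- unique(images$exam_id)
  f <- factor(images$exam_id, levels = ids)
  total_caps <- as.vector(tapply(images$n_capillaries, f, sum))
  total_width <- as.vector(tapply(images$width_mm, f, sum))
  if (any(total_caps == 0)) {
    stop("exam(s) with zero capillaries cannot be aggregated: ",
         paste(ids[total_caps == 0], collapse = ", "), call. = FALSE)
  }
  density <- if (method == "pooled") {
    total_caps / total_width
  } else {
    as.vector(tapply(images$n_capillaries / images$width_mm, f, mean))
  }
  data.frame(
    exam_id = ids,
    density = density,
    pct_giant = 100 * as.vector(tapply(images$n_giant, f, sum)) / total_caps,
    pct_abnormal = 100 * as.vector(tapply(images$n_abnormal, f, sum)) / total_caps,
    pct_tortuous = 100 * as.vector(tapply(images$n_tortuous, f, sum)) / total_caps,
    haemorrhages_present =
      as.vector(tapply(images$n_haemorrhages, f, sum)) >= 1,
    total_capillaries = as.integer(total_caps),
    total_width_mm = total_width,
    stringsAsFactors = FALSE
  )
}
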