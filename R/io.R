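# Delimited-text IO for the three table kinds the pipeline exchanges:
# per-image measurement tables, per-exam classification tables, and
# three-rater verdict tables. One dialect throughout: comma separator,
# "." decimal mark, UTF-8, header row required.

IMAGE_COLS <- c(
  "exam_id", "image_id", "calibrated", "n_capillaries", "width_mm",
  "n_giant", "n_abnormal", "n_tortuous", "n_haemorrhages"
)

CLASSIFICATION_COLS <- c(
  "exam_id", "density", "pct_giant", "pct_abnormal", "pct_tortuous",
  "haemorrhages_present", "rule1", "rule_stage_or_rule4", "pattern", "trace"
)

VERDICT_COLS <- c("exam_id", "rater_1", "rater_2", "rater_3")

FEATURE_COLS <- c(
  "exam_id", "density", "pct_giant", "pct_abnormal", "pct_tortuous",
  "haemorrhages_present", "total_capillaries", "total_width_mm"
)

#' Read and validate a per-image capillary measurement table
#'
#' The image table is the entry point of the pipeline: one row per NVC image,
#' carrying the raw counts produced by upstream capillary-detection software.
#' Counts (not percentages) are the canonical image-level representation;
#' percentages only exist at exam level after [aggregate_exams()]. A zero
#' haemorrhage count must be recorded explicitly: haemorrhage presence drives
#' the normal vs non-specific rule, so silent missingness is rejected.
#'
#' Required columns: `exam_id`, `image_id`, `calibrated` (0/1, constant
#' within an exam), `n_capillaries`, `width_mm` (millimetres of nailfold
#' imaged, > 0), `n_giant`, `n_abnormal`, `n_tortuous`, `n_haemorrhages`.
#' Morphology counts may not exceed `n_capillaries`.
#'
#' @param path path to a CSV file with the columns above.
#' @return a validated data frame of images, one row per image, grouped by
#'   exam in file order.
#' @seealso [qc_filter()], [aggregate_exams()], [write_image_table()]
#' @export
read_image_table <- function(path) {
  df <- read_csv_checked(path, IMAGE_COLS)
  df$exam_id <- as.character(df$exam_id)
  df$image_id <- as.character(df$image_id)
  for (col in c("calibrated", "n_capillaries", "n_giant", "n_abnormal",
                "n_tortuous", "n_haemorrhages")) {
    df[[col]] <- check_count_col(df, col)
  }
  df$width_mm <- check_numeric_col(df, "width_mm")
  df$calibrated <- df$calibrated == 1L
  validate_image_table(df)
  df
}

#' @rdname read_image_table
#' @param images a data frame as returned by [read_image_table()] or
#'   [generate_cohort()].
#' @export
write_image_table <- function(images, path) {
  validate_image_table(images)
  out <- images[, IMAGE_COLS]
  out$calibrated <- as.integer(out$calibrated)
  write_csv_plain(out, path)
}

#' Validate a per-image measurement table
#'
#' Checks the invariants every image row must satisfy; called by
#' [read_image_table()] and usable directly on in-memory tables. Errors name
#' the offending row and field.
#'
#' @inheritParams write_image_table
#' @return the input, invisibly, if valid.
#' @export
validate_image_table <- function(images) {
  stopifnot(is.data.frame(images))
  missing_cols <- setdiff(IMAGE_COLS, names(images))
  if (length(missing_cols) > 0) {
    stop("image table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fail_row <- function(rows, field, why) {
    stop(sprintf("image table row %d: invalid %s (%s)", rows[1], field, why),
         call. = FALSE)
  }
  for (col in c("n_capillaries", "n_giant", "n_abnormal", "n_tortuous",
                "n_haemorrhages")) {
    bad <- which(is.na(images[[col]]) | images[[col]] < 0)
    if (length(bad) > 0) fail_row(bad, col, "must be a non-negative count")
  }
  bad <- which(is.na(images$width_mm) | images$width_mm <= 0)
  if (length(bad) > 0) fail_row(bad, "width_mm", "must be > 0")
  for (col in c("n_giant", "n_abnormal", "n_tortuous")) {
    bad <- which(images[[col]] > images$n_capillaries)
    if (length(bad) > 0) fail_row(bad, col, "exceeds n_capillaries")
  }
  key <- paste(images$exam_id, images$image_id, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad) > 0) fail_row(bad, "image_id", "duplicated within exam")
  calib_per_exam <- tapply(images$calibrated, images$exam_id,
                           function(x) length(unique(x)))
  if (any(calib_per_exam > 1)) {
    stop("calibrated flag not constant within exam(s): ",
         paste(names(calib_per_exam)[calib_per_exam > 1], collapse = ", "),
         call. = FALSE)
  }
  invisible(images)
}

#' Read or write a classification result table
#'
#' One row per exam: the aggregated feature values the rules consumed, the
#' Rule 1 group, which staging rule decided the final label, the assigned
#' pattern, and the decision trace (semicolon-joined fired-condition labels)
#' for auditability. Writing then re-reading reproduces the table
#' field-for-field.
#'
#' @param results data frame as returned by [classify_exams()].
#' @param path file path.
#' @return `read_classification_table()`: the parsed data frame;
#'   `write_classification_table()`: the path, invisibly.
#' @export
write_classification_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  missing_cols <- setdiff(CLASSIFICATION_COLS, names(results))
  if (length(missing_cols) > 0) {
    stop("classification table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- results[, CLASSIFICATION_COLS]
  out$haemorrhages_present <- as.integer(out$haemorrhages_present)
  write_csv_plain(out, path)
}

#' @rdname write_classification_table
#' @export
read_classification_table <- function(path) {
  df <- read_csv_checked(path, CLASSIFICATION_COLS)
  df$exam_id <- as.character(df$exam_id)
  df$haemorrhages_present <- df$haemorrhages_present == 1L
  for (col in c("rule1", "rule_stage_or_rule4", "pattern", "trace")) {
    df[[col]] <- as.character(df[[col]])
  }
  assert_patterns(df$pattern)
  df
}

#' Read a three-rater verdict table
#'
#' Columns `exam_id`, `rater_1`, `rater_2`, `rater_3`, each verdict one of
#' the five pattern labels or `ungradable`. Exactly three raters per exam:
#' the consensus rule is defined for triples only.
#'
#' @param path file path.
#' @return a validated data frame of verdicts.
#' @seealso [consensus_table()]
#' @export
read_verdict_table <- function(path) {
  df <- read_csv_checked(path, VERDICT_COLS)
  df$exam_id <- as.character(df$exam_id)
  for (col in c("rater_1", "rater_2", "rater_3")) {
    df[[col]] <- as.character(df[[col]])
    assert_patterns(df[[col]], allow_ungradable = TRUE)
  }
  if (anyDuplicated(df$exam_id)) {
    stop("duplicate exam_id in verdict table", call. = FALSE)
  }
  df
}

#' @rdname read_verdict_table
#' @param verdicts a verdict data frame.
#' @export
write_verdict_table <- function(verdicts, path) {
  write_csv_plain(verdicts[, VERDICT_COLS], path)
}

#' Read or write an exam-level feature table
#'
#' One row per exam with the aggregated features the rules consume (see
#' [aggregate_exams()]). On read, percentages are checked to lie in
#' `[0, 100]` and the pooled-density identity
#' `density = total_capillaries / total_width_mm` is verified to within
#' 1e-9 relative tolerance (skipped for tables produced with the
#' `image_mean` density aggregate, where it does not hold by construction).
#'
#' @param features a feature data frame.
#' @param path file path.
#' @param check_pooled verify the pooled-density identity on read.
#' @return `read_feature_table()`: the parsed data frame.
#' @export
read_feature_table <- function(path, check_pooled = TRUE) {
  df <- read_csv_checked(path, FEATURE_COLS)
  df$exam_id <- as.character(df$exam_id)
  for (col in c("density", "pct_giant", "pct_abnormal", "pct_tortuous",
                "total_width_mm")) {
    df[[col]] <- check_numeric_col(df, col)
  }
  df$total_capillaries <- check_count_col(df, "total_capillaries")
  df$haemorrhages_present <- df$haemorrhages_present == 1L
  pcts <- c(df$pct_giant, df$pct_abnormal, df$pct_tortuous)
  if (any(pcts < 0 | pcts > 100) || any(df$density < 0)) {
    stop("feature table out of range: percentages must be in [0, 100] and density >= 0",
         call. = FALSE)
  }
  if (check_pooled && nrow(df) > 0) {
    pooled <- df$total_capillaries / df$total_width_mm
    rel <- abs(df$density - pooled) / pmax(pooled, .Machine$double.eps)
    bad <- which(rel > 1e-9)
    if (length(bad) > 0) {
      stop(sprintf("feature table row %d: density inconsistent with total_capillaries / total_width_mm",
                   bad[1]), call. = FALSE)
    }
  }
  df
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(features, path) {
  out <- features[, FEATURE_COLS]
  out$haemorrhages_present <- as.integer(out$haemorrhages_present)
  write_csv_plain(out, path)
}

# -- internal helpers ---------------------------------------------------------

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(basename(path), ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[, required_cols, drop = FALSE]
}

check_count_col <- function(df, col) {
  x <- df[[col]]
  if (is.character(x)) {
    suppressWarnings(xn <- as.numeric(x))
    bad <- which(is.na(xn) & !is.na(x))
    if (length(bad) > 0) {
      stop(sprintf("image table row %d: invalid %s (not a number: '%s')",
                   bad[1], col, x[bad[1]]), call. = FALSE)
    }
    x <- xn
  }
  bad <- which(!is.na(x) & x != round(x))
  if (length(bad) > 0) {
    stop(sprintf("image table row %d: invalid %s (not an integer)", bad[1], col),
         call. = FALSE)
  }
  as.integer(round(x))
}

check_numeric_col <- function(df, col) {
  x <- df[[col]]
  if (is.character(x)) {
    suppressWarnings(xn <- as.numeric(x))
    bad <- which(is.na(xn) & !is.na(x))
    if (length(bad) > 0) {
      stop(sprintf("image table row %d: invalid %s (not a number: '%s')",
                   bad[1], col, x[bad[1]]), call. = FALSE)
    }
    x <- xn
  }
  as.numeric(x)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
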