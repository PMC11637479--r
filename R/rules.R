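# The CAPI-score decision tree.
#
# Rule 1 splits SSc from non-SSc exams; Rules 2-3 stage SSc exams as early /
# active / late depending on whether density is above or below 5 caps/mm;
# Rule 4 splits the non-SSc side into normal vs non-specific. All comparisons
# use the exact computed feature values with no rounding, and the inequality
# directions are exactly the published ones (inclusive at <=6, >=5, >=10%,
# >=5%, >=33%, <=7%, >=15%, >=20%, >=2%; strict at >10% and at giant
# detection, i.e. pct_giant > 0).

#' Threshold set for the CAPI-score rules
#'
#' All eleven cut-offs of the decision tree in one explicit configuration
#' object. Defaults are the published values; any can be overridden for
#' sensitivity analyses. Units: `caps/mm` for the two density cut-offs,
#' percent of exam-wide capillaries for the rest.
#'
#' * `r1_density_max` (6): Rule 1 fires SSc when density <= this.
#' * `r1_abnormal_gt` (10): Rule 1 fires SSc when abnormal % is strictly
#'   above this. (The third Rule 1 disjunct, giant capillaries detected,
#'   has no tunable cut-off: any giant fires it.)
#' * `r23_density_split` (5): density >= split routes to Rule 2, below it
#'   to Rule 3.
#' * `r2_giant_ge` (10), `r2_abnormal_ge` (5): Rule 2 overrides early to
#'   active at or above these.
#' * `r3_giant_active_ge` (33), `r3_abnormal_active_le` (7): Rule 3's
#'   active override from the late default.
#' * `r3_giant_late_le` (7), `r3_abnormal_late_ge` (15): Rule 3's final
#'   late override, applied last and unconditionally.
#' * `r4_tortuous_ge` (20), `r4_abnormal_ge` (2): Rule 4 fires non-specific
#'   at or above these (haemorrhage presence is the third, threshold-free
#'   disjunct).
#'
#' @param ... named overrides of the defaults listed above.
#' @return an object of class `capi_thresholds` (a named list).
#' @examples
#' capi_thresholds()
#' capi_thresholds(r1_density_max = 7)  # Fast-Track-like density cut-off
#' @export
capi_thresholds <- function(...) {
  th <- list(
    r1_density_max = 6,
    r1_abnormal_gt = 10,
    r23_density_split = 5,
    r2_giant_ge = 10,
    r2_abnormal_ge = 5,
    r3_giant_active_ge = 33,
    r3_abnormal_active_le = 7,
    r3_giant_late_le = 7,
    r3_abnormal_late_ge = 15,
    r4_tortuous_ge = 20,
    r4_abnormal_ge = 2
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(th))
  if (length(bad) > 0) {
    stop("unknown threshold(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  th[names(overrides)] <- overrides
  vals <- unlist(th)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("thresholds must be finite and non-negative", call. = FALSE)
  }
  pct <- vals[!names(vals) %in% c("r1_density_max", "r23_density_split")]
  if (any(pct > 100)) stop("percentage thresholds must be <= 100", call. = FALSE)
  structure(th, class = "capi_thresholds")
}

#' @export
print.capi_thresholds <- function(x, ...) {
  cat("CAPI-score thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a threshold configuration file
#'
#' Flat `key = value` text file mirroring the fields of [capi_thresholds()];
#' omitted keys keep their defaults.
#'
#' @param path file path.
#' @param th a `capi_thresholds` object.
#' @return `read_thresholds()`: a `capi_thresholds` object.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(capi_thresholds())
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("threshold file must contain 'key = value' lines", call. = FALSE)
  }
  vals <- lapply(parts, function(p) as.numeric(trimws(p[2])))
  names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  do.call(capi_thresholds, vals)
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "capi_thresholds"))
  writeLines(sprintf("%s = %.17g", names(th), unlist(th)), path)
  invisible(path)
}

assert_fv <- function(fv) {
  needed <- c("density", "pct_giant", "pct_abnormal", "pct_tortuous",
              "haemorrhages_present")
  missing_f <- setdiff(needed, names(fv))
  if (length(missing_f) > 0) {
    stop("feature vector missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  pcts <- c(fv$pct_giant, fv$pct_abnormal, fv$pct_tortuous)
  if (fv$density < 0 || any(pcts < 0) || any(pcts > 100)) {
    stop("feature vector out of range: density must be >= 0 and percentages in [0, 100]",
         call. = FALSE)
  }
  invisible(fv)
}

#' Rule 1: SSc vs non-SSc
#'
#' An exam is indicative of an SSc pattern whenever capillary density is
#' <= 6 caps/mm, and/or giant capillaries are detected, and/or the proportion
#' of abnormal capillaries is > 10%. Otherwise it is non-SSc. The trace lists
#' every disjunct that fired.
#'
#' @param fv a single exam's feature vector: a list or one-row data frame
#'   with `density`, `pct_giant`, `pct_abnormal`, `pct_tortuous`,
#'   `haemorrhages_present` (see [aggregate_exams()]).
#' @param th a [capi_thresholds()] object.
#' @return list with `group` (`"ssc"` / `"non_ssc"`) and `trace` (character
#'   vector of fired-condition labels, in evaluation order).
#' @examples
#' th <- capi_thresholds()
#' rule1_ssc_vs_nonssc(list(density = 6, pct_giant = 0, pct_abnormal = 0,
#'                          pct_tortuous = 0, haemorrhages_present = FALSE), th)
#' @export
rule1_ssc_vs_nonssc <- function(fv, th = capi_thresholds()) {
  assert_fv(fv)
  trace <- character(0)
  if (fv$density <= th$r1_density_max) trace <- c(trace, "R1_DENSITY_LE_6")
  if (fv$pct_giant > 0) trace <- c(trace, "R1_GIANTS_DETECTED")
  if (fv$pct_abnormal > th$r1_abnormal_gt) trace <- c(trace, "R1_ABNORMAL_GT_10")
  list(group = if (length(trace) > 0) "ssc" else "non_ssc", trace = trace)
}

#' Rules 2-3: stage an SSc exam as early, active or late
#'
#' When density is at or above the 5 caps/mm split, the pattern is SSc-early
#' unless giant capillaries are >= 10% or abnormal capillaries are >= 5%, in
#' which case it is SSc-active (Rule 2). Below the split the pattern starts
#' as SSc-late; it becomes SSc-active if giants are >= 33% or abnormals are
#' <= 7%; yet, regardless of those conditions, it reverts to SSc-late — the
#' final override takes absolute precedence — if giants are <= 7% or
#' abnormals are >= 15% (Rule 3). The trace records the default, override,
#' and final-override firings in evaluation order.
#'
#' The caller must have established SSc membership ([rule1_ssc_vs_nonssc()]);
#' staging a non-SSc vector is a contract error.
#'
#' @inheritParams rule1_ssc_vs_nonssc
#' @return list with `pattern` (`"ssc_early"` / `"ssc_active"` /
#'   `"ssc_late"`), `rule` (`"rule2"` or `"rule3"`), and `trace`.
#' @export
stage_ssc <- function(fv, th = capi_thresholds()) {
  assert_fv(fv)
  r1 <- rule1_ssc_vs_nonssc(fv, th)
  if (r1$group != "ssc") {
    stop("stage_ssc() called on a non-SSc feature vector (Rule 1 did not fire)",
         call. = FALSE)
  }
  if (fv$density >= th$r23_density_split) {
    trace <- character(0)
    if (fv$pct_giant >= th$r2_giant_ge) trace <- c(trace, "R2_ACTIVE_GIANT_GE_10")
    if (fv$pct_abnormal >= th$r2_abnormal_ge) trace <- c(trace, "R2_ACTIVE_ABN_GE_5")
    if (length(trace) > 0) {
      return(list(pattern = "ssc_active", rule = "rule2", trace = trace))
    }
    return(list(pattern = "ssc_early", rule = "rule2", trace = "R2_EARLY_DEFAULT"))
  }
  trace <- "R3_LATE_DEFAULT"
  pattern <- "ssc_late"
  if (fv$pct_giant >= th$r3_giant_active_ge ||
      fv$pct_abnormal <= th$r3_abnormal_active_le) {
    trace <- c(trace, "R3_ACTIVE_OVERRIDE")
    pattern <- "ssc_active"
  }
  if (fv$pct_giant <= th$r3_giant_late_le ||
      fv$pct_abnormal >= th$r3_abnormal_late_ge) {
    trace <- c(trace, "R3_LATE_FINAL_OVERRIDE")
    pattern <- "ssc_late"
  }
  list(pattern = pattern, rule = "rule3", trace = trace)
}

#' Rule 4: normal vs non-specific among non-SSc exams
#'
#' A non-SSc exam is non-specific when one or more of the following hold:
#' tortuosities >= 20%, haemorrhages present, abnormal capillaries >= 2%.
#' Otherwise it is normal. Rule 4 only ever sees exams on the non-SSc side
#' of Rule 1 (which entails density > 6 caps/mm and no giants); calling it
#' on an SSc vector is a contract error.
#'
#' @inheritParams rule1_ssc_vs_nonssc
#' @return list with `pattern` (`"normal"` / `"non_specific"`), `rule`
#'   (`"rule4"`), and `trace`.
#' @export
rule4_normal_vs_nonspecific <- function(fv, th = capi_thresholds()) {
  assert_fv(fv)
  r1 <- rule1_ssc_vs_nonssc(fv, th)
  if (r1$group != "non_ssc") {
    stop("rule4_normal_vs_nonspecific() called on an SSc feature vector",
         call. = FALSE)
  }
  trace <- character(0)
  if (fv$pct_tortuous >= th$r4_tortuous_ge) trace <- c(trace, "R4_TORTUOUS_GE_20")
  if (isTRUE(fv$haemorrhages_present)) trace <- c(trace, "R4_HAEMORRHAGES")
  if (fv$pct_abnormal >= th$r4_abnormal_ge) trace <- c(trace, "R4_ABNORMAL_GE_2")
  if (length(trace) > 0) {
    return(list(pattern = "non_specific", rule = "rule4", trace = trace))
  }
  list(pattern = "normal", rule = "rule4", trace = "R4_NORMAL_DEFAULT")
}

#' CAPI-score: classify one exam's feature vector
#'
#' The full decision tree: Rule 1 first; SSc exams route through the staging
#' rules (2-3), non-SSc exams through Rule 4. Total on valid feature
#' vectors — always returns exactly one of the five pattern labels, together
#' with the concatenated decision trace and the rule that settled the label.
#'
#' @inheritParams rule1_ssc_vs_nonssc
#' @return list with `pattern`, `group`, `rule` (`"rule2"`, `"rule3"` or
#'   `"rule4"`), and `trace` (character vector; fired-condition labels in
#'   evaluation order, never empty).
#' @examples
#' th <- capi_thresholds()
#' fv <- list(density = 5.5, pct_giant = 15, pct_abnormal = 0,
#'            pct_tortuous = 0, haemorrhages_present = FALSE)
#' capi_score(fv, th)$pattern  # giants fire Rule 1; >=10% giants fire Rule 2
#' @export
capi_score <- function(fv, th = capi_thresholds()) {
  r1 <- rule1_ssc_vs_nonssc(fv, th)
  branch <- if (r1$group == "ssc") stage_ssc(fv, th) else
    rule4_normal_vs_nonspecific(fv, th)
  list(pattern = branch$pattern, group = r1$group, rule = branch$rule,
       trace = c(r1$trace, branch$trace))
}

#' Classify a table of exam-level feature vectors
#'
#' Vectorised application of [capi_score()] to a feature table (one row per
#' exam, as produced by [aggregate_exams()]). Returns the classification
#' table written by [write_classification_table()]: features, Rule 1 group,
#' deciding rule, pattern, and the semicolon-joined decision trace.
#'
#' @param features feature data frame (see [aggregate_exams()]).
#' @inheritParams rule1_ssc_vs_nonssc
#' @return data frame with columns `exam_id`, `density`, `pct_giant`,
#'   `pct_abnormal`, `pct_tortuous`, `haemorrhages_present`, `rule1`,
#'   `rule_stage_or_rule4`, `pattern`, `trace`.
#' @export
classify_features <- function(features, th = capi_thresholds()) {
  stopifnot(is.data.frame(features))
  d <- features$density
  g <- features$pct_giant
  a <- features$pct_abnormal
  tt <- features$pct_tortuous
  h <- features$haemorrhages_present
  if (any(d < 0) || any(c(g, a, tt) < 0) || any(c(g, a, tt) > 100)) {
    stop("feature table out of range: density must be >= 0 and percentages in [0, 100]",
         call. = FALSE)
  }

  ssc <- d <= th$r1_density_max | g > 0 | a > th$r1_abnormal_gt
  r2_active <- g >= th$r2_giant_ge | a >= th$r2_abnormal_ge
  r3_active <- g >= th$r3_giant_active_ge | a <= th$r3_abnormal_active_le
  r3_late <- g <= th$r3_giant_late_le | a >= th$r3_abnormal_late_ge
  r4_nonspec <- tt >= th$r4_tortuous_ge | h | a >= th$r4_abnormal_ge

  pattern <- ifelse(
    ssc,
    ifelse(d >= th$r23_density_split,
           ifelse(r2_active, "ssc_active", "ssc_early"),
           ifelse(r3_late, "ssc_late",
                  ifelse(r3_active, "ssc_active", "ssc_late"))),
    ifelse(r4_nonspec, "non_specific", "normal")
  )
  rule <- ifelse(ssc, ifelse(d >= th$r23_density_split, "rule2", "rule3"),
                 "rule4")

  # trace assembled vectorised, in the same evaluation order as capi_score()
  in_r2 <- ssc & d >= th$r23_density_split
  in_r3 <- ssc & d < th$r23_density_split
  trace <- rep("", nrow(features))
  add <- function(trace, cond, label) {
    ifelse(cond, paste(trace, label, sep = ";"), trace)
  }
  trace <- add(trace, d <= th$r1_density_max, "R1_DENSITY_LE_6")
  trace <- add(trace, g > 0, "R1_GIANTS_DETECTED")
  trace <- add(trace, a > th$r1_abnormal_gt, "R1_ABNORMAL_GT_10")
  trace <- add(trace, in_r2 & g >= th$r2_giant_ge, "R2_ACTIVE_GIANT_GE_10")
  trace <- add(trace, in_r2 & a >= th$r2_abnormal_ge, "R2_ACTIVE_ABN_GE_5")
  trace <- add(trace, in_r2 & !r2_active, "R2_EARLY_DEFAULT")
  trace <- add(trace, in_r3, "R3_LATE_DEFAULT")
  trace <- add(trace, in_r3 & r3_active, "R3_ACTIVE_OVERRIDE")
  trace <- add(trace, in_r3 & r3_late, "R3_LATE_FINAL_OVERRIDE")
  trace <- add(trace, !ssc & tt >= th$r4_tortuous_ge, "R4_TORTUOUS_GE_20")
  trace <- add(trace, !ssc & h, "R4_HAEMORRHAGES")
  trace <- add(trace, !ssc & a >= th$r4_abnormal_ge, "R4_ABNORMAL_GE_2")
  trace <- add(trace, !ssc & !r4_nonspec, "R4_NORMAL_DEFAULT")
  trace <- sub("^;", "", trace)

  exam_id <- if (is.null(features$exam_id)) {
    as.character(seq_len(nrow(features)))
  } else {
    as.character(features$exam_id)
  }
  data.frame(
    exam_id = exam_id,
    density = d, pct_giant = g, pct_abnormal = a, pct_tortuous = tt,
    haemorrhages_present = h,
    rule1 = ifelse(ssc, "ssc", "non_ssc"),
    rule_stage_or_rule4 = rule,
    pattern = pattern,
    trace = trace,
    stringsAsFactors = FALSE
  )
}

#' Classify exams straight from a per-image measurement table
#'
#' Convenience wrapper: QC-filter, aggregate, then classify. Exams failing
#' QC are dropped (retrievable via [qc_filter()]).
#'
#' @inheritParams qc_filter
#' @inheritParams rule1_ssc_vs_nonssc
#' @param method density aggregate, passed to [aggregate_exams()].
#' @return classification data frame (see [classify_features()]).
#' @export
classify_exams <- function(images, th = capi_thresholds(), min_images = 8,
                           method = "pooled") {
  qc <- qc_filter(images, min_images = min_images)
  keep <- qc$exam_id[qc$passed]
  classify_features(
    aggregate_exams(images[images$exam_id %in% keep, , drop = FALSE],
                    method = method),
    th
  )
}
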