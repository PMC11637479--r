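# Diagnostic-accuracy evaluation: confusion matrices with per-class
# precision (PPV) and recall (sensitivity), and accuracy, computed per
# algorithm step and overall on any paired (gold standard, prediction)
# dataset.

EVAL_STEPS <- c("rule1_binary", "ssc_staging", "nonssc_split", "overall_5class")

#' Confusion matrix of true vs predicted labels
#'
#' Rows are true labels, columns predicted labels, in the order of `labels`;
#' cell (t, p) counts the exams with truth t and prediction p.
#'
#' @param truth,predicted equal-length vectors of labels drawn from `labels`.
#' @param labels ordered label set defining the matrix dimensions.
#' @return an integer matrix with `dimnames = list(true = labels,
#'   predicted = labels)`.
#' @examples
#' confusion_matrix(c("ssc", "ssc", "non_ssc"), c("ssc", "non_ssc", "non_ssc"),
#'                  labels = c("ssc", "non_ssc"))
#' @export
confusion_matrix <- function(truth, predicted, labels) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad) > 0) {
    stop("label(s) outside the declared label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(truth, levels = labels), factor(predicted, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

eval_metrics <- function(m) {
  n <- sum(m)
  diag_m <- diag(m)
  col_tot <- colSums(m)
  row_tot <- rowSums(m)
  # undefined denominators (class absent from predictions / from truth)
  # reported as NA, never silently 0, and excluded from any averaging
  precision <- ifelse(col_tot > 0, diag_m / col_tot, NA_real_)
  recall <- ifelse(row_tot > 0, diag_m / row_tot, NA_real_)
  accuracy <- if (n > 0) sum(diag_m) / n else NA_real_
  list(precision = precision, recall = recall, accuracy = accuracy, n = n)
}

#' Evaluate one algorithm step against the gold standard
#'
#' Reproduces the stepwise evaluation protocol on a paired dataset of
#' gold-standard and predicted patterns (joined on `exam_id`):
#'
#' * `"rule1_binary"` — both sides mapped through [pattern_group()] and
#'   compared as SSc vs non-SSc over all paired exams.
#' * `"ssc_staging"` — restricted to exams whose *gold* label is an SSc
#'   pattern; early vs active vs late compared. Restriction is by gold
#'   label, so an exam the algorithm routed to the wrong side of Rule 1 is
#'   excluded from staging metrics rather than counted as a staging error.
#' * `"nonssc_split"` — restricted to exams whose gold label is non-SSc;
#'   normal vs non-specific compared.
#' * `"overall_5class"` — all five patterns on all paired exams.
#'
#' @param gold data frame with `exam_id` and `pattern` (gold standard, e.g.
#'   from [gold_standard_cohort()] or a simulated ground truth).
#' @param pred data frame with `exam_id` and `pattern` (predictions; a
#'   [classify_exams()] result works as-is).
#' @param step one of `"rule1_binary"`, `"ssc_staging"`, `"nonssc_split"`,
#'   `"overall_5class"`.
#' @return an object of class `capi_eval`: list with `step`, `labels`,
#'   `matrix` (rows = true, columns = predicted), `precision`, `recall`
#'   (named per-class vectors, `NA` where undefined), `accuracy`, `n`.
#' @seealso [evaluate_all()]
#' @export
step_evaluation <- function(gold, pred, step = EVAL_STEPS) {
  step <- match.arg(step)
  paired <- pair_by_exam(gold, pred)
  truth <- paired$gold
  predicted <- paired$pred
  if (step == "rule1_binary") {
    labels <- c("non_ssc", "ssc")
    truth <- pattern_group(truth)
    predicted <- pattern_group(predicted)
  } else if (step == "ssc_staging") {
    labels <- c("ssc_early", "ssc_active", "ssc_late")
    keep <- pattern_group(truth) == "ssc"
    truth <- truth[keep]
    predicted <- predicted[keep]
  } else if (step == "nonssc_split") {
    labels <- c("normal", "non_specific")
    keep <- pattern_group(truth) == "non_ssc"
    truth <- truth[keep]
    predicted <- predicted[keep]
  } else {
    labels <- capi_patterns()
  }
  n_gold_restricted <- length(truth)
  # a prediction on the other side of Rule 1 falls outside the step's label
  # set; such exams are excluded from the restricted comparison rather than
  # counted as staging/split errors
  if (step %in% c("ssc_staging", "nonssc_split")) {
    keep <- predicted %in% labels
    truth <- truth[keep]
    predicted <- predicted[keep]
  }
  m <- confusion_matrix(truth, predicted, labels)
  met <- eval_metrics(m)
  structure(
    list(step = step, labels = labels, matrix = m,
         precision = met$precision, recall = met$recall,
         accuracy = met$accuracy, n = met$n,
         n_gold_restricted = n_gold_restricted),
    class = "capi_eval"
  )
}

#' @export
print.capi_eval <- function(x, ...) {
  cat(sprintf("CAPI-score evaluation — step: %s (n = %d)\n", x$step, x$n))
  print(x$matrix)
  if (x$n > 0) {
    tab <- data.frame(precision = round(x$precision, 3),
                      recall = round(x$recall, 3))
    print(tab)
    cat(sprintf("accuracy: %.3f\n", x$accuracy))
  } else {
    cat("no paired exams in this step; metrics undefined\n")
  }
  invisible(x)
}

#' Run all four evaluation steps
#'
#' @inheritParams step_evaluation
#' @return named list of `capi_eval` objects, one per step.
#' @export
evaluate_all <- function(gold, pred) {
  stats::setNames(
    lapply(EVAL_STEPS, function(s) step_evaluation(gold, pred, s)),
    EVAL_STEPS
  )
}

#' Flatten evaluation reports into a metrics table
#'
#' One row per step x class (precision / recall) plus one accuracy row per
#' step; the machine-readable companion of the printed reports.
#'
#' @param reports a single `capi_eval` or a list of them (see
#'   [evaluate_all()]).
#' @return data frame with columns `step`, `class`, `metric`, `value`, `n`.
#' @export
evaluation_metrics_table <- function(reports) {
  if (inherits(reports, "capi_eval")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    rbind(
      data.frame(step = r$step, class = r$labels, metric = "precision",
                 value = unname(r$precision), n = r$n),
      data.frame(step = r$step, class = r$labels, metric = "recall",
                 value = unname(r$recall), n = r$n),
      data.frame(step = r$step, class = "(all)", metric = "accuracy",
                 value = r$accuracy, n = r$n)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pair_by_exam <- function(gold, pred) {
  stopifnot(is.data.frame(gold), is.data.frame(pred),
            all(c("exam_id", "pattern") %in% names(gold)),
            all(c("exam_id", "pattern") %in% names(pred)))
  assert_patterns(gold$pattern)
  assert_patterns(pred$pattern)
  merged <- merge(gold[, c("exam_id", "pattern")],
                  pred[, c("exam_id", "pattern")],
                  by = "exam_id", suffixes = c("_gold", "_pred"))
  if (nrow(merged) == 0) {
    stop("no exams shared between gold standard and predictions", call. = FALSE)
  }
  list(exam_id = merged$exam_id, gold = merged$pattern_gold,
       pred = merged$pattern_pred)
}
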