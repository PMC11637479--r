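# Independent oracles, written directly from the published rule sentences
# and from first principles, deliberately separate from the package's
# threshold-table engine and matrix-based metric code.

# Naive nested-conditional transcription of the four rules. Scalar.
naive_capi_oracle <- function(density, pct_giant, pct_abnormal, pct_tortuous,
                              haemorrhages_present) {
  # Rule 1: SSc whenever density <= 6 and/or giants detected and/or
  # abnormal > 10%
  if (density <= 6 || pct_giant > 0 || pct_abnormal > 10) {
    if (density >= 5) {
      # Rule 2: early unless giants >= 10% or abnormals >= 5% (then active)
      if (pct_giant >= 10 || pct_abnormal >= 5) "ssc_active" else "ssc_early"
    } else {
      # Rule 3: initially late; active if giants >= 33% or abnormals <= 7%;
      # yet, regardless of these conditions, late if giants <= 7% or
      # abnormals >= 15%
      out <- "ssc_late"
      if (pct_giant >= 33 || pct_abnormal <= 7) out <- "ssc_active"
      if (pct_giant <= 7 || pct_abnormal >= 15) out <- "ssc_late"
      out
    }
  } else {
    # Rule 4: non-specific when tortuosities >= 20% or haemorrhages present
    # or abnormals >= 2%; otherwise normal
    if (pct_tortuous >= 20 || haemorrhages_present || pct_abnormal >= 2) {
      "non_specific"
    } else {
      "normal"
    }
  }
}

# Brute-force consensus oracle: tally the most frequent label and its
# multiplicity.
tally_consensus_oracle <- function(verdicts) {
  tab <- sort(table(verdicts), decreasing = TRUE)
  if (tab[1] == 3) {
    list(outcome = names(tab)[1], level = "full")
  } else if (tab[1] == 2) {
    list(outcome = names(tab)[1], level = "majority")
  } else {
    list(outcome = "no_consensus", level = "none")
  }
}

# Loop-based metric oracle: counts matches and per-class tallies directly,
# no matrix algebra.
loop_metrics_oracle <- function(truth, predicted, labels) {
  n <- length(truth)
  acc <- if (n > 0) sum(truth == predicted) / n else NA_real_
  precision <- recall <- stats::setNames(rep(NA_real_, length(labels)), labels)
  for (lab in labels) {
    n_pred <- sum(predicted == lab)
    n_true <- sum(truth == lab)
    n_hit <- sum(truth == lab & predicted == lab)
    if (n_pred > 0) precision[lab] <- n_hit / n_pred
    if (n_true > 0) recall[lab] <- n_hit / n_true
  }
  list(accuracy = acc, precision = precision, recall = recall)
}

# Grid of feature vectors spanning all printed thresholds with +/- 1e-9
# refinement at every boundary.
threshold_grid <- function(eps = 1e-9) {
  around <- function(x) c(x - eps, x, x + eps)
  densities <- sort(unique(c(0, 0.5, 1:4, 4.5, around(5), 5.5, around(6),
                             7, 8, 9, 10, 11, 12)))
  abnormals <- sort(unique(c(0, 1, around(2), 3, around(5), 6, around(7),
                             around(10), 12, around(15), 20, 50, 100)))
  giants <- sort(unique(c(0, eps, 1, 5, around(7), 9, around(10), 20,
                          around(33), 50, 100)))
  tortuous <- sort(unique(c(0, 10, 19.9, around(20), 30, 100)))
  expand.grid(density = densities, pct_giant = giants,
              pct_abnormal = abnormals, pct_tortuous = tortuous,
              haemorrhages_present = c(FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE)
}

# Small valid image table used across IO / aggregation tests.
make_images <- function(exam_id = "E1", n = 8, caps = 10, width = 1.5,
                        giant = 0, abnormal = 0, tortuous = 0, haem = 0,
                        calibrated = TRUE) {
  data.frame(
    exam_id = exam_id,
    image_id = sprintf("%s_i%02d", exam_id, seq_len(n)),
    calibrated = calibrated,
    n_capillaries = as.integer(rep_len(caps, n)),
    width_mm = rep_len(width, n),
    n_giant = as.integer(rep_len(giant, n)),
    n_abnormal = as.integer(rep_len(abnormal, n)),
    n_tortuous = as.integer(rep_len(tortuous, n)),
    n_haemorrhages = as.integer(rep_len(haem, n)),
    stringsAsFactors = FALSE
  )
}

fv <- function(density, pct_giant = 0, pct_abnormal = 0, pct_tortuous = 0,
               haemorrhages_present = FALSE) {
  list(density = density, pct_giant = pct_giant, pct_abnormal = pct_abnormal,
       pct_tortuous = pct_tortuous, haemorrhages_present = haemorrhages_present)
}
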