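# Gold-standard derivation from three blinded rater verdicts: majority vote
# with >= 2/3 agreement, full consensus when all three agree.

#' Derive the consensus verdict from three rater verdicts
#'
#' Consensus occurs when at least 2 of the 3 blinded raters agree on a
#' verdict; agreement of all three is full consensus. `ungradable`
#' participates in the vote as an ordinary label (a 2-vote ungradable
#' majority is an ungradable consensus, excluded from pattern analysis
#' downstream). When all three verdicts differ there is no consensus.
#'
#' @param verdicts character vector of exactly three verdicts, each one of
#'   [capi_verdicts()].
#' @return list with `outcome` (the majority verdict, or `"no_consensus"`)
#'   and `level` (`"full"`, `"majority"`, `"none"`).
#' @examples
#' derive_consensus(c("ssc_early", "ssc_early", "ssc_active"))
#' derive_consensus(c("normal", "ssc_early", "ssc_late"))
#' @export
derive_consensus <- function(verdicts) {
  if (length(verdicts) != 3) {
    stop("exactly three rater verdicts are required, got ", length(verdicts),
         call. = FALSE)
  }
  assert_patterns(verdicts, allow_ungradable = TRUE)
  if (verdicts[1] == verdicts[2] && verdicts[2] == verdicts[3]) {
    return(list(outcome = verdicts[1], level = "full"))
  }
  if (verdicts[1] == verdicts[2] || verdicts[1] == verdicts[3]) {
    return(list(outcome = verdicts[1], level = "majority"))
  }
  if (verdicts[2] == verdicts[3]) {
    return(list(outcome = verdicts[2], level = "majority"))
  }
  list(outcome = "no_consensus", level = "none")
}

#' Consensus over a verdict table
#'
#' Applies [derive_consensus()] to every exam of a three-rater verdict table.
#'
#' @param verdicts data frame with columns `exam_id`, `rater_1`, `rater_2`,
#'   `rater_3` (see [read_verdict_table()]).
#' @return data frame with `exam_id`, `outcome`, `level`.
#' @export
consensus_table <- function(verdicts) {
  stopifnot(is.data.frame(verdicts))
  missing_cols <- setdiff(VERDICT_COLS, names(verdicts))
  if (length(missing_cols) > 0) {
    stop("verdict table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- lapply(seq_len(nrow(verdicts)), function(i) {
    derive_consensus(c(verdicts$rater_1[i], verdicts$rater_2[i],
                       verdicts$rater_3[i]))
  })
  data.frame(
    exam_id = as.character(verdicts$exam_id),
    outcome = vapply(res, `[[`, "", "outcome"),
    level = vapply(res, `[[`, "", "level"),
    stringsAsFactors = FALSE
  )
}

#' Gold-standard cohort from consensus results
#'
#' Restricts a consensus table to the exams that enter pattern analysis:
#' exams without consensus and exams whose consensus verdict is
#' `ungradable` are excluded. With `include_full_only = TRUE` only exams
#' whose verdict achieved full (3/3) consensus are retained, mirroring the
#' stricter gold standard used to re-assess performance.
#'
#' @param consensus data frame as returned by [consensus_table()].
#' @param include_full_only keep only full-consensus exams. Default `FALSE`
#'   (any >= 2/3 consensus).
#' @return data frame with `exam_id` and `pattern` (gold-standard label,
#'   one of [capi_patterns()]).
#' @export
gold_standard_cohort <- function(consensus, include_full_only = FALSE) {
  stopifnot(is.data.frame(consensus),
            all(c("exam_id", "outcome", "level") %in% names(consensus)))
  keep <- !consensus$outcome %in% c("no_consensus", "ungradable")
  if (include_full_only) keep <- keep & consensus$level == "full"
  out <- consensus[keep, c("exam_id", "outcome")]
  names(out) <- c("exam_id", "pattern")
  rownames(out) <- NULL
  assert_patterns(out$pattern)
  out
}
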