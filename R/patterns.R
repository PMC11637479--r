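#' Disease pattern and verdict vocabularies
#'
#' NVC disease patterns follow the five EULAR categories: `normal`,
#' `non_specific`, and the three stages of scleroderma microangiopathy
#' `ssc_early`, `ssc_active`, `ssc_late`. Raters may additionally return
#' `ungradable` when image quality precludes assignment; `ungradable` is a
#' valid rater verdict (and consensus outcome) but never an output of the
#' rule engine.
#'
#' @return `capi_patterns()`: character vector of the five pattern labels,
#'   in disease-severity order. `capi_verdicts()`: the five patterns plus
#'   `"ungradable"`.
#' @examples
#' capi_patterns()
#' capi_verdicts()
#' @export
capi_patterns <- function() {
  c("normal", "non_specific", "ssc_early", "ssc_active", "ssc_late")
}

#' @rdname capi_patterns
#' @export
capi_verdicts <- function() {
  c(capi_patterns(), "ungradable")
}

#' Map patterns to the SSc / non-SSc binary grouping
#'
#' The first CAPI-score rule discriminates scleroderma-pattern exams from the
#' rest: `ssc_early`, `ssc_active` and `ssc_late` form the `ssc` group,
#' `normal` and `non_specific` the `non_ssc` group.
#'
#' @param pattern character vector of pattern labels (see [capi_patterns()]).
#' @return character vector of the same length with values `"ssc"` /
#'   `"non_ssc"`.
#' @examples
#' pattern_group(c("normal", "ssc_late"))
#' @export
pattern_group <- function(pattern) {
  assert_patterns(pattern)
  ifelse(pattern %in% c("ssc_early", "ssc_active", "ssc_late"), "ssc", "non_ssc")
}

assert_patterns <- function(pattern, allow_ungradable = FALSE) {
  allowed <- if (allow_ungradable) capi_verdicts() else capi_patterns()
  bad <- setdiff(unique(pattern), allowed)
  if (length(bad) > 0) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(pattern)
}
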