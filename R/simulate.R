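# Seedable synthetic-cohort generator. Emulates the structure of a
# multi-centre NVC cohort — per-exam image counts, per-image nailfold widths,
# per-image capillary counts and morphology counts, three blinded rater
# verdicts — with known ground-truth patterns, so classification, consensus
# and evaluation can be exercised end to end without clinical data. All
# feature distributions are synthetic presets, not estimates of any
# clinical dataset.

#' Per-pattern generating profile
#'
#' Describes how exams of one disease pattern are simulated: a latent
#' exam-level capillary density (truncated-at-zero normal, caps/mm), marginal
#' per-capillary probabilities of being giant / abnormal / tortuous, and a
#' per-image haemorrhage intensity (expected haemorrhages per image, Poisson).
#'
#' @param pattern one of [capi_patterns()].
#' @param density_mean,density_sd latent exam density, caps/mm.
#' @param giant_rate,abnormal_rate,tortuous_rate per-capillary probabilities
#'   in `[0, 1]`.
#' @param haemorrhage_rate expected haemorrhages per image, >= 0.
#' @return an object of class `pattern_profile`.
#' @seealso [capi_preset()]
#' @export
pattern_profile <- function(pattern, density_mean, density_sd,
                            giant_rate = 0, abnormal_rate = 0,
                            tortuous_rate = 0, haemorrhage_rate = 0) {
  assert_patterns(pattern)
  rates <- c(giant_rate, abnormal_rate, tortuous_rate)
  stopifnot(density_mean > 0, density_sd >= 0,
            all(rates >= 0), all(rates <= 1), haemorrhage_rate >= 0)
  structure(
    list(pattern = pattern, density_mean = density_mean,
         density_sd = density_sd, giant_rate = giant_rate,
         abnormal_rate = abnormal_rate, tortuous_rate = tortuous_rate,
         haemorrhage_rate = haemorrhage_rate),
    class = "pattern_profile"
  )
}

#' Named simulation presets
#'
#' Two profile sets ship with the package:
#'
#' * `"separable"` — each pattern's feature distribution is concentrated
#'   well inside its rule region, so the classifier recovers the generating
#'   pattern almost surely. Used for closed-loop correctness testing.
#' * `"overlapping"` — means pulled toward the decision cut-offs, so
#'   patterns straddle thresholds and the confusion matrix is non-trivial.
#'   Used to exercise the evaluation pipeline.
#'
#' Both are synthetic by construction: they are chosen from the geometry of
#' the rules, not fitted to clinical feature distributions.
#'
#' @param name `"separable"` or `"overlapping"`.
#' @return named list of five [pattern_profile()] objects, one per pattern.
#' @export
capi_preset <- function(name = c("separable", "overlapping")) {
  name <- match.arg(name)
  if (name == "separable") {
    list(
      normal = pattern_profile("normal", 9.5, 0.8,
                               abnormal_rate = 0.002, tortuous_rate = 0.03),
      non_specific = pattern_profile("non_specific", 9.5, 0.8,
                                     abnormal_rate = 0.002,
                                     tortuous_rate = 0.35,
                                     haemorrhage_rate = 0.5),
      ssc_early = pattern_profile("ssc_early", 6.5, 0.3,
                                  giant_rate = 0.02, abnormal_rate = 0.01,
                                  tortuous_rate = 0.05,
                                  haemorrhage_rate = 0.1),
      ssc_active = pattern_profile("ssc_active", 5.5, 0.5,
                                   giant_rate = 0.20, abnormal_rate = 0.02,
                                   tortuous_rate = 0.05,
                                   haemorrhage_rate = 0.3),
      ssc_late = pattern_profile("ssc_late", 3.0, 0.5,
                                 giant_rate = 0.02, abnormal_rate = 0.25,
                                 tortuous_rate = 0.10,
                                 haemorrhage_rate = 0.2)
    )
  } else {
    list(
      normal = pattern_profile("normal", 7.5, 1.2,
                               abnormal_rate = 0.012, tortuous_rate = 0.15,
                               haemorrhage_rate = 0.02),
      non_specific = pattern_profile("non_specific", 7.5, 1.2,
                                     abnormal_rate = 0.025,
                                     tortuous_rate = 0.22,
                                     haemorrhage_rate = 0.1),
      ssc_early = pattern_profile("ssc_early", 5.5, 0.8,
                                  giant_rate = 0.05, abnormal_rate = 0.04,
                                  tortuous_rate = 0.08,
                                  haemorrhage_rate = 0.1),
      ssc_active = pattern_profile("ssc_active", 5.0, 0.8,
                                   giant_rate = 0.12, abnormal_rate = 0.08,
                                   tortuous_rate = 0.08,
                                   haemorrhage_rate = 0.2),
      ssc_late = pattern_profile("ssc_late", 4.0, 0.8,
                                 giant_rate = 0.05, abnormal_rate = 0.12,
                                 tortuous_rate = 0.10,
                                 haemorrhage_rate = 0.2)
    )
  }
}

#' Cohort simulation configuration
#'
#' Defaults emulate the reported cohort scale: 881 consensual exams with
#' pattern mix 231:326:162:122:40 (normal : non-specific : early : active :
#' late), 24.8 (s.d. 9.9) images per exam truncated at 8, and per-image
#' widths of 1.76 (s.d. 0.3) mm so the expected per-exam imaged width is
#' about 43.7 mm.
#'
#' @param n_exams number of exams to simulate (default 881).
#' @param pattern_mix proportions (or counts, normalised internally) over
#'   the five patterns, in [capi_patterns()] order.
#' @param images_per_exam_mean,images_per_exam_sd normal image count per
#'   exam, truncated at `min_images_sim` and rounded.
#' @param min_images_sim lower truncation of the image count (default 8, so
#'   every generated exam passes the default QC).
#' @param width_mm_mean,width_mm_sd per-image imaged nailfold width, mm
#'   (truncated > 0).
#' @param profiles named list of five [pattern_profile()]s (default
#'   `capi_preset("separable")`).
#' @param rater_error_rate probability a simulated rater misreports the true
#'   pattern into an adjacent one (default 0.2).
#' @param ungradable_rate probability a rater returns `ungradable` instead
#'   of grading (default 0).
#' @param qc_violation_rate fraction of exams with deliberately injected QC
#'   failures (too few images or missing calibration; default 0).
#' @param seed integer seed making the cohort fully reproducible.
#' @return an object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_exams = 881,
                          pattern_mix = c(231, 326, 162, 122, 40),
                          images_per_exam_mean = 24.8,
                          images_per_exam_sd = 9.9,
                          min_images_sim = 8,
                          width_mm_mean = 1.76,
                          width_mm_sd = 0.3,
                          profiles = capi_preset("separable"),
                          rater_error_rate = 0.2,
                          ungradable_rate = 0,
                          qc_violation_rate = 0,
                          seed = 1L) {
  stopifnot(n_exams >= 1, length(pattern_mix) == 5, all(pattern_mix >= 0),
            sum(pattern_mix) > 0, images_per_exam_mean > 0,
            images_per_exam_sd >= 0, min_images_sim >= 1, width_mm_mean > 0,
            width_mm_sd >= 0, rater_error_rate >= 0, rater_error_rate <= 1,
            ungradable_rate >= 0, ungradable_rate <= 1,
            qc_violation_rate >= 0, qc_violation_rate <= 1)
  if (!setequal(names(profiles), capi_patterns())) {
    stop("profiles must be a named list with one profile per pattern",
         call. = FALSE)
  }
  structure(
    list(n_exams = as.integer(n_exams),
         pattern_mix = stats::setNames(pattern_mix / sum(pattern_mix),
                                       capi_patterns()),
         images_per_exam_mean = images_per_exam_mean,
         images_per_exam_sd = images_per_exam_sd,
         min_images_sim = min_images_sim,
         width_mm_mean = width_mm_mean,
         width_mm_sd = width_mm_sd,
         profiles = profiles[capi_patterns()],
         rater_error_rate = rater_error_rate,
         ungradable_rate = ungradable_rate,
         qc_violation_rate = qc_violation_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# truncated-normal draw by rejection; sd = 0 degenerates to the mean
rtruncnorm_min <- function(n, mean, sd, min) {
  if (sd == 0) return(pmax(rep(mean, n), min))
  x <- stats::rnorm(n, mean, sd)
  repeat {
    bad <- which(x < min)
    if (length(bad) == 0) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
}

# vectorised image-level generation shared by generate_exam / generate_cohort;
# exam_idx maps each image to its exam
gen_image_rows <- function(exam_idx, latent_density, giant_rate,
                           abnormal_rate, tortuous_rate, haemorrhage_rate,
                           config) {
  n_img <- length(exam_idx)
  width <- rtruncnorm_min(n_img, config$width_mm_mean, config$width_mm_sd,
                          min = 0.05)
  caps <- stats::rpois(n_img, latent_density[exam_idx] * width)
  data.frame(
    n_capillaries = caps,
    width_mm = width,
    n_giant = stats::rbinom(n_img, caps, giant_rate[exam_idx]),
    n_abnormal = stats::rbinom(n_img, caps, abnormal_rate[exam_idx]),
    n_tortuous = stats::rbinom(n_img, caps, tortuous_rate[exam_idx]),
    n_haemorrhages = stats::rpois(n_img, haemorrhage_rate[exam_idx])
  )
}

#' Generate one synthetic NVC exam
#'
#' Draws the image count (truncated normal), per-image widths, per-image
#' capillary counts (Poisson with mean latent density x width), morphology
#' counts (binomial with the profile's per-capillary probabilities) and
#' haemorrhage counts (Poisson with the profile's per-image intensity).
#' Uses the current RNG state; seed with [set.seed()] or use
#' [generate_cohort()] for a fully reproducible cohort.
#'
#' @param profile a [pattern_profile()].
#' @param config a [cohort_config()] (image-count and width settings are
#'   used; the seed field is not consumed here).
#' @param exam_id identifier for the generated exam.
#' @return list with `images` (a per-image measurement data frame) and
#'   `pattern` (the generating ground-truth pattern).
#' @export
generate_exam <- function(profile, config = cohort_config(),
                          exam_id = "SIM1") {
  stopifnot(inherits(profile, "pattern_profile"),
            inherits(config, "cohort_config"))
  n_images <- round(rtruncnorm_min(1, config$images_per_exam_mean,
                                   config$images_per_exam_sd,
                                   config$min_images_sim))
  latent <- rtruncnorm_min(1, profile$density_mean, profile$density_sd, 0)
  rows <- gen_image_rows(rep(1L, n_images), latent, profile$giant_rate,
                         profile$abnormal_rate, profile$tortuous_rate,
                         profile$haemorrhage_rate, config)
  images <- cbind(
    data.frame(exam_id = exam_id,
               image_id = sprintf("%s_img%03d", exam_id, seq_len(n_images)),
               calibrated = TRUE, stringsAsFactors = FALSE),
    rows
  )
  list(images = images[, IMAGE_COLS], pattern = profile$pattern)
}

#' Simulate three blinded rater verdicts for one true pattern
#'
#' Each rater independently returns `ungradable` with probability
#' `ungradable_rate`; otherwise reports the true pattern with probability
#' `1 - rater_error_rate`, and with probability `rater_error_rate` a
#' uniformly chosen *adjacent* pattern along the severity chain
#' normal - non-specific - SSc-early - SSc-active - SSc-late (rater
#' discrepancies concentrate between neighbouring patterns).
#'
#' @param true_pattern one of [capi_patterns()].
#' @param rater_error_rate probability of an adjacent-pattern misreport.
#' @param ungradable_rate probability of an `ungradable` verdict.
#' @return character vector of three verdicts.
#' @export
generate_verdicts <- function(true_pattern, rater_error_rate = 0.2,
                              ungradable_rate = 0) {
  assert_patterns(true_pattern)
  stopifnot(length(true_pattern) == 1)
  chain <- capi_patterns()
  pos <- match(true_pattern, chain)
  neighbours <- chain[c(pos - 1, pos + 1)]
  neighbours <- neighbours[!is.na(neighbours)]
  vapply(1:3, function(i) {
    if (stats::runif(1) < ungradable_rate) return("ungradable")
    if (stats::runif(1) < rater_error_rate) {
      return(sample(neighbours, 1))
    }
    true_pattern
  }, "")
}

#' Generate a full synthetic cohort
#'
#' Draws `n_exams` ground-truth patterns from the configured pattern mix,
#' simulates each exam's image table and its three rater verdicts, and
#' returns the three linked tables. Fully reproducible: the configuration's
#' seed initialises the RNG, and identical configurations yield identical
#' tables. With `qc_violation_rate > 0`, the flagged fraction of exams is
#' deliberately spoiled (truncated below the QC image minimum, or marked
#' uncalibrated) to exercise the QC filter.
#'
#' @param config a [cohort_config()].
#' @return list of class `capi_cohort` with elements `images` (per-image
#'   measurement table), `verdicts` (three-rater verdict table), `truth`
#'   (`exam_id`, `pattern`, `qc_spoiled`), and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_exams = 20, seed = 42))
#' table(cohort$truth$pattern)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_exams
  exam_id <- sprintf("SIM%05d", seq_len(n))
  pattern <- sample(capi_patterns(), n, replace = TRUE,
                    prob = config$pattern_mix)

  n_images <- round(rtruncnorm_min(n, config$images_per_exam_mean,
                                   config$images_per_exam_sd,
                                   config$min_images_sim))
  spoiled <- stats::runif(n) < config$qc_violation_rate
  uncalibrated <- rep(FALSE, n)
  if (any(spoiled)) {
    # half the spoiled exams lose images below the QC minimum, half lose
    # calibration
    mode_flip <- stats::runif(sum(spoiled)) < 0.5
    n_images[spoiled][mode_flip] <-
      sample(seq_len(max(config$min_images_sim - 1, 1)),
             sum(mode_flip), replace = TRUE)
    uncalibrated[spoiled][!mode_flip] <- TRUE
  }

  prof_field <- function(field) {
    vapply(config$profiles, `[[`, 0, field)[pattern]
  }
  latent <- stats::rnorm(n, prof_field("density_mean"),
                         prof_field("density_sd"))
  repeat {
    bad <- which(latent < 0)
    if (length(bad) == 0) break
    latent[bad] <- stats::rnorm(length(bad), prof_field("density_mean")[bad],
                                prof_field("density_sd")[bad])
  }

  exam_idx <- rep(seq_len(n), n_images)
  rows <- gen_image_rows(exam_idx, latent, prof_field("giant_rate"),
                         prof_field("abnormal_rate"),
                         prof_field("tortuous_rate"),
                         prof_field("haemorrhage_rate"), config)
  img_seq <- sequence(n_images)
  images <- cbind(
    data.frame(exam_id = exam_id[exam_idx],
               image_id = sprintf("%s_img%03d", exam_id[exam_idx], img_seq),
               calibrated = !uncalibrated[exam_idx],
               stringsAsFactors = FALSE),
    rows
  )[, IMAGE_COLS]

  verdict_mat <- t(vapply(pattern, function(p) {
    generate_verdicts(p, config$rater_error_rate, config$ungradable_rate)
  }, character(3)))
  verdicts <- data.frame(
    exam_id = exam_id,
    rater_1 = verdict_mat[, 1],
    rater_2 = verdict_mat[, 2],
    rater_3 = verdict_mat[, 3],
    stringsAsFactors = FALSE
  )

  truth <- data.frame(exam_id = exam_id, pattern = pattern,
                      qc_spoiled = spoiled, stringsAsFactors = FALSE)
  structure(
    list(images = images, verdicts = verdicts, truth = truth,
         config = config),
    class = "capi_cohort"
  )
}

#' @export
print.capi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic NVC cohort: %d exams, %d images (seed %d)\n",
              nrow(x$truth), nrow(x$images), x$config$seed))
  print(table(x$truth$pattern)[capi_patterns()])
  invisible(x)
}
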