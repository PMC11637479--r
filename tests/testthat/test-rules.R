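th <- capi_thresholds()

test_that("Rule 1 fires on inclusive density, giant detection, strict abnormal", {
  r <- rule1_ssc_vs_nonssc(fv(6.0), th)
  expect_equal(r$group, "ssc")               # <=6 is inclusive
  expect_equal(r$trace, "R1_DENSITY_LE_6")

  r <- rule1_ssc_vs_nonssc(fv(9.0, pct_giant = 0.5), th)
  expect_equal(r$group, "ssc")               # any giant detected
  expect_equal(r$trace, "R1_GIANTS_DETECTED")

  expect_equal(rule1_ssc_vs_nonssc(fv(9.0, pct_abnormal = 10.0), th)$group,
               "non_ssc")                    # >10% is strict
  expect_equal(rule1_ssc_vs_nonssc(fv(9.0, pct_abnormal = 10.1), th)$group,
               "ssc")
  # multiple disjuncts are all recorded, in evaluation order
  r <- rule1_ssc_vs_nonssc(fv(5.0, pct_giant = 1, pct_abnormal = 20), th)
  expect_equal(r$trace, c("R1_DENSITY_LE_6", "R1_GIANTS_DETECTED",
                          "R1_ABNORMAL_GT_10"))
})

test_that("Rule 2 stages high-density SSc exams as early unless giants/abnormals override", {
  expect_equal(stage_ssc(fv(6.0), th)$pattern, "ssc_early")
  expect_equal(stage_ssc(fv(6.0, pct_abnormal = 5.0), th)$pattern,
               "ssc_active")                 # >=5% inclusive
  expect_equal(stage_ssc(fv(5.5, pct_giant = 10.0), th)$pattern,
               "ssc_active")                 # >=10% inclusive
  expect_equal(stage_ssc(fv(6.0, pct_abnormal = 4.9), th)$pattern,
               "ssc_early")
})

test_that("Rule 3 precedence: late default, active override, final late override wins", {
  # giants >= 33 fire the active override; no late condition holds
  r <- stage_ssc(fv(4.0, pct_giant = 40.0, pct_abnormal = 10.0), th)
  expect_equal(r$pattern, "ssc_active")
  expect_equal(r$trace, c("R3_LATE_DEFAULT", "R3_ACTIVE_OVERRIDE"))

  # no active override fires (10 < 33, 10 > 7): default late stands
  r <- stage_ssc(fv(4.0, pct_giant = 10.0, pct_abnormal = 10.0), th)
  expect_equal(r$pattern, "ssc_late")
  expect_equal(r$trace, "R3_LATE_DEFAULT")

  # active override fires (abnormal <= 7) but the final override
  # (giant <= 7) wins regardless
  r <- stage_ssc(fv(4.0, pct_giant = 5.0, pct_abnormal = 5.0), th)
  expect_equal(r$pattern, "ssc_late")
  expect_equal(r$trace, c("R3_LATE_DEFAULT", "R3_ACTIVE_OVERRIDE",
                          "R3_LATE_FINAL_OVERRIDE"))

  # active override fires (giant >= 33) but abnormal >= 15 reverts to late
  r <- stage_ssc(fv(4.0, pct_giant = 40.0, pct_abnormal = 20.0), th)
  expect_equal(r$pattern, "ssc_late")
  expect_equal(r$trace, c("R3_LATE_DEFAULT", "R3_ACTIVE_OVERRIDE",
                          "R3_LATE_FINAL_OVERRIDE"))
})

test_that("Rule 4 splits non-SSc exams with inclusive thresholds and haemorrhage presence", {
  expect_equal(rule4_normal_vs_nonspecific(fv(9, pct_tortuous = 20.0), th)$pattern,
               "non_specific")
  expect_equal(rule4_normal_vs_nonspecific(fv(9, haemorrhages_present = TRUE),
                                           th)$pattern, "non_specific")
  expect_equal(rule4_normal_vs_nonspecific(fv(9, pct_abnormal = 2.0), th)$pattern,
               "non_specific")
  r <- rule4_normal_vs_nonspecific(fv(9, pct_tortuous = 19.9,
                                      pct_abnormal = 1.9), th)
  expect_equal(r$pattern, "normal")
  expect_equal(r$trace, "R4_NORMAL_DEFAULT")
})

test_that("staging a non-SSc vector and Rule 4 on an SSc vector are contract errors", {
  expect_error(stage_ssc(fv(9.0), th), "non-SSc")
  expect_error(rule4_normal_vs_nonspecific(fv(4.0), th), "SSc")
  expect_error(capi_score(fv(9.0, pct_abnormal = 101), th), "out of range")
})

test_that("every printed threshold behaves inclusively or strictly as published", {
  eps <- 1e-9
  cases <- list(
    # density <= 6 (Rule 1, inclusive)
    list(fv(6.0), "ssc_early"), list(fv(6 + eps), "normal"),
    # giant detection strict at zero (Rule 1)
    list(fv(9, pct_giant = eps), "ssc_early"), list(fv(9), "normal"),
    # abnormal > 10 strict (Rule 1); 10.1 also trips Rule 4's >= 2
    list(fv(9, pct_abnormal = 10), "non_specific"),
    list(fv(9, pct_abnormal = 10 + eps), "ssc_active"),
    # density split at 5 (Rules 2/3): >= 5 goes through Rule 2
    list(fv(5.0), "ssc_early"), list(fv(5 - eps), "ssc_late"),
    # Rule 2 giants >= 10 inclusive
    list(fv(5.5, pct_giant = 10), "ssc_active"),
    list(fv(5.5, pct_giant = 10 - eps), "ssc_early"),
    # Rule 2 abnormal >= 5 inclusive
    list(fv(5.5, pct_abnormal = 5), "ssc_active"),
    list(fv(5.5, pct_abnormal = 5 - eps), "ssc_early"),
    # Rule 3 active override: giants >= 33 (with abnormal in (7,15) and
    # giants > 7 so no late condition masks it)
    list(fv(4, pct_giant = 33, pct_abnormal = 10), "ssc_active"),
    list(fv(4, pct_giant = 33 - eps, pct_abnormal = 10), "ssc_late"),
    # Rule 3 active override: abnormal <= 7 (giants > 7 to dodge the final
    # override)
    list(fv(4, pct_giant = 8, pct_abnormal = 7), "ssc_active"),
    list(fv(4, pct_giant = 8, pct_abnormal = 7 + eps), "ssc_late"),
    # Rule 3 final override: giants <= 7 reverts to late
    list(fv(4, pct_giant = 7, pct_abnormal = 5), "ssc_late"),
    list(fv(4, pct_giant = 7 + eps, pct_abnormal = 5), "ssc_active"),
    # Rule 3 final override: abnormal >= 15 reverts to late
    list(fv(4, pct_giant = 40, pct_abnormal = 15), "ssc_late"),
    list(fv(4, pct_giant = 40, pct_abnormal = 15 - eps), "ssc_active"),
    # Rule 4 tortuosities >= 20 inclusive
    list(fv(9, pct_tortuous = 20), "non_specific"),
    list(fv(9, pct_tortuous = 20 - eps), "normal"),
    # Rule 4 abnormal >= 2 inclusive
    list(fv(9, pct_abnormal = 2), "non_specific"),
    list(fv(9, pct_abnormal = 2 - eps), "normal"),
    # Rule 4 haemorrhage presence
    list(fv(9, haemorrhages_present = TRUE), "non_specific"),
    list(fv(9, haemorrhages_present = FALSE), "normal")
  )
  for (case in cases) {
    expect_equal(capi_score(case[[1]], th)$pattern, case[[2]],
                 info = paste(deparse(unlist(case[[1]])), collapse = ""))
  }
})

test_that("hand-traced full-tree classifications", {
  # rule 1 fires on density; density < 5; no active override (0 < 33,
  # 20 > 7); final override (giant <= 7, abnormal >= 15) -> late
  expect_equal(capi_score(fv(3.0, pct_abnormal = 20.0), th)$pattern, "ssc_late")
  # rule 1 fires on giants; density >= 5; giants >= 10 block early
  expect_equal(capi_score(fv(5.5, pct_giant = 15.0), th)$pattern, "ssc_active")
  # nothing fires anywhere
  expect_equal(capi_score(fv(9.0), th)$pattern, "normal")
})

test_that("the engine agrees with the naive rule transcription on a boundary-refined grid", {
  grid <- threshold_grid()
  expect_gt(nrow(grid), 1e5)
  engine <- classify_features(grid, th)
  oracle <- mapply(naive_capi_oracle, grid$density, grid$pct_giant,
                   grid$pct_abnormal, grid$pct_tortuous,
                   grid$haemorrhages_present)
  expect_identical(engine$pattern, unname(oracle))
})

test_that("classification is total, exclusive, and group-consistent", {
  set.seed(41)
  n <- 2000
  random_fv <- data.frame(
    density = runif(n, 0, 12),
    pct_giant = runif(n, 0, 100),
    pct_abnormal = runif(n, 0, 100),
    pct_tortuous = runif(n, 0, 100),
    haemorrhages_present = runif(n) < 0.5
  )
  res <- classify_features(random_fv, th)
  expect_true(all(res$pattern %in% capi_patterns()))
  expect_equal(pattern_group(res$pattern), res$rule1)
  for (i in sample(n, 50)) {
    scalar <- capi_score(as.list(random_fv[i, ]), th)
    expect_equal(scalar$pattern, res$pattern[i])
    expect_equal(paste(scalar$trace, collapse = ";"), res$trace[i])
    expect_gt(length(scalar$trace), 0)
  }
})

test_that("SSc membership is monotone decreasing in density", {
  set.seed(51)
  for (i in 1:50) {
    g <- runif(1, 0, 100)
    a <- runif(1, 0, 100)
    d <- runif(1, 0, 12)
    if (rule1_ssc_vs_nonssc(fv(d, pct_giant = g, pct_abnormal = a),
                            th)$group == "ssc") {
      for (d2 in c(d / 2, d * 0.9, 0)) {
        expect_equal(rule1_ssc_vs_nonssc(fv(d2, pct_giant = g,
                                            pct_abnormal = a), th)$group,
                     "ssc")
      }
    }
  }
})

test_that("threshold overrides shift the decision boundaries", {
  loose <- capi_thresholds(r1_density_max = 7)
  expect_equal(capi_score(fv(6.5), loose)$pattern, "ssc_early")
  expect_equal(capi_score(fv(6.5), th)$pattern, "normal")
  expect_error(capi_thresholds(bogus = 1), "unknown threshold")
  expect_error(capi_thresholds(r2_giant_ge = 120), "<= 100")
})
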