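test_that("trial generation is a pure function of its seed", {
  an <- anthro_h1l()
  a <- generate_stance_trial(an, list(marker_sigma = 2, sta_scale = 1), seed = 7)
  b <- generate_stance_trial(an, list(marker_sigma = 2, sta_scale = 1), seed = 7)
  expect_identical(a, b)
  g1 <- generate_gait_trial(an, list(marker_sigma = 1), seed = 9)
  g2 <- generate_gait_trial(an, list(marker_sigma = 1), seed = 9)
  expect_identical(g1, g2)
  c_ <- generate_stance_trial(an, list(marker_sigma = 2), seed = 8)
  expect_false(identical(a$markers$positions, c_$markers$positions))
})

test_that("stance truth has the ramp-plateau-ramp morphology at the calibrated level", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 0), seed = 5)
  fs <- tr$truth$force
  plateau <- fs$resultant[fs$cycle >= 35 & fs$cycle <= 65]
  expect_equal(mean(plateau), 259, tolerance = 0.01)
  # the 75%-of-max region contains the nominal plateau span
  thr <- 0.75 * max(fs$resultant)
  above <- fs$cycle[fs$resultant >= thr]
  expect_lte(min(above), 30)
  expect_gte(max(above), 70)
  # ramps fall below the threshold near the cycle ends
  expect_lt(fs$resultant[fs$cycle == 5], thr)
  expect_lt(fs$resultant[fs$cycle == 95], thr)
  expect_error(generate_stance_trial(an, list(plateau_span = c(-5, 70))), "span")
  # stance-phase sign convention in the reporting frame
  mid <- which(fs$cycle == 50)
  expect_gt(fs$f_ml[mid], 0)
  expect_lt(fs$f_pa[mid], 0)
  expect_lt(fs$f_is[mid], 0)
})

test_that("zero-noise trials are self-consistent through the pipeline", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 0), seed = 5)
  res <- run_combo(tr, tr$truth$force, tr$truth$combo)
  expect_equal(res$status, "ok")
  dif <- res$force$resultant - tr$truth$force$resultant
  expect_lt(sqrt(mean(dif^2)), 0.5)
})

test_that("gait truth has exactly two stance peaks at the calibrated magnitudes", {
  an <- anthro_h1l()
  tr <- generate_gait_trial(an, list(marker_sigma = 0), seed = 7)
  fs <- tr$truth$force
  st <- fs$resultant[fs$cycle <= tr$params$stance_end]
  locmax <- which(diff(sign(diff(st))) < 0) + 1L
  expect_equal(length(locmax), 2L)
  expect_equal(max(fs$resultant[abs(fs$cycle - 15) <= 8]), 255, tolerance = 0.01)
  expect_equal(max(fs$resultant[abs(fs$cycle - 45) <= 8]), 230, tolerance = 0.01)
  # events ordered within the cycle; toe off at the first peak phase
  expect_equal(tr$events$contra_toe_off, 15)
  expect_true(tr$events$contra_toe_off < tr$events$contra_heel_strike)
  expect_true(tr$events$contra_heel_strike <= tr$events$ipsi_toe_off)
  # force plate silent during swing
  sw <- tr$grf$time / max(tr$grf$time) * 100 > tr$params$stance_end + 1
  expect_true(all(abs(tr$grf$force[sw, 3]) < 1e-9))
  expect_error(generate_gait_trial(an, list(peak_phase = c(45, 15))), "increasing")
})

test_that("percent-body-weight peak parameters mean the same thing at any mass", {
  base <- reference_cohort()[1, ]
  an1 <- anthropometrics("A", base$side, base$age, base$sex, base$mass, base$height,
                         base$hjw_ct)
  an2 <- anthropometrics("B", base$side, base$age, base$sex, 2 * base$mass,
                         base$height, base$hjw_ct)
  sc <- c(thigh = 1, shank = 1)
  t1 <- generate_gait_trial(an1, list(marker_sigma = 0, true_scales = sc), seed = 3)
  t2 <- generate_gait_trial(an2, list(marker_sigma = 0, true_scales = sc), seed = 3)
  # the calibrated %BW peaks are mass-invariant ...
  for (tr in list(t1, t2)) {
    fs <- tr$truth$force
    expect_equal(max(fs$resultant[abs(fs$cycle - 15) <= 8]), 255, tolerance = 0.01)
    expect_equal(max(fs$resultant[abs(fs$cycle - 45) <= 8]), 230, tolerance = 0.01)
  }
  # ... while the newton-scale ground reaction grows with body weight
  expect_gt(max(t2$grf$force[, 3]) / max(t1$grf$force[, 3]), 1.7)
})

test_that("the soft-tissue artifact displaces only pelvis markers by the stated law", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 0), seed = 4)
  mk <- tr$markers
  # below the BMI threshold: no systematic offset
  low <- add_soft_tissue_artifact(mk, bmi = 24, scale = 2, seed = 1)
  pel <- which(mk$ids %in% c("LASI", "RASI", "LPSI", "RPSI"))
  dy <- low$positions[, pel, 2L] - mk$positions[, pel, 2L]
  expect_lt(max(abs(colMeans(dy))), 1e-3)
  # BMI 37.2 at scale 1: 12.2 mm outward per side
  hi <- add_soft_tissue_artifact(mk, bmi = 37.2, scale = 1, seed = 1)
  dy2 <- (hi$positions[, pel, 2L] - mk$positions[, pel, 2L]) * 1000
  lat <- ifelse(substr(mk$ids[pel], 1, 1) == "L", 1, -1)
  expect_equal(unname(colMeans(dy2) * lat), rep(12.2, 4), tolerance = 0.2)
  # non-pelvis markers untouched; scale 0 is the identity
  expect_identical(hi$positions[, -pel, ], mk$positions[, -pel, ])
  expect_identical(add_soft_tissue_artifact(mk, 37.2, 0), mk)
})

test_that("pseudo in vivo series follow the configured noise and misalignment", {
  tpl <- template_curve("one_leg_stance", magnitude = 259)
  clean <- generate_invivo_series(tpl, list(sd_bw = 0, misalign_deg = 0), seed = 2)
  expect_equal(as.matrix(clean[, 2:5]), as.matrix(tpl[, 2:5]), tolerance = 1e-12)
  # a pure 3-degree misalignment appears as a 3-degree 3D angular deviation
  rot3 <- generate_invivo_series(tpl, list(sd_bw = 0, misalign_deg = 3), seed = 2)
  win <- detect_pfp(tpl, "one_leg_stance")
  m <- mad_pfp(rot3, tpl, win)
  expect_equal(unname(m[["d3"]]), 3, tolerance = 0.1)
  expect_identical(generate_invivo_series(tpl, seed = 5),
                   generate_invivo_series(tpl, seed = 5))
  expect_error(generate_invivo_series(tpl, list(misalign_deg = 9)), "5")
})

test_that("cohort generation shares true scales across activities and writes a manifest", {
  coh <- generate_cohort(reference_cohort()[1:2, ], seed = 77)
  expect_named(coh$subjects, c("H1L", "H2R"))
  s1 <- coh$subjects$H1L
  expect_equal(s1$stance$params$true_scales, s1$gait$params$true_scales)
  expect_equal(nrow(coh$manifest), 4L)
  expect_true(all(c("subject_id", "activity", "seed", "truth_combo") %in%
                    names(coh$manifest)))
})
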