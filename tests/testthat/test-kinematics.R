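test_that("marker weights decay with residual and zero out invalid markers", {
  expect_equal(marker_weights(0, TRUE), 1)
  expect_equal(marker_weights(5, FALSE), 0)
  # w = 1 / (1 + (r/r0)^2) at r0 = 20 mm
  expect_equal(marker_weights(c(5, 50)), c(1 / (1 + 0.0625), 1 / (1 + 6.25)),
               tolerance = 1e-9)
  expect_true(all(diff(marker_weights(seq(0, 100, 5))) < 0))
  expect_error(marker_weights(-1), "non-negative")
})

test_that("pose reconstruction inverts forward kinematics exactly", {
  m <- scale_model(build_reference_model(anthro_h1l(), hjw_mode = "CT"), NULL)
  q <- setNames(numeric(16L), hipload:::Q_NAMES)
  q[1:3] <- c(0.12, -0.04, 0.91)
  q[4:6] <- c(0.04, -0.06, 0.25)
  q[7:11] <- c(-0.35, 0.12, 0.08, 0.5, 0.12)
  q[12:16] <- c(0.25, -0.07, 0.03, 0.7, -0.08)
  labs <- hipload:::markers_from_pose(m, q)
  sol <- hipload:::ik_frame(m, labs, rep(1, 25))
  expect_true(sol$ok)
  expect_lt(max(abs(sol$q - q)), 1e-10)
})

test_that("a rigid 10-degree rotation about the hip FE axis is recovered with zero residual", {
  m <- scale_model(build_reference_model(anthro_h1l(), hjw_mode = "CT"), NULL)
  q0 <- setNames(numeric(16L), hipload:::Q_NAMES)
  q0[3] <- 0.9
  q1 <- q0
  q1["L_fe"] <- deg2rad <- 10 * pi / 180
  labs <- hipload:::markers_from_pose(m, q1)
  sol <- hipload:::ik_frame(m, labs, rep(1, 25))
  expect_equal(unname(sol$q[["L_fe"]]) * 180 / pi, 10, tolerance = 1e-8)
  pred <- hipload:::markers_from_pose(m, sol$q)
  expect_lt(max(abs(pred - labs)), 1e-10)
})

test_that("noise-free trials recover the true segment scales", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 0), seed = 5)
  model <- scale_model(build_reference_model(an, hjw_mode = "CT"), NULL)
  fit <- optimize_parameters(model, tr$markers)
  expect_true(fit$converged)
  expect_equal(unname(fit$length_scales[["thigh"]]),
               unname(tr$params$true_scales[["thigh"]]), tolerance = 1e-3)
  expect_equal(unname(fit$length_scales[["shank"]]),
               unname(tr$params$true_scales[["shank"]]), tolerance = 1e-3)
  expect_equal(fit$hjw_c3d, an$hjw_ct)  # CT mode: frozen exactly
})

test_that("pelvic soft-tissue widening inflates the marker-based hip joint width", {
  an <- anthropometrics("H3L", "L", 59, "m", 90.9, 1.68, 174)
  # sta_scale 1.39 with BMI 32.2 gives a 10 mm outward shift per side
  tr <- generate_stance_trial(an, list(marker_sigma = 0, sta_scale = 1.39), seed = 11)
  model <- scale_model(build_reference_model(an, hjw_mode = "C3D"), NULL)
  fit <- optimize_parameters(model, tr$markers)
  over <- fit$hjw_c3d - an$hjw_ct
  # first-order prediction is +2 x 10 mm, damped by the leg-chain coupling
  expect_gt(over, 8)
  expect_lt(over, 30)
  # frozen CT width is untouched by the same data
  modelT <- scale_model(build_reference_model(an, hjw_mode = "CT"), NULL)
  fitT <- optimize_parameters(modelT, tr$markers)
  expect_identical(fitT$hjw_c3d, 174)
})

test_that("marker noise propagates to bounded residuals and small scale errors", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 2), seed = 12)
  model <- scale_model(build_reference_model(an, hjw_mode = "CT"), NULL)
  fit <- optimize_parameters(model, tr$markers)
  kin <- solve_frame_kinematics(model, tr$markers, scales = fit)
  # mean 3D residual of an isotropic sigma = 2 mm noise is ~ sigma * E|chi_3|
  expect_lt(kin$mean_abs_residual_mm, 2 * 2.5)
  expect_gt(kin$mean_abs_residual_mm, 2 * 1.0)
  expect_lt(abs(fit$length_scales[["thigh"]] - tr$params$true_scales[["thigh"]]), 0.03)
})

test_that("the scale optimization never worsens the marker objective", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 2), seed = 41)
  model <- scale_model(build_reference_model(an, hjw_mode = "CT"), NULL)
  fit <- optimize_parameters(model, tr$markers)
  frames <- seq(1, length(tr$markers$time), by = 4)
  w <- fit$weights
  obj_init <- hipload:::scale_objective(model, tr$markers, frames, w)
  fitted <- hipload:::set_scales_abs(model, fit$length_scales, hjw = fit$hjw_c3d)
  obj_fit <- hipload:::scale_objective(fitted, tr$markers, frames, w)
  expect_lte(obj_fit, obj_init + 1e-12)
})

test_that("pose solutions are invariant to a common rigid transform of all markers", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 1), seed = 21)
  model <- hipload:::set_scales_abs(
    scale_model(build_reference_model(an, hjw_mode = "CT"), NULL),
    c(tr$params$true_scales, foot = 1))
  kin1 <- solve_frame_kinematics(model, tr$markers)
  R <- hipload:::rot_zyx(0.2, -0.1, 0.7)
  shift <- c(1.5, -2, 0.3)
  mk2 <- tr$markers
  for (t in seq_along(mk2$time))
    mk2$positions[t, , ] <- mk2$positions[t, , ] %*% t(R) +
      rep(shift, each = length(mk2$ids))
  kin2 <- solve_frame_kinematics(model, mk2)
  # joint angles and residuals unchanged under the global motion
  joint_cols <- 7:16
  expect_equal(kin2$q[, joint_cols], kin1$q[, joint_cols], tolerance = 1e-8)
  expect_equal(kin2$residuals_mm, kin1$residuals_mm, tolerance = 1e-6)
})

test_that("dropout frames are interpolated and flagged", {
  an <- anthro_h1l()
  tr <- generate_stance_trial(an, list(marker_sigma = 0), seed = 31)
  mk <- tr$markers
  bad <- 10L
  mk$validity[bad, mk$segment == "pelvis"] <- FALSE
  model <- hipload:::set_scales_abs(
    scale_model(build_reference_model(an, hjw_mode = "CT"), NULL),
    c(tr$params$true_scales, foot = 1))
  kin <- solve_frame_kinematics(model, mk)
  expect_true(kin$flags[bad])
  expect_false(any(kin$flags[-bad]))
  expect_true(all(is.finite(kin$q[bad, ])))
})
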