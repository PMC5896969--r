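# A hand-built static single-leg stance in the frontal plane: the classic
# abductor statics problem with a closed-form solution. The trial holds the
# model in its neutral pose with the full supported weight applied at a
# medial center-of-pressure offset.
static_stance_fixture <- function(e_med = 0.1, mass = 61.162, side = "R",
                                  massless_legs = FALSE) {
  an <- anthropometrics("TOY", side, 50, "m", mass, 1.75, 170)
  model <- build_reference_model(an, hjw_mode = "CT")
  if (massless_legs) {
    for (sn in names(model$segments)) {
      if (!is.na(model$segments[[sn]]$side)) {
        model$segments[[sn]]$mass <- 0
        model$segments[[sn]]$inertia <- model$segments[[sn]]$inertia * 0
      }
    }
  }
  nT <- 13L
  rate <- 24
  time <- seq_len(nT) / rate
  legZ <- model$segments$femur_R$length + model$segments$tibia_R$length +
    hipload:::LENGTH_FRACTIONS[["ankle_h"]] * an$height
  Q <- matrix(0, nT, 16L)
  Q[, 3L] <- legZ
  kin <- hipload:::kin_from_q(model, Q, rate, time)
  poses <- fk_pose(model, Q[1, ])
  ank <- poses[[paste0("foot_", side)]]$t
  med <- -hipload:::side_sign(side)
  W <- mass * 9.81
  grf <- grf_data(time, cbind(rep(0, nT), 0, rep(W, nT)),
                  cbind(rep(poses[[paste0("femur_", side)]]$t[1L], nT),
                        poses[[paste0("femur_", side)]]$t[2L] + med * e_med, 0))
  list(model = model, kin = kin, grf = grf, W = W, side = side)
}

test_that("static stance produces the closed-form abduction moment demand", {
  # supported weight 600 N at 100 mm medial of the hip -> 60 N m abduction
  fx <- static_stance_fixture(e_med = 0.1, mass = 600 / 9.81, massless_legs = TRUE)
  loads <- net_joint_loads(fx$model, fx$kin, fx$grf, side = fx$side)
  mid <- 7L
  # abduction demand magnitude (frontal-plane component)
  expect_equal(abs(loads$demand[mid, 1L]), 60, tolerance = 0.5)
  expect_lt(abs(loads$demand[mid, 2L]), 1)   # no sagittal demand
  expect_equal(norm(loads$f_net[mid, ], "2"), 600, tolerance = 1)
})

test_that("demands are zero without loads and scale linearly with them", {
  fx <- static_stance_fixture(massless_legs = TRUE)
  grf0 <- fx$grf
  grf0$force[] <- 0
  l0 <- net_joint_loads(fx$model, fx$kin, grf0, side = fx$side)
  expect_lt(max(abs(l0$demand)), 1e-9)
  expect_lt(max(abs(l0$f_net)), 1e-9)
  l1 <- net_joint_loads(fx$model, fx$kin, fx$grf, side = fx$side)
  grf2 <- fx$grf
  grf2$force <- grf2$force * 2
  l2 <- net_joint_loads(fx$model, fx$kin, grf2, side = fx$side)
  expect_equal(l2$demand, 2 * l1$demand, tolerance = 1e-9)
})

test_that("force-plate series must cover the trial", {
  fx <- static_stance_fixture()
  grf_short <- grf_data(fx$grf$time[1:4], fx$grf$force[1:4, ], fx$grf$cop[1:4, ])
  expect_error(net_joint_loads(fx$model, fx$kin, grf_short, side = fx$side),
               "cover")
})

test_that("simple muscle strength is sigma times PCSA, independent of state", {
  fasc <- list(pcsa = 10)
  expect_equal(strength_simple(fasc, 90), 900)
  expect_equal(strength_simple(fasc, 40), 400)
  expect_error(strength_simple(fasc, 0), "positive")
})

test_that("Hill model reduces to the simple model at optimum and respects its curves", {
  fasc <- list(pcsa = 10, hill = list(optimal_fiber_length = 0.1, max_velocity = 8,
                                      passive_strain_scale = 1, flw = 0.45))
  at_opt <- strength_hill(fasc, 1, 0, 90)
  expect_equal(at_opt$active_cap, 900)
  expect_equal(at_opt$passive, 0)
  # Gaussian force-length: one width above optimum gives e^-1
  fl <- strength_hill(fasc, 1.45, 0, 90)
  expect_equal(fl$active_cap / 900, exp(-1), tolerance = 1e-9)
  # force-velocity endpoint: max shortening velocity -> zero active force
  expect_equal(strength_hill(fasc, 1, 8, 90)$active_cap, 0)
  # passive force engages monotonically above optimal length
  ps <- sapply(seq(1, 1.5, 0.1), function(l) strength_hill(fasc, l, 0, 90)$passive)
  expect_true(all(diff(ps) > 0))
  expect_equal(strength_hill(fasc, 0.9, 0, 90)$passive, 0)
})

test_that("the classic abductor problem yields the closed-form 1800 N reaction", {
  # single abductor, 50 mm arm, 60 N m abduction demand, 600 N supported
  # weight: muscle force 1200 N, contact force 600 + 1200 = 1800 N = 3 x W
  sol <- recruit_polynomial(recruitment_problem(matrix(0.05, 1, 1), 60, 2000))
  expect_equal(sol$f, 1200, tolerance = 1e-6)
  f_net <- c(0, 0, -600)            # pelvis load on the massless leg
  u <- c(0, 0, 1)                   # abductor pull, insertion toward origin
  contact <- f_net - sol$f * u
  expect_equal(hipload:::norm3(contact), 1800, tolerance = 1e-6)
  expect_equal(contact[3], -1800, tolerance = 1e-6)

  # the full fiber-fan model on the same statics: the fan recruits deep
  # short-arm fibers too, so the reaction exceeds the single-muscle bound
  fx <- static_stance_fixture(e_med = 0.1, mass = 600 / 9.81, massless_legs = TRUE)
  loads <- net_joint_loads(fx$model, fx$kin, fx$grf, side = fx$side)
  hip <- hip_reaction(fx$model, fx$kin, loads, combo_spec("CT", 90, "PN", "simple"))
  expect_equal(hip$status, "ok")
  mid <- 7L
  res <- norm(hip$force_femur[mid, ], "2")
  expect_gt(res / 600, 2.0)
  expect_lt(res / 600, 5.0)
  # reaction pushes down the femoral axis
  expect_lt(hip$force_femur[mid, "is"], 0)
})

test_that("mirrored toys produce mirrored reactions", {
  fxR <- static_stance_fixture(side = "R", massless_legs = TRUE)
  fxL <- static_stance_fixture(side = "L", massless_legs = TRUE)
  lR <- net_joint_loads(fxR$model, fxR$kin, fxR$grf, side = "R")
  lL <- net_joint_loads(fxL$model, fxL$kin, fxL$grf, side = "L")
  hR <- hip_reaction(fxR$model, fxR$kin, lR, combo_spec("CT", 90, "PN", "simple"))
  hL <- hip_reaction(fxL$model, fxL$kin, lL, combo_spec("CT", 90, "PN", "simple"))
  mid <- 7L
  expect_equal(norm(hR$force_femur[mid, ], "2"), norm(hL$force_femur[mid, ], "2"),
               tolerance = 1e-6)
  # the ML axis points right for both sides, so a physically mirrored force
  # appears with opposite in-frame sign (and identical after the left-side
  # mirror of the reporting transform)
  expect_equal(hR$force_femur[mid, "ml"], -hL$force_femur[mid, "ml"], tolerance = 1e-6)
})

test_that("per-frame infeasibility fails the whole trial", {
  fx <- static_stance_fixture(e_med = 0.1, mass = 600 / 9.81, massless_legs = TRUE)
  loads <- net_joint_loads(fx$model, fx$kin, fx$grf, side = fx$side)
  # a muscle strength far below the demand saturates the min/max criterion
  hip <- hip_reaction(fx$model, fx$kin, loads, combo_spec("CT", 2, "MM", "simple"))
  expect_equal(hip$status, "failed")
  expect_false(is.na(hip$fail_frame))
})
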