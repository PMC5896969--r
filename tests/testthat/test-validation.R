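ramp_series <- function(n = 101, frame = "OrthoLoad_femur") {
  cyc <- seq(0, 100, length.out = n)
  force_series(cyc, 0.3 * cyc, -0.1 * cyc, -0.95 * cyc, frame = frame, side = "R",
               subject_id = "S", activity = "one_leg_stance")
}

test_that("force series maintain their resultant invariant", {
  fs <- ramp_series()
  expect_equal(fs$resultant, sqrt(fs$f_ml^2 + fs$f_pa^2 + fs$f_is^2))
  expect_error(force_series(c(0, 0, 1), 1:3, 1:3, 1:3), "increasing")
})

test_that("body-weight normalization follows 100 F / (m g)", {
  expect_equal(normalize_bw(90 * 9.81, 90), 100)
  expect_equal(normalize_bw(0, 70), 0)
  expect_equal(normalize_bw(1800, 61.1620795), 300, tolerance = 1e-6)
  expect_error(normalize_bw(100, 0), "positive")
})

test_that("the OrthoLoad transform preserves resultants and mirrors the left side", {
  fs <- ramp_series(frame = "ISB_femur")
  id <- to_orthoload_frame(fs, rotation = c(0, 0, 0), side = "R")
  expect_equal(as.matrix(id[, 2:4]), as.matrix(fs[, 2:4]))
  expect_error(to_orthoload_frame(id), "already")
  rot <- to_orthoload_frame(fs, rotation = c(5, -3, 7), side = "R")
  expect_equal(rot$resultant, fs$resultant, tolerance = 1e-9)
  # a left series that is the ML mirror of a right one transforms identically
  fsL <- force_series(fs$cycle, -fs$f_ml, fs$f_pa, fs$f_is, frame = "ISB_femur",
                      side = "L", subject_id = "S", activity = "one_leg_stance")
  outL <- to_orthoload_frame(fsL, rotation = c(0, 0, 0), side = "L")
  outR <- to_orthoload_frame(fs, rotation = c(0, 0, 0), side = "R")
  expect_equal(as.matrix(outL[, 2:5]), as.matrix(outR[, 2:5]), tolerance = 1e-12)
})

test_that("cycle resampling interpolates linearly and preserves endpoints", {
  fs <- ramp_series(n = 51)
  rs <- resample_cycle(fs, n = 101)
  expect_equal(nrow(rs), 101)
  expect_equal(rs$f_ml[rs$cycle == 33], 0.3 * 33, tolerance = 1e-9)
  expect_equal(rs$f_is[c(1, 101)], fs$f_is[c(1, 51)])
  const <- force_series(seq(0, 100, 2), rep(1, 51), rep(2, 51), rep(3, 51))
  expect_equal(unique(round(resample_cycle(const)$f_pa, 12)), 2)
  bad <- data.frame(time = c(0, 2, 1), f_ml = 1:3, f_pa = 1:3, f_is = 1:3)
  expect_error(resample_cycle(bad), "increasing")
})

test_that("stance peak force phase is the central 75-percent plateau", {
  tpl <- template_curve("one_leg_stance", magnitude = 250, span = c(30, 70))
  win <- detect_pfp(tpl, "one_leg_stance")
  expect_equal(win$start_pct, 30)
  expect_equal(win$end_pct, 70)
  # constant resultant: every central sample is above threshold
  const <- force_series(0:100, rep(30, 101), rep(0, 101), rep(-100, 101))
  winc <- detect_pfp(const, "one_leg_stance")
  expect_equal(c(winc$start_pct, winc$end_pct), c(25, 75))
})

test_that("gait peak force phase is 5 percent wide around the peak nearest toe off", {
  tpl <- template_curve("level_walking", magnitude = 260, span = c(33, 48))
  win <- detect_pfp(tpl, "level_walking", events = list(contra_toe_off = 32))
  expect_equal(win$end_pct - win$start_pct, 5)
  expect_equal(win$start_pct, 33 - 2.5)
  expect_error(detect_pfp(tpl, "level_walking"), "toe-off")
  # a peak near the cycle start clips the window at zero
  cyc <- 0:100
  edge <- force_series(cyc, rep(0, 101), rep(0, 101),
                       -(20 + 100 * exp(-((cyc - 1) / 5)^2)))
  wine <- detect_pfp(edge, "level_walking", events = list(contra_toe_off = 2))
  expect_equal(wine$start_pct, 0)
  expect_lt(wine$end_pct - wine$start_pct, 5)
})

test_that("percentage deviation and MAPE follow their definitions", {
  tpl <- template_curve("one_leg_stance")
  win <- detect_pfp(tpl, "one_leg_stance")
  expect_equal(pd_pfp(tpl, tpl, win), 0)
  scaled <- force_series(tpl$cycle, tpl$f_ml * 1.1, tpl$f_pa * 1.1, tpl$f_is * 1.1)
  expect_equal(pd_pfp(scaled, tpl, win), 10, tolerance = 1e-9)
  expect_equal(mape_pfp(c(10, -10, 20)), 40 / 3, tolerance = 1e-12)
})

test_that("angular deviations match hand-computed vector angles", {
  fs <- function(v) force_series(0:100, rep(v[1], 101), rep(v[2], 101), rep(v[3], 101))
  win <- list(start_pct = 25, end_pct = 75)
  expect_equal(unname(mad_pfp(fs(c(1, 0, -2)), fs(c(1, 0, -2)), win)), rep(0, 4),
               tolerance = 1e-5)
  m <- mad_pfp(fs(c(1, 0, -2)), fs(c(1, -1, -2)), win)
  expect_equal(unname(m[["d3"]]), acos(5 / sqrt(5 * 6)) * 180 / pi, tolerance = 1e-9)
  # a 5-degree rotation in the frontal (ML-IS) plane: AA = 5, 3D = 5
  v <- c(1, 0, -2)
  ang <- 5 * pi / 180
  vr <- c(cos(ang) * v[1] - sin(ang) * v[3], 0, sin(ang) * v[1] + cos(ang) * v[3])
  m2 <- mad_pfp(fs(v), fs(vr), win)
  expect_equal(unname(m2[["aa"]]), 5, tolerance = 1e-9)
  expect_equal(unname(m2[["d3"]]), 5, tolerance = 1e-9)
})

test_that("component RMSE isolates the offset component", {
  tpl <- template_curve("one_leg_stance")
  expect_equal(unname(rmse_components(tpl, tpl)), rep(0, 4))
  off <- force_series(tpl$cycle, tpl$f_ml, tpl$f_pa, tpl$f_is + 10)
  r <- rmse_components(off, tpl)
  expect_equal(unname(r[["is"]]), 10, tolerance = 1e-9)
  expect_equal(unname(r[["ml"]]), 0)
  expect_equal(unname(r[["pa"]]), 0)
  c3 <- force_series(0:100, rep(3, 101), rep(0, 101), rep(0, 101))
  c0 <- force_series(0:100, rep(0, 101), rep(0, 101), rep(0, 101))
  expect_equal(unname(rmse_components(c3, c0)[["r"]]), 3)
})

test_that("correlation analysis recovers exact linear relations", {
  tpl <- template_curve("one_leg_stance")
  co <- correlate(tpl, tpl)
  expect_equal(co$r2, rep(1, 4), tolerance = 1e-12)
  expect_equal(co$slope, rep(1, 4), tolerance = 1e-12)
  expect_equal(co$intercept, rep(0, 4), tolerance = 1e-9)
  doubled <- force_series(tpl$cycle, 2 * tpl$f_ml, 2 * tpl$f_pa, 2 * tpl$f_is)
  co2 <- correlate(doubled, tpl)
  expect_equal(co2$slope, rep(2, 4), tolerance = 1e-12)
  expect_error(correlate(tpl[1:2, ], tpl[1:2, ]), "3")
})

test_that("independent noise shows no spurious correlation", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    a <- stats::rnorm(1000)
    b <- stats::rnorm(1000)
    ct <- stats::cor.test(a, b)
    if (unname(ct$estimate)^2 < 0.01 && ct$p.value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("Bland-Altman uses median and 1.45 IQR limits", {
  tpl <- template_curve("one_leg_stance")
  ba0 <- bland_altman(tpl, tpl)
  expect_equal(ba0$median_diff, rep(0, 4))
  expect_equal(ba0$loa_low, rep(0, 4))
  expect_equal(ba0$loa_high, rep(0, 4))
  # worked example d = 1..5: quartiles 2 and 4, LOA 3 -/+ 1.45 * 2
  base <- force_series(seq(0, 100, 25), rep(0, 5), rep(0, 5), rep(0, 5))
  shift <- force_series(base$cycle, 1:5, rep(0, 5), rep(0, 5))
  ba <- bland_altman(shift, base)
  ml <- ba[ba$quantity == "ml", ]
  expect_equal(ml$median_diff, 3)
  expect_equal(ml$iqr, 2)
  expect_equal(ml$loa_low, 0.1, tolerance = 1e-12)
  expect_equal(ml$loa_high, 5.9, tolerance = 1e-12)
  # shift equivariance
  shift2 <- force_series(base$cycle, 1:5 + 7, rep(0, 5), rep(0, 5))
  ba2 <- bland_altman(shift2, base)
  expect_equal(ba2[ba2$quantity == "ml", c("median_diff", "loa_low", "loa_high")],
               ml[, c("median_diff", "loa_low", "loa_high")] + 7)
})

test_that("nonparametric tests behave on identical, shifted and normal data", {
  tpl <- template_curve("one_leg_stance")
  nt <- nonparam_tests(tpl, tpl)
  expect_true(all(nt$mw_p > 0.99))
  big <- force_series(tpl$cycle, tpl$f_ml + 50, tpl$f_pa + 50, tpl$f_is + 50)
  nt2 <- nonparam_tests(big, tpl)
  expect_lt(nt2$mw_p[nt2$quantity == "ml"], 0.05)
  expect_error(nonparam_tests(tpl[1:4, ], tpl[1:4, ]), "8")
  # KS against the fitted normal accepts normal differences
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    d <- stats::rnorm(500)
    p <- suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d))$p.value)
    if (p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("metrics are zero if and only if the series coincide", {
  tpl <- template_curve("one_leg_stance")
  rep0 <- metrics_report(tpl, tpl, "one_leg_stance")
  expect_equal(rep0$pd_pfp, 0)
  expect_equal(unname(rep0$mad_pfp), rep(0, 4))
  expect_equal(unname(rep0$rmse), rep(0, 4))
  other <- force_series(tpl$cycle, tpl$f_ml + 1, tpl$f_pa, tpl$f_is)
  rep1 <- metrics_report(other, tpl, "one_leg_stance")
  expect_gt(unname(rep1$rmse[["ml"]]), 0)
})

test_that("the metric pipeline is invariant to a common rotation of both series", {
  tpl <- template_curve("one_leg_stance")
  noise <- generate_invivo_series(tpl, list(sd_bw = 4, misalign_deg = 0), seed = 3)
  R <- hipload:::rot_zyx(0.1, 0.05, -0.2)
  rot <- function(fs) {
    V <- as.matrix(fs[, c("f_ml", "f_pa", "f_is")]) %*% t(R)
    force_series(fs$cycle, V[, 1], V[, 2], V[, 3])
  }
  m1 <- metrics_report(tpl, noise, "one_leg_stance")
  m2 <- metrics_report(rot(tpl), rot(noise), "one_leg_stance")
  expect_equal(m2$pd_pfp, m1$pd_pfp, tolerance = 1e-9)
  expect_equal(m2$mad_pfp[["d3"]], m1$mad_pfp[["d3"]], tolerance = 1e-9)
  expect_equal(m2$rmse[["r"]], m1$rmse[["r"]], tolerance = 1e-9)
})
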