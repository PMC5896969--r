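# Synthetic OrthoLoad-style trials: marker trajectories, force-plate wrenches
# and pseudo in vivo hip forces with known ground truth. The ground-truth hip
# force is produced by the package's own inverse-dynamics machinery on the
# true (noise-free) poses, so every validation metric has a known-zero
# reference; simple curve templates are exposed separately for metric unit
# tests.

#' Marker trajectory container
#'
#' @param time Time stamps, s.
#' @param ids Marker labels (n).
#' @param segment Segment each marker belongs to (n).
#' @param positions T x n x 3 lab positions in meters.
#' @param validity T x n logical.
#' @param rate Sampling rate, Hz.
#' @return A `marker_data` object.
#' @export
marker_data <- function(time, ids, segment, positions, validity = NULL, rate = NULL) {
  if (length(time) < 2L) stop("need at least 2 frames")
  if (is.null(rate)) rate <- 1 / stats::median(diff(time))
  if (rate <= 0) stop("rate must be positive")
  if (is.null(validity)) validity <- matrix(TRUE, length(time), length(ids))
  structure(list(time = as.numeric(time), ids = ids, segment = segment,
                 positions = positions, validity = validity, rate = rate),
            class = "marker_data")
}

#' @export
print.marker_data <- function(x, ...) {
  cat(sprintf("<marker_data> %d markers x %d frames @ %.1f Hz (%.1f%% valid)\n",
              length(x$ids), length(x$time), x$rate, 100 * mean(x$validity)))
  invisible(x)
}

trial_data <- function(anthro, activity, markers, grf, events, truth, params, seed) {
  structure(list(anthro = anthro, side = anthro$side, activity = activity,
                 markers = markers, grf = grf, events = events, truth = truth,
                 params = params, seed = seed),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %s %s (side %s): %d frames, seed %s\n",
              x$anthro$subject_id, x$activity, x$side, length(x$markers$time),
              format(x$seed)))
  invisible(x)
}

# Kinematics result assembled directly from known generalized coordinates
# (the generator's truth path): identical differentiation pipeline as the
# marker-based solve.
kin_from_q <- function(model, Q, rate, time) {
  Qf <- apply(Q, 2L, lowpass, rate = rate, cutoff = 6)
  qd <- apply(Qf, 2L, central_diff, dt = 1 / rate)
  qdd <- apply(qd, 2L, central_diff, dt = 1 / rate)
  colnames(Q) <- colnames(qd) <- colnames(qdd) <- Q_NAMES
  structure(list(time = time, rate = rate, q = Q, qd = qd, qdd = qdd,
                 residuals_mm = matrix(0, nrow(Q), nrow(model$markers)),
                 flags = logical(nrow(Q)),
                 length_scales = model$length_scales, hjw_c3d = model$hjw,
                 mean_abs_residual_mm = 0, mean_abs_residual_bw = 0,
                 marker_mean_residual_mm = setNames(numeric(nrow(model$markers)),
                                                    model$markers$marker_id),
                 model = model),
            class = "kinematics_result")
}

# The designated "true" parameter combination used to produce ground truth.
true_combo <- function() combo_spec("CT", 90, "PN", "simple")

default_rotation <- function() c(0, 0, 0)

# Truth hip force series (%BW, OrthoLoad frame, 101-point cycle grid) from a
# true kinematics path and ground reaction.
truth_force_series <- function(model, kin, grf, anthro, activity) {
  loads <- net_joint_loads(model, kin, grf, side = anthro$side)
  hip <- hip_reaction(model, kin, loads, true_combo())
  if (hip$status != "ok")
    stop("truth pipeline failed at frame ", hip$fail_frame, " (", hip$fail_reason, ")")
  tt <- kin$time
  pct <- (tt - tt[1L]) / (tt[length(tt)] - tt[1L]) * 100
  fs <- force_series(pct, normalize_bw(hip$force_femur[, "ml"], anthro$mass),
                     normalize_bw(hip$force_femur[, "pa"], anthro$mass),
                     normalize_bw(hip$force_femur[, "is"], anthro$mass),
                     frame = "ISB_femur", side = anthro$side,
                     subject_id = anthro$subject_id, activity = activity)
  to_orthoload_frame(resample_cycle(fs), rotation = default_rotation())
}

stance_defaults <- function() {
  list(plateau_bw = 259, plateau_span = c(30, 70), duration = 2.5, rate = 24,
       marker_sigma = 2, sta_scale = 0, shift = 0.045, true_scales = NULL)
}

# Pose path for one-leg stance on the instrumented side: weight transfer onto
# the stance leg, pelvis shift over the foot, contralateral leg lifted during
# the plateau. `s` is the 0..1 support ramp.
stance_pose_path <- function(model, pct, s, params) {
  side <- model$anthro$side
  os <- if (side == "R") 6L else 11L
  oo <- if (side == "R") 11L else 6L
  ss <- side_sign(side)
  legZ <- model$segments[[paste0("femur_", side)]]$length +
    model$segments[[paste0("tibia_", side)]]$length +
    LENGTH_FRACTIONS[["ankle_h"]] * model$anthro$height
  nT <- length(pct)
  Q <- matrix(0, nT, 16L)
  sway <- 0.003 * sin(2 * pi * 3 * pct / 100) * s
  Q[, 1L] <- 0.002 * sin(2 * pi * 2 * pct / 100) * s
  Q[, 2L] <- ss * params$shift * s + sway
  Q[, 3L] <- legZ * (0.995 - 0.006 * s)
  Q[, 4L] <- ss * deg2rad(2) * s            # pelvic obliquity
  Q[, 5L] <- deg2rad(1) * s
  # stance leg: slight flexion/adduction, small knee bend
  Q[, os + 1L] <- -deg2rad(3) * s
  Q[, os + 2L] <- -ss * deg2rad(2.5) * s    # adduction as pelvis shifts over foot
  Q[, os + 4L] <- deg2rad(5) + deg2rad(3) * s
  Q[, os + 5L] <- deg2rad(2) * s
  # swing leg: lifted during the plateau
  Q[, oo + 1L] <- -deg2rad(30) * s
  Q[, oo + 4L] <- deg2rad(50) * s
  Q
}

#' Generate a synthetic one-leg-stance trial
#'
#' Builds a model-consistent one-leg-stance recording for one subject: the
#' resultant hip force has the characteristic ramp-plateau-ramp morphology
#' (weight transfer, single-leg support plateau, weight release). The ground
#' reaction equals the supported fraction of body weight, its center of
#' pressure migrates medially as the trunk shifts over the stance foot, and
#' the medial offset is calibrated so the ground-truth plateau hits the
#' requested magnitude. Markers are forward-kinematics positions plus
#' isotropic Gaussian noise; the truth hip force is computed through the
#' package's own dynamics under the designated true combination (CT hip joint
#' width, 90 N/cm^2, polynomial recruitment, simple muscle model).
#'
#' @param anthro An [anthropometrics()] object.
#' @param params Named overrides of the defaults: `plateau_bw` (259 %BW),
#'   `plateau_span` (c(30, 70) % cycle), `duration` (2.5 s), `rate` (24 Hz),
#'   `marker_sigma` (2 mm), `sta_scale` (0, see
#'   [add_soft_tissue_artifact()]), `true_scales` (named thigh/shank true
#'   length scales; drawn in (0.95, 1.05) from the seed when NULL).
#' @param seed Integer seed; the trial is a pure function of
#'   (anthro, params, seed).
#' @return A `trial_data` object with `truth` (force series, kinematics,
#'   model, combo).
#' @export
generate_stance_trial <- function(anthro, params = list(), seed = 1) {
  p <- modifyList(stance_defaults(), params)
  if (p$plateau_span[1L] <= 0 || p$plateau_span[2L] >= 100 ||
      p$plateau_span[1L] >= p$plateau_span[2L])
    stop("plateau span must lie strictly inside (0, 100)")
  with_seed(seed, {
    if (is.null(p$true_scales))
      p$true_scales <- c(thigh = stats::runif(1, 0.95, 1.05),
                         shank = stats::runif(1, 0.95, 1.05))
    model <- build_reference_model(anthro, hjw_mode = "CT")
    model <- scale_model(model, NULL)  # apply cross-section law
    model <- set_scales_abs(model, c(p$true_scales, foot = 1))
    time <- seq(0, p$duration, by = 1 / p$rate)
    pct <- time / p$duration * 100
    lo <- p$plateau_span[1L]; hi <- p$plateau_span[2L]
    s <- smootherstep(pct, lo - 12, lo) - smootherstep(pct, hi, hi + 12)
    Q <- stance_pose_path(model, pct, s, p)
    kin <- kin_from_q(model, Q, p$rate, time)
    W <- anthro$mass * G_ACC
    rho <- 0.5 + 0.5 * s

    make_grf <- function(e_med) {
      geo_ank <- t(vapply(seq_along(time), function(t)
        fk_pose(model, Q[t, ])[[paste0("foot_", anthro$side)]]$t, numeric(3L)))
      med <- -side_sign(anthro$side)  # +y medial for right, -y for left
      cop <- cbind(geo_ank[, 1L] + 0.03, geo_ank[, 2L] + med * e_med * s, 0)
      grf_data(time, cbind(0, 0, rho * W), cop)
    }
    plateau_mean <- function(e_med) {
      fs <- truth_force_series(model, kin, make_grf(e_med), anthro, "one_leg_stance")
      mean(fs$resultant[fs$cycle >= lo + 5 & fs$cycle <= hi - 5])
    }
    # secant calibration of the medial COP offset to the plateau target
    e0 <- 0.04; e1 <- 0.09
    f0 <- plateau_mean(e0); f1 <- plateau_mean(e1)
    for (i in 1:4) {
      if (abs(f1 - f0) < 1e-9) break
      e2 <- max(0, e1 + (p$plateau_bw - f1) * (e1 - e0) / (f1 - f0))
      e0 <- e1; f0 <- f1
      e1 <- e2; f1 <- plateau_mean(e1)
      if (abs(f1 - p$plateau_bw) < 0.25) break
    }
    grf <- make_grf(e1)
    truth_fs <- truth_force_series(model, kin, grf, anthro, "one_leg_stance")

    pos <- array(NA_real_, c(length(time), nrow(model$markers), 3L))
    for (t in seq_along(time)) pos[t, , ] <- markers_from_pose(model, Q[t, ])
    pos <- pos + array(stats::rnorm(length(pos), 0, p$marker_sigma / 1000), dim(pos))
    mk <- marker_data(time, model$markers$marker_id, model$markers$segment, pos,
                      rate = p$rate)
    if (p$sta_scale > 0)
      mk <- add_soft_tissue_artifact(mk, anthro$bmi, p$sta_scale,
                                     seed = seed + 101L)
    trial_data(anthro, "one_leg_stance", mk, grf, events = list(),
               truth = list(force = truth_fs, kin = kin, model = model,
                            combo = true_combo(), cop_offset = e1),
               params = p, seed = seed)
  })
}

gait_defaults <- function() {
  list(peak_bw = c(255, 230), peak_phase = c(15, 45), swing_min = NULL,
       stance_end = 60, duration = 1.25, rate = 48, speed = 1.1,
       marker_sigma = 2, sta_scale = 0, e_lat = 0.03, true_scales = NULL)
}

gait_pose_path <- function(model, pct, params) {
  side <- model$anthro$side
  os <- if (side == "R") 6L else 11L
  oo <- if (side == "R") 11L else 6L
  ss <- side_sign(side)
  legZ <- model$segments[[paste0("femur_", side)]]$length +
    model$segments[[paste0("tibia_", side)]]$length +
    LENGTH_FRACTIONS[["ankle_h"]] * model$anthro$height
  phi <- 2 * pi * pct / 100
  # flexion held through loading response, extension into late stance,
  # smooth return during swing; C2-continuous and periodic over the cycle
  hip_fe <- function(pc) -10 + 40 * (1 - smootherstep(pc, 8, 52) +
                                       smootherstep(pc, 62, 100))
  knee_f <- function(pc) 8 + 10 * exp(-((pc - 13) / 10)^2) +
    35 * exp(-((pc - 72) / 20)^2) + 35 * exp(-((pc + 28) / 20)^2)
  ankle_f <- function(pc) 3 * sin(2 * pi * pc / 100)
  contra <- (pct + 50) %% 100
  nT <- length(pct)
  Q <- matrix(0, nT, 16L)
  Q[, 1L] <- params$speed * pct / 100 * params$duration
  Q[, 2L] <- ss * 0.02 * cos(phi - 0.2 * pi)
  Q[, 3L] <- legZ * 0.985 + 0.012 * cos(2 * phi - 0.3 * pi)
  Q[, 4L] <- ss * deg2rad(2) * sin(phi)
  Q[, 5L] <- deg2rad(1.5) * sin(phi + 0.5 * pi)
  Q[, 6L] <- deg2rad(3) * sin(phi + pi)
  Q[, os + 1L] <- -deg2rad(hip_fe(pct))
  Q[, os + 2L] <- -ss * deg2rad(2.5) * sin(phi + 0.2 * pi)
  Q[, os + 3L] <- deg2rad(2) * sin(phi)
  Q[, os + 4L] <- deg2rad(knee_f(pct))
  Q[, os + 5L] <- deg2rad(ankle_f(pct))
  Q[, oo + 1L] <- -deg2rad(hip_fe(contra))
  Q[, oo + 2L] <- ss * deg2rad(2.5) * sin(phi + 0.2 * pi)
  Q[, oo + 4L] <- deg2rad(knee_f(contra))
  Q[, oo + 5L] <- deg2rad(ankle_f(contra))
  Q
}

#' Generate a synthetic level-walking trial
#'
#' One full gait cycle of the instrumented leg (ipsilateral heel strike to
#' heel strike). The vertical ground reaction has the classic double-hump
#' profile over the stance phase, with the hump magnitudes calibrated so the
#' ground-truth resultant hip force reaches the requested peaks at the
#' requested phases; the contralateral toe-off event is placed at the first
#' peak phase and the contralateral heel strike near the second. The
#' force-plate signal is zero during swing.
#'
#' @param anthro An [anthropometrics()] object.
#' @param params Overrides of the defaults: `peak_bw` (c(255, 230) %BW),
#'   `peak_phase` (c(15, 45) % cycle, strictly increasing), `stance_end`
#'   (60%), `duration` (1.1 s), `rate` (55 Hz), `speed` (1.2 m/s),
#'   `marker_sigma` (2 mm), `sta_scale` (0), `true_scales`.
#' @param seed Integer seed.
#' @return A `trial_data` object with gait `events` (percent cycle) and the
#'   ground truth.
#' @export
generate_gait_trial <- function(anthro, params = list(), seed = 1) {
  p <- modifyList(gait_defaults(), params)
  if (diff(p$peak_phase) <= 0) stop("peak phases must be strictly increasing")
  with_seed(seed, {
    if (is.null(p$true_scales))
      p$true_scales <- c(thigh = stats::runif(1, 0.95, 1.05),
                         shank = stats::runif(1, 0.95, 1.05))
    model <- build_reference_model(anthro, hjw_mode = "CT")
    model <- scale_model(model, NULL)
    model <- set_scales_abs(model, c(p$true_scales, foot = 1))
    time <- seq(0, p$duration, by = 1 / p$rate)
    pct <- time / p$duration * 100
    Q <- gait_pose_path(model, pct, p)
    kin <- kin_from_q(model, Q, p$rate, time)
    W <- anthro$mass * G_ACC
    p1 <- p$peak_phase[1L]; p2 <- p$peak_phase[2L]; se <- p$stance_end
    taper <- smootherstep(pct, 0, 12) * (1 - smootherstep(pct, se - 10, se))
    ank <- t(vapply(seq_along(time), function(t)
      fk_pose(model, Q[t, ])[[paste0("foot_", anthro$side)]]$t, numeric(3L)))
    med <- -side_sign(anthro$side)

    # double-hump vertical profile; the force vector points from the center
    # of pressure toward the body mass center (inverted-pendulum direction),
    # so the ground-reaction line passes close to the hip and the joint
    # moments stay physiological
    make_grf <- function(g1, g2) {
      core <- 0.22 + g1 * exp(-((pct - p1) / 8)^2) + g2 * exp(-((pct - p2) / 8)^2)
      fz <- W * taper * core
      cop_x <- ank[, 1L] - 0.04 + 0.19 * pmin(pct, se) / se
      cop <- cbind(cop_x, ank[, 2L] + med * p$e_lat * taper, 0)
      target <- Q[, 1:3] + rep(c(0, 0, 0.18), each = length(pct))
      dirs <- target - cop
      F <- dirs * (fz / pmax(dirs[, 3L], 1e-6))
      grf_data(time, F, cop)
    }
    peaks_of <- function(g1, g2) {
      fs <- truth_force_series(model, kin, make_grf(g1, g2), anthro, "level_walking")
      m1 <- max(fs$resultant[abs(fs$cycle - p1) <= 8])
      m2 <- max(fs$resultant[abs(fs$cycle - p2) <= 8])
      c(m1, m2)
    }
    # per-hump secant calibration of the gains to the requested peaks
    g <- c(0.6, 0.5)
    pk <- peaks_of(g[1L], g[2L])
    g_prev <- g; pk_prev <- pk
    g <- pmax(0.02, g * p$peak_bw / pk)
    for (i in 1:5) {
      pk <- peaks_of(g[1L], g[2L])
      if (max(abs(pk - p$peak_bw)) < 0.5) break
      step <- (p$peak_bw - pk) * (g - g_prev) / (pk - pk_prev)
      step[!is.finite(step)] <- 0
      g_prev <- g; pk_prev <- pk
      g <- pmax(0.02, g + step)
    }
    grf <- make_grf(g[1L], g[2L])
    truth_fs <- truth_force_series(model, kin, grf, anthro, "level_walking")

    pos <- array(NA_real_, c(length(time), nrow(model$markers), 3L))
    for (t in seq_along(time)) pos[t, , ] <- markers_from_pose(model, Q[t, ])
    pos <- pos + array(stats::rnorm(length(pos), 0, p$marker_sigma / 1000), dim(pos))
    mk <- marker_data(time, model$markers$marker_id, model$markers$segment, pos,
                      rate = p$rate)
    if (p$sta_scale > 0)
      mk <- add_soft_tissue_artifact(mk, anthro$bmi, p$sta_scale, seed = seed + 101L)
    events <- list(ipsi_heel_strike = 0, contra_toe_off = p1,
                   contra_heel_strike = min(p2 + 3, se), ipsi_toe_off = se)
    trial_data(anthro, "level_walking", mk, grf, events = events,
               truth = list(force = truth_fs, kin = kin, model = model,
                            combo = true_combo(), hump_gains = g),
               params = p, seed = seed)
  })
}

#' Inject a pelvic soft-tissue artifact into marker data
#'
#' Displaces the four pelvis markers laterally outward by
#' `scale * max(0, bmi - 25)` mm per side (skin markers over adipose tissue
#' sit further from the bony landmarks the heavier the subject), plus a slow
#' zero-mean random drift. All other markers are unchanged. This is the
#' mechanism by which a marker-optimized hip joint width overestimates the
#' CT-measured one.
#'
#' @param markers A `marker_data` object.
#' @param bmi Subject BMI, kg/m^2.
#' @param scale Artifact scale (mm lateral offset per BMI unit above 25);
#'   `0` is the identity.
#' @param seed Seed for the drift component.
#' @return The displaced `marker_data`.
#' @export
add_soft_tissue_artifact <- function(markers, bmi, scale, seed = 1) {
  stopifnot(inherits(markers, "marker_data"))
  if (scale < 0) stop("scale must be non-negative")
  if (scale == 0) return(markers)
  offset_m <- scale * max(0, bmi - 25) / 1000
  pelvic <- which(markers$ids %in% c("LASI", "RASI", "LPSI", "RPSI"))
  nT <- length(markers$time)
  with_seed(seed, {
    for (j in pelvic) {
      lat <- if (substr(markers$ids[j], 1L, 1L) == "L") 1 else -1
      drift <- smooth_noise(nT, sd = scale * 1.5 / 1000, corr_len = markers$rate)
      markers$positions[, j, 2L] <- markers$positions[, j, 2L] + lat * offset_m + drift
    }
    markers
  })
}

#' Generate a pseudo in vivo hip force series
#'
#' Telemetry measurement stand-in: the ground-truth series plus smooth
#' correlated noise per component and a small fixed frame misalignment
#' (rotation of the force vectors about the posterior-anterior axis).
#'
#' @param truth A `force_series` on the 0-100% grid (OrthoLoad frame).
#' @param noise_params List: `sd_bw` (noise SD per component, %BW, default 3,
#'   the accuracy scale of instrumented-implant telemetry),
#'   `corr_len` (correlation length in % cycle, default 8), `misalign_deg`
#'   (rotation, default 2, at most 5).
#' @param seed Integer seed.
#' @return An `invivo_series` (also a `force_series`).
#' @export
generate_invivo_series <- function(truth, noise_params = list(), seed = 1) {
  stopifnot(inherits(truth, "force_series"))
  np <- modifyList(list(sd_bw = 3, corr_len = 8, misalign_deg = 2), noise_params)
  if (abs(np$misalign_deg) > 5) stop("misalignment must be at most 5 degrees")
  with_seed(seed, {
    V <- as.matrix(truth[, c("f_ml", "f_pa", "f_is")])
    if (np$misalign_deg != 0) {
      R <- rot_axis(c(0, 1, 0), deg2rad(np$misalign_deg))
      V <- t(R %*% t(V))
    }
    n <- nrow(V)
    for (k in 1:3) V[, k] <- V[, k] + smooth_noise(n, np$sd_bw, np$corr_len)
    out <- force_series(truth$cycle, V[, 1L], V[, 2L], V[, 3L],
                        frame = attr(truth, "frame"), side = attr(truth, "side"),
                        subject_id = attr(truth, "subject_id"),
                        activity = attr(truth, "activity"))
    class(out) <- c("invivo_series", class(out))
    attr(out, "noise_params") <- np
    out
  })
}

#' Generate a full synthetic cohort
#'
#' One stance and one walking trial per subject, with matching pseudo in vivo
#' series, all reproducible from the master seed. Per-subject true length
#' scales are drawn once and shared between the two activities.
#'
#' @param cohort A cohort table like [reference_cohort()].
#' @param stance_params,gait_params Parameter overrides for the generators.
#' @param noise_params In vivo noise parameters ([generate_invivo_series()]).
#' @param seed Master seed.
#' @return A list with `subjects` (per subject: `anthro`, `stance`, `gait`,
#'   `vivo_stance`, `vivo_gait`) and a `manifest` data.frame.
#' @export
generate_cohort <- function(cohort = reference_cohort(), stance_params = list(),
                            gait_params = list(), noise_params = list(), seed = 1) {
  subjects <- list()
  manifest <- NULL
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    an <- anthropometrics(r$subject_id, r$side, r$age, r$sex, r$mass, r$height, r$hjw_ct)
    sseed <- (abs(seed) * 97L + i * 131L) %% .Machine$integer.max
    ts <- with_seed(sseed, c(thigh = stats::runif(1, 0.95, 1.05),
                             shank = stats::runif(1, 0.95, 1.05)))
    sp <- modifyList(stance_params, list(true_scales = ts))
    gp <- modifyList(gait_params, list(true_scales = ts))
    st <- generate_stance_trial(an, sp, seed = sseed + 1L)
    gt <- generate_gait_trial(an, gp, seed = sseed + 2L)
    vs <- generate_invivo_series(st$truth$force, noise_params, seed = sseed + 3L)
    vg <- generate_invivo_series(gt$truth$force, noise_params, seed = sseed + 4L)
    subjects[[r$subject_id]] <- list(anthro = an, stance = st, gait = gt,
                                     vivo_stance = vs, vivo_gait = vg)
    manifest <- rbind(manifest, data.frame(
      subject_id = r$subject_id, side = r$side,
      activity = c("one_leg_stance", "level_walking"),
      seed = c(sseed + 1L, sseed + 2L), vivo_seed = c(sseed + 3L, sseed + 4L),
      truth_combo = "CT/90/PN/simple", stringsAsFactors = FALSE))
  }
  list(subjects = subjects, manifest = manifest)
}

#' Template force curves for metric unit tests
#'
#' Simple parametric resultant shapes (not produced by the dynamics pipeline):
#' a stance trapezoid with a plateau and sub-threshold shoulders, and a gait
#' double-peak curve. The force is placed mostly on the inferior-superior
#' component with a typical medial and posterior share.
#'
#' @param activity `"one_leg_stance"` or `"level_walking"`.
#' @param magnitude Plateau or first-peak resultant, %BW.
#' @param span Stance plateau span (percent), or the two gait peak phases.
#' @param n Grid size.
#' @return A `force_series` in the OrthoLoad frame.
#' @export
template_curve <- function(activity = c("one_leg_stance", "level_walking"),
                           magnitude = 250, span = NULL, n = 101) {
  activity <- match.arg(activity)
  cyc <- seq(0, 100, length.out = n)
  if (activity == "one_leg_stance") {
    if (is.null(span)) span <- c(30, 70)
    base <- 0.45 * magnitude
    res <- base + (magnitude - base) * (smootherstep(cyc, span[1L] - 1.6, span[1L]) -
                                          smootherstep(cyc, span[2L], span[2L] + 1.6))
  } else {
    if (is.null(span)) span <- c(15, 45)
    res <- 0.2 * magnitude +
      0.8 * magnitude * exp(-((cyc - span[1L]) / 7)^2) +
      0.72 * magnitude * exp(-((cyc - span[2L]) / 7)^2)
    res <- res * (smootherstep(cyc, 0, 6) * (1 - smootherstep(cyc, 55, 62)) + 0.08)
  }
  dirv <- unit3(c(0.3, -0.1, -0.95))
  force_series(cyc, res * dirv[1L], res * dirv[2L], res * dirv[3L],
               frame = "OrthoLoad_femur", side = "R",
               subject_id = "template", activity = activity)
}
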