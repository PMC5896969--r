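# Step 2 of the simulation: inverse dynamics over the instrumented leg and
# the per-frame hip reaction force under a given parameter combination.

#' Constant-strength muscle model
#'
#' @param fascicle A fascicle entry of a `body_model`.
#' @param sigma Muscle strength (specific tension) in N/cm^2.
#' @return Instantaneous strength in N (`sigma * PCSA`), independent of
#'   length and velocity.
#' @export
strength_simple <- function(fascicle, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  sigma * fascicle$pcsa
}

# Force-velocity factor; y = normalized velocity / max velocity, shortening
# positive. Hill hyperbola for shortening (zero at y = 1), steep eccentric
# branch saturating at 1.5 for lengthening.
fv_curve <- function(y) {
  ifelse(y >= 1, 0,
         ifelse(y >= 0, (1 - y) / (1 + 4 * y),
                1.5 - 0.5 * (1 + y) / (1 - 30 * y)))
}

#' Hill-type muscle model
#'
#' Instantaneous strength of a fascicle with a contractile element modulated
#' by Gaussian force-length and hyperbolic force-velocity curves, plus a
#' parallel passive element that engages above optimal length. The tendon is
#' treated as rigid and no activation dynamics are modeled: the curves are
#' evaluated at the kinematics-derived musculotendon length and velocity.
#'
#' @param fascicle A fascicle entry of a `body_model` (uses `pcsa` and the
#'   `hill` parameter list: `flw` force-length width, `max_velocity` in
#'   optimal lengths/s, `passive_strain_scale`).
#' @param norm_length Musculotendon length / optimal length.
#' @param norm_velocity Shortening velocity in optimal lengths/s (positive =
#'   shortening).
#' @param sigma Muscle strength in N/cm^2.
#' @return `list(active_cap, passive)` in N: the activation-scalable cap
#'   `sigma * pcsa * fl * fv` and the activation-independent passive force
#'   (zero at or below optimal length, monotone above).
#' @export
strength_hill <- function(fascicle, norm_length, norm_velocity, sigma) {
  stopifnot(is.finite(norm_length), is.finite(norm_velocity))
  h <- fascicle$hill
  fl <- exp(-((norm_length - 1) / h$flw)^2)
  fv <- fv_curve(norm_velocity / h$max_velocity)
  passive <- sigma * fascicle$pcsa * h$passive_strain_scale *
    (max(0, norm_length - 1) / 0.5)^2
  list(active_cap = sigma * fascicle$pcsa * fl * fv, passive = passive)
}

#' Force-plate data container
#'
#' @param time Time stamps, s.
#' @param force T x 3 ground reaction force in the lab frame, N.
#' @param cop T x 3 center of pressure in the lab frame, m.
#' @param tz Optional free vertical moment, N m (default 0).
#' @param plate_id Plate label.
#' @return A `grf_data` object.
#' @export
grf_data <- function(time, force, cop, tz = rep(0, length(time)), plate_id = "plate1") {
  force <- rbind(force); cop <- rbind(cop)
  stopifnot(length(time) == nrow(force), nrow(force) == nrow(cop))
  structure(list(time = as.numeric(time), force = force, cop = cop,
                 tz = as.numeric(tz), plate_id = plate_id),
            class = "grf_data")
}

interp_cols <- function(time, X, tout) {
  apply(rbind(X), 2L, function(col) stats::approx(time, col, xout = tout, rule = 2)$y)
}

# Angular velocity series (T x 3, lab frame) from a list/array of rotation
# matrices via central finite rotation differences.
angular_velocity <- function(Rs, dt) {
  nT <- length(Rs)
  W <- matrix(0, nT, 3L)
  for (t in seq_len(nT)) {
    t0 <- max(1L, t - 1L); t1 <- min(nT, t + 1L)
    dR <- Rs[[t1]] %*% t(Rs[[t0]])
    ang <- acos(max(-1, min(1, (sum(diag(dR)) - 1) / 2)))
    if (ang > 1e-12) {
      ax <- c(dR[3L, 2L] - dR[2L, 3L], dR[1L, 3L] - dR[3L, 1L], dR[2L, 1L] - dR[1L, 2L]) /
        (2 * sin(ang))
      W[t, ] <- ax * ang / ((t1 - t0) * dt)
    }
  }
  W
}

# Per-frame geometry of the instrumented leg: segment poses, COM positions,
# hip center, fascicle attachment points in the lab frame.
leg_frame_geometry <- function(model, kin, side) {
  nT <- nrow(kin$q)
  segn <- paste0(c("femur_", "tibia_", "foot_"), side)
  fasc <- Filter(function(f) f$side == side, model$fascicles)
  nf <- length(fasc)
  out <- list(
    hip = matrix(NA_real_, nT, 3L),
    com = lapply(segn, function(s) matrix(NA_real_, nT, 3L)),
    R = lapply(segn, function(s) vector("list", nT)),
    org = array(NA_real_, c(nT, nf, 3L)),
    ins = array(NA_real_, c(nT, nf, 3L)),
    fascicles = fasc, segments = segn)
  names(out$com) <- names(out$R) <- segn
  for (t in seq_len(nT)) {
    poses <- fk_pose(model, kin$q[t, ])
    s <- side_sign(side)
    out$hip[t, ] <- poses[[paste0("femur_", side)]]$t
    for (sn in segn) {
      seg <- model$segments[[sn]]
      out$com[[sn]][t, ] <- poses[[sn]]$t + poses[[sn]]$R %*% seg$com
      out$R[[sn]][[t]] <- poses[[sn]]$R
    }
    pp <- poses$pelvis; pf <- poses[[paste0("femur_", side)]]
    for (j in seq_len(nf)) {
      f <- fasc[[j]]
      out$org[t, j, ] <- pp$t + pp$R %*% f$origin
      out$ins[t, j, ] <- pf$t + pf$R %*% f$insertion
    }
  }
  out
}

#' Net hip loads from inverse dynamics
#'
#' Bottom-up Newton-Euler over the instrumented leg (foot, shank, thigh):
#' gravitational and ground-reaction terms are exact, inertial terms use the
#' low-pass-filtered segment accelerations and finite-rotation angular rates.
#' Returns, per frame, the intersegmental force the pelvis must apply at the
#' hip and the net hip moment demand the hip-spanning muscles must generate.
#'
#' @param model A scaled `body_model` (typically `kin$model`).
#' @param kin A `kinematics_result`.
#' @param grf A `grf_data` object, time-synchronized with the trial.
#' @param side Leg to analyze, `"L"` or `"R"`; default the subject's
#'   instrumented side.
#' @return A `net_loads` object with `demand` (T x 3 hip moment, N m, lab
#'   frame), `f_net` (T x 3 intersegmental force, N), frame geometry, and the
#'   interpolated ground reaction.
#' @export
net_joint_loads <- function(model, kin, grf, side = model$anthro$side) {
  stopifnot(inherits(kin, "kinematics_result"), inherits(grf, "grf_data"))
  tt <- kin$time
  dtr <- 0.5 / kin$rate
  if (min(grf$time) > min(tt) + dtr || max(grf$time) < max(tt) - dtr)
    stop("force-plate series does not cover the motion trial")
  geo <- leg_frame_geometry(model, kin, side)
  Fg <- interp_cols(grf$time, grf$force, tt)
  cop <- interp_cols(grf$time, grf$cop, tt)
  tz <- stats::approx(grf$time, grf$tz, xout = tt, rule = 2)$y
  nT <- length(tt)
  g <- c(0, 0, -G_ACC)

  demand <- matrix(0, nT, 3L)
  f_net <- matrix(0, nT, 3L)
  acc <- list(); omg <- list(); alp <- list()
  for (sn in geo$segments) {
    pos_f <- apply(geo$com[[sn]], 2L, lowpass, rate = kin$rate, cutoff = 6)
    vel <- apply(pos_f, 2L, central_diff, dt = 1 / kin$rate)
    acc[[sn]] <- apply(vel, 2L, central_diff, dt = 1 / kin$rate)
    omg[[sn]] <- angular_velocity(geo$R[[sn]], 1 / kin$rate)
    alp[[sn]] <- apply(omg[[sn]], 2L, central_diff, dt = 1 / kin$rate)
  }
  for (t in seq_len(nT)) {
    h <- geo$hip[t, ]
    Fsum <- -Fg[t, ]
    Msum <- -cross3(cop[t, ] - h, Fg[t, ]) - c(0, 0, tz[t])
    for (sn in geo$segments) {
      seg <- model$segments[[sn]]
      a <- acc[[sn]][t, ]
      Fi <- seg$mass * (a - g)
      Fsum <- Fsum + Fi
      R <- geo$R[[sn]][[t]]
      Iw <- R %*% diag(seg$inertia) %*% t(R)
      Msum <- Msum + cross3(geo$com[[sn]][t, ] - h, Fi) +
        as.numeric(Iw %*% alp[[sn]][t, ]) + cross3(omg[[sn]][t, ], as.numeric(Iw %*% omg[[sn]][t, ]))
    }
    f_net[t, ] <- Fsum
    demand[t, ] <- Msum
  }
  structure(list(time = tt, demand = demand, f_net = f_net, geometry = geo,
                 grf_interp = list(force = Fg, cop = cop, tz = tz), side = side),
            class = "net_loads")
}

#' Parameter combination
#'
#' One cell of the factorial design: hip-joint-width source, muscle strength,
#' recruitment criterion, muscle model.
#'
#' @param hjw_mode `"C3D"` or `"CT"`.
#' @param sigma Muscle strength, N/cm^2 (the study compares 40 and 90).
#' @param recruitment `"PN"` (third-power polynomial) or `"MM"` (min/max).
#' @param muscle_model `"simple"` or `"hill"`.
#' @return A `combo_spec`.
#' @export
combo_spec <- function(hjw_mode = c("CT", "C3D"), sigma = 90,
                       recruitment = c("PN", "MM"), muscle_model = c("simple", "hill")) {
  hjw_mode <- match.arg(hjw_mode)
  recruitment <- match.arg(recruitment)
  muscle_model <- match.arg(muscle_model)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(hjw_mode = hjw_mode, sigma = sigma, recruitment = recruitment,
                 muscle_model = muscle_model), class = "combo_spec")
}

#' @export
print.combo_spec <- function(x, ...) {
  cat(sprintf("<combo_spec> %s-HJW | %g N/cm^2 | %s | %s\n",
              x$hjw_mode, x$sigma, x$recruitment, x$muscle_model))
  invisible(x)
}

#' All 16 combinations of the factorial design
#' @return A list of [combo_spec()] objects.
#' @export
combo_grid <- function() {
  grid <- expand.grid(hjw_mode = c("C3D", "CT"), sigma = c(40, 90),
                      recruitment = c("PN", "MM"), muscle_model = c("simple", "hill"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    combo_spec(grid$hjw_mode[i], grid$sigma[i], grid$recruitment[i], grid$muscle_model[i]))
}

# Per-frame instantaneous strengths (T x n) for a combo.
fascicle_strengths <- function(model, loads, combo, rate) {
  fasc <- loads$geometry$fascicles
  nT <- length(loads$time)
  n <- length(fasc)
  Nmat <- matrix(NA_real_, nT, n)
  if (combo$muscle_model == "simple") {
    Ns <- vapply(fasc, strength_simple, 0, sigma = combo$sigma)
    Nmat[] <- rep(Ns, each = nT)
    return(Nmat)
  }
  len <- sapply(seq_len(n), function(j)
    sqrt(rowSums((loads$geometry$org[, j, , drop = FALSE] -
                    loads$geometry$ins[, j, , drop = FALSE])^2)))
  len <- rbind(len)
  for (j in seq_len(n)) {
    l0 <- fasc[[j]]$hill$optimal_fiber_length
    lnorm <- lowpass(len[, j], rate, 6) / l0
    vnorm <- -central_diff(lnorm, 1 / rate)  # shortening positive, in l0/s
    for (t in seq_len(nT)) {
      sh <- strength_hill(fasc[[j]], lnorm[t], vnorm[t], combo$sigma)
      Nmat[t, j] <- max(sh$active_cap + sh$passive, 1e-6)
    }
  }
  Nmat
}

#' Hip reaction force for one trial and one parameter combination
#'
#' Runs the per-frame muscle recruitment over the net loads and assembles the
#' hip joint reaction: the intersegmental force minus the vector sum of the
#' hip-spanning fascicle pulls, expressed in the femur-fixed (ISB-style)
#' frame: ML along the axis pointing right (for both sides, as recommended,
#' so a left-side series is the mirror of a right-side one), PA anterior,
#' IS proximal. A single
#' infeasible frame fails the whole trial, mirroring the exclusion of
#' unsuccessful simulations.
#'
#' @param model A scaled `body_model` (use `kin$model`).
#' @param kin A `kinematics_result`.
#' @param loads A `net_loads` from [net_joint_loads()].
#' @param combo A [combo_spec()].
#' @param pn_bounded Enforce strength caps in the polynomial criterion
#'   (default FALSE; the min/max criterion is always capped).
#' @return A `hip_force_result`: `time`, `force_femur` (T x 3, N, columns
#'   ml/pa/is), `status` (`ok` or `failed`), failure bookkeeping, per-frame
#'   forces and max activation.
#' @export
hip_reaction <- function(model, kin, loads, combo, pn_bounded = FALSE) {
  stopifnot(inherits(loads, "net_loads"), inherits(combo, "combo_spec"))
  geo <- loads$geometry
  fasc <- geo$fascicles
  nT <- length(loads$time)
  n <- length(fasc)
  Nmat <- fascicle_strengths(model, loads, combo, kin$rate)
  Fml <- matrix(NA_real_, nT, 3L, dimnames = list(NULL, c("ml", "pa", "is")))
  fmat <- matrix(NA_real_, nT, n, dimnames = list(NULL, names(fasc)))
  maxact <- rep(NA_real_, nT)
  axial <- rep(NA_real_, nT)
  fail_frame <- NA_integer_
  fail_status <- NA_character_
  side <- loads$side
  for (t in seq_len(nT)) {
    h <- geo$hip[t, ]
    U <- matrix(0, 3L, n)
    A <- matrix(0, 3L, n)
    for (j in seq_len(n)) {
      u <- unit3(geo$org[t, j, ] - geo$ins[t, j, ])
      U[, j] <- u
      A[, j] <- cross3(geo$ins[t, j, ] - h, u)
    }
    # recruitment equilibrium about the two axes orthogonal to the femur long
    # axis (flexion-extension and ab/adduction); the small axial-rotation
    # moment is carried by an ideal torque provider standing in for the deep
    # rotator group absent from the reduced fascicle set, and is reported.
    Rf <- geo$R[[paste0("femur_", side)]][[t]]
    P <- Rf[, 1:2, drop = FALSE]
    prob <- recruitment_problem(t(P) %*% A, drop(t(P) %*% loads$demand[t, ]),
                                Nmat[t, ])
    sol <- if (combo$recruitment == "PN")
      recruit_polynomial(prob, p = 3, bounded = pn_bounded)
    else recruit_minmax(prob, bounded = TRUE)
    if (sol$status != "ok") {
      fail_frame <- t
      fail_status <- sol$status
      break
    }
    fmat[t, ] <- sol$f
    maxact[t] <- max(sol$activations)
    axial[t] <- sum(Rf[, 3L] * (loads$demand[t, ] - drop(A %*% sol$f)))
    contact <- loads$f_net[t, ] - drop(U %*% sol$f)
    floc <- drop(t(Rf) %*% contact)
    # ISB-style components: ML along the axis pointing right (both sides, so
    # the left series mirrors the right), PA anterior, IS proximal
    Fml[t, ] <- c(-floc[2L], floc[1L], floc[3L])
  }
  status <- if (is.na(fail_frame)) "ok" else "failed"
  structure(list(time = loads$time, force_femur = Fml, status = status,
                 fail_frame = fail_frame, fail_reason = fail_status,
                 forces = fmat, max_activation = maxact,
                 axial_torque = axial, side = side, combo = combo),
            class = "hip_force_result")
}

#' @export
print.hip_force_result <- function(x, ...) {
  if (x$status == "ok") {
    res <- sqrt(rowSums(x$force_femur^2))
    cat(sprintf("<hip_force_result> ok | peak resultant %.0f N | max activation %.2f\n",
                max(res), max(x$max_activation, na.rm = TRUE)))
  } else {
    cat(sprintf("<hip_force_result> FAILED at frame %d (%s)\n", x$fail_frame, x$fail_reason))
  }
  invisible(x)
}
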