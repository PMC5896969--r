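# Step 1 of the simulation: marker-driven pose reconstruction and parameter
# (segment length / hip joint width) optimization.
#
# Generalized coordinates q (length 16, radians/meters):
#   1:3   pelvis position (lab)
#   4:6   pelvis orientation (roll, pitch, yaw; R = Rz Ry Rx)
#   7:11  right leg: hip (fe, aa, ie Cardan y-x-z), knee, ankle
#   12:16 left leg:  hip (fe, aa, ie), knee, ankle
# Hip Cardan convention: rotation about the pelvis ML (y) axis first; positive
# ry tilts the thigh posteriorly, so anatomical flexion = -fe. Knee/ankle
# positive = flexion (about segment y axis).

Q_NAMES <- c("px", "py", "pz", "roll", "pitch", "yaw",
             "R_fe", "R_aa", "R_ie", "R_knee", "R_ankle",
             "L_fe", "L_aa", "L_ie", "L_knee", "L_ankle")

#' Forward kinematics of the lower-limb model
#'
#' @param model A `body_model`.
#' @param q Generalized coordinate vector (length 16, see package internals).
#' @return A list of segment poses, each `list(R = 3x3 rotation, t = origin)`.
#' @export
fk_pose <- function(model, q) {
  q <- as.numeric(q)
  R_p <- rot_zyx(q[4L], q[5L], q[6L])
  t_p <- q[1:3]
  poses <- list(pelvis = list(R = R_p, t = t_p))
  hw <- model$hjw / 2000
  for (sd in c("R", "L")) {
    off <- if (sd == "R") 6L else 11L
    s <- side_sign(sd)
    h <- t_p + R_p %*% c(0, s * hw, 0)
    R_f <- R_p %*% rot_yxz(q[off + 1L], q[off + 2L], q[off + 3L])
    lt <- model$segments[[paste0("femur_", sd)]]$length
    ls <- model$segments[[paste0("tibia_", sd)]]$length
    k <- h + R_f %*% c(0, 0, -lt)
    R_s <- R_f %*% rot_y(q[off + 4L])
    a <- k + R_s %*% c(0, 0, -ls)
    R_ft <- R_s %*% rot_y(q[off + 5L])
    poses[[paste0("femur_", sd)]] <- list(R = R_f, t = as.numeric(h))
    poses[[paste0("tibia_", sd)]] <- list(R = R_s, t = as.numeric(k))
    poses[[paste0("foot_", sd)]] <- list(R = R_ft, t = as.numeric(a))
  }
  poses$hat <- poses$pelvis
  poses
}

# Lab positions (n x 3, meters) of the model's markers for one pose.
markers_from_pose <- function(model, q) {
  poses <- fk_pose(model, q)
  mk <- model$markers
  out <- matrix(NA_real_, nrow(mk), 3L, dimnames = list(mk$marker_id, NULL))
  for (seg in unique(mk$segment)) {
    i <- which(mk$segment == seg)
    p <- poses[[seg]]
    out[i, ] <- cbind(mk$lx[i], mk$ly[i], mk$lz[i]) %*% t(p$R) +
      rep(p$t, each = length(i))
  }
  out
}

#' Marker weights from residuals
#'
#' Weighting used to handle marker dropouts and soft-tissue outliers: invalid
#' markers get weight 0 and weights decay with the marker's residual as
#' `w = 1 / (1 + (r / r0)^2)`.
#'
#' @param residuals Non-negative per-marker residuals in mm.
#' @param validity Logical (or 0/1) vector; invalid entries get weight 0.
#' @param r0 Residual scale in mm at which the weight drops to 1/2 (default 20).
#' @return Weights in `[0, 1]`.
#' @export
marker_weights <- function(residuals, validity = rep(TRUE, length(residuals)), r0 = 20) {
  if (any(residuals < 0, na.rm = TRUE)) stop("residuals must be non-negative")
  w <- as.numeric(validity) / (1 + (residuals / r0)^2)
  w[!is.finite(w)] <- 0
  w
}

# Weighted Kabsch: rotation R and translation t with p ~ R l + t.
kabsch <- function(locals, labs, w) {
  ws <- sum(w)
  cl <- colSums(locals * w) / ws
  cb <- colSums(labs * w) / ws
  Lc <- sweep(locals, 2L, cl)
  Pc <- sweep(labs, 2L, cb)
  H <- t(Pc * w) %*% Lc
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = as.numeric(cb - R %*% cl))
}

# Rotation-only Kabsch about a fixed center: p - center ~ R l.
kabsch_fixed <- function(locals, labs_centered, w) {
  H <- t(labs_centered * w) %*% locals
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Closed-form 1-dof angle about local +y under parent rotation Rp and known
# joint center: minimizes weighted marker residuals.
solve_revolute_y <- function(locals, labs, center, Rp, w) {
  Z <- t(t(labs) - center) %*% Rp  # == Rp^T (p - center), rows
  A <- sum(w * (Z[, 1L] * locals[, 1L] + Z[, 3L] * locals[, 3L]))
  B <- sum(w * (Z[, 1L] * locals[, 3L] - Z[, 3L] * locals[, 1L]))
  if (abs(A) < 1e-300 && abs(B) < 1e-300) return(NA_real_)
  atan2(B, A)
}

# Precomputed numeric marker structure for fast per-frame solves.
ik_prep <- function(model) {
  mk <- model$markers
  L <- cbind(mk$lx, mk$ly, mk$lz)
  idx <- lapply(c("pelvis", "femur_R", "tibia_R", "foot_R",
                  "femur_L", "tibia_L", "foot_L"),
                function(seg) which(mk$segment == seg))
  names(idx) <- c("pelvis", "femur_R", "tibia_R", "foot_R",
                  "femur_L", "tibia_L", "foot_L")
  list(L = L, idx = idx, hw = model$hjw / 2000,
       lt = c(R = model$segments$femur_R$length, L = model$segments$femur_L$length),
       ls = c(R = model$segments$tibia_R$length, L = model$segments$tibia_L$length))
}

# One-frame hierarchical weighted least-squares pose reconstruction.
# labs: 25 x 3 lab positions (m); w: per-marker weights for this frame.
ik_frame <- function(model, labs, w, prep = ik_prep(model)) {
  L <- prep$L
  hw <- prep$hw
  q <- setNames(numeric(16L), Q_NAMES)

  ip <- prep$idx$pelvis
  usable <- ip[w[ip] > 0 & is.finite(labs[ip, 1L])]
  if (length(usable) < 3L) return(list(q = q, ok = FALSE))
  kp <- kabsch(L[usable, , drop = FALSE], labs[usable, , drop = FALSE], w[usable])
  q[1:3] <- kp$t
  q[4:6] <- euler_zyx(kp$R)
  ok <- TRUE

  for (sd in c("R", "L")) {
    off <- if (sd == "R") 6L else 11L
    s <- side_sign(sd)
    h <- kp$t + kp$R %*% c(0, s * hw, 0)
    it <- prep$idx[[paste0("femur_", sd)]]
    ut <- it[w[it] > 0 & is.finite(labs[it, 1L])]
    if (length(ut) < 3L) { ok <- FALSE; next }
    R_f <- kabsch_fixed(L[ut, , drop = FALSE],
                        t(t(labs[ut, , drop = FALSE]) - as.numeric(h)), w[ut])
    q[off + 1:3] <- euler_yxz(t(kp$R) %*% R_f)
    R_f <- kp$R %*% rot_yxz(q[off + 1L], q[off + 2L], q[off + 3L])

    lt <- prep$lt[[sd]]
    ls <- prep$ls[[sd]]
    is_ <- prep$idx[[paste0("tibia_", sd)]]
    us <- is_[w[is_] > 0 & is.finite(labs[is_, 1L])]
    if_ <- prep$idx[[paste0("foot_", sd)]]
    uf <- if_[w[if_] > 0 & is.finite(labs[if_, 1L])]
    if (length(us) < 1L || length(uf) < 1L) { ok <- FALSE; next }

    solve_distal <- function(R_f) {
      kc <- as.numeric(h + R_f %*% c(0, 0, -lt))
      th <- solve_revolute_y(L[us, , drop = FALSE],
                             labs[us, , drop = FALSE], kc, R_f, w[us])
      if (!is.finite(th)) return(NULL)
      R_s <- R_f %*% rot_y(th)
      ac <- as.numeric(kc + R_s %*% c(0, 0, -ls))
      tha <- solve_revolute_y(L[uf, , drop = FALSE],
                              labs[uf, , drop = FALSE], ac, R_s, w[uf])
      if (!is.finite(tha)) return(NULL)
      list(knee = th, ankle = tha)
    }
    dist <- solve_distal(R_f)
    if (is.null(dist)) { ok <- FALSE; next }

    # block refinement: re-fit the hip rotation against all leg markers with
    # the distal joint angles held (locals composed into the femur frame),
    # then re-solve knee and ankle; two sweeps approximate the joint
    # least-squares fit of the whole chain
    leg_idx <- c(ut, us, uf)
    Lt_ <- L[ut, , drop = FALSE]
    Ls_ <- L[us, , drop = FALSE]
    Lf_ <- L[uf, , drop = FALSE]
    labs_leg_c <- t(t(labs[leg_idx, , drop = FALSE]) - as.numeric(h))
    for (sweep in 1:2) {
      Rk <- rot_y(dist$knee)
      Ra <- rot_y(dist$ankle)
      kn <- c(0, 0, -lt)
      locs <- rbind(
        Lt_,
        Ls_ %*% t(Rk) + rep(kn, each = nrow(Ls_)),
        (Lf_ %*% t(Ra) + rep(c(0, 0, -ls), each = nrow(Lf_))) %*% t(Rk) +
          rep(kn, each = nrow(Lf_)))
      R_f <- kabsch_fixed(locs, labs_leg_c, w[leg_idx])
      d2 <- solve_distal(R_f)
      if (is.null(d2)) break
      dist <- d2
    }
    q[off + 1:3] <- euler_yxz(t(kp$R) %*% R_f)
    q[off + 4L] <- dist$knee
    q[off + 5L] <- dist$ankle
  }
  list(q = q, ok = ok)
}

set_scales_abs <- function(model, scales, hjw = model$hjw) {
  model$length_scales[names(scales)] <- scales
  model$hjw <- hjw
  rebuild_geometry(model)
}

# Objective for the parameter optimization: total weighted squared marker
# residual (m^2) over the selected frames.
scale_objective <- function(model, markers, frames, w) {
  prep <- ik_prep(model)
  tot <- 0
  for (t in frames) {
    labs <- markers$positions[t, , ]
    wt <- w * markers$validity[t, ]
    sol <- ik_frame(model, labs, wt, prep)
    if (!sol$ok) {
      tot <- tot + 1  # heavy penalty for unreconstructable frames
      next
    }
    pred <- markers_from_pose(model, sol$q)
    r2 <- rowSums((labs - pred)^2)
    r2[!is.finite(r2)] <- 0
    tot <- tot + sum(wt * r2)
  }
  tot
}

#' Optimize segment lengths (and hip joint width) from marker trajectories
#'
#' The first simulation step: finds the per-subject thigh and shank length
#' scales -- and, unless the hip joint width is frozen to its CT value -- the
#' marker-based hip joint width, by minimizing the summed weighted squared
#' marker residuals of the per-frame pose reconstruction. A first unweighted
#' pass estimates per-marker residuals, which are converted once into weights
#' with [marker_weights()] (soft-tissue and dropout handling) before the final
#' pass.
#'
#' @param model A `body_model`; its `hjw_mode` decides whether HJW is free.
#' @param markers A `marker_data` object (see [synthetic trials][generate_stance_trial]
#'   or [read_marker_csv()]).
#' @param opts List of options: `max_frames` (default 25) frames used in the
#'   optimization (evenly strided), `r0` weighting scale in mm, `two_pass`
#'   (default TRUE), `maxit` optimizer iteration cap, `cluster_weight`
#'   (default 0.2) structural prior weight for the soft-tissue-prone proximal
#'   thigh markers (greater trochanter and thigh-shaft cluster), so the bony
#'   pelvis and knee landmarks dominate the scale estimation.
#' @return A list with `length_scales`, `hjw_c3d` (mm), per-marker `weights`,
#'   the final objective `value` and a `converged` flag.
#' @export
optimize_parameters <- function(model, markers, opts = list()) {
  stopifnot(inherits(model, "body_model"), inherits(markers, "marker_data"))
  o <- modifyList(list(max_frames = 15L, r0 = 20, two_pass = TRUE, maxit = 200L,
                       cluster_weight = 0.2), opts)
  nT <- length(markers$time)
  stride <- max(1L, floor(nT / o$max_frames))
  frames <- seq(1L, nT, by = stride)
  free_hjw <- model$hjw_mode == "C3D"
  hjw0 <- model$hjw
  nmk <- nrow(model$markers)

  run_pass <- function(w, par0 = NULL) {
    if (is.null(par0)) par0 <- c(thigh = 1, shank = 1, if (free_hjw) c(hjw = 1))
    fn <- function(par) {
      m2 <- set_scales_abs(model, c(thigh = par[[1L]], shank = par[[2L]], foot = 1),
                           hjw = if (free_hjw) hjw0 * par[[3L]] else hjw0)
      scale_objective(m2, markers, frames, w)
    }
    stats::optim(par0, fn, method = "L-BFGS-B",
                 lower = rep(0.7, length(par0)), upper = rep(1.3, length(par0)),
                 control = list(maxit = o$maxit, factr = 1e6))
  }

  w0 <- rep(1, nmk)
  w0[grepl("GTR|THI", model$markers$marker_id)] <- o$cluster_weight
  fit <- run_pass(w0)
  weights <- w0
  if (o$two_pass) {
    mfit <- set_scales_abs(model, c(thigh = fit$par[[1L]], shank = fit$par[[2L]], foot = 1),
                           hjw = if (free_hjw) hjw0 * fit$par[[3L]] else hjw0)
    res <- residual_matrix(mfit, markers, frames, w0)
    rms <- sqrt(colMeans(res^2, na.rm = TRUE)) * 1000  # mm
    rms[!is.finite(rms)] <- 0
    weights <- w0 * marker_weights(rms, r0 = o$r0)
    fit <- run_pass(weights, par0 = fit$par)
  }
  list(length_scales = c(thigh = unname(fit$par[[1L]]), shank = unname(fit$par[[2L]]), foot = 1),
       hjw_c3d = if (free_hjw) unname(hjw0 * fit$par[[3L]]) else hjw0,
       weights = weights, value = fit$value,
       converged = fit$convergence == 0)
}

# Residual matrix (frames x markers, meters) for given weights.
residual_matrix <- function(model, markers, frames, w) {
  prep <- ik_prep(model)
  out <- matrix(NA_real_, length(frames), nrow(model$markers))
  for (j in seq_along(frames)) {
    t <- frames[j]
    labs <- markers$positions[t, , ]
    wt <- w * markers$validity[t, ]
    sol <- ik_frame(model, labs, wt, prep)
    if (!sol$ok) next
    pred <- markers_from_pose(model, sol$q)
    out[j, ] <- sqrt(rowSums((labs - pred)^2))
  }
  out
}

#' Per-frame pose solution over a whole trial
#'
#' Reconstructs the generalized-coordinate time series from markers with the
#' hierarchical weighted least-squares cascade (Kabsch fit of the pelvis+trunk
#' body, rotation-only fit of each thigh about its hip center, closed-form
#' revolute solutions at knee and ankle), then differentiates the coordinates
#' twice through a zero-phase 2nd-order low-pass filter (6 Hz cutoff).
#' Frames whose marker support is insufficient are linearly interpolated and
#' flagged.
#'
#' @param model A `body_model`.
#' @param markers A `marker_data` object.
#' @param scales Optional result of [optimize_parameters()]; when supplied the
#'   model is rescaled (and, in C3D mode, its HJW replaced) before solving.
#' @return A `kinematics_result`: coordinate matrix `q` (frames x 16), its
#'   filtered derivatives `qd`, `qdd`, per-frame per-marker `residuals_mm`,
#'   `length_scales`, `hjw_c3d`, interpolation `flags`, and the scaled model.
#' @export
solve_frame_kinematics <- function(model, markers, scales = NULL) {
  stopifnot(inherits(model, "body_model"), inherits(markers, "marker_data"))
  w <- rep(1, nrow(model$markers))
  if (!is.null(scales)) {
    model <- set_scales_abs(model, scales$length_scales, hjw = scales$hjw_c3d)
    if (!is.null(scales$weights)) w <- scales$weights
  }
  nT <- length(markers$time)
  Q <- matrix(NA_real_, nT, 16L, dimnames = list(NULL, Q_NAMES))
  Rmm <- matrix(NA_real_, nT, nrow(model$markers),
                dimnames = list(NULL, model$markers$marker_id))
  flags <- logical(nT)
  prep <- ik_prep(model)
  for (t in seq_len(nT)) {
    labs <- markers$positions[t, , ]
    wt <- w * markers$validity[t, ]
    sol <- ik_frame(model, labs, wt, prep)
    flags[t] <- !sol$ok
    if (sol$ok) {
      Q[t, ] <- sol$q
      Rmm[t, ] <- sqrt(rowSums((labs - markers_from_pose(model, sol$q))^2)) * 1000
    }
  }
  if (all(flags)) stop("no frame could be reconstructed: marker set under-determined")
  if (any(flags)) {
    okf <- which(!flags)
    for (jc in seq_len(16L))
      Q[flags, jc] <- stats::approx(okf, Q[okf, jc], xout = which(flags), rule = 2)$y
  }
  rate <- markers$rate
  Qf <- apply(Q, 2L, lowpass, rate = rate, cutoff = 6)
  qd <- apply(Qf, 2L, central_diff, dt = 1 / rate)
  qdd <- apply(qd, 2L, central_diff, dt = 1 / rate)
  colnames(qd) <- colnames(qdd) <- Q_NAMES
  mean_res <- colMeans(abs(Rmm), na.rm = TRUE)
  structure(
    list(time = markers$time, rate = rate, q = Q, qd = qd, qdd = qdd,
         residuals_mm = Rmm, flags = flags,
         length_scales = model$length_scales, hjw_c3d = model$hjw,
         mean_abs_residual_mm = mean(Rmm, na.rm = TRUE),
         # reporting convention: marker residual as a %-of-body-height
         mean_abs_residual_bw = 100 * mean(Rmm, na.rm = TRUE) / 1000 / model$anthro$height,
         marker_mean_residual_mm = mean_res,
         model = model),
    class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf("<kinematics_result> %d frames @ %.1f Hz | mean |residual| %.2f mm | HJW %.1f mm\n",
              nrow(x$q), x$rate, x$mean_abs_residual_mm, x$hjw_c3d))
  if (any(x$flags)) cat(sprintf("  %d frame(s) interpolated\n", sum(x$flags)))
  invisible(x)
}
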