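# Validation of simulated against in vivo hip joint forces: frame
# transformation, body-weight normalization, cycle resampling, peak-force-
# phase extraction, and the four error metrics with nonparametric statistics.

#' Cycle-normalized hip force series
#'
#' Three-component hip joint force on a 0-100% motion-cycle grid in percent
#' body weight (%BW). Components: `f_ml` medial-lateral, `f_pa`
#' posterior-anterior (positive anterior), `f_is` inferior-superior (positive
#' superior). In the reporting (OrthoLoad-style) frame, positive `f_ml` is
#' medial for both sides; a stance-phase hip contact force therefore has
#' `f_ml > 0`, `f_pa < 0`, `f_is < 0`.
#'
#' @param cycle Strictly increasing cycle grid in percent (0..100).
#' @param f_ml,f_pa,f_is Components in %BW.
#' @param frame `"ISB_femur"` or `"OrthoLoad_femur"`.
#' @param side `"L"` or `"R"`.
#' @param subject_id,activity Metadata labels.
#' @return A `force_series` data.frame with a `resultant` column.
#' @export
force_series <- function(cycle, f_ml, f_pa, f_is,
                         frame = c("ISB_femur", "OrthoLoad_femur"),
                         side = "R", subject_id = NA_character_,
                         activity = NA_character_) {
  frame <- match.arg(frame)
  if (any(diff(cycle) <= 0)) stop("cycle grid must be strictly increasing")
  df <- data.frame(cycle = cycle, f_ml = f_ml, f_pa = f_pa, f_is = f_is)
  df$resultant <- sqrt(df$f_ml^2 + df$f_pa^2 + df$f_is^2)
  structure(df, class = c("force_series", "data.frame"),
            frame = frame, side = side, subject_id = subject_id,
            activity = activity)
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("<force_series> %s %s [%s, side %s]: %d points, peak resultant %.0f %%BW\n",
              attr(x, "subject_id"), attr(x, "activity"), attr(x, "frame"),
              attr(x, "side"), nrow(x), max(x$resultant)))
  invisible(x)
}

#' Normalize a force to percent body weight
#'
#' @param force_n Force in N.
#' @param mass_kg Body mass in kg; must be positive.
#' @return Force in %BW: `100 * F / (mass * 9.81)`.
#' @export
normalize_bw <- function(force_n, mass_kg) {
  if (!is.finite(mass_kg) || mass_kg <= 0) stop("mass must be positive")
  100 * force_n / (mass_kg * G_ACC)
}

#' Transform a force series into the OrthoLoad femoral frame
#'
#' Applies the configured fixed rotation between the ISB-style femoral frame
#' and the OrthoLoad femoral frame, and mirrors left-side series in the
#' medial-lateral component so both sides share the convention that positive
#' `f_ml` points medially. The resultant is preserved exactly.
#'
#' @param series A `force_series` in the `ISB_femur` frame.
#' @param rotation Either a 3x3 rotation matrix or angles in degrees
#'   `c(rx, ry, rz)` applied as `Rz Ry Rx` on the (ml, pa, is) components;
#'   default no rotation.
#' @param side Side of the series; default its `side` attribute.
#' @return The transformed `force_series` (frame `OrthoLoad_femur`).
#' @export
to_orthoload_frame <- function(series, rotation = c(0, 0, 0), side = attr(series, "side")) {
  stopifnot(inherits(series, "force_series"))
  if (attr(series, "frame") != "ISB_femur")
    stop("series is already in the OrthoLoad frame")
  R <- if (is.matrix(rotation)) rotation
  else rot_zyx(deg2rad(rotation[1L]), deg2rad(rotation[2L]), deg2rad(rotation[3L]))
  V <- t(R %*% t(as.matrix(series[, c("f_ml", "f_pa", "f_is")])))
  if (identical(side, "L")) V[, 1L] <- -V[, 1L]
  force_series(series$cycle, V[, 1L], V[, 2L], V[, 3L], frame = "OrthoLoad_femur",
               side = side, subject_id = attr(series, "subject_id"),
               activity = attr(series, "activity"))
}

#' Resample a force series onto a uniform cycle grid
#'
#' @param series A `force_series`, or a data.frame with `cycle` (or `time`)
#'   plus component columns.
#' @param n Number of grid points (default 101: 0, 1, ..., 100%).
#' @return The series linearly interpolated onto the uniform grid.
#' @export
resample_cycle <- function(series, n = 101) {
  x <- if ("cycle" %in% names(series)) series$cycle else series$time
  if (length(x) < 2L) stop("need at least 2 samples")
  if (any(diff(x) <= 0)) stop("cycle/time must be strictly increasing")
  grid <- seq(min(x), max(x), length.out = n)
  pct <- (grid - min(x)) / (max(x) - min(x)) * 100
  comp <- lapply(c("f_ml", "f_pa", "f_is"), function(cn)
    stats::approx(x, series[[cn]], xout = grid)$y)
  force_series(pct, comp[[1L]], comp[[2L]], comp[[3L]],
               frame = if (inherits(series, "force_series")) attr(series, "frame") else "ISB_femur",
               side = if (inherits(series, "force_series")) attr(series, "side") else "R",
               subject_id = attr(series, "subject_id"),
               activity = attr(series, "activity"))
}

#' Peak force phase window
#'
#' For one-leg stance: the motion cycle is restricted to its central half
#' (25-75%, omitting the lifting and lowering of the leg), and the window is
#' the longest contiguous run with resultant at or above 75% of the maximum
#' within that central part (the plateau). For level walking: the local
#' maximum of the resultant nearest the contralateral toe-off event, plus or
#' minus 2.5% of the gait cycle (clipped to 0-100%).
#'
#' @param series A `force_series` (uses its resultant; conventionally the in
#'   vivo series defines the window).
#' @param activity `"one_leg_stance"` or `"level_walking"`.
#' @param events Named event phases in percent cycle; walking requires
#'   `contra_toe_off`.
#' @return A `pfp_window`: `list(start_pct, end_pct)`.
#' @export
detect_pfp <- function(series, activity = c("one_leg_stance", "level_walking"),
                       events = NULL) {
  activity <- match.arg(activity)
  cyc <- series$cycle
  res <- series$resultant
  if (activity == "one_leg_stance") {
    central <- which(cyc >= 25 & cyc <= 75)
    if (!length(central)) stop("cycle grid has no central 25-75% samples")
    thr <- 0.75 * max(res[central])
    above <- res[central] >= thr
    if (!any(above)) stop("empty plateau: maximum lies outside the central window")
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    idx <- central[starts[best]:ends[best]]
    win <- list(start_pct = cyc[idx[1L]], end_pct = cyc[idx[length(idx)]])
  } else {
    if (is.null(events) || is.null(events[["contra_toe_off"]]))
      stop("level walking requires the contralateral toe-off event")
    cto <- events[["contra_toe_off"]]
    n <- length(res)
    locmax <- which(diff(sign(diff(res))) < 0) + 1L
    if (!length(locmax)) stop("no local maximum in the resultant")
    pk <- locmax[which.min(abs(cyc[locmax] - cto))]
    win <- list(start_pct = max(0, cyc[pk] - 2.5), end_pct = min(100, cyc[pk] + 2.5))
  }
  structure(win, class = "pfp_window")
}

window_mask <- function(series, window) {
  series$cycle >= window$start_pct - 1e-9 & series$cycle <= window$end_pct + 1e-9
}

#' Percentage deviation of the peak force phase
#'
#' `100 * (mean sim resultant - mean vivo resultant) / mean vivo resultant`
#' over the window; one value per subject.
#'
#' @param sim,vivo `force_series` on a common grid.
#' @param window A `pfp_window`.
#' @return Signed percentage deviation.
#' @export
pd_pfp <- function(sim, vivo, window) {
  m <- window_mask(vivo, window)
  if (!any(m)) stop("empty PFP window")
  mv <- mean(vivo$resultant[m])
  if (abs(mv) < .Machine$double.eps) stop("in vivo PFP mean is zero")
  ms <- mean(sim$resultant[window_mask(sim, window)])
  100 * (ms - mv) / mv
}

#' Mean absolute percentage error over subjects
#'
#' @param pd Vector of per-subject percentage deviations ([pd_pfp()]).
#' @return Mean of the absolute deviations, %.
#' @export
mape_pfp <- function(pd) mean(abs(pd))

angle_deg <- function(a, b) {
  na <- norm3(a); nb <- norm3(b)
  if (na < 1e-12 || nb < 1e-12) return(0)
  rad2deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}

#' Angular deviation of the peak force phase
#'
#' Angle between the window-mean simulated and in vivo force vectors, in 3D
#' and projected into the three anatomical planes: flexion-extension
#' (sagittal, PA-IS components), adduction-abduction (frontal, ML-IS), and
#' internal-external rotation (transverse, ML-PA). Absolute values in degrees.
#'
#' @inheritParams pd_pfp
#' @return Named vector `c(fe, aa, ie, d3)` in degrees.
#' @export
mad_pfp <- function(sim, vivo, window) {
  ms <- window_mask(sim, window)
  mv <- window_mask(vivo, window)
  if (!any(ms) || !any(mv)) stop("empty PFP window")
  vs <- c(mean(sim$f_ml[ms]), mean(sim$f_pa[ms]), mean(sim$f_is[ms]))
  vv <- c(mean(vivo$f_ml[mv]), mean(vivo$f_pa[mv]), mean(vivo$f_is[mv]))
  proj <- function(v, keep) v[keep]
  c(fe = abs(angle_deg(c(proj(vs, 2:3), 0), c(proj(vv, 2:3), 0))),
    aa = abs(angle_deg(c(proj(vs, c(1, 3)), 0), c(proj(vv, c(1, 3)), 0))),
    ie = abs(angle_deg(c(proj(vs, 1:2), 0), c(proj(vv, 1:2), 0))),
    d3 = abs(angle_deg(vs, vv)))
}

#' Component root-mean-square errors over the full cycle
#'
#' @inheritParams pd_pfp
#' @return Named vector `c(ml, pa, is, r)` in %BW; `r` is the RMSE of the
#'   resultants.
#' @export
rmse_components <- function(sim, vivo) {
  if (nrow(sim) != nrow(vivo)) stop("series length mismatch")
  rm_ <- function(a, b) sqrt(mean((a - b)^2))
  c(ml = rm_(sim$f_ml, vivo$f_ml), pa = rm_(sim$f_pa, vivo$f_pa),
    is = rm_(sim$f_is, vivo$f_is), r = rm_(sim$resultant, vivo$resultant))
}

#' Correlation analysis per component and resultant
#'
#' Squared Pearson correlation between simulated and in vivo samples pooled
#' over the full cycle (and, at cohort level, over subjects), with the
#' two-sided significance test of zero correlation and the linear regression
#' of sim on vivo.
#'
#' @param sim,vivo Data frames (or `force_series`) with components on a
#'   common grid; rows may pool several subjects.
#' @return A data.frame with one row per quantity: `r2`, `p`, `slope`,
#'   `intercept`, `n`.
#' @export
correlate <- function(sim, vivo) {
  if (nrow(sim) != nrow(vivo)) stop("series length mismatch")
  if (nrow(sim) < 3L) stop("need at least 3 paired samples")
  one <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(c(r2 = NA_real_, p = NA_real_, slope = NA_real_, intercept = NA_real_, n = length(x)))
    ct <- stats::cor.test(x, y)
    fit <- stats::lm(y ~ x)
    c(r2 = unname(ct$estimate)^2, p = ct$p.value,
      slope = unname(stats::coef(fit)[2L]), intercept = unname(stats::coef(fit)[1L]),
      n = length(x))
  }
  out <- rbind(ml = one(vivo$f_ml, sim$f_ml), pa = one(vivo$f_pa, sim$f_pa),
               is = one(vivo$f_is, sim$f_is), r = one(vivo$resultant, sim$resultant))
  data.frame(quantity = rownames(out), out, row.names = NULL)
}

#' Bland-Altman comparison with nonparametric limits of agreement
#'
#' Differences `d = sim - vivo` are pooled over the cycle (and subjects); the
#' limits of agreement are `median(d) +/- 1.45 * IQR(d)`, with quartiles by
#' linear interpolation of the order statistics (the default quantile
#' convention).
#'
#' @inheritParams correlate
#' @return A data.frame per quantity: `median_diff`, `loa_low`, `loa_high`,
#'   `iqr`.
#' @export
bland_altman <- function(sim, vivo) {
  if (nrow(sim) == 0L) stop("empty input")
  if (nrow(sim) != nrow(vivo)) stop("series length mismatch")
  one <- function(d) {
    md <- stats::median(d)
    iq <- unname(diff(stats::quantile(d, c(0.25, 0.75), type = 7)))
    c(median_diff = md, loa_low = md - 1.45 * iq, loa_high = md + 1.45 * iq, iqr = iq)
  }
  out <- rbind(ml = one(sim$f_ml - vivo$f_ml), pa = one(sim$f_pa - vivo$f_pa),
               is = one(sim$f_is - vivo$f_is), r = one(sim$resultant - vivo$resultant))
  data.frame(quantity = rownames(out), out, row.names = NULL)
}

#' Normality and location tests
#'
#' Kolmogorov-Smirnov test of the differences `sim - vivo` against a normal
#' distribution with the sample's mean and standard deviation, and the
#' two-sided Mann-Whitney U test of the pooled simulated versus in vivo
#' samples, per component and resultant.
#'
#' @inheritParams correlate
#' @param alpha Significance level reported alongside the p-values.
#' @return A data.frame per quantity: `ks_p`, `mw_p`, `alpha`.
#' @export
nonparam_tests <- function(sim, vivo, alpha = 0.05) {
  if (nrow(sim) != nrow(vivo)) stop("series length mismatch")
  if (nrow(sim) < 8L) stop("need at least 8 samples")
  one <- function(x, y) {
    d <- x - y
    ks <- if (stats::sd(d) < 1e-12) NA_real_
    else suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d))$p.value)
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    c(ks_p = ks, mw_p = mw)
  }
  out <- rbind(ml = one(sim$f_ml, vivo$f_ml), pa = one(sim$f_pa, vivo$f_pa),
               is = one(sim$f_is, vivo$f_is), r = one(sim$resultant, vivo$resultant))
  data.frame(quantity = rownames(out), out, alpha = alpha, row.names = NULL)
}

#' Per-subject metrics report
#'
#' Computes the full deviation suite between a simulated and an in vivo force
#' series for one subject and activity: the peak-force-phase window (from the
#' in vivo series), the percentage deviation and angular deviations over that
#' window, component RMSE over the full cycle, correlation, Bland-Altman, and
#' the nonparametric tests.
#'
#' @param sim,vivo `force_series` in the OrthoLoad frame on a common grid.
#' @param activity `"one_leg_stance"` or `"level_walking"`.
#' @param events Event list for walking (see [detect_pfp()]).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(sim, vivo, activity, events = NULL) {
  win <- detect_pfp(vivo, activity, events)
  structure(
    list(window = win,
         pd_pfp = pd_pfp(sim, vivo, win),
         mad_pfp = mad_pfp(sim, vivo, win),
         rmse = rmse_components(sim, vivo),
         correlation = correlate(sim, vivo),
         bland_altman = bland_altman(sim, vivo),
         tests = nonparam_tests(sim, vivo),
         subject_id = attr(sim, "subject_id"), activity = activity),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s %s | PFP [%.1f, %.1f]%%\n",
              x$subject_id, x$activity, x$window$start_pct, x$window$end_pct))
  cat(sprintf("  PD^PFP %+.1f%% | MAD^PFP 3D %.1f deg | RMSE_R %.1f %%BW\n",
              x$pd_pfp, x$mad_pfp[["d3"]], x$rmse[["r"]]))
  invisible(x)
}
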