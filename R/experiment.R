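# Orchestration of the factorial study: one pipeline run per (subject,
# activity, parameter combination), the muscle-strength sweep, and the
# cohort-level aggregation tables.

#' Run the full pipeline for one trial and one parameter combination
#'
#' Executes kinematics (parameter optimization and per-frame pose solve),
#' inverse dynamics with the combination's muscle model, strength and
#' recruitment criterion, and the validation metrics against the in vivo
#' series. Failed recruitments (infeasible frames) are recorded and excluded
#' from metrics, mirroring the exclusion of unsuccessful simulations.
#'
#' @param trial A `trial_data` object.
#' @param vivo The matching in vivo `force_series` (OrthoLoad frame).
#' @param combo A [combo_spec()].
#' @param kin Optional precomputed `kinematics_result` for this trial and
#'   `combo$hjw_mode` (lets sweeps share the expensive kinematic step).
#' @param rotation ISB-to-OrthoLoad rotation passed to
#'   [to_orthoload_frame()].
#' @param pn_bounded Enforce strength caps for the polynomial criterion.
#' @return A list: `status` (`ok`/`failed`), `force` (simulated
#'   `force_series`, %BW, OrthoLoad frame, 101-point grid) or `NULL`,
#'   `metrics` ([metrics_report()]) or `NULL`, `kin`, failure details.
#' @export
run_combo <- function(trial, vivo, combo, kin = NULL,
                      rotation = default_rotation(), pn_bounded = FALSE) {
  stopifnot(inherits(trial, "trial_data"), inherits(combo, "combo_spec"))
  an <- trial$anthro
  if (is.null(kin)) kin <- combo_kinematics(trial, combo$hjw_mode)
  loads <- net_joint_loads(kin$model, kin, trial$grf, side = an$side)
  hip <- hip_reaction(kin$model, kin, loads, combo, pn_bounded = pn_bounded)
  if (hip$status != "ok") {
    return(list(status = "failed", reason = hip$fail_reason,
                fail_frame = hip$fail_frame, force = NULL, metrics = NULL,
                kin = kin, combo = combo))
  }
  tt <- hip$time
  pct <- (tt - tt[1L]) / (tt[length(tt)] - tt[1L]) * 100
  fs <- force_series(pct, normalize_bw(hip$force_femur[, "ml"], an$mass),
                     normalize_bw(hip$force_femur[, "pa"], an$mass),
                     normalize_bw(hip$force_femur[, "is"], an$mass),
                     frame = "ISB_femur", side = an$side,
                     subject_id = an$subject_id, activity = trial$activity)
  fs <- to_orthoload_frame(resample_cycle(fs), rotation = rotation)
  metrics <- metrics_report(fs, vivo, trial$activity, trial$events)
  list(status = "ok", force = fs, metrics = metrics, kin = kin, combo = combo,
       max_activation = max(hip$max_activation, na.rm = TRUE))
}

# Kinematic step for a trial under one hjw_mode (CT frozen / C3D free).
combo_kinematics <- function(trial, hjw_mode, opts = list()) {
  model <- build_reference_model(trial$anthro, hjw_mode = hjw_mode)
  model <- scale_model(model, NULL)
  fit <- optimize_parameters(model, trial$markers, opts)
  solve_frame_kinematics(model, trial$markers, scales = fit)
}

# Cache of kinematics per (subject, activity, hjw_mode) for a cohort.
cohort_kinematics <- function(cohort, hjw_modes = c("C3D", "CT"), opts = list(),
                              progress = FALSE) {
  cache <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    for (act in c("stance", "gait")) {
      for (hm in hjw_modes) {
        key <- paste(sid, act, hm, sep = "|")
        cache[[key]] <- combo_kinematics(sub[[act]], hm, opts)
        if (progress) message("kinematics ", key)
      }
    }
  }
  cache
}

#' Factorial parameter sweep over a synthetic cohort
#'
#' Runs every parameter combination for every subject and both activities
#' (16 x 10 x 2 = 320 runs for the default design and cohort), reusing the
#' kinematic solution per (subject, activity, hip-joint-width mode).
#' Unsuccessful runs are recorded in the failure ledger and excluded from the
#' per-combination aggregation.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param combos List of [combo_spec()]s (default the full 16-cell grid).
#' @param kin_cache Optional precomputed [cohort kinematics][run_combo]
#'   cache.
#' @param rotation ISB-to-OrthoLoad rotation.
#' @return A `sweep_result` list: `runs` (one row per run), `table`
#'   (per-combination aggregates: n successful, MAPE and MAD mean and SD over
#'   subjects, pooled RMSE and r^2), `failures`, and the cache.
#' @export
factorial_sweep <- function(cohort, combos = combo_grid(), kin_cache = NULL,
                            rotation = default_rotation()) {
  if (is.null(kin_cache)) {
    modes <- unique(vapply(combos, `[[`, "", "hjw_mode"))
    kin_cache <- cohort_kinematics(cohort, modes)
  }
  runs <- NULL
  results <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    for (act in c("stance", "gait")) {
      trial <- sub[[act]]
      vivo <- sub[[if (act == "stance") "vivo_stance" else "vivo_gait"]]
      for (ci in seq_along(combos)) {
        cb <- combos[[ci]]
        key <- paste(sid, act, cb$hjw_mode, sep = "|")
        res <- run_combo(trial, vivo, cb, kin = kin_cache[[key]],
                         rotation = rotation)
        res$vivo <- vivo
        rkey <- paste(sid, act, ci, sep = "|")
        results[[rkey]] <- res
        runs <- rbind(runs, data.frame(
          subject_id = sid, activity = trial$activity,
          hjw_mode = cb$hjw_mode, sigma = cb$sigma,
          recruitment = cb$recruitment, muscle_model = cb$muscle_model,
          status = res$status,
          pd_pfp = if (res$status == "ok") res$metrics$pd_pfp else NA_real_,
          mad_fe = if (res$status == "ok") res$metrics$mad_pfp[["fe"]] else NA_real_,
          mad_aa = if (res$status == "ok") res$metrics$mad_pfp[["aa"]] else NA_real_,
          mad_ie = if (res$status == "ok") res$metrics$mad_pfp[["ie"]] else NA_real_,
          mad_3d = if (res$status == "ok") res$metrics$mad_pfp[["d3"]] else NA_real_,
          rmse_r = if (res$status == "ok") res$metrics$rmse[["r"]] else NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  table <- aggregate_sweep(runs, results, combos)
  failures <- runs[runs$status != "ok", , drop = FALSE]
  structure(list(runs = runs, table = table, failures = failures,
                 results = results, kin_cache = kin_cache),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs (%d failed) over %d combination cells\n",
              nrow(x$runs), nrow(x$failures), nrow(x$table)))
  invisible(x)
}

# Per-combination aggregation: subject-level MAPE/MAD statistics, plus RMSE
# and r^2 pooled over all successful subjects' resampled cycles.
aggregate_sweep <- function(runs, results, combos) {
  key_cols <- c("activity", "hjw_mode", "sigma", "recruitment", "muscle_model")
  cells <- unique(runs[, key_cols])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    ci <- which(vapply(combos, function(cb)
      cb$hjw_mode == cell$hjw_mode && cb$sigma == cell$sigma &&
        cb$recruitment == cell$recruitment && cb$muscle_model == cell$muscle_model,
      NA))[1L]
    sel <- runs$activity == cell$activity & runs$hjw_mode == cell$hjw_mode &
      runs$sigma == cell$sigma & runs$recruitment == cell$recruitment &
      runs$muscle_model == cell$muscle_model
    ok <- sel & runs$status == "ok"
    pool_sim <- NULL; pool_vivo <- NULL
    for (k in which(ok)) {
      sid <- runs$subject_id[k]
      act <- if (runs$activity[k] == "one_leg_stance") "stance" else "gait"
      res <- results[[paste(sid, act, ci, sep = "|")]]
      pool_sim <- rbind(pool_sim, as.data.frame(res$force))
      pool_vivo <- rbind(pool_vivo, as.data.frame(res$vivo))
    }
    if (!is.null(pool_sim)) {
      rmse_pool <- rmse_components(pool_sim, pool_vivo)
      corr <- correlate(pool_sim, pool_vivo)
    } else {
      rmse_pool <- c(ml = NA_real_, pa = NA_real_, is = NA_real_, r = NA_real_)
      corr <- data.frame(quantity = c("ml", "pa", "is", "r"), r2 = NA_real_,
                         p = NA_real_)
    }
    apd <- abs(runs$pd_pfp[ok])
    row <- data.frame(
      cell, n = sum(ok),
      mape_pfp = mean(apd), mape_pfp_sd = stats::sd(apd),
      mad_fe = mean(runs$mad_fe[ok]), mad_fe_sd = stats::sd(runs$mad_fe[ok]),
      mad_aa = mean(runs$mad_aa[ok]), mad_aa_sd = stats::sd(runs$mad_aa[ok]),
      mad_ie = mean(runs$mad_ie[ok]), mad_ie_sd = stats::sd(runs$mad_ie[ok]),
      mad_3d = mean(runs$mad_3d[ok]), mad_3d_sd = stats::sd(runs$mad_3d[ok]),
      rmse_ml = unname(rmse_pool[["ml"]]), rmse_pa = unname(rmse_pool[["pa"]]),
      rmse_is = unname(rmse_pool[["is"]]), rmse_r = unname(rmse_pool[["r"]]),
      r2_ml = corr$r2[corr$quantity == "ml"], r2_pa = corr$r2[corr$quantity == "pa"],
      r2_is = corr$r2[corr$quantity == "is"], r2_r = corr$r2[corr$quantity == "r"],
      p_r = corr$p[corr$quantity == "r"],
      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  out
}

#' Muscle-strength sweep
#'
#' Gradually varies the muscle strength for the CT hip joint width, polynomial
#' recruitment and simple muscle model, with the strength caps enforced (the
#' saturation effect under investigation), and reports the mean absolute
#' error of the resultant hip force over the full motion cycle per strength,
#' with Mann-Whitney tests between consecutive strengths. Above the level at
#' which no fascicle reaches its maximum force the solution is
#' strength-invariant and the error curve is flat; below it the recruitment
#' redistributes and the error grows.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param sigmas Ascending muscle strengths, N/cm^2.
#' @param combo_base Base combination fields (hjw_mode, recruitment,
#'   muscle_model).
#' @param kin_cache Optional precomputed kinematics cache.
#' @param rotation ISB-to-OrthoLoad rotation.
#' @return A `strength_sweep` list: `mae` (per run), `summary` (per sigma),
#'   `tests` (consecutive-sigma Mann-Whitney p-values).
#' @export
strength_sweep <- function(cohort, sigmas = c(20, 25, 30, 45, 60, 90),
                           combo_base = list(hjw_mode = "CT", recruitment = "PN",
                                             muscle_model = "simple"),
                           kin_cache = NULL, rotation = default_rotation()) {
  if (is.unsorted(sigmas)) stop("sigmas must be sorted ascending")
  if (is.null(kin_cache)) kin_cache <- cohort_kinematics(cohort, combo_base$hjw_mode)
  mae <- NULL
  for (sg in sigmas) {
    cb <- combo_spec(combo_base$hjw_mode, sg, combo_base$recruitment,
                     combo_base$muscle_model)
    for (sid in names(cohort$subjects)) {
      sub <- cohort$subjects[[sid]]
      for (act in c("stance", "gait")) {
        trial <- sub[[act]]
        vivo <- sub[[if (act == "stance") "vivo_stance" else "vivo_gait"]]
        key <- paste(sid, act, cb$hjw_mode, sep = "|")
        res <- run_combo(trial, vivo, cb, kin = kin_cache[[key]],
                         rotation = rotation, pn_bounded = TRUE)
        mae <- rbind(mae, data.frame(
          sigma = sg, subject_id = sid, activity = trial$activity,
          status = res$status,
          mae_r = if (res$status == "ok")
            mean(abs(res$force$resultant - vivo$resultant)) else NA_real_,
          max_activation = if (res$status == "ok") res$max_activation else NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  summary <- do.call(rbind, lapply(split(mae, mae$sigma), function(df) data.frame(
    sigma = df$sigma[1L], n = sum(df$status == "ok"),
    mae_r = mean(df$mae_r, na.rm = TRUE), mae_r_sd = stats::sd(df$mae_r, na.rm = TRUE),
    max_activation = suppressWarnings(max(df$max_activation, na.rm = TRUE)))))
  summary <- summary[order(summary$sigma), ]
  tests <- NULL
  if (length(sigmas) > 1L) {
    for (i in seq_len(length(sigmas) - 1L)) {
      a <- mae$mae_r[mae$sigma == sigmas[i] & mae$status == "ok"]
      b <- mae$mae_r[mae$sigma == sigmas[i + 1L] & mae$status == "ok"]
      p <- if (length(a) >= 2L && length(b) >= 2L)
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value) else NA_real_
      tests <- rbind(tests, data.frame(sigma_low = sigmas[i], sigma_high = sigmas[i + 1L],
                                       mw_p = p))
    }
  }
  structure(list(mae = mae, summary = summary, tests = tests),
            class = "strength_sweep")
}

#' @export
print.strength_sweep <- function(x, ...) {
  cat("<strength_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Aggregate per-subject values into a cohort table
#'
#' Cohort mean and standard deviation per (activity, component, series) group
#' of a per-subject table, with mean-absolute-error cells above 50 %BW
#' flagged, following the convention of the per-subject full-cycle reports.
#'
#' @param per_subject A data.frame with columns `subject_id`, `value`, and
#'   optionally `activity`, `component`, `series` (e.g. `"AB"` simulated,
#'   `"OL"` in vivo, `"MAE"`); or a plain numeric vector treated as one MAE
#'   group.
#' @param flag_threshold Flagging threshold for MAE cells, %BW (default 50).
#' @return A list: `table` (group rows with `mean`, `sd`, `n`, `n_flagged`)
#'   and `cells` (the input with a per-cell `flagged` column).
#' @export
aggregate_report <- function(per_subject, flag_threshold = 50) {
  if (is.numeric(per_subject)) {
    per_subject <- data.frame(subject_id = seq_along(per_subject),
                              value = per_subject, series = "MAE",
                              stringsAsFactors = FALSE)
  }
  if (anyNA(per_subject$value)) stop("missing subject value in per-subject table")
  for (col in c("activity", "component", "series"))
    if (is.null(per_subject[[col]])) per_subject[[col]] <- "all"
  per_subject$flagged <- per_subject$series == "MAE" &
    per_subject$value > flag_threshold
  groups <- split(per_subject,
                  list(per_subject$activity, per_subject$component, per_subject$series),
                  drop = TRUE)
  table <- do.call(rbind, lapply(groups, function(df) data.frame(
    activity = df$activity[1L], component = df$component[1L], series = df$series[1L],
    n = nrow(df), mean = mean(df$value), sd = stats::sd(df$value),
    n_flagged = sum(df$flagged), stringsAsFactors = FALSE)))
  rownames(table) <- NULL
  list(table = table, cells = per_subject)
}
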