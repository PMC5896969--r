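# Plain-text file interfaces: marker and force-plate CSVs (lab frame,
# right-handed, +z up, coordinates in mm), cycle-normalized force CSVs in
# %BW, and the YAML model description.

#' Write / read marker trajectories as CSV
#'
#' Long format: `time_s, marker_id, x_mm, y_mm, z_mm, valid`.
#'
#' @param markers A `marker_data` object.
#' @param path Output file.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_data"))
  nT <- length(markers$time)
  n <- length(markers$ids)
  df <- data.frame(
    time_s = rep(markers$time, each = n),
    marker_id = rep(markers$ids, nT),
    x_mm = as.vector(t(markers$positions[, , 1L])) * 1000,
    y_mm = as.vector(t(markers$positions[, , 2L])) * 1000,
    z_mm = as.vector(t(markers$positions[, , 3L])) * 1000,
    valid = as.integer(as.vector(t(markers$validity))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @param segment_map Named vector mapping marker ids to model segments;
#'   defaults to the standard 25-marker set of [build_reference_model()].
#' @return `read_marker_csv` returns a `marker_data` object.
#' @export
read_marker_csv <- function(path, segment_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker_id", "x_mm", "y_mm", "z_mm", "valid")
  if (!all(need %in% names(df))) stop("marker CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  ids <- unique(df$marker_id)
  time <- sort(unique(df$time_s))
  nT <- length(time); n <- length(ids)
  pos <- array(NA_real_, c(nT, n, 3L))
  val <- matrix(FALSE, nT, n)
  ti <- match(df$time_s, time); mi <- match(df$marker_id, ids)
  idx <- cbind(ti, mi)
  pos[cbind(idx, 1L)] <- df$x_mm / 1000
  pos[cbind(idx, 2L)] <- df$y_mm / 1000
  pos[cbind(idx, 3L)] <- df$z_mm / 1000
  val[idx] <- df$valid > 0
  if (is.null(segment_map)) {
    ref <- marker_set_geometry(1.75, 0.085, 0.43, 0.43, 0.27, 0.068)
    segment_map <- setNames(ref$segment, ref$marker_id)
  }
  marker_data(time, ids, unname(segment_map[ids]), pos, val)
}

#' Write / read a force-plate series as CSV
#'
#' Columns: `time_s, Fx_N, Fy_N, Fz_N, COPx_mm, COPy_mm, plate_id`.
#'
#' @param grf A `grf_data` object.
#' @param path Output file.
#' @export
write_grf_csv <- function(grf, path) {
  stopifnot(inherits(grf, "grf_data"))
  df <- data.frame(time_s = grf$time,
                   Fx_N = grf$force[, 1L], Fy_N = grf$force[, 2L], Fz_N = grf$force[, 3L],
                   COPx_mm = grf$cop[, 1L] * 1000, COPy_mm = grf$cop[, 2L] * 1000,
                   plate_id = grf$plate_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grf_csv
#' @return `read_grf_csv` returns a `grf_data` object.
#' @export
read_grf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "Fx_N", "Fy_N", "Fz_N", "COPx_mm", "COPy_mm")
  if (!all(need %in% names(df))) stop("force-plate CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  grf_data(df$time_s, cbind(df$Fx_N, df$Fy_N, df$Fz_N),
           cbind(df$COPx_mm / 1000, df$COPy_mm / 1000, 0),
           plate_id = if ("plate_id" %in% names(df)) df$plate_id[1L] else "plate1")
}

#' Write / read a cycle-normalized force series as CSV
#'
#' Columns: `cycle_pct, F_ML_pctBW, F_PA_pctBW, F_IS_pctBW, side, subject_id,
#' activity` (frame recorded in a comment-free extra column).
#'
#' @param series A `force_series`.
#' @param path Output file.
#' @export
write_force_csv <- function(series, path) {
  stopifnot(inherits(series, "force_series"))
  df <- data.frame(cycle_pct = series$cycle, F_ML_pctBW = series$f_ml,
                   F_PA_pctBW = series$f_pa, F_IS_pctBW = series$f_is,
                   side = attr(series, "side"), subject_id = attr(series, "subject_id"),
                   activity = attr(series, "activity"), frame = attr(series, "frame"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @return `read_force_csv` returns a `force_series`.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  force_series(df$cycle_pct, df$F_ML_pctBW, df$F_PA_pctBW, df$F_IS_pctBW,
               frame = if ("frame" %in% names(df)) df$frame[1L] else "OrthoLoad_femur",
               side = df$side[1L], subject_id = df$subject_id[1L],
               activity = df$activity[1L])
}

#' Write / read a body model description (YAML)
#'
#' Flat key-value header (subject, hip joint width and mode, scale factors)
#' plus tabular sections for segments, joints and fascicles; attachment
#' coordinates in mm, PCSA in cm^2.
#'
#' @param model A `body_model`.
#' @param path Output file.
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  an <- model$anthro
  doc <- list(
    subject = list(subject_id = an$subject_id, side = an$side, age = an$age,
                   sex = an$sex, mass_kg = an$mass, height_m = an$height,
                   hjw_ct_mm = an$hjw_ct),
    hjw_mm = model$hjw, hjw_mode = model$hjw_mode,
    length_scales = as.list(model$length_scales),
    cross_section_scale = model$cross_section_scale,
    n_fascicles = model$n_fascicles,
    segments = lapply(model$segments, function(s)
      list(name = s$name, mass_kg = s$mass, length_mm = s$length * 1000,
           com_mm = as.numeric(s$com) * 1000,
           inertia_kgm2 = if (is.null(s$inertia)) NULL else as.numeric(s$inertia))),
    joints = model$joints,
    fascicles = lapply(model$fascicles, function(f)
      list(name = f$name, side = f$side, pcsa_cm2 = f$pcsa,
           origin_segment = f$origin_segment, origin_mm = as.numeric(f$origin) * 1000,
           insertion_segment = f$insertion_segment,
           insertion_mm = as.numeric(f$insertion) * 1000,
           hill = f$hill)))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' @rdname write_model_file
#' @return `read_model_file` returns the `body_model` rebuilt from the file's
#'   subject block and parameters (geometry is regenerated, guaranteeing the
#'   model invariants).
#' @export
read_model_file <- function(path) {
  doc <- yaml::read_yaml(path)
  an <- anthropometrics(doc$subject$subject_id, doc$subject$side, doc$subject$age,
                        doc$subject$sex, doc$subject$mass_kg, doc$subject$height_m,
                        doc$subject$hjw_ct_mm)
  model <- build_reference_model(an, n_fascicles = doc$n_fascicles,
                                 hjw_mode = doc$hjw_mode)
  model$cross_section_scale <- doc$cross_section_scale
  model <- set_scales_abs(model, unlist(doc$length_scales), hjw = doc$hjw_mm)
  model
}

#' Write a cohort manifest
#'
#' One row per generated trial: subject, side, activity, generator seed, in
#' vivo seed, and the truth combination.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param path Output CSV.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
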