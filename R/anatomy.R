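#' Subject anthropometrics
#'
#' Bundles the per-subject measurements that drive model construction: body
#' mass and height, the instrumented side, and the hip joint width (HJW, the
#' distance between the left and right hip joint centers) measured on a
#' postoperative CT scan.
#'
#' @param subject_id Subject label, e.g. `"H1L"`.
#' @param side Instrumented side, `"L"` or `"R"`.
#' @param age Age in years.
#' @param sex `"m"` or `"f"`.
#' @param mass Body mass in kg; must be positive.
#' @param height Body height in m; must be positive.
#' @param hjw_ct CT-measured hip joint width in mm; must be positive.
#'
#' @return An object of class `anthropometrics`.
#' @export
anthropometrics <- function(subject_id, side, age, sex, mass, height, hjw_ct) {
  side <- match.arg(side, c("L", "R"))
  sex <- match.arg(sex, c("m", "f"))
  if (!is.finite(mass) || mass <= 0) stop("invalid anthropometrics: mass must be positive")
  if (!is.finite(height) || height <= 0) stop("invalid anthropometrics: height must be positive")
  if (!is.finite(hjw_ct) || hjw_ct <= 0) stop("invalid anthropometrics: hjw_ct must be positive")
  structure(
    list(subject_id = as.character(subject_id), side = side, age = age, sex = sex,
         mass = mass, height = height, bmi = compute_bmi(mass, height),
         hjw_ct = hjw_ct),
    class = "anthropometrics")
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat(sprintf("<anthropometrics> %s (%s, %s): %.1f kg, %.2f m, BMI %.1f, CT-HJW %d mm\n",
              x$subject_id, x$side, x$sex, x$mass, x$height, x$bmi, round(x$hjw_ct)))
  invisible(x)
}

#' Body mass index
#'
#' @param mass Body mass in kg.
#' @param height Body height in m; must be positive.
#' @return BMI in kg/m^2, rounded to one decimal as reported in cohort tables.
#' @export
compute_bmi <- function(mass, height) {
  if (any(!is.finite(height)) || any(height <= 0)) stop("height must be positive")
  round(mass / height^2, 1)
}

#' Ten-subject reference cohort
#'
#' Anthropometrics of the ten instrumented-prosthesis (Hip III) subjects used
#' as the default synthetic cohort: identifier, implanted side, age, sex, body
#' mass, height, BMI, and CT-measured hip joint width.
#'
#' @return A data.frame with one row per subject.
#' @export
reference_cohort <- function() {
  data.frame(
    subject_id = c("H1L", "H2R", "H3L", "H4L", "H5L", "H6R", "H7R", "H8L", "H9L", "H10R"),
    side = c("L", "R", "L", "L", "L", "R", "R", "L", "L", "R"),
    age = c(55, 61, 59, 50, 62, 68, 52, 55, 54, 53),
    sex = c("m", "m", "m", "m", "f", "m", "m", "m", "m", "f"),
    mass = c(77.5, 78.2, 90.9, 81.1, 87.2, 83.1, 93.4, 85.2, 122.0, 101.4),
    height = c(1.78, 1.72, 1.68, 1.78, 1.68, 1.76, 1.79, 1.78, 1.81, 1.62),
    bmi = c(24.5, 26.4, 32.2, 25.6, 30.9, 26.8, 29.1, 26.9, 37.2, 38.6),
    hjw_ct = c(166, 160, 174, 174, 186, 157, 172, 180, 174, 176),
    stringsAsFactors = FALSE)
}

# Standard segment mass fractions (HAT lump includes the pelvis) and length
# proportions relative to body height. The fractions sum to exactly 1 with two
# legs, so segment masses conserve body mass by construction.
MASS_FRACTIONS <- c(pelvis = 0.142, hat = 0.536, thigh = 0.100, shank = 0.0465, foot = 0.0145)
LENGTH_FRACTIONS <- c(thigh = 0.245, shank = 0.246, foot = 0.152, ankle_h = 0.039)

# Reference individual for the cross-section scaling law.
REF_MASS <- 75
REF_HEIGHT <- 1.75

side_sign <- function(side) ifelse(side == "L", 1, -1)

# Hip-spanning fascicle group definitions, parametric in half hip joint width
# `hw` (m) and thigh length `lt` (m). Origins are pelvis-local (origin
# mid-hip), insertions femur-local (origin hip center, z up, segment along
# -z). `s` is the side sign (+1 left, -1 right). PCSA in cm^2. Each group is
# a fan of fibers: `spread` displaces the two sub-fascicle origins (and, less,
# insertions) in opposite directions, giving staggered moment arms so that
# recruitment saturates gradually as strength falls.
fascicle_table <- function(hw, lt, s) {
  list(
    list(name = "glut_med_ant", pcsa = 20, spread = c(0.025, 0, 0.01),
         origin = c(0.03, s * (hw + 0.035), 0.10), insertion = c(-0.005, s * 0.055, -0.045)),
    list(name = "glut_med_post", pcsa = 25, spread = c(0.025, 0, 0.01),
         origin = c(-0.04, s * (hw + 0.030), 0.10), insertion = c(-0.012, s * 0.055, -0.045)),
    list(name = "glut_max", pcsa = 45, spread = c(0.02, s * 0.05, 0.03),
         origin = c(-0.09, s * 0.02, 0.06), insertion = c(-0.02, s * 0.035, -0.09)),
    list(name = "iliopsoas", pcsa = 25, spread = c(0.012, 0, 0.02),
         origin = c(0.05, s * 0.045, 0.01), insertion = c(-0.015, -s * 0.02, -0.055)),
    list(name = "adductor", pcsa = 30, spread = c(0.02, 0, 0.03),
         origin = c(0.055, s * 0.025, -0.01), insertion = c(-0.01, -s * 0.005, -0.18)),
    # sub b is a tensor-fasciae-latae equivalent: lateral origin, iliotibial
    # insertion, a second-line abductor with a shorter arm than gluteus medius
    list(name = "rect_fem", pcsa = 25, share = c(0.5, 0.35, 0.30),
         spread = c(0.012, 0, 0.01),
         origin = c(0.05, s * (hw + 0.005), 0.01), insertion = c(0.035, 0, -0.90 * lt),
         origin_b = c(0.05, s * (hw + 0.03), 0.02),
         insertion_b = c(0.01, s * 0.05, -0.90 * lt))
  )
}

# Rebuild the geometric part (segments, fascicle attachments, marker locals)
# of a model from its stored parameters. Called by every mutator so that hip
# centers, attachments and marker placements stay consistent with hjw and the
# current scale factors.
rebuild_geometry <- function(model) {
  an <- model$anthro
  H <- an$height
  M <- an$mass
  hw <- model$hjw / 2000  # mm -> m, half-width
  sc <- model$length_scales
  k <- model$cross_section_scale
  kp <- sqrt(k)  # perpendicular linear dimensions

  lt <- LENGTH_FRACTIONS[["thigh"]] * H * sc[["thigh"]]
  ls <- LENGTH_FRACTIONS[["shank"]] * H * sc[["shank"]]
  lf <- LENGTH_FRACTIONS[["foot"]] * H * sc[["foot"]]
  ah <- LENGTH_FRACTIONS[["ankle_h"]] * H * sc[["foot"]]

  segs <- list(
    pelvis = list(name = "pelvis", side = NA, mass = MASS_FRACTIONS[["pelvis"]] * M,
                  length = 2 * hw, com = c(0, 0, 0.02), parent = NA),
    hat = list(name = "hat", side = NA, mass = MASS_FRACTIONS[["hat"]] * M,
               length = 0.4 * H, com = c(0, 0, 0.22 * H), parent = "pelvis"))
  for (sd in c("R", "L")) {
    s <- side_sign(sd)
    rg <- function(m, l) m * (0.33 * l)^2  # slender-rod radius of gyration
    segs[[paste0("femur_", sd)]] <- list(
      name = paste0("femur_", sd), side = sd, mass = MASS_FRACTIONS[["thigh"]] * M,
      length = lt, com = c(0, 0, -0.433 * lt),
      inertia = c(rg(MASS_FRACTIONS[["thigh"]] * M, lt), rg(MASS_FRACTIONS[["thigh"]] * M, lt),
                  0.02 * rg(MASS_FRACTIONS[["thigh"]] * M, lt)),
      parent = "pelvis", joint_offset = c(0, s * hw, 0))
    segs[[paste0("tibia_", sd)]] <- list(
      name = paste0("tibia_", sd), side = sd, mass = MASS_FRACTIONS[["shank"]] * M,
      length = ls, com = c(0, 0, -0.433 * ls),
      inertia = c(rg(MASS_FRACTIONS[["shank"]] * M, ls), rg(MASS_FRACTIONS[["shank"]] * M, ls),
                  0.02 * rg(MASS_FRACTIONS[["shank"]] * M, ls)),
      parent = paste0("femur_", sd), joint_offset = c(0, 0, -lt))
    segs[[paste0("foot_", sd)]] <- list(
      name = paste0("foot_", sd), side = sd, mass = MASS_FRACTIONS[["foot"]] * M,
      length = lf, com = c(0.25 * lf, 0, -0.7 * ah),
      inertia = rep(rg(MASS_FRACTIONS[["foot"]] * M, lf), 3L),
      parent = paste0("tibia_", sd), joint_offset = c(0, 0, -ls))
  }
  model$segments <- segs

  joints <- list(
    list(name = "hip_R", kind = "spherical", parent = "pelvis", child = "femur_R", dof = 3L),
    list(name = "hip_L", kind = "spherical", parent = "pelvis", child = "femur_L", dof = 3L),
    list(name = "knee_R", kind = "revolute", parent = "femur_R", child = "tibia_R",
         axis = c(0, 1, 0), dof = 1L),
    list(name = "knee_L", kind = "revolute", parent = "femur_L", child = "tibia_L",
         axis = c(0, 1, 0), dof = 1L),
    list(name = "ankle_R", kind = "revolute", parent = "tibia_R", child = "foot_R",
         axis = c(0, 1, 0), dof = 1L),
    list(name = "ankle_L", kind = "revolute", parent = "tibia_L", child = "foot_L",
         axis = c(0, 1, 0), dof = 1L))
  model$joints <- joints

  fas <- list()
  for (sd in c("R", "L")) {
    s <- side_sign(sd)
    hipc <- c(0, s * hw, 0)  # hip center, pelvis-local
    for (f in fascicle_table(hw, lt, s)) {
      share <- if (is.null(f$share)) c(0.50, 0.50, 0.40) else f$share
      for (sub in 1:3) {
        if (sub == 2L && !is.null(f$origin_b)) {
          org <- f$origin_b
          ins <- f$insertion_b
        } else if (sub >= 2L) {
          # intermediate and deep fibers: attachments contracted toward the
          # hip center, working at ~0.62x and ~0.35x the superficial arms --
          # the staggered reserve lines of a pennate fiber fan
          fac <- c(NA, 0.62, 0.35)[sub]
          org <- hipc + fac * (f$origin + f$spread - hipc)
          ins <- fac * (f$insertion - 0.3 * f$spread)
        } else {
          org <- f$origin - f$spread
          ins <- f$insertion + 0.3 * f$spread
        }
        # perpendicular (x, y) coordinates follow the cross-section scale
        org[1:2] <- org[1:2] * kp
        ins[1:2] <- ins[1:2] * kp
        # hip centers themselves are fixed by hjw, so restore the hw term
        org[2] <- org[2] + s * hw * (1 - kp)
        fl <- list(name = paste0(f$name, "_", c("a", "b", "c")[sub], "_", sd),
                   side = sd, group = f$name,
                   origin_segment = "pelvis", origin = org,
                   insertion_segment = paste0("femur_", sd), insertion = ins,
                   pcsa = f$pcsa * k * share[sub])
        fl$hill <- list(optimal_fiber_length = NA_real_, max_velocity = 8,
                        passive_strain_scale = 1, flw = 0.45)
        fas[[fl$name]] <- fl
      }
    }
  }
  # reference (optimal) musculotendon length: straight-line length in the
  # neutral pose, used to normalize Hill force-length/velocity inputs
  for (nm in names(fas)) {
    f <- fas[[nm]]
    s <- side_sign(f$side)
    org_h <- f$origin - c(0, s * hw, 0)
    fas[[nm]]$hill$optimal_fiber_length <- norm3(org_h - f$insertion)
  }
  model$fascicles <- fas

  model$markers <- marker_set_geometry(H, hw, lt, ls, lf, ah)
  model
}

# 25-marker set: 4 pelvis + 3 trunk markers on the pelvis+HAT body, 9 per leg.
# Pelvis marker lateral coordinates sit at +/- half hip joint width so that the
# marker-optimized HJW responds one-to-one to pelvic soft-tissue widening.
marker_set_geometry <- function(H, hw, lt, ls, lf, ah) {
  rows <- list(
    c("LASI", "pelvis", 0.08, hw, 0.02), c("RASI", "pelvis", 0.08, -hw, 0.02),
    c("LPSI", "pelvis", -0.09, hw, 0.03), c("RPSI", "pelvis", -0.09, -hw, 0.03),
    c("C7", "pelvis", -0.06, 0, 0.29 * H), c("CLAV", "pelvis", 0.06, 0, 0.27 * H),
    c("T10", "pelvis", -0.08, 0, 0.16 * H))
  for (sd in c("R", "L")) {
    s <- side_sign(sd)
    fm <- paste0("femur_", sd); tb <- paste0("tibia_", sd); ft <- paste0("foot_", sd)
    rows <- c(rows, list(
      c(paste0(sd, "GTR"), fm, 0.0, s * 0.06, -0.02),
      c(paste0(sd, "THI"), fm, 0.03, s * 0.05, -0.5 * lt),
      c(paste0(sd, "KNEL"), fm, 0.0, s * 0.055, -lt),
      c(paste0(sd, "KNEM"), fm, 0.0, -s * 0.045, -lt),
      c(paste0(sd, "TIB"), tb, 0.025, s * 0.04, -0.5 * ls),
      c(paste0(sd, "ANKL"), tb, 0.0, s * 0.04, -ls),
      c(paste0(sd, "ANKM"), tb, 0.0, -s * 0.035, -ls),
      c(paste0(sd, "HEE"), ft, -0.05, 0, -0.3 * ah),
      c(paste0(sd, "TOE"), ft, 0.75 * lf, s * 0.01, -0.8 * ah)))
  }
  df <- data.frame(
    marker_id = vapply(rows, `[[`, "", 1L),
    segment = vapply(rows, `[[`, "", 2L),
    lx = as.numeric(vapply(rows, `[[`, "", 3L)),
    ly = as.numeric(vapply(rows, `[[`, "", 4L)),
    lz = as.numeric(vapply(rows, `[[`, "", 5L)),
    stringsAsFactors = FALSE)
  df
}

#' Build the simplified lower-limb reference model
#'
#' Constructs a reduced musculoskeletal model for one subject: a pelvis with a
#' rigid head-arms-trunk (HAT) lump, bilateral femur/shank/foot chains
#' (spherical hips, revolute knees and ankles), and a configurable set of
#' hip-spanning muscle fascicle groups per leg (gluteus medius anterior and
#' posterior, gluteus maximus, iliopsoas, an adductor equivalent and a rectus
#' femoris equivalent), each split into two sub-fascicles with staggered
#' attachment points so the group behaves like a fiber fan with a range of
#' moment arms. Segment masses are fixed anthropometric fractions of body
#' mass and therefore always sum to the body mass; segment lengths are
#' proportional to body height.
#'
#' @param anthro An [anthropometrics()] object.
#' @param n_fascicles Number of hip-spanning fascicle groups per leg (2..6);
#'   the default 6 keeps the muscle-redundancy problem non-trivial for the
#'   3-degree-of-freedom hip.
#' @param hjw_mode `"CT"` (hip joint width fixed to the CT measurement and
#'   frozen during kinematic optimization) or `"C3D"` (initialized from a
#'   height-based estimate and free to be optimized from the markers).
#'
#' @return A `body_model` object.
#' @export
build_reference_model <- function(anthro, n_fascicles = 6, hjw_mode = c("CT", "C3D")) {
  stopifnot(inherits(anthro, "anthropometrics"))
  hjw_mode <- match.arg(hjw_mode)
  if (n_fascicles < 2 || n_fascicles > 6)
    stop("n_fascicles must be between 2 and 6 per leg")
  hjw0 <- if (hjw_mode == "CT") anthro$hjw_ct else 100 * anthro$height
  model <- structure(
    list(anthro = anthro, hjw = hjw0, hjw_mode = hjw_mode,
         length_scales = c(thigh = 1, shank = 1, foot = 1),
         cross_section_scale = 1, n_fascicles = n_fascicles),
    class = "body_model")
  model <- rebuild_geometry(model)
  if (n_fascicles < 6) {
    groups <- vapply(fascicle_table(0.08, 0.4, 1), `[[`, "", "name")[seq_len(n_fascicles)]
    model$fascicles <- Filter(function(f) f$group %in% groups, model$fascicles)
  }
  model
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %s: %.1f kg, %.2f m | HJW %.1f mm (%s%s)\n",
              x$anthro$subject_id, x$anthro$mass, x$anthro$height, x$hjw, x$hjw_mode,
              if (x$hjw_mode == "CT") ", frozen" else ""))
  cat(sprintf("  %d segments, %d joints, %d fascicles; length scales thigh %.3f shank %.3f; PCSA scale %.3f\n",
              length(x$segments), length(x$joints), length(x$fascicles),
              x$length_scales[["thigh"]], x$length_scales[["shank"]], x$cross_section_scale))
  invisible(x)
}

#' Apply segment-length and strength scaling
#'
#' Multiplies segment lengths by the supplied per-segment factors (typically
#' the output of the marker-based parameter optimization) and applies the
#' mass-and-height cross-section law: the physiological cross-sectional areas
#' (and hence muscle strengths) are multiplied by
#' `k = sqrt((mass/mass_ref) / (height/height_ref))` with reference values
#' 75 kg and 1.75 m, while perpendicular linear dimensions scale by `sqrt(k)`.
#'
#' @param model A `body_model`.
#' @param length_scales Named positive factors, any of `thigh`, `shank`,
#'   `foot`; omitted entries keep their current value.
#' @param anthro Anthropometrics used for the cross-section law; defaults to
#'   the model's own.
#' @return The rescaled `body_model`.
#' @export
scale_model <- function(model, length_scales = NULL, anthro = model$anthro) {
  stopifnot(inherits(model, "body_model"))
  if (!is.null(length_scales)) {
    if (any(!is.finite(length_scales)) || any(length_scales <= 0))
      stop("length scales must be positive")
    nm <- names(length_scales)
    if (is.null(nm) || !all(nm %in% names(model$length_scales)))
      stop("length_scales must be named with segments among: ",
           paste(names(model$length_scales), collapse = ", "))
    model$length_scales[nm] <- model$length_scales[nm] * length_scales
  }
  model$cross_section_scale <-
    sqrt((anthro$mass / REF_MASS) / (anthro$height / REF_HEIGHT))
  rebuild_geometry(model)
}

#' Set the hip joint width
#'
#' Places the hip centers symmetrically at `+/- hjw_mm / 2` from the
#' mid-sagittal plane and records whether the value is frozen (`"CT"` mode,
#' not altered by the kinematic parameter optimization) or free (`"C3D"`).
#'
#' @param model A `body_model`.
#' @param hjw_mm Hip joint width in mm; must be positive.
#' @param mode `"CT"` or `"C3D"`.
#' @return The updated `body_model`.
#' @export
set_hjw <- function(model, hjw_mm, mode = model$hjw_mode) {
  stopifnot(inherits(model, "body_model"))
  if (!is.finite(hjw_mm) || hjw_mm <= 0) stop("hjw_mm must be positive")
  mode <- match.arg(mode, c("CT", "C3D"))
  model$hjw <- hjw_mm
  model$hjw_mode <- mode
  rebuild_geometry(model)
}

#' Mirror a model about the mid-sagittal plane
#'
#' Swaps left/right labels and flips lateral coordinates. Applying it twice is
#' the identity.
#'
#' @param model A `body_model`.
#' @return The mirrored `body_model`.
#' @export
mirror_model <- function(model) {
  stopifnot(inherits(model, "body_model"))
  an <- model$anthro
  an$side <- if (an$side == "L") "R" else "L"
  model$anthro <- an
  rebuild_geometry(model)
}

# Total modeled mass (should always equal body mass).
model_mass <- function(model) sum(vapply(model$segments, `[[`, 0, "mass"))
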