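# Independent oracles and small fixtures used across the test files.

# Dense grid search over the feasible set {C f = d, 0 <= f (<= cap)} for
# problems with at most 3 muscles: the feasible set is parameterized by a
# particular solution plus the nullspace of C, and the criterion is evaluated
# on a dense grid of nullspace coefficients. Independent of the package's
# solvers (direct enumeration).
grid_oracle <- function(C, d, N, criterion = c("pn", "mm"), p = 3,
                        cap = NULL, ngrid = 401, box = NULL) {
  criterion <- match.arg(criterion)
  C <- rbind(C)
  n <- ncol(C)
  stopifnot(n <= 3)
  f0 <- MASS::ginv(C) %*% d
  ns <- MASS::Null(t(C))
  evalf <- function(f) {
    if (any(f < -1e-9)) return(Inf)
    if (!is.null(cap) && any(f > cap + 1e-9)) return(Inf)
    if (criterion == "pn") sum((pmax(f, 0) / N)^p) else max(pmax(f, 0) / N)
  }
  if (is.null(ns) || ncol(ns) == 0) {
    f <- pmax(as.numeric(f0), 0)
    return(list(f = f, value = evalf(as.numeric(f0))))
  }
  k <- ncol(ns)
  if (is.null(box)) box <- 2 * max(abs(f0), sum(abs(d)) / max(abs(C)), N)
  best <- Inf; fbest <- NULL; abest <- rep(0, k)
  search <- function(center, half, npts) {
    if (k == 1L) {
      for (a in seq(center[1L] - half, center[1L] + half, length.out = npts)) {
        f <- as.numeric(f0 + ns * a)
        v <- evalf(f)
        if (v < best) { best <<- v; fbest <<- f; abest <<- a }
      }
    } else {
      g1 <- seq(center[1L] - half, center[1L] + half, length.out = npts)
      g2 <- seq(center[2L] - half, center[2L] + half, length.out = npts)
      for (a in g1) for (b in g2) {
        f <- as.numeric(f0 + ns %*% c(a, b))
        v <- evalf(f)
        if (v < best) { best <<- v; fbest <<- f; abest <<- c(a, b) }
      }
    }
  }
  npts <- if (k == 1L) ngrid else 101
  half <- box
  search(rep(0, k), half, npts)
  for (zoom in 1:3) {  # refine around the coarse optimum
    half <- half * 4 / (npts - 1)
    search(abest, half, npts)
  }
  list(f = pmax(fbest, 0), value = best)
}

# Subject H1L of the reference cohort, used widely as the default fixture.
anthro_h1l <- function() anthropometrics("H1L", "L", 55, "m", 77.5, 1.78, 166)

# Frontal-plane single-leg-stance toy: supported weight W at a medial offset
# e from the hip, one abductor with moment arm r. Closed-form statics.
frontal_toy <- function(W = 600, e = 0.1, r = 0.05) {
  list(demand = W * e,          # abduction moment demand, N m
       muscle_force = W * e / r,
       reaction = W + W * e / r)  # vertical equilibrium, classic result
}

# Memoized heavy fixtures shared by the acceptance tests.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

clean_cohort <- function() fixture("clean_cohort", function() {
  generate_cohort(stance_params = list(marker_sigma = 0),
                  gait_params = list(marker_sigma = 0),
                  noise_params = list(sd_bw = 0, misalign_deg = 0),
                  seed = 424242)
})

noisy_cohort <- function() fixture("noisy_cohort", function() {
  generate_cohort(stance_params = list(marker_sigma = 2, sta_scale = 1),
                  gait_params = list(marker_sigma = 2, sta_scale = 1),
                  seed = 424242)
})

noisy_kin_cache <- function() fixture("noisy_kin_cache", function() {
  hipload:::cohort_kinematics(noisy_cohort())
})
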