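# Independent oracles used across the suite. These deliberately avoid the
# package's own tracing/solver code paths: closed forms, brute-force
# marching and grid search, and 2x2 paraxial matrix optics.

mean_angle <- function() incident_angle(-5.03, 0.01)

sphere_eye <- function(R = 7.76) {
  eye_biometry("left", Ra = R, Qa = 0, Rp = 6.56, Qp = 0,
               CCT = 0.55, ACD = 3.36, Pup = 3.24, Pup_X = 0, Pup_Y = 0)
}

# Closed-form Purkinje apex-plane coordinate for a spherical cornea:
# perpendicular incidence at P = C - R d, backprojected along d to z = 0.
sphere_purkinje_oracle <- function(R, angle) {
  d <- incident_direction(angle)
  P <- c(0, 0, R) - R * d
  (P - d * (P[3] / d[3]))[1:2]
}

# Brute-force ray/conic intersection: march along the ray until the
# implicit conic changes sign, then bisect. Independent of the quadratic.
march_intersect_oracle <- function(origin, direction, R, Q, z0,
                                   step = 1e-3, tmax = 40) {
  Fimp <- function(t) {
    p <- origin + t * direction
    s <- p[3] - z0
    p[1]^2 + p[2]^2 - 2 * R * s + (1 + Q) * s^2
  }
  t0 <- 0
  f0 <- Fimp(t0)
  repeat {
    t1 <- t0 + step
    if (t1 > tmax) stop("marching oracle found no intersection")
    f1 <- Fimp(t1)
    if (sign(f0) != sign(f1)) break
    t0 <- t1; f0 <- f1
  }
  for (i in 1:100) {
    tm <- (t0 + t1) / 2
    fm <- Fimp(tm)
    if (sign(fm) == sign(f0)) { t0 <- tm; f0 <- fm } else t1 <- tm
  }
  origin + (t0 + t1) / 2 * direction
}

# 2x2 paraxial (y, n*u) transfer through the cornea from z = 0- (air) to a
# plane z_t in the aqueous.
paraxial_system <- function(b, z_t) {
  P1 <- (1.376 - 1) / b$Ra
  P2 <- (1.336 - 1.376) / b$Rp
  R1 <- matrix(c(1, -P1, 0, 1), 2)
  T1 <- matrix(c(1, 0, b$CCT / 1.376, 1), 2)
  R2 <- matrix(c(1, -P2, 0, 1), 2)
  T2 <- matrix(c(1, 0, (z_t - b$CCT) / 1.336, 1), 2)
  T2 %*% R2 %*% T1 %*% R1
}

# Paraxial entrance-pupil magnification: apparent transverse magnification
# of the stop plane viewed from air along the axis.
paraxial_ep_magnification <- function(b, z_stop) {
  Si <- solve(paraxial_system(b, z_stop))
  a <- Si[1, 1]; bb <- Si[1, 2]; cc <- Si[2, 1]; d <- Si[2, 2]
  a - cc * bb / d
}

# Multi-level vectorised grid search for the landmark offsets, refining a
# 41 x 41 grid around the running optimum. Objective evaluated with the
# package's low-level tracer but the *search* is exhaustive, providing an
# algorithm-independent check of the Newton solvers.
grid_landmark_oracle <- function(b, angle, which = c("pupil", "purkinje"),
                                 z_ref = b$CCT, levels = 7, span = 4) {
  which <- match.arg(which)
  d <- incident_direction(angle)
  obj <- function(ox, oy) {
    n <- length(ox)
    DIR <- matrix(d, n, 3, byrow = TRUE)
    O <- cbind(ox, oy, 0) + DIR * (-10 / d[3])
    if (which == "pupil") {
      tr <- cwchord:::.trace_core(O, DIR, b$Ra, b$Qa, b$Rp, b$Qp, b$CCT, z_ref)
      (tr$plane[, 1] - b$Pup_X)^2 + (tr$plane[, 2] - b$Pup_Y)^2
    } else {
      P1 <- cwchord:::.intersect_conic(O, DIR, b$Ra, b$Qa, 0)
      N1 <- cwchord:::.conic_normal(P1, b$Ra, b$Qa, 0)
      D1 <- cwchord:::.refract(DIR, N1, 1, 1.376)
      1 - rowSums(DIR * D1)
    }
  }
  ctr <- c(0, 0)
  for (lv in seq_len(levels)) {
    g <- seq(-span / 2, span / 2, length.out = 41)
    gx <- rep(ctr[1] + g, times = 41)
    gy <- rep(ctr[2] + g, each = 41)
    v <- obj(gx, gy)
    v[is.na(v)] <- Inf
    k <- which.min(v)
    ctr <- c(gx[k], gy[k])
    span <- 4 * (g[2] - g[1])
  }
  ctr
}

random_eyes <- function(n, seed) {
  synthesize_population(population_spec(n, seed = seed))
}
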