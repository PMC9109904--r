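# Geometric raytracing through a two-surface aspheric cornea.
#
# Conventions: origin at the corneal front apex, X right, Y superior, Z
# towards the retina; all geometry left-normalised. Surfaces are conics
# z = z0 + sag(r) with implicit form  x^2 + y^2 - 2 R s + (1+Q) s^2 = 0,
# s = z - z0. Refractive indices are fixed at 1.0 (air), 1.376 (cornea),
# 1.336 (aqueous), after the Liou-Brennan schematic eye.

N_AIR     <- 1.0
N_CORNEA  <- 1.376
N_AQUEOUS <- 1.336

# ---- quaternion utilities (rotation of landmark coordinates) ----------------

# unit quaternion for a rotation of `deg` degrees about `axis` (unit 3-vector)
.quat <- function(axis, deg) {
  h <- deg * pi / 360
  c(cos(h), sin(h) * axis)
}

.quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[-1] * b[-1]),
    a[1] * b[-1] + b[1] * a[-1] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

.quat_conj <- function(q) c(q[1], -q[-1])

# rotate the rows of an n x 3 matrix by unit quaternion q:
# v' = v + 2 q_v x (q_v x v + w v)
.quat_rotate <- function(q, P) {
  P <- .as_mat3(P)
  w <- q[1]; qv <- q[-1]
  cx <- function(a1, a2, a3, b1, b2, b3)
    cbind(a2 * b3 - a3 * b2, a3 * b1 - a1 * b3, a1 * b2 - a2 * b1)
  t1 <- cx(qv[1], qv[2], qv[3], P[, 1], P[, 2], P[, 3]) + w * P
  P + 2 * cx(qv[1], qv[2], qv[3], t1[, 1], t1[, 2], t1[, 3])
}

.as_mat3 <- function(p) {
  if (is.matrix(p)) p else matrix(p, ncol = 3)
}

# rotation taking the instrument axis (0,0,1) onto the incident direction:
# rotate about Y by -I_X, then about X by +I_Y. The Y-axis sign is calibrated
# so that a -5 deg horizontal angle puts the Purkinje reflex on the nasal
# (negative X) side, as observed clinically for left-normalised eyes.
.incident_quat <- function(angle) {
  .quat_mul(.quat(c(1, 0, 0), angle$I_Y), .quat(c(0, 1, 0), -angle$I_X))
}

#' Incident ray angle
#'
#' @param I_X,I_Y horizontal / vertical tilt of the fixation beam relative
#'   to the corneal optical axis, degrees (|angle| < 90). Negative `I_X`
#'   tilts the beam so that it arrives from the nasal visual field of a
#'   left-normalised eye.
#' @return list of class `incident_angle`.
#' @export
incident_angle <- function(I_X = 0, I_Y = 0) {
  stopifnot(abs(I_X) < 90, abs(I_Y) < 90)
  structure(list(I_X = I_X, I_Y = I_Y), class = "incident_angle")
}

#' Direction vector of an incident angle
#'
#' Unit direction of a beam with tilt (`I_X`, `I_Y`), travelling towards
#' the retina (positive Z component).
#'
#' @param angle [incident_angle()].
#' @return unit 3-vector.
#' @export
incident_direction <- function(angle) {
  as.vector(.quat_rotate(.incident_quat(angle), c(0, 0, 1)))
}

# ---- model construction ------------------------------------------------------

#' Conic corneal surface
#'
#' @param R apex radius of curvature, mm (> 0).
#' @param Q asphericity (conic constant); 0 is a sphere, -1 < Q < 0 a
#'   prolate ellipsoid.
#' @param apex_z axial apex position, mm.
#' @param n_before,n_after refractive indices on either side.
#' @return list of class `conic_surface`.
#' @export
conic_surface <- function(R, Q = 0, apex_z = 0, n_before = 1, n_after = 1) {
  stopifnot(R > 0)
  structure(list(R = R, Q = Q, apex_z = apex_z,
                 n_before = n_before, n_after = n_after),
            class = "conic_surface")
}

#' Build the optical model of one eye
#'
#' Two coaxial conic corneal surfaces plus a decentred circular aperture
#' stop. Two referencing conventions are configurable; the defaults
#' reproduce the published translation model this package implements:
#'
#' * `stop_depth`: `"chamber"` places the stop a full chamber depth behind
#'   the cornea (z = CCT + ACD), treating the exported ACD as the depth of
#'   the aqueous chamber distal to the cornea; `"apex"` places it at
#'   z = ACD (apex-referenced).
#' * `pupil_reference`: plane at which the pupil-centre landmark ray is
#'   required to reach the exported decentration (`Pup_X`, `Pup_Y`).
#'   `"cornea_back"` (z = CCT) mirrors how the tomographer's en-face pupil
#'   coordinates are referenced, immediately behind the cornea, so the
#'   landmark does not double-count oblique parallax across the chamber;
#'   `"stop"` uses the stop plane itself (the strict chief-ray reading).
#'
#' @param biometry one-row [eye_biometry()] record (right eyes are
#'   left-normalised automatically).
#' @param stop_depth,pupil_reference see above.
#' @return list of class `eye_model` with elements `front`, `back`
#'   ([conic_surface()]), `stop` (centre, diameter, z), `pupil_ref_z`, and
#'   the normalised `biometry`.
#' @export
eye_model <- function(biometry,
                      stop_depth = c("chamber", "apex"),
                      pupil_reference = c("cornea_back", "stop")) {
  stop_depth <- match.arg(stop_depth)
  pupil_reference <- match.arg(pupil_reference)
  if (nrow(biometry) != 1L) stop("eye_model() takes a single biometry row")
  bad <- validate_biometry(biometry)
  if (length(bad))
    stop("degenerate biometry: ", paste(bad, collapse = "; "), call. = FALSE)
  b <- flip_to_left_eye(biometry)
  z_stop <- if (stop_depth == "chamber") b$CCT + b$ACD else b$ACD
  structure(list(
    front = conic_surface(b$Ra, b$Qa, 0, N_AIR, N_CORNEA),
    back  = conic_surface(b$Rp, b$Qp, b$CCT, N_CORNEA, N_AQUEOUS),
    stop  = list(x = b$Pup_X, y = b$Pup_Y, z = z_stop, diameter = b$Pup),
    pupil_ref_z = if (pupil_reference == "cornea_back") b$CCT else z_stop,
    biometry = b), class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  b <- x$biometry
  cat(sprintf(paste0(
    "<eye_model> left-normalised\n",
    "  front: R = %.3f mm, Q = %+.3f   back: R = %.3f mm, Q = %+.3f (z = %.3f)\n",
    "  stop:  %.2f mm diameter at (%+.2f, %+.2f, %.2f) mm; pupil ref z = %.2f mm\n"),
    b$Ra, b$Qa, b$Rp, b$Qp, b$CCT,
    x$stop$diameter, x$stop$x, x$stop$y, x$stop$z, x$pupil_ref_z))
  invisible(x)
}

# ---- surface geometry --------------------------------------------------------

#' Axial sag of a conic surface
#'
#' Standard conic sagitta `z = c r^2 / (1 + sqrt(1 - (1+Q) c^2 r^2))` with
#' curvature `c = 1/R`, measured from the apex.
#'
#' @param surface [conic_surface()].
#' @param r radial distance from the axis, mm (vectorised).
#' @return sag in mm (0 at the apex).
#' @export
conic_sag <- function(surface, r) {
  cv <- 1 / surface$R
  disc <- 1 - (1 + surface$Q) * cv^2 * r^2
  if (any(disc < 0)) {
    bad <- r[disc < 0]
    stop(sprintf("conic sag undefined at r = %.4f mm (R = %.3f, Q = %.3f)",
                 bad[1], surface$R, surface$Q), call. = FALSE)
  }
  cv * r^2 / (1 + sqrt(disc))
}

#' Outward unit normal of a conic surface
#'
#' Gradient of the implicit conic, normalised and oriented towards the
#' instrument (negative Z component). For a sphere this is the unit vector
#' from the centre of curvature to the point, with that orientation.
#'
#' @param surface [conic_surface()].
#' @param point 3-vector (or n x 3 matrix) on the surface.
#' @param tol on-surface tolerance in mm.
#' @return unit normal(s), same shape as `point`.
#' @export
surface_normal <- function(surface, point, tol = 1e-9) {
  P <- .as_mat3(point)
  s <- P[, 3] - surface$apex_z
  r <- sqrt(P[, 1]^2 + P[, 2]^2)
  if (any(abs(s - conic_sag(surface, r)) > tol))
    stop("point is not on the surface (|dz| > tol)", call. = FALSE)
  N <- .conic_normal(P, surface$R, surface$Q, surface$apex_z)
  if (!is.matrix(point)) as.vector(N) else N
}

# unnormalised-gradient-based unit normal; vectorised, no on-surface check
.conic_normal <- function(P, R, Q, z0) {
  s <- P[, 3] - z0
  G <- cbind(P[, 1], P[, 2], (1 + Q) * s - R)
  G / sqrt(rowSums(G^2))
}

# ---- ray-surface intersection ------------------------------------------------

# Vectorised closed-form intersection of rays (O, D) with the near sheet of a
# conic. R, Q, z0 may be scalars or length-n vectors. Returns n x 3 points
# (NA rows: miss). The quadratic is solved in the numerically stable form.
.intersect_conic <- function(O, D, R, Q, z0, tmin = 1e-9) {
  n <- nrow(O)
  if (length(R) == 1L) { R <- rep(R, n); Q <- rep(Q, n); z0 <- rep(z0, n) }
  k <- 1 + Q
  oz <- O[, 3] - z0
  A <- D[, 1]^2 + D[, 2]^2 + k * D[, 3]^2
  B <- 2 * (O[, 1] * D[, 1] + O[, 2] * D[, 2]) + 2 * D[, 3] * (k * oz - R)
  C <- O[, 1]^2 + O[, 2]^2 + oz * (k * oz - 2 * R)
  t <- rep(NA_real_, n)
  lin <- !is.na(A) & abs(A) < 1e-14
  t[lin & abs(B) > 0] <- -(C / B)[lin & abs(B) > 0]
  disc <- B^2 - 4 * A * C
  qd <- !is.na(disc) & !lin & disc >= 0
  if (any(qd)) {
    sq <- sqrt(disc[qd])
    qq <- -(B[qd] + sign(B[qd] + (B[qd] == 0)) * sq) / 2
    t1 <- qq / A[qd]
    t2 <- ifelse(qq != 0, C[qd] / qq, t1)
    # keep roots on the near (anterior) sheet: (1+Q) s < R
    pick <- function(tt) {
      s <- oz[qd] + tt * D[qd, 3]
      ok <- tt > tmin & k[qd] * s < R[qd]
      ifelse(ok, tt, Inf)
    }
    tq <- pmin(pick(t1), pick(t2))
    # fall back to the smallest positive root if the sheet test rejects both
    tq2 <- pmin(ifelse(t1 > tmin, t1, Inf), ifelse(t2 > tmin, t2, Inf))
    tq[!is.finite(tq)] <- tq2[!is.finite(tq)]
    tq[!is.finite(tq)] <- NA_real_
    t[qd] <- tq
  }
  O + t * D
}

#' Intersect a ray with a conic surface
#'
#' Closed-form quadratic intersection, choosing the hit on the anterior
#' sheet nearest the apex region.
#'
#' @param ray list with `origin` (3-vector, mm) and `direction`
#'   (unit 3-vector, positive Z component).
#' @param surface [conic_surface()].
#' @return intersection point (3-vector).
#' @export
intersect_ray_surface <- function(ray, surface) {
  P <- .intersect_conic(.as_mat3(ray$origin), .as_mat3(ray$direction),
                        surface$R, surface$Q, surface$apex_z)
  if (anyNA(P))
    stop("ray misses the surface", call. = FALSE)
  as.vector(P)
}

# ---- refraction --------------------------------------------------------------

# vectorised vector Snell law; D, N are n x 3, N oriented against D (N.D < 0).
# Rows beyond the critical angle come back as NA (flagged downstream); the
# scalar wrapper turns them into an error.
.refract <- function(D, N, n1, n2) {
  ci <- -rowSums(D * N)
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  k[k < 0] <- NA_real_
  eta * D + (eta * ci - sqrt(k)) * N
}

#' Refract a direction at a surface normal (vector Snell law)
#'
#' @param direction unit incidence direction.
#' @param normal unit surface normal, oriented against the incoming ray
#'   (`sum(direction * normal) < 0`).
#' @param n1,n2 refractive indices before / after the interface.
#' @return unit refracted direction; errors on total internal reflection.
#' @export
refract_ray <- function(direction, normal, n1, n2) {
  out <- as.vector(.refract(.as_mat3(direction), .as_mat3(normal), n1, n2))
  if (anyNA(out))
    stop("total internal reflection", call. = FALSE)
  out
}

# ---- incident rays and full traces ------------------------------------------

RAY_START_Z <- -10  # mm in front of the apex; any negative value is equivalent

#' Build a collimated incident ray
#'
#' A ray with direction given by the incident angle, positioned so that its
#' (unrefracted) line crosses the corneal apex plane z = 0 at the requested
#' lateral offset.
#'
#' @param angle [incident_angle()].
#' @param offset length-2 lateral offset (x, y) at the apex plane, mm.
#' @return list with `origin` and unit `direction` (class `light_ray`).
#' @export
make_incident_ray <- function(angle, offset = c(0, 0)) {
  d <- incident_direction(angle)
  structure(list(origin = c(offset[1], offset[2], 0) + d * (RAY_START_Z / d[3]),
                 direction = d), class = "light_ray")
}

# Vectorised core trace: rays (O, D) through front and back surface to the
# plane z = z_plane. Surface parameters may be per-ray vectors. Returns a
# list of matrices; rows with NA mark misses/TIR.
.trace_core <- function(O, D, Ra, Qa, Rp, Qp, CCT, z_plane) {
  P1 <- .intersect_conic(O, D, Ra, Qa, 0)
  N1 <- .conic_normal(P1, Ra, Qa, 0)
  D1 <- .refract(D, N1, N_AIR, N_CORNEA)
  P2 <- .intersect_conic(P1, D1, Rp, Qp, CCT)
  N2 <- .conic_normal(P2, Rp, Qp, CCT)
  D2 <- .refract(D1, N2, N_CORNEA, N_AQUEOUS)
  tt <- (z_plane - P2[, 3]) / D2[, 3]
  Pp <- P2 + tt * D2
  list(P1 = P1, D1 = D1, P2 = P2, D2 = D2, plane = Pp)
}

#' Trace a ray through both corneal surfaces to the pupillary plane
#'
#' Refracts at the corneal front and back surfaces and propagates the
#' aqueous segment to the plane `z = z_plane` (the model's stop plane by
#' default).
#'
#' @param ray a `light_ray` (see [make_incident_ray()]).
#' @param model [eye_model()].
#' @param z_plane target plane, mm; defaults to the stop plane.
#' @return list with per-segment rays (`segments`: origins and directions
#'   in air, cornea, aqueous) and `point`, the crossing of the target
#'   plane.
#' @export
trace_to_pupil_plane <- function(ray, model, z_plane = model$stop$z) {
  b <- model$biometry
  tr <- .trace_core(.as_mat3(ray$origin), .as_mat3(ray$direction),
                    b$Ra, b$Qa, b$Rp, b$Qp, b$CCT, z_plane)
  if (anyNA(tr$plane))
    stop("ray misses the cornea", call. = FALSE)
  list(segments = list(
         air     = list(origin = as.vector(ray$origin),
                        direction = as.vector(ray$direction)),
         cornea  = list(origin = as.vector(tr$P1), direction = as.vector(tr$D1)),
         aqueous = list(origin = as.vector(tr$P2), direction = as.vector(tr$D2))),
       point = as.vector(tr$plane))
}
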