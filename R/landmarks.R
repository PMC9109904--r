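# Landmark rays defining the Chang-Waring chord.
#
# Two rays are solved per eye: the pupil-centre ray (steered so its
# transverse coordinates reach the exported pupil decentration at the
# model's pupil reference plane) and the Purkinje ray (perpendicular
# incidence on the corneal front surface, i.e. the ray that is not bent and
# marks the first Purkinje reflex PI). Both are reported where the incident
# ray crosses the corneal apex plane z = 0, then rotated onto the plane
# perpendicular to the incident beam — the frame in which a coaxially
# fixating instrument reads them out.

# ---- batched 2-D Newton solver ----------------------------------------------
#
# fn(OX, OY) must return a list(x=, y=) of residual components for n
# simultaneous problems. Each problem is solved with a damped Newton
# iteration using finite-difference Jacobians; the mapping offset ->
# residual is nearly affine for this geometry, so convergence is fast.
.newton2d_batch <- function(fn, n, tol, max_iter = 200L, h = 1e-6) {
  OX <- numeric(n); OY <- numeric(n)
  iter <- integer(n); resid <- rep(Inf, n)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    f0 <- fn(OX, OY)
    resid <- sqrt(f0$x^2 + f0$y^2)
    resid[is.na(resid)] <- Inf
    active <- active & resid > tol
    if (!any(active)) break
    iter[active] <- it
    fx <- fn(OX + h * active, OY)
    fy <- fn(OX, OY + h * active)
    j11 <- (fx$x - f0$x) / h; j21 <- (fx$y - f0$y) / h
    j12 <- (fy$x - f0$x) / h; j22 <- (fy$y - f0$y) / h
    det <- j11 * j22 - j12 * j21
    det[!active | !is.finite(det) | det == 0] <- NA
    dx <- (j22 * f0$x - j12 * f0$y) / det
    dy <- (j11 * f0$y - j21 * f0$x) / det
    step <- sqrt(dx^2 + dy^2)
    damp <- pmin(1, 1 / pmax(step, 1))  # cap steps at 1 mm
    upd <- active & is.finite(dx) & is.finite(dy)
    OX[upd] <- OX[upd] - (damp * dx)[upd]
    OY[upd] <- OY[upd] - (damp * dy)[upd]
  }
  f0 <- fn(OX, OY)
  resid <- sqrt(f0$x^2 + f0$y^2)
  list(x = OX, y = OY, iterations = iter, residual = resid,
       converged = is.finite(resid) & resid <= tol)
}

# per-eye incident-ray bundle builder used by the batch solvers
.incident_rays <- function(OX, OY, DIR) {
  O <- cbind(OX, OY, 0) + DIR * (RAY_START_Z / DIR[, 3])
  list(O = O, D = DIR)
}

# batched pupil-centre solve over a biometry table + per-eye directions
.solve_pupil_batch <- function(b, DIR, z_ref, tol) {
  fn <- function(OX, OY) {
    r <- .incident_rays(OX, OY, DIR)
    tr <- .trace_core(r$O, r$D, b$Ra, b$Qa, b$Rp, b$Qp, b$CCT, z_ref)
    list(x = tr$plane[, 1] - b$Pup_X, y = tr$plane[, 2] - b$Pup_Y)
  }
  .newton2d_batch(fn, nrow(b), tol)
}

# batched perpendicular-incidence (Purkinje) solve; residual is the
# transverse difference between refracted and incident directions, with the
# 1 - dot(incident, refracted) criterion checked on the solution
.solve_purkinje_batch <- function(b, DIR, tol_dot) {
  fn <- function(OX, OY) {
    r <- .incident_rays(OX, OY, DIR)
    P1 <- .intersect_conic(r$O, r$D, b$Ra, b$Qa, 0)
    N1 <- .conic_normal(P1, b$Ra, b$Qa, 0)
    D1 <- .refract(r$D, N1, N_AIR, N_CORNEA)
    list(x = D1[, 1] - DIR[, 1], y = D1[, 2] - DIR[, 2])
  }
  # transverse direction residual; the stop tolerance is far below
  # sqrt(tol_dot) so the solved offset is accurate to ~1e-9 mm
  sol <- .newton2d_batch(fn, nrow(b), tol = min(1e-10, sqrt(tol_dot)))
  r <- .incident_rays(sol$x, sol$y, DIR)
  P1 <- .intersect_conic(r$O, r$D, b$Ra, b$Qa, 0)
  N1 <- .conic_normal(P1, b$Ra, b$Qa, 0)
  D1 <- .refract(r$D, N1, N_AIR, N_CORNEA)
  sol$one_minus_dot <- 1 - rowSums(DIR * D1)
  sol$converged <- sol$converged & sol$one_minus_dot <= tol_dot
  sol
}

#' Locate the pupil-centre landmark ray
#'
#' Steers an incident ray of fixed direction laterally until, traced
#' through both corneal surfaces, its transverse coordinates at the
#' model's pupil reference plane match the exported pupil decentration
#' (`Pup_X`, `Pup_Y`). The landmark is the ray's crossing of the corneal
#' apex plane z = 0.
#'
#' @param model [eye_model()].
#' @param angle [incident_angle()].
#' @param tol residual tolerance at the reference plane, mm.
#' @param max_iter Newton iteration cap.
#' @return named vector `c(PupC_X, PupC_Y)` with attributes `iterations`
#'   and `residual`.
#' @export
find_pupil_centre_ray <- function(model, angle, tol = 1e-9, max_iter = 200L) {
  b <- model$biometry
  DIR <- .as_mat3(incident_direction(angle))
  sol <- .solve_pupil_batch(b, DIR, model$pupil_ref_z, tol)
  if (!sol$converged)
    stop(sprintf("pupil-centre solver did not converge (residual %.3g mm)",
                 sol$residual), call. = FALSE)
  structure(c(PupC_X = sol$x, PupC_Y = sol$y),
            iterations = sol$iterations, residual = sol$residual)
}

#' Locate the Purkinje reflex PI landmark ray
#'
#' Finds the incident ray that meets the corneal front surface
#' perpendicularly — the ray that is collinear with the surface normal,
#' is not refracted, and is specularly back-reflected towards the coaxial
#' light source, marking the first Purkinje image. The criterion is the
#' dot product between the normalised incident and refracted directions,
#' driven to 1 within `tol`.
#'
#' @param model [eye_model()].
#' @param angle [incident_angle()].
#' @param tol tolerance on `1 - dot`, unitless.
#' @param max_iter Newton iteration cap.
#' @return named vector `c(PurkinjeC_X, PurkinjeC_Y)` (apex-plane
#'   crossing) with attributes `iterations` and `one_minus_dot`.
#' @export
find_purkinje_ray <- function(model, angle, tol = 1e-12, max_iter = 200L) {
  b <- model$biometry
  DIR <- .as_mat3(incident_direction(angle))
  sol <- .solve_purkinje_batch(b, DIR, tol)
  if (!sol$converged)
    stop(sprintf("Purkinje solver did not converge (1 - dot = %.3g)",
                 sol$one_minus_dot), call. = FALSE)
  structure(c(PurkinjeC_X = sol$x, PurkinjeC_Y = sol$y),
            iterations = sol$iterations, one_minus_dot = sol$one_minus_dot)
}

#' Project a point onto the plane perpendicular to the incident ray
#'
#' Applies the inverse of the incident rotation (about the corneal apex,
#' composed from the two axis rotations as unit quaternions) and returns
#' the rotated X and Y — the coordinates a coaxially aligned instrument
#' reads on the plane perpendicular to its axis.
#'
#' @param point 3-vector (or n x 3 matrix), mm.
#' @param angle [incident_angle()].
#' @return length-2 vector (or n x 2 matrix) of in-plane coordinates, mm.
#' @export
project_to_ray_plane <- function(point, angle) {
  q <- .quat_conj(.incident_quat(angle))
  P <- .quat_rotate(q, point)
  if (is.matrix(point)) P[, 1:2, drop = FALSE] else P[1, 1:2]
}

#' Compute the Chang-Waring chord of one eye
#'
#' Runs both landmark solvers, rotates the apex-plane landmarks onto the
#' ray-perpendicular plane, and differences them:
#' `CW = PupR - PurkinjeR`. Positive `CW_X` means the pupil centre sits
#' temporal to the Purkinje reflex in the instrument's view.
#'
#' @param model [eye_model()].
#' @param angle [incident_angle()].
#' @param pupil_tol,purkinje_tol solver tolerances.
#' @return list of class `cw_landmarks` with apex-plane coordinates
#'   (`PupC_*`, `PurkinjeC_*`), rotated coordinates (`PupR_*`,
#'   `PurkinjeR_*`), the chord (`CW_X`, `CW_Y`) and solver diagnostics.
#' @export
compute_cw_chord <- function(model, angle,
                             pupil_tol = 1e-9, purkinje_tol = 1e-12) {
  pc <- find_pupil_centre_ray(model, angle, tol = pupil_tol)
  pk <- find_purkinje_ray(model, angle, tol = purkinje_tol)
  pr <- project_to_ray_plane(c(pc[1], pc[2], 0), angle)
  kr <- project_to_ray_plane(c(pk[1], pk[2], 0), angle)
  structure(list(
    PupC_X = unname(pc[1]), PupC_Y = unname(pc[2]),
    PurkinjeC_X = unname(pk[1]), PurkinjeC_Y = unname(pk[2]),
    PupR_X = pr[1], PupR_Y = pr[2],
    PurkinjeR_X = kr[1], PurkinjeR_Y = kr[2],
    CW_X = pr[1] - kr[1], CW_Y = pr[2] - kr[2],
    diagnostics = list(
      pupil_iterations = attr(pc, "iterations"),
      pupil_residual = attr(pc, "residual"),
      purkinje_iterations = attr(pk, "iterations"),
      purkinje_one_minus_dot = attr(pk, "one_minus_dot"))),
    class = "cw_landmarks")
}

#' @export
print.cw_landmarks <- function(x, ...) {
  cat(sprintf(paste0(
    "<cw_landmarks>\n",
    "  PupC      (%+.4f, %+.4f) mm    PurkinjeC (%+.4f, %+.4f) mm\n",
    "  PupR      (%+.4f, %+.4f) mm    PurkinjeR (%+.4f, %+.4f) mm\n",
    "  CW chord  (%+.4f, %+.4f) mm\n"),
    x$PupC_X, x$PupC_Y, x$PurkinjeC_X, x$PurkinjeC_Y,
    x$PupR_X, x$PupR_Y, x$PurkinjeR_X, x$PurkinjeR_Y,
    x$CW_X, x$CW_Y))
  invisible(x)
}
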