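# Entrance-pupil footprint tracing and constraining-ellipse fitting.
#
# A collimated bundle is traced through the cornea; rays passing the
# aperture stop are marked and their incident-segment crossings of the
# corneal apex plane form the entrance-pupil footprint. The footprint is
# summarised by its moment-based constraining ellipse, whose long diameter
# relative to the anatomical pupil gives the entrance-pupil magnification.

# hexagonally packed grid covering a disc of diameter `d` with about
# `n_target` points (uniform areal density, deterministic)
.hex_disc <- function(d, n_target) {
  area_per <- pi * (d / 2)^2 / n_target
  h <- sqrt(2 * area_per / sqrt(3))      # lattice spacing
  ny <- ceiling(d / (h * sqrt(3) / 2))
  pts <- do.call(rbind, lapply(-ny:ny, function(iy) {
    y <- iy * h * sqrt(3) / 2
    xoff <- if (iy %% 2 == 0) 0 else h / 2
    nx <- ceiling(d / h)
    x <- (-nx:nx) * h + xoff
    cbind(x, y)
  }))
  pts[pts[, 1]^2 + pts[, 2]^2 <= (d / 2)^2, , drop = FALSE]
}

#' Trace a collimated ray bundle and mark the entrance-pupil footprint
#'
#' Rays form an equidistant (hexagonally packed) grid over a disc of
#' `bundle_diameter`, collimated along the incident direction, its
#' cross-section perpendicular to the beam and centred on the corneal
#' apex. A ray is marked when its traced crossing of the stop plane lies
#' within the stop radius of the stop centre. Returned points are the
#' marked rays' incident-segment crossings of the apex plane z = 0 — the
#' footprint a coaxial instrument sees.
#'
#' @param model [eye_model()].
#' @param angle [incident_angle()].
#' @param n_rays approximate bundle size (>= 100); default 10000.
#' @param bundle_diameter bundle diameter, mm; must exceed the pupil.
#' @return n x 2 matrix of footprint points with attribute `n_total`
#'   (rays traced).
#' @export
trace_pupil_bundle <- function(model, angle, n_rays = 10000,
                               bundle_diameter = 7) {
  stopifnot(n_rays >= 100)
  if (bundle_diameter <= model$stop$diameter)
    stop("bundle_diameter must exceed the pupil diameter", call. = FALSE)
  b <- model$biometry
  g <- .hex_disc(bundle_diameter, n_rays)
  q <- .incident_quat(angle)
  d <- incident_direction(angle)
  O <- .quat_rotate(q, cbind(g[, 1], g[, 2], 0))
  O <- O + rep(d, each = nrow(O)) * RAY_START_Z
  D <- matrix(d, nrow(O), 3, byrow = TRUE)
  tr <- .trace_core(O, D, b$Ra, b$Qa, b$Rp, b$Qp, b$CCT, model$stop$z)
  marked <- !is.na(tr$plane[, 1]) &
    (tr$plane[, 1] - model$stop$x)^2 + (tr$plane[, 2] - model$stop$y)^2 <=
    (model$stop$diameter / 2)^2
  if (!any(marked))
    stop("no rays pass the aperture stop (degenerate aperture)", call. = FALSE)
  tt <- -O[, 3] / D[, 3]
  apex <- O + tt * D
  structure(apex[marked, 1:2, drop = FALSE], n_total = nrow(O))
}

#' Fit the moment-based constraining ellipse of a point set
#'
#' Centre is the centroid; principal axes are the eigenvectors of the 2x2
#' second-central-moment matrix; diameters are `4 * sqrt(eigenvalue)`, the
#' scaling under which a uniformly filled disc of diameter d returns
#' diameters d (so footprint diameters compare directly with the
#' anatomical pupil diameter).
#'
#' @param points n x 2 matrix, n >= 10, not collinear.
#' @return list of class `cw_ellipse`: `centre` (x, y), `D_long`,
#'   `D_short` (mm), `A_long`, `A_short` (axis orientations, degrees in
#'   (-90, 90]), `aspect` = D_long / D_short, `n_points`.
#' @export
fit_constraining_ellipse <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 10) stop("need at least 10 points", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  S <- crossprod(Pc) / nrow(P)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(e$values))
    stop("degenerate (rank-deficient) moment matrix", call. = FALSE)
  ang <- function(v) {
    a <- atan2(v[2], v[1]) * 180 / pi
    ((a + 90) %% 180) - 90  # fold to (-90, 90]
  }
  structure(list(centre = c(x = ctr[1], y = ctr[2]),
                 D_long = 4 * sqrt(e$values[1]),
                 D_short = 4 * sqrt(e$values[2]),
                 A_long = ang(e$vectors[, 1]),
                 A_short = ang(e$vectors[, 2]),
                 aspect = sqrt(e$values[1] / e$values[2]),
                 n_points = nrow(P)),
            class = "cw_ellipse")
}

#' @export
print.cw_ellipse <- function(x, ...) {
  cat(sprintf(paste0(
    "<cw_ellipse> centre (%+.3f, %+.3f) mm\n",
    "  D_long %.3f mm @ %.1f deg, D_short %.3f mm @ %.1f deg, aspect %.4f",
    " (n = %d)\n"),
    x$centre[1], x$centre[2], x$D_long, x$A_long, x$D_short, x$A_short,
    x$aspect, x$n_points))
  invisible(x)
}

#' Entrance-pupil metrics of one eye
#'
#' Traces the bundle, rotates the marked footprint onto the plane
#' perpendicular to the incident ray (the instrument's view), fits the
#' constraining ellipse there, and reports the entrance-pupil
#' magnification `D_long / Pup - 1`.
#'
#' @inheritParams trace_pupil_bundle
#' @return list of class `cw_entrance_pupil`: the rotated-plane ellipse
#'   (`EllipseR_X`, `EllipseR_Y`, `D_long`, `D_short`, `A_long`,
#'   `A_short`, `aspect`), the unrotated footprint centre (`EllipseC_X`,
#'   `EllipseC_Y`), `magnification`, and `n_marked`.
#' @export
entrance_pupil_metrics <- function(model, angle, n_rays = 10000,
                                   bundle_diameter = 7) {
  fp <- trace_pupil_bundle(model, angle, n_rays, bundle_diameter)
  ctr0 <- colMeans(fp)
  rot <- project_to_ray_plane(cbind(fp[, 1], fp[, 2], 0), angle)
  ell <- fit_constraining_ellipse(rot)
  structure(list(
    EllipseC_X = ctr0[1], EllipseC_Y = ctr0[2],
    EllipseR_X = unname(ell$centre[1]), EllipseR_Y = unname(ell$centre[2]),
    D_long = ell$D_long, D_short = ell$D_short,
    A_long = ell$A_long, A_short = ell$A_short,
    aspect = ell$aspect,
    magnification = ell$D_long / model$stop$diameter - 1,
    n_marked = nrow(fp)), class = "cw_entrance_pupil")
}

#' @export
print.cw_entrance_pupil <- function(x, ...) {
  cat(sprintf(paste0(
    "<cw_entrance_pupil> centre (rotated) (%+.3f, %+.3f) mm\n",
    "  D_long %.3f / D_short %.3f mm, aspect %.4f, magnification %+.1f%%",
    " (n_marked = %d)\n"),
    x$EllipseR_X, x$EllipseR_Y, x$D_long, x$D_short, x$aspect,
    100 * x$magnification, x$n_marked))
  invisible(x)
}
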