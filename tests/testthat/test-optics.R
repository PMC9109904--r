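# Surface geometry, refraction and tracing primitives.

test_that("conic sag matches closed forms and the implicit-equation oracle", {
  sph <- conic_surface(R = 7.76, Q = 0)
  expect_identical(conic_sag(sph, 0), 0)
  # sphere closed form R - sqrt(R^2 - r^2)
  expect_equal(conic_sag(sph, 2), 7.76 - sqrt(7.76^2 - 4), tolerance = 1e-12)
  # aspheric: numeric root of the implicit conic as independent oracle
  con <- conic_surface(R = 7.76, Q = -0.22)
  s_oracle <- uniroot(function(s) 4 - 2 * 7.76 * s + (1 - 0.22) * s^2,
                      c(0, 1), tol = 1e-14)$root
  expect_equal(conic_sag(con, 2), s_oracle, tolerance = 1e-10)
  expect_equal(round(conic_sag(con, 2), 4), 0.2612)
  # domain error beyond the equator of an oblate conic
  expect_error(conic_sag(conic_surface(R = 2, Q = 1), 2), "undefined at r")
})

test_that("surface normal has the sphere-centre property and is smooth", {
  sph <- conic_surface(R = 7.76, Q = 0)
  expect_equal(surface_normal(sph, c(0, 0, 0)), c(0, 0, -1))
  p <- c(2, 0, conic_sag(sph, 2))
  n <- surface_normal(sph, p)
  expect_equal(sum(n^2), 1, tolerance = 1e-12)
  centre_dir <- (p - c(0, 0, 7.76)) / 7.76
  expect_equal(n, centre_dir, tolerance = 1e-12)
  expect_lt(n[3], 0)
  # continuity between nearby points (aspheric)
  con <- conic_surface(R = 7.76, Q = -0.22)
  n1 <- surface_normal(con, c(1.5, 0.5, conic_sag(con, sqrt(1.5^2 + 0.5^2))))
  n2 <- surface_normal(con, c(1.501, 0.5,
                              conic_sag(con, sqrt(1.501^2 + 0.5^2))))
  expect_gt(sum(n1 * n2), 0.9999)
  expect_error(surface_normal(sph, c(2, 0, 1)), "not on the surface")
})

test_that("ray-surface intersection agrees with sag and the marching oracle", {
  sph <- conic_surface(R = 7.76, Q = 0)
  axial <- list(origin = c(0, 0, -10), direction = c(0, 0, 1))
  expect_equal(intersect_ray_surface(axial, sph), c(0, 0, 0),
               tolerance = 1e-12)
  off <- list(origin = c(2, 0, -10), direction = c(0, 0, 1))
  expect_equal(intersect_ray_surface(off, sph)[3], 7.76 - sqrt(7.76^2 - 4),
               tolerance = 1e-10)
  # oblique rays vs brute-force marching/bisection on several conics
  set.seed(42)
  for (i in 1:10) {
    R <- runif(1, 6, 9); Q <- runif(1, -0.5, 0.2); z0 <- runif(1, 0, 1)
    d <- c(runif(2, -0.15, 0.15), 1); d <- d / sqrt(sum(d^2))
    o <- c(runif(2, -1, 1), -8)
    surf <- conic_surface(R, Q, z0)
    p <- intersect_ray_surface(list(origin = o, direction = d), surf)
    expect_lt(max(abs(p - march_intersect_oracle(o, d, R, Q, z0))), 1e-8)
    # point satisfies z = apex_z + sag(r)
    expect_equal(p[3] - z0, conic_sag(surf, sqrt(p[1]^2 + p[2]^2)),
                 tolerance = 1e-10)
  }
  expect_error(
    intersect_ray_surface(list(origin = c(20, 0, -10), direction = c(0, 0, 1)),
                          sph), "misses")
})

test_that("vector Snell law: scalar check, invariant and coplanarity", {
  n <- c(0, 0, -1)
  d <- c(0, 0, 1)
  expect_equal(refract_ray(d, n, 1, 1.376), d)           # normal incidence
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(refract_ray(d30, n, 1.3, 1.3), d30)       # equal indices
  t30 <- refract_ray(d30, n, 1, 1.376)
  expect_equal(t30[1], 0.5 / 1.376, tolerance = 1e-12)   # scalar Snell
  expect_lt(abs(asin(t30[1]) * 180 / pi - 21.3074), 1e-3)
  # properties over random geometries
  set.seed(7)
  for (i in 1:25) {
    d <- c(runif(2, -0.4, 0.4), 1); d <- d / sqrt(sum(d^2))
    nv <- c(runif(2, -0.3, 0.3), -1); nv <- nv / sqrt(sum(nv^2))
    n1 <- runif(1, 1, 1.5); n2 <- runif(1, 1, 1.5)
    tr <- refract_ray(d, nv, n1, n2)
    expect_equal(sum(tr^2), 1, tolerance = 1e-12)
    sin_i <- sqrt(1 - sum(d * nv)^2)
    sin_t <- sqrt(1 - sum(tr * nv)^2)
    expect_lt(abs(n1 * sin_i - n2 * sin_t), 1e-10)
    # refracted direction lies in the incidence plane
    expect_lt(abs(det(cbind(d, nv, tr))), 1e-10)
  }
  expect_error(refract_ray(c(sin(1.2), 0, cos(1.2)), n, 1.5, 1.0),
               "total internal reflection")
})

test_that("incident ray construction follows the calibrated convention", {
  r0 <- make_incident_ray(incident_angle(0, 0))
  expect_equal(r0$direction, c(0, 0, 1))
  expect_equal(r0$origin[1:2], c(0, 0))
  # for I_X = -5 the direction tilts temporally: x component +sin(5 deg)
  a <- incident_angle(-5, 0)
  expect_equal(incident_direction(a)[1], sin(5 * pi / 180), tolerance = 1e-12)
  # inverse rotation returns the axis
  expect_equal(project_to_ray_plane(incident_direction(a), a), c(0, 0),
               tolerance = 1e-12)
  a2 <- incident_angle(-5.03, 3.2)
  d2 <- incident_direction(a2)
  q <- cwchord:::.quat_conj(cwchord:::.incident_quat(a2))
  expect_equal(as.vector(cwchord:::.quat_rotate(q, d2)), c(0, 0, 1),
               tolerance = 1e-12)
  # the unrefracted line crosses z = 0 at the requested offset
  r <- make_incident_ray(a2, offset = c(0.4, -0.7))
  hit <- r$origin - r$direction * (r$origin[3] / r$direction[3])
  expect_equal(hit[1:2], c(0.4, -0.7), tolerance = 1e-12)
  expect_equal(sum(r$direction^2), 1, tolerance = 1e-12)
})

test_that("tracing to the pupillary plane honours Snell at both surfaces", {
  m <- eye_model(mean_eye())
  axial_centred <- eye_model(eye_biometry("left", Ra = 7.76, Qa = -0.22,
                                          Rp = 6.56, Qp = -0.11, CCT = 0.55,
                                          ACD = 3.36, Pup = 3.24))
  tr0 <- trace_to_pupil_plane(make_incident_ray(incident_angle(0, 0)),
                              axial_centred)
  expect_equal(tr0$point, c(0, 0, axial_centred$stop$z), tolerance = 1e-12)

  tr <- trace_to_pupil_plane(make_incident_ray(mean_angle(), c(0.5, -0.3)), m)
  expect_equal(tr$point[3], m$stop$z, tolerance = 1e-12)
  for (seg in list(c("air", "cornea"), c("cornea", "aqueous"))) {
    s1 <- tr$segments[[seg[1]]]; s2 <- tr$segments[[seg[2]]]
    surf <- if (seg[1] == "air") m$front else m$back
    nv <- surface_normal(surf, s2$origin)
    n1 <- surf$n_before; n2 <- surf$n_after
    sin_i <- sqrt(max(0, 1 - sum(s1$direction * nv)^2))
    sin_t <- sqrt(max(0, 1 - sum(s2$direction * nv)^2))
    expect_lt(abs(n1 * sin_i - n2 * sin_t), 1e-10)
  }
})

test_that("mirror symmetry: negating I_X and Pup_X negates X, keeps Y", {
  b <- eye_biometry("left", Ra = 7.7, Qa = -0.25, Rp = 6.5, Qp = -0.1,
                    CCT = 0.54, ACD = 3.2, Pup = 3.5,
                    Pup_X = -0.25, Pup_Y = -0.12)
  bm <- b; bm$Pup_X <- -bm$Pup_X
  a <- incident_angle(-4.4, 1.3); am <- incident_angle(4.4, 1.3)
  t1 <- trace_to_pupil_plane(make_incident_ray(a, c(0.3, 0.2)), eye_model(b))
  t2 <- trace_to_pupil_plane(make_incident_ray(am, c(-0.3, 0.2)),
                             eye_model(bm))
  expect_lt(abs(t1$point[1] + t2$point[1]), 1e-10)
  expect_lt(abs(t1$point[2] - t2$point[2]), 1e-10)
})

test_that("paraxial limit agrees with 2x2 matrix optics to 1e-4 mm", {
  b <- flip_to_left_eye(mean_eye())
  m <- eye_model(mean_eye())
  S <- paraxial_system(b, m$stop$z)
  for (th in c(0.1, -0.1, 0.05)) {
    for (y0 in c(0, 0.05)) {
      tr <- trace_to_pupil_plane(
        make_incident_ray(incident_angle(-th, 0), c(y0, 0)), m)
      # paraxial chief ray: u = tan(theta), reduced angle in air = u
      u <- tan(th * pi / 180)
      yw <- S %*% c(y0 + u * 0, u)   # refraction at z = 0
      expect_lt(abs(tr$point[1] - yw[1]), 1e-4)
    }
  }
})

test_that("left-eye normalisation flips Pup_X only and is involutive", {
  r <- eye_biometry("right", Ra = 7.8, Qa = -0.2, Rp = 6.6, Qp = -0.1,
                    CCT = 0.55, ACD = 3.4, Pup = 3, Pup_X = 0.30, Pup_Y = 0.1)
  l <- flip_to_left_eye(r)
  expect_identical(l$laterality, "left")
  expect_equal(l$Pup_X, -0.30)
  expect_equal(l$Pup_Y, r$Pup_Y)
  expect_equal(l[c("Ra", "Qa", "Rp", "Qp", "CCT", "ACD", "Pup")],
               r[c("Ra", "Qa", "Rp", "Qp", "CCT", "ACD", "Pup")])
  expect_identical(flip_to_left_eye(l), l)       # left eyes unchanged
  expect_error(flip_to_left_eye(data.frame(laterality = "both", Pup_X = 1)),
               "laterality")
})

test_that("degenerate biometry is rejected at model construction", {
  expect_error(eye_biometry("left", Ra = 7.8, Qa = 0, Rp = 6.6, Qp = 0,
                            CCT = 0.55, ACD = 0.4, Pup = 3), "ACD")
  expect_error(eye_biometry("left", Ra = 7.8, Qa = 0, Rp = 6.6, Qp = 0,
                            CCT = 0.55, ACD = 3.4, Pup = -1), "Pup")
  b <- mean_eye(); b$Ra <- -2
  expect_error(eye_model(b), "Ra")
})
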