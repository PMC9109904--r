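# Monte-Carlo machinery: truncated-normal incident-angle sampling, synthetic
# biometry generation emulating the normative cohort marginals, batch
# simulation, and summary tables.

# rejection sampler for a truncated normal; exact and simple at the mild
# truncations used here (acceptance >= 68%)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::pnorm(c(lower, upper), mean, sd)
  if (diff(p) <= 0)
    stop("infeasible truncation bounds", call. = FALSE)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / max(diff(p), 1e-3)) + 16L
    x <- stats::rnorm(m, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample incident ray angles
#'
#' Draws the fixation-beam tilt used for the Monte-Carlo simulation:
#' `I_X ~ N(-5, 2)` degrees with samples outside `[-9, -1]` discarded, and
#' `I_Y ~ N(0, 2)` degrees truncated to `[-4, 4]`. The -5 degree mean
#' horizontal tilt reflects the temporally decentred fovea of the
#' Liou-Brennan schematic eye; the truncation keeps the tilt within the
#' physiologically plausible range.
#'
#' @param n number of draws.
#' @param seed optional RNG seed for reproducibility.
#' @param mean_x,sd_x,range_x horizontal distribution (degrees).
#' @param mean_y,sd_y,range_y vertical distribution (degrees).
#' @return data.frame with columns `I_X`, `I_Y`.
#' @export
sample_incident_angles <- function(n, seed = NULL,
                                   mean_x = -5, sd_x = 2, range_x = c(-9, -1),
                                   mean_y = 0, sd_y = 2, range_y = c(-4, 4)) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(I_X = .rtruncnorm(n, mean_x, sd_x, range_x[1], range_x[2]),
             I_Y = .rtruncnorm(n, mean_y, sd_y, range_y[1], range_y[2]))
}

#' Specification of a synthetic biometry population
#'
#' Marginal means/SDs default to the normative cohort statistics
#' ([biometry_norms()]); each parameter is truncated to its 5%/95%
#' percentile range extended by two SDs. `Ra` and `Rp` are drawn jointly
#' with the configured correlation (corneal front and back curvature are
#' strongly coupled); asphericities are independent of the radii.
#'
#' @param n sample size.
#' @param seed optional RNG seed.
#' @param norms data.frame in the layout of [biometry_norms()].
#' @param ra_rp_cor Ra-Rp Pearson correlation in (-1, 1); default 0.85.
#' @return list of class `cw_population_spec`.
#' @export
population_spec <- function(n, seed = NULL, norms = biometry_norms(),
                            ra_rp_cor = 0.85) {
  stopifnot(n >= 1, abs(ra_rp_cor) < 1, all(norms$sd >= 0))
  bounds <- cbind(lo = norms$cl5 - 2 * norms$sd, hi = norms$cl95 + 2 * norms$sd)
  rownames(bounds) <- norms$param
  structure(list(n = n, seed = seed, norms = norms, bounds = bounds,
                 ra_rp_cor = ra_rp_cor), class = "cw_population_spec")
}

#' Generate a synthetic biometry table
#'
#' Draws `spec$n` left-normalised eyes with truncated-normal marginals and
#' the configured Ra-Rp correlation (bivariate normal, jointly rejected
#' outside either parameter's bounds). Deterministic under `spec$seed`.
#'
#' @param spec [population_spec()].
#' @return data.frame of `eye_biometry` columns (laterality `"left"`).
#' @export
synthesize_population <- function(spec) {
  stopifnot(inherits(spec, "cw_population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nm <- spec$norms
  rownames(nm) <- nm$param
  n <- spec$n
  draw1 <- function(p) .rtruncnorm(n, nm[p, "mean"], nm[p, "sd"],
                                   spec$bounds[p, "lo"], spec$bounds[p, "hi"])
  # joint Ra-Rp: correlated normal pairs, rejected jointly outside bounds
  rho <- spec$ra_rp_cor
  ra <- numeric(0); rp <- numeric(0)
  if (nm["Ra", "sd"] == 0 || nm["Rp", "sd"] == 0) {
    ra <- draw1("Ra"); rp <- draw1("Rp")
  } else {
    pr <- stats::pnorm(spec$bounds["Ra", ], nm["Ra", "mean"], nm["Ra", "sd"])
    pp <- stats::pnorm(spec$bounds["Rp", ], nm["Rp", "mean"], nm["Rp", "sd"])
    if (diff(pr) <= 0 || diff(pp) <= 0)
      stop("infeasible truncation bounds for Ra/Rp", call. = FALSE)
    tries <- 0L
    while (length(ra) < n) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("infeasible truncation bounds for Ra/Rp (rejection stalled)",
             call. = FALSE)
      m <- 2L * (n - length(ra)) + 16L
      z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
      x1 <- nm["Ra", "mean"] + nm["Ra", "sd"] * z1
      x2 <- nm["Rp", "mean"] + nm["Rp", "sd"] * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- x1 >= spec$bounds["Ra", "lo"] & x1 <= spec$bounds["Ra", "hi"] &
            x2 >= spec$bounds["Rp", "lo"] & x2 <= spec$bounds["Rp", "hi"]
      ra <- c(ra, x1[ok]); rp <- c(rp, x2[ok])
    }
    ra <- ra[seq_len(n)]; rp <- rp[seq_len(n)]
  }
  out <- data.frame(laterality = "left", Ra = ra,
                    Qa = draw1("Qa"), Rp = rp, Qp = draw1("Qp"),
                    CCT = draw1("CCT"), ACD = draw1("ACD"),
                    Pup = draw1("Pup"),
                    Pup_X = draw1("Pup_X"), Pup_Y = draw1("Pup_Y"))
  bad <- validate_biometry(out)
  if (length(bad))
    stop("synthetic draw violated biometry invariants: ",
         paste(bad, collapse = "; "), call. = FALSE)
  out
}

#' Run the raytracing Monte-Carlo over a population
#'
#' For every eye, solves both landmark rays at its incident angle and
#' computes the CW chord; optionally traces entrance-pupil bundles on a
#' subsample (bundle tracing is the expensive step). Solver failures are
#' flagged per row in the `error` column, never dropped silently.
#'
#' @param population biometry table (right eyes are left-normalised).
#' @param angles data.frame with columns `I_X`, `I_Y`, one row per eye.
#' @param ellipse compute entrance-pupil metrics? (`FALSE`, `TRUE`, or an
#'   integer subsample size; `TRUE` means all eyes).
#' @param n_rays bundle size per eye for the ellipse step.
#' @param bundle_diameter bundle diameter, mm.
#' @param stop_depth,pupil_reference model conventions, see [eye_model()].
#' @param pupil_tol,purkinje_tol solver tolerances.
#' @return data.frame: biometry, angles, landmark and chord columns,
#'   ellipse columns (NA where not computed), `error` (NA when clean).
#' @export
run_monte_carlo <- function(population, angles, ellipse = FALSE,
                            n_rays = 2000, bundle_diameter = 7,
                            stop_depth = "chamber",
                            pupil_reference = "cornea_back",
                            pupil_tol = 1e-9, purkinje_tol = 1e-12) {
  b <- flip_to_left_eye(as.data.frame(population))
  angles <- as.data.frame(angles)
  if (nrow(b) != nrow(angles))
    stop("population and angles must have equal lengths", call. = FALSE)
  n <- nrow(b)
  bad <- validate_biometry(b)
  if (length(bad))
    stop("invalid biometry rows: ", paste(bad, collapse = "; "), call. = FALSE)

  DIR <- t(vapply(seq_len(n), function(i)
    incident_direction(incident_angle(angles$I_X[i], angles$I_Y[i])),
    numeric(3)))
  z_stop <- if (stop_depth == "chamber") b$CCT + b$ACD else b$ACD
  z_ref <- if (pupil_reference == "cornea_back") b$CCT else z_stop

  pc <- .solve_pupil_batch(b, DIR, z_ref, pupil_tol)
  pk <- .solve_purkinje_batch(b, DIR, purkinje_tol)

  # per-eye rotation of the apex-plane landmarks onto the ray-perpendicular
  # plane (z = 0 points, so only X/Y mix appreciably)
  rot2 <- function(x, y) {
    out <- matrix(NA_real_, n, 2)
    for (i in seq_len(n))
      out[i, ] <- project_to_ray_plane(
        c(x[i], y[i], 0), incident_angle(angles$I_X[i], angles$I_Y[i]))
    out
  }
  pr <- rot2(pc$x, pc$y)
  kr <- rot2(pk$x, pk$y)

  res <- data.frame(b, angles,
                    PupC_X = pc$x, PupC_Y = pc$y,
                    PurkinjeC_X = pk$x, PurkinjeC_Y = pk$y,
                    PupR_X = pr[, 1], PupR_Y = pr[, 2],
                    PurkinjeR_X = kr[, 1], PurkinjeR_Y = kr[, 2],
                    CW_X = pr[, 1] - kr[, 1], CW_Y = pr[, 2] - kr[, 2],
                    EllipseR_X = NA_real_, EllipseR_Y = NA_real_,
                    D_long = NA_real_, D_short = NA_real_,
                    aspect = NA_real_, magnification = NA_real_,
                    error = NA_character_)
  fail <- !pc$converged | !pk$converged
  res$error[fail] <- "landmark solver did not converge"
  res[fail, c("PupC_X", "PupC_Y", "PurkinjeC_X", "PurkinjeC_Y",
              "PupR_X", "PupR_Y", "PurkinjeR_X", "PurkinjeR_Y",
              "CW_X", "CW_Y")] <- NA_real_

  if (!identical(ellipse, FALSE)) {
    idx <- which(!fail)
    if (is.numeric(ellipse) && length(idx) > ellipse)
      idx <- idx[seq_len(ellipse)]
    for (i in idx) {
      em <- tryCatch(
        entrance_pupil_metrics(
          eye_model(res[i, seq_len(ncol(b))],
                    stop_depth = stop_depth,
                    pupil_reference = pupil_reference),
          incident_angle(angles$I_X[i], angles$I_Y[i]),
          n_rays = n_rays, bundle_diameter = bundle_diameter),
        error = function(e) e)
      if (inherits(em, "error")) {
        res$error[i] <- paste("ellipse:", conditionMessage(em))
      } else {
        res$EllipseR_X[i] <- em$EllipseR_X
        res$EllipseR_Y[i] <- em$EllipseR_Y
        res$D_long[i] <- em$D_long
        res$D_short[i] <- em$D_short
        res$aspect[i] <- em$aspect
        res$magnification[i] <- em$magnification
      }
    }
  }
  nf <- sum(!is.na(res$error))
  if (nf) message(nf, " of ", n, " rows flagged in the error column")
  res
}

#' Summary table of a results (or biometry) table
#'
#' Column-wise MEAN, SD (n-1 denominator), MEDIAN and the empirical
#' 5th/95th percentiles of every numeric column.
#'
#' @param results data.frame with >= 2 rows.
#' @param na.rm drop NAs per column (default TRUE).
#' @return data.frame with rows MEAN, SD, MEDIAN, CL5, CL95.
#' @export
summarize_population <- function(results, na.rm = TRUE) {
  stopifnot(nrow(results) >= 2)
  num <- vapply(results, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to summarise", call. = FALSE)
  X <- results[num]
  out <- rbind(
    MEAN   = vapply(X, mean, numeric(1), na.rm = na.rm),
    SD     = vapply(X, stats::sd, numeric(1), na.rm = na.rm),
    MEDIAN = vapply(X, stats::median, numeric(1), na.rm = na.rm),
    CL5    = vapply(X, stats::quantile, numeric(1), probs = 0.05,
                    na.rm = na.rm, names = FALSE),
    CL95   = vapply(X, stats::quantile, numeric(1), probs = 0.95,
                    na.rm = na.rm, names = FALSE))
  as.data.frame(out)
}
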