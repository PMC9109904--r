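#' Construct a validated single-eye biometry record
#'
#' Bundles the anterior-segment parameters needed by the optical model:
#' corneal front/back apex radii and asphericities, central corneal
#' thickness, external anterior chamber depth (front apex to lens apex),
#' pupil diameter and pupil-centre decentration.
#'
#' @param laterality `"left"` or `"right"` (case-insensitive; `"OS"`/`"OD"`
#'   accepted).
#' @param Ra,Rp corneal front/back apex radius of curvature, mm (> 0).
#' @param Qa,Qp corneal front/back asphericity (conic constant), unitless.
#' @param CCT central corneal thickness, mm (> 0).
#' @param ACD external anterior chamber depth, mm (> CCT).
#' @param Pup pupil diameter, mm (> 0).
#' @param Pup_X,Pup_Y pupil-centre decentration, mm. In left-normalised
#'   geometry positive X is temporal, positive Y superior.
#' @return A one-row `data.frame` of class `eye_biometry`.
#' @examples
#' eye_biometry("left", Ra = 7.76, Qa = -0.22, Rp = 6.56, Qp = -0.11,
#'              CCT = 0.55, ACD = 3.36, Pup = 3.24,
#'              Pup_X = -0.30, Pup_Y = -0.10)
#' @export
eye_biometry <- function(laterality, Ra, Qa, Rp, Qp, CCT, ACD, Pup,
                         Pup_X = 0, Pup_Y = 0) {
  b <- data.frame(laterality = .norm_laterality(laterality),
                  Ra = Ra, Qa = Qa, Rp = Rp, Qp = Qp, CCT = CCT,
                  ACD = ACD, Pup = Pup, Pup_X = Pup_X, Pup_Y = Pup_Y)
  bad <- validate_biometry(b)
  if (length(bad))
    stop("invalid biometry: ", paste(bad, collapse = "; "), call. = FALSE)
  class(b) <- c("eye_biometry", "data.frame")
  b
}

.norm_laterality <- function(x) {
  out <- c(left = "left", l = "left", os = "left",
           right = "right", r = "right", od = "right")[tolower(trimws(x))]
  if (anyNA(out))
    stop("unknown laterality token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Check biometry invariants
#'
#' Returns a character vector of violated invariants (empty when valid).
#' Row-wise checks: positive radii, thickness and pupil diameter, and an
#' anterior chamber deeper than the cornea is thick.
#'
#' @param b data.frame with the `eye_biometry` columns.
#' @return character vector of messages, one per violated rule.
#' @export
validate_biometry <- function(b) {
  msg <- character()
  chk <- function(ok, what) {
    if (any(!ok)) msg <<- c(msg, paste0(what, " (row ",
                                        paste(which(!ok), collapse = ", "), ")"))
  }
  chk(b$Ra > 0, "Ra must be > 0")
  chk(b$Rp > 0, "Rp must be > 0")
  chk(b$CCT > 0, "CCT must be > 0")
  chk(b$ACD > b$CCT, "ACD must exceed CCT")
  chk(b$Pup > 0, "Pup must be > 0")
  msg
}

#' Mirror right eyes into left-eye geometry
#'
#' The optical model is rotationally symmetric apart from the horizontal
#' decentrations, so a right eye is equivalent to a left eye with the sign
#' of `Pup_X` flipped (the vertical axis is unchanged). After
#' normalisation every record reads `laterality == "left"` and positive X
#' is temporal.
#'
#' @param biometry `eye_biometry` record(s) (any data.frame with the
#'   required columns).
#' @return The same table with right-eye rows mirrored.
#' @export
flip_to_left_eye <- function(biometry) {
  lat <- .norm_laterality(biometry$laterality)
  right <- lat == "right"
  biometry$Pup_X[right] <- -biometry$Pup_X[right]
  biometry$laterality <- "left"
  biometry
}

#' Normative anterior-segment statistics
#'
#' Per-parameter mean, standard deviation and 5th/95th percentiles of the
#' large-clinic Casia2 cohort that the synthetic population generator
#' emulates, for left-normalised eyes.
#'
#' @return data.frame with columns `param`, `mean`, `sd`, `cl5`, `cl95`.
#' @export
biometry_norms <- function() {
  data.frame(
    param = c("Ra", "Qa", "Rp", "Qp", "CCT", "ACD", "Pup", "Pup_X", "Pup_Y"),
    mean  = c(7.76, -0.22, 6.56, -0.11, 0.55, 3.36, 3.24, -0.30, -0.10),
    sd    = c(0.28,  0.13, 0.25,  0.11, 0.04, 0.40, 0.81,  0.21,  0.19),
    cl5   = c(7.33, -0.44, 6.17, -0.33, 0.49, 2.67, 2.45, -0.70, -0.40),
    cl95  = c(8.27, -0.01, 6.99,  0.06, 0.60, 3.99, 4.66,  0.00,  0.20))
}

#' The cohort-mean left eye
#'
#' Convenience constructor for the mean biometry of [biometry_norms()];
#' handy as a deterministic test and demonstration eye.
#'
#' @return `eye_biometry` row at the normative means.
#' @export
mean_eye <- function() {
  n <- biometry_norms()
  m <- as.list(stats::setNames(n$mean, n$param))
  eye_biometry("left", Ra = m$Ra, Qa = m$Qa, Rp = m$Rp, Qp = m$Qp,
               CCT = m$CCT, ACD = m$ACD, Pup = m$Pup,
               Pup_X = m$Pup_X, Pup_Y = m$Pup_Y)
}
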