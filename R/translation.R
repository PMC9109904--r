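# Stepwise multivariable linear translation between the CW chord and the
# incident ray angle (angle Alpha).
#
# The forward model predicts (CW_X, CW_Y) from biometry plus (I_X, I_Y);
# the reverse model is obtained by exact algebraic inversion and predicts
# (I_X, I_Y) from biometry plus (CW_X, CW_Y). Effect sizes are chosen by a
# forward/backward stepwise search on per-term t-test p-values.

CW_REGRESSORS <- c("Ra", "Qa", "Rp", "Qp", "CCT", "ACD", "Pup",
                   "Pup_X", "Pup_Y", "I_X", "I_Y")
CW_ANGLES <- c("I_X", "I_Y")
CW_CHORD <- c("CW_X", "CW_Y")

# OLS with per-coefficient t statistics; X includes the intercept column
.ols <- function(y, X) {
  XtX <- crossprod(X)
  XtXi <- tryCatch(solve(XtX), error = function(e)
    stop("rank-deficient regressor set: ",
         paste(colnames(X), collapse = ", "), call. = FALSE))
  cf <- drop(XtXi %*% crossprod(X, y))
  res <- drop(y - X %*% cf)
  df <- length(y) - ncol(X)
  if (df <= 0) stop("need more observations than regressors", call. = FALSE)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  tv <- cf / se
  list(coef = stats::setNames(cf, colnames(X)), se = se, t = tv,
       p = 2 * stats::pt(-abs(tv), df), residuals = res,
       rmse = sqrt(mean(res^2)), sigma = sqrt(s2), df = df,
       r.squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

#' Stepwise forward/backward regressor selection
#'
#' Starting from the constant model, repeatedly adds the candidate with
#' the smallest addition p-value below `p_enter`, then removes the
#' included term with the largest p-value at or above `p_remove`, until no
#' change occurs or a stopping criterion fires (iteration cap, step size
#' below `1e-9`, or RMSE improvement below `1e-12`). P-values are the
#' usual OLS t statistics.
#'
#' @param y response vector.
#' @param X data.frame or matrix of candidate regressors (no intercept
#'   column; one is always included).
#' @param p_enter,p_remove entry/removal significance thresholds.
#' @param max_iter iteration cap.
#' @return logical mask over `colnames(X)` with attribute `trace`, the
#'   add/drop history.
#' @export
stepwise_select <- function(y, X, p_enter = 0.05, p_remove = 0.05,
                            max_iter = 100L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  sel <- stats::setNames(rep(FALSE, ncol(X)), colnames(X))
  ic <- matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)"))
  fit_for <- function(mask) .ols(y, cbind(ic, X[, mask, drop = FALSE]))
  rmse_prev <- sqrt(mean((y - mean(y))^2))
  hist <- character()
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    cand <- names(sel)[!sel]
    if (length(cand)) {
      pv <- vapply(cand, function(v) {
        m <- sel; m[v] <- TRUE
        unname(fit_for(m)$p[v])
      }, numeric(1))
      if (min(pv) < p_enter) {
        v <- cand[which.min(pv)]
        sel[v] <- TRUE
        hist <- c(hist, paste0("+", v))
        changed <- TRUE
      }
    }
    if (any(sel)) {
      f <- fit_for(sel)
      pin <- f$p[names(sel)[sel]]
      if (max(pin) >= p_remove) {
        v <- names(pin)[which.max(pin)]
        sel[v] <- FALSE
        hist <- c(hist, paste0("-", v))
        changed <- TRUE
      }
      rmse <- fit_for(sel)$rmse
      if (changed && abs(rmse_prev - rmse) < 1e-12) break
      rmse_prev <- rmse
    }
    if (!changed) break
  }
  attr(sel, "trace") <- hist
  sel
}

# assemble the design matrix for a set of regressor names
.design <- function(data, regressors) {
  miss <- setdiff(regressors, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  cbind("(Intercept)" = 1, as.matrix(as.data.frame(data)[regressors]))
}

#' Fit the CW chord translation model
#'
#' Fits, per chord component, an ordinary least-squares model over the
#' stepwise-selected regressors (or user-supplied masks), assembles the
#' 2-row forward coefficient matrix over `(Intercept, regressors)`, and
#' derives the reverse matrix predicting the incident angle from biometry
#' plus the chord by exact algebraic inversion.
#'
#' @param data results table containing the responses `CW_X`, `CW_Y` and
#'   the regressor columns (e.g. from [run_monte_carlo()]).
#' @param candidates candidate regressor names; defaults to the full
#'   biometry + angle set.
#' @param p_enter,p_remove stepwise thresholds (see [stepwise_select()]).
#' @param masks optional list with logical masks `CW_X`, `CW_Y` over
#'   `candidates`, bypassing the stepwise search.
#' @return object of class `cw_translation`: `forward` and `reverse`
#'   coefficient matrices (masked-out terms exactly 0), `masks`, per-row
#'   `diagnostics` (coefficient tables, RMSE, sigma, R^2), `fitted`,
#'   `residuals`, `n`, `call`.
#' @seealso [predict.cw_translation()], [invert_translation()],
#'   [cw_translation_2022()]
#' @export
cw_translation <- function(data, candidates = CW_REGRESSORS,
                           p_enter = 0.05, p_remove = 0.05, masks = NULL) {
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[c(candidates, CW_CHORD)])
  data <- data[keep, , drop = FALSE]
  X <- .design(data, candidates)
  fits <- list(); msk <- list()
  fitted <- matrix(NA_real_, nrow(data), 2, dimnames = list(NULL, CW_CHORD))
  resid <- fitted
  fw <- matrix(0, 2, length(candidates) + 1,
               dimnames = list(CW_CHORD, colnames(X)))
  for (resp in CW_CHORD) {
    y <- data[[resp]]
    m <- if (is.null(masks)) {
      stepwise_select(y, X[, -1, drop = FALSE], p_enter, p_remove)
    } else {
      stats::setNames(as.logical(masks[[resp]]), candidates)
    }
    f <- .ols(y, X[, c(TRUE, unname(m)), drop = FALSE])
    fw[resp, names(f$coef)] <- f$coef
    fitted[, resp] <- X %*% fw[resp, ]
    resid[, resp] <- y - fitted[, resp]
    fits[[resp]] <- f
    msk[[resp]] <- m
  }
  structure(list(forward = fw,
                 reverse = invert_translation(fw),
                 masks = msk,
                 diagnostics = lapply(fits, function(f)
                   list(coefficients = cbind(estimate = f$coef, se = f$se,
                                             t = f$t, p = f$p),
                        rmse = f$rmse, sigma = f$sigma,
                        r.squared = f$r.squared, df = f$df)),
                 fitted = fitted, residuals = resid,
                 n = nrow(data), call = match.call()),
            class = "cw_translation")
}

#' Invert a forward translation matrix
#'
#' Solves the forward system algebraically for the angles. With `A` the
#' 2x2 block of angle coefficients and `B` the biometry block,
#' `CW = A I + B x + b0` inverts to `I = A^{-1} (CW - B x - b0)`. For the
#' published effect structure `A` is diagonal, so the reverse CW
#' coefficient is the reciprocal of the forward angle coefficient. The
#' inversion is an exact identity: composing forward then reverse
#' reproduces the angles.
#'
#' @param forward 2 x (p+1) forward matrix (rows `CW_X`, `CW_Y`; columns
#'   `(Intercept)`, biometry regressors, `I_X`, `I_Y`), or a
#'   `cw_translation` object.
#' @return 2 x (p+1) reverse matrix with rows `I_X`, `I_Y` and the angle
#'   columns replaced by `CW_X`, `CW_Y`.
#' @export
invert_translation <- function(forward) {
  if (inherits(forward, "cw_translation")) forward <- forward$forward
  resp <- rownames(forward)
  in_names <- if (all(CW_ANGLES %in% colnames(forward))) CW_ANGLES else CW_CHORD
  out_names <- if (identical(in_names, CW_ANGLES)) CW_CHORD else CW_ANGLES
  A <- forward[, in_names, drop = FALSE]
  if (abs(det(A)) < 1e-12)
    stop("angle coefficient block is singular; model cannot be reversed",
         call. = FALSE)
  Ai <- solve(A)
  other <- setdiff(colnames(forward), in_names)
  rev <- cbind(-Ai %*% forward[, other, drop = FALSE], Ai)
  dimnames(rev) <- list(in_names, c(other, resp))
  rev
}

# evaluate a coefficient matrix on newdata
.translate_eval <- function(mat, newdata) {
  X <- .design(newdata, setdiff(colnames(mat), "(Intercept)"))
  out <- X %*% t(mat)
  colnames(out) <- paste0(sub("_([XY])$", "_\\1M", rownames(mat)))
  out
}

#' Predict CW chord or incident angle from a translation model
#'
#' @param object `cw_translation` model.
#' @param newdata data.frame with the biometry regressors plus, for
#'   `direction = "cw"`, the angles `I_X`, `I_Y`, or for
#'   `direction = "alpha"`, the chord `CW_X`, `CW_Y`.
#' @param direction `"cw"` (forward) or `"alpha"` (reverse).
#' @param ... unused.
#' @return n x 2 matrix of predictions (`CW_XM`/`CW_YM` in mm, or
#'   `I_XM`/`I_YM` in degrees).
#' @export
predict.cw_translation <- function(object, newdata,
                                   direction = c("cw", "alpha"), ...) {
  direction <- match.arg(direction)
  mat <- if (direction == "cw") object$forward else object$reverse
  .translate_eval(mat, newdata)
}

#' Predict the CW chord of one or more eyes
#'
#' Convenience wrapper around [predict.cw_translation()] taking biometry
#' and incident angle separately.
#'
#' @param biometry biometry row(s).
#' @param angle [incident_angle()] or data.frame with `I_X`, `I_Y`.
#' @param model `cw_translation` model.
#' @return n x 2 matrix `CW_XM`, `CW_YM` (mm).
#' @export
predict_cw <- function(biometry, angle, model) {
  nd <- cbind(as.data.frame(biometry),
              data.frame(I_X = angle$I_X, I_Y = angle$I_Y))
  predict(model, nd, direction = "cw")
}

#' Predict the incident angle (angle Alpha) from a measured CW chord
#'
#' @param biometry biometry row(s).
#' @param cw length-2 vector `c(CW_X, CW_Y)` or data.frame with `CW_X`,
#'   `CW_Y`, mm.
#' @param model `cw_translation` model.
#' @return n x 2 matrix `I_XM`, `I_YM` (degrees).
#' @export
predict_alpha <- function(biometry, cw, model) {
  if (!is.data.frame(cw)) cw <- data.frame(CW_X = cw[1], CW_Y = cw[2])
  nd <- cbind(as.data.frame(biometry), cw)
  predict(model, nd, direction = "alpha")
}

#' Compact coefficient matrices of a translation model
#'
#' @param object `cw_translation`.
#' @param direction `"cw"` (forward), `"alpha"` (reverse) or `"both"`.
#' @param compact drop regressor columns that are zero in both rows
#'   (yielding the canonical 2 x 10 layout when `Qp` and `Pup` are
#'   unselected).
#' @param ... unused.
#' @return coefficient matrix, or list of both.
#' @export
coef.cw_translation <- function(object, direction = c("both", "cw", "alpha"),
                                compact = FALSE, ...) {
  direction <- match.arg(direction)
  squeeze <- function(m) {
    if (!compact) return(m)
    keep <- colnames(m) == "(Intercept)" | colSums(m != 0) > 0
    m[, keep, drop = FALSE]
  }
  switch(direction,
         cw = squeeze(object$forward),
         alpha = squeeze(object$reverse),
         both = list(forward = squeeze(object$forward),
                     reverse = squeeze(object$reverse)))
}

#' @export
residuals.cw_translation <- function(object, ...) object$residuals

#' @export
fitted.cw_translation <- function(object, ...) object$fitted

#' @export
print.cw_translation <- function(x, digits = 4, ...) {
  cat("<cw_translation> CW chord <-> incident angle (angle Alpha)\n")
  if (!is.null(x$n)) cat("  fitted on", x$n, "eyes\n")
  cat("\nForward (CW in mm):\n")
  print(round(coef(x, "cw", compact = TRUE), digits))
  cat("\nReverse (angle in degrees):\n")
  print(round(coef(x, "alpha", compact = TRUE), digits))
  invisible(x)
}

#' @export
summary.cw_translation <- function(object, ...) {
  structure(list(model = object), class = "summary.cw_translation")
}

#' @export
print.summary.cw_translation <- function(x, ...) {
  m <- x$model
  print(m)
  for (resp in names(m$diagnostics)) {
    d <- m$diagnostics[[resp]]
    if (is.null(d)) next
    cat(sprintf("\n%s: RMSE %.4f, sigma %.4f, R^2 %.4f\n",
                resp, d$rmse, d$sigma, d$r.squared))
    stats::printCoefmat(d$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                        cs.ind = 1:2, tst.ind = 3)
  }
  invisible(x)
}

#' Diagnostic plot: model prediction versus raytraced value
#'
#' Scatter of predicted against observed chord components (forward) or
#' angle components (reverse) on a results table, with the identity line.
#'
#' @param x `cw_translation`.
#' @param data results table with observed responses and regressors.
#' @param direction `"cw"` or `"alpha"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cw_translation <- function(x, data, direction = c("cw", "alpha"), ...) {
  direction <- match.arg(direction)
  pred <- predict(x, data, direction)
  obs_names <- if (direction == "cw") CW_CHORD else CW_ANGLES
  unit <- if (direction == "cw") "mm" else "deg"
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (j in 1:2) {
    obs <- data[[obs_names[j]]]
    graphics::plot(obs, pred[, j],
                   xlab = sprintf("raytraced %s [%s]", obs_names[j], unit),
                   ylab = sprintf("model %s [%s]", colnames(pred)[j], unit),
                   pch = 16, cex = 0.4, col = "#00000055", ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' The published 2022 reference translation matrices
#'
#' Loads the bundled forward coefficient matrix of the 2022 reference
#' translation model (fitted on a raytraced clinical cohort of 8959 eyes)
#' and derives its reverse by exact inversion. See the JSON fixture in
#' `inst/extdata/` for the provenance notes, including the intercept-sign
#' and second-row parsing corrections applied.
#'
#' @return `cw_translation` object (without fit diagnostics).
#' @export
cw_translation_2022 <- function() {
  path <- system.file("extdata", "cw_translation_reference_2022.json",
                      package = "cwchord", mustWork = TRUE)
  read_translation_json(path)
}
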