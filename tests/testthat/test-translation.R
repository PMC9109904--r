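# Stepwise selection, translation-model fitting, inversion and prediction.

make_linear_data <- function(n = 300, seed = 2) {
  set.seed(seed)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n))
  X$y <- 2 + 1.5 * X$x1 + rnorm(n, sd = 1e-4)
  X
}

test_that("stepwise selects exactly the true regressor", {
  d <- make_linear_data()
  sel <- stepwise_select(d$y, d[paste0("x", 1:5)])
  expect_true(sel["x1"])
  expect_identical(sum(sel), 1L)
})

test_that("stepwise errors on rank-deficient candidate sets", {
  d <- make_linear_data()
  d$x2 <- 2 * d$x1
  sel_in <- c(x1 = TRUE, x2 = TRUE, x3 = FALSE, x4 = FALSE, x5 = FALSE)
  expect_error(cwchord:::.ols(d$y, cbind(1, as.matrix(d[c("x1", "x2")]))),
               "rank-deficient")
})

test_that("noiseless linear responses are recovered exactly", {
  set.seed(2)
  n <- 200
  eyes <- random_eyes(n, seed = 21)
  ang <- sample_incident_angles(n, seed = 22)
  d <- cbind(eyes, ang)
  beta <- c(0.5, 0.09, -0.13)
  d$CW_X <- beta[1] + beta[2] * d$Ra + beta[3] * d$I_X
  d$CW_Y <- -0.01 + 1.02 * d$Pup_Y - 0.128 * d$I_Y
  fit <- cw_translation(d)
  expect_equal(unname(fit$forward["CW_X", c("(Intercept)", "Ra", "I_X")]),
               beta, tolerance = 1e-10)
  expect_equal(unname(fit$forward["CW_Y", "Pup_Y"]), 1.02, tolerance = 1e-10)
  # masked-out coefficients are exactly zero
  expect_identical(unname(fit$forward["CW_X", "Pup"]), 0)
  expect_true(all(fit$forward["CW_X", !c(TRUE, fit$masks$CW_X)] == 0))
})

test_that("model inversion is an exact algebraic identity", {
  eyes <- random_eyes(400, seed = 51)
  ang <- sample_incident_angles(400, seed = 52)
  res <- run_monte_carlo(eyes, ang)
  fit <- cw_translation(res)
  # forward then reverse on shared covariates recovers the angles exactly
  cwm <- predict(fit, res, direction = "cw")
  nd <- res
  nd$CW_X <- cwm[, "CW_XM"]; nd$CW_Y <- cwm[, "CW_YM"]
  alpha <- predict(fit, nd, direction = "alpha")
  expect_equal(alpha[, "I_XM"], res$I_X, tolerance = 1e-9)
  expect_equal(alpha[, "I_YM"], res$I_Y, tolerance = 1e-9)
  # reverse CW coefficient is the reciprocal of the forward angle coefficient
  expect_equal(fit$reverse["I_X", "CW_X"], 1 / fit$forward["CW_X", "I_X"],
               tolerance = 1e-12)
  # inverting twice returns the forward matrix
  twice <- invert_translation(fit$reverse)
  expect_equal(twice[, colnames(fit$forward)], fit$forward, tolerance = 1e-12)
  # singular angle block cannot be reversed
  fw0 <- fit$forward; fw0[, c("I_X", "I_Y")] <- 0
  expect_error(invert_translation(fw0), "singular")
})

test_that("regression coefficient of I_X matches the raytracer's derivative", {
  eyes <- random_eyes(400, seed = 61)
  ang <- sample_incident_angles(400, seed = 62)
  fit <- cw_translation(run_monte_carlo(eyes, ang))
  m <- eye_model(mean_eye())
  h <- 0.1
  fd <- (compute_cw_chord(m, incident_angle(-5.03 + h, 0.01))$CW_X -
         compute_cw_chord(m, incident_angle(-5.03 - h, 0.01))$CW_X) / (2 * h)
  expect_lt(abs(fit$forward["CW_X", "I_X"] - fd), 0.01)
})

test_that("prediction workflow and the bundled 2022 reference model", {
  ref <- cw_translation_2022()
  expect_s3_class(ref, "cw_translation")
  expect_equal(unname(ref$forward["CW_X", "I_X"]), -0.1286)
  expect_equal(unname(ref$forward["CW_Y", "Pup_Y"]), 1.0199)
  expect_equal(unname(ref$reverse["I_X", "CW_X"]), -1 / 0.1286,
               tolerance = 1e-12)
  # evaluating the reference matrices at the cohort means reproduces the
  # cohort-mean chord (this fixes the printed intercept's sign)
  cwm <- predict_cw(mean_eye(), mean_angle(), ref)
  expect_lt(abs(cwm[1, "CW_XM"] - 0.33), 0.05)
  expect_lt(abs(cwm[1, "CW_YM"] - (-0.10)), 0.05)
  # round trip through the same model recovers the angle exactly
  b <- mean_eye()
  back <- predict_alpha(b, c(cwm[1, 1], cwm[1, 2]), ref)
  expect_equal(unname(back[1, ]), c(-5.03, 0.01), tolerance = 1e-9)
  # an all-zero model predicts zero
  z <- ref; z$forward[] <- 0
  expect_equal(unname(predict_cw(b, mean_angle(), z)[1, ]), c(0, 0))
})

test_that("held-out prediction quality on synthetic eyes", {
  eyes <- random_eyes(700, seed = 81)
  ang <- sample_incident_angles(700, seed = 82)
  res <- run_monte_carlo(eyes, ang)
  train <- res[1:500, ]; test <- res[501:700, ]
  fit <- cw_translation(train)
  pred <- predict(fit, test, direction = "cw")
  for (j in 1:2) {
    obs <- test[[c("CW_X", "CW_Y")[j]]]
    r2 <- 1 - sum((obs - pred[, j])^2) / sum((obs - mean(obs))^2)
    expect_gt(r2, 0.95)
  }
  alpha <- predict(fit, test, direction = "alpha")
  expect_lt(sqrt(mean((alpha[, "I_XM"] - test$I_X)^2)), 0.5)
  expect_lt(sqrt(mean((alpha[, "I_YM"] - test$I_Y)^2)), 0.5)
})

test_that("translation model JSON round trip preserves the model", {
  eyes <- random_eyes(200, seed = 91)
  ang <- sample_incident_angles(200, seed = 92)
  fit <- cw_translation(run_monte_carlo(eyes, ang))
  path <- tempfile(fileext = ".json")
  write_translation_json(fit, path)
  back <- read_translation_json(path)
  expect_equal(back$forward, fit$forward, tolerance = 1e-12)
  expect_equal(back$reverse, fit$reverse, tolerance = 1e-12)
  expect_equal(lapply(back$masks, unname),
               lapply(fit$masks, function(m) unname(as.logical(m))))
})

test_that("summary and compact coefficient accessors work", {
  eyes <- random_eyes(200, seed = 95)
  ang <- sample_incident_angles(200, seed = 96)
  fit <- cw_translation(run_monte_carlo(eyes, ang))
  expect_output(print(summary(fit)), "RMSE")
  cmp <- coef(fit, "cw", compact = TRUE)
  expect_true(all(colSums(cmp[, -1, drop = FALSE] != 0) > 0))
  expect_identical(dim(residuals(fit)), dim(fitted(fit)))
})
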