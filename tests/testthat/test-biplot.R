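test_that("joint biplot markers reproduce the core-slice product identity", {
  fit <- tiny_fit(seed = 201)
  for (ref in c("C", "B", "A")) {
    rmax <- switch(ref, A = fit$ranks[1], B = fit$ranks[2], C = fit$ranks[3])
    for (r in seq_len(rmax)) {
      bp <- joint_biplot(fit, reference = ref, r = r)
      left <- switch(ref, C = fit$A, B = fit$A, A = fit$B)
      right <- switch(ref, C = fit$B, B = fit$C, A = fit$C)
      expect_lt(max(abs(bp$row_markers %*% t(bp$col_markers) -
                          left %*% bp$slice %*% t(right))), 1e-12)
    }
  }
  expect_error(joint_biplot(fit, reference = "C", r = 5), "out of range")
})

test_that("joint biplot degenerates correctly for zero and rank-1 cores", {
  fit <- tiny_fit(seed = 202)
  fit0 <- fit; fit0$G[, , 1] <- 0
  bp <- joint_biplot(fit0, reference = "C", r = 1)
  expect_equal(max(abs(bp$row_markers)), 0)
  expect_equal(max(abs(bp$col_markers)), 0)

  # scalar core slice: markers proportional to A u sqrt(d) and B v sqrt(d)
  fit1 <- tiny_fit(seed = 203, ranks = c(1, 1, 1))
  bp1 <- joint_biplot(fit1, reference = "C", r = 1)
  d1 <- abs(fit1$G[1, 1, 1])
  I <- nrow(fit1$A); J <- nrow(fit1$B)
  expect_equal(abs(bp1$row_markers),
               (I / J)^(1 / 4) * abs(fit1$A) * sqrt(d1),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(abs(bp1$col_markers),
               (J / I)^(1 / 4) * abs(fit1$B) * sqrt(d1),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("interactive biplot markers reproduce the fitted criterion", {
  fit <- tiny_fit(seed = 204)
  J <- nrow(fit$B); K <- nrow(fit$C)
  bp <- interactive_biplot(fit)
  expect_equal(nrow(bp$col_markers), J * K)
  expect_equal(bp$ids[1], "S1RP1")
  expect_equal(bp$ids[J + 1], "S2RP1")   # attribute index fastest
  full <- bp$row_markers %*% t(bp$col_markers)
  expect_lt(max(abs(full - predict_y(fit$A, fit$G, fit$B, fit$C))), 1e-12)
  # restriction to one attribute keeps one marker per source
  one <- interactive_biplot(fit, attribute = 2)
  expect_equal(nrow(one$col_markers), K)
  expect_true(all(one$attribute == 2))
  expect_error(interactive_biplot(fit, attribute = 99), "unknown attribute")
})

test_that("triplot adds predictor markers that reproduce the fitted X", {
  fit <- tiny_fit(seed = 205)
  bp <- triplot(fit)
  expect_equal(nrow(bp$extra_markers), ncol(fit$X))
  expect_lt(max(abs(bp$row_markers %*% t(bp$extra_markers) -
                      fitted(fit, "X"))), 1e-12)
})

test_that("regression-weight markers carry the predictor-to-response weights", {
  fit <- tiny_fit(seed = 206)
  bp <- regression_weight_biplot(fit)
  Z <- fit$W_X %*% t(fit$P_Y)
  expect_equal(bp$Z, Z, tolerance = 1e-14)
  expect_lt(max(abs(bp$row_markers %*% t(bp$col_markers) - Z)), 1e-12)
  # X Z reproduces the fitted criterion block
  expect_lt(max(abs(fit$X %*% Z - predict_y(fit$A, fit$G, fit$B, fit$C))),
            1e-10)
  # marker inner product equals the matrix entry, elementwise
  expect_equal(drop(bp$row_markers[3, ] %*% bp$col_markers[5, ]), Z[3, 5])
})

test_that("interpolation returns training scores exactly and is linear", {
  sim <- simulate_t3pcovr(I = 10, J = 4, K = 3, L = 5, snr_x = 5,
                          snr_y = 5, seed = 207)
  fit <- t3pcovr(preprocess(sim$data), c(2, 2, 2), n_starts = 2, seed = 207)
  # a raw training row interpolates to its own score row
  for (i in c(1, 6)) {
    got <- interpolate_obs(fit, sim$data$X[i, ])
    expect_equal(got$scores, fit$A[i, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$predictions,
                 predict_y(fit$A, fit$G, fit$B, fit$C)[i, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # the raw column means map to the origin
  expect_equal(interpolate_obs(fit, colMeans(sim$data$X))$scores,
               c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  # linearity on the preprocessed scale
  set.seed(1); x1 <- rnorm(5); x2 <- rnorm(5)
  s12 <- interpolate_obs(fit, x1 + x2, raw = FALSE)$scores
  expect_equal(s12, interpolate_obs(fit, x1, raw = FALSE)$scores +
                 interpolate_obs(fit, x2, raw = FALSE)$scores,
               tolerance = 1e-12)
  expect_error(interpolate_obs(fit, 1:3), "expected 5")
})

test_that("graded axis scales place ticks along the direction vector", {
  ticks <- axis_scale_markers(c(0.6, 0.8), c(-2, 0, 2))
  expect_equal(ticks$x, c(-1.2, 0, 1.2))
  expect_equal(ticks$y, c(-1.6, 0, 1.6))
  # symmetric about the origin for +-mu
  expect_equal(ticks[1, c("x", "y")], -ticks[3, c("x", "y")],
               ignore_attr = TRUE)

  info <- list(mean = c(a = 10, b = 0), scale = c(a = 2, b = 1))
  lab <- axis_scale_markers(c(1, 0), c(-1, 0, 1), info, "a")
  # labels are back-transformed: mean + sd * mu; mu = 0 labels the mean
  expect_equal(as.numeric(lab$label), c(8, 10, 12))
  expect_error(axis_scale_markers(c(0, 0), 1), "nonzero")
})

test_that("biplot objects print and plot without error", {
  fit <- tiny_fit(seed = 208)
  bp <- triplot(fit)
  expect_output(print(bp), "triplot")
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(bp))
  expect_no_error(plot(joint_biplot(fit)))
})
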