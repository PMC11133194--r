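test_that("rational initialization is orthonormal and spans the data subspaces", {
  set.seed(101)
  sim <- simulate_t3pcovr(I = 12, J = 5, K = 4, L = 6, ranks = c(2, 2, 2),
                          snr_x = 5, snr_y = 5, seed = 101)
  X <- sim$data$X; Y <- sim$data$Y
  ini <- init_rational(X, Y, c(2, 2, 2))
  expect_equal(crossprod(ini$B), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(crossprod(ini$C), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(crossprod(ini$A), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  # B0 spans the same subspace as the top-2 left singular vectors of Y_B
  sv <- svd(unfold(Y, "B"))$u[, 1:2]
  expect_gt(subspace_congruence(ini$B, sv), 1 - 1e-10)
  # deterministic: identical on a second call
  expect_identical(ini, init_rational(X, Y, c(2, 2, 2)))
})

test_that("rational init plus one regression step nails noiseless rank-1 data", {
  sim <- simulate_t3pcovr(I = 8, J = 4, K = 3, L = 5, ranks = c(1, 1, 1),
                          snr_x = Inf, snr_y = Inf, seed = 5)
  fit <- t3pcovr(sim$data, c(1, 1, 1), n_starts = 1, max_iter = 1, seed = 1)
  expect_lt(fit$loss, 1e-10)
})

test_that("random and perturbed initializations are reproducible and shaped", {
  set.seed(1); a <- init_random(c(6, 4, 3), c(2, 2, 2))
  set.seed(1); b <- init_random(c(6, 4, 3), c(2, 2, 2))
  set.seed(2); c2 <- init_random(c(6, 4, 3), c(2, 2, 2))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$A, c2$A)))
  expect_equal(dim(a$A), c(6L, 2L))
  expect_equal(crossprod(a$B), diag(2), tolerance = 1e-12, ignore_attr = TRUE)

  sim <- simulate_t3pcovr(seed = 3)
  rat <- init_rational(sim$data$X, sim$data$Y, c(2, 2, 2))
  expect_identical(init_perturbed(rat, 0), rat)
  set.seed(4)
  p1 <- init_perturbed(rat, 0.05)
  expect_equal(crossprod(p1$B), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  # larger perturbations land farther from the rational start on average
  dist_at <- function(s) mean(replicate(20, {
    p <- init_perturbed(rat, s); sqrt(sum((p$A - rat$A)^2))
  }))
  set.seed(5)
  expect_gt(dist_at(0.5), dist_at(0.05))
})

test_that("one ALS cycle never increases the loss and fixes converged states", {
  set.seed(111)
  for (rep in 1:20) {
    I <- sample(4:9, 1); J <- sample(2:5, 1); K <- sample(2:4, 1)
    L <- sample(2:5, 1)
    r <- c(sample(1:2, 1), sample(1:min(J, 2), 1), sample(1:min(K, 2), 1))
    if (!ranks_valid(r, c(I, J, K, L))) next
    X <- matrix(rnorm(I * L), I)
    Y <- rand_array(I, J, K)
    alpha <- runif(1)
    ini <- init_random(c(I, J, K), r)
    W <- MASS::ginv(X) %*% ini$A
    A <- X %*% W
    reg <- t3pcovr:::regress_core(A, ini$B, ini$C, X, unfold(Y, "A"))
    st <- list(A = A, B = ini$B, C = ini$C, G = reg$G, P_X = reg$P_X, W_X = W)
    l0 <- t3pcovr_loss(st$A, st$B, st$C, st$G, st$P_X, alpha, X,
                       unfold(Y, "A"))
    st1 <- als_cycle(st, X, Y, alpha)
    l1 <- t3pcovr_loss(st1$A, st1$B, st1$C, st1$G, st1$P_X, alpha, X,
                       unfold(Y, "A"))
    expect_lte(l1, l0 + 1e-12)
  }

  fit <- tiny_fit(seed = 7, tol = 1e-10)
  st <- list(A = fit$A, B = fit$B, C = fit$C, G = fit$G, P_X = fit$P_X,
             W_X = fit$W_X)
  st1 <- als_cycle(st, fit$X, fit$Y, fit$alpha)
  l1 <- t3pcovr_loss(st1$A, st1$B, st1$C, st1$G, st1$P_X, fit$alpha,
                     fit$X, unfold(fit$Y, "A"))
  expect_lt(fit$loss - l1, 1e-8 * fit$loss + 1e-14)
})

test_that("the fit satisfies its structural invariants", {
  fit <- tiny_fit(seed = 13)
  expect_lt(max(abs(fit$A - fit$X %*% fit$W_X)), 1e-8)
  expect_equal(crossprod(fit$B), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(crossprod(fit$C), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(fit$loss_history) <= 1e-12))
  expect_true(fit$converged)
  # P_Y is the Kronecker-structured regression weight matrix
  expect_equal(fit$P_Y,
               kronecker(fit$C, fit$B) %*% t(unfold(fit$G, "A")),
               ignore_attr = TRUE, tolerance = 1e-12)
  # reported scalar residuals match the residual matrices
  expect_equal(fit$rss_x, sum((fit$X - fitted(fit, "X"))^2))
  expect_equal(fit$rss_y,
               sum((unfold(fit$Y, "A") - unfold(fitted(fit, "Y"), "A"))^2))
})

test_that("refitting with the same seed reproduces the solution exactly", {
  f1 <- tiny_fit(seed = 19)
  f2 <- tiny_fit(seed = 19)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$loss, f2$loss)
})

test_that("noiseless data at the true complexity is fitted exactly", {
  sim <- simulate_t3pcovr(snr_x = Inf, snr_y = Inf, seed = 23)
  fit <- t3pcovr(sim$data, c(2, 2, 2), n_starts = 2, seed = 23)
  expect_lt(fit$loss, 1e-10)
})

test_that("alpha = 1 reduces to principal component regression on X", {
  for (s in 1:3) {
    sim <- simulate_t3pcovr(I = 12, J = 4, K = 3, L = 6, snr_x = 5,
                            snr_y = 5, seed = 300 + s)
    pd <- preprocess(sim$data)
    fit <- t3pcovr(pd, c(2, 2, 2), alpha = 1, n_starts = 2, tol = 1e-12,
                   seed = s)
    pc <- svd(pd$X)$u[, 1:2]
    cosines <- svd(crossprod(qr.Q(qr(fit$A)), pc))$d
    expect_gt(min(cosines), 1 - 1e-8)
  }
})

test_that("alpha = 0 at full attribute/source rank reduces to RRR", {
  for (s in 1:3) {
    sim <- simulate_t3pcovr(I = 12, J = 4, K = 3, L = 6, seed = 400 + s)
    pd <- preprocess(sim$data)
    fit <- t3pcovr(pd, c(2, 4, 3), alpha = 0, n_starts = 1, tol = 1e-14,
                   max_iter = 5000, delta_tol = 1e-11, seed = s)
    YA <- unfold(pd$Y, "A")
    H <- pd$X %*% MASS::ginv(pd$X)
    sv <- svd(H %*% YA)
    Yrrr <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
    expect_lt(max(abs(predict_y(fit$A, fit$G, fit$B, fit$C) - Yrrr)), 1e-8)
  }
})

test_that("a single-source array (K = 1) degrades gracefully to two-way", {
  sim <- simulate_t3pcovr(I = 10, J = 5, K = 1, L = 4, ranks = c(2, 2, 1),
                          snr_x = 5, snr_y = 5, seed = 31)
  fit <- t3pcovr(sim$data, c(2, 2, 1), n_starts = 2, seed = 31)
  expect_equal(dim(fit$C), c(1L, 1L))
  expect_true(all(diff(fit$loss_history) <= 1e-12))
})

test_that("subspace congruence scores identical and orthogonal spaces correctly", {
  set.seed(37)
  U <- qr.Q(qr(matrix(rnorm(20), 10)))
  expect_equal(subspace_congruence(U, U), 1)
  expect_equal(subspace_congruence(U, U %*% matrix(c(0, 1, -1, 0), 2)), 1)
  V <- qr.Q(qr(matrix(rnorm(20), 10)))
  expect_lt(subspace_congruence(U, V), 1)
})
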