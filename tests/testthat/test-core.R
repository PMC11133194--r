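test_that("unfolding follows the attribute-fastest convention in every mode", {
  # index-arithmetic oracle on the fully labeled 2x2x2 array
  Y <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    Y[i, j, k] <- 100 * i + 10 * j + k
  for (i in 1:2)
    expect_equal(unfold(Y, "A")[i, ],
                 c(Y[i, 1, 1], Y[i, 2, 1], Y[i, 1, 2], Y[i, 2, 2]))

  set.seed(11)
  Yr <- rand_array(3, 4, 2)
  for (m in c("A", "B", "C"))
    expect_equal(unfold(Yr, m), unfold_oracle(Yr, m))

  expect_equal(unfold(array(5, c(1, 1, 1)), "A"), matrix(5, 1, 1))
})

test_that("fold is the exact inverse of unfold for all modes", {
  set.seed(21)
  for (d in list(c(3, 4, 2), c(2, 2, 5), c(1, 3, 2), c(4, 1, 1))) {
    Y <- rand_array(d[1], d[2], d[3])
    for (m in c("A", "B", "C"))
      expect_identical(fold(unfold(Y, m), m, d), Y)
  }
})

test_that("predict_y matches the elementwise trilinear sum", {
  set.seed(31)
  for (case in list(list(d = c(4, 3, 2), r = c(2, 2, 2)),
                    list(d = c(5, 5, 5), r = c(3, 2, 2)),
                    list(d = c(3, 3, 3), r = c(1, 1, 1)))) {
    A <- matrix(rnorm(case$d[1] * case$r[1]), case$d[1])
    B <- matrix(rnorm(case$d[2] * case$r[2]), case$d[2])
    C <- matrix(rnorm(case$d[3] * case$r[3]), case$d[3])
    G <- array(rnorm(prod(case$r)), case$r)
    expect_equal(predict_y(A, G, B, C), predict_oracle(A, G, B, C),
                 tolerance = 1e-12)
  }
  # zero core and identity factors
  A <- diag(2); B <- diag(2); C <- diag(2)
  expect_equal(predict_y(A, array(0, c(2, 2, 2)), B, C), matrix(0, 2, 4))
  G <- array(rnorm(8), c(2, 2, 2))
  expect_equal(predict_y(A, G, B, C), unfold(G, "A"))
})

test_that("beta follows the norm-weighted reparameterization", {
  # alpha = 0.5 with ||Y||^2 = 3, ||X||^2 = 1 gives beta = 0.75
  X <- matrix(1)                        # ||X||^2 = 1
  Y_A <- matrix(c(1, 1, 1), 1)          # ||Y||^2 = 3
  expect_equal(beta_from_alpha(0.5, X, Y_A), 0.75)
  expect_equal(beta_from_alpha(0, X, Y_A), 0)
  expect_equal(beta_from_alpha(1, X, Y_A), 1)
  # equal norms: beta = alpha
  Yeq <- matrix(1)
  for (a in c(0.1, 0.4, 0.9)) expect_equal(beta_from_alpha(a, X, Yeq), a)
  # strictly increasing in alpha
  b <- vapply(seq(0, 1, 0.1),
              function(a) beta_from_alpha(a, X, Y_A), numeric(1))
  expect_true(all(diff(b) > 0))
  expect_error(beta_from_alpha(0.5, matrix(0), Y_A), "positive norm")
})

test_that("the normalized and concatenated loss forms are proportional", {
  set.seed(41)
  for (rep in 1:10) {
    I <- 5; J <- 3; K <- 2; L <- 4; r <- c(2, 2, 2)
    X <- matrix(rnorm(I * L), I)
    Y_A <- matrix(rnorm(I * J * K), I)
    A <- matrix(rnorm(I * r[1]), I)
    B <- matrix(rnorm(J * r[2]), J)
    C <- matrix(rnorm(K * r[3]), K)
    G <- array(rnorm(prod(r)), r)
    P_X <- matrix(rnorm(L * r[1]), L)
    alpha <- runif(1)
    l6 <- t3pcovr_loss(A, B, C, G, P_X, alpha, X, Y_A)
    beta <- beta_from_alpha(alpha, X, Y_A)
    QS <- t3pcovr:::build_qs(B, C, G, P_X, beta, X, Y_A)
    l7 <- t3pcovr:::loss_qs(A, QS)
    cc <- t3pcovr:::loss_constant(alpha, X, Y_A)
    expect_equal(l6, cc * l7, tolerance = 1e-12)
  }
})

test_that("loss endpoints behave as the normalization dictates", {
  set.seed(51)
  I <- 6; J <- 3; K <- 2; L <- 4
  X <- matrix(rnorm(I * L), I)
  B <- qr.Q(qr(matrix(rnorm(J * 2), J)))
  C <- qr.Q(qr(matrix(rnorm(K * 2), K)))
  G <- array(rnorm(8), c(2, 2, 2))
  A <- matrix(rnorm(I * 2), I)
  Y_A <- predict_y(A, G, B, C)
  P_X <- t(MASS::ginv(A) %*% X)
  # perfect fit in both blocks
  expect_equal(t3pcovr_loss(A, B, C, G, P_X, 0.5, A %*% t(P_X), Y_A), 0)
  # zero fitted X with alpha = 1: loss is exactly 1
  expect_equal(t3pcovr_loss(A, B, C, G, matrix(0, L, 2), 1, X, Y_A), 1)
})

test_that("coupled_data validates shapes and rank admissibility is enforced", {
  X <- matrix(rnorm(12), 4)
  expect_error(coupled_data(X, array(0, c(3, 2, 2))), "mismatch")
  expect_error(coupled_data(X, matrix(0, 4, 2)), "three-way")
  Xna <- X; Xna[1] <- NA
  expect_error(coupled_data(Xna, array(0, c(4, 2, 2))), "missing")

  dims <- c(8, 7, 6, 10)
  expect_true(ranks_valid(c(2, 2, 2), dims))
  expect_false(ranks_valid(c(2, 1, 1), dims))   # R1 > R2*R3
  expect_false(ranks_valid(c(1, 8, 1), dims))   # R2 > J
  expect_true(ranks_valid(c(1, 1, 1), dims))
  expect_false(ranks_valid(c(9, 3, 3), dims))   # R1 > I
})
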