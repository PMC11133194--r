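#' Tucker3 fitted values for the criterion array
#'
#' Computes the mode-A matricized fitted values
#' \code{A \%*\% G_A \%*\% t(C \%x\% B)}: object scores \code{A} times
#' the mode-1 matricized core times the Kronecker-structured attribute
#' and source components.
#'
#' @param A object-score matrix, \code{I x R1}.
#' @param G core array, \code{R1 x R2 x R3} (a matrix is accepted when
#'   \code{R3 = 1}).
#' @param B attribute component matrix, \code{J x R2}.
#' @param C source component matrix, \code{K x R3}.
#' @return fitted \code{I x JK} matrix, columns ordered attribute
#'   fastest (column \code{(k - 1) * J + j}).
#' @export
predict_y <- function(A, G, B, C) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (is.matrix(G)) G <- array(G, c(dim(G), 1L))
  dG <- dim(G)
  if (ncol(A) != dG[1L] || ncol(B) != dG[2L] || ncol(C) != dG[3L])
    stop("core dimensions do not match the component matrices")
  GA <- unfold(G, "A")                      # R1 x R2R3, column (r3-1)R2+r2
  A %*% GA %*% t(kronecker(C, B))
}

#' Convert the loss weight alpha to the concatenation weight beta
#'
#' The normalized two-block loss with weight \code{alpha} is
#' proportional to an unnormalized loss on the concatenated matrix
#' \code{[sqrt(beta) X | sqrt(1 - beta) Y_A]} with
#' \code{beta = alpha * ||Y_A||^2 / (alpha * ||Y_A||^2 +
#' (1 - alpha) * ||X||^2)} (squared Frobenius norms). \code{beta} is
#' the weight actually used inside the ALS updates.
#'
#' @param alpha weighting parameter in \code{[0, 1]}; 1 emphasizes
#'   summarizing \code{X} (principal component regression limit), 0
#'   emphasizes predicting \code{Y} (reduced rank regression limit).
#' @param X preprocessed predictor matrix.
#' @param Y_A preprocessed criterion array, mode-A matricized.
#' @return \code{beta} in \code{[0, 1]}.
#' @export
beta_from_alpha <- function(alpha, X, Y_A) {
  stopifnot(alpha >= 0, alpha <= 1)
  nx <- fnorm2(X); ny <- fnorm2(Y_A)
  if (nx <= 0 || ny <= 0) stop("both data blocks must have positive norm")
  alpha * ny / (alpha * ny + (1 - alpha) * nx)
}

#' Tucker3-PCovR loss
#'
#' The weighted, normalized least-squares criterion
#' \deqn{\alpha \|X - A P_X'\|^2 / \|X\|^2 +
#'       (1-\alpha) \|Y_A - A G_A (C \otimes B)'\|^2 / \|Y_A\|^2,}
#' minimized by \code{\link{t3pcovr}}. All reported losses in the
#' package are on this normalized scale (a perfect fit gives 0; fitting
#' both blocks by zero gives 1).
#'
#' @inheritParams predict_y
#' @param P_X predictor loading matrix, \code{L x R1}.
#' @param alpha weighting parameter in \code{[0, 1]}.
#' @param X,Y_A the (preprocessed) data blocks, \code{Y_A} matricized.
#' @return nonnegative scalar.
#' @export
t3pcovr_loss <- function(A, B, C, G, P_X, alpha, X, Y_A) {
  rx <- X - A %*% t(P_X)
  ry <- Y_A - predict_y(A, G, B, C)
  alpha * fnorm2(rx) / fnorm2(X) + (1 - alpha) * fnorm2(ry) / fnorm2(Y_A)
}

# Concatenated form of the loss: || Q - A S^T ||^2 with
#   Q = [ sqrt(beta) X | sqrt(1-beta) Y_A ]
#   S^T = [ sqrt(beta) P_X^T | sqrt(1-beta) G_A (C (x) B)^T ].
# Equal to t3pcovr_loss() divided by the constant
#   c = (alpha ||Y_A||^2 + (1-alpha) ||X||^2) / (||X||^2 ||Y_A||^2),
# which is parameter-free, so the two forms order candidate solutions
# identically; the ALS updates work on this form.
build_qs <- function(B, C, G, P_X, beta, X, Y_A) {
  GA <- unfold(if (is.matrix(G)) array(G, c(dim(G), 1L)) else G, "A")
  PY <- kronecker(C, B) %*% t(GA)          # JK x R1
  list(Q = cbind(sqrt(beta) * X, sqrt(1 - beta) * Y_A),
       S = rbind(sqrt(beta) * P_X, sqrt(1 - beta) * PY))
}

loss_constant <- function(alpha, X, Y_A) {
  nx <- fnorm2(X); ny <- fnorm2(Y_A)
  (alpha * ny + (1 - alpha) * nx) / (nx * ny)
}

loss_qs <- function(A, QS) fnorm2(QS$Q - A %*% t(QS$S))
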