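#' Simulate coupled data with known Tucker3-PCovR structure
#'
#' Generates a predictor matrix and a criterion array sharing a common
#' set of object components, plus ground truth for recovery studies.
#' The construction mirrors the model: orthonormal object scores
#' \code{A} and random loadings \code{P_X} give the predictor signal
#' \code{A P_X'}; orthonormal \code{B}, \code{C} and a random core
#' \code{G} give the criterion signal \code{A G_A (C \%x\% B)'};
#' i.i.d. Gaussian noise is added to each block, scaled so that the
#' Frobenius signal-to-noise ratio matches the request. The weight
#' matrix \code{W_X} is the pseudoinverse solution \code{A = X W_X} on
#' the noiseless predictor block, so in the noiseless limit the model
#' holds exactly and the fitted loss at the true complexity is
#' numerically zero.
#'
#' The default dimensions (8 objects, 7 attributes, 6 sources, 10
#' covariates, complexity (2,2,2)) reproduce the shape of a typical
#' small situation-response study: persons by emotional responses by
#' situations, explained by dispositional traits.
#'
#' @param I,J,K number of objects, attributes, sources.
#' @param L number of covariates.
#' @param ranks true complexity \code{c(R1, R2, R3)}.
#' @param snr_x,snr_y Frobenius signal-to-noise ratio per block
#'   (\code{Inf} for noiseless).
#' @param seed optional integer seed.
#' @return list with \code{data} (a raw \code{\link{coupled_data}}) and
#'   \code{truth} (list with \code{A}, \code{B}, \code{C}, \code{G},
#'   \code{P_X}, \code{W_X}, the noise-free blocks \code{X_signal},
#'   \code{Y_signal}, realized noise s.d.s and the arguments).
#' @export
#' @examples
#' sim <- simulate_t3pcovr(seed = 7)
#' sim$data
simulate_t3pcovr <- function(I = 8, J = 7, K = 6, L = 10,
                             ranks = c(2, 2, 2), snr_x = 10, snr_y = 10,
                             seed = NULL) {
  ranks <- as.integer(ranks)
  if (!ranks_valid(ranks, c(I, J, K, L)))
    stop("invalid ranks for the requested dimensions")
  stopifnot(snr_x > 0, snr_y > 0)
  if (!is.null(seed)) set.seed(seed)

  A <- orth(matrix(stats::rnorm(I * ranks[1L]), I))
  B <- orth(matrix(stats::rnorm(J * ranks[2L]), J))
  C <- orth(matrix(stats::rnorm(K * ranks[3L]), K))
  G <- array(stats::rnorm(prod(ranks)), ranks)
  P_X <- matrix(stats::rnorm(L * ranks[1L]), L)

  X_signal <- A %*% t(P_X)
  Y_signal <- predict_y(A, G, B, C)          # I x JK

  add_noise <- function(signal, snr) {
    if (is.infinite(snr)) return(list(x = signal, sd = 0))
    E <- matrix(stats::rnorm(length(signal)), nrow(signal))
    E <- E * sqrt(fnorm2(signal)) / (snr * sqrt(fnorm2(E)))
    list(x = signal + E, sd = stats::sd(as.vector(E)))
  }
  nx <- add_noise(X_signal, snr_x)
  ny <- add_noise(Y_signal, snr_y)

  W_X <- pinv(X_signal) %*% A                # A = X_signal W_X exactly
  data <- coupled_data(nx$x, fold(ny$x, "A", c(I, J, K)))
  truth <- list(A = A, B = B, C = C, G = G, P_X = P_X, W_X = W_X,
                X_signal = X_signal,
                Y_signal = fold(Y_signal, "A", c(I, J, K)),
                noise_sd_x = nx$sd, noise_sd_y = ny$sd,
                snr_x = snr_x, snr_y = snr_y, ranks = ranks, seed = seed)
  list(data = data, truth = truth)
}
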