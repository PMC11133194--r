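#' Varimax rotation of a component matrix
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion,
#' with Kaiser row-normalization applied and undone (default on). A
#' single-column matrix is returned unchanged with an identity
#' rotation.
#'
#' @param M loading/component matrix.
#' @param normalize apply Kaiser row-normalization during the
#'   optimization.
#' @return list with \code{M_rot = M \%*\% T} and the orthogonal
#'   rotation matrix \code{T}.
#' @export
varimax_rotation <- function(M, normalize = TRUE) {
  M <- as.matrix(M)
  if (ncol(M) < 2L)
    return(list(M_rot = M, T = diag(1L)))
  vm <- stats::varimax(M, normalize = normalize, eps = 1e-10)
  Tm <- vm$rotmat
  list(M_rot = M %*% Tm, T = Tm)
}

#' Rotate a fitted model without changing its fit
#'
#' Exploits the rotational freedom of the decomposition: any of the
#' attribute components (\code{B}), source components (\code{C}) or the
#' predictor loadings (\code{PX}) can be rotated orthogonally — by
#' varimax, or by user-supplied orthogonal matrices — provided the core
#' array (and for \code{PX} also the object scores and weights) is
#' counterrotated. Fitted values and the loss are exactly unchanged.
#'
#' Rotating \code{PX} rotates \code{P_X}, \code{A} and \code{W_X} by
#' the same matrix and counterrotates the first mode of the core, so
#' both the predictor factorization \code{X = A P_X'} and the criterion
#' factorization stay consistent through the shared object mode.
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @param modes subset of \code{c("B", "C", "PX")} to rotate.
#' @param rotations optional named list of orthogonal matrices (names
#'   in \code{modes}) overriding varimax, e.g. for reflection tests.
#' @param normalize Kaiser normalization for varimax.
#' @return the rotated fit (class \code{"t3pcovr"}), with a
#'   \code{rotation} element recording the applied matrices.
#' @export
#' @examples
#' sim <- simulate_t3pcovr(seed = 2)
#' fit <- t3pcovr(preprocess(sim$data), c(2, 2, 2), n_starts = 2, seed = 2)
#' rot <- rotate_fit(fit, modes = c("B", "C"))
#' abs(rot$loss - fit$loss) < 1e-12
rotate_fit <- function(fit, modes = c("B", "C", "PX"), rotations = NULL,
                       normalize = TRUE) {
  stopifnot(inherits(fit, "t3pcovr"))
  bad <- setdiff(modes, c("B", "C", "PX"))
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  applied <- list()

  get_T <- function(mode, M) {
    if (!is.null(rotations[[mode]])) {
      Tm <- as.matrix(rotations[[mode]])
      if (max(abs(crossprod(Tm) - diag(ncol(Tm)))) > 1e-8)
        stop("supplied rotation for ", mode, " is not orthogonal")
      Tm
    } else varimax_rotation(M, normalize = normalize)$T
  }

  rot <- function(M, Tm) {
    out <- M %*% Tm
    dimnames(out) <- dimnames(M)     # component labels survive the mixing
    out
  }
  if ("B" %in% modes) {
    Tb <- get_T("B", fit$B)
    fit$B <- rot(fit$B, Tb)
    fit$G <- ttm(fit$G, t(Tb), 2L)
    applied$B <- Tb
  }
  if ("C" %in% modes) {
    Tc <- get_T("C", fit$C)
    fit$C <- rot(fit$C, Tc)
    fit$G <- ttm(fit$G, t(Tc), 3L)
    applied$C <- Tc
  }
  if ("PX" %in% modes) {
    Tp <- get_T("PX", fit$P_X)
    fit$P_X <- rot(fit$P_X, Tp)
    fit$A <- rot(fit$A, Tp)
    fit$W_X <- rot(fit$W_X, Tp)
    fit$G <- ttm(fit$G, t(Tp), 1L)
    applied$PX <- Tp
  }

  fit$P_Y <- kronecker(fit$C, fit$B) %*% t(unfold(fit$G, "A"))
  dimnames(fit$P_Y) <- list(
    as.vector(outer(fit$labels$attributes, fit$labels$sources,
                    function(a, s) paste(s, a, sep = ":"))),
    paste0("Comp", seq_len(fit$ranks[1L])))
  fit$rotation <- applied
  fit
}
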