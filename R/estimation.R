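orth <- function(M) {
  q <- qr.Q(qr(M))
  q[, seq_len(min(ncol(M), ncol(q))), drop = FALSE]
}

# sign convention: per column, the entry largest in absolute value is
# made positive (first one on ties); returns +-1 per column
column_signs <- function(M) {
  apply(M, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

# leading left singular vectors, padded with an orthonormal complement
# (deterministic, from the identity) if the matrix rank falls short
leading_vectors <- function(M, r, warn_label) {
  sv <- svd(M, nu = min(r, min(dim(M))), nv = 0L)
  U <- sv$u
  nonzero <- sum(sv$d > max(dim(M)) * .Machine$double.eps * max(sv$d, 0))
  if (nonzero < r) {
    warning(sprintf("rank of %s (%d) below requested %d; padding with an orthonormal complement",
                    warn_label, nonzero, r))
  }
  if (ncol(U) < r) {
    Q <- qr.Q(qr(cbind(U, diag(nrow(M)))))
    U <- Q[, seq_len(r), drop = FALSE]
  }
  U <- U[, seq_len(r), drop = FALSE]
  sweep(U, 2L, column_signs(U), "*")
}

#' Rational (deterministic) initialization
#'
#' Starts the components from the spectral structure of the data:
#' \code{B0} and \code{C0} are the leading left singular vectors of the
#' mode-B and mode-C matricizations of \code{Y}; \code{A0} comes from
#' the leading left singular vectors of the column-concatenated block
#' \code{[X | Y_A]}, so both blocks inform the shared object mode.
#' Eigenvector signs are fixed (largest-absolute entry positive), so
#' the result is deterministic.
#'
#' @param X preprocessed predictor matrix, \code{I x L}.
#' @param Y preprocessed criterion array, \code{I x J x K}.
#' @param ranks complexity \code{c(R1, R2, R3)}.
#' @return list with orthonormal \code{A}, \code{B}, \code{C}.
#' @export
init_rational <- function(X, Y, ranks) {
  list(A = leading_vectors(cbind(X, unfold(Y, "A")), ranks[1L], "[X | Y_A]"),
       B = leading_vectors(unfold(Y, "B"), ranks[2L], "Y_B"),
       C = leading_vectors(unfold(Y, "C"), ranks[3L], "Y_C"))
}

#' Random initialization
#'
#' Standard-normal entries for all three component matrices; \code{B0}
#' and \code{C0} are then orthonormalized (QR) so the orthonormality
#' invariants hold from the first iteration.
#'
#' @param dims \code{c(I, J, K)} criterion dimensions.
#' @param ranks complexity \code{c(R1, R2, R3)}.
#' @return list with \code{A}, \code{B}, \code{C}.
#' @export
init_random <- function(dims, ranks) {
  list(A = matrix(stats::rnorm(dims[1L] * ranks[1L]), dims[1L]),
       B = orth(matrix(stats::rnorm(dims[2L] * ranks[2L]), dims[2L])),
       C = orth(matrix(stats::rnorm(dims[3L] * ranks[3L]), dims[3L])))
}

#' Perturbed (pseudo-random) initialization
#'
#' A rational start plus independent \code{N(0, perturb_scale^2)} noise
#' on every entry; \code{B0} and \code{C0} are re-orthonormalized.
#' \code{perturb_scale = 0} reproduces the rational start exactly.
#'
#' @param init0 a rational initialization (list \code{A}, \code{B},
#'   \code{C}).
#' @param perturb_scale standard deviation of the perturbation.
#' @return list with \code{A}, \code{B}, \code{C}.
#' @export
init_perturbed <- function(init0, perturb_scale = 0.1) {
  if (perturb_scale == 0) return(init0)
  jitter <- function(M) M + matrix(stats::rnorm(length(M), sd = perturb_scale),
                                   nrow(M))
  list(A = jitter(init0$A), B = orth(jitter(init0$B)),
       C = orth(jitter(init0$C)))
}

# conditional regression of the core and the predictor loadings on A
# (B, C orthonormal): P_X^T = (A^T A)^- A^T X,
# G_A = (A^T A)^- A^T Y_A (C (x) B)
regress_core <- function(A, B, C, X, Y_A) {
  AtA <- crossprod(A)
  singular <- FALSE
  solve_ata <- function(rhs) {
    out <- tryCatch(solve(AtA, rhs), error = function(e) NULL)
    if (is.null(out)) {
      singular <<- TRUE                 # reported once per fit, not per cycle
      out <- pinv(AtA) %*% rhs
    }
    out
  }
  PXt <- solve_ata(crossprod(A, X))
  GA <- solve_ata(crossprod(A, Y_A) %*% kronecker(C, B))
  list(P_X = t(PXt),
       G = array(GA, c(ncol(A), ncol(B), ncol(C))),
       singular = singular)
}

procrustes_orth <- function(M) {
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' One full ALS cycle
#'
#' Performs the four conditional updates on a model state: (1) the
#' weight matrix \code{W_X} minimizing the concatenated-form loss with
#' all other parameters fixed (and \code{A = X W_X}); (2) the attribute
#' components \code{B} by orthonormal Procrustes on the mode-B
#' matricization; (3) the source components \code{C} likewise; (4) the
#' core array and predictor loadings by multivariate regression on
#' \code{A}. Each update is a conditional minimizer, so the loss cannot
#' increase over the cycle.
#'
#' @param state list with \code{A}, \code{B}, \code{C}, \code{G},
#'   \code{P_X}, \code{W_X} (as produced by \code{\link{t3pcovr}}
#'   internals or an initialization followed by
#'   \code{als_cycle}'s own regression).
#' @param X,Y preprocessed predictor matrix and criterion array.
#' @param alpha weighting parameter.
#' @return updated state list (same elements).
#' @export
als_cycle <- function(state, X, Y, alpha) {
  Y_A <- unfold(Y, "A"); Y_B <- unfold(Y, "B"); Y_C <- unfold(Y, "C")
  beta <- beta_from_alpha(alpha, X, Y_A)

  # (1) weight step
  QS <- build_qs(state$B, state$C, state$G, state$P_X, beta, X, Y_A)
  W <- pinv(crossprod(X)) %*% crossprod(X, QS$Q) %*% QS$S %*%
    pinv(crossprod(QS$S))
  A <- X %*% W

  # (2) attribute components
  FB <- kronecker(state$C, A) %*% t(unfold(state$G, "B"))
  B <- procrustes_orth(Y_B %*% FB)

  # (3) source components
  FC <- kronecker(B, A) %*% t(unfold(state$G, "C"))
  C <- procrustes_orth(Y_C %*% FC)

  # (4) core + loadings regression
  reg <- regress_core(A, B, C, X, Y_A)
  list(A = A, B = B, C = C, G = reg$G, P_X = reg$P_X, W_X = W,
       singular = reg$singular)
}

# run ALS from one initialization until convergence
als_run <- function(init0, X, Y, alpha, tol, max_iter, delta_tol = 0) {
  Y_A <- unfold(Y, "A")
  # put A into X's column space (A = X W_X is part of the model), then
  # regress core/loadings so the recorded loss sequence starts at a
  # state all later cycles can only improve
  W <- pinv(X) %*% init0$A
  A <- X %*% W
  reg <- regress_core(A, init0$B, init0$C, X, Y_A)
  state <- list(A = A, B = init0$B, C = init0$C, G = reg$G,
                P_X = reg$P_X, W_X = W)
  loss <- t3pcovr_loss(state$A, state$B, state$C, state$G, state$P_X,
                       alpha, X, Y_A)
  yhat <- predict_y(state$A, state$G, state$B, state$C)
  history <- loss
  converged <- FALSE
  singular <- isTRUE(reg$singular)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    state <- als_cycle(state, X, Y, alpha)
    singular <- singular || isTRUE(state$singular)
    new_loss <- t3pcovr_loss(state$A, state$B, state$C, state$G,
                             state$P_X, alpha, X, Y_A)
    history <- c(history, new_loss)
    loss_done <- loss - new_loss < tol * max(loss, .Machine$double.eps)
    # near a flat optimum the loss decrease can underflow while the
    # parameters are still contracting; an optional secondary rule on
    # the movement of the fitted values guards high-accuracy runs
    if (delta_tol > 0) {
      new_yhat <- predict_y(state$A, state$G, state$B, state$C)
      fit_done <- max(abs(new_yhat - yhat)) < delta_tol
      yhat <- new_yhat
    } else fit_done <- TRUE
    loss <- new_loss
    if (loss_done && fit_done) {
      converged <- TRUE
      break
    }
  }
  list(state = state, loss = loss, history = history,
       converged = converged, n_iter = iter, singular = singular)
}

#' Fit the Tucker3-PCovR model
#'
#' Estimates object scores \code{A = X W_X}, predictor loadings
#' \code{P_X}, orthonormal attribute and source components \code{B},
#' \code{C} and the core array \code{G} minimizing the weighted
#' normalized loss (see \code{\link{t3pcovr_loss}}) by alternating
#' least squares with a multi-start strategy: the first start is the
#' deterministic rational initialization, the remaining
#' \code{n_starts - 1} are perturbed (default) or fully random starts,
#' and the solution with the lowest loss is kept.
#'
#' The data should normally be preprocessed first (see
#' \code{\link{preprocess}}); the loss norms are computed on the
#' matrices actually entering the fit.
#'
#' @param data a \code{\link{coupled_data}} object (preprocessed or
#'   not; no transformation is applied here).
#' @param ranks Tucker3 complexity \code{c(R1, R2, R3)}.
#' @param alpha weighting parameter in \code{[0, 1]}; 0.5 balances
#'   summarizing \code{X} and predicting \code{Y}.
#' @param n_starts number of ALS starts (default 20: one rational plus
#'   19 perturbed).
#' @param init type of the non-rational starts: \code{"perturbed"}
#'   (rational plus noise, default) or \code{"random"}.
#' @param perturb_scale noise s.d. for perturbed starts.
#' @param tol relative loss-decrease convergence threshold.
#' @param max_iter maximum ALS cycles per start.
#' @param delta_tol optional secondary convergence rule: when positive,
#'   a start is declared converged only once the maximum absolute
#'   change of the fitted criterion values over a cycle is also below
#'   this value. Useful for high-accuracy runs where the loss decrease
#'   underflows before the parameters settle; 0 (default) disables it.
#' @param seed optional integer; one master seed spawns independent
#'   per-start streams, making the multi-start reproducible.
#' @return an object of class \code{"t3pcovr"}: list with the component
#'   matrices \code{A}, \code{B}, \code{C}, core array \code{G},
#'   loadings \code{P_X}, weights \code{W_X}, derived response markers
#'   \code{P_Y} (\code{JK x R1}), \code{alpha}, \code{beta},
#'   \code{ranks}, \code{loss}, \code{loss_history} (winning start),
#'   \code{converged}, \code{n_iter}, per-start summary \code{starts},
#'   the analyzed blocks \code{X} and \code{Y}, \code{labels} and any
#'   \code{preprocess} info carried over from \code{data}.
#' @export
#' @examples
#' sim <- simulate_t3pcovr(seed = 1)
#' fit <- t3pcovr(preprocess(sim$data), ranks = c(2, 2, 2),
#'                n_starts = 3, seed = 1)
#' fit$loss
t3pcovr <- function(data, ranks, alpha = 0.5, n_starts = 20,
                    init = c("perturbed", "random"), perturb_scale = 0.1,
                    tol = 1e-8, max_iter = 500, seed = NULL,
                    delta_tol = 0) {
  stopifnot(inherits(data, "coupled_data"))
  init <- match.arg(init)
  ranks <- as.integer(ranks)
  d <- c(dim(data$Y), ncol(data$X))
  if (!ranks_valid(ranks, d))
    stop(sprintf("complexity (%s) is not admissible for dimensions I=%d, J=%d, K=%d, L=%d",
                 paste(ranks, collapse = ","), d[1L], d[2L], d[3L], d[4L]))
  stopifnot(alpha >= 0, alpha <= 1, tol > 0, n_starts >= 1)
  X <- data$X
  Y <- data$Y
  Y_A <- unfold(Y, "A")

  if (!is.null(seed)) set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)

  rat <- init_rational(X, Y, ranks)
  best <- NULL
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      init0 <- rat
      itype <- "rational"
    } else {
      set.seed(start_seeds[s])
      if (init == "perturbed") {
        init0 <- init_perturbed(rat, perturb_scale)
        itype <- "perturbed"
      } else {
        init0 <- init_random(dim(Y), ranks)
        itype <- "random"
      }
    }
    run <- als_run(init0, X, Y, alpha, tol, max_iter, delta_tol)
    starts[[s]] <- list(start = s, init = itype, loss = run$loss,
                        n_iter = run$n_iter, converged = run$converged,
                        singular = run$singular)
    if (is.null(best) || run$loss < best$loss) best <- run
  }
  if (any(vapply(starts, function(s) isTRUE(s$singular), logical(1))))
    warning("rank-deficient A'A encountered (R1 exceeds the rank of X); ",
            "Moore-Penrose pseudoinverse used in the regression step")

  fit <- finalize_fit(best, X, Y, alpha, ranks, data)
  fit$starts <- do.call(rbind, lapply(starts, as.data.frame))
  fit$seed <- seed
  fit
}

# apply the sign convention, derive P_Y and residual norms, assemble
# the fit object
finalize_fit <- function(run, X, Y, alpha, ranks, data) {
  st <- run$state
  Y_A <- unfold(Y, "A")
  # columns of B and C: largest-absolute entry positive, core
  # counter-flipped; same for A (through P_X, W_X and the core)
  sb <- column_signs(st$B); sc <- column_signs(st$C)
  st$B <- sweep(st$B, 2L, sb, "*")
  st$C <- sweep(st$C, 2L, sc, "*")
  st$G <- ttm(ttm(st$G, diag(sb, length(sb)), 2L), diag(sc, length(sc)), 3L)
  sa <- column_signs(st$A)
  st$A <- sweep(st$A, 2L, sa, "*")
  st$W_X <- sweep(st$W_X, 2L, sa, "*")
  st$P_X <- sweep(st$P_X, 2L, sa, "*")
  st$G <- ttm(st$G, diag(sa, length(sa)), 1L)

  P_Y <- kronecker(st$C, st$B) %*% t(unfold(st$G, "A"))
  labels <- data$labels
  comp <- function(r) paste0("Comp", seq_len(r))
  dimnames(st$A) <- list(labels$objects, comp(ranks[1L]))
  dimnames(st$B) <- list(labels$attributes, comp(ranks[2L]))
  dimnames(st$C) <- list(labels$sources, comp(ranks[3L]))
  dimnames(st$P_X) <- list(labels$covariates, comp(ranks[1L]))
  dimnames(st$W_X) <- list(labels$covariates, comp(ranks[1L]))
  jk <- as.vector(outer(labels$attributes, labels$sources,
                        function(a, s) paste(s, a, sep = ":")))
  dimnames(P_Y) <- list(jk, comp(ranks[1L]))

  Xhat <- st$A %*% t(st$P_X)
  Yhat <- predict_y(st$A, st$G, st$B, st$C)
  structure(list(
    A = st$A, B = st$B, C = st$C, G = st$G, P_X = st$P_X, W_X = st$W_X,
    P_Y = P_Y, alpha = alpha, beta = beta_from_alpha(alpha, X, Y_A),
    ranks = ranks, loss = run$loss, loss_history = run$history,
    converged = run$converged, n_iter = run$n_iter,
    rss_x = fnorm2(X - Xhat), rss_y = fnorm2(Y_A - Yhat),
    X = X, Y = Y, labels = labels, preprocess = data$preprocess),
    class = "t3pcovr")
}

#' @export
print.t3pcovr <- function(x, ...) {
  cat("Tucker3-PCovR fit\n")
  cat(sprintf("  complexity (R1,R2,R3): (%s)   alpha = %.3g  beta = %.3g\n",
              paste(x$ranks, collapse = ","), x$alpha, x$beta))
  cat(sprintf("  loss = %.6g  (%s after %d iterations)\n", x$loss,
              if (x$converged) "converged" else "max iterations reached",
              x$n_iter))
  cat(sprintf("  X: %.1f%% of sum of squares explained\n",
              100 * (1 - x$rss_x / fnorm2(x$X))))
  cat(sprintf("  Y: %.1f%% of sum of squares explained\n",
              100 * (1 - x$rss_y / fnorm2(unfold(x$Y, "A")))))
  invisible(x)
}

#' Fitted values for a Tucker3-PCovR model
#'
#' @param object a \code{\link{t3pcovr}} fit.
#' @param block \code{"Y"} (criterion, returned as an
#'   \code{I x J x K} array) or \code{"X"} (predictors).
#' @param ... unused.
#' @return fitted array or matrix on the preprocessed scale.
#' @export
fitted.t3pcovr <- function(object, block = c("Y", "X"), ...) {
  block <- match.arg(block)
  if (block == "X") return(object$A %*% t(object$P_X))
  fold(predict_y(object$A, object$G, object$B, object$C), "A", dim(object$Y))
}

#' Congruence between two component subspaces
#'
#' Cosines of the principal angles between the column spaces of two
#' matrices (singular values of the cross-product of their orthonormal
#' bases), summarized by their mean. A value of 1 means identical
#' subspaces; used to score recovery of the generating components in
#' simulation.
#'
#' @param U,V matrices with the same number of rows.
#' @return mean cosine in \code{[0, 1]}.
#' @export
subspace_congruence <- function(U, V) {
  qu <- orth(as.matrix(U)); qv <- orth(as.matrix(V))
  mean(svd(crossprod(qu, qv), nu = 0, nv = 0)$d)
}
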