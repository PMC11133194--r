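#' Coupled two-way / three-way dataset
#'
#' Bundles a predictor matrix \code{X} (objects x covariates) and a
#' criterion array \code{Y} (objects x attributes x sources) that share
#' their first (object) mode. This pair is the unit of analysis for
#' \code{\link{t3pcovr}}.
#'
#' @param X numeric matrix, \code{I x L}, objects in rows.
#' @param Y numeric 3-way array, \code{I x J x K}, objects in the first
#'   mode.
#' @param object_names,covariate_names,attribute_names,source_names
#'   optional character labels for the four index sets; defaults are
#'   taken from the dimnames of \code{X} and \code{Y} or generated.
#'
#' @return An object of class \code{"coupled_data"}: a list with
#'   elements \code{X}, \code{Y}, \code{labels} (a list of the four
#'   label vectors) and, after \code{\link{preprocess}}, a
#'   \code{preprocess} element describing the applied transforms.
#' @export
#' @examples
#' X <- matrix(rnorm(8 * 10), 8, 10)
#' Y <- array(rnorm(8 * 7 * 6), c(8, 7, 6))
#' cd <- coupled_data(X, Y)
#' dim(cd$X); dim(cd$Y)
coupled_data <- function(X, Y,
                         object_names = NULL, covariate_names = NULL,
                         attribute_names = NULL, source_names = NULL) {
  X <- as.matrix(X)
  if (!is.array(Y) || length(dim(Y)) != 3L)
    stop("'Y' must be a three-way array (objects x attributes x sources)")
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("'X' contains missing or non-finite values")
  if (anyNA(Y) || any(!is.finite(Y)))
    stop("'Y' contains missing or non-finite values")
  if (nrow(X) != dim(Y)[1L])
    stop(sprintf("object mode mismatch: nrow(X) = %d but dim(Y)[1] = %d",
                 nrow(X), dim(Y)[1L]))
  if (nrow(X) < 2L) stop("at least two objects are required")
  if (ncol(X) < 1L || any(dim(Y) < 1L)) stop("all dimensions must be >= 1")

  dn <- function(given, have, n, prefix) {
    if (!is.null(given)) {
      stopifnot(length(given) == n)
      as.character(given)
    } else if (!is.null(have)) as.character(have)
    else paste0(prefix, seq_len(n))
  }
  labels <- list(
    objects    = dn(object_names, rownames(X), nrow(X), "obj"),
    covariates = dn(covariate_names, colnames(X), ncol(X), "x"),
    attributes = dn(attribute_names, dimnames(Y)[[2L]], dim(Y)[2L], "attr"),
    sources    = dn(source_names, dimnames(Y)[[3L]], dim(Y)[3L], "src"))
  dimnames(X) <- list(labels$objects, labels$covariates)
  dimnames(Y) <- list(labels$objects, labels$attributes, labels$sources)
  structure(list(X = X, Y = Y, labels = labels, preprocess = NULL),
            class = "coupled_data")
}

#' @export
print.coupled_data <- function(x, ...) {
  d <- dim(x$Y)
  cat("Coupled dataset\n")
  cat(sprintf("  X: %d objects x %d covariates\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  Y: %d objects x %d attributes x %d sources\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  preprocessed: %s\n", !is.null(x$preprocess)))
  invisible(x)
}

#' Matricize (unfold) a three-way array
#'
#' Rearranges an \code{I x J x K} array into a matrix along one mode,
#' using the column ordering in which the first non-unfolded mode runs
#' fastest. For mode \code{"A"} the result is \code{I x JK} with column
#' \code{(k - 1) * J + j}; this matches the row ordering of the
#' Kronecker product \code{C \%x\% B}, so the Tucker3 fitted values can
#' be written \code{A \%*\% G_A \%*\% t(C \%x\% B)}. Modes \code{"B"}
#' and \code{"C"} give \code{J x IK} (column \code{(k - 1) * I + i})
#' and \code{K x IJ} (column \code{(j - 1) * I + i}).
#'
#' @param Y a three-way numeric array.
#' @param mode one of \code{"A"}, \code{"B"}, \code{"C"} (first, second,
#'   third mode).
#' @return a numeric matrix.
#' @seealso \code{\link{fold}}, the exact inverse.
#' @export
#' @examples
#' Y <- array(seq_len(24), c(2, 3, 4))
#' unfold(Y, "A")[1, 4] == Y[1, 1, 2]
unfold <- function(Y, mode = c("A", "B", "C")) {
  mode <- match.arg(mode)
  if (!is.array(Y) || length(dim(Y)) != 3L)
    stop("'Y' must be a three-way array")
  d <- dim(Y)
  switch(mode,
    A = matrix(Y, d[1L], d[2L] * d[3L]),
    B = matrix(aperm(Y, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L]),
    C = matrix(aperm(Y, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L]))
}

#' Fold a matricized array back into three-way form
#'
#' Exact inverse of \code{\link{unfold}} for the same mode and target
#' dimensions.
#'
#' @param M matrix produced by \code{\link{unfold}}.
#' @param mode the mode that was unfolded.
#' @param dims integer vector \code{c(I, J, K)} of the original array.
#' @return a three-way array with \code{dim = dims}.
#' @export
fold <- function(M, mode = c("A", "B", "C"), dims) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L)
  switch(mode,
    A = array(M, dims),
    B = aperm(array(M, dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L)),
    C = aperm(array(M, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
}

# mode-n product of a 3-way array with a matrix:
# (ttm(G, M, 1))[p',q,r] = sum_p M[p, p'] ... transposed convention is
# handled by the caller; here result[s,q,r] = sum_p M[s,p] G[p,q,r] etc.
ttm <- function(G, M, mode) {
  d <- dim(G)
  out_d <- d
  out_d[mode] <- nrow(M)
  fold(M %*% unfold(G, c("A", "B", "C")[mode]),
       c("A", "B", "C")[mode], out_d)
}

#' Validate a Tucker3 complexity for given data dimensions
#'
#' A complexity \code{(R1, R2, R3)} is admissible when each rank fits
#' its mode (\code{R1 <= min(I, L + J * K)}, \code{R2 <= J},
#' \code{R3 <= K}) and the Tucker product constraints hold
#' (\code{R1 <= R2 * R3}, \code{R2 <= R1 * R3}, \code{R3 <= R1 * R2}),
#' without which some components cannot carry independent information.
#'
#' @param ranks integer vector \code{c(R1, R2, R3)}.
#' @param dims integer vector \code{c(I, J, K, L)}.
#' @return \code{TRUE} or \code{FALSE} (invisibly a reason attribute on
#'   failure).
#' @export
ranks_valid <- function(ranks, dims) {
  r <- as.integer(ranks); d <- as.integer(dims)
  stopifnot(length(r) == 3L, length(d) == 4L)
  if (any(r < 1L)) return(FALSE)
  if (r[1L] > min(d[1L], d[4L] + d[2L] * d[3L])) return(FALSE)
  if (r[2L] > d[2L] || r[3L] > d[3L]) return(FALSE)
  r[1L] <= r[2L] * r[3L] && r[2L] <= r[1L] * r[3L] && r[3L] <= r[1L] * r[2L]
}

# Moore-Penrose via MASS; kept behind one name so the tolerance is
# uniform package-wide.
pinv <- function(M) MASS::ginv(M)

fnorm2 <- function(M) sum(M * M)
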