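new_biplot <- function(kind, row_markers, col_markers, extra = NULL,
                       details = list()) {
  structure(c(list(kind = kind, row_markers = row_markers,
                   col_markers = col_markers, extra_markers = extra),
              details),
            class = "t3pcovr_biplot")
}

trunc2 <- function(M) M[, seq_len(min(2L, ncol(M))), drop = FALSE]

#' Joint biplot for one reference-mode component
#'
#' Displays two modes jointly, conditional on one component \code{r} of
#' the third (reference) mode. The corresponding core slice \code{G_r}
#' is decomposed by SVD, \code{G_r = U D V'}, and the display
#' coordinates are \code{A*_r = (n1/n2)^(1/4) A U D^(1/2)} and
#' \code{B*_r = (n2/n1)^(1/4) B V D^(1/2)} (for the default display
#' modes A and B with \code{n1 = I}, \code{n2 = J} levels; the
#' fourth-root factors equalize the spread of the two marker sets).
#' The marker inner products reproduce \code{A G_r B'} exactly in full
#' dimension; plots use the first two columns (largest singular
#' values).
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @param reference mode held at a single component: \code{"C"}
#'   (default; display objects x attributes), \code{"B"} (objects x
#'   sources) or \code{"A"} (attributes x sources).
#' @param r component index within the reference mode.
#' @return a \code{"t3pcovr_biplot"} object with \code{row_markers},
#'   \code{col_markers} (full-dimensional; use columns 1:2 for
#'   plotting), the core slice and its SVD.
#' @export
joint_biplot <- function(fit, reference = c("C", "B", "A"), r = 1L) {
  stopifnot(inherits(fit, "t3pcovr"))
  reference <- match.arg(reference)
  rmax <- switch(reference, A = fit$ranks[1L], B = fit$ranks[2L],
                 C = fit$ranks[3L])
  if (r < 1L || r > rmax)
    stop(sprintf("component index r = %d out of range 1..%d for mode %s",
                 r, rmax, reference))
  rk <- fit$ranks
  slice <- switch(reference,                # explicit shapes survive rank-1
    C = matrix(fit$G[, , r], rk[1L], rk[2L]),  # objects x attributes
    B = matrix(fit$G[, r, ], rk[1L], rk[3L]),  # objects x sources
    A = matrix(fit$G[r, , ], rk[2L], rk[3L]))  # attributes x sources
  left <- switch(reference, C = fit$A, B = fit$A, A = fit$B)
  right <- switch(reference, C = fit$B, B = fit$C, A = fit$C)
  sv <- svd(slice)
  n1 <- nrow(left); n2 <- nrow(right)
  Ds <- diag(sqrt(sv$d), length(sv$d))
  Astar <- (n1 / n2)^(1 / 4) * left %*% sv$u %*% Ds
  Bstar <- (n2 / n1)^(1 / 4) * right %*% sv$v %*% Ds
  rownames(Astar) <- rownames(left)
  rownames(Bstar) <- rownames(right)
  new_biplot("joint", Astar, Bstar,
             details = list(reference = reference, r = r, slice = slice,
                            svd = sv))
}

#' Interactive biplot: objects against attribute-by-source combinations
#'
#' Row markers are the object scores \code{A}; column markers are the
#' rows of \code{P_Y = ((C \%x\% B) G_A')}, one marker per
#' (attribute, source) cell, labeled in the \code{"SkRPj"} style
#' (source k, attribute/response j). Full-dimensional inner products
#' reproduce the fitted criterion values exactly; a 2-D plot shows
#' their rank-2 part.
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @param attribute,source optional single attribute (index or label)
#'   or source to restrict the column markers to, which keeps the
#'   display readable for large \code{J * K}.
#' @return a \code{"t3pcovr_biplot"} object.
#' @export
interactive_biplot <- function(fit, attribute = NULL, source = NULL) {
  stopifnot(inherits(fit, "t3pcovr"))
  J <- length(fit$labels$attributes); K <- length(fit$labels$sources)
  Bstar <- fit$P_Y
  ids <- as.vector(outer(seq_len(J), seq_len(K),
                         function(j, k) sprintf("S%dRP%d", k, j)))
  att <- rep(seq_len(J), times = K)
  src <- rep(seq_len(K), each = J)
  keep <- rep(TRUE, J * K)
  if (!is.null(attribute)) {
    j <- if (is.character(attribute)) match(attribute, fit$labels$attributes)
         else as.integer(attribute)
    if (is.na(j) || j < 1L || j > J) stop("unknown attribute: ", attribute)
    keep <- keep & att == j
  }
  if (!is.null(source)) {
    k <- if (is.character(source)) match(source, fit$labels$sources)
         else as.integer(source)
    if (is.na(k) || k < 1L || k > K) stop("unknown source: ", source)
    keep <- keep & src == k
  }
  cm <- Bstar[keep, , drop = FALSE]
  new_biplot("interactive", fit$A, cm,
             details = list(ids = ids[keep], attribute = att[keep],
                            source = src[keep]))
}

#' Triplot: objects, predictors and responses in one display
#'
#' Combines the interactive biplot (objects \code{A} against response
#' markers \code{P_Y}) with predictor markers from the rows of
#' \code{P_X}, whose inner products with \code{A} reproduce the fitted
#' predictor block. Angles between predictor and response markers
#' reflect the correlation structure linking the two sets.
#'
#' @inheritParams interactive_biplot
#' @return a \code{"t3pcovr_biplot"} object; predictors are in
#'   \code{extra_markers}.
#' @export
triplot <- function(fit, attribute = NULL, source = NULL) {
  bp <- interactive_biplot(fit, attribute = attribute, source = source)
  bp$kind <- "triplot"
  bp$extra_markers <- fit$P_X
  bp
}

#' Regression-weight biplot
#'
#' Shows the regression weights \code{Z = W_X P_Y'} of every original
#' predictor on every (attribute, source) response cell: predictor
#' markers are the rows of \code{W_X}, response markers the rows of
#' \code{P_Y}, and the inner product of a predictor marker with a
#' response marker is the weight of that predictor for that response.
#' Since \code{Y_A} is fitted by \code{X W_X P_Y'}, projecting the
#' predictor markers onto a response direction ranks the predictors by
#' the size and sign of their effect.
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @return a \code{"t3pcovr_biplot"} object with \code{Z} included.
#' @export
regression_weight_biplot <- function(fit) {
  stopifnot(inherits(fit, "t3pcovr"))
  Z <- fit$W_X %*% t(fit$P_Y)
  new_biplot("regression_weight", fit$W_X, fit$P_Y,
             details = list(Z = Z))
}

#' Interpolate a new observation into the display
#'
#' Places a new predictor profile on the biplot as the weighted sum of
#' the interpolation vectors (the rows of \code{W_X}):
#' \code{a = x' W_X}, where \code{x} is the new profile on the
#' preprocessed scale. Raw-unit input is transformed with the
#' preprocessing stored in the fit. Response predictions follow as
#' \code{a P_Y'}. For a training object this returns its row of
#' \code{A} exactly, because \code{A = X W_X}.
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @param x_new numeric vector of length \code{L} (raw units when the
#'   fit carries preprocessing info, otherwise already preprocessed).
#' @param raw logical; is \code{x_new} on the raw scale? Defaults to
#'   \code{TRUE} when preprocessing info is available.
#' @return list with \code{scores} (length \code{R1}) and
#'   \code{predictions} (length \code{JK}, named).
#' @export
interpolate_obs <- function(fit, x_new, raw = !is.null(fit$preprocess)) {
  stopifnot(inherits(fit, "t3pcovr"))
  x_new <- as.numeric(x_new)
  if (length(x_new) != nrow(fit$W_X))
    stop(sprintf("expected %d predictor values, got %d",
                 nrow(fit$W_X), length(x_new)))
  if (raw) {
    if (is.null(fit$preprocess))
      stop("fit carries no preprocessing info; supply preprocessed values")
    x_new <- drop(apply_preprocess_x(fit$preprocess$x, x_new))
  }
  a <- drop(x_new %*% fit$W_X)
  list(scores = a, predictions = drop(a %*% t(fit$P_Y)))
}

#' Graded scale markers along a biplot direction
#'
#' Tick positions for a predictor direction \code{w}: the value
#' \code{mu} (on the preprocessed scale) sits at \code{(mu * w1,
#' mu * w2)}. Labels show the original units, \code{mean + sd * mu},
#' so the plot can be read in the variable's own scale; \code{mu = 0}
#' is the origin and predicts the variable's mean.
#'
#' @param direction 2-vector (typically the first two entries of a row
#'   of \code{W_X} or \code{P_X}).
#' @param values tick values on the preprocessed (standardized) scale.
#' @param info optional \code{preprocess$x} info for back-transformed
#'   labels.
#' @param variable column index or name of the variable within
#'   \code{info}.
#' @return data frame with \code{x}, \code{y}, \code{mu} and
#'   \code{label}.
#' @export
axis_scale_markers <- function(direction, values, info = NULL,
                               variable = NULL) {
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 2L)
  if (all(direction == 0)) stop("direction vector must be nonzero")
  mu <- as.numeric(values)
  lab <- mu
  if (!is.null(info)) {
    v <- if (is.character(variable)) match(variable, names(info$mean))
         else as.integer(variable)
    if (is.na(v)) stop("unknown variable: ", variable)
    lab <- info$mean[v] + info$scale[v] * mu
  }
  data.frame(x = mu * direction[1L], y = mu * direction[2L],
             mu = mu, label = format(lab, digits = 4))
}

#' @export
print.t3pcovr_biplot <- function(x, ...) {
  cat(sprintf("%s biplot: %d row markers, %d column markers%s\n",
              x$kind, nrow(x$row_markers), nrow(x$col_markers),
              if (!is.null(x$extra_markers))
                sprintf(", %d predictor markers", nrow(x$extra_markers))
              else ""))
  invisible(x)
}

#' Plot a biplot coordinate object
#'
#' Minimal base-graphics rendering of the first two marker columns:
#' rows as points, columns (and predictors, if present) as arrows from
#' the origin.
#'
#' @param x a \code{"t3pcovr_biplot"} object.
#' @param labels draw marker labels.
#' @param ... passed to \code{plot}.
#' @export
plot.t3pcovr_biplot <- function(x, labels = TRUE, ...) {
  rm2 <- trunc2(x$row_markers); cm2 <- trunc2(x$col_markers)
  em2 <- if (!is.null(x$extra_markers)) trunc2(x$extra_markers)
  if (ncol(rm2) < 2L) { rm2 <- cbind(rm2, 0); cm2 <- cbind(cm2, 0)
                        if (!is.null(em2)) em2 <- cbind(em2, 0) }
  all_xy <- rbind(rm2, cm2, em2)
  graphics::plot(all_xy, type = "n", xlab = "Dim 1", ylab = "Dim 2", ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::points(rm2, pch = 19, col = "grey25")
  graphics::arrows(0, 0, cm2[, 1L], cm2[, 2L], length = 0.07,
                   col = "steelblue")
  if (!is.null(em2))
    graphics::arrows(0, 0, em2[, 1L], em2[, 2L], length = 0.07,
                     col = "firebrick")
  if (labels) {
    graphics::text(rm2, labels = rownames(rm2), pos = 3, cex = 0.7)
    cl <- if (!is.null(x$ids)) x$ids else rownames(cm2)
    graphics::text(cm2, labels = cl, pos = 3, cex = 0.7, col = "steelblue")
    if (!is.null(em2))
      graphics::text(em2, labels = rownames(em2), pos = 3, cex = 0.7,
                     col = "firebrick")
  }
  invisible(x)
}
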