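#' Center and standardize the predictor matrix
#'
#' Each covariate (column) of \code{X} gets mean 0 and standard
#' deviation 1 (denominator \code{n - 1}). Columns with zero variance
#' cannot be standardized and raise an error naming the column.
#'
#' @param X numeric matrix, objects in rows.
#' @param center,scale logical; apply centering / scaling.
#' @return list with \code{X} (the transformed matrix) and \code{info}
#'   (list with \code{mean} and \code{scale} vectors plus the flags),
#'   sufficient to transform new observations identically or to invert
#'   the transform.
#' @export
standardize_x <- function(X, center = TRUE, scale = TRUE) {
  X <- as.matrix(X)
  m <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, m, "-")
  if (scale) {
    s <- apply(Xc, 2L, stats::sd)
    bad <- which(s <= .Machine$double.eps * 1e2)
    if (length(bad)) {
      nm <- colnames(X)[bad]
      if (is.null(nm)) nm <- as.character(bad)
      stop("zero-variance covariate column(s): ", paste(nm, collapse = ", "))
    }
  } else s <- rep(1, ncol(X))
  Xs <- sweep(Xc, 2L, s, "/")
  dimnames(Xs) <- dimnames(X)
  list(X = Xs,
       info = list(mean = m, scale = s, center = center, scaled = scale))
}

#' Center and normalize the criterion array
#'
#' Centers every (attribute, source) column across objects, then scales
#' each attribute so that its pooled variance over all objects and
#' sources is 1 (denominator \code{I * K - 1}); one scale per attribute,
#' shared across sources, mirroring the usual treatment of
#' situation-response data where each response scale is normalized as a
#' whole. Set \code{scale_mode = "attribute-source"} for full
#' autoscaling of every (attribute, source) column, or \code{"none"} to
#' center only.
#'
#' @param Y numeric three-way array (objects x attributes x sources).
#' @param center logical; center across objects.
#' @param scale_mode \code{"attribute"} (default), \code{"attribute-source"}
#'   or \code{"none"}.
#' @return list with \code{Y} and \code{info} (per-(attribute, source)
#'   means, per-attribute or per-column scales, flags).
#' @export
preprocess_y <- function(Y, center = TRUE,
                         scale_mode = c("attribute", "attribute-source", "none")) {
  scale_mode <- match.arg(scale_mode)
  if (!is.array(Y) || length(dim(Y)) != 3L)
    stop("'Y' must be a three-way array")
  d <- dim(Y)
  if (center && d[1L] < 2L)
    stop("cannot center across a single object (I = 1)")
  m <- if (center) apply(Y, c(2L, 3L), mean) else matrix(0, d[2L], d[3L])
  Yc <- sweep(Y, c(2L, 3L), m, "-")
  s <- switch(scale_mode,
    none = matrix(1, d[2L], d[3L]),
    attribute = {
      v <- apply(Yc, 2L, function(sl) sum(sl^2)) / (d[1L] * d[3L] - 1)
      check_scale(sqrt(v), dimnames(Y)[[2L]], "attribute")
      matrix(sqrt(v), d[2L], d[3L])
    },
    `attribute-source` = {
      v <- apply(Yc, c(2L, 3L), function(col) sum(col^2)) / (d[1L] - 1)
      check_scale(sqrt(v), NULL, "attribute-source column")
      sqrt(v)
    })
  Ys <- sweep(Yc, c(2L, 3L), s, "/")
  dimnames(Ys) <- dimnames(Y)
  list(Y = Ys,
       info = list(mean = m, scale = s, center = center,
                   scale_mode = scale_mode))
}

check_scale <- function(s, names, what) {
  bad <- which(s <= .Machine$double.eps * 1e2)
  if (length(bad)) {
    nm <- if (!is.null(names)) names[bad] else as.character(bad)
    stop("zero post-centering variation for ", what, "(s): ",
         paste(nm, collapse = ", "))
  }
  invisible(s)
}

#' Preprocess a coupled dataset
#'
#' Applies \code{\link{standardize_x}} to the predictor block and
#' \code{\link{preprocess_y}} to the criterion block, recording the
#' transforms on the returned object so that new observations can be
#' mapped to the same scale (needed by \code{\link{interpolate_obs}})
#' and the raw data recovered.
#'
#' @param data a \code{\link{coupled_data}} object.
#' @param center_x,scale_x,center_y options passed through.
#' @param y_scale scaling mode for \code{Y}; see
#'   \code{\link{preprocess_y}}.
#' @return a \code{coupled_data} object with transformed blocks and a
#'   \code{preprocess} element (\code{x} and \code{y} info lists).
#' @export
#' @examples
#' cd <- coupled_data(matrix(rnorm(40), 8), array(rnorm(8 * 3 * 2), c(8, 3, 2)))
#' pd <- preprocess(cd)
#' round(colMeans(pd$X), 12)
preprocess <- function(data, center_x = TRUE, scale_x = TRUE,
                       center_y = TRUE,
                       y_scale = c("attribute", "attribute-source", "none")) {
  stopifnot(inherits(data, "coupled_data"))
  y_scale <- match.arg(y_scale)
  px <- standardize_x(data$X, center = center_x, scale = scale_x)
  py <- preprocess_y(data$Y, center = center_y, scale_mode = y_scale)
  out <- data
  out$X <- px$X
  out$Y <- py$Y
  out$preprocess <- list(x = px$info, y = py$info)
  out
}

#' Apply or invert stored preprocessing transforms
#'
#' \code{apply_preprocess_x} maps raw predictor rows onto the scale of
#' the fitted (preprocessed) data; \code{invert_preprocess} recovers the
#' raw blocks of a preprocessed \code{coupled_data}.
#'
#' @param info the \code{preprocess$x} element of a preprocessed
#'   dataset or fit.
#' @param X raw matrix (or single row) of predictor values.
#' @return transformed matrix / restored \code{coupled_data}.
#' @export
apply_preprocess_x <- function(info, X) {
  X <- if (is.null(dim(X))) matrix(X, 1L) else as.matrix(X)
  if (ncol(X) != length(info$mean))
    stop(sprintf("expected %d covariates, got %d", length(info$mean), ncol(X)))
  sweep(sweep(X, 2L, info$mean, "-"), 2L, info$scale, "/")
}

#' @rdname apply_preprocess_x
#' @param data a preprocessed \code{coupled_data} object.
#' @export
invert_preprocess <- function(data) {
  stopifnot(inherits(data, "coupled_data"), !is.null(data$preprocess))
  ix <- data$preprocess$x; iy <- data$preprocess$y
  out <- data
  out$X <- sweep(sweep(data$X, 2L, ix$scale, "*"), 2L, ix$mean, "+")
  out$Y <- sweep(sweep(data$Y, c(2L, 3L), iy$scale, "*"),
                 c(2L, 3L), iy$mean, "+")
  out$preprocess <- NULL
  out
}
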