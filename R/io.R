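#' Read a coupled dataset from delimited files
#'
#' The predictor file is a CSV matrix with object labels in the first
#' column and covariate names in the header. The criterion file is
#' either long format (columns \code{object, attribute, source, value},
#' header required) or \code{K} stacked \code{I x J} tables (columns
#' \code{source, object} then attributes). Mode levels are ordered by
#' first appearance; objects are matched between blocks by label and
#' must coincide exactly.
#'
#' @param x_path path to the predictor CSV.
#' @param y_path path to the criterion CSV.
#' @param y_format \code{"long"} or \code{"stacked"}.
#' @return a \code{\link{coupled_data}} object.
#' @export
read_coupled <- function(x_path, y_path, y_format = c("long", "stacked")) {
  y_format <- match.arg(y_format)
  xt <- utils::read.csv(x_path, check.names = FALSE)
  X <- as.matrix(xt[, -1L, drop = FALSE])
  rownames(X) <- as.character(xt[[1L]])
  if (anyDuplicated(rownames(X)))
    stop("duplicate object labels in ", x_path)

  if (y_format == "long") {
    yt <- utils::read.csv(y_path, check.names = FALSE)
    need <- c("object", "attribute", "source", "value")
    if (!all(need %in% names(yt)))
      stop("long-format criterion file must have columns: ",
           paste(need, collapse = ", "))
    obj <- unique(as.character(yt$object))
    att <- unique(as.character(yt$attribute))
    src <- unique(as.character(yt$source))
    Y <- array(NA_real_, c(length(obj), length(att), length(src)),
               dimnames = list(obj, att, src))
    idx <- cbind(match(as.character(yt$object), obj),
                 match(as.character(yt$attribute), att),
                 match(as.character(yt$source), src))
    if (anyDuplicated(idx))
      stop("duplicate (object, attribute, source) cell(s) in ", y_path)
    Y[idx] <- yt$value
    if (anyNA(Y)) {
      miss <- which(is.na(Y), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing cell in %s: object %s, attribute %s, source %s",
                   y_path, obj[miss[1L]], att[miss[2L]], src[miss[3L]]))
    }
  } else {
    yt <- utils::read.csv(y_path, check.names = FALSE)
    if (!all(c("source", "object") %in% names(yt)))
      stop("stacked criterion file must have 'source' and 'object' columns")
    src <- unique(as.character(yt$source))
    obj <- unique(as.character(yt$object))
    att <- setdiff(names(yt), c("source", "object"))
    Y <- array(NA_real_, c(length(obj), length(att), length(src)),
               dimnames = list(obj, att, src))
    for (k in seq_along(src)) {
      blk <- yt[yt$source == src[k], , drop = FALSE]
      if (anyDuplicated(blk$object))
        stop("duplicate object rows for source ", src[k], " in ", y_path)
      Y[match(as.character(blk$object), obj), , k] <-
        as.matrix(blk[, att, drop = FALSE])
    }
    if (anyNA(Y)) stop("incomplete stacked criterion table in ", y_path)
  }

  if (!setequal(rownames(X), dimnames(Y)[[1L]]))
    stop("object sets differ between the predictor and criterion files")
  Y <- Y[rownames(X), , , drop = FALSE]
  coupled_data(X, Y)
}

#' Write a coupled dataset to delimited files
#'
#' Counterpart of \code{\link{read_coupled}}: writes \code{X.csv}
#' (matrix with object labels) and \code{Y_long.csv} (long format)
#' into \code{dir}.
#'
#' @param data a \code{\link{coupled_data}} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_coupled <- function(data, dir) {
  stopifnot(inherits(data, "coupled_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xt <- data.frame(object = rownames(data$X), data$X, check.names = FALSE)
  utils::write.csv(xt, file.path(dir, "X.csv"), row.names = FALSE)
  d <- dim(data$Y)
  long <- data.frame(
    object = rep(data$labels$objects, times = d[2L] * d[3L]),
    attribute = rep(rep(data$labels$attributes, each = d[1L]), times = d[3L]),
    source = rep(data$labels$sources, each = d[1L] * d[2L]),
    value = as.vector(data$Y))
  utils::write.csv(long, file.path(dir, "Y_long.csv"), row.names = FALSE)
  invisible(dir)
}

write_matrix <- function(M, path, label) {
  df <- data.frame(rownames(M), M, check.names = FALSE)
  names(df)[1L] <- label
  utils::write.csv(df, path, row.names = FALSE)
}

read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- as.character(df[[1L]])
  M
}

#' Serialize / restore a fitted model
#'
#' \code{write_fit} stores a fit as plain-text files in a directory:
#' \code{A.csv}, \code{B.csv}, \code{C.csv}, \code{PX.csv},
#' \code{WX.csv}, \code{PY.csv} (full precision), the core in long
#' format \code{core.csv} (columns \code{r1, r2, r3, value}, which
#' avoids any matricization-order ambiguity on disk), and
#' \code{meta.json} with the scalars (alpha, beta, ranks, loss, loss
#' history, iterations, convergence, seed, package version).
#' \code{read_fit} reverses this losslessly, except that the analyzed
#' data blocks are reattached only if \code{X.csv} / \code{Y_long.csv}
#' are present in the directory (written when \code{include_data} is
#' \code{TRUE}).
#'
#' @param fit a \code{\link{t3pcovr}} fit.
#' @param dir directory to write to / read from.
#' @param include_data also store the analyzed (preprocessed) blocks so
#'   the fit can be fully reconstructed.
#' @return \code{dir} invisibly; for \code{read_fit} the fit object.
#' @export
write_fit <- function(fit, dir, include_data = TRUE) {
  stopifnot(inherits(fit, "t3pcovr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 17); on.exit(options(old))
  write_matrix(fit$A, file.path(dir, "A.csv"), "object")
  write_matrix(fit$B, file.path(dir, "B.csv"), "attribute")
  write_matrix(fit$C, file.path(dir, "C.csv"), "source")
  write_matrix(fit$P_X, file.path(dir, "PX.csv"), "covariate")
  write_matrix(fit$W_X, file.path(dir, "WX.csv"), "covariate")
  write_matrix(fit$P_Y, file.path(dir, "PY.csv"), "cell")
  rk <- dim(fit$G)
  core <- data.frame(r1 = rep(seq_len(rk[1L]), times = rk[2L] * rk[3L]),
                     r2 = rep(rep(seq_len(rk[2L]), each = rk[1L]), rk[3L]),
                     r3 = rep(seq_len(rk[3L]), each = rk[1L] * rk[2L]),
                     value = as.vector(fit$G))
  utils::write.csv(core, file.path(dir, "core.csv"), row.names = FALSE)
  meta <- list(alpha = fit$alpha, beta = fit$beta, ranks = fit$ranks,
               loss = fit$loss, loss_history = fit$loss_history,
               converged = fit$converged, n_iter = fit$n_iter,
               seed = fit$seed,
               rss_x = fit$rss_x, rss_y = fit$rss_y,
               labels = fit$labels,
               preprocess = fit$preprocess,
               version = as.character(utils::packageVersion("t3pcovr")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  if (include_data)
    write_coupled(structure(list(X = fit$X, Y = fit$Y, labels = fit$labels),
                            class = "coupled_data"), dir)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  need <- c("A.csv", "B.csv", "C.csv", "PX.csv", "WX.csv", "PY.csv",
            "core.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("fit directory ", dir, " is incomplete; missing: ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  core <- utils::read.csv(file.path(dir, "core.csv"))
  rk <- as.integer(meta$ranks)
  G <- array(0, rk)
  G[cbind(core$r1, core$r2, core$r3)] <- core$value
  fit <- list(A = read_matrix(file.path(dir, "A.csv")),
              B = read_matrix(file.path(dir, "B.csv")),
              C = read_matrix(file.path(dir, "C.csv")),
              G = G,
              P_X = read_matrix(file.path(dir, "PX.csv")),
              W_X = read_matrix(file.path(dir, "WX.csv")),
              P_Y = read_matrix(file.path(dir, "PY.csv")),
              alpha = meta$alpha, beta = meta$beta, ranks = rk,
              loss = meta$loss, loss_history = meta$loss_history,
              converged = meta$converged, n_iter = meta$n_iter,
              seed = meta$seed, rss_x = meta$rss_x, rss_y = meta$rss_y,
              labels = lapply(meta$labels, as.character),
              preprocess = restore_preprocess(meta$preprocess))
  if (file.exists(file.path(dir, "X.csv")) &&
      file.exists(file.path(dir, "Y_long.csv"))) {
    cd <- read_coupled(file.path(dir, "X.csv"), file.path(dir, "Y_long.csv"))
    fit$X <- cd$X
    fit$Y <- cd$Y
  }
  structure(fit, class = "t3pcovr")
}

restore_preprocess <- function(pp) {
  if (is.null(pp)) return(NULL)
  if (!is.null(pp$x)) {
    pp$x$mean <- unlist(pp$x$mean); pp$x$scale <- unlist(pp$x$scale)
  }
  if (!is.null(pp$y)) {
    pp$y$mean <- if (is.list(pp$y$mean)) do.call(rbind, pp$y$mean)
                 else as.matrix(pp$y$mean)
    pp$y$scale <- if (is.list(pp$y$scale)) do.call(rbind, pp$y$scale)
                  else as.matrix(pp$y$scale)
  }
  pp
}
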