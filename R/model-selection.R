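#' Enumerate admissible Tucker3 complexities
#'
#' All triples \code{(R1, R2, R3)} between \code{(1, 1, 1)} and
#' \code{max_ranks} that are admissible for the data dimensions (see
#' \code{\link{ranks_valid}}); e.g. \code{(2, 1, 1)} is excluded
#' because a two-dimensional object mode cannot interact with a single
#' attribute-by-source pattern.
#'
#' @param dims \code{c(I, J, K, L)}.
#' @param max_ranks upper bounds \code{c(R1max, R2max, R3max)}.
#' @return data frame with columns \code{R1}, \code{R2}, \code{R3}.
#' @export
enumerate_ranks <- function(dims, max_ranks) {
  max_ranks <- as.integer(max_ranks)
  grid <- expand.grid(R1 = seq_len(max_ranks[1L]),
                      R2 = seq_len(max_ranks[2L]),
                      R3 = seq_len(max_ranks[3L]))
  keep <- apply(grid, 1L, function(r) ranks_valid(r, dims))
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$R1 + out$R2 + out$R3, out$R1, out$R2, out$R3), , drop = FALSE]
}

#' CHULL selection over a set of fitted complexities
#'
#' Scree-based model selection: each candidate is summarized by its
#' complexity \code{c = R1 + R2 + R3} and its misfit \code{f} (the
#' converged loss). Per complexity only the best (lowest-loss) model is
#' kept; the models on the lower-left boundary of the convex hull of
#' the (complexity, misfit) cloud are retained; and every hull model
#' with both neighbors gets the st-ratio
#' \deqn{st_i = \frac{(f_{i-1} - f_i) / (c_i - c_{i-1})}
#'            {(f_i - f_{i+1}) / (c_{i+1} - c_i)},}
#' the ratio of the loss decrease gained per unit complexity before the
#' model to the decrease after it. The model with the highest st-ratio
#' is selected (hull endpoints are ineligible); ties go to the lower
#' complexity, and ties in fit at equal complexity are broken
#' lexicographically on \code{(R1, R2, R3)}.
#'
#' @param entries data frame with columns \code{R1}, \code{R2},
#'   \code{R3} and \code{loss} (one row per fitted model).
#' @return object of class \code{"t3pcovr_chull"}: the input table with
#'   added columns \code{complexity}, \code{on_hull}, \code{st}, plus
#'   elements \code{selected} (the chosen \code{c(R1, R2, R3)}) and
#'   \code{hull} (the hull sub-table).
#' @export
#' @examples
#' tab <- data.frame(R1 = 1:4, R2 = 1:4, R3 = 1:4,
#'                   loss = c(0.50, 0.30, 0.20, 0.18))
#' chull_select(tab)$selected
chull_select <- function(entries) {
  stopifnot(all(c("R1", "R2", "R3", "loss") %in% names(entries)))
  tab <- as.data.frame(entries)
  tab$complexity <- tab$R1 + tab$R2 + tab$R3
  tab <- tab[order(tab$complexity, tab$loss, tab$R1, tab$R2, tab$R3), ]
  rownames(tab) <- NULL

  # best model per complexity
  best_idx <- !duplicated(tab$complexity)
  cand <- which(best_idx)

  # keep only candidates with strictly decreasing loss as complexity
  # grows (dominated points can never be on the lower-left hull)
  dec <- c()
  for (i in cand) {
    if (!length(dec) || tab$loss[i] < tab$loss[dec[length(dec)]])
      dec <- c(dec, i)
  }

  # lower convex hull by the monotone-chain rule on (complexity, loss)
  hull <- c()
  for (i in dec) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies strictly above segment a--i; collinear points
      # (to machine precision) stay on the hull so a linear scree
      # yields st = 1 everywhere
      lhs <- (tab$loss[b] - tab$loss[a]) * (tab$complexity[i] - tab$complexity[a])
      rhs <- (tab$loss[i] - tab$loss[a]) * (tab$complexity[b] - tab$complexity[a])
      eps <- 1e-12 * max(abs(lhs), abs(rhs), 1)
      if (lhs > rhs + eps) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }

  tab$on_hull <- seq_len(nrow(tab)) %in% hull
  tab$st <- NA_real_
  if (length(hull) >= 3L) {
    for (m in 2L:(length(hull) - 1L)) {
      i0 <- hull[m - 1L]; i1 <- hull[m]; i2 <- hull[m + 1L]
      num <- (tab$loss[i0] - tab$loss[i1]) /
        (tab$complexity[i1] - tab$complexity[i0])
      den <- (tab$loss[i1] - tab$loss[i2]) /
        (tab$complexity[i2] - tab$complexity[i1])
      tab$st[i1] <- num / den
    }
    eligible <- hull[!is.na(tab$st[hull])]
    sel <- eligible[which.max(tab$st[eligible])]
    # which.max already favors the first (= lowest-complexity) maximum
  } else {
    warning("fewer than 3 hull points; selecting the lowest-loss model")
    sel <- tab[order(tab$loss, tab$complexity), ][1L, ]
    sel <- which(tab$R1 == sel$R1 & tab$R2 == sel$R2 & tab$R3 == sel$R3 &
                   tab$loss == sel$loss)[1L]
  }

  structure(list(table = tab,
                 selected = unlist(tab[sel, c("R1", "R2", "R3")]),
                 hull = tab[tab$on_hull, , drop = FALSE]),
            class = "t3pcovr_chull")
}

#' @export
print.t3pcovr_chull <- function(x, ...) {
  cat("CHULL model selection\n")
  print(x$table, digits = 4)
  cat(sprintf("selected complexity: (%s)\n",
              paste(x$selected, collapse = ",")))
  invisible(x)
}

#' Fit a complexity grid and select a model by CHULL
#'
#' Runs \code{\link{t3pcovr}} for every admissible complexity up to
#' \code{max_ranks} and applies \code{\link{chull_select}} to the
#' resulting (complexity, loss) table.
#'
#' @param data a (preprocessed) \code{\link{coupled_data}} object.
#' @param alpha weighting parameter, fixed across the grid.
#' @param max_ranks upper bounds \code{c(R1max, R2max, R3max)}.
#' @param ... further arguments passed to \code{\link{t3pcovr}}
#'   (\code{n_starts}, \code{tol}, \code{seed}, ...).
#' @return a \code{\link{chull_select}} result with an extra
#'   \code{fits} element (the per-complexity fitted models, named
#'   \code{"R1,R2,R3"}).
#' @export
select_ranks <- function(data, alpha = 0.5, max_ranks = c(4, 4, 4), ...) {
  grid <- enumerate_ranks(c(dim(data$Y), ncol(data$X)), max_ranks)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- unlist(grid[i, ])
    fits[[i]] <- t3pcovr(data, ranks = r, alpha = alpha, ...)
  }
  names(fits) <- apply(grid, 1L, paste, collapse = ",")
  grid$loss <- vapply(fits, function(f) f$loss, numeric(1))
  res <- chull_select(grid)
  res$fits <- fits
  res
}

#' Scree / hull plot for a CHULL result
#'
#' @param x a \code{\link{chull_select}} result.
#' @param ... passed to \code{plot}.
#' @export
plot.t3pcovr_chull <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$complexity, tab$loss, xlab = "complexity (R1+R2+R3)",
                 ylab = "loss", pch = 1, ...)
  hull <- x$hull
  graphics::lines(hull$complexity, hull$loss, col = "steelblue")
  graphics::points(hull$complexity, hull$loss, pch = 19, col = "steelblue")
  selc <- sum(x$selected)
  self <- hull$loss[hull$complexity == selc][1L]
  graphics::points(selc, self, pch = 19, col = "firebrick", cex = 1.4)
  invisible(x)
}
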