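# 8-connected local minima of a potential grid (linear indices).
# A cell is a local minimum if no 8-neighbour is strictly lower and at
# least one is strictly higher (flat plateaus at the floor are excluded
# by requiring the cell to be below the grid's ceiling).
local_minima <- function(U) {
  n1 <- nrow(U); n2 <- ncol(U)
  pad <- matrix(Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- U
  lower_exists <- matrix(FALSE, n1, n2)
  equal_all <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)]
    lower_exists <- lower_exists | (nb < U)
    equal_all <- equal_all & (nb == U)
  }
  which(!lower_exists & !equal_all & U < max(U))
}

#' Barrier heights from a potential grid
#'
#' Identifies the two deepest local minima of `U` and the saddle between
#' them as the minimax cell: over all 8-connected grid paths joining the
#' minima, the path minimizing its maximum `U`; that maximum defines
#' `U_saddle`. Computed by a threshold flood fill (binary search over the
#' level at which the two minima become connected). Barriers are
#' `U_saddle - U_min`, the global-stability measure of each basin.
#'
#' @param land a `grn_landscape` with `U` computed, or a bare matrix of
#'   potentials.
#' @param order_by optional list of two points (grid coordinates,
#'   `c(x, y)`) used to order the minima, e.g. the stem and differentiated
#'   attractor projections; minimum 1 is the one nearest `order_by[[1]]`.
#' @return Object of class `grn_barrier`: `U_min1`, `U_min2`, `U_saddle`,
#'   `barrier1`, `barrier2`, `min1`, `min2` (grid coordinates), `minima`
#'   (all local minima found).
#' @export
barrier_heights <- function(land, order_by = NULL) {
  if (inherits(land, "grn_landscape")) {
    if (is.null(land$U)) land <- potential_from_probability(land)
    U <- land$U; gx <- land$x; gy <- land$y
  } else {
    U <- land; gx <- seq_len(nrow(U)); gy <- seq_len(ncol(U))
  }
  mins <- local_minima(U)
  if (length(mins) < 2)
    stop("monostable landscape: fewer than 2 local minima on the grid")
  mins <- mins[order(U[mins])]
  m1 <- mins[1]; m2 <- mins[2]
  if (!is.null(order_by)) {
    loc <- function(idx) c(gx[(idx - 1) %% nrow(U) + 1],
                           gy[(idx - 1) %/% nrow(U) + 1])
    d11 <- max(abs(loc(m1) - order_by[[1]]))
    d21 <- max(abs(loc(m2) - order_by[[1]]))
    if (d21 < d11) { tmp <- m1; m1 <- m2; m2 <- tmp }
  }
  Us <- minimax_level(U, m1, m2)
  loc <- function(idx) c(gx[(idx - 1) %% nrow(U) + 1],
                         gy[(idx - 1) %/% nrow(U) + 1])
  structure(list(U_min1 = U[m1], U_min2 = U[m2], U_saddle = Us,
                 barrier1 = Us - U[m1], barrier2 = Us - U[m2],
                 min1 = loc(m1), min2 = loc(m2), minima = mins),
            class = "grn_barrier")
}

#' @export
print.grn_barrier <- function(x, ...) {
  cat(sprintf("U_min1 = %.4g at (%.3g, %.3g); U_min2 = %.4g at (%.3g, %.3g)\n",
              x$U_min1, x$min1[1], x$min1[2], x$U_min2, x$min2[1], x$min2[2]))
  cat(sprintf("U_saddle = %.4g; barrier1 = %.4g, barrier2 = %.4g\n",
              x$U_saddle, x$barrier1, x$barrier2))
  invisible(x)
}

# Smallest level L such that cells with U <= L connect m1 to m2 under
# 8-connectivity; L is attained at a grid cell (the minimax saddle).
minimax_level <- function(U, m1, m2) {
  lv <- sort(unique(as.numeric(U)))
  lv <- lv[lv >= max(U[m1], U[m2])]
  lo <- 1L; hi <- length(lv)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_at(U, lv[mid], m1, m2)) hi <- mid else lo <- mid + 1L
  }
  lv[lo]
}

connected_at <- function(U, level, m1, m2) {
  n1 <- nrow(U); n2 <- ncol(U)
  open <- U <= level
  seen <- matrix(FALSE, n1, n2)
  queue <- integer(n1 * n2); qh <- 1L; qt <- 1L
  queue[1L] <- m1; seen[m1] <- TRUE
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    if (v == m2) return(TRUE)
    i <- (v - 1L) %% n1 + 1L; j <- (v - 1L) %/% n1 + 1L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      w <- ii + (jj - 1L) * n1
      if (!seen[w] && open[w]) { seen[w] <- TRUE; qt <- qt + 1L; queue[qt] <- w }
    }
  }
  FALSE
}
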