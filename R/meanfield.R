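# Landscape-grid container shared by the mean-field and histogram routes.
new_landscape <- function(x, y, P, axes, method, U = NULL) {
  structure(list(x = x, y = y, P = P, U = U, axes = axes, method = method),
            class = "grn_landscape")
}

#' @export
print.grn_landscape <- function(x, ...) {
  cat(sprintf("%s landscape on %d x %d grid over %s in [%.3g, %.3g] x [%.3g, %.3g]\n",
              x$method, length(x$x), length(x$y),
              paste(x$axes, collapse = " / "),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  if (!is.null(x$U))
    cat(sprintf("U range: %.3g .. %.3g (%d local minima)\n", min(x$U),
                max(x$U), length(local_minima(x$U))))
  invisible(x)
}

#' Plot a potential landscape
#'
#' Filled image of the potential `U = -ln P` with contour overlay; paths
#' can be drawn on top with [lines()].
#'
#' @param x a `grn_landscape` with `U` computed.
#' @param nlevels contour levels.
#' @param ... passed to [graphics::image()].
#' @export
plot.grn_landscape <- function(x, nlevels = 15, ...) {
  if (is.null(x$U)) x <- potential_from_probability(x)
  graphics::image(x$x, x$y, x$U, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = x$axes[1], ylab = x$axes[2], ...)
  graphics::contour(x$x, x$y, x$U, nlevels = nlevels, add = TRUE,
                    col = "white", lwd = 0.5)
  invisible(x)
}

#' Propagate Gaussian moments to stationarity
#'
#' Diagonal moment closure of the stochastic dynamics around one basin:
#' the mean follows the deterministic rate equations,
#' `dxbar/dt = F(xbar)`, and each diagonal variance follows
#' `dsigma_i/dt = 2 A_ii(xbar) sigma_i + 2 D` with `A` the Jacobian at the
#' mean (cross-covariances dropped by the mean-field splitting). At a
#' stable fixed point the stationary variance is `-D / A_ii`, i.e. `D/k`
#' for an isolated linear gene.
#'
#' @param net a [grn].
#' @param p a [hill_params].
#' @param x0 initial mean, inside the target basin.
#' @param D diffusion coefficient (>= 0).
#' @param t_end integration horizon.
#' @param stat_tol stationarity tolerance on `|dsigma/dt|`.
#' @return Object of class `grn_basin`: `mean`, `variance`, `weight` (NA,
#'   fill from [find_attractors()] weights).
#' @export
propagate_moments <- function(net, p, x0, D, t_end = 500, stat_tol = 1e-10) {
  stopifnot(D >= 0)
  N <- nrow(net$nodes)
  rhs <- function(t, y, parms) {
    x <- pmax(y[1:N], 0)
    s <- y[(N + 1):(2 * N)]
    Adiag <- diag(grn_jacobian(net, p, x))
    list(c(grn_force(net, p, x), 2 * Adiag * s + 2 * D))
  }
  out <- deSolve::ode(y = c(as.numeric(x0), rep(0, N)),
                      times = c(0, t_end / 2, t_end), func = rhs,
                      parms = NULL, method = "lsoda")
  y <- out[nrow(out), -1]
  m <- pmax(y[1:N], 0)
  s <- y[(N + 1):(2 * N)]
  Adiag <- diag(grn_jacobian(net, p, m))
  if (any(Adiag >= 0 & D > 0)) {
    bad <- which(Adiag >= 0)
    stop("variance diverges for gene(s) ",
         paste(net$nodes$name[bad], collapse = ", "),
         " (nonnegative local relaxation rate)")
  }
  dsig <- 2 * Adiag * s + 2 * D
  if (max(abs(dsig)) > stat_tol) {
    # close the remaining gap with the local fixed-point solution
    s <- ifelse(Adiag < 0, -D / Adiag, s)
  }
  names(m) <- names(s) <- net$nodes$name
  structure(list(mean = m, variance = s, weight = NA_real_),
            class = "grn_basin")
}

#' @export
print.grn_basin <- function(x, ...) {
  cat(sprintf("Gaussian basin (weight %s)\n",
              ifelse(is.na(x$weight), "unset", format(x$weight))))
  print(utils::head(rbind(mean = x$mean, variance = x$variance), 2))
  invisible(x)
}

#' Weighted Gaussian mixture probability on a 2-D grid
#'
#' Builds the steady-state probability as the basin-weighted sum of
#' diagonal Gaussians, marginalized to two coordinates (with a diagonal
#' covariance, integrating out the other genes just drops their factors),
#' and renormalizes on the grid.
#'
#' @param basins list of `grn_basin` objects with weights set (weights
#'   are renormalized to sum to 1).
#' @param axes character(2) of gene names kept as coordinates.
#' @param net the [grn] (resolves gene names).
#' @param xlim,ylim,bins grid specification; defaults 100 x 100 over
#'   `[0, 2.5]^2`.
#' @return A `grn_landscape` with `P` computed and `U` filled via
#'   [potential_from_probability()].
#' @export
mixture_probability <- function(basins, axes, net, xlim = c(0, 2.5),
                                ylim = c(0, 2.5), bins = 100) {
  stopifnot(length(basins) >= 1, length(axes) == 2)
  ix <- match(axes, net$nodes$name)
  if (any(is.na(ix))) stop("axis gene(s) not in the network: ",
                           paste(axes[is.na(ix)], collapse = ", "))
  w <- vapply(basins, function(b) b$weight, 0)
  if (any(is.na(w))) stop("basin weights must be set")
  w <- w / sum(w)
  gx <- seq(xlim[1], xlim[2], length.out = bins)
  gy <- seq(ylim[1], ylim[2], length.out = bins)
  P <- matrix(0, bins, bins)
  for (i in seq_along(basins)) {
    b <- basins[[i]]
    sdx <- sqrt(max(b$variance[ix[1]], 1e-12))
    sdy <- sqrt(max(b$variance[ix[2]], 1e-12))
    P <- P + w[i] * (stats::dnorm(gx, b$mean[ix[1]], sdx) %o%
                     stats::dnorm(gy, b$mean[ix[2]], sdy))
  }
  P <- P / sum(P)
  potential_from_probability(new_landscape(gx, gy, P, axes, "meanfield"))
}

#' Potential from steady-state probability
#'
#' The dimensionless potential is `U = -ln P`, with `P` floored at
#' `floor * max(P)` so empty cells stay finite. Minima of `U` coincide
#' with maxima of `P`.
#'
#' @param land a `grn_landscape` with `P` computed.
#' @param floor relative probability floor (small positive).
#' @return The landscape with `U` filled in.
#' @export
potential_from_probability <- function(land, floor = 1e-12) {
  stopifnot(inherits(land, "grn_landscape"), floor > 0)
  land$U <- -log(pmax(land$P, floor * max(land$P)))
  land$floor <- floor
  land
}

#' Steady-state probability flux on the grid
#'
#' The 2-D projected flux `J = F P - D grad P` (central differences for
#' the gradient). At a detailed-balance steady state with
#' `F = -D grad U`, `J` vanishes; a nonzero divergence-free remainder is
#' the curl flux that bends kinetic paths away from gradient descent.
#' Also returns the decomposition residual `F - (J/P - D grad U)`, which
#' is zero up to discretization wherever `P` is above the floor.
#'
#' @param land a `grn_landscape` with `P` (and `U`) computed.
#' @param Fx,Fy matrices of the projected force components per grid cell.
#' @param D diffusion coefficient.
#' @return Object of class `grn_flux`: `Jx`, `Jy`, `div` (interior
#'   divergence), `res_x`, `res_y`.
#' @export
flux_2d <- function(land, Fx, Fy, D) {
  P <- land$P
  if (!all(dim(Fx) == dim(P)) || !all(dim(Fy) == dim(P)))
    stop("force grids must match the landscape grid")
  hx <- land$x[2] - land$x[1]
  hy <- land$y[2] - land$y[1]
  dPdx <- central_diff(P, hx, 1)
  dPdy <- central_diff(P, hy, 2)
  Jx <- Fx * P - D * dPdx
  Jy <- Fy * P - D * dPdy
  div <- central_diff(Jx, hx, 1) + central_diff(Jy, hy, 2)
  if (is.null(land$U)) land <- potential_from_probability(land)
  dUdx <- central_diff(land$U, hx, 1)
  dUdy <- central_diff(land$U, hy, 2)
  Pf <- pmax(P, (if (is.null(land$floor)) 1e-12 else land$floor) * max(P))
  structure(list(Jx = Jx, Jy = Jy, div = div,
                 res_x = Fx - (Jx / Pf - D * dUdx),
                 res_y = Fy - (Jy / Pf - D * dUdy)),
            class = "grn_flux")
}

central_diff <- function(M, h, dim) {
  n <- dim(M)[dim]
  if (dim == 1) {
    out <- (M[c(2:n, n), ] - M[c(1, 1:(n - 1)), ]) /
      matrix(rep(c(h, rep(2 * h, n - 2), h), ncol(M)), n)
  } else {
    out <- (M[, c(2:n, n)] - M[, c(1, 1:(n - 1))]) /
      matrix(rep(c(h, rep(2 * h, n - 2), h), each = nrow(M)), nrow(M))
  }
  out
}

#' Write a landscape to TSV
#'
#' Long-format table of `(x, y, P, U)` with a commented header recording
#' the axis names, bounds, resolution and method.
#'
#' @param land a `grn_landscape`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(land, path) {
  if (is.null(land$U)) land <- potential_from_probability(land)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axes: %s, %s", land$axes[1], land$axes[2]),
               sprintf("# bounds: [%g, %g] x [%g, %g]", min(land$x),
                       max(land$x), min(land$y), max(land$y)),
               sprintf("# resolution: %d x %d", length(land$x), length(land$y)),
               sprintf("# method: %s", land$method),
               "x\ty\tP\tU"), con)
  grid <- expand.grid(i = seq_along(land$x), j = seq_along(land$y))
  writeLines(sprintf("%.8g\t%.8g\t%.8g\t%.8g", land$x[grid$i], land$y[grid$j],
                     land$P[cbind(grid$i, grid$j)],
                     land$U[cbind(grid$i, grid$j)]), con)
  invisible(path)
}

#' Evaluate a 2-gene network's force on a landscape grid
#'
#' Convenience for flux computations on two-gene systems, where the
#' projection is exact: returns the two force components evaluated at
#' every grid cell.
#'
#' @param net a two-gene [grn].
#' @param p a [hill_params].
#' @param land a `grn_landscape` over the two genes.
#' @return List with matrices `Fx`, `Fy`.
#' @export
force_grid <- function(net, p, land) {
  stopifnot(nrow(net$nodes) == 2)
  nx <- length(land$x); ny <- length(land$y)
  Fx <- matrix(0, nx, ny); Fy <- matrix(0, nx, ny)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    f <- grn_force(net, p, c(land$x[i], land$y[j]))
    Fx[i, j] <- f[1]; Fy[i, j] <- f[2]
  }
  list(Fx = Fx, Fy = Fy)
}
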