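#' Stochastic simulation configuration
#'
#' @param dt Euler-Maruyama time step (> 0).
#' @param steps number of steps (>= 1).
#' @param D isotropic diffusion coefficient (>= 0); the driving noise has
#'   autocorrelation `<eta(t) eta(t')> = 2 D delta(t - t')`.
#' @param seed optional integer seed.
#' @param record_every record every this many steps.
#' @param lower lower reflecting bound applied after each step; 0 for
#'   expression levels (concentrations cannot go negative), `-Inf` to
#'   disable for analytic benchmarks.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, steps = 1e5, D = 0.05, seed = NULL,
                       record_every = 1L, lower = 0) {
  stopifnot(dt > 0, steps >= 1, D >= 0, record_every >= 1)
  structure(list(dt = dt, steps = steps, D = D, seed = seed,
                 record_every = as.integer(record_every), lower = lower),
            class = "sim_config")
}

#' Simulate Langevin dynamics of a network
#'
#' Euler-Maruyama integration of `dx = F(x) dt + sqrt(2 D dt) xi` with
#' independent standard-normal increments per gene; states are clamped at
#' zero from below (expression levels are concentrations). With `D = 0`
#' this is plain Euler integration of the rate equations. The same seed
#' yields a bit-identical trajectory.
#'
#' @param net a [grn].
#' @param p a [hill_params].
#' @param x0 nonnegative initial state.
#' @param cfg a [sim_config].
#' @param schedule optional numeric vector (length `cfg$steps` or 1)
#'   overriding, per step, the strength of the edges in `schedule_edges`
#'   (used by activation annealing).
#' @param schedule_edges integer edge-row indices whose weight follows
#'   `schedule`; default all default-strength activation edges.
#' @return Object of class `grn_traj`: matrix of recorded states
#'   (rows = time points, columns = genes) with attribute `times`.
#' @export
simulate_network <- function(net, p, x0, cfg, schedule = NULL,
                             schedule_edges = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  lo0 <- if (is.null(cfg$lower)) 0 else cfg$lower
  if (any(x0 < lo0)) stop("initial state below the lower bound")
  ea <- edge_arrays(net, p)
  mask <- integer(length(ea$src))
  if (!is.null(schedule)) {
    if (is.null(schedule_edges))
      schedule_edges <- which(net$edges$sign == "act" & is.na(net$edges$strength))
    mask[schedule_edges] <- 1L
    if (length(schedule) == 1L) schedule <- rep(schedule, 2L)
  } else schedule <- numeric(0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lower <- if (is.null(cfg$lower)) 0 else cfg$lower
  X <- simulate_grn_cpp(as.numeric(x0), ea$src, ea$tgt, ea$act, ea$w,
                        mask, as.numeric(schedule), p$k, p$S, p$n,
                        cfg$dt, cfg$steps, cfg$D, cfg$record_every, lower)
  colnames(X) <- net$nodes$name
  structure(X, times = seq(0, by = cfg$dt * cfg$record_every,
                           length.out = nrow(X)),
            class = c("grn_traj", "matrix", "array"))
}

#' Histogram landscape from trajectories
#'
#' Bins trajectory points on two chosen coordinates, normalizes the
#' 2-D histogram to a probability and takes `U = -ln P` (floored). The
#' coordinates are either two gene names (columns of the trajectory) or a
#' two-column matrix of precomputed coordinates such as [rmsd_coords()].
#'
#' @param traj a `grn_traj` matrix, or a list of them.
#' @param axes character(2) of gene names, or a matrix/data.frame with two
#'   columns of coordinates (one row per trajectory row).
#' @param bins number of bins per axis.
#' @param lims list with `x` and `y` ranges; default data range padded 5%.
#' @param floor probability floor relative to the maximum before the log.
#' @return A `grn_landscape` (fields `x`, `y`, `P`, `U`, `axes`, `method`).
#' @export
histogram_landscape <- function(traj, axes, bins = 100, lims = NULL,
                                floor = 1e-12) {
  if (is.list(traj) && !is.matrix(traj)) traj <- do.call(rbind, traj)
  if (!nrow(traj)) stop("empty trajectory")
  if (is.character(axes)) {
    xy <- traj[, axes, drop = FALSE]
    axis_names <- axes
  } else {
    xy <- as.matrix(axes)
    if (ncol(xy) != 2 || nrow(xy) != nrow(traj))
      stop("coordinate matrix must have 2 columns and one row per state")
    axis_names <- colnames(xy)
    if (is.null(axis_names)) axis_names <- c("coord1", "coord2")
  }
  if (is.null(lims)) {
    pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
    lims <- list(x = pad(range(xy[, 1])), y = pad(range(xy[, 2])))
  }
  bx <- seq(lims$x[1], lims$x[2], length.out = bins + 1)
  by <- seq(lims$y[1], lims$y[2], length.out = bins + 1)
  ix <- findInterval(xy[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2], by, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
  P <- matrix(tabulate((ix[keep] - 1L) + (iy[keep] - 1L) * bins + 1L,
                       bins * bins), bins, bins)
  P <- P / sum(P)
  land <- new_landscape(x = (bx[-1] + bx[-(bins + 1)]) / 2,
                        y = (by[-1] + by[-(bins + 1)]) / 2,
                        P = P, axes = axis_names, method = "langevin")
  land <- potential_from_probability(land, floor = floor)
  if (length(local_minima(land$U)) < 2)
    warning("histogram landscape has fewer than 2 local minima; ",
            "trajectories may not cover both basins")
  land
}

#' Root-mean-squared-distance coordinates
#'
#' Projects an N-dimensional trajectory to two coordinates, the RMSD of
#' each state to two reference states (typically the two attractor
#' minima): `RMSD_r(x) = sqrt(mean((x - r)^2))`.
#'
#' @param traj state matrix (rows = time points).
#' @param ref1,ref2 reference states of length `ncol(traj)`.
#' @return Matrix with columns `RMSD1`, `RMSD2`.
#' @export
rmsd_coords <- function(traj, ref1, ref2) {
  traj <- as.matrix(traj)
  if (length(ref1) != ncol(traj) || length(ref2) != ncol(traj))
    stop("reference length does not match the number of genes")
  cbind(RMSD1 = sqrt(rowMeans((traj - rep(ref1, each = nrow(traj)))^2)),
        RMSD2 = sqrt(rowMeans((traj - rep(ref2, each = nrow(traj)))^2)))
}

#' Mean first passage time between attractors
#'
#' Launches independent stochastic passages from the source state; a
#' passage completes when the trajectory first enters the max-norm ball
#' of radius `radius` around the target state. Reports the mean, the
#' standard error over passages and the passage count.
#'
#' @param system a [grn] (with `p` a [hill_params]) or a `double_well`
#'   oracle from [make_double_well_oracle()] (then `p` is ignored).
#' @param p kinetic parameters (networks only).
#' @param cfg a [sim_config]; `cfg$D` is the noise level and `cfg$seed`
#'   makes the estimate reproducible.
#' @param source,target attractor states (numeric vectors; scalars for the
#'   double well).
#' @param radius capture radius; default 10% of the max-norm separation.
#' @param n_passages number of passages (>= 1).
#' @param max_steps per-passage step budget.
#' @return Object of class `grn_mfpt`: `mean`, `sem`, `n_passages`,
#'   `times`, `n_timeout`.
#' @export
estimate_mfpt <- function(system, p = NULL, cfg, source, target,
                          radius = NULL, n_passages = 100,
                          max_steps = 1e7) {
  stopifnot(inherits(cfg, "sim_config"), n_passages >= 1, cfg$D > 0)
  if (is.null(radius)) radius <- 0.1 * max(abs(source - target))
  stopifnot(radius > 0)
  if (max(abs(source - target)) <= radius) {
    return(structure(list(mean = 0, sem = 0, n_passages = n_passages,
                          times = rep(0, n_passages), n_timeout = 0L),
                     class = "grn_mfpt"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(system, "double_well")) {
    times <- mfpt_dw_cpp(system$h, system$D, source, target, radius,
                         cfg$dt, max_steps, n_passages)
  } else if (inherits(system, "grn")) {
    ea <- edge_arrays(system, p)
    times <- mfpt_grn_cpp(as.numeric(source), as.numeric(target), radius,
                          ea$src, ea$tgt, ea$act, ea$w, p$k, p$S, p$n,
                          cfg$dt, cfg$D, max_steps, n_passages)
  } else stop("unsupported system type: ", class(system)[1])
  n_timeout <- sum(is.na(times))
  if (n_timeout == n_passages)
    stop("step budget (", format(max_steps), ") exhausted before any ",
         "passage; increase D or max_steps")
  ok <- times[!is.na(times)]
  structure(list(mean = mean(ok),
                 sem = stats::sd(ok) / sqrt(length(ok)),
                 n_passages = length(ok), times = times,
                 n_timeout = n_timeout),
            class = "grn_mfpt")
}

#' @export
print.grn_mfpt <- function(x, ...) {
  cat(sprintf("MFPT = %.4g +/- %.2g (SEM, %d passages%s)\n", x$mean, x$sem,
              x$n_passages,
              if (x$n_timeout) sprintf(", %d timed out", x$n_timeout) else ""))
  invisible(x)
}
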