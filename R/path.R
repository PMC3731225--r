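#' Dominant-path optimization settings
#'
#' @param n_points path discretization points including endpoints (>= 3).
#' @param total_time path duration (> 0).
#' @param n_starts multi-start count (straight line plus seeded noisy
#'   initializations; lowest action wins, ties broken by the
#'   lexicographically smallest first interior point).
#' @param maxit,reltol optimizer budget and tolerance (L-BFGS-B).
#' @param seed integer seed for the multi-start noise.
#' @param lower per-coordinate lower bound (0 for expression levels,
#'   `-Inf` for unconstrained systems).
#' @return Object of class `path_config`.
#' @export
path_config <- function(n_points = 50, total_time = 12, n_starts = 5,
                        maxit = 1500, reltol = 1e-10, seed = 1, lower = 0) {
  stopifnot(n_points >= 3, total_time > 0, n_starts >= 1)
  structure(list(n_points = as.integer(n_points), total_time = total_time,
                 n_starts = as.integer(n_starts), maxit = maxit,
                 reltol = reltol, seed = seed, lower = lower),
            class = "path_config")
}

as_force <- function(system, p) {
  if (inherits(system, "grn")) {
    force_closures(system, p)
  } else if (is.function(system)) {
    list(F = system, J = function(x) fd_jacobian(system, x))
  } else stop("system must be a grn or a force function")
}

# Fast force/Jacobian closures with the edge arrays resolved once.
force_closures <- function(net, p) {
  ea <- edge_arrays(net, p)
  N <- nrow(net$nodes); Sn <- p$S^p$n; n <- p$n; k <- p$k
  src1 <- ea$src + 1L; tgt1 <- ea$tgt + 1L
  isact <- ea$act == 1L; w <- ea$w
  Fv <- function(x) {
    x <- pmax(x, 0)
    xn <- x^n
    hu <- xn / (Sn + xn)
    hd <- Sn / (Sn + xn)
    f <- -k * x
    contrib <- w * ifelse(isact, hu[src1], hd[src1])
    for (e in seq_along(src1)) f[tgt1[e]] <- f[tgt1[e]] + contrib[e]
    f
  }
  Jv <- function(x) {
    x <- pmax(x, 0)
    xn <- x^n
    dup <- n * Sn * x^(n - 1) / (Sn + xn)^2
    J <- diag(-k, N)
    dv <- ifelse(isact, dup[src1], -dup[src1]) * w
    for (e in seq_along(src1))
      J[tgt1[e], src1[e]] <- J[tgt1[e], src1[e]] + dv[e]
    J
  }
  list(F = Fv, J = Jv)
}

fd_jacobian <- function(F, x, h = 1e-6) {
  f0 <- F(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h
    J[, j] <- (F(x + e) - F(x - e)) / (2 * h)
  }
  J
}

#' Onsager-Machlup action of a discretized path
#'
#' Zeroth-order (in D) Onsager-Machlup functional
#' \deqn{S = \int \sum_i \frac{(\dot x_i - F_i(x))^2}{4 D}\,dt,}
#' discretized with segment-midpoint velocities and force evaluations:
#' paths that follow the deterministic flow have zero action, and the
#' action scales exactly as 1/D for a fixed geometry. The divergence
#' correction term is omitted (recorded in the result metadata);
#' dominant-path ranking is unchanged at small D.
#'
#' @param points path matrix (rows = points, columns = genes).
#' @param times strictly increasing time vector, one per point.
#' @param system a [grn] or a force function `F(x)`.
#' @param p kinetic parameters (networks only).
#' @param D diffusion coefficient (> 0).
#' @return Nonnegative action scalar.
#' @export
path_action <- function(points, times, system, p = NULL, D) {
  stopifnot(D > 0, nrow(points) >= 3)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  fr <- as_force(system, p)
  action_core(points, times, fr$F, D)
}

action_core <- function(points, times, F, D) {
  n <- nrow(points)
  dt <- diff(times)
  S <- 0
  for (k in seq_len(n - 1)) {
    v <- (points[k + 1, ] - points[k, ]) / dt[k]
    m <- (points[k + 1, ] + points[k, ]) / 2
    r <- v - F(m)
    S <- S + dt[k] * sum(r^2) / (4 * D)
  }
  S
}

# Analytic gradient of the midpoint-discretized action with respect to
# the interior points (endpoints pinned).
action_grad <- function(points, times, F, J, D) {
  n <- nrow(points); N <- ncol(points)
  dt <- diff(times)
  G <- matrix(0, n, N)
  for (k in seq_len(n - 1)) {
    v <- (points[k + 1, ] - points[k, ]) / dt[k]
    m <- (points[k + 1, ] + points[k, ]) / 2
    r <- v - F(m)
    Jt_r <- crossprod(J(m), r)
    G[k + 1, ] <- G[k + 1, ] + r / (2 * D) - dt[k] * Jt_r / (4 * D)
    G[k, ]     <- G[k, ]     - r / (2 * D) - dt[k] * Jt_r / (4 * D)
  }
  G[2:(n - 1), , drop = FALSE]
}

#' Dominant kinetic path by action minimization
#'
#' Minimizes the Onsager-Machlup action over the interior points of a
#' discretized path with both endpoints pinned at the requested attractor
#' states, from multiple seeded initializations (straight line plus
#' noise). For gradient force fields the optimal uphill and downhill
#' paths coincide; curl flux in non-gradient networks makes the forward
#' and reverse dominant paths differ (irreversibility).
#'
#' @param system a [grn] or force function.
#' @param p kinetic parameters (networks only).
#' @param D diffusion coefficient (> 0).
#' @param start,end endpoint states (typically stable attractors).
#' @param cfg a [path_config].
#' @return Object of class `grn_path`: `points`, `times`, `action`,
#'   `action_straight`, `converged`, `om_order` (metadata: zeroth-order
#'   functional).
#' @export
optimize_path <- function(system, p = NULL, D, start, end, cfg = path_config()) {
  stopifnot(D > 0, length(start) == length(end))
  if (max(abs(start - end)) == 0) stop("start and end coincide")
  fr <- as_force(system, p)
  n <- cfg$n_points; N <- length(start)
  times <- seq(0, cfg$total_time, length.out = n)
  straight <- outer(seq(0, 1, length.out = n), end - start) +
    rep(start, each = n)
  S_straight <- action_core(straight, times, fr$F, D)
  obj <- function(theta) {
    pts <- straight
    pts[2:(n - 1), ] <- matrix(theta, n - 2, N)
    action_core(pts, times, fr$F, D)
  }
  grd <- function(theta) {
    pts <- straight
    pts[2:(n - 1), ] <- matrix(theta, n - 2, N)
    as.numeric(action_grad(pts, times, fr$F, fr$J, D))
  }
  set.seed(cfg$seed)
  best <- NULL
  scale <- max(abs(end - start))
  for (s in seq_len(cfg$n_starts)) {
    init <- straight[2:(n - 1), , drop = FALSE]
    if (s > 1) {
      bump <- matrix(stats::rnorm((n - 2) * N, sd = 0.15 * scale), n - 2, N)
      bump <- bump * sin(pi * seq_len(n - 2) / (n - 1))  # keep ends anchored
      init <- init + bump
      if (is.finite(cfg$lower)) init <- pmax(init, cfg$lower)
    }
    fit <- stats::optim(as.numeric(init), obj, grd, method = "L-BFGS-B",
                        lower = cfg$lower,
                        control = list(maxit = cfg$maxit,
                                       factr = cfg$reltol / 1e-15))
    cand <- list(value = fit$value, par = fit$par, conv = fit$convergence == 0)
    if (is.null(best) || cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) <= 1e-12 &&
         lex_less(cand$par[1:N], best$par[1:N])))
      best <- cand
  }
  if (best$value > S_straight + 1e-8)
    warning(sprintf("optimizer did not reduce the action below the straight line (%.4g > %.4g)",
                    best$value, S_straight))
  pts <- straight
  pts[2:(n - 1), ] <- matrix(best$par, n - 2, N)
  if (inherits(system, "grn")) colnames(pts) <- system$nodes$name
  structure(list(points = pts, times = times, action = best$value,
                 action_straight = S_straight, converged = best$conv,
                 om_order = "OM action, O(D^0), no divergence correction"),
            class = "grn_path")
}

#' Write a dominant path to TSV
#'
#' Time column followed by one column per gene; the action and the
#' functional variant are recorded in commented header lines.
#'
#' @param path_obj a `grn_path`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_path <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "grn_path"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# action: %.12g", path_obj$action),
               sprintf("# functional: %s", path_obj$om_order)), con)
  cn <- colnames(path_obj$points)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(path_obj$points)))
  writeLines(paste(c("time", cn), collapse = "\t"), con)
  utils::write.table(cbind(time = path_obj$times, path_obj$points), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.grn_path <- function(x, ...) {
  cat(sprintf("Dominant path: %d points, action %.5g (straight line %.5g)%s\n",
              nrow(x$points), x$action, x$action_straight,
              if (!x$converged) " [optimizer not fully converged]" else ""))
  invisible(x)
}

# Resample a polyline at m points equally spaced in arc length, so
# curve comparisons do not depend on how vertices cluster along the path.
resample_arclength <- function(P, m = 200) {
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(P[rep(1, m), , drop = FALSE])
  su <- seq(0, s[length(s)], length.out = m)
  apply(P, 2, function(col) stats::approx(s, col, xout = su, ties = "ordered")$y)
}

# Discrete Frechet distance between two polylines (Euclidean point metric).
frechet_distance <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  ca <- matrix(NA_real_, n, m)
  ca[1, 1] <- d(1, 1)
  for (i in 2:n) ca[i, 1] <- max(ca[i - 1, 1], d(i, 1))
  for (j in 2:m) ca[1, j] <- max(ca[1, j - 1], d(1, j))
  for (i in 2:n) for (j in 2:m)
    ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]), d(i, j))
  ca[n, m]
}

#' Irreversibility of a forward/reverse path pair
#'
#' Discrete Frechet distance between the forward path and the reversed
#' backward path, normalized by the Euclidean separation of the
#' endpoints. Zero for exactly retraced paths; strictly positive when
#' curl flux splits the differentiation and reprogramming routes.
#'
#' @param path_fwd,path_rev `grn_path` objects (or point matrices) whose
#'   endpoint pairs match in opposite order.
#' @param tol endpoint-matching tolerance.
#' @return Nonnegative scalar.
#' @export
irreversibility_index <- function(path_fwd, path_rev, tol = 1e-6) {
  A <- if (inherits(path_fwd, "grn_path")) path_fwd$points else as.matrix(path_fwd)
  B <- if (inherits(path_rev, "grn_path")) path_rev$points else as.matrix(path_rev)
  Brev <- B[rev(seq_len(nrow(B))), , drop = FALSE]
  if (max(abs(A[1, ] - Brev[1, ])) > tol ||
      max(abs(A[nrow(A), ] - Brev[nrow(Brev), ])) > tol)
    stop("paths do not share endpoint pairs in opposite order")
  sep <- sqrt(sum((A[1, ] - A[nrow(A), ])^2))
  m <- 4 * max(nrow(A), nrow(Brev))
  frechet_distance(resample_arclength(A, m), resample_arclength(Brev, m)) / sep
}
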