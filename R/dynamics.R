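#' Hill-kinetics force field
#'
#' Time derivative of the expression state under the additive Hill rate
#' law: first-order degradation plus one saturating activation term per
#' incoming activation link and one repression term per incoming
#' repression link (see [hill_params()]). Self-edges use the gene's own
#' level (self-activation / self-repression). There is no basal
#' production term, and regulators combine additively.
#'
#' @param net a [grn].
#' @param p a [hill_params].
#' @param x nonnegative state vector, one entry per gene.
#' @return Derivative vector of length `nrow(net$nodes)`.
#' @export
grn_force <- function(net, p, x) {
  N <- nrow(net$nodes)
  if (length(x) != N) stop("state length ", length(x), " != node count ", N)
  if (any(x < 0)) stop("state components must be nonnegative")
  ea <- edge_arrays(net, p)
  Sn <- p$S^p$n
  xn <- x^p$n
  hu <- xn / (Sn + xn)
  hd <- Sn / (Sn + xn)
  f <- -p$k * x
  contrib <- ea$w * ifelse(ea$act == 1L, hu[ea$src + 1L], hd[ea$src + 1L])
  f + as.numeric(rowsum(c(contrib, numeric(N)),
                        c(ea$tgt + 1L, seq_len(N))))
}

#' Analytic Jacobian of the force field
#'
#' Entry (i, j) is the partial derivative of the i-th rate with respect to
#' gene j, evaluated from the closed-form Hill derivatives; it is zero
#' whenever j neither regulates i nor equals i.
#'
#' @inheritParams grn_force
#' @return Dense N x N matrix.
#' @export
grn_jacobian <- function(net, p, x) {
  N <- nrow(net$nodes)
  if (length(x) != N) stop("state length ", length(x), " != node count ", N)
  if (any(x < 0)) stop("state components must be nonnegative")
  ea <- edge_arrays(net, p)
  Sn <- p$S^p$n
  xn <- x^p$n
  # d/dx x^n/(S^n+x^n) = n S^n x^(n-1) / (S^n+x^n)^2 ; repression is its negative
  dup <- p$n * Sn * x^(p$n - 1) / (Sn + xn)^2
  J <- diag(-p$k, N)
  for (e in seq_along(ea$src)) {
    j <- ea$src[e] + 1L; i <- ea$tgt[e] + 1L
    J[i, j] <- J[i, j] + ea$w[e] * (if (ea$act[e] == 1L) dup[j] else -dup[j])
  }
  dimnames(J) <- list(net$nodes$name, net$nodes$name)
  J
}

#' Locate stable attractors by multi-start integration
#'
#' Integrates the deterministic rate equations from uniform random initial
#' states, polishes converged endpoints by Newton iteration, deduplicates
#' fixed points within a max-norm tolerance and verifies linear stability
#' from the Jacobian eigenvalues. The basin weight of each attractor is
#' the fraction of starts converging to it, so weights sum to 1.
#'
#' @inheritParams grn_force
#' @param n_starts number of random initial states (>= 1).
#' @param box sampling bounds, either `c(lo, hi)` for all genes or an
#'   N x 2 matrix. Default `c(0, 3)` covers the Hill saturation range at
#'   `S = 0.5`.
#' @param seed optional integer seed; same seed gives identical results.
#' @param tol max-norm deduplication tolerance between fixed points.
#' @param t_end,dt integration horizon and RK4 time step.
#' @return Object of class `grn_attractors`: `states` (attractors x genes),
#'   `weights`, `eig_max` (largest real part), `labels`, `n_starts`,
#'   `n_converged`.
#' @export
find_attractors <- function(net, p, n_starts = 500, box = c(0, 3), seed = NULL,
                            tol = 0.05, t_end = 200, dt = 0.1) {
  stopifnot(n_starts >= 1, all(is.finite(box)))
  N <- nrow(net$nodes)
  if (!is.matrix(box)) box <- matrix(rep(box, each = N), N, 2)
  if (!is.null(seed)) set.seed(seed)
  x0 <- matrix(stats::runif(n_starts * N, box[, 1], box[, 2]),
               n_starts, N, byrow = TRUE)
  ea <- edge_arrays(net, p)
  fc <- force_closures(net, p)
  ends <- integrate_grn_cpp(x0, ea$src, ea$tgt, ea$act, ea$w,
                            p$k, p$S, p$n, dt, as.integer(round(t_end / dt)))
  # re-integrate endpoints still moving (slow manifolds near saddles)
  n_steps <- as.integer(round(t_end / dt))
  for (pass in 1:3) {
    res <- apply(ends, 1, function(x) max(abs(fc$F(x))))
    moving <- which(res > 1e-6)
    if (!length(moving)) break
    ends[moving, ] <- integrate_grn_cpp(ends[moving, , drop = FALSE],
                                        ea$src, ea$tgt, ea$act, ea$w,
                                        p$k, p$S, p$n, dt, n_steps)
  }
  # group identical endpoints at tol resolution, then greedy-merge the
  # group representatives in max-norm, Newton-polish one representative
  # per cluster and re-merge the polished fixed points
  key <- apply(round(ends / tol), 1, paste, collapse = ",")
  grp <- split(seq_len(n_starts), key)
  reps <- lapply(grp, function(ix) ends[ix[1], ])
  members <- grp
  ord <- order(-lengths(members))
  reps <- reps[ord]; members <- members[ord]
  ci <- integer(0); cl_rep <- list(); cl_members <- list()
  for (j in seq_along(reps)) {
    x <- reps[[j]]
    hit <- 0L
    for (i in seq_along(cl_rep))
      if (max(abs(x - cl_rep[[i]])) < tol) { hit <- i; break }
    if (hit == 0L) {
      cl_rep[[length(cl_rep) + 1L]] <- x
      cl_members[[length(cl_rep)]] <- members[[j]]
    } else cl_members[[hit]] <- c(cl_members[[hit]], members[[j]])
  }
  fixed <- list(); counts <- integer(0); ok <- 0L
  for (j in seq_along(cl_rep)) {
    x <- newton_polish_fc(fc, cl_rep[[j]])
    if (is.null(x)) next
    ok <- ok + length(cl_members[[j]])
    hit <- 0L
    for (i in seq_along(fixed))
      if (max(abs(x - fixed[[i]])) < tol) { hit <- i; break }
    if (hit == 0L) {
      fixed[[length(fixed) + 1L]] <- x
      counts <- c(counts, length(cl_members[[j]]))
    } else counts[hit] <- counts[hit] + length(cl_members[[j]])
  }
  if (!length(fixed))
    stop("no start converged within the step budget (t_end = ", t_end, ")")
  states <- do.call(rbind, fixed)
  colnames(states) <- net$nodes$name
  eig_max <- apply(states, 1, function(x)
    max(Re(eigen(grn_jacobian(net, p, x), only.values = TRUE)$values)))
  stable <- eig_max < 0
  states <- states[stable, , drop = FALSE]
  counts <- counts[stable]
  eig_max <- eig_max[stable]
  if (!nrow(states))
    stop("no stable attractor found (all endpoints linearly unstable)")
  o <- order(-counts, apply(states, 1, paste, collapse = ","))
  structure(list(states = states[o, , drop = FALSE],
                 weights = counts[o] / sum(counts),
                 eig_max = eig_max[o],
                 labels = rep(NA_character_, sum(stable)),
                 n_starts = n_starts, n_converged = ok),
            class = "grn_attractors")
}

newton_polish <- function(net, p, x, max_iter = 50, ftol = 1e-10) {
  newton_polish_fc(force_closures(net, p), x, max_iter, ftol)
}

newton_polish_fc <- function(fc, x, max_iter = 50, ftol = 1e-10) {
  for (i in seq_len(max_iter)) {
    f <- fc$F(x)
    if (max(abs(f)) < ftol) return(x)
    step <- tryCatch(solve(fc$J(x), f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    x <- pmax(x - step, 0)
  }
  if (max(abs(fc$F(x))) < 1e-8) x else NULL
}

#' @export
print.grn_attractors <- function(x, digits = 4, ...) {
  cat(sprintf("%d stable attractor(s) from %d starts (%d converged)\n",
              nrow(x$states), x$n_starts, x$n_converged))
  df <- data.frame(weight = round(x$weights, digits),
                   eig_max = signif(x$eig_max, 3))
  nshow <- min(ncol(x$states), 6)
  df <- cbind(df, round(x$states[, seq_len(nshow), drop = FALSE], digits))
  if (ncol(x$states) > nshow) df$`...` <- "..."
  print(df)
  invisible(x)
}

#' Label attractors as stem-like or differentiated-like
#'
#' Compares the expression of a stem marker against a differentiation
#' marker in each attractor: the attractor with the higher stem/diff
#' contrast is labelled `"stem"`, the other `"differentiated"`.
#'
#' @param att a `grn_attractors` (exactly 2 attractors).
#' @param net the network the attractors belong to.
#' @param stem,diff marker gene names (defaults NANOG / GATA6).
#' @return `att` with `labels` filled in.
#' @export
label_attractors <- function(att, net, stem = "NANOG", diff = "GATA6") {
  stopifnot(nrow(att$states) == 2)
  s <- att$states[, stem] - att$states[, diff]
  att$labels <- ifelse(seq_len(2) == which.max(s), "stem", "differentiated")
  att
}
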