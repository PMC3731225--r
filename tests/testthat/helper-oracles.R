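# Shared fixtures and independent oracles used across the suite.

# Stable fixed points of the two-gene motif at a = 0.5, b = 1, k = 1,
# S = 0.5, n = 4, located by multi-start integration + Newton root
# polishing before the suite was written (independent of find_attractors'
# clustering) and frozen here.
MOTIF_A05_HI <- 1.4938014848349
MOTIF_A05_LO <- 0.0123964635661
motif_states <- function() rbind(stem = c(MOTIF_A05_HI, MOTIF_A05_LO),
                                 diff = c(MOTIF_A05_LO, MOTIF_A05_HI))

# Central finite-difference Jacobian of an arbitrary force function.
fd_jac <- function(F, x, h = 1e-6) {
  f0 <- F(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h
    J[, j] <- (F(x + e) - F(x - e)) / (2 * h)
  }
  J
}

# Independent minimax-saddle oracle: bottleneck (minimax) edge weight on
# the minimum spanning tree of the 8-connected grid graph with edge
# weight max(U[u], U[v]); the MST bottleneck path realizes the minimax
# path value.
mst_saddle_oracle <- function(U, m1, m2) {
  n1 <- nrow(U); n2 <- ncol(U)
  idx <- function(i, j) (j - 1L) * n1 + i
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (j in seq_len(n2)) for (i in seq_len(n1))
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2) {
        from <- c(from, idx(i, j)); to <- c(to, idx(ii, jj))
        w <- c(w, max(U[i, j], U[ii, jj]))
      }
    }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  mt <- igraph::mst(g)
  ep <- igraph::shortest_paths(mt, m1, m2, output = "epath")$epath[[1]]
  max(igraph::E(mt)$weight[as.integer(ep)])
}

# Finite-volume Fokker-Planck time-marcher: steady state of
# dP/dt = -div(F P) + D lap(P) on a rectangular grid with no-flux
# boundaries. Independent of the package's flux_2d discretization.
fp_steady_state <- function(gx, gy, Fx_face_x, Fy_face_y, D, dt, n_iter,
                            n_polish = 0) {
  nx <- length(gx); ny <- length(gy)
  hx <- gx[2] - gx[1]; hy <- gy[2] - gy[1]
  P <- matrix(1 / (nx * ny), nx, ny)
  step <- function(P, central) {
    Pw <- P[-nx, ]; Pe <- P[-1, ]
    adv <- if (central) Fx_face_x * (Pw + Pe) / 2
           else ifelse(Fx_face_x > 0, Fx_face_x * Pw, Fx_face_x * Pe)
    fx <- adv - D * (Pe - Pw) / hx                 # (nx-1) x ny
    Ps <- P[, -ny]; Pn <- P[, -1]
    advy <- if (central) Fy_face_y * (Ps + Pn) / 2
            else ifelse(Fy_face_y > 0, Fy_face_y * Ps, Fy_face_y * Pn)
    fy <- advy - D * (Pn - Ps) / hy                # nx x (ny-1)
    div <- matrix(0, nx, ny)
    div[-nx, ] <- div[-nx, ] + fx / hx
    div[-1, ] <- div[-1, ] - fx / hx
    div[, -ny] <- div[, -ny] + fy / hy
    div[, -1] <- div[, -1] - fy / hy
    P <- P - dt * div
    P[P < 0] <- 0
    P / sum(P)
  }
  # robust first-order upwind march into the basin of the steady state,
  # then second-order central polishing for an accurate stationary P
  for (it in seq_len(n_iter)) P <- step(P, central = FALSE)
  for (it in seq_len(n_polish)) P <- step(P, central = TRUE)
  P
}

# Labelled attractors of the packaged 52-gene network at the balanced
# working point, computed once per test run (the multi-start search is
# the most expensive step shared across files).
stemcell_attractors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- make_stemcell_network()
      att <- find_attractors(net, stemcell_params(), n_starts = 4000,
                             seed = 11)
      cache <<- label_attractors(att, net)
    }
    cache
  }
})

# A single-gene network with no regulation: pure linear degradation.
isolated_gene <- function() {
  grn(data.frame(id = 1, name = "G"),
      data.frame(source = character(0), target = character(0),
                 sign = character(0)))
}
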