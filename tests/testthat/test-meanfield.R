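test_that("moment closure is exact for linear degradation", {
  p <- hill_params(k = 1)
  b <- propagate_moments(isolated_gene(), p, x0 = 1, D = 0.05)
  expect_equal(unname(b$mean), 0, tolerance = 1e-8)
  expect_equal(unname(b$variance), 0.05, tolerance = 1e-8)  # sigma_ss = D/k
  # noiseless limit: zero variance, mean at the deterministic attractor
  b0 <- propagate_moments(isolated_gene(), p, x0 = 1, D = 0)
  expect_equal(unname(b0$variance), 0, tolerance = 1e-10)
  # mean equation reduces to the ODE: motif mean lands on the attractor
  m <- make_two_gene_motif(a = 0.5)
  bm <- propagate_moments(m$network, m$params, motif_states()[1, ] + 0.05,
                          D = 0.01)
  expect_equal(unname(bm$mean), unname(motif_states()[1, ]), tolerance = 1e-6)
})

test_that("stationary closure variances track Langevin in-basin variances", {
  m <- make_two_gene_motif(a = 0.5)
  D <- 0.05
  s <- motif_states()[1, ]
  b <- propagate_moments(m$network, m$params, s, D)
  # unclamped comparison: the closure has no boundary at zero
  cfg <- sim_config(dt = 0.01, steps = 1e6, D = D, seed = 13,
                    record_every = 5, lower = -Inf)
  tr <- simulate_network(m$network, m$params, s, cfg)
  inb <- apply(tr, 1, function(x) max(abs(x - s)) < 0.6)
  v <- apply(tr[inb, ], 2, stats::var)
  expect_lt(max(abs(b$variance - v) / v), 0.15)
})

test_that("gaussian mixture probability marginalizes and normalizes", {
  m <- make_two_gene_motif(a = 0.5)
  net <- m$network
  mk_basin <- function(mean, w)
    structure(list(mean = stats::setNames(mean, net$nodes$name),
                   variance = stats::setNames(c(0.02, 0.02), net$nodes$name),
                   weight = w), class = "grn_basin")
  # single basin: unimodal with the max-P cell at the mean
  l1 <- mixture_probability(list(mk_basin(c(1, 0.5), 1)),
                            c("GATA1", "PU1"), net, bins = 60)
  ij <- which(l1$P == max(l1$P), arr.ind = TRUE)
  expect_lt(abs(l1$x[ij[1]] - 1), 0.03)
  expect_lt(abs(l1$y[ij[2]] - 0.5), 0.03)
  expect_equal(sum(l1$P), 1, tolerance = 1e-6)

  # two basins weighted 0.1/0.9: integrated masses in that ratio
  l2 <- mixture_probability(list(mk_basin(c(0.5, 0.5), 0.1),
                                 mk_basin(c(2, 2), 0.9)),
                            c("GATA1", "PU1"), net, bins = 100)
  near1 <- sum(l2$P[l2$x < 1.25, l2$y < 1.25])
  near2 <- sum(l2$P[l2$x > 1.25, l2$y > 1.25])
  expect_equal(near2 / near1, 9, tolerance = 0.02)
  expect_error(mixture_probability(list(mk_basin(c(1, 1), 1)),
                                   c("GATA1", "NOPE"), net), "not in the network")
})

test_that("potential is the negative log probability with a floor", {
  land <- grnland:::new_landscape(1:3, 1:3,
                                  matrix(exp(-1), 3, 3) / (9 * exp(-1)),
                                  c("x", "y"), "test")
  land <- potential_from_probability(land)
  expect_equal(land$U, matrix(-log(1 / 9), 3, 3))  # uniform P, constant U
  P <- matrix(c(exp(-1), rep(exp(-3), 8)), 3, 3)
  land2 <- potential_from_probability(grnland:::new_landscape(1:3, 1:3, P,
                                                              c("x", "y"), "t"))
  expect_equal(which.min(land2$U), which.max(P))
  expect_equal(land2$U[1, 1], 1)  # P = e^{-1} gives U = 1 before renormalization
})

test_that("flux vanishes at detailed balance and satisfies the decomposition", {
  D <- 0.05
  flux_of <- function(nx, ny) {
    gx <- seq(-1.6, 1.6, length.out = nx)
    gy <- seq(-1.2, 1.2, length.out = ny)
    P <- outer(gx, gy, function(x, y) exp(-((x^2 - 1)^2 + 0.5 * y^2) / D))
    P <- P / sum(P)
    land <- potential_from_probability(
      grnland:::new_landscape(gx, gy, P, c("x", "y"), "analytic"))
    Fx <- outer(gx, gy, function(x, y) -4 * x * (x^2 - 1))
    Fy <- outer(gx, gy, function(x, y) -y)
    list(fl = flux_2d(land, Fx, Fy, D), P = P, Fx = Fx, land = land)
  }
  coarse <- flux_of(80, 60)
  fine <- flux_of(160, 120)
  # gradient system with Boltzmann statistics: flux is zero up to O(h^2),
  # so halving the grid spacing cuts the residual flux ~4-fold
  scale_c <- max(abs(coarse$Fx) * coarse$P)
  scale_f <- max(abs(fine$Fx) * fine$P)
  expect_lt(max(abs(fine$fl$Jx)) / scale_f, 0.05)
  expect_lt(max(abs(fine$fl$Jy)) / scale_f, 0.05)
  expect_lt(max(abs(fine$fl$Jx)) / scale_f,
            0.5 * max(abs(coarse$fl$Jx)) / scale_c)
  # decomposition residual F - (J/P - D grad U) ~ 0 on the well-sampled core
  big <- fine$P > 0.3 * max(fine$P)
  fscale <- max(abs(fine$Fx))
  expect_lt(max(abs(fine$fl$res_x[big])) / fscale, 0.05)
  expect_lt(max(abs(fine$fl$res_y[big])) / fscale, 0.05)
  expect_error(flux_2d(fine$land, fine$Fx[1:10, ], fine$Fx, D), "match")
})

test_that("steady-state flux of the motif is nearly divergence-free", {
  # true steady state from an independent finite-volume Fokker-Planck
  # marcher; the package then computes J and its interior divergence
  m <- make_two_gene_motif(a = 0.5)
  D <- 0.05
  gx <- seq(0.005, 2.495, length.out = 50); gy <- gx
  hx <- gx[2] - gx[1]
  fc <- grnland:::force_closures(m$network, m$params)
  xf <- (gx[-1] + gx[-50]) / 2
  Fx_face <- outer(xf, gy, Vectorize(function(x, y) fc$F(c(x, y))[1]))
  Fy_face <- outer(gx, xf, Vectorize(function(x, y) fc$F(c(x, y))[2]))
  P <- fp_steady_state(gx, gy, Fx_face, Fy_face, D, dt = 2e-4,
                       n_iter = 20000, n_polish = 15000)
  land <- potential_from_probability(
    grnland:::new_landscape(gx, gy, P, c("GATA1", "PU1"), "fp"))
  fg <- force_grid(m$network, m$params, land)
  fl <- flux_2d(land, fg$Fx, fg$Fy, D)
  inner <- 4:47
  ratio <- sum(abs(fl$div[inner, inner])) * hx /
    sum(sqrt(fl$Jx[inner, inner]^2 + fl$Jy[inner, inner]^2))
  expect_lt(ratio, 0.02)
  # and the curl flux itself is NOT zero (nonequilibrium system)
  expect_gt(sum(sqrt(fl$Jx[inner, inner]^2 + fl$Jy[inner, inner]^2)) * hx,
            2e-3)
})

test_that("mean-field and Langevin landscapes agree globally on the motif", {
  m <- make_two_gene_motif(a = 0.5)
  D <- 0.05
  att <- find_attractors(m$network, m$params, n_starts = 300, seed = 1)
  basins <- lapply(seq_len(2), function(i) {
    b <- propagate_moments(m$network, m$params, att$states[i, ], D)
    b$weight <- att$weights[i]; b
  })
  lmf <- mixture_probability(basins, c("GATA1", "PU1"), m$network, bins = 60)
  cfg <- sim_config(dt = 0.01, steps = 6e6, D = D, seed = 2, record_every = 10)
  tr <- simulate_network(m$network, m$params, att$states[1, ], cfg)
  llv <- histogram_landscape(tr, c("GATA1", "PU1"), bins = 60,
                             lims = list(x = c(0, 2.5), y = c(0, 2.5)))
  keep <- llv$P > stats::quantile(llv$P[llv$P > 0], 0.10)
  expect_gte(stats::cor(lmf$U[keep], llv$U[keep], method = "spearman"), 0.7)
})
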