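test_that("the two-gene motif is built with the canonical constants", {
  m <- make_two_gene_motif(a = 1.2)
  expect_equal(nrow(m$network$nodes), 2)
  expect_equal(nrow(m$network$edges), 4)
  expect_equal(sum(m$network$edges$sign == "act"), 2)
  expect_equal(m$params$a, 1.2)
  expect_equal(m$params$b, 1)
  expect_equal(m$params$S, 0.5)
  expect_equal(m$params$n, 4)
  expect_equal(m$config$D, 0.05)
  expect_error(make_two_gene_motif(a = -1), "a > 0")
  # gene-swap symmetry of the force field
  p <- m$params
  for (r in 1:5) {
    x <- stats::runif(2, 0, 2.5)
    expect_equal(grn_force(m$network, p, x), rev(grn_force(m$network, p, rev(x))))
  }
})

test_that("the packaged 52-gene network matches its published totals", {
  net <- make_stemcell_network()
  expect_equal(nrow(net$nodes), 52)
  expect_equal(nrow(net$edges), 123)
  expect_equal(sum(net$edges$sign == "act"), 84)
  expect_equal(sum(net$edges$sign == "rep"), 39)
  expect_equal(sum(net$nodes$role == "stem_marker"), 11)
  expect_equal(sum(net$nodes$role == "diff_marker"), 11)
  # gene order numbers fixed by the published link tables
  expect_equal(net$nodes$name[c(1:5, 7, 11, 16, 22)],
               c("OCT4", "SOX2", "NANOG", "OCT4SOX2", "KLF4", "ZIC3",
                 "PBX1", "GATA6", "CDX2"))
  # text-mandated links present
  has_edge <- function(s, t, sign)
    any(net$edges$source == match(s, net$nodes$name) &
        net$edges$target == match(t, net$nodes$name) &
        net$edges$sign == sign)
  expect_true(has_edge("CDX2", "OCT4", "rep"))       # key repression R1
  expect_true(has_edge("OCT4", "GATA6", "rep"))
  expect_true(has_edge("NANOG", "GATA6", "rep"))
  expect_true(has_edge("GATA4", "GATA6", "rep"))
  expect_true(has_edge("LMCD1", "GATA6", "rep"))
  expect_true(has_edge("PRDM14", "GATA6", "rep"))
  expect_true(has_edge("GATA6", "NANOG", "rep"))     # mutual antagonism
  expect_true(has_edge("OCT4", "CDX2", "rep"))
  for (s in c("NANOG", "GATA6", "CDX2"))             # self-activations
    expect_true(has_edge(s, s, "act"))
  # the 14 key activations
  A <- list(c("NANOG", "OCT4"), c("OCT4SOX2", "OCT4"), c("NANOG", "SOX2"),
            c("OCT4SOX2", "SOX2"), c("NANOG", "NANOG"), c("OCT4SOX2", "NANOG"),
            c("KLF4", "NANOG"), c("ZIC3", "NANOG"), c("PBX1", "NANOG"),
            c("OCT4", "OCT4SOX2"), c("SOX2", "OCT4SOX2"), c("SOX2", "ZIC3"),
            c("NANOG", "ZIC3"), c("NANOG", "PBX1"))
  for (a in A) expect_true(has_edge(a[1], a[2], "act"))
  expect_true(all(net$edges$provenance %in% c("text", "figure")))
  # regeneration is stable (integrity-checked construction)
  expect_identical(make_stemcell_network()$edges, net$edges)
})

test_that("the packaged fixture file round-trips to the generated network", {
  net <- make_stemcell_network()
  f <- system.file("extdata", "stemcell52.tsv", package = "grnland")
  fa <- system.file("extdata", "stemcell52_nodes.tsv", package = "grnland")
  expect_true(nzchar(f))
  disk <- read_network(f, annotations_path = fa)
  expect_identical(disk$nodes, net$nodes)
  expect_identical(disk$edges[, c("source", "target", "sign")],
                   net$edges[, c("source", "target", "sign")])
})

test_that("random toggle networks are deterministic and bistable", {
  expect_error(make_random_toggle_network(0), "n_per_side")
  n1 <- make_random_toggle_network(1, 0, seed = 4)
  expect_equal(nrow(n1$nodes), 4)
  expect_identical(make_random_toggle_network(1, 0, seed = 4)$edges, n1$edges)
  expect_false(identical(make_random_toggle_network(1, 0, seed = 5)$edges,
                         n1$edges))
  # no isolated nodes, no duplicate edges
  n2 <- make_random_toggle_network(2, 3, seed = 1)
  deg <- tabulate(c(n2$edges$source, n2$edges$target), nrow(n2$nodes))
  expect_true(all(deg > 0))
  expect_equal(anyDuplicated(n2$edges[, c("source", "target", "sign")]), 0)
  att <- find_attractors(n2, hill_params(a = 0.3, b = 0.5),
                         n_starts = 500, seed = 2)
  expect_equal(nrow(att$states), 2)
})

test_that("the double-well oracle is self-consistent", {
  dw <- make_double_well_oracle(h = 0.25, D = 0.05)
  expect_equal(dw$V(0) - dw$V(1), 0.25)            # barrier is exactly h
  expect_equal(dw$force(0.5), -4 * 0.25 * 0.5 * (0.25 - 1))
  # Boltzmann-constructed grid landscape recovers h within one cell
  gx <- seq(-1.8, 1.8, length.out = 121)
  P <- exp(-dw$V(gx) / dw$D)
  U2 <- -log(pmax(outer(P / sum(P), rep(1 / 3, 3)), 1e-300))
  br <- barrier_heights(U2)
  cell_dU <- max(abs(base::diff(-dw$V(gx) / dw$D)))
  expect_lt(abs(br$barrier1 * dw$D - dw$h), cell_dU * dw$D)
  # quadrature MFPT is finite and grows as noise shrinks
  t1 <- make_double_well_oracle(0.25, 0.06)$mfpt(-1, 1)
  t2 <- make_double_well_oracle(0.25, 0.04)$mfpt(-1, 1)
  expect_true(is.finite(t1) && is.finite(t2))
  expect_gt(t2, t1)
})
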