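test_that("link perturbation rescales exactly one Hill term", {
  m <- make_two_gene_motif(a = 0.5)
  net <- m$network; p <- m$params
  # delta = 0: identical dynamics everywhere
  n0 <- perturb_link(net, "GATA1", "PU1", "rep", 0, p)
  for (r in 1:5) {
    x <- stats::runif(2, 0, 2.5)
    expect_identical(grn_force(n0, p, x), grn_force(net, p, x))
  }
  # delta = +0.5 scales that one term by 1.5
  n1 <- perturb_link(net, "GATA1", "GATA1", "act", 0.5, p)
  x <- c(0.8, 0.3)
  hu <- x[1]^4 / (0.5^4 + x[1]^4)
  expect_equal(grn_force(n1, p, x)[1] - grn_force(net, p, x)[1], 0.5 * p$a * hu)
  expect_equal(grn_force(n1, p, x)[2], grn_force(net, p, x)[2])
  expect_error(perturb_link(net, "GATA1", "PU1", "rep", -1, p), "> -1")
})

test_that("gene knockdown removes production and leaves decay", {
  net <- make_stemcell_network()
  kd <- knockdown_gene(net, "GATA6")
  expect_equal(sum(kd$edges$target == 16), 0)
  expect_gt(sum(kd$edges$source == 16), 0)   # outgoing links remain
  # an isolated knocked-down gene decays exponentially at rate k
  g1 <- knockdown_gene(isolated_gene(), "G")
  tr <- simulate_network(g1, hill_params(k = 1), 1,
                         sim_config(dt = 0.001, steps = 2000, D = 0))
  expect_equal(unname(tr[nrow(tr), 1]), exp(-2), tolerance = 3e-3)
  expect_error(knockdown_gene(net, "NOPE"), "unknown")
})

test_that("marker knockdowns shift global stability in opposite directions", {
  net <- make_stemcell_network()
  p <- stemcell_params()
  # differentiation-marker knockdown stabilizes the stem state: the
  # differentiated basin shrinks away entirely
  att_g6 <- find_attractors(knockdown_gene(knockdown_gene(net, "GATA6"),
                                           "CDX2"),
                            p, n_starts = 2000, seed = 11)
  expect_equal(nrow(att_g6$states), 1)
  expect_gt(att_g6$states[1, "NANOG"], att_g6$states[1, "GATA6"])
  # stem-marker knockdown promotes differentiation: the stem basin loses
  # weight (here it vanishes and the differentiated fate takes over)
  att_ng <- find_attractors(knockdown_gene(net, "NANOG"), p,
                            n_starts = 2000, seed = 11)
  top <- att_ng$states[which.max(att_ng$weights), ]
  expect_gt(top["GATA6"], top["NANOG"])
})

test_that("a zero-perturbation scan leaves every metric unchanged", {
  net <- make_random_toggle_network(1, 0, seed = 1)
  p <- hill_params(a = 0.5, b = 0.5)
  targets <- data.frame(source = c("HUB1", "HUB2"),
                        target = c("HUB1", "HUB2"),
                        sign = c("act", "act"), stringsAsFactors = FALSE)
  cfg <- sim_config(dt = 0.01, steps = 1e6, D = 0.05, seed = 31)
  sc <- sensitivity_scan(net, p, targets, delta = 0, cfg = cfg,
                         axes = c("HUB1", "HUB2"))
  expect_true(all(sc$ok))
  expect_true(all(sc$delta_barrier_stem == 0))
  expect_true(all(sc$delta_barrier_diff == 0))
  expect_true(all(sc$delta_mfpt_diff == 0))
  expect_true(all(sc$delta_mfpt_repro == 0))
})

test_that("strengthening a repression tilts the landscape the expected way", {
  # In this rate law the repression constant scales the production that
  # is RELEASED when the repressor is low, so strengthening the stem
  # hub's repression of the differentiated hub deepens the TARGET's own
  # high state (the differentiated basin) and flattens the stem basin.
  # Verified against direct barrier recomputation at +/-20%.
  net <- make_random_toggle_network(1, 0, seed = 1)
  p <- hill_params(a = 0.5, b = 0.5)
  cfg <- sim_config(dt = 0.01, steps = 2e6, D = 0.05, seed = 31)
  targets <- data.frame(source = c("HUB1", "HUB1"),
                        target = c("HUB2", "HUB2"),
                        sign = "rep", stringsAsFactors = FALSE)
  up <- sensitivity_scan(net, p, targets[1, ], delta = 0.2, cfg = cfg,
                         axes = c("HUB1", "HUB2"))
  dn <- sensitivity_scan(net, p, targets[2, ], delta = -0.2, cfg = cfg,
                         axes = c("HUB1", "HUB2"))
  expect_true(up$ok && dn$ok)
  expect_lt(up$delta_barrier_stem, 0)
  expect_gt(up$delta_barrier_diff, 0)
  # and the -20% perturbation moves every barrier the opposite way
  expect_gt(dn$delta_barrier_stem, 0)
  expect_lt(dn$delta_barrier_diff, 0)
})

test_that("links are ranked by total barrier impact", {
  rec <- data.frame(target = c("L1", "L2", "L3"), delta = 0.2, ok = TRUE,
                    delta_barrier_stem = c(0.5, 0.1, 0.3),
                    delta_barrier_diff = 0,
                    delta_mfpt_diff = NA, delta_mfpt_repro = NA)
  class(rec) <- c("grn_sensitivity", class(rec))
  expect_equal(rank_links(rec)$target, c("L1", "L3", "L2"))
  expect_equal(nrow(rank_links(rec, top_k = 1)), 1)
  expect_equal(rank_links(rec[1, ])$target, "L1")
  rec$delta <- c(0.2, 0.2, 0.3)
  expect_error(rank_links(rec), "mix")
  # a strong cross-repression outranks a weak one on the toggle
  net <- make_random_toggle_network(1, 0, seed = 1)
  net <- set_link_strength(net, "HUB1", "HUB2", "rep", 0.6)
  net <- set_link_strength(net, "HUB2", "HUB1", "rep", 0.25)
  p <- hill_params(a = 0.5, b = 0.5)
  cfg <- sim_config(dt = 0.01, steps = 2e6, D = 0.05, seed = 41)
  targets <- data.frame(source = c("HUB1", "HUB2"),
                        target = c("HUB2", "HUB1"),
                        sign = "rep", stringsAsFactors = FALSE)
  sc <- sensitivity_scan(net, p, targets, delta = 0.2,
                         metrics = "barrier", cfg = cfg,
                         axes = c("HUB1", "HUB2"))
  expect_equal(rank_links(sc)$target[1], "HUB1-|HUB2")
})

test_that("annealing validates schedules and detects hysteresis", {
  expect_error(anneal_schedule(0.5, 0.5), "differ")
  m <- make_two_gene_motif(a = 0.5)
  net <- set_link_strength(m$network, "PU1", "GATA1", "rep", 0.3)
  a1_edge <- which(net$edges$source == 1 & net$edges$target == 1 &
                   net$edges$sign == "act")
  stem_ref <- c(1.6893384, 0.0076154)
  diff_ref <- c(0.0037189, 1.4938019)
  sch <- anneal_schedule(1.4, 0.1, rate = 5e-4)
  an <- anneal_activation(net, m$params, sch,
                          sim_config(dt = 0.01, D = 0.01, seed = 1,
                                     record_every = 20),
                          stem_ref, diff_ref, schedule_edges = a1_edge)
  expect_lt(an$a_c1, an$a_c2)
  expect_true(an$a_c1 >= 0.1 && an$a_c1 <= 1.4)
})

test_that("slower ramps push the jump toward the deterministic fold", {
  # continuation oracle: track the stem-like fixed point while lowering
  # the self-activation until Newton loses it -- the fold location
  m <- make_two_gene_motif(a = 0.5)
  net <- set_link_strength(m$network, "PU1", "GATA1", "rep", 0.3)
  p <- m$params
  fold <- NA
  x <- c(1.6893384, 0.0076154)
  for (a1 in seq(1.4, 0.05, by = -0.01)) {
    neta <- set_link_strength(net, "GATA1", "GATA1", "act", a1)
    x_new <- grnland:::newton_polish(neta, p, x)
    if (is.null(x_new) || x_new[1] < 0.5) { fold <- a1; break }
    x <- x_new
  }
  expect_false(is.na(fold))
  # with nearly deterministic dynamics, halving the ramp rate twice moves
  # the down-sweep jump monotonically toward (up to) the fold
  a1_edge <- which(net$edges$source == 1 & net$edges$target == 1 &
                   net$edges$sign == "act")
  stem_ref <- c(1.6893384, 0.0076154); diff_ref <- c(0.0037189, 1.4938019)
  acs <- sapply(c(4e-3, 2e-3, 1e-3), function(rate) {
    an <- anneal_activation(net, p, anneal_schedule(1.4, 0.1, rate = rate),
                            sim_config(dt = 0.01, D = 5e-4, seed = 3,
                                       record_every = 20),
                            stem_ref, diff_ref, schedule_edges = a1_edge,
                            sweeps = "forward")
    an$a_c1
  })
  expect_true(all(diff(acs) > 0))
  expect_true(all(acs <= fold + 0.05))
})
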