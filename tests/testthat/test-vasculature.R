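spec10 <- lattice_spec(c(10L, 10L, 10L))

test_that("Poiseuille conductance follows the quartic law", {
  g0 <- segment_conductance(10, 40, 1e-3)
  expect_equal(segment_conductance(20, 40, 1e-3) / g0, 16)
  expect_equal(segment_conductance(10, 80, 1e-3) / g0, 0.5)
  expect_equal(g0, pi * 10^4 / (8 * 1e-3 * 40))
  expect_error(segment_conductance(-1, 40, 1e-3), "positive")
})

test_that("in-vivo viscosity law: monotone in haematocrit, published value at d=10", {
  expect_gte(relative_viscosity(24, 0), 1)
  expect_gt(relative_viscosity(24, 0.45), relative_viscosity(24, 0.30))
  # independent evaluation of the published in-vivo law at d = 10, H = 0.45
  d <- 10
  mu45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  dfac <- (d / (d - 1.1))^2  # endothelial wall-layer factor
  expected <- (1 + (mu45 - 1) * dfac) * dfac  # H-ratio term is 1 at H = 0.45
  expect_equal(relative_viscosity(10, 0.45), expected, tolerance = 1e-12)
  expect_error(relative_viscosity(10, 1.2), "haematocrit")
})

test_that("single-segment flow matches the closed form", {
  net <- straight_net(spec10, n = 2L, p_in = 30, p_out = 20, radius = 10)
  net <- solve_flow(net)
  seg <- net$segments
  mu <- 1.2e-3 * relative_viscosity(20, 0)
  G <- segment_conductance(10, 40, mu)      # um^3/(Pa s)
  q_expect <- G * 10 * 133.322 * 60          # um^3/min
  expect_equal(seg$flow, q_expect, tolerance = 1e-10)
  expect_gt(seg$flow, 0)  # from node 1 (high P) to node 2
})

test_that("symmetric Y-bifurcation splits the parent flow in half", {
  net <- solve_flow(y_net(spec10))
  seg <- net$segments
  expect_equal(abs(seg$flow[2]), abs(seg$flow[1]) / 2, tolerance = 1e-10)
  expect_equal(abs(seg$flow[3]), abs(seg$flow[1]) / 2, tolerance = 1e-10)
})

test_that("sparse flow solve matches a dense Kirchhoff oracle", {
  set.seed(31)
  for (rep in 1:10) {
    net <- random_net(spec10, n_nodes = 6L)
    sol <- solve_flow(net)
    oracle_p <- dense_flow_oracle(net, spec10)
    expect_lt(max(abs(sol$nodes$p - oracle_p)) / max(abs(oracle_p)), 1e-10)
    expect_lt(tumorvasc:::flow_imbalance(sol), 1e-10)
  }
})

test_that("flow solve rejects networks without prescribed pressures", {
  nodes <- data.frame(id = 1:2, i = c(0L, 1L), j = 0L, k = 0L,
                      role = "interior", pressure = NA_real_,
                      h_in = NA_real_)
  segs <- data.frame(a = 1L, b = 2L, radius = 10)
  net <- new_vascular_network(nodes, segs, spec10)
  expect_error(solve_flow(net), "singular|pressure-prescribed")
  # tolerated when explicitly requested: zero flow, unperfused
  z <- solve_flow(net, on_floating = "zero")
  expect_equal(z$segments$flow, 0)
  expect_false(z$segments$perfused)
})

test_that("haematocrit propagates with red-cell flux conservation", {
  # single path: every segment carries the inlet haematocrit
  net <- straight_net(spec10, n = 5L)
  net <- propagate_haematocrit(solve_flow(net))
  expect_equal(net$segments$haematocrit, rep(0.45, 4))
  # symmetric bifurcation: both daughters carry the parent haematocrit
  net <- propagate_haematocrit(solve_flow(y_net(spec10)))
  expect_equal(net$segments$haematocrit, rep(0.45, 3))
  # random networks: inlet and outlet red-cell fluxes balance to 1e-10
  set.seed(77)
  for (rep in 1:10) {
    net <- propagate_haematocrit(solve_flow(random_net(spec10, 8L)))
    seg <- net$segments; nodes <- net$nodes
    ia <- match(seg$a, nodes$id); ib <- match(seg$b, nodes$id)
    rbc <- abs(seg$flow) * seg$haematocrit
    up <- ifelse(seg$flow >= 0, ia, ib); dn <- ifelse(seg$flow >= 0, ib, ia)
    # per-node conservation at interior nodes
    for (v in which(nodes$role == "interior")) {
      rin <- sum(rbc[dn == v]); rout <- sum(rbc[up == v])
      expect_lt(abs(rin - rout) / max(rbc, 1e-12), 1e-10)
    }
    # global balance: net red-cell flux over all boundary nodes is zero
    net_bnd <- 0
    for (v in which(nodes$role != "interior"))
      net_bnd <- net_bnd + sum(rbc[up == v]) - sum(rbc[dn == v])
    expect_lt(abs(net_bnd) / max(rbc, 1e-12), 1e-10)
  }
})

test_that("wall shear stress obeys both equivalent formulas", {
  net <- propagate_haematocrit(solve_flow(straight_net(spec10, n = 4L)))
  net <- solve_flow(net)  # refresh with updated viscosity
  seg <- net$segments; nodes <- net$nodes
  ia <- match(seg$a, nodes$id); ib <- match(seg$b, nodes$id)
  dp_pa <- abs(nodes$p[ia] - nodes$p[ib]) * 133.322
  tau_alt <- dp_pa * seg$radius / (2 * seg$length) * 10  # dyn/cm^2
  expect_equal(wall_shear_stress(net), tau_alt, tolerance = 1e-12)
  # zero flow gives zero shear
  z <- straight_net(spec10, n = 3L, p_in = 25, p_out = 25)
  z <- solve_flow(z)
  expect_equal(wall_shear_stress(z), c(0, 0))
  # doubling the pressure drop doubles the shear (same plasma viscosity)
  n1 <- solve_flow(straight_net(spec10, n = 4L))
  n2 <- solve_flow(straight_net(spec10, n = 4L, p_in = 40, p_out = 20))
  expect_equal(wall_shear_stress(n2), 2 * wall_shear_stress(n1),
               tolerance = 1e-10)
})

test_that("radius adaptation is one multiplicative pass with clamping", {
  params <- vessel_params()
  params$enable_wss <- FALSE; params$enable_pressure <- FALSE
  params$enable_metabolic <- FALSE; params$enable_shrink <- FALSE
  net <- propagate_haematocrit(solve_flow(straight_net(spec10, n = 4L)))
  r0 <- net$segments$radius
  # all stimuli off: identity
  net1 <- adapt_radius(net, o2 = 0.2, dt = 30, spec10, params)
  expect_identical(net1$segments$radius, r0)
  # shrink-only: two steps give exactly R (1 - dt k_s)^2 (no equilibration)
  params$enable_shrink <- TRUE
  s <- -params$k_shrink
  n1 <- adapt_radius(net, 0.2, 30, spec10, params)
  n2 <- adapt_radius(n1, 0.2, 30, spec10, params)
  expect_equal(n2$segments$radius, r0 * (1 + 30 * s)^2, tolerance = 1e-12)
  # clamping at r_max
  params$enable_shrink <- FALSE; params$enable_wss <- TRUE
  params$k_wss <- 1  # huge growth stimulus
  big <- adapt_radius(net, 0.2, 30, spec10, params)
  expect_true(all(big$segments$radius == params$r_max))
  still <- adapt_radius(big, 0.2, 30, spec10, params)
  expect_true(all(still$segments$radius == params$r_max))
})

test_that("pruning clock semantics: accumulate, reset, remove", {
  params <- vessel_params()
  # zero-flow segment with clock already at t_prune is removed after a step
  net <- solve_flow(straight_net(spec10, n = 3L, p_in = 25, p_out = 25))
  net$segments$clock <- params$t_prune
  pruned <- prune_vessels(net, dt = 30, params)
  expect_equal(nrow(pruned$segments), 0L)
  # interior node orphaned by the removal disappears, boundary nodes stay
  expect_true(all(pruned$nodes$role != "interior"))
  # a segment at or above tau_crit resets its clock and is retained
  net2 <- solve_flow(straight_net(spec10, n = 3L))
  expect_true(all(net2$segments$wss >= params$tau_crit))
  net2$segments$clock <- params$t_prune - 1
  kept <- prune_vessels(net2, dt = 30, params)
  expect_equal(nrow(kept$segments), 2L)
  expect_equal(kept$segments$clock, c(0, 0))
})

test_that("a dying middle segment leaves stubs that then starve", {
  # three-segment path; kill the middle one and re-solve: the stubs carry no
  # flow, become unperfused and start accumulating clock
  params <- vessel_params()
  net <- solve_flow(straight_net(spec10, n = 4L))
  expect_true(all(net$segments$perfused))
  net$segments <- net$segments[-2L, ]
  net <- solve_flow(net, q_floor = params$q_floor)
  expect_false(any(net$segments$perfused))
  step1 <- prune_vessels(net, 30, params)
  expect_equal(step1$segments$clock, c(30, 30))
  # removing a zero-flow segment leaves the other flows unchanged
  full <- solve_flow(y_net(spec10))
  aug <- full
  # dangling zero-flow stub: new interior node hanging off node 2
  aug$nodes <- rbind(aug$nodes,
                     data.frame(id = 9L, i = 1L, j = 2L, k = 0L,
                                role = "interior", pressure = NA_real_,
                                h_in = NA_real_,
                                lin = tumorvasc:::site_lin(c(1L, 2L, 0L),
                                                           spec10),
                                p = NA_real_))
  aug$segments <- rbind(aug$segments,
                        data.frame(a = 2L, b = 9L, radius = 8, length = 40,
                                   flow = 0, haematocrit = 0, wss = 0,
                                   clock = 0, perfused = FALSE))
  aug <- solve_flow(aug)
  expect_equal(aug$segments$flow[1:3], full$segments$flow, tolerance = 1e-10)
})

test_that("network snapshot tables round-trip exactly", {
  # simulated networks have unit-length segments between lattice sites, so
  # export -> import reproduces the graph exactly
  net <- straight_net(spec10, n = 6L)
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  write_network_tables(net, spec10, nf, ef)
  tabs <- read_network_tables(nf, ef)
  re <- import_network(tabs$nodes, tabs$edges, spec10)
  expect_equal(sort(as.integer(re$nodes$lin)), sort(as.integer(net$nodes$lin)))
  expect_equal(nrow(re$segments), nrow(net$segments))
  expect_equal(re$segments$radius, net$segments$radius)
  expect_identical(re$nodes$role, net$nodes$role)
  unlink(c(nf, ef))
})
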