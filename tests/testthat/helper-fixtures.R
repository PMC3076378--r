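# Shared fixtures: tiny configs and hand-built networks used across tests.

small_growth_config <- function(dims = c(10L, 10L, 10L),
                                implant = list(centre = c(4L, 4L, 6L),
                                               half = 1L), ...) {
  default_config(list(lattice = list(dims = dims),
                      scenario = list(implant = implant), ...))
}

# implant placed in the recoverable hypoxic band between the vessels: the
# regime of the elimination studies (all cells arrest early; survival needs
# re-oxygenation before the quiescence clock runs out)
hostile_config <- function(p_o2 = 3116, dims = c(10L, 10L, 10L)) {
  cfg <- default_config(list(lattice = list(dims = dims),
                             scenario = list(implant = list(
                               centre = c(4L, 7L, 5L), half = 1L))))
  cfg$fields$p_o2 <- p_o2
  cfg
}

# one straight vessel: n nodes along x, inlet at x0 (pressure p_in), outlet
# at the far end
straight_net <- function(spec, n = 5L, p_in = 30, p_out = 20, radius = 10,
                         h_in = 0.45, j = 0L, k = 0L) {
  nodes <- data.frame(id = seq_len(n), i = 0:(n - 1L), j = j, k = k,
                      role = c("inlet", rep("interior", n - 2L), "outlet"),
                      pressure = c(p_in, rep(NA, n - 2L), p_out),
                      h_in = c(h_in, rep(NA, n - 1L)))
  segs <- data.frame(a = 1:(n - 1L), b = 2:n, radius = radius)
  new_vascular_network(nodes, segs, spec)
}

# symmetric Y bifurcation: inlet -> junction -> two identical daughters to
# equal-pressure outlets
y_net <- function(spec, radius = 8) {
  nodes <- data.frame(
    id = 1:4,
    i = c(0L, 1L, 2L, 2L), j = c(1L, 1L, 0L, 2L), k = 0L,
    role = c("inlet", "interior", "outlet", "outlet"),
    pressure = c(30, NA, 20, 20),
    h_in = c(0.45, NA, NA, NA))
  segs <- data.frame(a = c(1L, 2L, 2L), b = c(2L, 3L, 4L), radius = radius)
  new_vascular_network(nodes, segs, spec)
}

# random connected network on <= n_nodes lattice sites with 1 inlet and 1-2
# outlets; used by the flow-solver oracle sweeps
random_net <- function(spec, n_nodes = 8L, radius_range = c(4, 12)) {
  repeat {
    sites <- unique(cbind(sample(0:(spec$dims[1] - 1L), n_nodes * 2,
                                 replace = TRUE),
                          sample(0:(spec$dims[2] - 1L), n_nodes * 2,
                                 replace = TRUE),
                          sample(0:(spec$dims[3] - 1L), n_nodes * 2,
                                 replace = TRUE)))
    if (nrow(sites) >= n_nodes) break
  }
  sites <- sites[seq_len(n_nodes), , drop = FALSE]
  a <- integer(0); b <- integer(0)
  for (v in 2:n_nodes) {  # random spanning tree
    a <- c(a, v); b <- c(b, sample.int(v - 1L, 1L))
  }
  extra <- sample.int(n_nodes, 2L)
  if (extra[1] != extra[2] &&
      !any((a == max(extra) & b == min(extra)) |
             (a == min(extra) & b == max(extra)))) {
    a <- c(a, extra[1]); b <- c(b, extra[2])
  }
  n_out <- sample(1:2, 1L)
  role <- rep("interior", n_nodes)
  bnd <- sample.int(n_nodes, 1L + n_out)
  role[bnd[1L]] <- "inlet"
  role[bnd[-1L]] <- "outlet"
  pressure <- rep(NA_real_, n_nodes)
  pressure[bnd[1L]] <- 30 + runif(1, 0, 5)
  pressure[bnd[-1L]] <- 20 + runif(n_out, 0, 3)
  h_in <- ifelse(role == "inlet", 0.45, NA_real_)
  nodes <- data.frame(id = seq_len(n_nodes), i = sites[, 1], j = sites[, 2],
                      k = sites[, 3], role = role, pressure = pressure,
                      h_in = h_in)
  segs <- data.frame(a = a, b = b,
                     radius = runif(length(a), radius_range[1],
                                    radius_range[2]))
  new_vascular_network(nodes, segs, spec)
}

# Independent dense oracle for the Kirchhoff pressure system: build the
# nodal equations by hand (loops, base::solve) from the same conductances.
dense_flow_oracle <- function(net, spec, mu_plasma_cP = 1.2) {
  nodes <- net$nodes; seg <- net$segments
  nn <- nrow(nodes)
  mu <- mu_plasma_cP * 1e-3 *
    relative_viscosity(2 * seg$radius, pmin(pmax(seg$haematocrit, 0), 1))
  G <- pi * seg$radius^4 / (8 * mu * seg$length)
  A <- matrix(0, nn, nn); rhs <- numeric(nn)
  for (v in seq_len(nn)) {
    if (nodes$role[v] != "interior") {
      A[v, v] <- 1
      rhs[v] <- nodes$pressure[v] * 133.322
    } else {
      for (s in seq_len(nrow(seg))) {
        ia <- match(seg$a[s], nodes$id); ib <- match(seg$b[s], nodes$id)
        if (ia == v) { A[v, v] <- A[v, v] + G[s]; A[v, ib] <- A[v, ib] - G[s] }
        if (ib == v) { A[v, v] <- A[v, v] + G[s]; A[v, ia] <- A[v, ia] - G[s] }
      }
    }
  }
  solve(A, rhs) / 133.322  # mmHg
}
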