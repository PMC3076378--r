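# Unit conventions for haemodynamics: lengths um, pressures mmHg at the
# interface (converted to Pa internally), viscosity Pa.s internally
# (plasma viscosity given in cP), flows reported in um^3/min, wall shear
# stress in dyn/cm^2.
.MMHG_PA <- 133.322
.PA_DYN_CM2 <- 10

#' Construct a vascular network
#'
#' The network is a graph of nodes at lattice sites and segments connecting
#' face-adjacent nodes. Inlet/outlet nodes carry prescribed pressures; inlets
#' additionally carry the inflow haematocrit.
#'
#' @param nodes data.frame with columns \code{id} (unique integers), \code{i,
#'   j, k} (0-based canonical site coordinates), \code{role} one of
#'   \code{"interior"}, \code{"inlet"}, \code{"outlet"}, \code{pressure}
#'   (mmHg, finite for inlet/outlet, NA for interior) and \code{h_in}
#'   (inflow haematocrit, finite in \[0,1\] for inlets).
#' @param segments data.frame with columns \code{a}, \code{b} (node ids) and
#'   \code{radius} (um). Flow-state columns (\code{flow}, \code{haematocrit},
#'   \code{wss}, \code{clock}, \code{perfused}) are added if absent.
#' @param spec a [lattice_spec()]; segment lengths are minimal-image
#'   distances under its boundary conditions.
#' @return object of class \code{"vascular_network"}.
#' @export
new_vascular_network <- function(nodes, segments, spec) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$role %in% c("interior", "inlet", "outlet")))
    stop("node role must be interior/inlet/outlet")
  bnd <- nodes$role != "interior"
  if (any(!is.finite(nodes$pressure[bnd])))
    stop("inlet/outlet nodes must carry a finite pressure")
  if (is.null(nodes$h_in)) nodes$h_in <- NA_real_
  inl <- nodes$role == "inlet"
  if (any(!is.finite(nodes$h_in[inl]) | nodes$h_in[inl] < 0 |
          nodes$h_in[inl] > 1))
    stop("inlet nodes must carry inflow haematocrit in [0,1]")
  nodes$lin <- site_lin(as.matrix(nodes[, c("i", "j", "k")]), spec)
  if (nrow(segments) > 0L) {
    if (!all(c(segments$a, segments$b) %in% nodes$id))
      stop("segment endpoint references a missing node")
    if (any(segments$a == segments$b)) stop("self-loop segment")
    key <- paste(pmin(segments$a, segments$b), pmax(segments$a, segments$b))
    if (anyDuplicated(key)) stop("duplicate segment between a node pair")
    if (any(!is.finite(segments$radius) | segments$radius <= 0))
      stop("segment radii must be positive")
    ia <- match(segments$a, nodes$id); ib <- match(segments$b, nodes$id)
    L <- numeric(nrow(segments))
    for (s in seq_len(nrow(segments))) {
      L[s] <- sqrt(sum(wrapped_displacement(
        unlist(nodes[ia[s], c("i", "j", "k")]),
        unlist(nodes[ib[s], c("i", "j", "k")]), spec)^2))
    }
    if (any(L <= 0)) stop("zero-length segment (endpoints snap to one site)")
    segments$length <- L
  } else {
    segments <- data.frame(a = integer(0), b = integer(0),
                           radius = numeric(0), length = numeric(0))
  }
  for (col in c("flow", "haematocrit", "wss"))
    if (is.null(segments[[col]])) segments[[col]] <- rep(0, nrow(segments))
  if (is.null(segments$clock)) segments$clock <- rep(0, nrow(segments))
  if (is.null(segments$perfused))
    segments$perfused <- rep(FALSE, nrow(segments))
  structure(list(nodes = nodes, segments = segments),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf(
    "vascular_network: %d nodes (%d inlets, %d outlets), %d segments (%d perfused)\n",
    nrow(x$nodes), sum(x$nodes$role == "inlet"),
    sum(x$nodes$role == "outlet"), nrow(x$segments),
    sum(x$segments$perfused)))
  invisible(x)
}

#' Poiseuille conductance of a vessel segment
#'
#' \eqn{G = \pi R^4 / (8 \mu L)} in consistent units.
#'
#' @param R radius, \code{L} length, \code{mu} dynamic viscosity; all > 0.
#' @param L,mu see above.
#' @return conductance (volume flow per unit pressure drop).
#' @export
segment_conductance <- function(R, L, mu) {
  if (any(R <= 0) || any(L <= 0) || any(mu <= 0))
    stop("R, L and mu must all be positive")
  pi * R^4 / (8 * mu * L)
}

#' In-vivo relative apparent blood viscosity
#'
#' The empirical diameter- and haematocrit-dependent law for apparent blood
#' viscosity in microvessels in vivo (Pries et al. lineage): relative to
#' plasma, increasing in haematocrit, with the pronounced minimum near
#' 7-10 um diameter from the Fahraeus-Lindqvist effect.
#'
#' @param diameter vessel diameter in um (> 1.1).
#' @param haematocrit tube haematocrit in \[0, 1\].
#' @return viscosity multiplier relative to plasma (>= 1 at H = 0).
#' @export
relative_viscosity <- function(diameter, haematocrit) {
  if (any(haematocrit < 0 | haematocrit > 1))
    stop("haematocrit must lie in [0,1]")
  if (any(diameter <= 1.1)) stop("diameter must exceed 1.1 um")
  d <- diameter
  mu45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  dfac <- (d / (d - 1.1))^2
  (1 + (mu45 - 1) *
     (((1 - haematocrit)^cc - 1) / ((1 - 0.45)^cc - 1)) * dfac) * dfac
}

# apparent dynamic viscosity in Pa.s
segment_viscosity <- function(radius, haematocrit, mu_plasma_cP = 1.2) {
  mu_plasma_cP * 1e-3 * relative_viscosity(2 * radius, haematocrit)
}

#' Solve the Kirchhoff pressure/flow system of a vascular network
#'
#' Nodal pressures satisfy conservation of volumetric flow at every interior
#' node with Poiseuille conductances on segments; inlet/outlet pressures are
#' prescribed. Solved by direct sparse LU factorisation: perfusion decisions
#' (is a vessel flowing at all?) need higher accuracy than the iterative
#' field solves.
#'
#' @param net a [new_vascular_network()].
#' @param mu_plasma_cP plasma viscosity in centipoise (default 1.2).
#' @param q_floor flow magnitude (um^3/min) below which a segment is flagged
#'   unperfused.
#' @param on_floating what to do with connected components that contain no
#'   pressure-prescribed node: \code{"error"} (default; the system is
#'   singular) or \code{"zero"} (assign zero flow and unperfused status;
#'   used by the engine, where pruning can transiently orphan sub-networks).
#' @return the network with updated \code{nodes$p} (solved pressures, mmHg)
#'   and segment \code{flow} (um^3/min, signed a to b), \code{haematocrit}-
#'   dependent viscosity, \code{wss} (dyn/cm^2) and \code{perfused} flags.
#' @export
solve_flow <- function(net, mu_plasma_cP = 1.2, q_floor = 1e3,
                       on_floating = c("error", "zero")) {
  on_floating <- match.arg(on_floating)
  nodes <- net$nodes; seg <- net$segments
  nn <- nrow(nodes)
  nodes$p <- rep(NA_real_, nn)
  if (nrow(seg) == 0L) {
    bnd <- nodes$role != "interior"
    nodes$p[bnd] <- nodes$pressure[bnd]
    net$nodes <- nodes
    return(net)
  }
  ia <- match(seg$a, nodes$id); ib <- match(seg$b, nodes$id)
  mu <- segment_viscosity(seg$radius, pmin(pmax(seg$haematocrit, 0), 1),
                          mu_plasma_cP)
  G <- segment_conductance(seg$radius, seg$length, mu)  # um^3/(Pa s)

  # component analysis: every component needs a prescribed-pressure node
  g <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nn - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  bnd <- nodes$role != "interior"
  good_comp <- unique(comp[bnd])
  floating <- !(comp %in% good_comp)
  if (any(floating[c(ia, ib)]) && on_floating == "error")
    stop("network component without a pressure-prescribed node: singular flow system")
  solve_seg <- !(floating[ia] | floating[ib])

  fixed <- bnd & !floating
  if (!any(fixed)) {
    if (on_floating == "error")
      stop("no pressure-prescribed node in the network")
    seg$flow <- 0; seg$wss <- 0; seg$perfused <- FALSE
    net$nodes <- nodes; net$segments <- seg
    return(net)
  }
  ii <- c(ia[solve_seg], ib[solve_seg], ia[solve_seg], ib[solve_seg])
  jj <- c(ib[solve_seg], ia[solve_seg], ia[solve_seg], ib[solve_seg])
  Gs <- G[solve_seg]
  xx <- c(-Gs, -Gs, Gs, Gs)
  # overwrite rows of fixed nodes with identity
  keep <- !(fixed[ii])
  ii <- c(ii[keep], which(fixed)); jj <- c(jj[keep], which(fixed))
  xx <- c(xx[keep], rep(1, sum(fixed)))
  # floating nodes (if tolerated) get identity rows with zero rhs
  if (any(floating)) {
    ii <- c(ii, which(floating)); jj <- c(jj, which(floating))
    xx <- c(xx, rep(1, sum(floating)))
  }
  # isolated solvable interior nodes (no solve_seg touching them) also need
  # identity rows to keep the matrix nonsingular
  touched <- rep(FALSE, nn)
  touched[c(ia[solve_seg], ib[solve_seg])] <- TRUE
  lonely <- !touched & !fixed & !floating
  if (any(lonely)) {
    ii <- c(ii, which(lonely)); jj <- c(jj, which(lonely))
    xx <- c(xx, rep(1, sum(lonely)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  b <- numeric(nn)
  b[fixed] <- nodes$pressure[fixed] * .MMHG_PA
  p_pa <- as.numeric(Matrix::solve(A, b))
  nodes$p <- p_pa / .MMHG_PA

  q_s <- G * (p_pa[ia] - p_pa[ib])        # um^3/s, signed a->b
  q_s[!solve_seg] <- 0
  seg$flow <- q_s * 60                     # um^3/min
  tau_pa <- 4 * mu * abs(q_s) / (pi * seg$radius^3)
  seg$wss <- tau_pa * .PA_DYN_CM2
  seg$perfused <- abs(seg$flow) >= q_floor & solve_seg
  seg$wss[!solve_seg] <- 0
  net$nodes <- nodes
  net$segments <- seg
  net
}

# max relative flow imbalance over interior nodes (diagnostic / tests)
flow_imbalance <- function(net) {
  nodes <- net$nodes; seg <- net$segments
  if (nrow(seg) == 0L) return(0)
  ia <- match(seg$a, nodes$id); ib <- match(seg$b, nodes$id)
  bal <- numeric(nrow(nodes))
  bal <- bal + unname(tapply(c(-seg$flow, seg$flow), c(ia, ib), sum)[
    as.character(seq_len(nrow(nodes)))])
  bal[is.na(bal)] <- 0
  interior <- nodes$role == "interior"
  scale <- max(abs(seg$flow), 1e-300)
  max(abs(bal[interior]), 0) / scale
}

#' Propagate haematocrit through a solved network
#'
#' Red-cell flux is conserved at every node. At diverging bifurcations the
#' red-cell flux splits in proportion to the daughter volumetric flows (all
#' outflows of a node carry the node's mixed haematocrit). Because steady
#' Kirchhoff flow runs from high to low pressure, processing nodes in order
#' of decreasing solved pressure visits every segment's upstream node first;
#' no fixed-point iteration is needed. Unperfused segments get haematocrit 0.
#'
#' @param net a network with solved flows (see [solve_flow()]).
#' @return the network with updated segment \code{haematocrit}.
#' @export
propagate_haematocrit <- function(net) {
  nodes <- net$nodes; seg <- net$segments
  if (nrow(seg) == 0L) return(net)
  if (all(is.na(nodes$p))) stop("solve flows before propagating haematocrit")
  ia <- match(seg$a, nodes$id); ib <- match(seg$b, nodes$id)
  # orient by flow sign: from = upstream node
  from <- ifelse(seg$flow >= 0, ia, ib)
  to <- ifelse(seg$flow >= 0, ib, ia)
  H <- numeric(nrow(seg))
  q <- abs(seg$flow)
  live <- seg$perfused & q > 0
  ord <- order(-nodes$p)
  rbc_in <- numeric(nrow(nodes))
  q_in <- numeric(nrow(nodes))
  for (v in ord) {
    out_segs <- which(live & from == v)
    if (length(out_segs) == 0L) next
    q_out <- sum(q[out_segs])
    # red cells available to the outflows: the mixed upstream flux, plus the
    # prescribed-haematocrit supply at inlets; boundary nodes that emit more
    # than they receive supply plasma (dilution), never fabricate red cells
    avail <- rbc_in[v]
    if (nodes$role[v] == "inlet" && is.finite(nodes$h_in[v]))
      avail <- avail + max(q_out - q_in[v], 0) * nodes$h_in[v]
    h_node <- avail / max(q_in[v], q_out, 1e-300)
    h_node <- min(max(h_node, 0), 1)
    H[out_segs] <- h_node
    dst <- to[out_segs]
    rbc_add <- q[out_segs] * h_node
    for (s2 in seq_along(out_segs)) {
      rbc_in[dst[s2]] <- rbc_in[dst[s2]] + rbc_add[s2]
      q_in[dst[s2]] <- q_in[dst[s2]] + q[out_segs[s2]]
    }
  }
  H[!live] <- 0
  seg$haematocrit <- H
  net$segments <- seg
  net
}

#' Wall shear stress of vessel segments
#'
#' \eqn{\tau = 4 \mu |Q| / (\pi R^3)}, reported in dyn/cm^2; equals
#' \eqn{|\Delta P| R / (2 L)} for Poiseuille flow.
#'
#' @param net a network with solved flows.
#' @return numeric vector of per-segment wall shear stress (dyn/cm^2).
#' @export
wall_shear_stress <- function(net) net$segments$wss

#' Default vessel adaptation and pruning parameters
#'
#' Stimulus constants follow the structural-adaptation lineage (wall shear,
#' intravascular pressure, metabolic demand, shrinking tendency), rescaled to
#' per-minute units; each term can be switched off to study reduced models.
#' See the methods vignette for the functional forms and calibration.
#'
#' @return named list of parameters.
#' @export
vessel_params <- function() {
  list(
    r_min = 2,            # um
    r_max = 25,           # um
    r_init = 6,           # um, newly anastomosed vessels
    r_parent = 12,        # um, initial parent vessels
    mu_plasma_cP = 1.2,
    q_floor = 1e3,        # um^3/min: below this a segment is unperfused
    tau_crit = 3,         # dyn/cm^2: low-WSS pruning threshold
    t_prune = 600,        # min a segment may stay below tau_crit
    h_in = 0.45,          # inflow haematocrit
    k_wss = 5e-4, tau_ref = 1,      # 1/min, dyn/cm^2
    k_press = 5e-4, p_ref = 20,     # 1/min, mmHg
    k_met = 5e-4, q_ref = 2e5,      # 1/min, um^3/min RBC flux scale
    k_shrink = 6e-4,                # 1/min
    enable_wss = TRUE, enable_pressure = TRUE,
    enable_metabolic = TRUE, enable_shrink = TRUE
  )
}

# total adaptation stimulus (1/min) per perfused segment
adaptation_stimulus <- function(tau, p_mmhg, rbc_flux, local_o2, params) {
  s <- numeric(length(tau))
  if (params$enable_wss)
    s <- s + params$k_wss * log10(1 + tau / params$tau_ref)
  if (params$enable_pressure)
    s <- s - params$k_press * log10(1 + pmax(p_mmhg, 0) / params$p_ref)
  if (params$enable_metabolic)
    s <- s + params$k_met *
      log10(1 + params$q_ref / ((rbc_flux + 1) * (1 + pmax(local_o2, 0))))
  if (params$enable_shrink) s <- s - params$k_shrink
  s
}

#' Structural adaptation of vessel radii (one pass per time-step)
#'
#' Each perfused segment's radius is updated once per macro time-step,
#' \deqn{R \leftarrow \mathrm{clamp}(R (1 + \Delta t\, S_{tot}),\ R_{min},\ R_{max}),}
#' where the total stimulus sums a wall-shear term (growth under high shear),
#' a pressure set-point term (shrinkage at high pressure), a metabolic term
#' (growth where red-cell flux and local oxygen are low) and a constant
#' shrinking tendency. Radii are never iterated to a steady state within a
#' step: adaptation evolves on the same timescale as cell movement and
#' proliferation. Unperfused segments are left untouched (the pruning clock
#' handles them).
#'
#' @param net network with solved flows and haematocrit.
#' @param o2 oxygen field values in linear site order (or a scalar).
#' @param dt macro time-step (min).
#' @param spec a [lattice_spec()].
#' @param params see [vessel_params()].
#' @return network with updated radii.
#' @export
adapt_radius <- function(net, o2, dt, spec, params = vessel_params()) {
  seg <- net$segments
  if (nrow(seg) == 0L) return(net)
  o2 <- rep_len(as.numeric(o2), spec$n)
  ia <- match(seg$a, net$nodes$id); ib <- match(seg$b, net$nodes$id)
  o2_seg <- (o2[net$nodes$lin[ia]] + o2[net$nodes$lin[ib]]) / 2
  p_seg <- (net$nodes$p[ia] + net$nodes$p[ib]) / 2
  rbc <- abs(seg$flow) * seg$haematocrit
  s <- adaptation_stimulus(seg$wss, p_seg, rbc, o2_seg, params)
  if (any(!is.finite(s[seg$perfused]))) stop("non-finite adaptation stimulus")
  upd <- seg$perfused
  seg$radius[upd] <- pmin(pmax(seg$radius[upd] * (1 + dt * s[upd]),
                               params$r_min), params$r_max)
  net$segments <- seg
  net
}

#' Prune chronically low-shear or unperfused vessel segments
#'
#' Segments whose wall shear stress stays below \code{tau_crit} (or that are
#' unperfused) accumulate a low-flow clock; the clock resets whenever the
#' shear recovers. Segments whose clock reaches \code{t_prune} are removed
#' (a segment with zero flow from the start disappears after exactly
#' \code{ceiling(t_prune / dt)} steps), along with interior nodes left
#' without any segment.
#'
#' @param net network with current flows/WSS.
#' @param dt macro time-step (min).
#' @param params see [vessel_params()].
#' @return pruned network.
#' @export
prune_vessels <- function(net, dt, params = vessel_params()) {
  seg <- net$segments
  if (nrow(seg) == 0L) return(net)
  low <- (!seg$perfused) | seg$wss < params$tau_crit
  seg$clock <- ifelse(low, seg$clock + dt, 0)
  drop <- seg$clock >= params$t_prune
  seg <- seg[!drop, , drop = FALSE]
  keep_nodes <- net$nodes$role != "interior" |
    net$nodes$id %in% c(seg$a, seg$b)
  net$segments <- seg
  net$nodes <- net$nodes[keep_nodes, , drop = FALSE]
  net
}

# linear site indices covered by the network (segment endpoints)
vessel_site_lins <- function(net) {
  used <- net$nodes$id %in% c(net$segments$a, net$segments$b)
  unique(net$nodes$lin[used])
}

# refresh occupancy vessel mask from the network
update_vessel_occupancy <- function(occ, net) {
  occ$vessel[] <- FALSE
  occ$vessel[vessel_site_lins(net)] <- TRUE
  invisible(occ)
}

#' Write / read a vascular network as plain-text tables
#'
#' Nodes: \code{id, x_um, y_um, z_um, role, pressure_mmhg,
#' inflow_haematocrit}; edges: \code{a, b, radius_um}. This is also the
#' import format for experimentally derived graphs (see [import_network()]).
#' Integer-site networks round-trip exactly.
#'
#' @param net a [new_vascular_network()].
#' @param spec a [lattice_spec()] (site coordinates are scaled to um).
#' @param node_file,edge_file paths of the tab-delimited output files.
#' @return invisibly, the list of the two data.frames.
#' @export
write_network_tables <- function(net, spec, node_file, edge_file) {
  nd <- data.frame(id = net$nodes$id,
                   x_um = net$nodes$i * spec$spacing,
                   y_um = net$nodes$j * spec$spacing,
                   z_um = net$nodes$k * spec$spacing,
                   role = net$nodes$role,
                   pressure_mmhg = net$nodes$pressure,
                   inflow_haematocrit = net$nodes$h_in)
  ed <- data.frame(a = net$segments$a, b = net$segments$b,
                   radius_um = net$segments$radius)
  utils::write.table(nd, node_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(ed, edge_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(nodes = nd, edges = ed))
}

#' @rdname write_network_tables
#' @return \code{read_network_tables}: list with \code{nodes} and
#'   \code{edges} data.frames in the tabular interchange format.
#' @export
read_network_tables <- function(node_file, edge_file) {
  list(nodes = utils::read.table(node_file, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
       edges = utils::read.table(edge_file, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}
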