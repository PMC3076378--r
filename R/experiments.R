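#' Percentile bootstrap confidence interval for a mean
#'
#' Draws \code{B} resamples with replacement, computes each resample's mean,
#' and returns the \code{(alpha/2, 1 - alpha/2)} percentiles of the
#' resampled means together with the sample mean.
#'
#' @param samples numeric vector (>= 2 values; a degenerate all-equal sample
#'   returns a zero-width interval).
#' @param level confidence level in (0, 1), default 0.95.
#' @param B number of bootstrap resamples (>= 200), default 2000.
#' @return named numeric vector \code{c(mean, lower, upper)}.
#' @export
bootstrap_mean_ci <- function(samples, level = 0.95, B = 2000L) {
  n <- length(samples)
  if (n == 0L) stop("empty sample")
  if (n < 2L) stop("need at least 2 samples to bootstrap")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  if (B < 200L) stop("B must be >= 200")
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  means <- rowMeans(matrix(samples[idx], nrow = B))
  alpha <- 1 - level
  qs <- unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  c(mean = mean(samples), lower = qs[1L], upper = qs[2L])
}

#' Ensemble summary of a scalar trajectory over seeds
#'
#' Runs over a matrix of per-seed trajectories (rows = time points, columns
#' = seeds): the mean curve with pointwise bootstrap confidence bands, and
#' the long-time value per seed (mean over the final fraction of the
#' trajectory) with its own bootstrap CI across seeds.
#'
#' @param traj numeric matrix, time points x seeds.
#' @param times time stamps for the rows.
#' @param level CI level; \code{B} bootstrap resamples.
#' @param B number of bootstrap resamples.
#' @param tail_frac final fraction of the trajectory averaged into the
#'   long-time value (default 0.1).
#' @return list with \code{bands} (data.frame time, mean, lower, upper) and
#'   \code{long_time} (per-seed values plus \code{c(mean, lower, upper)}).
#' @export
ensemble_summary <- function(traj, times, level = 0.95, B = 2000L,
                             tail_frac = 0.1) {
  stopifnot(is.matrix(traj), nrow(traj) == length(times), ncol(traj) >= 2)
  bands <- t(apply(traj, 1L, bootstrap_mean_ci, level = level, B = B))
  tail_rows <- max(1L, ceiling(nrow(traj) * tail_frac))
  lt <- colMeans(traj[seq(nrow(traj) - tail_rows + 1L, nrow(traj)), ,
                      drop = FALSE])
  list(bands = data.frame(time = times, mean = bands[, "mean"],
                          lower = bands[, "lower"], upper = bands[, "upper"]),
       long_time = list(per_seed = lt,
                        ci = bootstrap_mean_ci(lt, level = level, B = B)))
}

#' Has the tumour been eliminated by the decision horizon?
#'
#' TRUE iff the non-quiescent tumour-cell count reaches zero at some time at
#' or before \code{t_theta}; FALSE (survived) iff the count stays positive
#' throughout \code{[0, t_theta]}. The horizon must be long enough that the
#' hostile environment's influence has played out (several days).
#'
#' @param times time stamps (min), increasing from 0.
#' @param counts non-quiescent tumour-cell counts at those times.
#' @param t_theta decision horizon (min), default 14 days.
#' @return logical.
#' @export
eliminated <- function(times, counts, t_theta = 14 * 24 * 60) {
  stopifnot(length(times) == length(counts))
  upto <- times <= t_theta
  if (any(counts[upto] == 0L)) return(TRUE)
  if (max(times) < t_theta)
    stop("trajectory ends before the decision horizon and never reaches 0")
  FALSE
}

#' Extrapolate an elimination probability to a tiled domain
#'
#' If the \code{N} subdomains of an \code{N}-fold domain behave
#' independently, the whole tumour is eliminated only when every subdomain
#' is tumour-free: \eqn{P_N = P_1^N}.
#'
#' @param P1 single-subdomain elimination probability in \[0, 1\].
#' @param N integer >= 1, the domain-size factor.
#' @return extrapolated probability.
#' @export
extrapolate_elimination <- function(P1, N) {
  if (any(P1 < 0 | P1 > 1)) stop("P1 must lie in [0,1]")
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  P1^N
}

#' Tumour-elimination study across domain sizes and hostility levels
#'
#' For each combination of domain size (tile count N of the base subdomain
#' along y) and hostility level (oxygen permeability coefficient; the
#' published pairing reduces 3800 to 3116 to mimic a vascular-targeting
#' agent), runs an ensemble of realisations of a tumour implanted in the
#' countercurrent-pair tissue unit, records the elimination frequency with a
#' bootstrap CI, and adds the independence extrapolation \eqn{P_1^N} from
#' the single-subdomain estimate at the same hostility.
#'
#' @param base_config configuration of the single subdomain (its lattice is
#'   tiled along y for N > 1); the scenario must include a tumour implant.
#' @param sizes integer vector of tile counts (must include 1).
#' @param p_o2_levels numeric vector of oxygen permeability coefficients.
#' @param realisations ensemble size per combination.
#' @param seed base seed; realisation r of every combination uses
#'   \code{seed + r} so hostility levels are seed-paired.
#' @param t_theta decision horizon (min).
#' @param level,B bootstrap CI parameters.
#' @return data.frame with one row per (size, hostility): \code{n_tiles},
#'   \code{p_o2}, \code{realisations}, \code{eliminated}, \code{p_elim},
#'   \code{lower}, \code{upper}, \code{p_extrapolated}.
#' @export
elimination_study <- function(base_config, sizes = c(1L, 2L),
                              p_o2_levels = c(3800, 3116),
                              realisations = 100L, seed = 1L,
                              t_theta = 14 * 24 * 60,
                              level = 0.95, B = 2000L) {
  if (realisations < 1L) stop("need at least one realisation")
  if (!1L %in% sizes) stop("sizes must include 1 (the base subdomain)")
  sizes <- sort(unique(as.integer(sizes)))
  rows <- list()
  p1 <- setNames(rep(NA_real_, length(p_o2_levels)),
                 as.character(p_o2_levels))
  for (po2 in p_o2_levels) {
    for (nt in sizes) {
      cfg <- base_config
      cfg$lattice$dims[2] <- cfg$lattice$dims[2] * nt
      cfg$fields$p_o2 <- po2
      cfg$scenario$n_tiles <- nt
      # implant one tumour cube per subdomain, tiled with the vessels
      base_imp <- base_config$scenario$implant
      if (is.null(base_imp)) stop("base_config must specify a tumour implant")
      scen <- if (nt == 1L) "countercurrent_pair" else "tiled_pairs"
      wy <- base_config$lattice$dims[2]
      outcomes <- logical(realisations)
      for (r in seq_len(realisations)) {
        cfg_r <- cfg
        run <- run_elimination_realisation(scen, cfg_r, base_imp, nt, wy,
                                           seed + r, t_theta)
        outcomes[r] <- eliminated(run$summary$time_min,
                                  run$summary$n_cancer_active, t_theta)
      }
      ci <- bootstrap_mean_ci(as.numeric(outcomes), level = level, B = B)
      if (nt == 1L) p1[as.character(po2)] <- ci["mean"]
      rows[[length(rows) + 1L]] <- data.frame(
        n_tiles = nt, p_o2 = po2, realisations = realisations,
        eliminated = sum(outcomes), p_elim = unname(ci["mean"]),
        lower = unname(ci["lower"]), upper = unname(ci["upper"]),
        p_extrapolated = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$p_extrapolated <- extrapolate_elimination(
    p1[as.character(out$p_o2)], out$n_tiles)
  rownames(out) <- NULL
  out
}

# one elimination realisation: implant replicated per tile, early stop when
# the non-quiescent tumour count reaches zero
run_elimination_realisation <- function(scenario, cfg, base_implant, n_tiles,
                                        tile_wy, seed, t_theta) {
  # multi-tile implants: engine implants a cube per tile via implant_tiles
  cfg$scenario$implant <- base_implant
  cfg$scenario$implant_tiles <- list(n = n_tiles, wy = tile_wy)
  run_sim(scenario, cfg, seed = seed, t_end_min = t_theta,
          stop_when = function(state, row) row$n_cancer_active == 0L)
}

#' Import an experimentally derived vascular graph
#'
#' Takes node and edge tables in the interchange format (nodes: id, x_um,
#' y_um, z_um, role, pressure_mmhg, inflow_haematocrit; edges: a, b,
#' radius_um), snaps node coordinates to the nearest lattice sites,
#' subdivides edges longer than one lattice step into face-adjacent chains
#' (a deterministic axis-ordered staircase: x first, then y, then z), merges
#' duplicate segments, and validates that the result admits a flow solve.
#'
#' @param nodes,edges data.frames in the interchange format.
#' @param spec a [lattice_spec()].
#' @return a [new_vascular_network()] that has passed [solve_flow()].
#' @export
import_network <- function(nodes, edges, spec) {
  req_n <- c("id", "x_um", "y_um", "z_um", "role")
  if (!all(req_n %in% names(nodes))) stop("node table lacks required columns")
  if (!all(c("a", "b", "radius_um") %in% names(edges)))
    stop("edge table lacks required columns")
  miss <- setdiff(c(edges$a, edges$b), nodes$id)
  if (length(miss))
    stop("edge references missing node(s): ", paste(miss, collapse = ", "))
  if (!any(nodes$role == "inlet") || !any(nodes$role == "outlet"))
    stop("network needs at least one inlet and one outlet")
  co <- round(cbind(nodes$x_um, nodes$y_um, nodes$z_um) / spec$spacing)
  co <- pmin(pmax(co, 0), matrix(rep(spec$dims - 1L, each = nrow(co)),
                                 ncol = 3L))
  lin <- site_lin(co, spec)
  # nodes snapping to one site must agree on role/pressure
  if (anyDuplicated(lin)) {
    for (l in unique(lin[duplicated(lin)])) {
      grp <- which(lin == l)
      pr <- nodes$pressure_mmhg[grp]
      if (length(unique(nodes$role[grp])) > 1L ||
          length(unique(pr[is.finite(pr)])) > 1L)
        stop("nodes snap to the same lattice site with contradictory roles/pressures")
    }
  }
  canon_id <- nodes$id[match(lin, lin)]  # first node id per site
  remap <- stats::setNames(canon_id, nodes$id)
  keep <- !duplicated(lin)
  nd <- data.frame(id = nodes$id[keep], i = co[keep, 1L], j = co[keep, 2L],
                   k = co[keep, 3L], role = nodes$role[keep],
                   pressure = if ("pressure_mmhg" %in% names(nodes))
                     nodes$pressure_mmhg[keep] else NA_real_,
                   h_in = if ("inflow_haematocrit" %in% names(nodes))
                     nodes$inflow_haematocrit[keep] else NA_real_)
  next_id <- max(nd$id) + 1L
  seg_a <- integer(0); seg_b <- integer(0); seg_r <- numeric(0)
  site_of <- stats::setNames(site_lin(as.matrix(nd[, c("i", "j", "k")]), spec),
                             nd$id)
  lin_to_id <- stats::setNames(nd$id, site_of)
  for (e in seq_len(nrow(edges))) {
    a <- unname(remap[as.character(edges$a[e])])
    b <- unname(remap[as.character(edges$b[e])])
    if (a == b) next  # endpoints collapsed to one site
    sa <- unlist(nd[match(a, nd$id), c("i", "j", "k")])
    sb <- unlist(nd[match(b, nd$id), c("i", "j", "k")])
    path <- staircase_path(sa, sb, spec)
    ids <- integer(nrow(path))
    ids[1L] <- a; ids[nrow(path)] <- b
    if (nrow(path) > 2L) {
      for (p in 2L:(nrow(path) - 1L)) {
        l <- site_lin(path[p, ], spec)
        hit <- lin_to_id[as.character(l)]
        if (!is.na(hit)) {
          ids[p] <- hit
        } else {
          nd <- rbind(nd, data.frame(id = next_id, i = path[p, 1L],
                                     j = path[p, 2L], k = path[p, 3L],
                                     role = "interior",
                                     pressure = NA_real_, h_in = NA_real_))
          lin_to_id[as.character(l)] <- next_id
          ids[p] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    for (p in seq_len(nrow(path) - 1L)) {
      if (ids[p] == ids[p + 1L]) next
      seg_a <- c(seg_a, ids[p]); seg_b <- c(seg_b, ids[p + 1L])
      seg_r <- c(seg_r, edges$radius_um[e])
    }
  }
  key <- paste(pmin(seg_a, seg_b), pmax(seg_a, seg_b))
  keep_seg <- !duplicated(key)
  net <- new_vascular_network(
    nd, data.frame(a = seg_a[keep_seg], b = seg_b[keep_seg],
                   radius = seg_r[keep_seg]), spec)
  solve_flow(net)  # errors if the imported graph is structurally singular
  net
}

# deterministic face-adjacent lattice path from sa to sb: walk x, then y,
# then z, one unit step at a time, taking the minimal-image direction on
# periodic axes
staircase_path <- function(sa, sb, spec) {
  cur <- as.integer(sa)
  path <- matrix(cur, ncol = 3L)
  for (ax in 1:3) {
    d <- sb[ax] - cur[ax]
    if (spec$bc[ax] == "periodic") {
      n <- spec$dims[ax]
      d <- d - n * round(d / n)
    }
    stp <- sign(d)
    while (d != 0L) {
      cur[ax] <- cur[ax] + stp
      if (spec$bc[ax] == "periodic") cur[ax] <- cur[ax] %% spec$dims[ax]
      path <- rbind(path, cur)
      d <- d - stp
    }
  }
  path
}

#' Generate a synthetic irregular 3D vascular graph
#'
#' Stands in for a microscopy-derived network: a connected random geometric
#' tree over irregular 3D coordinates with a few extra cross-links,
#' prescribed numbers of inlet and outlet nodes with a pressure spread, and
#' inflow haematocrit on the inlets. The construction guarantees a
#' nonsingular flow solve (connected, with at least one prescribed pressure
#' per component).
#'
#' @param n_nodes number of graph nodes (>= 4).
#' @param spec a [lattice_spec()] bounding the coordinates.
#' @param n_inlets,n_outlets boundary node counts.
#' @param p_range inlet/outlet pressure spread (mmHg), default c(20, 35).
#' @param extra_edges number of additional random cross-links.
#' @param radius_range segment radius range (um).
#' @param h_in inflow haematocrit.
#' @return list of \code{nodes} and \code{edges} tables in the interchange
#'   format. Deterministic for a fixed R random seed.
#' @export
synthetic_network_fixture <- function(n_nodes = 12L, spec = lattice_spec(
                                        c(12L, 12L, 12L)),
                                      n_inlets = 2L, n_outlets = 2L,
                                      p_range = c(20, 35),
                                      extra_edges = 2L,
                                      radius_range = c(6, 14),
                                      h_in = 0.45) {
  stopifnot(n_nodes >= 4L, n_inlets >= 1L, n_outlets >= 1L,
            n_inlets + n_outlets <= n_nodes)
  ext <- (spec$dims - 1L) * spec$spacing
  repeat {
    xyz <- cbind(stats::runif(n_nodes, 0, ext[1]),
                 stats::runif(n_nodes, 0, ext[2]),
                 stats::runif(n_nodes, 0, ext[3]))
    # distinct lattice sites after snapping, so import never merges nodes
    if (!anyDuplicated(site_lin(round(xyz / spec$spacing), spec))) break
  }
  # random spanning tree: connect each node to a random earlier node,
  # preferring nearby ones (weights ~ 1/d^2)
  a <- integer(0); b <- integer(0)
  for (v in 2L:n_nodes) {
    d2 <- colSums((t(xyz[seq_len(v - 1L), , drop = FALSE]) - xyz[v, ])^2)
    w <- 1 / (d2 + spec$spacing^2)
    u <- stats::runif(1) * sum(w)
    a <- c(a, v); b <- c(b, which(cumsum(w) >= u)[1L])
  }
  for (e in seq_len(extra_edges)) {
    cand <- sample.int(n_nodes, 2L)
    key <- paste(pmin(a, b), pmax(a, b))
    if (!paste(min(cand), max(cand)) %in% key) {
      a <- c(a, cand[1L]); b <- c(b, cand[2L])
    }
  }
  role <- rep("interior", n_nodes)
  bnd <- sample.int(n_nodes, n_inlets + n_outlets)
  role[bnd[seq_len(n_inlets)]] <- "inlet"
  role[bnd[n_inlets + seq_len(n_outlets)]] <- "outlet"
  pressure <- rep(NA_real_, n_nodes)
  pressure[role == "inlet"] <- p_range[2] - stats::runif(n_inlets) *
    diff(p_range) * 0.2
  pressure[role == "outlet"] <- p_range[1] + stats::runif(n_outlets) *
    diff(p_range) * 0.2
  hh <- ifelse(role == "inlet", h_in, NA_real_)
  list(nodes = data.frame(id = seq_len(n_nodes), x_um = xyz[, 1],
                          y_um = xyz[, 2], z_um = xyz[, 3], role = role,
                          pressure_mmhg = pressure,
                          inflow_haematocrit = hh),
       edges = data.frame(a = a, b = b,
                          radius_um = stats::runif(length(a),
                                                   radius_range[1],
                                                   radius_range[2])))
}
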