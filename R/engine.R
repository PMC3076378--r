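#' Default simulation configuration
#'
#' A nested list of every model parameter with its default. Field, vessel,
#' cell and angiogenesis sections delegate to the module-level parameter
#' constructors; overrides can be supplied as a nested list and are merged
#' recursively. The methods vignette documents units and provenance of every
#' default.
#'
#' @param overrides nested list merged over the defaults.
#' @return configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    lattice = list(dims = c(50L, 50L, 50L), spacing = 40,
                   bc = c("reflecting", "reflecting", "reflecting")),
    dt = 30,  # min, the macro time-step
    fields = list(
      oxygen = list(D = 2.5e4, decay = 0.01), # um^2/min, 1/min
      vegf = list(D = 2.5e4, decay = 0.05, vessel_sink = 1.0),
      p_o2 = 3800,           # oxygen permeability coefficient (model units)
      perm_scale = 1 / 15,   # fixes the permeability unit (vignette)
      h_ref = 0.45,          # haematocrit giving blood oxygen 1
      rtol = 1e-8
    ),
    vessels = vessel_params(),
    cells = cell_params(),
    angio = angio_params(),
    scenario = list(
      mean_pressure = 25, pressure_drop = 10,  # mmHg, countercurrent pair
      unit_means = c(20, 25, 30, 35),          # eight-vessel unit means
      fill_normal = TRUE,
      implant = NULL  # list(centre = c(i,j,k), half = 1) or NULL
    )
  )
  merge_config(cfg, overrides)
}

merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read and validate a YAML configuration file
#'
#' @param path YAML file of overrides over [default_config()].
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(default_config(yaml::read_yaml(path)))
}

#' Validate a configuration list
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly, after checking ranges and shapes.
#' @export
validate_config <- function(cfg) {
  lattice_spec(cfg$lattice$dims, cfg$lattice$spacing, cfg$lattice$bc)
  stopifnot(cfg$dt > 0, cfg$fields$oxygen$D > 0, cfg$fields$vegf$D > 0,
            cfg$fields$oxygen$decay >= 0, cfg$fields$vegf$decay >= 0,
            cfg$fields$p_o2 >= 0,
            cfg$vessels$r_min > 0, cfg$vessels$r_max >= cfg$vessels$r_min,
            cfg$cells$capacity >= 1, cfg$angio$r_exclusion >= 0,
            cfg$cells$p_move >= 0, cfg$cells$p_move <= 1)
  if (!is.null(cfg$scenario$implant)) {
    spec <- lattice_spec(cfg$lattice$dims, cfg$lattice$spacing,
                         cfg$lattice$bc)
    ctr <- cfg$scenario$implant$centre; half <- cfg$scenario$implant$half
    if (any(ctr - half < 0) || any(ctr + half >= spec$dims))
      stop("tumour implant extends outside the domain")
  }
  invisible(cfg)
}

# Implant centres: the configured cube, replicated once per tile along y
# when scenario$implant_tiles = list(n, wy) is set (tiled domains implant
# one tumour cube per subdomain).
implant_centres <- function(config) {
  imp <- config$scenario$implant
  if (is.null(imp)) return(list())
  tiles <- config$scenario$implant_tiles
  if (is.null(tiles)) return(list(imp$centre))
  lapply(seq_len(tiles$n) - 1L, function(t)
    imp$centre + c(0L, t * tiles$wy, 0L))
}

# ---- scenario construction ---------------------------------------------

# straight parent vessel along x at (j, k), pressure from p_in at the inflow
# end to p_out at the other; direction +1 means inflow at x = 0.
parent_vessel <- function(spec, j, k, p_in, p_out, h_in, radius,
                          direction = 1L, id0 = 0L) {
  nx <- spec$dims[1]
  if (j < 0 || j >= spec$dims[2] || k < 0 || k >= spec$dims[3])
    stop("parent vessel lies off the lattice")
  ids <- id0 + seq_len(nx)
  role <- rep("interior", nx)
  pressure <- rep(NA_real_, nx)
  hh <- rep(NA_real_, nx)
  inlet <- if (direction > 0) 1L else nx
  outlet <- if (direction > 0) nx else 1L
  role[inlet] <- "inlet"; role[outlet] <- "outlet"
  pressure[inlet] <- p_in; pressure[outlet] <- p_out
  hh[inlet] <- h_in
  nodes <- data.frame(id = ids, i = 0:(nx - 1L), j = j, k = k, role = role,
                      pressure = pressure, h_in = hh)
  segments <- data.frame(a = ids[-nx], b = ids[-1L], radius = radius)
  list(nodes = nodes, segments = segments)
}

# stack vessel descriptors (j, k, mean pressure, direction) into a network
build_parent_network <- function(spec, vdesc, drop, h_in, radius) {
  nodes <- NULL; segments <- NULL; id0 <- 0L
  for (v in vdesc) {
    pv <- parent_vessel(spec, v$j, v$k, v$mean + drop / 2, v$mean - drop / 2,
                        h_in, radius, v$direction, id0)
    nodes <- rbind(nodes, pv$nodes)
    segments <- rbind(segments, pv$segments)
    id0 <- id0 + spec$dims[1]
  }
  new_vascular_network(nodes, segments, spec)
}

# vessel descriptors for the scenarios; tiling replicates a base unit along y
scenario_vessels <- function(scenario, spec, cfg) {
  ny <- spec$dims[2]; nz <- spec$dims[3]
  m <- cfg$scenario$mean_pressure
  if (scenario %in% c("countercurrent_pair", "tiled_pairs")) {
    ntile <- if (scenario == "countercurrent_pair") 1L else
      as.integer(cfg$scenario$n_tiles)
    if (is.na(ntile) || ntile < 1L) stop("tiled_pairs needs n_tiles >= 1")
    if (ny %% ntile != 0L) stop("y-extent not divisible by the tile count")
    wy <- ny %/% ntile
    jc <- (wy - 1L) %/% 2L
    z1 <- nz %/% 3L; z2 <- (2L * nz) %/% 3L
    vd <- list()
    for (t in seq_len(ntile) - 1L) {
      vd <- c(vd, list(
        list(j = t * wy + jc, k = z2, mean = m, direction = 1L),   # upper
        list(j = t * wy + jc, k = z1, mean = m, direction = -1L))) # lower
    }
    vd
  } else if (scenario %in% c("eight_vessel_unit", "tiled_units")) {
    ntile <- if (scenario == "eight_vessel_unit") 1L else
      as.integer(cfg$scenario$n_tiles)
    if (is.na(ntile) || ntile < 1L) stop("tiled_units needs n_tiles >= 1")
    if (ny %% ntile != 0L) stop("y-extent not divisible by the tile count")
    wy <- ny %/% ntile
    # 2 columns in y, 4 rows in z; means arranged so every nearest parent
    # vessel has a different mean pressure (4 distinct means among 8 vessels)
    jj <- c(wy %/% 4L, (3L * wy) %/% 4L)
    kk <- pmin(((2L * (0:3) + 1L) * nz) %/% 8L, nz - 1L)
    mm <- cfg$scenario$unit_means
    mean_grid <- rbind(c(mm[2], mm[4]), c(mm[3], mm[1]),
                       c(mm[2], mm[4]), c(mm[3], mm[1]))
    vd <- list()
    for (t in seq_len(ntile) - 1L) {
      for (r in 1:4) for (cix in 1:2) {
        vd <- c(vd, list(list(j = t * wy + jj[cix], k = kk[r],
                              mean = mean_grid[r, cix],
                              direction = if ((r + cix) %% 2L == 0L) 1L else -1L)))
      }
    }
    vd
  } else stop("unknown scenario: ", scenario)
}

#' Initialise a simulation state
#'
#' Builds the initial vascular network for the chosen scenario (straight
#' parent vessels on lattice lines: a countercurrent pair with equal mean
#' pressures and opposite drops; its y-tiled replicas; the eight-vessel unit
#' with equal drops and four distinct mean pressures arranged so adjacent
#' vessels differ in mean; or an imported network), optionally fills the
#' domain with normal cells, implants a cube of cancer cells by replacement,
#' solves blood flow, haematocrit and both diffusible fields once, and seeds
#' the random stream.
#'
#' @param scenario one of \code{"countercurrent_pair"},
#'   \code{"tiled_pairs"}, \code{"eight_vessel_unit"}, \code{"tiled_units"},
#'   \code{"imported_network"} (requires \code{config$scenario$network}, a
#'   \code{vascular_network} or a list of node/edge tables).
#' @param config see [default_config()]; \code{config$scenario$n_tiles} sets
#'   the replica count for tiled scenarios.
#' @param seed integer seed for the Mersenne-Twister stream.
#' @return a \code{simulation_state}: list with \code{time} (min),
#'   \code{spec}, \code{cells}, \code{net}, \code{sprouts}, \code{occ},
#'   \code{oxygen}, \code{vegf}, \code{config}, \code{next_cell_id},
#'   \code{step_count}.
#' @export
init_state <- function(scenario, config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  spec <- lattice_spec(config$lattice$dims, config$lattice$spacing,
                       config$lattice$bc)
  if (scenario == "imported_network") {
    nw <- config$scenario$network
    if (is.null(nw)) stop("imported_network scenario needs scenario$network")
    net <- if (inherits(nw, "vascular_network")) nw else
      import_network(nw$nodes, nw$edges, spec)
  } else {
    vd <- scenario_vessels(scenario, spec, config)
    net <- build_parent_network(spec, vd, config$scenario$pressure_drop,
                                config$vessels$h_in, config$vessels$r_parent)
  }
  occ <- new_occupancy(spec, config$cells$capacity)
  update_vessel_occupancy(occ, net)

  cells <- NULL
  if (isTRUE(config$scenario$fill_normal)) {
    sites <- site_from_lin(seq_len(spec$n), spec)
    kind <- rep("normal", spec$n)
    for (ctr in implant_centres(config)) {
      half <- config$scenario$implant$half
      inside <- abs(sites[, 1] - ctr[1]) <= half &
        abs(sites[, 2] - ctr[2]) <= half &
        abs(sites[, 3] - ctr[3]) <= half
      kind[inside] <- "cancer"
    }
    cells <- new_cells(kind, sites, spec,
                       phase = stats::runif(spec$n))
  } else if (!is.null(config$scenario$implant)) {
    half <- config$scenario$implant$half
    g <- NULL
    for (ctr in implant_centres(config)) {
      g <- rbind(g, as.matrix(expand.grid(
        i = (ctr[1] - half):(ctr[1] + half),
        j = (ctr[2] - half):(ctr[2] + half),
        k = (ctr[3] - half):(ctr[3] + half))))
    }
    cells <- new_cells(rep("cancer", nrow(g)), g, spec,
                       phase = stats::runif(nrow(g)))
  } else {
    cells <- new_cells(character(0), matrix(integer(0), ncol = 3), spec)
  }
  if (nrow(cells)) {
    nrm <- cells$kind == "normal"
    cnt <- rowsum(rep(1L, sum(nrm)), cells$lin[nrm])
    occ$normal[as.integer(rownames(cnt))] <- cnt[, 1]
    cnt <- rowsum(rep(1L, sum(!nrm)), cells$lin[!nrm])
    if (nrow(cnt)) occ$cancer[as.integer(rownames(cnt))] <- cnt[, 1]
    if (any(occ$normal + occ$cancer > occ$capacity))
      stop("initial cells exceed carrying capacity")
  }

  state <- list(time = 0, spec = spec, cells = cells, net = net,
                sprouts = list(), occ = occ,
                oxygen = numeric(spec$n), vegf = numeric(spec$n),
                config = config, next_cell_id = nrow(cells) + 1L,
                step_count = 0L, scenario = scenario)
  class(state) <- "simulation_state"
  state$net <- solve_flow(state$net, config$vessels$mu_plasma_cP,
                          config$vessels$q_floor, on_floating = "zero")
  state$net <- propagate_haematocrit(state$net)
  state <- solve_state_fields(state)
  state
}

# assemble and solve both diffusible fields from the current state
solve_state_fields <- function(state) {
  cfg <- state$config; spec <- state$spec
  n <- spec$n
  csink <- numeric(n)
  if (nrow(state$cells)) {
    kc <- ifelse(state$cells$kind == "cancer", cfg$cells$o2_consume_cancer,
                 cfg$cells$o2_consume_normal)
    agg <- rowsum(kc, state$cells$lin)
    csink[as.integer(rownames(agg))] <- agg[, 1]
  }
  vx <- vessel_exchange_coefficients(state$net, spec, cfg$fields$p_o2,
                                     cfg$fields$h_ref, cfg$fields$perm_scale)
  sys <- list(A = field_operator(spec, cfg$fields$oxygen$D,
                                 cfg$fields$oxygen$decay,
                                 sink = csink + vx$sink),
              b = vx$source, spec = spec)
  state$oxygen <- solve_field(sys, x0 = state$oxygen, rtol = cfg$fields$rtol)

  vsrc <- numeric(n)
  if (nrow(state$cells)) {
    rate <- vegf_secretion_rate(state$cells$kind, state$cells$status,
                                state$oxygen[state$cells$lin], cfg$cells)
    agg <- rowsum(rate, state$cells$lin)
    vsrc[as.integer(rownames(agg))] <- agg[, 1]
  }
  vsink <- numeric(n)
  vlins <- vessel_site_lins(state$net)
  vsink[vlins] <- cfg$fields$vegf$vessel_sink
  sysv <- list(A = field_operator(spec, cfg$fields$vegf$D,
                                  cfg$fields$vegf$decay, sink = vsink),
               b = vsrc, spec = spec)
  state$vegf <- solve_field(sysv, x0 = state$vegf, rtol = cfg$fields$rtol)
  state
}

#' Advance the simulation by one macro time-step
#'
#' The update order is fixed: (1) the quasi-steady oxygen and VEGF fields
#' are re-solved from the current cell and vessel configuration; (2) cells
#' are updated in stable id order (subcellular state, death rules, movement,
#' division) and endothelial tips step and attempt anastomosis in creation
#' order; (3) the vessel network is updated (flow, haematocrit, one radius
#' adaptation pass, pruning) and new sprouts are initiated on eligible sites
#' in lexicographic site order. Time then advances by \code{dt}.
#'
#' @param state a \code{simulation_state}.
#' @return the advanced state.
#' @export
step_state <- function(state) {
  cfg <- state$config; spec <- state$spec; dt <- cfg$dt
  # (1) diffusible fields
  state <- solve_state_fields(state)

  # (2a) cells, stable id order
  cells <- state$cells
  if (nrow(cells)) {
    cells <- cells[order(cells$id), , drop = FALSE]
    cells <- subcellular_step(cells, state$oxygen[cells$lin], dt, cfg$cells)
    dc <- death_check(cells, state$occ, spec, cfg$cells)
    cells <- dc$cells
    # movement: one Bernoulli draw per cell (id order), then destination
    # draws for the movers in id order
    if (nrow(cells)) {
      lin <- cells$lin; kindc <- cells$kind == "cancer"
      occ <- state$occ
      u <- stats::runif(nrow(cells))
      movers <- which(u < cfg$cells$p_move)
      for (m in movers) {
        dest <- move_lin(lin[m], occ, spec)
        if (!is.na(dest)) {
          if (kindc[m]) {
            occ$cancer[lin[m]] <- occ$cancer[lin[m]] - 1L
            occ$cancer[dest] <- occ$cancer[dest] + 1L
          } else {
            occ$normal[lin[m]] <- occ$normal[lin[m]] - 1L
            occ$normal[dest] <- occ$normal[dest] + 1L
          }
          lin[m] <- dest
        }
      }
      # division
      ready <- which(cells$phase >= 1 & cells$status == "cycling")
      d_lin <- integer(0); d_mother <- integer(0)
      for (m in ready) {
        dest <- division_lin(lin[m], occ, spec)
        if (is.na(dest)) next  # contact-inhibited: phase held at 1
        cells$phase[m] <- 0
        if (kindc[m]) occ$cancer[dest] <- occ$cancer[dest] + 1L
        else occ$normal[dest] <- occ$normal[dest] + 1L
        d_lin <- c(d_lin, dest); d_mother <- c(d_mother, m)
      }
      moved <- lin != cells$lin
      if (any(moved)) {
        cells$lin[moved] <- lin[moved]
        ms <- site_from_lin(lin[moved], spec)
        cells$i[moved] <- ms[, 1]; cells$j[moved] <- ms[, 2]
        cells$k[moved] <- ms[, 3]
      }
      if (length(d_lin)) {
        ds <- site_from_lin(d_lin, spec)
        daughters <- data.frame(
          id = state$next_cell_id + seq_along(d_lin) - 1L,
          kind = cells$kind[d_mother], status = "cycling",
          i = ds[, 1], j = ds[, 2], k = ds[, 3], lin = d_lin, phase = 0,
          p53 = cells$p53[d_mother], vegf = cells$vegf[d_mother],
          qclock = 0)
        state$next_cell_id <- state$next_cell_id + length(d_lin)
        cells <- rbind(cells, daughters)
      }
    }
  }
  state$cells <- cells

  # (2b) endothelial tips, creation order
  si <- 1L
  while (si <= length(state$sprouts)) {
    state$sprouts[[si]] <- tip_step(state$sprouts[[si]], state$vegf, spec,
                                    dt, cfg$angio)
    res <- try_anastomose(si, state$sprouts, state$net, spec,
                          cfg$vessels$r_init, cfg$angio$t_sprout_death)
    state$net <- res$net
    state$sprouts <- res$sprouts
    if (res$outcome == "still-growing") si <- si + 1L
    else if (res$outcome == "connected" && !is.na(res$partner) &&
             res$partner < si) si <- si - 1L
    # connected/dead: sprout(s) removed, si now points at the next one
  }
  update_vessel_occupancy(state$occ, state$net)

  # (3) vessel network update
  state$net <- solve_flow(state$net, cfg$vessels$mu_plasma_cP,
                          cfg$vessels$q_floor, on_floating = "zero")
  state$net <- propagate_haematocrit(state$net)
  state$net <- adapt_radius(state$net, state$oxygen, dt, spec, cfg$vessels)
  state$net <- prune_vessels(state$net, dt, cfg$vessels)
  update_vessel_occupancy(state$occ, state$net)

  # sprout initiation on eligible vessel sites, lexicographic site order
  elig <- eligible_sprout_sites(state$net, state$sprouts, spec,
                                cfg$angio$r_exclusion)
  if (length(elig)) {
    p <- sprout_probability(state$vegf[elig], dt, cfg$angio)
    u <- stats::runif(length(elig))
    hits <- which(u < p)
    for (hix in hits) {
      lin <- elig[hix]
      # re-check exclusion against sprouts created earlier this step
      if (length(state$sprouts)) {
        s0 <- site_from_lin(lin, spec)[1L, ]
        too_close <- FALSE
        for (sp in state$sprouts) {
          if (site_distance(matrix(sp$path[1L, ], ncol = 3), s0, spec) <=
              cfg$angio$r_exclusion) { too_close <- TRUE; break }
        }
        if (too_close) next
      }
      nid <- state$net$nodes$id[match(lin, state$net$nodes$lin)]
      state$sprouts <- c(state$sprouts,
                         list(new_sprout(nid, site_from_lin(lin, spec)[1L, ])))
    }
  }

  state$time <- state$time + dt
  state$step_count <- state$step_count + 1L
  state
}

#' Per-step summary of a simulation state
#'
#' @param state a \code{simulation_state}.
#' @return one-row data.frame: time (min and h), cell counts by kind and
#'   status, tumour/normal/vessel volume fractions, segment count, total
#'   vascular volume (um^3) and active sprout count.
#' @export
summarise_state <- function(state) {
  cells <- state$cells
  cancer <- cells$kind == "cancer"
  quiescent <- cancer & cells$status == "quiescent"
  seg <- state$net$segments
  data.frame(
    time_min = state$time,
    time_h = state$time / 60,
    n_normal = sum(!cancer),
    n_cancer = sum(cancer),
    n_cancer_active = sum(cancer & !quiescent),
    n_quiescent = sum(quiescent),
    tumour_vf = volume_fraction(state$occ, "tumour"),
    normal_vf = volume_fraction(state$occ, "normal"),
    vessel_vf = volume_fraction(state$occ, "vessel"),
    n_segments = nrow(seg),
    vascular_volume = sum(pi * seg$radius^2 * seg$length),
    n_sprouts = length(state$sprouts)
  )
}

#' Run a simulation
#'
#' Initialises the requested scenario and advances it step by step, recording
#' a summary row per step (including t = 0).
#'
#' @param scenario see [init_state()].
#' @param config see [default_config()].
#' @param seed RNG seed.
#' @param t_end_min simulated duration (min); must be a multiple of
#'   \code{config$dt}.
#' @param snapshot_every record a full state snapshot every this many steps
#'   (0 = none).
#' @param stop_when optional function(state, summary_row) returning TRUE to
#'   end the run early (used by the elimination studies to stop once the
#'   last non-quiescent tumour cell has died).
#' @return list of class \code{"simulation_run"}: \code{summary} data.frame,
#'   final \code{state}, \code{snapshots} list, and the stop reason.
#' @export
run_sim <- function(scenario, config = default_config(), seed = 1L,
                    t_end_min = 1440, snapshot_every = 0L,
                    stop_when = NULL) {
  if (abs(t_end_min / config$dt - round(t_end_min / config$dt)) > 1e-9)
    stop("t_end_min must be a multiple of the time-step")
  n_steps <- as.integer(round(t_end_min / config$dt))
  state <- init_state(scenario, config, seed)
  rows <- vector("list", n_steps + 1L)
  rows[[1L]] <- summarise_state(state)
  snapshots <- list()
  stopped <- "t_end"
  for (s in seq_len(n_steps)) {
    state <- step_state(state)
    rows[[s + 1L]] <- summarise_state(state)
    if (snapshot_every > 0L && s %% snapshot_every == 0L)
      snapshots[[length(snapshots) + 1L]] <- snapshot_state(state)
    if (!is.null(stop_when) && isTRUE(stop_when(state, rows[[s + 1L]]))) {
      stopped <- "stop_when"
      rows <- rows[seq_len(s + 1L)]
      break
    }
  }
  structure(list(summary = do.call(rbind, rows), state = state,
                 snapshots = snapshots, stopped = stopped,
                 scenario = scenario, seed = seed),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "simulation_run: scenario %s, seed %d, %d steps to t = %.1f h\n",
    x$scenario, x$seed, nrow(x$summary) - 1L, last$time_h))
  cat(sprintf(
    "  final: %d normal, %d cancer (%d active), vf tumour %.3f vessel %.3f\n",
    last$n_normal, last$n_cancer, last$n_cancer_active, last$tumour_vf,
    last$vessel_vf))
  invisible(x)
}

# Hierarchical snapshot of one time point: cell table, network tables,
# fields as flat arrays in (k, j, i)-major linear order, active sprouts.
snapshot_state <- function(state) {
  list(time_min = state$time,
       cells = state$cells[, c("id", "kind", "status", "i", "j", "k",
                               "phase", "p53", "vegf")],
       nodes = state$net$nodes, segments = state$net$segments,
       oxygen = state$oxygen, vegf = state$vegf,
       sprouts = lapply(state$sprouts, function(s)
         list(origin = s$path[1L, ], path = s$path, age = s$age)))
}

# Occupancy audit: recompute occupancy from the cell table and network and
# compare with the incrementally maintained arrays. Used by tests after
# every step; returns TRUE or a descriptive error.
audit_occupancy <- function(state) {
  occ <- state$occ; spec <- state$spec
  nrm <- array(0L, spec$dims); cnc <- array(0L, spec$dims)
  if (nrow(state$cells)) {
    isn <- state$cells$kind == "normal"
    t1 <- rowsum(rep(1L, sum(isn)), state$cells$lin[isn])
    nrm[as.integer(rownames(t1))] <- t1[, 1]
    t2 <- rowsum(rep(1L, sum(!isn)), state$cells$lin[!isn])
    if (nrow(t2)) cnc[as.integer(rownames(t2))] <- t2[, 1]
  }
  ves <- array(FALSE, spec$dims)
  ves[vessel_site_lins(state$net)] <- TRUE
  if (!identical(as.vector(nrm), as.vector(occ$normal)))
    stop("occupancy audit failed: normal counts")
  if (!identical(as.vector(cnc), as.vector(occ$cancer)))
    stop("occupancy audit failed: cancer counts")
  if (!identical(as.vector(ves), as.vector(occ$vessel)))
    stop("occupancy audit failed: vessel mask")
  if (any(nrm + cnc > occ$capacity))
    stop("occupancy audit failed: carrying capacity exceeded")
  TRUE
}
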