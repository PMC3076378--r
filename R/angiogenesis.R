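#' Default angiogenesis parameters
#'
#' @return named list: maximum sprouting rate and VEGF half-saturation of the
#'   saturating sprout-probability law, the sprout exclusion radius, the
#'   chemotactic sensitivity of endothelial tip cells, the weight floor that
#'   keeps the tip walk irreducible, and the sprout survival time before an
#'   unconnected sprout dies back.
#' @export
angio_params <- function() {
  list(
    p_sprout_max = 2e-3,   # 1/min: saturating sprout initiation rate
    v_half = 0.05,         # VEGF units: half-saturation of initiation
    r_exclusion = 60,      # um: no new sprout within this radius of another
    chi = 2.0,             # chemotactic sensitivity (per VEGF unit)
    move_floor = 0.01,     # epsilon floor on tip move weights
    t_sprout_death = 3000  # min: unconnected sprouts die back after this
  )
}

#' VEGF-dependent sprout initiation probability
#'
#' Saturating in the local VEGF concentration:
#' \deqn{p = \Delta t\, P_{max}\, V / (V + V_{1/2}),}
#' capped at 1. Zero VEGF gives zero probability; at \eqn{V = V_{1/2}} the
#' probability is half its saturating value.
#'
#' @param V local VEGF concentration (>= 0, vectorised).
#' @param dt macro time-step (min).
#' @param params see [angio_params()].
#' @return probability in \[0, 1\].
#' @export
sprout_probability <- function(V, dt, params = angio_params()) {
  if (any(!is.finite(V)) || any(V < 0)) stop("VEGF concentration must be >= 0")
  pmin(dt * params$p_sprout_max * V / (V + params$v_half), 1)
}

# Sprout record: origin node id + site, path matrix (rows are sites, first
# row = origin), age in minutes.
new_sprout <- function(origin_id, origin_site) {
  list(origin_id = origin_id,
       path = matrix(as.integer(origin_site), ncol = 3L),
       age = 0)
}

#' Vessel sites eligible to initiate a new sprout
#'
#' All vessel-occupied sites whose minimal-image distance to every active
#' sprout origin exceeds the exclusion radius. The exclusion radius prevents
#' sprouts emerging on top of each other; reducing it is one of the changes
#' that lets the vasculature colonise 3D domains.
#'
#' @param net vascular network.
#' @param sprouts list of active sprouts.
#' @param spec a [lattice_spec()].
#' @param r_ex exclusion radius (um, >= 0).
#' @return integer vector of eligible linear site indices, sorted (the
#'   engine draws initiation in this lexicographic order).
#' @export
eligible_sprout_sites <- function(net, sprouts, spec, r_ex) {
  if (r_ex < 0) stop("exclusion radius must be >= 0")
  lins <- sort(vessel_site_lins(net))
  if (length(lins) == 0L || length(sprouts) == 0L || r_ex == 0) return(lins)
  sites <- site_from_lin(lins, spec)
  keep <- rep(TRUE, length(lins))
  for (sp in sprouts) {
    d <- site_distance(sites, sp$path[1L, ], spec)
    keep <- keep & d > r_ex
  }
  lins[keep]
}

#' One chemotactic step of an endothelial tip cell
#'
#' The tip performs a biased random walk: each admissible lattice neighbour
#' (boundary-condition handled) is weighted by
#' \eqn{\max(\epsilon,\ 1 + \chi (V_{nb} - V_{tip}))} and the move is drawn
#' from the normalised weights. Tips traverse cell-occupied sites freely
#' (they do not count against the carrying capacity). With no admissible
#' neighbour the tip stays. Age advances by \code{dt} either way.
#'
#' @param sprout a sprout record.
#' @param vegf VEGF field values in linear site order.
#' @param spec a [lattice_spec()].
#' @param dt macro time-step (min).
#' @param params see [angio_params()]; \code{chi} is the chemotactic
#'   sensitivity (set 0 for an unbiased walk).
#' @return the sprout with its path extended and age advanced. Consumes one
#'   uniform draw when there is more than one admissible move.
#' @export
tip_step <- function(sprout, vegf, spec, dt, params = angio_params()) {
  tip <- sprout$path[nrow(sprout$path), ]
  nb <- site_neighbours(tip, spec, "face")
  sprout$age <- sprout$age + dt
  if (nrow(nb) == 0L) return(sprout)
  v_here <- vegf[site_lin(tip, spec)]
  v_nb <- vegf[site_lin(nb, spec)]
  w <- pmax(params$move_floor, 1 + params$chi * (v_nb - v_here))
  cw <- cumsum(w)
  pick <- findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L
  sprout$path <- rbind(sprout$path, nb[pick, ])
  sprout
}

#' Attempt anastomosis of a sprout
#'
#' If the tip has reached a vessel-occupied site (other than its own origin)
#' or the current site of another active tip, the sprout's path is converted
#' into vessel segments of radius \code{r_init} and inserted into the
#' network (new interior nodes are created along the path; duplicate
#' segments are never created; the new vessels await the next flow solve to
#' become perfused). If instead the sprout has exceeded its survival time,
#' it dies and its path is discarded. Otherwise it keeps growing.
#'
#' @param idx index of the sprout to check within \code{sprouts}.
#' @param sprouts list of active sprouts (the partner sprout is consumed
#'   too when two tips meet).
#' @param net vascular network.
#' @param spec a [lattice_spec()].
#' @param r_init radius of newly formed vessels (um).
#' @param t_death sprout survival time (min).
#' @return list \code{outcome} (\code{"connected"}, \code{"still-growing"},
#'   \code{"dead"}), \code{net}, \code{sprouts} (with consumed sprouts
#'   removed), and \code{partner} (index of a co-consumed sprout or NA).
#' @export
try_anastomose <- function(idx, sprouts, net, spec, r_init = 6,
                           t_death = 3000) {
  sp <- sprouts[[idx]]
  tip <- sp$path[nrow(sp$path), ]
  tip_lin <- site_lin(tip, spec)
  origin_lin <- site_lin(sp$path[1L, ], spec)
  vlins <- vessel_site_lins(net)
  partner <- NA_integer_
  hit_vessel <- (tip_lin %in% vlins) && tip_lin != origin_lin &&
    nrow(sp$path) > 1L
  if (!hit_vessel && nrow(sp$path) > 1L) {
    for (o in seq_along(sprouts)) {
      if (o == idx) next
      ot <- sprouts[[o]]$path[nrow(sprouts[[o]]$path), ]
      if (site_lin(ot, spec) == tip_lin) { partner <- o; break }
    }
  }
  if (hit_vessel || !is.na(partner)) {
    paths <- list(sp$path)
    if (!is.na(partner)) {
      # join the partner's path tip-to-tip: both end at the meeting site
      pp <- sprouts[[partner]]$path
      paths <- c(paths, list(pp))
    }
    for (p in paths) net <- splice_path(net, p, spec, r_init)
    drop <- c(idx, if (!is.na(partner)) partner)
    sprouts <- sprouts[-drop]
    return(list(outcome = "connected", net = net, sprouts = sprouts,
                partner = partner))
  }
  if (sp$age > t_death) {
    sprouts <- sprouts[-idx]
    return(list(outcome = "dead", net = net, sprouts = sprouts,
                partner = NA_integer_))
  }
  list(outcome = "still-growing", net = net, sprouts = sprouts,
       partner = NA_integer_)
}

# Insert a tip path (rows = consecutive, face-adjacent sites) into the
# network: reuse nodes where a site already hosts one, create interior nodes
# elsewhere, add unit segments, skip duplicates and self-loops.
splice_path <- function(net, path, spec, r_init) {
  lins <- site_lin(path, spec)
  node_ids <- integer(length(lins))
  next_id <- if (nrow(net$nodes)) max(net$nodes$id) + 1L else 1L
  for (p in seq_along(lins)) {
    hit <- which(net$nodes$lin == lins[p])
    if (length(hit)) {
      node_ids[p] <- net$nodes$id[hit[1L]]
    } else {
      s <- path[p, ]
      net$nodes <- rbind(net$nodes,
                         data.frame(id = next_id, i = s[1], j = s[2],
                                    k = s[3], role = "interior",
                                    pressure = NA_real_, h_in = NA_real_,
                                    p = NA_real_,
                                    lin = lins[p])[names(net$nodes)])
      node_ids[p] <- next_id
      next_id <- next_id + 1L
    }
  }
  for (p in seq_len(length(lins) - 1L)) {
    a <- node_ids[p]; b <- node_ids[p + 1L]
    if (a == b) next
    dup <- any((net$segments$a == a & net$segments$b == b) |
                 (net$segments$a == b & net$segments$b == a))
    if (dup) next
    len <- sqrt(sum(wrapped_displacement(path[p, ], path[p + 1L, ], spec)^2))
    net$segments <- rbind(net$segments,
                          data.frame(a = a, b = b, radius = r_init,
                                     length = len, flow = 0, haematocrit = 0,
                                     wss = 0, clock = 0, perfused = FALSE))
  }
  net
}
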