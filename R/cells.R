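#' Default cellular parameters
#'
#' Oxygen concentrations are in normalised model units in which fully
#' oxygenated blood (inlet haematocrit) has concentration ~1. The two cell
#' kinds differ where the biology demands it: cancer cells consume more
#' oxygen than normal cells, and they start secreting VEGF at a higher
#' oxygen level (a lesser degree of hypoxia suffices to trigger release).
#' The subcellular closure is a cycle-phase variable plus linear p53 and
#' intracellular-VEGF kinetics with oxygen-switched production/decay; see
#' the methods vignette for forms, units and calibration.
#'
#' @return named list of parameters.
#' @export
cell_params <- function() {
  p <- list(
    capacity = 1L,            # cells per lattice site
    p_move = 0.1,             # per-step movement probability
    # cell cycle: T_cycle(O2) = t_min * (O2 + c_phi) / O2, decreasing in O2
    t_min_normal = 3000,      # min
    t_min_cancer = 1600,      # min
    c_phi = 0.1,              # O2 units
    # cancer quiescence thresholds (enter below, exit above) and survival
    o2_quiesce_enter = 0.10,
    o2_quiesce_exit = 0.12,
    q_arrest_rate = 0.023,    # 1/min: hazard of arrest while O2 < enter
    t_quiesce_max = 600,      # min a cancer cell survives quiescence
    # p53: dp/dt = a - (b0 + b1 * O2^2/(O2^2 + c^2)) * p  (Hill-2 switch)
    p53_prod = 0.03,          # conc/min
    p53_deg0 = 0.005,         # 1/min (hypoxic floor)
    p53_deg1 = 0.3,           # 1/min (oxygen-stimulated degradation)
    o2_half_p53 = 0.08,       # O2 units, half-point of the Hill-2 switch
    p53_thresh_high = 0.5,    # normal-cell death threshold, no cancer nearby
    p53_thresh_low = 0.1,     # threshold with cancer in the neighbourhood
    # intracellular VEGF mirrors p53 with hypoxia-switched production
    vegf_prod = 0.02, vegf_deg0 = 0.01, vegf_deg1 = 0.19,
    o2_half = 0.1,            # O2 units (VEGF kinetics)
    # oxygen thresholds for VEGF secretion onset (cancer > normal)
    o2_vegf_normal = 0.03,
    o2_vegf_cancer = 0.08,
    vegf_secretion = 0.04,    # conc/min added to the extracellular field
    # oxygen consumption (per-site linear sink while the site is occupied)
    o2_consume_normal = 2.0,  # 1/min
    o2_consume_cancer = 4.0   # 1/min
  )
  stopifnot(p$o2_vegf_cancer > p$o2_vegf_normal,
            p$o2_consume_cancer > p$o2_consume_normal)
  p
}

# Cell table constructor. Cells are rows of a data.frame; `lin` caches the
# linear site index. Status: "cycling" or "quiescent"; dead cells are removed
# immediately by death_check.
new_cells <- function(kind, sites, spec, phase = 0) {
  n <- length(kind)
  if (n == 0L)
    return(data.frame(id = integer(0), kind = character(0),
                      status = character(0), i = integer(0), j = integer(0),
                      k = integer(0), lin = integer(0), phase = numeric(0),
                      p53 = numeric(0), vegf = numeric(0),
                      qclock = numeric(0)))
  sites <- matrix(as.integer(sites), ncol = 3L)
  data.frame(id = seq_len(n), kind = kind, status = "cycling",
             i = sites[, 1L], j = sites[, 2L], k = sites[, 3L],
             lin = site_lin(sites, spec), phase = rep_len(phase, n),
             p53 = 0, vegf = 0, qclock = 0)
}

#' Advance the subcellular state of every cell over one macro time-step
#'
#' The cycle phase advances by \eqn{\Delta t / T_{cycle}(O_2)} with
#' \eqn{T_{cycle} = T_{min}(O_2 + c_\phi)/O_2} (shorter cycles at high
#' oxygen, arrest as oxygen vanishes). Cancer cells whose local oxygen falls
#' below the quiescence-entry threshold become quiescent (phase frozen,
#' clock running) and re-enter the cycle above the exit threshold. p53 and
#' intracellular VEGF follow linear kinetics with oxygen-dependent
#' degradation; the coefficients are constant over a macro step, so the
#' exact exponential update is applied.
#'
#' @param cells cell table.
#' @param o2 local oxygen per cell (same length as \code{nrow(cells)}).
#' @param dt macro time-step (min).
#' @param params see [cell_params()].
#' @return updated cell table.
#' @export
subcellular_step <- function(cells, o2, dt, params = cell_params()) {
  if (nrow(cells) == 0L) return(cells)
  if (any(!is.finite(o2)) || any(o2 < 0)) stop("local oxygen must be >= 0")
  cancer <- cells$kind == "cancer"
  # quiescence transitions (cancer only), hysteresis between the thresholds;
  # entry is a per-step hazard (cells arrest asynchronously, as at a cycle
  # checkpoint), exit on re-oxygenation is immediate
  at_risk <- which(cancer & cells$status == "cycling" &
                     o2 < params$o2_quiesce_enter)
  if (length(at_risk)) {
    p_arrest <- 1 - exp(-params$q_arrest_rate * dt)
    enter <- at_risk[stats::runif(length(at_risk)) < p_arrest]
    cells$status[enter] <- "quiescent"
  }
  exit <- cancer & cells$status == "quiescent" & o2 > params$o2_quiesce_exit
  cells$status[exit] <- "cycling"
  cells$qclock[exit] <- 0
  quiescent <- cells$status == "quiescent"
  cells$qclock[quiescent] <- cells$qclock[quiescent] + dt

  t_min <- ifelse(cancer, params$t_min_cancer, params$t_min_normal)
  t_cycle <- t_min * (o2 + params$c_phi) / pmax(o2, 1e-12)
  adv <- !quiescent
  cells$phase[adv] <- pmin(cells$phase[adv] + dt / t_cycle[adv], 1)

  # exact update of the linear ODE x' = a - b x over dt
  o2f53 <- o2^2 / (o2^2 + params$o2_half_p53^2)
  b53 <- params$p53_deg0 + params$p53_deg1 * o2f53
  fp53 <- params$p53_prod / b53
  cells$p53 <- fp53 + (cells$p53 - fp53) * exp(-b53 * dt)
  hypox <- o2 < ifelse(cancer, params$o2_vegf_cancer, params$o2_vegf_normal)
  o2f <- o2 / (o2 + params$o2_half)
  bv <- params$vegf_deg0 + params$vegf_deg1 * o2f
  av <- ifelse(hypox | quiescent, params$vegf_prod, 0)
  fv <- av / bv
  cells$vegf <- fv + (cells$vegf - fv) * exp(-bv * dt)
  if (any(!is.finite(cells$p53)) || any(!is.finite(cells$vegf)))
    stop("non-finite subcellular state")
  cells
}

#' Apply the death rules and remove dead cells
#'
#' A normal cell dies when its p53 level exceeds a threshold that switches to
#' the LOW value when cancer cells occupy its neighbourhood (its own site or
#' a face neighbour) and the HIGH value otherwise -- surviving tumour cells
#' thereby increase the death rate of nearby normal cells. A quiescent
#' cancer cell dies once its quiescence clock exceeds the maximum quiescence
#' duration.
#'
#' @param cells cell table.
#' @param occ occupancy (for the cancer-presence neighbourhood mask).
#' @param spec a [lattice_spec()].
#' @param params see [cell_params()].
#' @return list \code{cells} (survivors), \code{died} (number removed);
#'   occupancy counts are updated in place.
#' @export
death_check <- function(cells, occ, spec, params = cell_params()) {
  if (nrow(cells) == 0L) return(list(cells = cells, died = 0L))
  cancer_near <- neighbourhood_any(occ$cancer > 0L, spec)
  thresh <- ifelse(cancer_near[cells$lin],
                   params$p53_thresh_low, params$p53_thresh_high)
  die_normal <- cells$kind == "normal" & cells$p53 > thresh
  die_cancer <- cells$kind == "cancer" & cells$status == "quiescent" &
    cells$qclock > params$t_quiesce_max
  die <- die_normal | die_cancer
  if (any(die)) {
    for (kind in c("normal", "cancer")) {
      lin <- cells$lin[die & cells$kind == kind]
      if (length(lin)) {
        dec <- rowsum(rep(1L, length(lin)), lin)
        idx <- as.integer(rownames(dec))
        if (kind == "normal") occ$normal[idx] <- occ$normal[idx] - dec[, 1L]
        else occ$cancer[idx] <- occ$cancer[idx] - dec[, 1L]
      }
    }
  }
  list(cells = cells[!die, , drop = FALSE], died = sum(die))
}

#' Attempt division of one cell
#'
#' A cell whose cycle phase has reached 1 places a daughter uniformly at
#' random among the admissible sites with spare carrying capacity: its own
#' site plus the face neighbours. Both cells restart at phase 0. If no
#' admissible site has capacity the division is deferred (contact
#' inhibition): the phase is held at 1.
#'
#' @param site the mother's site (0-based triple).
#' @param occ occupancy.
#' @param spec a [lattice_spec()].
#' @return the daughter's site (triple) or \code{NULL} when blocked.
#'   Consumes one uniform draw from the R random stream when > 1 option.
#' @export
attempt_division <- function(site, occ, spec) {
  lin <- division_lin(site_lin(site, spec), occ, spec)
  if (is.na(lin)) return(NULL)
  site_from_lin(lin, spec)[1L, ]
}

# linear-index hot path: candidate = own site + face neighbours with spare
# capacity, uniform draw; NA when contact-inhibited
division_lin <- function(lin, occ, spec) {
  cand <- c(lin, spec$nb_face[lin, ])
  cand <- cand[!is.na(cand)]
  free <- cand[(occ$normal[cand] + occ$cancer[cand]) < occ$capacity]
  nf <- length(free)
  if (nf == 0L) return(NA_integer_)
  if (nf == 1L) free else free[floor(stats::runif(1) * nf) + 1L]
}

#' Attempt a random-walk move of one cell
#'
#' Destination sampled among the face neighbours with spare capacity,
#' weighted by the free capacity at each (a capacity-reinforced kernel; with
#' the default capacity of 1 this is uniform over empty neighbours). Returns
#' \code{NULL} when all neighbours are full (the cell stays put).
#'
#' @inheritParams attempt_division
#' @return new site or \code{NULL}.
#' @export
move_cell <- function(site, occ, spec) {
  lin <- move_lin(site_lin(site, spec), occ, spec)
  if (is.na(lin)) return(NULL)
  site_from_lin(lin, spec)[1L, ]
}

move_lin <- function(lin, occ, spec) {
  nb <- spec$nb_face[lin, ]
  nb <- nb[!is.na(nb)]
  freecap <- occ$capacity - (occ$normal[nb] + occ$cancer[nb])
  ok <- freecap > 0L
  if (!any(ok)) return(NA_integer_)
  w <- freecap[ok]
  opts <- nb[ok]
  if (length(opts) == 1L) return(opts)
  cw <- cumsum(w)
  opts[findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L]
}

#' VEGF secretion rate of a cell
#'
#' Cells secrete VEGF at a constant rate while hypoxic (local oxygen below
#' the kind-specific onset threshold -- higher for cancer cells) or while
#' quiescent, and not at all otherwise.
#'
#' @param kind \code{"normal"} or \code{"cancer"} (vectorised).
#' @param status \code{"cycling"} or \code{"quiescent"}.
#' @param o2 local oxygen concentration.
#' @param params see [cell_params()].
#' @return secretion rate (conc/min) per cell.
#' @export
vegf_secretion_rate <- function(kind, status, o2, params = cell_params()) {
  onset <- ifelse(kind == "cancer", params$o2_vegf_cancer,
                  params$o2_vegf_normal)
  ifelse(o2 < onset | status == "quiescent", params$vegf_secretion, 0)
}
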