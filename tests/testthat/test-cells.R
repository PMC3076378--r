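spec8 <- lattice_spec(c(8L, 8L, 8L))

make_cells <- function(kind, sites, spec = spec8, phase = 0) {
  tumorvasc:::new_cells(kind, sites, spec, phase)
}

test_that("cycle phase crosses 1 after about T_min at saturating oxygen", {
  p <- cell_params()
  cells <- make_cells("cancer", c(3L, 3L, 3L))
  o2 <- 50  # saturating: T_cycle -> t_min (O2 + c)/O2 ~ t_min
  t_cycle <- p$t_min_cancer * (o2 + p$c_phi) / o2
  steps_needed <- ceiling(t_cycle / 30)
  for (s in seq_len(steps_needed - 1L)) {
    cells <- subcellular_step(cells, o2, 30, p)
    expect_lt(cells$phase, 1)
  }
  cells <- subcellular_step(cells, o2, 30, p)
  expect_equal(cells$phase, 1)
})

test_that("hypoxic cancer cells arrest and freeze their cycle phase", {
  p <- cell_params()
  p$q_arrest_rate <- 1e6  # effectively instantaneous entry for this check
  cells <- make_cells("cancer", c(3L, 3L, 3L), phase = 0.4)
  set.seed(1)
  cells <- subcellular_step(cells, p$o2_quiesce_enter / 2, 30, p)
  expect_equal(cells$status, "quiescent")
  expect_equal(cells$phase, 0.4)
  expect_equal(cells$qclock, 30)
  # re-oxygenation above the exit threshold resumes cycling
  cells <- subcellular_step(cells, p$o2_quiesce_exit + 0.05, 30, p)
  expect_equal(cells$status, "cycling")
  expect_equal(cells$qclock, 0)
  expect_gt(cells$phase, 0.4)
})

test_that("quiescence entry is a hazard, not a synchronous switch", {
  p <- cell_params()
  n <- 4000L
  cells <- make_cells(rep("cancer", n),
                      cbind(rep(3L, n), rep(3L, n), rep(3L, n)))
  set.seed(2)
  cells <- subcellular_step(cells, rep(p$o2_quiesce_enter / 2, n), 30, p)
  frac <- mean(cells$status == "quiescent")
  expected <- 1 - exp(-p$q_arrest_rate * 30)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("sustained anoxia drives p53 monotonically toward its hypoxic fixed point", {
  p <- cell_params()
  cells <- make_cells("normal", c(3L, 3L, 3L))
  fp <- p$p53_prod / p$p53_deg0  # O2 = 0 fixed point
  prev <- 0
  vals <- numeric(50)
  for (s in 1:50) {
    cells <- subcellular_step(cells, 0, 30, p)
    vals[s] <- cells$p53
  }
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < fp))
  # exact exponential relaxation of the linear ODE
  t <- 30 * (1:50)
  expect_equal(vals, fp * (1 - exp(-p$p53_deg0 * t)), tolerance = 1e-10)
})

test_that("death rules: p53 threshold switch and quiescence timeout", {
  p <- cell_params()
  spec <- spec8
  # normal cell with p53 between the two thresholds: survives alone, dies
  # with a cancer neighbour
  mid <- (p$p53_thresh_low + p$p53_thresh_high) / 2
  occ <- new_occupancy(spec)
  cells <- make_cells("normal", c(3L, 3L, 3L))
  cells$p53 <- mid
  occ$normal[cells$lin] <- 1L
  res <- death_check(cells, occ, spec, p)
  expect_equal(res$died, 0L)
  # p53 = 0 always survives
  cells0 <- cells; cells0$p53 <- 0
  expect_equal(death_check(cells0, occ, spec, p)$died, 0L)
  # add a cancer cell next door: LOW threshold now applies
  occ2 <- new_occupancy(spec)
  both <- rbind(cells, make_cells("cancer", c(4L, 3L, 3L)))
  both$id <- 1:2; both$p53 <- c(mid, 0)
  occ2$normal[both$lin[1]] <- 1L; occ2$cancer[both$lin[2]] <- 1L
  res2 <- death_check(both, occ2, spec, p)
  expect_equal(res2$died, 1L)
  expect_equal(res2$cells$kind, "cancer")
  expect_equal(sum(occ2$normal), 0L)
  # quiescent cancer cell beyond the survival time is removed
  occ3 <- new_occupancy(spec)
  qc <- make_cells("cancer", c(2L, 2L, 2L))
  qc$status <- "quiescent"; qc$qclock <- p$t_quiesce_max + 30
  occ3$cancer[qc$lin] <- 1L
  expect_equal(death_check(qc, occ3, spec, p)$died, 1L)
})

test_that("division respects carrying capacity and places daughters uniformly", {
  spec <- spec8
  occ <- new_occupancy(spec)
  site <- c(3L, 3L, 3L)
  # all 6 neighbours and own site full: blocked
  occ$normal[tumorvasc:::site_lin(site, spec)] <- 1L
  nb <- site_neighbours(site, spec)
  occ$normal[tumorvasc:::site_lin(nb, spec)] <- 1L
  expect_null(attempt_division(site, occ, spec))
  # exactly one free neighbour: chosen with certainty
  free <- nb[4, ]
  occ$normal[tumorvasc:::site_lin(free, spec)] <- 0L
  expect_equal(attempt_division(site, occ, spec), free,
               ignore_attr = TRUE)
  # two free neighbours: ~50/50 over 1e4 draws
  occ$normal[tumorvasc:::site_lin(nb[1, ], spec)] <- 0L
  set.seed(3)
  picks <- replicate(1e4, attempt_division(site, occ, spec)[1])
  frac <- mean(picks == nb[1, 1])
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("movement is blocked by full neighbourhoods and isotropic on empty ones", {
  spec <- spec8
  occ <- new_occupancy(spec)
  site <- c(3L, 3L, 3L)
  nb <- site_neighbours(site, spec)
  occ$normal[tumorvasc:::site_lin(nb, spec)] <- 1L
  expect_null(move_cell(site, occ, spec))
  # empty lattice: all 6 directions equiprobable within 3 SE over 1e4 draws
  occ2 <- new_occupancy(spec)
  set.seed(4)
  dest <- t(replicate(1e4, move_cell(site, occ2, spec)))
  keys <- paste(dest[, 1], dest[, 2], dest[, 3])
  tab <- table(keys)
  expect_equal(length(tab), 6L)
  se <- sqrt((1 / 6) * (5 / 6) / 1e4)
  expect_true(all(abs(tab / 1e4 - 1 / 6) < 3 * se))
})

test_that("periodic wrap moves have the same statistics as interior moves", {
  spec <- lattice_spec(c(6L, 6L, 6L), bc = "periodic")
  occ <- new_occupancy(spec)
  edge <- c(0L, 3L, 3L)
  set.seed(5)
  dest <- t(replicate(1e4, move_cell(edge, occ, spec)))
  keys <- paste(dest[, 1], dest[, 2], dest[, 3])
  tab <- table(keys)
  expect_equal(length(tab), 6L)  # incl. the wrapped neighbour (5,3,3)
  expect_true(paste(5, 3, 3) %in% names(tab))
  se <- sqrt((1 / 6) * (5 / 6) / 1e4)
  expect_true(all(abs(tab / 1e4 - 1 / 6) < 3 * se))
})

test_that("VEGF secretion follows hypoxia and quiescence rules", {
  p <- cell_params()
  # normoxic cycling normal cell: silent
  expect_equal(vegf_secretion_rate("normal", "cycling", 0.5, p), 0)
  # quiescent cancer cell: secretes regardless of oxygen
  expect_gt(vegf_secretion_rate("cancer", "quiescent", 0.5, p), 0)
  # oxygen between the onset thresholds: cancer secretes, normal does not
  mid <- (p$o2_vegf_normal + p$o2_vegf_cancer) / 2
  expect_gt(vegf_secretion_rate("cancer", "cycling", mid, p), 0)
  expect_equal(vegf_secretion_rate("normal", "cycling", mid, p), 0)
})

test_that("raising uniform oxygen weakly increases a patch's 200-step population", {
  # cells-module ensemble at fixed ambient oxygen, no vessels: mean final
  # population is non-decreasing in O2 (20 seeds per level)
  p <- cell_params()
  spec <- lattice_spec(c(8L, 8L, 8L))
  run_patch <- function(o2, seed) {
    set.seed(seed)
    occ <- new_occupancy(spec)
    sites <- as.matrix(expand.grid(i = 3:4, j = 3:4, k = 3:4))
    cells <- make_cells(rep("cancer", nrow(sites)), sites, spec,
                        phase = runif(nrow(sites)))
    occ$cancer[cells$lin] <- 1L
    for (s in 1:200) {
      if (nrow(cells) == 0L) break
      cells <- subcellular_step(cells, rep(o2, nrow(cells)), 30, p)
      res <- death_check(cells, occ, spec, p)
      cells <- res$cells
      ready <- which(cells$phase >= 1 & cells$status == "cycling")
      for (m in ready) {
        dest <- tumorvasc:::division_lin(cells$lin[m], occ, spec)
        if (is.na(dest)) next
        cells$phase[m] <- 0
        occ$cancer[dest] <- occ$cancer[dest] + 1L
        ds <- tumorvasc:::site_from_lin(dest, spec)
        cells <- rbind(cells, data.frame(
          id = max(cells$id) + 1L, kind = "cancer", status = "cycling",
          i = ds[1], j = ds[2], k = ds[3], lin = dest, phase = 0, p53 = 0,
          vegf = 0, qclock = 0))
      }
    }
    nrow(cells)
  }
  levels <- c(0.05, 0.2, 0.6)
  means <- vapply(levels, function(o2)
    mean(vapply(1:20, function(sd) run_patch(o2, sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("cell count changes only through division and death in engine steps", {
  cfg <- small_growth_config()
  state <- init_state("countercurrent_pair", cfg, seed = 9)
  for (s in 1:10) {
    n0 <- nrow(state$cells)
    id0 <- state$next_cell_id
    state <- step_state(state)
    births <- state$next_cell_id - id0
    deaths <- n0 + births - nrow(state$cells)
    expect_gte(deaths, 0)
    expect_equal(nrow(state$cells), n0 + births - deaths)
    expect_true(tumorvasc:::audit_occupancy(state))
  }
})
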