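# Event-driven core: exact ballistic propagation, impulsive collision rules,
# conservation laws, thermostat statistics, and oracle equivalence of the
# optimized and naive schedulers.

# bare two-bead topology with a single non-bonded hard-core potential
two_bead_topo <- function(masses = c(50, 50), hard_core = 5, box = 0,
                          shells = NULL) {
  types <- data.frame(label = "b", radius = hard_core / 2, charge = 0,
                      hydro = 0)
  beads <- data.frame(type = 1L, mass = masses, radius = hard_core / 2,
                      charge = 0, residue = NA_integer_,
                      domain = NA_character_, role = "bead",
                      entity = "fixture")
  pot <- if (is.null(shells)) step_potential(hard_core, hard_core + 1e-4, 0)
         else shells
  dmd_topology(beads, list(pot), matrix(1L, 1, 1), box = box)
}

no_thermo <- function(seed = 1, frame_interval_ns = 0.005)
  engine_config(thermostat_rate = 0, seed = seed,
                frame_interval_ns = frame_interval_ns)

test_that("zero-duration and free-flight runs are exact", {
  topo <- two_bead_topo()
  st <- system_state(rbind(c(0, 0, 0), c(20, 0, 0)),
                     rbind(c(0.1, 0, 0), c(-0.05, 0.02, 0)))
  tr0 <- run_dmd(topo, st, 0, no_thermo())
  expect_length(tr0$times, 1)
  expect_identical(tr0$frames[[1]], st$positions)
  # no interaction within range: straight lines
  dur_tu <- 100
  tr <- run_dmd(topo, st, tu_to_ns(dur_tu), no_thermo())
  expect_equal(tr$final_state$positions,
               st$positions + dur_tu * st$velocities, tolerance = 1e-12)
  expect_equal(sum(tr$diagnostics$n_events), 0)
})

test_that("head-on hard-core collision happens at the predicted time and exchanges velocities", {
  # |r| = 10, closing speed 1, core 5 -> contact at t = 5; equal masses
  topo <- two_bead_topo()
  st <- system_state(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  tr <- run_dmd(topo, st, tu_to_ns(8), no_thermo())
  # after the exchange at t=5, bead 1 retraces: x1(8) = 0.5*5 - 0.5*3
  expect_equal(tr$final_state$positions[1, ], c(2.5 - 1.5, 0, 0),
               tolerance = 1e-10)
  expect_equal(tr$final_state$velocities[1, ], c(-0.5, 0, 0))
  expect_equal(tr$final_state$velocities[2, ], c(0.5, 0, 0))
})

test_that("oblique collisions agree with a dense time-scan oracle", {
  topo <- two_bead_topo()
  set.seed(42)
  for (case in 1:5) {
    p2 <- c(12, runif(2, -2, 2))
    v1 <- c(runif(1, 0.3, 0.6), runif(2, -0.1, 0.1))
    st <- system_state(rbind(c(0, 0, 0), p2), rbind(v1, -v1))
    # oracle: scan |r(t)| on a dense grid, refine by bisection to 1e-12
    relp <- p2; relv <- -2 * v1
    f <- function(t) sqrt(sum((relp + t * relv)^2)) - 5
    grid <- seq(0, 40, by = 0.001)
    gi <- which(vapply(grid, f, 0) < 0)[1]
    t_star <- uniroot(f, c(grid[gi - 1], grid[gi]), tol = 1e-13)$root
    # the engine must coast freely until t_star (velocities untouched,
    # positions exactly ballistic) ...
    tr <- run_dmd(topo, st, tu_to_ns(t_star * 0.999), no_thermo())
    expect_equal(unname(tr$final_state$positions),
                 unname(st$positions + t_star * 0.999 * st$velocities),
                 tolerance = 1e-9)
    expect_equal(unname(tr$final_state$velocities), unname(st$velocities))
    # ... and have bounced off the core just after it
    tr2 <- run_dmd(topo, st, tu_to_ns(t_star * 1.001), no_thermo())
    expect_false(isTRUE(all.equal(unname(tr2$final_state$velocities),
                                  unname(st$velocities))))
  }
})

test_that("well transmission converts potential to kinetic energy exactly", {
  well <- step_potential(2, c(4, 8), c(-0.3, 0))
  topo <- two_bead_topo(shells = well, hard_core = 2)
  st <- system_state(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0.05, 0, 0), c(-0.05, 0, 0)))
  ke <- function(v, m = c(50, 50)) sum(0.5 * m * rowSums(v^2))
  # two crossings: the outer zero shell at 8 (no kick), then the well edge
  # at 4 where exactly 0.3 kcal/mol of potential becomes kinetic energy
  tr <- run_dmd(topo, st, tu_to_ns(65), no_thermo())
  expect_equal(tr$diagnostics$n_events[["pair"]], 2)
  expect_equal(ke(tr$final_state$velocities) - ke(st$velocities), 0.3,
               tolerance = 1e-12)
  # momentum conserved exactly
  expect_equal(colSums(50 * tr$final_state$velocities),
               colSums(50 * st$velocities))
})

test_that("reflection at an energy step conserves kinetic energy and negates radial motion", {
  # barrier +5 too high for the approach energy: elastic reflection
  barrier <- step_potential(2, c(4, 8), c(5, 0))
  topo <- two_bead_topo(shells = barrier, hard_core = 2)
  st <- system_state(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0.05, 0, 0), c(-0.05, 0, 0)))
  tr <- run_dmd(topo, st, tu_to_ns(65), no_thermo())
  expect_equal(tr$diagnostics$n_events[["pair"]], 2)  # outer shell + step
  expect_equal(tr$final_state$velocities,
               rbind(c(-0.05, 0, 0), c(0.05, 0, 0)))
})

test_that("steering impulses realize the requested force with the unit conversion", {
  # single steered bead, m = 100 Da, F = 10 pN, interval 1 t.u.
  types <- data.frame(label = "b", radius = 1, charge = 0, hydro = 0)
  beads <- data.frame(type = 1L, mass = c(100, 100), radius = 1, charge = 0,
                      residue = NA_integer_, domain = NA_character_,
                      role = "bead", entity = "fixture")
  topo <- dmd_topology(beads, list(step_potential(2, 2.1, 0)),
                       matrix(1L, 1, 1))
  st <- system_state(rbind(c(0, 0, 0), c(50, 0, 0)))
  n_iv <- 20
  cfg <- no_thermo()
  tr <- run_dmd(topo, st, tu_to_ns(n_iv), cfg,
                steer = list(group = 1L, force_pN = 10,
                             direction = c(1, 0, 0)))
  dv_expected <- (10 / pn_per_kcalmolA()) / 100 * 1  # F dt / m
  expect_equal(tr$final_state$velocities[1, 1], n_iv * dv_expected,
               tolerance = 1e-12)
  expect_equal(tr$final_state$velocities[2, ], c(0, 0, 0))
  # two impulses of F match one impulse of 2F in total momentum (linearity)
  tr2 <- run_dmd(topo, st, tu_to_ns(n_iv), cfg,
                 steer = list(group = 1L, force_pN = 20,
                              direction = c(1, 0, 0)))
  expect_equal(tr2$final_state$velocities[1, 1],
               2 * tr$final_state$velocities[1, 1], tolerance = 1e-12)
  # F = 0 leaves the state unchanged
  tr0 <- run_dmd(topo, st, tu_to_ns(n_iv), cfg,
                 steer = list(group = 1L, force_pN = 0,
                              direction = c(1, 0, 0)))
  expect_equal(tr0$final_state$positions, st$positions)
})

test_that("thermostat resampling reproduces the equipartition temperature", {
  # 50-bead ideal gas in a box
  nb <- 50
  types <- data.frame(label = "b", radius = 1, charge = 0, hydro = 0)
  beads <- data.frame(type = 1L, mass = 60, radius = 1, charge = 0,
                      residue = NA_integer_, domain = NA_character_,
                      role = "bead", entity = "fixture")[rep(1, nb), ]
  topo <- dmd_topology(beads, list(step_potential(2, 2.1, 0)),
                       matrix(1L, 1, 1), box = 100)
  g <- as.matrix(expand.grid(seq(10, 90, length.out = 4),
                             seq(10, 90, length.out = 4),
                             seq(10, 90, length.out = 4)))[seq_len(nb), ]
  st <- system_state(g, make_mb_velocity_sample(nb, 300, 60, seed = 3))
  cfg <- engine_config(temperature = 300, thermostat_rate = 0.2, seed = 9,
                       frame_interval_ns = 0.002)
  tr <- run_dmd(topo, st, 0.5, cfg)
  expect_gt(tr$diagnostics$n_events[["thermostat"]], 1e4)
  # speeds sampled from independent short runs (final states decorrelate)
  kT <- kT_kcalmol(300)
  sp <- numeric(0)
  for (s in 1:6) {
    cfg_s <- engine_config(temperature = 300, thermostat_rate = 0.2,
                           seed = s, frame_interval_ns = 0.01)
    tr_s <- run_dmd(topo, st, 0.05, cfg_s)
    sp <- c(sp, sqrt(rowSums(tr_s$final_state$velocities^2)))
  }
  # Kolmogorov-Smirnov against the Maxwell-Boltzmann speed distribution
  mb_cdf <- function(s) pchisq(60 * s^2 / kT, df = 3)
  ks <- suppressWarnings(stats::ks.test(sp, mb_cdf))
  expect_gt(ks$p.value, 0.01)
  ke_dof <- 0.5 * 60 * sp^2 / 3
  se <- sd(ke_dof) / sqrt(length(ke_dof))
  expect_lt(abs(mean(ke_dof) - kT / 2), 3 * se)
  # T -> 0 limit: resampled velocities vanish
  cfg0 <- engine_config(temperature = 1e-12, thermostat_rate = 0.5, seed = 2,
                        frame_interval_ns = 0.01)
  tr0 <- run_dmd(topo, st, 0.05, cfg0)
  expect_lt(max(abs(tr0$final_state$velocities)), 1e-5)
})

test_that("optimized and reference schedulers are bit-identical on seeded systems", {
  # >= 5 seeded cases covering bonds, wells, thermostat and steering
  for (s in 1:6) {
    sys <- small_test_system(nb = 8, seed = s)
    cfg <- engine_config(temperature = 300, thermostat_rate = 0.1, seed = s,
                         frame_interval_ns = 0.002)
    steer <- if (s %% 2 == 0)
      list(group = c(5L, 6L), force_pN = 15, direction = c(1, 0.5, 0))
    else NULL
    fast <- run_dmd(sys$topology, sys$state, 0.2, cfg, steer = steer)
    ref <- reference_run(sys$topology, sys$state, 0.2, cfg, steer = steer)
    expect_gt(sum(fast$diagnostics$n_events), 1e3)
    expect_identical(fast$frames, ref$frames)
    expect_identical(fast$final_state$positions, ref$final_state$positions)
    expect_identical(fast$final_state$velocities, ref$final_state$velocities)
  }
})

test_that("energy ledger is conserved and hard cores are never violated", {
  sys <- small_test_system(nb = 10, seed = 4)
  cfg <- engine_config(temperature = 300, thermostat_rate = 0.1, seed = 4,
                       frame_interval_ns = 0.002)
  tr <- run_dmd(sys$topology, sys$state, 0.6, cfg)
  expect_gt(sum(tr$diagnostics$n_events), 1e4)
  expect_lt(tr$diagnostics$max_ledger_dev, 1e-6)
  expect_false(tr$diagnostics$overlap_seen)
  # no frame shows a pair below the 3.0 A core (bonded/Go pairs excluded)
  expect_gt(min(min_pair_distance(tr, exclude = rbind(c(1, 2), c(3, 4)))),
            3.0 - 1e-7)
})

test_that("total momentum is conserved exactly without walls and thermostat", {
  well <- step_potential(3, c(5, 9), c(-0.4, 0.2))
  topo <- two_bead_topo(masses = c(37, 81), shells = well, hard_core = 3)
  st <- system_state(rbind(c(0, 0, 0), c(11, 1.5, -0.7)),
                     rbind(c(0.06, 0.01, 0), c(-0.04, -0.03, 0.02)))
  tr <- run_dmd(topo, st, tu_to_ns(300), no_thermo())
  expect_gt(tr$diagnostics$n_events[["pair"]], 0)
  p0 <- colSums(c(37, 81) * st$velocities)
  p1 <- colSums(c(37, 81) * tr$final_state$velocities)
  expect_equal(p1, p0, tolerance = 1e-13)
})

test_that("runs are deterministic in the seed and immobilized beads never move", {
  sys <- small_test_system(nb = 8, seed = 7)
  topo <- set_immobilized(sys$topology, c(7L, 8L))
  cfg <- engine_config(seed = 7, frame_interval_ns = 0.005)
  a <- run_dmd(topo, sys$state, 0.2, cfg)
  b <- run_dmd(topo, sys$state, 0.2, cfg)
  expect_identical(a$frames, b$frames)
  for (fr in a$frames) {
    expect_equal(fr[7, ], unname(sys$state$positions[7, ]))
    expect_equal(fr[8, ], unname(sys$state$positions[8, ]))
  }
  # steered and immobilized sets must be disjoint
  expect_error(run_dmd(topo, sys$state, 0.01, cfg,
                       steer = list(group = 8L, force_pN = 5,
                                    direction = c(1, 0, 0))),
               "disjoint")
})

test_that("a bonded pair never escapes its window over a long run", {
  fx <- make_two_bead_system(well_depth = 0, well_range = c(4, 6),
                             hard_core = 3.6)
  cfg <- engine_config(seed = 5, thermostat_rate = 0.1,
                       frame_interval_ns = tu_to_ns(10))
  tr <- run_dmd(fx$topology, fx$state, tu_to_ns(1e4), cfg,
                track_pair = c(1, 2), store_frames = FALSE)
  expect_lte(max(tr$track_distances), 6 + 1e-6)
  expect_gte(min(tr$track_distances), 3.6 - 1e-6)
})
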