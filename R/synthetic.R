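# Self-describing synthetic systems and scripted fixtures: every stage of
# the pipeline is testable without external data.

#' Two-bead bonded pair in a square well (analytic testbed)
#'
#' A single bonded pair in a two-shell potential: an attractive inner
#' shell `(hard_core, well_range[1]]` of depth `well_depth` and an outer
#' shell `(well_range[1], well_range[2]]` of zero energy bounded by an
#' infinite wall.  The analytic equilibrium occupancy of the inner shell
#' is the Boltzmann-weighted shell-volume ratio
#' `V_in e^(E/kT) / (V_in e^(E/kT) + V_out)` with `V` the differences of
#' cubed radii; for a head-on pair the wall-bounce period is closed-form.
#'
#' @param well_depth inner-shell depth (kcal/mol, >= 0)
#' @param well_range inner and outer shell boundaries (Angstrom)
#' @param masses the two bead masses (Da)
#' @param temperature K (used for the analytic occupancy)
#' @param hard_core inner infinite wall (Angstrom)
#' @return list: `topology`, `state` (head-on initial condition),
#'   `analytic` (inner-shell occupancy, head-on bounce period function)
#' @export
make_two_bead_system <- function(well_depth = 0.3, well_range = c(4, 6),
                                 masses = c(50, 50), temperature = 300,
                                 hard_core = 2) {
  stopifnot(well_range[1] > hard_core, well_range[2] > well_range[1])
  types <- data.frame(label = "bead", radius = hard_core / 2, charge = 0,
                      hydro = 0)
  beads <- data.frame(type = 1L, mass = masses, radius = hard_core / 2,
                      charge = 0, residue = NA_integer_,
                      domain = NA_character_, role = "bead",
                      entity = "fixture")
  pot <- step_potential(hard_core, well_range, c(-well_depth, 0),
                        infinite_outer_wall = TRUE)
  topo <- dmd_topology(beads, list(pot), matrix(0L, 1, 1),
                       overrides = data.frame(i = 1L, j = 2L, pot = 1L))
  attr(topo, "types") <- types
  mid <- mean(well_range)
  st <- system_state(rbind(c(0, 0, 0), c(mid, 0, 0)))
  kT <- kT_kcalmol(temperature)
  v_in <- well_range[1]^3 - hard_core^3
  v_out <- well_range[2]^3 - well_range[1]^3
  w <- v_in * exp(well_depth / kT)
  # head-on bounce period for relative speed v outside/inside the well
  period <- function(v_rel) {
    mu <- prod(masses) / sum(masses)
    v_in_shell <- sqrt(v_rel^2 + 2 * well_depth / mu)
    2 * ((well_range[2] - well_range[1]) / v_rel +
         (well_range[1] - hard_core) / v_in_shell)
  }
  list(topology = topo, state = st,
       analytic = list(occupancy_inner = w / (w + v_out),
                       v_in = v_in, v_out = v_out,
                       head_on_period = period))
}

#' Synthetic charged-patch dimer test system
#'
#' Wraps [build_synthetic_dimer()] (interfacial Go patch on residues 1-5,
#' positively charged loop patch distal to the interface) and optionally
#' pairs it with an anionic polymer in a box.
#'
#' @param n_res residues per domain
#' @param patch_size number of charged patch residues
#' @param patch_charge per-residue patch charge (0 disables the patch)
#' @param seed integer seed
#' @param with_plastic also build and place a PS 20-mer
#' @param box_side box side (Angstrom) when assembling
#' @param ... passed to [build_synthetic_dimer()]
#' @return the `cadherin_model`, or a `dmd_system` when `with_plastic`
#' @export
make_patch_dimer_system <- function(n_res = 24, patch_size = 4,
                                    patch_charge = 1, seed = 1,
                                    with_plastic = FALSE, box_side = 120,
                                    ...) {
  start <- round(2 * n_res / 3)
  patch <- start + seq_len(patch_size) - 1L
  dimer <- build_synthetic_dimer(
    n_res_per_domain = n_res,
    patch_spec = list(residues = patch, charge = patch_charge),
    seed = seed, ...)
  if (!with_plastic) return(dimer)
  pl <- build_polymer("PS", seed = seed)
  assemble(dimer, pl, box_side = box_side, seed = seed)
}

#' Scripted-contact trajectory fixture
#'
#' Builds a trajectory whose tagged-bead geometry realizes a scripted
#' inter-selection contact series exactly: `n_channels` A/B bead pairs are
#' isolated 100 Angstrom apart; at frame f the first `contacts[f]` pairs
#' sit at `near` (in contact) and the rest at `far`.  The expected analysis
#' outputs (first dissociation time, per-channel contact frequency) are
#' attached, so fixtures are self-describing.
#'
#' @param times frame times (ns, strictly increasing)
#' @param contacts_series integer contact count per frame
#' @param n_channels number of A/B pairs (default `max(contacts_series)`)
#' @param near,far in/out-of-contact distances (Angstrom)
#' @return list: `trajectory`, `sel_a`, `sel_b`, `beads`,
#'   `expected` (first_zero_time_ns, channel_frequency)
#' @export
make_scripted_trajectory <- function(times, contacts_series,
                                     n_channels = NULL, near = 3,
                                     far = 20) {
  stopifnot(length(times) == length(contacts_series),
            all(diff(times) > 0), all(contacts_series >= 0))
  if (is.null(n_channels)) n_channels <- max(contacts_series, 1)
  stopifnot(all(contacts_series <= n_channels), near < 6.5, far > 6.5)
  k <- seq_len(n_channels)
  base_x <- (k - 1) * 100
  frames <- lapply(contacts_series, function(cc) {
    d <- ifelse(k <= cc, near, far)
    rbind(cbind(base_x, 0, 0), cbind(base_x, d, 0))
  })
  sel_a <- k; sel_b <- n_channels + k
  beads <- data.frame(type = 1L, mass = 100, radius = 1,
                      charge = 0, residue = c(k, k),
                      domain = rep(c("A", "B"), each = n_channels),
                      role = "bead", entity = "fixture")
  first0 <- which(contacts_series == 0)[1]
  traj <- structure(list(times = times, frames = frames,
                         final_state = system_state(frames[[length(frames)]]),
                         diagnostics = list(n_events = c(pair = 0, wall = 0,
                                                         thermostat = 0,
                                                         steer = 0),
                                            max_ledger_dev = 0,
                                            steer_work = 0,
                                            thermo_increment = 0,
                                            overlap_seen = FALSE)),
                    class = "dmd_trajectory")
  list(trajectory = traj, sel_a = sel_a, sel_b = sel_b, beads = beads,
       expected = list(
         first_zero_time_ns = if (is.na(first0)) NA_real_ else times[first0],
         channel_frequency = vapply(k, function(ch)
           mean(contacts_series >= ch), 0)))
}

#' Maxwell-Boltzmann velocity sample
#'
#' Each component of bead i is drawn from a normal distribution with
#' variance kT/m_i; reproducible from the seed, with the caller's RNG
#' state untouched.
#'
#' @param n number of beads
#' @param temperature K
#' @param masses per-bead masses (Da), length n (or scalar)
#' @param seed integer seed
#' @return n x 3 velocity matrix (Angstrom per time unit)
#' @export
make_mb_velocity_sample <- function(n, temperature, masses, seed = 1) {
  masses <- rep_len(masses, n)
  sdv <- sqrt(kT_kcalmol(temperature) / masses)
  local_seed(seed, matrix(rnorm(3 * n, sd = rep(sdv, 3)), n, 3))
}
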