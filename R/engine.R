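# R-facing wrapper around the event-driven core.

#' Engine configuration
#'
#' @param temperature thermostat temperature (K, > 0)
#' @param thermostat_rate Anderson thermostat collision rate per mobile bead
#'   per time unit (>= 0; 0 disables the thermostat)
#' @param steer_interval spacing of steering impulses (time units)
#' @param seed integer seed for the engine's own deterministic generator
#' @param frame_interval_ns spacing of emitted frames (ns)
#' @return an object of class `engine_config`
#' @export
engine_config <- function(temperature = 300, thermostat_rate = 0.1,
                          steer_interval = 1, seed = 1,
                          frame_interval_ns = 0.005) {
  stopifnot(temperature > 0, thermostat_rate >= 0, steer_interval > 0,
            frame_interval_ns > 0)
  structure(list(temperature = temperature,
                 thermostat_rate = thermostat_rate,
                 steer_interval = steer_interval,
                 seed = as.integer(seed),
                 frame_interval_ns = frame_interval_ns),
            class = "engine_config")
}

#' Run an event-driven DMD simulation
#'
#' Advances the system exactly between impulsive events (shell crossings,
#' wall bounces, thermostat resamplings, steering impulses), emitting frames
#' at a fixed stride.  Output is bit-identical for identical inputs, seed
#' and mode pairings: the optimized and reference schedulers execute the
#' same event sequence.
#'
#' @param topology a [dmd_topology()]
#' @param state a [system_state()]
#' @param duration_ns run length (ns); 0 returns the initial frame only
#' @param config an [engine_config()]
#' @param steer optional constant-force steering: a list with elements
#'   `group` (bead ids), `force_pN` (magnitude, pN) and `direction`
#'   (3-vector, normalized internally).  The force is realized as periodic
#'   momentum impulses every `config$steer_interval` time units, distributed
#'   over the group in proportion to mass (uniform acceleration).
#' @param mode `"fast"` (event heap with lazy invalidation) or `"reference"`
#'   (naive full re-prediction after every event; the correctness oracle)
#' @param store_frames keep frame coordinates (set `FALSE` for long
#'   observable-only runs)
#' @param track_pair optional pair of bead ids whose exact time-weighted
#'   shell occupancy and per-frame distance are recorded
#' @return an object of class `dmd_trajectory`: `times` (ns), `frames`
#'   (list of n x 3 matrices), `final_state`, `diagnostics` (event counts,
#'   energy-ledger drift, steering work, thermostat energy, overlap flag),
#'   and, when tracked, `track_distances` / `track_region_time`
#' @export
run_dmd <- function(topology, state, duration_ns,
                    config = engine_config(), steer = NULL,
                    mode = c("fast", "reference"),
                    store_frames = TRUE, track_pair = NULL) {
  stopifnot(inherits(topology, "dmd_topology"),
            inherits(state, "system_state"), duration_ns >= 0)
  mode <- match.arg(mode)
  n <- nrow(topology$beads)
  stopifnot(nrow(state$positions) == n)

  mobile <- !(seq_len(n) %in% topology$immobilized)
  steer_group <- integer()
  steer_dv <- c(0, 0, 0)
  steer_interval <- config$steer_interval
  if (!is.null(steer) && length(steer$group) && steer$force_pN != 0) {
    stopifnot(all(steer$group >= 1), all(steer$group <= n))
    if (any(!mobile[steer$group]))
      stop("steered and immobilized sets must be disjoint")
    dir <- steer$direction / sqrt(sum(steer$direction^2))
    f <- pn_to_kcalmolA(steer$force_pN)          # kcal/mol/A
    m_tot <- sum(topology$beads$mass[steer$group])
    # total momentum increment F * dt, distributed in proportion to mass:
    # every group bead receives the same velocity increment
    steer_dv <- dir * f * steer_interval / m_tot
    steer_group <- as.integer(steer$group)
  }

  if (duration_ns == 0) {
    return(structure(list(
      times = 0, frames = list(state$positions),
      final_state = state,
      diagnostics = list(n_events = c(pair = 0, wall = 0, thermostat = 0,
                                      steer = 0),
                         max_ledger_dev = 0, steer_work = 0,
                         thermo_increment = 0, overlap_seen = FALSE)),
      class = "dmd_trajectory"))
  }

  duration_tu <- ns_to_tu(duration_ns)
  n_frames <- max(1L, round(duration_ns / config$frame_interval_ns))
  stride_tu <- duration_tu / n_frames

  pots <- lapply(topology$potentials, function(p)
    list(boundaries = c(p$hard_core, p$edges), energies = p$energies,
         infinite_outer_wall = p$infinite_outer_wall))
  ov <- topology$overrides
  res <- .dmd_run_cpp(
    positions = state$positions, velocities = state$velocities,
    mass = topology$beads$mass, type = as.integer(topology$beads$type),
    mobile = mobile, potentials = pots, nb_table = topology$nb_table,
    overrides = cbind(as.integer(ov$i), as.integer(ov$j)),
    override_pot = as.integer(ov$pot),
    box = topology$box, kT = kT_kcalmol(config$temperature),
    thermo_rate = config$thermostat_rate,
    steer_group = steer_group, steer_interval = steer_interval,
    steer_dv = steer_dv,
    duration = duration_tu, frame_stride = stride_tu,
    seed = as.double(config$seed), mode = if (mode == "fast") 0L else 1L,
    store_frames = store_frames,
    track_pair = if (is.null(track_pair)) c(0L, 0L)
                 else as.integer(track_pair))

  out <- list(
    times = state$time + tu_to_ns(res$times),
    frames = if (store_frames) res$frames else NULL,
    final_state = system_state(res$final_positions, res$final_velocities,
                               time = state$time + duration_ns),
    diagnostics = list(n_events = res$n_events,
                       max_ledger_dev = res$max_ledger_dev,
                       steer_work = res$steer_work,
                       thermo_increment = res$thermo_increment,
                       overlap_seen = res$overlap_seen))
  if (!is.null(track_pair)) {
    out$track_distances <- res$track_distances
    out$track_region_time <- res$track_region_time
  }
  structure(out, class = "dmd_trajectory")
}

#' @rdname run_dmd
#' @param ... arguments passed on to [run_dmd()]
#' @export
reference_run <- function(topology, state, duration_ns,
                          config = engine_config(), ...) {
  run_dmd(topology, state, duration_ns, config, mode = "reference", ...)
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat("<dmd_trajectory>", length(x$times), "frames,",
      format(max(x$times) - min(x$times), digits = 4), "ns;",
      "events:", paste(names(x$diagnostics$n_events),
                       x$diagnostics$n_events, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `dmd_trajectory`
#' @return integer
#' @export
n_frames <- function(trajectory) length(trajectory$times)
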