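# The three simulation campaigns: polymer collapse, replica binding, and
# steered constant-force pulling.

#' Campaign specification
#'
#' @param replicas number of independent replicas
#' @param duration_ns per-replica duration (ns)
#' @param forces_pN applied constant forces (pN, non-negative); pulling only
#' @param seeds integer seed per replica (length must equal `replicas`)
#' @param frame_interval_ns frame stride (ns)
#' @param constraint_mode `"backbone_constrained"` (binding),
#'   `"one_domain_immobilized"` (pulling) or `"free"`
#' @return an object of class `campaign_spec`
#' @export
campaign_spec <- function(replicas = 10, duration_ns = 2,
                          forces_pN = c(0, 10, 20), seeds = NULL,
                          frame_interval_ns = 0.01,
                          constraint_mode = c("backbone_constrained",
                                              "one_domain_immobilized",
                                              "free")) {
  constraint_mode <- match.arg(constraint_mode)
  if (is.null(seeds)) seeds <- seq_len(replicas)
  stopifnot(length(seeds) == replicas, all(forces_pN >= 0))
  structure(list(replicas = replicas, duration_ns = duration_ns,
                 forces_pN = forces_pN, seeds = as.integer(seeds),
                 frame_interval_ns = frame_interval_ns,
                 constraint_mode = constraint_mode),
            class = "campaign_spec")
}

#' Campaign presets
#'
#' `"paper"` presets reproduce the reference protocol scale (binding: 30
#' replicas of 50 ns; pulling: 30 replicas of 100 ns at 0/10/20 pN).
#' `"desk"` presets are reduced-scale defaults suitable for tests and
#' interactive runs.
#'
#' @param name `"paper"` or `"desk"`
#' @param kind `"binding"` or `"pulling"`
#' @return a [campaign_spec()]
#' @export
campaign_preset <- function(name = c("desk", "paper"),
                            kind = c("binding", "pulling")) {
  name <- match.arg(name); kind <- match.arg(kind)
  if (name == "paper") {
    if (kind == "binding")
      campaign_spec(30, 50, numeric(0), frame_interval_ns = 0.05)
    else
      campaign_spec(30, 100, c(0, 10, 20), frame_interval_ns = 0.05,
                    constraint_mode = "one_domain_immobilized")
  } else {
    if (kind == "binding")
      campaign_spec(10, 2, numeric(0), frame_interval_ns = 0.01)
    else
      campaign_spec(20, 1, c(0, 10, 20), frame_interval_ns = 0.01,
                    constraint_mode = "one_domain_immobilized")
  }
}

#' Collapse and equilibrate a nanoplastic chain
#'
#' Thermostatted run from the extended conformation; the radius of
#' gyration is recorded per frame.  The reference protocol collapses a
#' 20-monomer carboxylated PS chain into a compact globule of effective
#' diameter ~15 Angstrom.
#'
#' @param polymer a [build_polymer()] model
#' @param duration_ns run length (ns)
#' @param seed integer seed (engine + initial velocities)
#' @param temperature K
#' @param frame_interval_ns frame stride (ns)
#' @return class `collapse_run`: `trajectory`, `times`, `rg` (per frame,
#'   Angstrom), `final_state`, `polymer`
#' @export
collapse_equilibrate <- function(polymer, duration_ns = 5, seed = 1,
                                 temperature = 300,
                                 frame_interval_ns = 0.01) {
  stopifnot(inherits(polymer, "polymer_model"))
  vel <- make_mb_velocity_sample(nrow(polymer$beads), temperature,
                                 polymer$beads$mass, seed = seed + 211L)
  st <- system_state(polymer$state$positions, vel)
  cfg <- engine_config(temperature = temperature, seed = seed,
                       frame_interval_ns = frame_interval_ns)
  tr <- run_dmd(polymer$topology, st, duration_ns, cfg)
  rg <- vapply(tr$frames, gyration_radius, 0, masses = polymer$beads$mass)
  structure(list(trajectory = tr, times = tr$times, rg = rg,
                 final_state = tr$final_state, polymer = polymer,
                 seed = seed),
            class = "collapse_run")
}

#' Replica binding campaign
#'
#' For each replica the plastic is placed afresh at random (>=
#' `min_separation` from the dimer), the dimer backbone is immobilized
#' with side chains free, initial velocities are redrawn from
#' Maxwell-Boltzmann, and the system is run for the spec duration.
#'
#' @param dimer a `cadherin_model`
#' @param plastic a `polymer_model`
#' @param spec a [campaign_spec()] with `constraint_mode =
#'   "backbone_constrained"`
#' @param plastic_state optional collapsed-conformation [system_state()]
#' @param box_side,min_separation box geometry (Angstrom)
#' @param temperature K
#' @return class `binding_campaign`: list `replicas` of
#'   `list(system, trajectory, seed)` plus the spec
#' @export
binding_campaign <- function(dimer, plastic, spec = campaign_preset("desk"),
                             plastic_state = NULL, box_side = 120,
                             min_separation = 12, temperature = 300) {
  stopifnot(spec$constraint_mode == "backbone_constrained")
  reps <- lapply(seq_len(spec$replicas), function(r) {
    sd <- spec$seeds[r]
    sys <- assemble(dimer, plastic, plastic_state = plastic_state,
                    box_side = box_side, min_separation = min_separation,
                    seed = sd)
    topo <- set_immobilized(sys$topology,
                            bead_ids(sys, entity = "dimer",
                                     role = "backbone"))
    vel <- make_mb_velocity_sample(nrow(sys$beads), temperature,
                                   sys$beads$mass, seed = sd + 211L)
    st <- system_state(sys$state$positions, vel)
    cfg <- engine_config(temperature = temperature, seed = sd,
                         frame_interval_ns = spec$frame_interval_ns)
    tr <- run_dmd(topo, st, spec$duration_ns, cfg)
    list(system = sys, trajectory = tr, seed = sd)
  })
  structure(list(replicas = reps, spec = spec), class = "binding_campaign")
}

# resolve the steered / immobilized bead sets and pulling direction for one
# pulling run on a dimer or an assembled system
.pulling_setup <- function(x, pulled_domain, immobilized_domain) {
  model <- if (inherits(x, "dmd_system")) x$dimer else x
  swap <- model$swap_set
  imm <- bead_ids(x, domain = immobilized_domain, role = "backbone")
  imm <- setdiff(imm, bead_ids(x, domain = immobilized_domain,
                               residues = swap))
  grp <- setdiff(bead_ids(x, domain = pulled_domain),
                 bead_ids(x, domain = pulled_domain, residues = swap))
  bbp <- bead_ids(x, domain = pulled_domain, role = "backbone")
  res <- x$beads$residue[bbp]
  pos <- if (inherits(x, "dmd_system")) x$state$positions
         else model$state$positions
  # EC1-to-EC2 direction: from the interface-proximal terminus (residue 1)
  # toward the C-terminal backbone bead (the EC2 attachment side)
  from <- pos[bbp[which.min(res)], ]
  to <- pos[bbp[which.max(res)], ]
  dir <- to - from
  list(immobilized = imm, group = grp, direction = dir / sqrt(sum(dir^2)))
}

#' Steered constant-force pulling campaign
#'
#' One domain's backbone is immobilized (its domain-swapped residues 1-5
#' stay free); all non-swap beads of the other domain are pulled by a
#' constant force along the domain's residue-1 to C-terminus direction
#' (the EC1-to-EC2 axis).  Each (force, replica) run proceeds in chunks
#' until the inter-domain contact count first reaches zero or the spec
#' duration is exhausted (censored).
#'
#' @param x a `cadherin_model` or an assembled `dmd_system` (e.g. with the
#'   plastic pre-bound at the charged patch)
#' @param spec a [campaign_spec()]; its `forces_pN` grid is used
#' @param pulled_domain,immobilized_domain domain labels (must differ)
#' @param temperature K
#' @param cutoff_nm contact cutoff for dissociation detection (nm)
#' @param chunk_ns chunk length between dissociation checks (ns)
#' @param keep_trajectories retain per-replica trajectories (memory-heavy)
#' @return class `pulling_campaign`: `records` data.frame (force_pN,
#'   replica, seed, time_ns, censored), the spec, and optionally
#'   `trajectories`
#' @export
pulling_campaign <- function(x, spec = campaign_preset("desk", "pulling"),
                             pulled_domain = "B", immobilized_domain = "A",
                             temperature = 300, cutoff_nm = 0.65,
                             chunk_ns = 0.1, keep_trajectories = FALSE) {
  stopifnot(pulled_domain != immobilized_domain)
  setup <- .pulling_setup(x, pulled_domain, immobilized_domain)
  topo0 <- if (inherits(x, "dmd_system")) x$topology else x$topology
  topo <- set_immobilized(topo0, setup$immobilized)
  pos0 <- if (inherits(x, "dmd_system")) x$state$positions
          else x$state$positions
  ids_a <- bead_ids(x, domain = immobilized_domain)
  ids_b <- bead_ids(x, domain = pulled_domain)
  beads <- if (inherits(x, "dmd_system")) x$beads else x$beads

  records <- NULL; trajs <- list()
  for (f in spec$forces_pN) {
    for (r in seq_len(spec$replicas)) {
      sd <- spec$seeds[r] + 7919L * match(f, spec$forces_pN)
      vel <- make_mb_velocity_sample(nrow(pos0), temperature, beads$mass,
                                     seed = sd + 211L)
      st <- system_state(pos0, vel)
      steer <- if (f > 0) list(group = setup$group, force_pN = f,
                               direction = setup$direction) else NULL
      t_diss <- NA_real_; censored <- TRUE
      chunks <- ceiling(spec$duration_ns / chunk_ns - 1e-9)
      traj_acc <- NULL
      for (ck in seq_len(chunks)) {
        cfg <- engine_config(temperature = temperature,
                             seed = sd + ck,
                             frame_interval_ns = spec$frame_interval_ns)
        len <- min(chunk_ns, spec$duration_ns - (ck - 1) * chunk_ns)
        tr <- run_dmd(topo, st, len, cfg, steer = steer)
        if (keep_trajectories) traj_acc <- c(traj_acc, list(tr))
        cc <- vapply(tr$frames, function(fr)
          contacts(fr, ids_a, ids_b, cutoff_nm)$count, 0L)
        hit <- which(cc == 0L)
        if (length(hit)) {
          t_diss <- tr$times[hit[1]]
          censored <- FALSE
          break
        }
        st <- tr$final_state
      }
      if (censored) t_diss <- spec$duration_ns
      records <- rbind(records, data.frame(
        force_pN = f, replica = r, seed = sd, time_ns = t_diss,
        censored = censored))
      if (keep_trajectories)
        trajs[[paste0("F", f, "_r", r)]] <- traj_acc
    }
  }
  structure(list(records = records, spec = spec,
                 pulled_domain = pulled_domain,
                 immobilized_domain = immobilized_domain,
                 direction = setup$direction,
                 trajectories = if (keep_trajectories) trajs),
            class = "pulling_campaign")
}
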