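# Shared fixtures, built in code.

# a small interacting test system: nb beads with a mix of a bonded window
# pair, a Go-well pair and generic hard-core/vdW non-bonded interactions,
# inside a reflective box
small_test_system <- function(nb = 8, box = 25, seed = 1) {
  stopifnot(nb >= 4)
  types <- data.frame(label = "b", radius = 1.5, charge = 0, hydro = 0.2)
  beads <- data.frame(type = 1L, mass = 40 + 5 * seq_len(nb), radius = 1.5,
                      charge = 0, residue = NA_integer_,
                      domain = NA_character_, role = "bead",
                      entity = "fixture")
  cons <- data.frame(i = c(1L, 3L), j = c(2L, 4L),
                     kind = c("bond", "go"),
                     r0 = c(4, 5), width = c(0.1, 1), energy = c(0, 0.4))
  topo <- cgdmd:::build_topology(beads, types, cons, box = box)
  # beads on a loose grid, clear of hard-core contact; the bonded pair and
  # the Go pair start inside their windows/wells
  g <- as.matrix(expand.grid(x = c(6, 12, 18), y = c(6, 12, 18),
                             z = c(8, 16)))[seq_len(nb), ]
  g[2, ] <- g[1, ] + c(0, 0, 4)
  g[4, ] <- g[3, ] + c(0, 0, 4.5)
  vel <- make_mb_velocity_sample(nb, 300, beads$mass, seed = seed)
  list(topology = topo, state = system_state(g, vel))
}

# minimum inter-bead distance over all frames for overlap checks
min_pair_distance <- function(trajectory, exclude = NULL) {
  vapply(trajectory$frames, function(fr) {
    d <- cgdmd:::cross_dist(fr, fr)
    diag(d) <- Inf
    if (!is.null(exclude))
      for (k in seq_len(nrow(exclude)))
        d[exclude[k, 1], exclude[k, 2]] <- d[exclude[k, 2], exclude[k, 1]] <- Inf
    min(d)
  }, 0)
}
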