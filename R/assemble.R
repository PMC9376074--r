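# Combine a dimer model and a nanoplastic into a simulation box.

.ION <- list(Cl = list(mass = 35.45, radius = 2.2, charge = -1),
             Na = list(mass = 22.99, radius = 1.9, charge = 1))

#' Assemble a dimer + nanoplastic system in a reflective cubic box
#'
#' The dimer is centered in the box; the plastic (in the conformation given
#' by `plastic_state`, e.g. a collapsed globule) is placed with a uniformly
#' random rotation and position subject to a minimum bead-to-bead
#' separation from the dimer (default 12 Angstrom), or docked against the
#' charged patch for pre-bound starting states.  Optionally monovalent
#' counter-ions are added to neutralize the net system charge.
#'
#' @param dimer a `cadherin_model`
#' @param plastic optional `polymer_model`
#' @param plastic_state optional [system_state()] for the plastic (defaults
#'   to its build conformation)
#' @param box_side cubic box side (Angstrom)
#' @param min_separation minimum initial dimer-plastic bead separation
#'   (Angstrom)
#' @param neutralize add counter-ion beads to bring the net charge to zero
#' @param seed integer seed (placement and rotation)
#' @param placement `"random"` (uniform, the binding-campaign default) or
#'   `"patch"` (docked at contact distance against the charged turn patch)
#' @param patch_domain for `"patch"` placement, dock against this domain's
#'   patch only (default: the centroid of all patch residues)
#' @param max_attempts placement attempts before failing
#' @param es [electrostatics_params()]
#' @return an object of class `dmd_system`: merged `topology`, `state`,
#'   `beads`, id vectors (`dimer_ids`, `plastic_ids`, `ion_ids`) and the
#'   placement metadata
#' @export
assemble <- function(dimer, plastic = NULL, plastic_state = NULL,
                     box_side = 120, min_separation = 12,
                     neutralize = FALSE, seed = 1,
                     placement = c("random", "patch"), patch_domain = NULL,
                     max_attempts = 500, es = electrostatics_params()) {
  stopifnot(inherits(dimer, "cadherin_model"))
  placement <- match.arg(placement)
  ctr <- box_side / 2
  dpos <- dimer$state$positions
  dpos <- sweep(dpos, 2, colMeans(dpos) - ctr)

  topo <- dimer$topology
  attr(topo, "types") <- attr(dimer$topology, "types")
  beads <- dimer$beads
  pos <- dpos
  plastic_ids <- integer()

  if (!is.null(plastic)) {
    stopifnot(inherits(plastic, "polymer_model"))
    ppos0 <- if (is.null(plastic_state)) plastic$state$positions
             else plastic_state$positions
    ppos0 <- sweep(ppos0, 2, colMeans(ppos0))
    margin <- max(plastic$beads$radius) + 0.1
    placed <- local_seed(seed, {
      R <- random_rotation()
      pr <- ppos0 %*% t(R)
      ext <- max(abs(pr))
      ok <- NULL
      if (placement == "random") {
        for (k in seq_len(max_attempts)) {
          cen <- runif(3, margin + ext, box_side - margin - ext)
          cand <- sweep(pr, 2, -cen)
          if (min(cross_dist(dpos, cand)) >= min_separation) { ok <- cand; break }
        }
      } else {
        pb <- dpos[bead_ids(dimer, residues = dimer$patch_residues,
                            role = "side", domain = patch_domain),
                   , drop = FALSE]
        pc <- colMeans(pb)
        dir <- pc - colMeans(dpos)
        dir <- dir / sqrt(sum(dir^2))
        rsum <- outer(dimer$beads$radius, plastic$beads$radius, "+")
        for (d in seq(2, box_side / 2, by = 0.5)) {
          cand <- sweep(pr, 2, -(pc + d * dir))
          if (all(cross_dist(dpos, cand) - rsum >= 0.4) &&
              all(cand > margin & cand < box_side - margin)) { ok <- cand; break }
        }
      }
      ok
    })
    if (is.null(placed))
      stop("failed to place the nanoplastic after ", max_attempts,
           " attempts (box too small for the requested separation?)")
    topo <- merge_topologies(topo, plastic$topology,
                             cross_nb = cross_nb_closure(es),
                             box = box_side)
    plastic_ids <- nrow(beads) + seq_len(nrow(plastic$beads))
    beads <- topo$beads
    pos <- rbind(pos, placed)
  }

  ion_ids <- integer()
  if (neutralize) {
    q <- sum(beads$charge)
    n_ions <- abs(round(q))
    if (n_ions > 0) {
      ion <- if (q > 0) .ION$Cl else .ION$Na
      itypes <- data.frame(label = if (q > 0) "Cl" else "Na",
                           radius = ion$radius, charge = ion$charge,
                           hydro = 0.02)
      ibeads <- data.frame(type = 1L, mass = ion$mass, radius = ion$radius,
                           charge = ion$charge, residue = NA_integer_,
                           domain = NA_character_, role = "ion",
                           entity = "ion")[rep(1, n_ions), ]
      rownames(ibeads) <- NULL
      itopo <- build_topology(ibeads, itypes, NULL, es)
      ipos <- local_seed(seed + 7L, {
        out <- matrix(NA_real_, n_ions, 3)
        for (k in seq_len(n_ions)) {
          for (a in seq_len(max_attempts)) {
            cand <- runif(3, ion$radius + 0.1, box_side - ion$radius - 0.1)
            ref <- rbind(pos, out[seq_len(k - 1), , drop = FALSE])
            if (min(cross_dist(ref, rbind(cand))) >= 5) { out[k, ] <- cand; break }
          }
          if (anyNA(out[k, ])) stop("failed to place counter-ion ", k)
        }
        out
      })
      topo <- merge_topologies(topo, itopo, cross_nb = cross_nb_closure(es),
                               box = box_side)
      ion_ids <- nrow(beads) + seq_len(n_ions)
      beads <- topo$beads
      pos <- rbind(pos, ipos)
    }
  }

  topo$box <- box_side
  structure(list(topology = topo, state = system_state(pos), beads = beads,
                 dimer = dimer, plastic = plastic,
                 dimer_ids = seq_len(nrow(dimer$beads)),
                 plastic_ids = plastic_ids, ion_ids = ion_ids,
                 box_side = box_side, min_separation = min_separation,
                 placement = placement, seed = seed),
            class = "dmd_system")
}

#' @export
print.dmd_system <- function(x, ...) {
  cat("<dmd_system>", nrow(x$beads), "beads (",
      length(x$dimer_ids), "dimer,", length(x$plastic_ids), "plastic,",
      length(x$ion_ids), "ion ) in a", x$box_side, "A box\n")
  invisible(x)
}
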