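# System containers: bead table + interaction tables (topology) and the
# dynamic state (positions, velocities, time).

#' Construct a DMD topology
#'
#' A topology holds the per-bead metadata, the registry of step potentials,
#' the type-pair table resolving non-bonded interactions, the per-pair
#' overrides (bond windows, 1-3/1-4 windows, Go wells, calcium-coordination
#' bonds; an override replaces the non-bonded potential for that pair), the
#' immobilized bead set and the reflective box.
#'
#' @param beads data.frame with columns `type` (integer index into the type
#'   registry), `mass` (Da), `radius` (Angstrom), `charge` (e), and optional
#'   annotation columns `residue`, `domain`, `role`, `entity`
#' @param potentials list of [step_potential()]s (the registry)
#' @param nb_table integer matrix, `nb_table[a, b]` = index into `potentials`
#'   for the non-bonded potential of type pair (a, b); 0 = no interaction
#' @param overrides data.frame with columns `i`, `j` (1-based bead ids) and
#'   `pot` (index into `potentials`)
#' @param immobilized integer vector of bead ids held fixed (infinite
#'   effective mass: zero velocity, excluded from thermostat and steering,
#'   still collide)
#' @param box reflective cubic box side length (Angstrom); 0 = unbounded
#' @return an object of class `dmd_topology`
#' @export
dmd_topology <- function(beads, potentials, nb_table,
                         overrides = data.frame(i = integer(), j = integer(),
                                                pot = integer()),
                         immobilized = integer(), box = 0) {
  stopifnot(is.data.frame(beads),
            all(c("type", "mass", "radius", "charge") %in% names(beads)),
            is.list(potentials), is.matrix(nb_table),
            nrow(nb_table) == ncol(nb_table))
  n <- nrow(beads)
  if (nrow(overrides)) {
    stopifnot(all(overrides$i >= 1), all(overrides$j <= n),
              all(overrides$i != overrides$j),
              all(overrides$pot >= 1),
              all(overrides$pot <= length(potentials)))
    ij <- cbind(pmin(overrides$i, overrides$j),
                pmax(overrides$i, overrides$j))
    if (anyDuplicated(ij))
      stop("duplicate pair overrides: every pair must resolve to exactly one potential")
    overrides <- data.frame(i = ij[, 1], j = ij[, 2], pot = overrides$pot)
  }
  stopifnot(all(immobilized >= 1), all(immobilized <= n))
  if (max(beads$type) > nrow(nb_table))
    stop("bead type outside the nb_table")
  structure(list(beads = beads, potentials = potentials,
                 nb_table = nb_table, overrides = overrides,
                 immobilized = sort(unique(as.integer(immobilized))),
                 box = box),
            class = "dmd_topology")
}

#' @export
print.dmd_topology <- function(x, ...) {
  cat("<dmd_topology>", nrow(x$beads), "beads,",
      length(x$potentials), "potentials,",
      nrow(x$overrides), "pair overrides,",
      length(x$immobilized), "immobilized;",
      if (x$box > 0) paste0("box ", format(x$box), " A") else "unbounded",
      "\n")
  invisible(x)
}

#' Construct a system state
#'
#' @param positions n x 3 matrix (Angstrom)
#' @param velocities n x 3 matrix (Angstrom per time unit); defaults to rest
#' @param time simulation time (ns)
#' @return an object of class `system_state`
#' @export
system_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  stopifnot(dim(velocities)[1] == nrow(positions), ncol(velocities) == 3)
  structure(list(positions = positions, velocities = velocities,
                 time = time),
            class = "system_state")
}

#' Mark beads as immobilized
#'
#' @param topology a [dmd_topology()]
#' @param ids bead ids to hold fixed (replaces the current set)
#' @return the modified topology
#' @export
set_immobilized <- function(topology, ids) {
  stopifnot(inherits(topology, "dmd_topology"))
  topology$immobilized <- sort(unique(as.integer(ids)))
  topology
}

# Merge two topologies into one system (bead ids of `b` are offset by
# nrow(a$beads); potentials are concatenated; the nb table becomes block
# diagonal unless `cross_nb` supplies type-pair potentials across the two).
# cross_nb: function(type_a_row, type_b_row) -> step_potential or NULL,
# where the rows come from the per-topology `types` attribute.
merge_topologies <- function(a, b, cross_nb = NULL, box = max(a$box, b$box)) {
  na <- nrow(a$beads); ta <- nrow(a$nb_table)
  beads_b <- b$beads
  beads_b$type <- beads_b$type + ta
  beads <- rbind(a$beads, beads_b)
  pots <- c(a$potentials, b$potentials)
  tb <- nrow(b$nb_table)
  nb <- matrix(0L, ta + tb, ta + tb)
  nb[seq_len(ta), seq_len(ta)] <- a$nb_table
  nb[ta + seq_len(tb), ta + seq_len(tb)] <-
    b$nb_table + ifelse(b$nb_table > 0L, length(a$potentials), 0L)
  types_a <- attr(a, "types"); types_b <- attr(b, "types")
  if (!is.null(cross_nb)) {
    for (p in seq_len(ta)) for (q in seq_len(tb)) {
      pot <- cross_nb(types_a[p, ], types_b[q, ])
      if (!is.null(pot)) {
        pots[[length(pots) + 1L]] <- pot
        nb[p, ta + q] <- nb[ta + q, p] <- length(pots)
      }
    }
  }
  ov <- rbind(a$overrides,
              data.frame(i = b$overrides$i + na, j = b$overrides$j + na,
                         pot = b$overrides$pot + length(a$potentials)))
  out <- dmd_topology(beads, pots, nb, ov,
                      immobilized = c(a$immobilized, b$immobilized + na),
                      box = box)
  attr(out, "types") <- rbind(types_a, types_b)
  out
}
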