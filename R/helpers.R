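# Internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  Builders are pure functions of (inputs, seed).
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Pairwise distances between two coordinate matrices (na x 3, nb x 3).
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

# Uniform random rotation matrix (from a quaternion).
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Non-bonded potential for a type pair: hard core at the radius sum, one
# shallow attractive (hydrophobic-like) shell, plus discretized screened
# electrostatics for charged pairs.
nb_pair_potential <- function(ra, rb, qa, qb, ha, hb,
                              es = electrostatics_params(),
                              vdw_range_factor = 1.6) {
  hc <- ra + rb
  depth <- sqrt(ha * hb)
  parts <- list()
  if (depth > 0)
    parts <- c(parts, list(step_potential(hc, vdw_range_factor * hc, -depth)))
  qq <- qa * qb
  if (qq != 0 && es$cutoff > hc) {
    r <- seq(hc, es$cutoff, length.out = 201)
    dh <- cbind(r, debye_huckel_energy(qa, qb, r, es))
    parts <- c(parts, list(discretize(dh, es$n_shells, es$cutoff)))
  }
  if (!length(parts)) return(step_potential(hc, hc * 1.0001, 0))
  combine_potentials(parts)
}

# Build a dmd_topology from a bead table, a type registry and a constraint
# table.  types: data.frame(label, radius, charge, hydro).  constraints:
# data.frame(i, j, kind ("bond"|"window"|"go"), r0, width, energy) where for
# bonds/windows `width` is the tolerance fraction and for go wells the well
# half-width (energy = well depth, stored positive).
build_topology <- function(beads, types, constraints, es = electrostatics_params(),
                           box = 0, immobilized = integer()) {
  nt <- nrow(types)
  pots <- list()
  nb <- matrix(0L, nt, nt)
  for (p in seq_len(nt)) for (q in p:nt) {
    pots[[length(pots) + 1L]] <- nb_pair_potential(
      types$radius[p], types$radius[q], types$charge[p], types$charge[q],
      types$hydro[p], types$hydro[q], es)
    nb[p, q] <- nb[q, p] <- length(pots)
  }
  ov <- data.frame(i = integer(), j = integer(), pot = integer())
  if (!is.null(constraints) && nrow(constraints)) {
    cpots <- lapply(seq_len(nrow(constraints)), function(k) {
      with(constraints[k, ], switch(kind,
        bond = ,
        window = make_bond_window(r0, width),
        # a Go well keeps the physical excluded volume of the two beads
        go = make_go_well(r0, energy, width,
                          hard_core = beads$radius[i] + beads$radius[j]),
        stop("unknown constraint kind: ", kind)))
    })
    ov <- data.frame(i = constraints$i, j = constraints$j,
                     pot = length(pots) + seq_along(cpots))
    pots <- c(pots, cpots)
  }
  topo <- dmd_topology(beads, pots, nb, ov, immobilized = immobilized,
                       box = box)
  attr(topo, "types") <- types
  topo
}

# Cross-entity non-bonded closure used when merging topologies.
cross_nb_closure <- function(es) {
  function(ta, tb) nb_pair_potential(ta$radius, tb$radius, ta$charge,
                                     tb$charge, ta$hydro, tb$hydro, es)
}
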