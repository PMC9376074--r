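# Step-function pair potentials: the engine's only interaction primitive.
#
# A step potential is a hard core plus a ladder of spherical shells, each with
# a constant energy; the energy beyond the outermost edge is exactly zero
# unless the potential is a bond window, in which case the outermost edge is
# an infinite wall.

#' Construct a step-function pair potential
#'
#' @param hard_core inner infinite-wall distance (Angstrom)
#' @param edges strictly increasing shell boundary distances (Angstrom),
#'   all greater than `hard_core`
#' @param energies energy of each shell (kcal/mol); `energies[k]` applies on
#'   `(boundary[k-1], boundary[k]]` where `boundary = c(hard_core, edges)`.
#'   Beyond the last edge the energy is exactly 0 unless
#'   `infinite_outer_wall`.
#' @param infinite_outer_wall if `TRUE` the last edge is an infinite wall
#'   (bonded pairs can never separate beyond it)
#' @return an object of class `step_potential`
#' @export
step_potential <- function(hard_core, edges, energies,
                           infinite_outer_wall = FALSE) {
  stopifnot(is.numeric(hard_core), length(hard_core) == 1L, hard_core >= 0,
            is.numeric(edges), length(edges) >= 1L,
            is.numeric(energies), length(energies) == length(edges))
  if (any(diff(c(hard_core, edges)) <= 0))
    stop("edges must be strictly increasing and exceed the hard core")
  if (any(!is.finite(energies)))
    stop("shell energies must be finite")
  structure(list(hard_core = hard_core,
                 edges = as.numeric(edges),
                 energies = as.numeric(energies),
                 infinite_outer_wall = isTRUE(infinite_outer_wall)),
            class = "step_potential")
}

#' @export
print.step_potential <- function(x, ...) {
  cat("<step_potential> hard core", format(x$hard_core), "A,",
      length(x$edges), "shell(s)",
      if (x$infinite_outer_wall) "(infinite outer wall)" else "", "\n")
  b <- c(x$hard_core, x$edges)
  for (k in seq_along(x$energies))
    cat(sprintf("  (%.4g, %.4g]  %+.5g kcal/mol\n", b[k], b[k + 1],
                x$energies[k]))
  invisible(x)
}

#' Evaluate a step potential at given distances
#'
#' Returns the energy of the unique shell containing each `r`: `Inf` inside
#' the hard core (or beyond an infinite outer wall), the shell energy within
#' a shell, and 0 beyond the last edge otherwise.
#'
#' @param pot a [step_potential()]
#' @param r distances (Angstrom), vectorized
#' @return energies (kcal/mol)
#' @export
evaluate_potential <- function(pot, r) {
  stopifnot(inherits(pot, "step_potential"), is.numeric(r))
  b <- c(pot$hard_core, pot$edges)
  idx <- findInterval(r, b, left.open = FALSE)  # 0 = inside core
  out <- numeric(length(r))
  out[idx == 0 | r <= pot$hard_core] <- Inf
  inside <- idx >= 1 & idx <= length(pot$energies) & r > pot$hard_core
  out[inside] <- pot$energies[idx[inside]]
  beyond <- idx > length(pot$energies)
  out[beyond] <- if (pot$infinite_outer_wall) Inf else 0
  out
}

#' Screened-electrostatics parameters (Debye-Hueckel)
#'
#' Houses the relative permittivity, the Debye screening length and the
#' Coulomb prefactor used for charged bead pairs.  Defaults are effective
#' coarse-grained choices: `dielectric = 10`, `debye_length = 10` Angstrom,
#' `coulomb_constant = 332.06` kcal*A/mol per unit-charge pair.
#'
#' @param dielectric relative permittivity (>= 1, dimensionless)
#' @param debye_length screening length (Angstrom, > 0)
#' @param coulomb_constant energy*distance per unit-charge pair (kcal*A/mol)
#' @param cutoff interaction truncation distance; default `3 * debye_length`
#' @param n_shells shells used when the potential is discretized
#' @return an object of class `electrostatics_params`
#' @export
electrostatics_params <- function(dielectric = 10, debye_length = 10,
                                  coulomb_constant = 332.06,
                                  cutoff = 3 * debye_length,
                                  n_shells = 10L) {
  stopifnot(debye_length > 0, dielectric >= 1, cutoff > 0, n_shells >= 1)
  structure(list(dielectric = dielectric, debye_length = debye_length,
                 coulomb_constant = coulomb_constant, cutoff = cutoff,
                 n_shells = as.integer(n_shells)),
            class = "electrostatics_params")
}

#' Debye-Hueckel screened Coulomb energy
#'
#' `E(r) = C * q1 * q2 * exp(-r / lambda_D) / (eps * r)`; the sign follows
#' the product of the charges.
#'
#' @param q1,q2 charges (units of e)
#' @param r separation (Angstrom, > 0), vectorized
#' @param params an [electrostatics_params()]
#' @return energy (kcal/mol)
#' @export
debye_huckel_energy <- function(q1, q2, r, params = electrostatics_params()) {
  stopifnot(inherits(params, "electrostatics_params"))
  if (any(r <= 0)) stop("invalid geometry: r must be positive")
  params$coulomb_constant * q1 * q2 * exp(-r / params$debye_length) /
    (params$dielectric * r)
}

#' Discretize a sampled continuous potential into a step potential
#'
#' The range `[hard_core, r_cut]` (where `hard_core` is the smallest sampled
#' distance) is split into `n_shells` equal-width shells; each shell's energy
#' is the continuous potential evaluated (by linear interpolation of the
#' samples) at the shell midpoint.  Energy at and beyond `r_cut` is 0.
#'
#' @param sampled two-column matrix or data.frame of (distance, energy)
#'   samples covering the range, distances strictly increasing
#' @param n_shells number of shells (>= 1)
#' @param r_cut outer truncation distance; must be within the sampled range
#' @return a [step_potential()]
#' @export
discretize <- function(sampled, n_shells, r_cut) {
  sampled <- as.matrix(sampled)
  stopifnot(ncol(sampled) == 2, nrow(sampled) >= 2, n_shells >= 1)
  r <- sampled[, 1]; e <- sampled[, 2]
  if (any(diff(r) <= 0)) stop("sample distances must be strictly increasing")
  hc <- r[1]
  if (r_cut > max(r) + 1e-9 || r_cut <= hc)
    stop("samples must cover [hard_core, r_cut]")
  edges <- hc + (r_cut - hc) * seq_len(n_shells) / n_shells
  mid <- (c(hc, edges[-n_shells]) + edges) / 2
  energies <- approx(r, e, xout = mid, rule = 2)$y
  step_potential(hc, edges, energies)
}

#' A Go contact record
#'
#' A native residue-residue contact stabilized by a single attractive square
#' well between the two side (C-beta) beads.  The default well depth of
#' 0.3 kcal/mol is about 0.5 kT at 300 K.
#'
#' @param residue_i,residue_j 1-based residue indices (must differ)
#' @param native_distance native side-bead separation (Angstrom)
#' @param well_energy well depth, stored positive (kcal/mol)
#' @param well_half_width half-width of the well (Angstrom)
#' @return an object of class `go_contact`
#' @export
go_contact <- function(residue_i, residue_j, native_distance,
                       well_energy = 0.3, well_half_width = 1.0) {
  stopifnot(residue_i != residue_j, well_energy > 0,
            native_distance > well_half_width, well_half_width > 0)
  structure(list(residue_i = residue_i, residue_j = residue_j,
                 native_distance = native_distance,
                 well_energy = well_energy,
                 well_half_width = well_half_width),
            class = "go_contact")
}

#' Single attractive square well (Go-potential form)
#'
#' Depth `well_energy` on `[native_distance - half_width,
#' native_distance + half_width]`, zero outside, hard core at a configurable
#' inner radius (default: two half-widths inside the well, floored at a
#' quarter of the native distance).
#'
#' @param native_distance well center (Angstrom)
#' @param well_energy well depth, positive (kcal/mol)
#' @param half_width well half-width (Angstrom); `native_distance >
#'   half_width > 0`
#' @param hard_core inner infinite-wall distance
#' @return a [step_potential()] whose well shell has energy `-well_energy`
#' @export
make_go_well <- function(native_distance, well_energy = 0.3, half_width = 1.0,
                         hard_core = NULL) {
  stopifnot(native_distance > half_width, half_width > 0, well_energy > 0)
  if (is.null(hard_core))
    hard_core <- max(native_distance - 2 * half_width, native_distance / 4)
  lo <- native_distance - half_width
  hi <- native_distance + half_width
  if (hard_core >= lo) {
    # well reaches down to contact: single attractive shell above the core
    return(step_potential(hard_core, hi, -well_energy))
  }
  step_potential(hard_core, c(lo, hi), c(0, -well_energy))
}

#' Infinite-wall bond window
#'
#' Bonds (and the 1-3 / 1-4 distance windows standing in for angle and
#' dihedral terms) are hard distance windows: infinite walls at
#' `r0 * (1 - tolerance_fraction)` and `r0 * (1 + tolerance_fraction)`.
#'
#' @param r0 equilibrium distance (Angstrom)
#' @param tolerance_fraction half-width as a fraction of `r0`, in (0, 1)
#' @param min_width smallest admissible full window width (Angstrom);
#'   degenerate windows are rejected
#' @return a [step_potential()] with `infinite_outer_wall = TRUE`
#' @export
make_bond_window <- function(r0, tolerance_fraction, min_width = 0.01) {
  stopifnot(r0 > 0, tolerance_fraction > 0, tolerance_fraction < 1)
  if (2 * r0 * tolerance_fraction < min_width)
    stop("bond window narrower than the configured minimum width")
  step_potential(r0 * (1 - tolerance_fraction),
                 r0 * (1 + tolerance_fraction), 0,
                 infinite_outer_wall = TRUE)
}

#' Sum several step potentials acting on the same pair
#'
#' The merged potential lives on the union of the edge grids; each merged
#' shell's energy is the sum of the component energies there.  The hard core
#' is the maximum of the component hard cores; if any component has an
#' infinite outer wall, the innermost such wall bounds the result.
#'
#' @param potentials list of [step_potential()]s
#' @return a [step_potential()]
#' @export
combine_potentials <- function(potentials) {
  stopifnot(length(potentials) >= 1,
            all(vapply(potentials, inherits, TRUE, "step_potential")))
  if (length(potentials) == 1L) return(potentials[[1]])
  hc <- max(vapply(potentials, `[[`, 0, "hard_core"))
  walls <- vapply(potentials, function(p)
    if (p$infinite_outer_wall) max(p$edges) else Inf, 0)
  outer_wall <- min(walls)
  edges <- sort(unique(unlist(lapply(potentials, `[[`, "edges"))))
  edges <- edges[edges > hc & edges <= outer_wall]
  if (is.finite(outer_wall) && !(outer_wall %in% edges))
    edges <- sort(c(edges, outer_wall))
  if (!length(edges)) stop("combined potential has no admissible shells")
  mid <- (c(hc, edges[-length(edges)]) + edges) / 2
  energies <- rowSums(vapply(potentials, function(p) {
    e <- evaluate_potential(p, mid)
    e[!is.finite(e)] <- 0  # inside a component's zero-width tail
    e
  }, numeric(length(mid))))
  # drop trailing zero shells of an open potential (keeps ranges tight)
  inf_outer <- is.finite(outer_wall)
  if (!inf_outer) {
    while (length(energies) > 1 && energies[length(energies)] == 0) {
      energies <- energies[-length(energies)]
      edges <- edges[-length(edges)]
    }
  }
  step_potential(hc, edges, energies, infinite_outer_wall = inf_outer)
}

#' Serialize step potentials to a plain-text table (and read them back)
#'
#' One row per shell: `name  hard_core  edge  energy  infinite_outer_wall`.
#' The format is documented, diffable, and sufficient to rebuild the
#' potential set bit-exactly.
#'
#' @param potentials named list of [step_potential()]s
#' @param path file path
#' @return `write_potential_table` returns `path` invisibly;
#'   `read_potential_table` returns a named list of potentials.
#' @export
write_potential_table <- function(potentials, path) {
  stopifnot(is.list(potentials), !is.null(names(potentials)))
  rows <- do.call(rbind, lapply(names(potentials), function(nm) {
    p <- potentials[[nm]]
    data.frame(pair_type = nm, hard_core = p$hard_core, edge = p$edges,
               energy = p$energies,
               infinite_outer_wall = p$infinite_outer_wall)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cgdmd step-potential table: pair_type hard_core edge energy infinite_outer_wall", con)
  write.table(format(rows, digits = 17), con, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_potential_table
#' @export
read_potential_table <- function(path) {
  tab <- read.table(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$pair_type), function(d) {
    o <- order(d$edge)
    step_potential(d$hard_core[1], d$edge[o], d$energy[o],
                   infinite_outer_wall = d$infinite_outer_wall[1])
  })
  out[unique(tab$pair_type)]
}
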