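# Nanoplastic bead-polymer models (polystyrene / PMMA chemistries).

# Per-monomer formula masses (Da) and default effective hydrophobicities
# (kcal/mol; the pair well depth is the geometric mean of the two beads').
.polymer_chem <- list(
  PS   = list(mass = 104, hydro = 1.5, anionic_fraction = 0.5),
  PMMA = list(mass = 100, hydro = 1.2, anionic_fraction = 0.25))

.CARBOXYLATE <- list(mass = 44, radius = 1.6, charge = -1, hydro = 0.05)

#' Build a coarse-grained nanoplastic bead polymer
#'
#' One backbone bead per monomer (styrene 104 Da, methyl methacrylate
#' 100 Da) connected by infinite-wall bond windows, with anionic
#' carboxylate surface beads attached to a seed-chosen subset of monomers.
#' PMMA is modelled like PS with a weaker effective hydrophobicity and, by
#' default, a smaller carboxylated fraction (demethylation of a subset of
#' repeats).  The initial conformation is an extended zig-zag chain.
#'
#' @param chemistry `"PS"` or `"PMMA"`
#' @param n_monomers chain length (>= 2); 20 is the reference chain,
#'   builds are supported up to at least 80-mers
#' @param anionic_fraction fraction of monomers carrying a carboxylate
#'   bead, in `[0, 1]`; defaults: PS 0.5, PMMA 0.25
#' @param seed integer; fixes which monomers are carboxylated
#' @param bead_radius monomer bead radius (Angstrom)
#' @param bond_length backbone bond window center (Angstrom)
#' @param hydro effective hydrophobic well depth scale for monomer beads
#'   (kcal/mol); default per chemistry
#' @param es [electrostatics_params()]
#' @return an object of class `polymer_model` with elements `beads`,
#'   `topology`, `state` (extended conformation), `carboxylated` (monomer
#'   indices), `net_charge`
#' @export
build_polymer <- function(chemistry = c("PS", "PMMA"), n_monomers = 20,
                          anionic_fraction = NULL, seed = 1,
                          bead_radius = 2.0, bond_length = 4.0,
                          hydro = NULL, es = electrostatics_params()) {
  chemistry <- match.arg(chemistry)
  chem <- .polymer_chem[[chemistry]]
  stopifnot(n_monomers >= 2)
  if (is.null(anionic_fraction)) anionic_fraction <- chem$anionic_fraction
  if (anionic_fraction < 0 || anionic_fraction > 1)
    stop("anionic_fraction must be in [0, 1]")
  if (is.null(hydro)) hydro <- chem$hydro

  n_carb <- round(anionic_fraction * n_monomers)
  carbox <- if (n_carb > 0)
    local_seed(seed, sort(sample.int(n_monomers, n_carb))) else integer()

  types <- data.frame(label = c("monomer", "carboxylate"),
                      radius = c(bead_radius, .CARBOXYLATE$radius),
                      charge = c(0, .CARBOXYLATE$charge),
                      hydro = c(hydro, .CARBOXYLATE$hydro))

  # extended zig-zag backbone: bond length and a ~116 degree bond angle
  i <- seq_len(n_monomers)
  dy <- sqrt(bond_length^2 - (bond_length * 0.85)^2)
  bb <- cbind(i * bond_length * 0.85, (i %% 2) * dy, 0)
  carb_xyz <- bb[carbox, , drop = FALSE]
  if (n_carb > 0)
    carb_xyz[, 3] <- ifelse(carbox %% 2 == 0, 1, -1) *
      (bead_radius + .CARBOXYLATE$radius)

  beads <- data.frame(
    type = c(rep(1L, n_monomers), rep(2L, n_carb)),
    mass = c(rep(chem$mass, n_monomers), rep(.CARBOXYLATE$mass, n_carb)),
    radius = c(rep(bead_radius, n_monomers), rep(.CARBOXYLATE$radius, n_carb)),
    charge = c(rep(0, n_monomers), rep(.CARBOXYLATE$charge, n_carb)),
    residue = c(i, carbox),
    domain = NA_character_,
    role = c(rep("monomer", n_monomers), rep("carboxylate", n_carb)),
    entity = "plastic")

  cons <- data.frame(
    i = c(head(i, -1), if (n_carb) n_monomers + seq_len(n_carb)),
    j = c(i[-1],       if (n_carb) carbox),
    kind = "bond",
    r0 = c(rep(bond_length, n_monomers - 1),
           rep(bead_radius + .CARBOXYLATE$radius, n_carb)),
    width = 0.1, energy = 0)
  # 1-3 windows keep the backbone angle near its zig-zag value
  if (n_monomers >= 3) {
    r13 <- sqrt(sum((bb[3, ] - bb[1, ])^2))
    cons <- rbind(cons, data.frame(i = i[1:(n_monomers - 2)],
                                   j = i[3:n_monomers], kind = "window",
                                   r0 = r13, width = 0.15, energy = 0))
  }

  topo <- build_topology(beads, types, cons, es)
  structure(list(chemistry = chemistry, n_monomers = n_monomers,
                 anionic_fraction = anionic_fraction,
                 carboxylated = carbox,
                 net_charge = sum(beads$charge),
                 beads = beads, topology = topo,
                 state = system_state(rbind(bb, carb_xyz)),
                 seed = seed),
            class = "polymer_model")
}

#' @export
print.polymer_model <- function(x, ...) {
  cat("<polymer_model>", x$chemistry, paste0(x$n_monomers, "-mer,"),
      length(x$carboxylated), "carboxylate bead(s), net charge",
      x$net_charge, "e\n")
  invisible(x)
}
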