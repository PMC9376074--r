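# Cadherin EC1 dimer models: two-bead-per-residue coarse graining with an
# interfacial (domain-swap) Go patch, calcium-coordination bond windows and
# residue-typed side-bead charges.

.CA_COORD_RESIDUES <- c(11, 62, 64, 96, 99)  # Glu11, Asp62, Glu64, Asp96, Asp99
.SWAP_SET <- 1:5                             # domain-swapped N-terminal strand

# side-bead charge by residue name
.residue_charge <- function(resid) {
  ifelse(resid %in% c("ARG", "LYS"), 1, ifelse(resid %in% c("ASP", "GLU"), -1, 0))
}

# formula masses of amino-acid residues (Da, minus water)
.RES_MASS <- c(ALA = 71, ARG = 156, ASN = 114, ASP = 115, CYS = 103,
               GLN = 128, GLU = 129, GLY = 57, HIS = 137, ILE = 113,
               LEU = 113, LYS = 128, MET = 131, PHE = 147, PRO = 97,
               SER = 87, THR = 101, TRP = 186, TYR = 163, VAL = 99)

.BB_MASS <- 56      # N-CA-C-O backbone unit
.BB_RADIUS <- 1.9
.SIDE_RADIUS <- 1.8
.BB_HYDRO <- 0.10
.SIDE_HYDRO <- 0.10
.SWAP_HYDRO <- 0.50  # the swap strand docks into a hydrophobic pocket

# assemble a cadherin_model from per-domain bead coordinates + annotations
.finish_dimer <- function(bb, side, residue, domain, charge, side_mass,
                          go_cutoff, interface_energy, intra_energy,
                          well_half_width, es, angle_map, patch_residues,
                          ca_bonds = TRUE, interface_cutoff = go_cutoff) {
  n <- length(residue)
  swap <- residue %in% .SWAP_SET
  # types: backbone; neutral side; charged sides (+/-); swap-strand side
  lab <- ifelse(charge > 0, "side_pos", ifelse(charge < 0, "side_neg",
                ifelse(swap, "side_swap", "side")))
  types <- data.frame(label = c("backbone", "side", "side_pos", "side_neg",
                                "side_swap"),
                      radius = c(.BB_RADIUS, rep(.SIDE_RADIUS, 4)),
                      charge = c(0, 0, 1, -1, 0),
                      hydro = c(.BB_HYDRO, .SIDE_HYDRO, .SIDE_HYDRO,
                                .SIDE_HYDRO, .SWAP_HYDRO))
  side_type <- match(lab, types$label)

  beads <- data.frame(
    type = c(rep(1L, n), side_type),
    mass = c(rep(.BB_MASS, n), side_mass),
    radius = c(rep(.BB_RADIUS, n), rep(.SIDE_RADIUS, n)),
    charge = c(rep(0, n), charge),
    residue = c(residue, residue),
    domain = c(domain, domain),
    role = c(rep("backbone", n), rep("side", n)),
    entity = "dimer")
  pos <- rbind(bb, side)
  bb_id <- seq_len(n)
  side_id <- n + seq_len(n)

  dist2 <- function(a, b) sqrt(sum((pos[a, ] - pos[b, ])^2))
  cons <- NULL
  ca_pairs <- character()
  add <- function(i, j, kind, r0, width, energy = 0)
    rbind(cons, data.frame(i = i, j = j, kind = kind, r0 = r0,
                           width = width, energy = energy))
  for (d in unique(domain)) {
    ix <- which(domain == d)
    o <- ix[order(residue[ix])]
    nn <- length(o)
    consec <- function(k) cbind(o[seq_len(nn - k)], o[seq_len(nn - k) + k])
    for (k in 1:3) {
      if (nn <= k) next
      p <- consec(k)
      keep <- residue[p[, 2]] - residue[p[, 1]] == k  # skip over chain gaps
      p <- p[keep, , drop = FALSE]
      if (!nrow(p)) next
      r0 <- vapply(seq_len(nrow(p)), function(q) dist2(p[q, 1], p[q, 2]), 0)
      cons <- add(p[, 1], p[, 2], if (k == 1) "bond" else "window", r0,
                  width = c(0.08, 0.10, 0.12)[k])
    }
    # backbone-side bonds
    r0 <- vapply(ix, function(q) dist2(q, q + n), 0)
    cons <- add(ix, ix + n, "bond", r0, width = 0.08)
    # calcium-coordination bond windows among the acidic loop side beads
    if (ca_bonds) {
      ca <- ix[residue[ix] %in% .CA_COORD_RESIDUES]
      if (length(ca) >= 2) {
        pr <- t(combn(ca, 2))
        r0 <- vapply(seq_len(nrow(pr)), function(q)
          dist2(pr[q, 1] + n, pr[q, 2] + n), 0)
        keep <- r0 <= 14
        if (any(keep)) {
          cons <- add(pr[keep, 1] + n, pr[keep, 2] + n, "window",
                      r0[keep], width = 0.10)
          ca_pairs <- c(ca_pairs, paste(pr[keep, 1] + n, pr[keep, 2] + n))
        }
      }
    }
  }

  # Go contacts between side (C-beta) beads
  sdist <- cross_dist(pos[side_id, ], pos[side_id, ])
  go <- NULL
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- sdist[a, b]
    if (d > max(go_cutoff, interface_cutoff)) next
    same <- domain[a] == domain[b]
    if (same && d > go_cutoff) next
    if (!same && d > interface_cutoff) next
    # pairs already constrained as calcium-coordination bonds keep them
    if (paste(side_id[a], side_id[b]) %in% ca_pairs) next
    if (same && abs(residue[a] - residue[b]) >= 3) {
      go <- rbind(go, data.frame(i = side_id[a], j = side_id[b],
                                 res_i = residue[a], res_j = residue[b],
                                 domain_i = domain[a], domain_j = domain[b],
                                 native = d, energy = intra_energy,
                                 interface = FALSE))
    } else if (!same && (swap[a] || swap[b])) {
      go <- rbind(go, data.frame(i = side_id[a], j = side_id[b],
                                 res_i = residue[a], res_j = residue[b],
                                 domain_i = domain[a], domain_j = domain[b],
                                 native = d, energy = interface_energy,
                                 interface = TRUE))
    }
  }
  if (!is.null(go) && nrow(go))
    cons <- add(go$i, go$j, "go", go$native, width = well_half_width,
                energy = go$energy)

  topo <- build_topology(beads, types, cons, es)
  structure(list(beads = beads, topology = topo,
                 state = system_state(pos),
                 n_res = n / 2, residues = sort(unique(residue)),
                 domains = unique(domain), swap_set = .SWAP_SET,
                 go_contacts = go,
                 patch_residues = patch_residues,
                 angle_map = angle_map),
            class = "cadherin_model")
}

#' Build a synthetic two-domain cadherin-like dimer
#'
#' A desk-scale stand-in preserving the EC1 dimer architecture: two
#' helical coarse-grained domains (one backbone and one side bead per
#' residue) joined by an interfacial Go patch on the N-terminal residues
#' 1-5 of each domain (the domain-swap analog), with a configurable
#' positively charged "turn region" patch on a loop distal to the
#' interface.  Geometry is deterministic in the seed.
#'
#' @param n_res_per_domain residues per domain (>= 10)
#' @param patch_spec list with `residues` (indices of the charged patch;
#'   default a 4-residue block around two thirds of the chain) and `charge`
#'   (per-residue side charge, default +1)
#' @param seed integer seed
#' @param go_cutoff native-contact distance cutoff between side beads
#'   (Angstrom)
#' @param interface_cutoff capture cutoff for cross-domain (interface)
#'   contacts; wider than `go_cutoff` so the swap strands engage their
#'   full contact shell
#' @param interface_energy interface Go well depth (kcal/mol); the default
#'   0.3 is about 0.5 kT at 300 K
#' @param intra_energy intra-domain Go well depth (kcal/mol)
#' @param well_half_width Go well half-width (Angstrom)
#' @param es [electrostatics_params()]
#' @return an object of class `cadherin_model`
#' @export
build_synthetic_dimer <- function(n_res_per_domain = 24,
                                  patch_spec = list(residues = NULL,
                                                    charge = 1),
                                  seed = 1, go_cutoff = 8,
                                  interface_cutoff = 11,
                                  interface_energy = 0.3,
                                  intra_energy = 0.3,
                                  well_half_width = 1.5,
                                  es = electrostatics_params()) {
  n <- n_res_per_domain
  stopifnot(n >= 10)
  patch <- patch_spec$residues
  if (is.null(patch)) patch <- round(2 * n / 3) + 0:3
  patch <- patch[patch <= n]
  if (any(patch %in% .SWAP_SET))
    stop("patch residues must be disjoint from the interface residues 1-5")
  pq <- if (is.null(patch_spec$charge)) 1 else patch_spec$charge

  # helical domain: ~100 degrees twist, 1.5 A rise per residue
  i <- seq_len(n)
  th <- i * 100 * pi / 180
  a_hel <- 2.3; rise <- 1.5
  bbA <- cbind(a_hel * cos(th), a_hel * sin(th), rise * i)
  sdA <- cbind((a_hel + 3) * cos(th), (a_hel + 3) * sin(th), rise * i)
  # domain B: rotate pi about x, shift so residues 1-5 run antiparallel to
  # A's, then separate along +x until free of hard-core overlap
  rot <- function(m) cbind(m[, 1], -m[, 2], -m[, 3])
  z_shift <- rise * 6
  jitter <- local_seed(seed, runif(1, 0, 2 * pi))  # seedable phase offset
  thB <- th + jitter
  bbB0 <- rot(cbind(a_hel * cos(thB), a_hel * sin(thB), rise * i))
  sdB0 <- rot(cbind((a_hel + 3) * cos(thB), (a_hel + 3) * sin(thB), rise * i))
  bbB0[, 3] <- bbB0[, 3] + z_shift
  sdB0[, 3] <- sdB0[, 3] + z_shift
  allA <- rbind(bbA, sdA)
  min_gap <- .BB_RADIUS + .SIDE_RADIUS  # most conservative core sum is 2r_side
  for (xoff in seq(6, 30, by = 0.25)) {
    bbB <- bbB0; sdB <- sdB0
    bbB[, 1] <- bbB[, 1] + xoff
    sdB[, 1] <- sdB[, 1] + xoff
    dmin <- min(cross_dist(allA, rbind(bbB, sdB)))
    if (dmin > 2 * .SIDE_RADIUS + 0.3 && dmin > min_gap + 0.3) break
  }

  charge <- ifelse(i %in% patch, pq, 0)
  mod <- .finish_dimer(
    bb = rbind(bbA, bbB), side = rbind(sdA, sdB),
    residue = c(i, i), domain = rep(c("A", "B"), each = n),
    charge = c(charge, charge), side_mass = rep(54, 2 * n),
    go_cutoff = go_cutoff, interface_cutoff = interface_cutoff,
    interface_energy = interface_energy,
    intra_energy = intra_energy, well_half_width = well_half_width,
    es = es,
    angle_map = list(s = c(max(10, n - 10), n), x = c(max(12, n - 8), n)),
    patch_residues = patch)
  mod$seed <- seed
  mod
}

#' Build a cadherin EC1 dimer model from a PDB structure
#'
#' Coarse grains each residue of the two chains to a backbone bead at the
#' C-alpha and a side bead at the C-beta (for glycine, a virtual site
#' 1.5 Angstrom along the bisector of N-CA-C, opposite the backbone).
#' Side-bead charges follow residue type (Arg/Lys +1, Asp/Glu -1).
#' Intra-domain Go contacts connect C-beta pairs within `go_cutoff`;
#' interface Go contacts (well depth `interface_energy`, default
#' 0.3 kcal/mol) are restricted to cross-chain contacts involving the
#' domain-swapped N-terminal residues 1-5.  Calcium coordination is
#' modelled as pairwise bond windows among the side beads of Glu11,
#' Asp62, Glu64, Asp96 and Asp99.
#'
#' @param pdb PDB text (single string or character vector of lines) or a
#'   file path
#' @param chains length-2 character vector of chain identifiers
#' @param go_cutoff C-beta contact cutoff (Angstrom)
#' @param interface_energy,intra_energy,well_half_width Go well parameters
#' @param es [electrostatics_params()]
#' @return an object of class `cadherin_model`
#' @export
build_dimer_from_pdb <- function(pdb, chains = c("A", "B"), go_cutoff = 8,
                                 interface_energy = 0.3, intra_energy = 0.3,
                                 well_half_width = 1.2,
                                 es = electrostatics_params()) {
  parsed <- read_pdb(pdb)
  at <- parsed$atoms
  stopifnot(length(chains) == 2)
  missing <- setdiff(chains, unique(at$chain))
  if (length(missing))
    stop("chain(s) not present in the structure: ",
         paste(missing, collapse = ", "))

  bb <- NULL; side <- NULL; residue <- integer(); domain <- character()
  charge <- numeric(); side_mass <- numeric()
  for (d in seq_along(chains)) {
    ch <- at[at$chain == chains[d], ]
    for (rn in unique(ch$resno)) {
      res <- ch[ch$resno == rn, ]
      ca <- res[res$elety == "CA", ]
      if (!nrow(ca))
        stop("residue ", rn, " of chain ", chains[d], " lacks a CA atom")
      ca <- as.numeric(ca[1, c("x", "y", "z")])
      cb <- res[res$elety == "CB", ]
      if (nrow(cb)) {
        cb <- as.numeric(cb[1, c("x", "y", "z")])
      } else {
        npos <- res[res$elety == "N", ]; cpos <- res[res$elety == "C", ]
        if (!nrow(npos) || !nrow(cpos))
          stop("glycine ", rn, " of chain ", chains[d],
               " lacks N/C atoms for the virtual C-beta")
        u1 <- as.numeric(npos[1, c("x", "y", "z")]) - ca
        u2 <- as.numeric(cpos[1, c("x", "y", "z")]) - ca
        u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
        bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
        cb <- ca + 1.5 * bis
      }
      bb <- rbind(bb, ca); side <- rbind(side, cb)
      residue <- c(residue, rn)
      domain <- c(domain, c("A", "B")[d])
      rname <- res$resid[1]
      charge <- c(charge, .residue_charge(rname))
      m <- .RES_MASS[[rname]]
      side_mass <- c(side_mass, max(if (is.null(m)) 110 else m - .BB_MASS, 15))
    }
  }
  .finish_dimer(bb = bb, side = side, residue = residue, domain = domain,
                charge = charge, side_mass = side_mass,
                go_cutoff = go_cutoff, interface_energy = interface_energy,
                intra_energy = intra_energy,
                well_half_width = well_half_width, es = es,
                angle_map = list(s = c(88, 98), x = c(92, 99)),
                patch_residues = integer())
}

#' @export
print.cadherin_model <- function(x, ...) {
  gi <- if (!is.null(x$go_contacts)) sum(x$go_contacts$interface) else 0
  gn <- if (!is.null(x$go_contacts)) nrow(x$go_contacts) else 0
  cat("<cadherin_model>", x$n_res, "residues/domain;",
      gn, "Go contacts (", gi, "interface );",
      length(x$patch_residues), "charged patch residue(s)\n")
  invisible(x)
}

#' Bead ids of a dimer or assembled system by annotation
#'
#' @param x a `cadherin_model` or `dmd_system`
#' @param domain optional domain label filter (`"A"`/`"B"`)
#' @param role optional role filter (`"backbone"`/`"side"`)
#' @param residues optional residue index filter
#' @param entity optional entity filter (`"dimer"`, `"plastic"`, `"ion"`)
#' @return integer bead ids
#' @export
bead_ids <- function(x, domain = NULL, role = NULL, residues = NULL,
                     entity = NULL) {
  beads <- x$beads
  keep <- rep(TRUE, nrow(beads))
  if (!is.null(entity)) keep <- keep & beads$entity %in% entity
  if (!is.null(domain)) keep <- keep & !is.na(beads$domain) &
      beads$domain %in% domain
  if (!is.null(role)) keep <- keep & beads$role %in% role
  if (!is.null(residues)) keep <- keep & !is.na(beads$residue) &
      beads$residue %in% residues
  which(keep)
}
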