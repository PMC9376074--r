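# Model builders: polymers, dimers (synthetic and structure-derived),
# and system assembly.

test_that("polymer chains have the stated composition and charge accounting", {
  pl <- build_polymer("PS", 20, seed = 1)
  expect_equal(sum(pl$beads$role == "monomer"), 20)
  expect_equal(pl$beads$mass[1], 104)  # styrene formula mass
  expect_equal(pl$net_charge, -length(pl$carboxylated))
  pmma <- build_polymer("PMMA", 20, seed = 1)
  expect_equal(pmma$beads$mass[1], 100)
  expect_equal(length(pmma$carboxylated), round(0.25 * 20))
  # anionic fraction limits
  p0 <- build_polymer("PS", 20, anionic_fraction = 0)
  expect_equal(p0$net_charge, 0)
  p1 <- build_polymer("PS", 20, anionic_fraction = 1)
  expect_equal(p1$net_charge, -20)
  expect_error(build_polymer("PS", 20, anionic_fraction = 1.2), "\\[0, 1\\]")
  # the size-scan upper bound builds and has a single-path backbone
  p80 <- build_polymer("PS", 80, seed = 3)
  expect_equal(sum(p80$beads$role == "monomer"), 80)
  bonds <- p80$topology$overrides
  bb_bonds <- bonds[bonds$i <= 80 & bonds$j <= 80, ]
  # single-path connectivity: exactly the n-1 consecutive backbone bonds
  consec <- bb_bonds[abs(bb_bonds$i - bb_bonds$j) == 1, ]
  expect_equal(nrow(consec), 79)
  expect_setequal(paste(consec$i, consec$j),
                  paste(1:79, 2:80))
})

test_that("polymer builders are pure functions of (inputs, seed)", {
  a <- build_polymer("PS", 20, seed = 5)
  b <- build_polymer("PS", 20, seed = 5)
  c <- build_polymer("PS", 20, seed = 6)
  expect_identical(a$topology, b$topology)
  expect_identical(a$state, b$state)
  expect_false(identical(a$carboxylated, c$carboxylated))
  # builders leave the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(build_polymer("PS", 20, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("synthetic dimers respect the interface architecture", {
  dm <- build_synthetic_dimer(24, seed = 1)
  # charged patch is disjoint from the swap interface residues 1-5
  expect_length(intersect(dm$patch_residues, 1:5), 0)
  expect_error(build_synthetic_dimer(24,
      patch_spec = list(residues = 3:6, charge = 1)), "disjoint")
  # interface contacts cross domains and involve the swap set
  go <- dm$go_contacts
  iface <- go[go$interface, ]
  expect_gt(nrow(iface), 0)
  expect_true(all(iface$domain_i != iface$domain_j))
  expect_true(all(iface$res_i %in% 1:5 | iface$res_j %in% 1:5))
  # intra-domain contacts stay within a domain at sequence separation >= 3
  intra <- go[!go$interface, ]
  expect_true(all(intra$domain_i == intra$domain_j))
  expect_true(all(abs(intra$res_i - intra$res_j) >= 3))
  # zero-charge patch gives a neutral protein
  dm0 <- build_synthetic_dimer(24, patch_spec = list(residues = 16:19,
                                                     charge = 0), seed = 1)
  expect_equal(sum(dm0$beads$charge), 0)
  # interface well depth is the 0.3 kcal/mol Go energy scale
  expect_true(all(iface$energy == 0.3))
  # determinism
  expect_identical(build_synthetic_dimer(24, seed = 2)$state,
                   build_synthetic_dimer(24, seed = 2)$state)
})

test_that("Go contact extraction equals a brute-force all-pairs filter", {
  dm <- build_synthetic_dimer(20, seed = 3)
  pos <- dm$state$positions
  side <- bead_ids(dm, role = "side")
  # independent all-pairs filter over side beads
  expected <- 0L
  for (a in seq_along(side)) for (b in seq_along(side)) {
    if (a >= b) next
    ia <- side[a]; ib <- side[b]
    d <- sqrt(sum((pos[ia, ] - pos[ib, ])^2))
    same <- dm$beads$domain[ia] == dm$beads$domain[ib]
    sep <- abs(dm$beads$residue[ia] - dm$beads$residue[ib])
    swap <- dm$beads$residue[ia] %in% 1:5 || dm$beads$residue[ib] %in% 1:5
    if (same && sep >= 3 && d <= 8) expected <- expected + 1L
    if (!same && swap && d <= 11) expected <- expected + 1L
  }
  expect_equal(nrow(dm$go_contacts), expected)
})

test_that("structure-derived dimers coarse-grain the synthetic PDB fixture correctly", {
  pdb <- synthetic_dimer_pdb(100)
  dm <- build_dimer_from_pdb(pdb)
  # both chains coarse-grained with equal residue counts
  expect_equal(sum(dm$beads$domain == "A"), 200)  # backbone + side
  expect_equal(sum(dm$beads$domain == "B"), 200)
  expect_equal(dm$n_res, 100)
  # the five calcium-coordination residues participate per domain
  for (d in c("A", "B")) {
    acidic <- bead_ids(dm, domain = d, role = "side",
                       residues = c(11, 62, 64, 96, 99))
    expect_length(acidic, 5)
  }
  # residue-typed charges: Arg/Lys +1, Asp/Glu -1
  expect_equal(unname(dm$beads$charge[bead_ids(dm, domain = "A",
                                               role = "side",
                                               residues = 30)]), 1)
  expect_equal(unname(dm$beads$charge[bead_ids(dm, domain = "A",
                                               role = "side",
                                               residues = 11)]), -1)
  # interface Go wells carry the 0.3 kcal/mol energy
  iface <- dm$go_contacts[dm$go_contacts$interface, ]
  if (nrow(iface)) expect_true(all(iface$energy == 0.3))
  # backbone beads sit on the C-alpha coordinates
  at <- read_pdb(pdb)$atoms
  ca1 <- as.numeric(at[at$chain == "A" & at$resno == 1 &
                       at$elety == "CA", c("x", "y", "z")])
  bb1 <- dm$state$positions[bead_ids(dm, domain = "A", role = "backbone",
                                     residues = 1), ]
  expect_equal(unname(bb1), ca1, tolerance = 1e-3)  # PDB precision
})

test_that("assembly respects separation, neutrality and determinism", {
  dm <- build_synthetic_dimer(16, seed = 1)
  pl <- build_polymer("PS", 10, seed = 1)
  # minimum separation >= 12 A in the initial frame across seeded placements
  for (s in 1:25) {
    sys <- assemble(dm, pl, seed = s, box_side = 90)
    d <- cgdmd:::cross_dist(sys$state$positions[sys$dimer_ids, ],
                            sys$state$positions[sys$plastic_ids, ])
    expect_gte(min(d), 12)
    # everything inside the box
    expect_true(all(sys$state$positions >= 0 &
                    sys$state$positions <= sys$box_side))
  }
  # same seed, same placement; different seed, different placement
  expect_identical(assemble(dm, pl, seed = 4)$state,
                   assemble(dm, pl, seed = 4)$state)
  expect_false(identical(assemble(dm, pl, seed = 4)$state$positions,
                         assemble(dm, pl, seed = 5)$state$positions))
  # counter-ions bring the net charge to zero
  sysn <- assemble(dm, pl, seed = 2, neutralize = TRUE)
  expect_equal(sum(sysn$beads$charge), 0)
  expect_gt(length(sysn$ion_ids), 0)
  # an impossible placement fails with a diagnostic
  expect_error(assemble(dm, pl, seed = 1, box_side = 45,
                        min_separation = 40, max_attempts = 20),
               "failed to place")
})
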