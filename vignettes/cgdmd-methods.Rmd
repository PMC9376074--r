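---
title: "Coarse-grained event-driven DMD of cadherin dimers and nanoplastics: models and methods"
author: "cgdmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgdmd methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Anionic nanoplastic particles can open gaps in endothelial monolayers by
interfering with the adherens junctions that VE-cadherin forms between
cells.  The adhesive unit is a *trans* dimer of the outermost extracellular
domain (EC1) of two opposing cadherins, held together by a strand-swapped
N-terminal segment (residues 1–5).  `cgdmd` provides a desk-scale,
fully inspectable simulation pipeline for the computational half of that
story: do anionic polymer particles bind the EC1 dimer, where, and does
that binding promote dissociation of the dimer under piconewton-scale
pulling forces?

## Discrete molecular dynamics

All interactions are piecewise-constant (step-function) radial pair
potentials.  Between events every bead moves ballistically; at a shell
boundary the pair receives an impulse along the line of centers:

* step down (entering a lower-energy shell): the radial relative velocity
  grows so that kinetic + potential energy is conserved exactly;
* step up with enough radial kinetic energy: transmission, again exactly
  energy-conserving;
* step up with insufficient energy, a hard core, or a bond wall: elastic
  reflection.

Momentum is conserved to the last bit at every pair event because the two
beads receive the identical impulse with opposite signs.  The engine
(`run_dmd()`) is event-driven with a binary heap, per-bead validity stamps
and a scheduling horizon; its only correctness definition is bit-exact
equivalence with a naive scheduler (`reference_run()`) that re-predicts
every pair after every event.  Both schedulers share every prediction and
resolution code path; predictions are pure functions of the stored bead
states, which is what makes bit-exactness achievable.  Frames are virtual
views of the state, so emitting them cannot perturb the event sequence.

Units are Angstrom, kcal/mol and Dalton, giving a derived time unit of
`sqrt(Da A^2 / (kcal/mol))` ≈ 48.9 fs (reported as the ~50 fs simulation
step); 1 kcal/mol/A ≈ 69.48 pN converts pulling forces.

Temperature is maintained by an Anderson thermostat: beads are picked at
exponential waiting times (rate 0.1 per mobile bead per time unit by
default — the collision frequency is a modelling choice, exposed in
`engine_config()`) and their velocities redrawn from the
Maxwell–Boltzmann distribution.  A constant pulling force is realized as
periodic momentum impulses (default every time unit) distributed over the
steered group in proportion to mass, i.e. a uniform acceleration; halving
the interval does not change campaign outcomes beyond replica noise, which
is the convergence check for this discretization.

## Potentials

* **Bonds, angles, dihedrals** — infinite-wall distance windows
  (`make_bond_window()`): bonds at ±8% of the native length, 1–3 windows at
  ±10%, 1–4 windows at ±12%.  Event-driven dynamics admits only radial
  discontinuities, so angle terms are represented as 1–3/1–4 windows, the
  standard DMD device.
* **Gō wells** (`make_go_well()`) — a single attractive square well of
  depth 0.3 kcal/mol (≈ 0.5 kT at 300 K) centred on the native side-bead
  distance, assigned only between natively contacting residue pairs.  The
  hard core of a Gō pair is the physical bead-contact distance, so a well
  never creates artificial excluded volume.
* **Screened electrostatics** — Debye–Hückel,
  `E = C q1 q2 exp(-r/λ)/(ε r)`, discretized into 10 equal-width shells by
  midpoint evaluation out to a cutoff of 3λ.  Defaults ε = 10, λ = 10 Å are
  effective coarse-grained choices (the screening appropriate to an
  implicit-solvent bead model, not a literal physiological ionic
  strength); both are config-exposed in `electrostatics_params()`.
* **Hydrophobic-like attraction** — one shallow shell from bead contact to
  1.6× contact, of depth `sqrt(h_i h_j)` for per-type hydrophobicity
  parameters `h`.  This is the effective stand-in for the all-atom van der
  Waals and implicit-solvation detail, which is out of scope at this
  resolution.

## Models

**Cadherin EC1 dimer.**  Two beads per residue: a backbone bead (56 Da) at
the Cα and a side bead at the Cβ (for glycine a virtual site 1.5 Å along
the N–Cα–C bisector).  Side beads carry residue-typed charges (Arg/Lys +1,
Asp/Glu −1).  Intra-domain Gō contacts connect Cβ pairs within 8 Å at
sequence separation ≥ 3; interface Gō contacts are restricted to
cross-domain contacts involving the swap segment (residues 1–5), captured
out to 11 Å so the strand engages its full contact shell.  Ca²⁺
coordination (Glu11, Asp62, Glu64, Asp96, Asp99) is modelled as pairwise
bond windows among those side beads.  `build_dimer_from_pdb()` derives all
native distances from a two-chain structure; `build_synthetic_dimer()`
builds a desk-scale stand-in from two helical domains joined antiparallel
at their N-termini, with a positively charged 4-residue "turn" patch
placed two-thirds of the way along each chain, distal to the interface.
The swap-segment side beads are more hydrophobic (h = 0.5 vs 0.1
elsewhere), reflecting the hydrophobic docking of the swapped strand; this
is also what lets an uncharged polymer find the interface.

**Nanoplastics.**  One bead per monomer (styrene 104 Da, methyl
methacrylate 100 Da), bond windows along the chain, 1–3 windows keeping a
realistic backbone angle, and anionic carboxylate beads (−1 e) on a
seed-chosen monomer subset — half of the monomers for PS, a quarter for
PMMA ("a subset" is not quantified by the reference protocol; both are
parameters).  PMMA differs from PS by its monomer mass and a weaker
effective hydrophobicity.  Monomer bead radius (2.0 Å) and hydrophobicity
(PS 1.5 kcal/mol) were calibrated once so that the default 20-mer
carboxylated PS chain collapses in 5 ns at 300 K to a globule of effective
diameter ≈ 15–16 Å, the reference equilibrated size; the effective
diameter is defined by the uniform-sphere convention
`D = 2 sqrt(5/3) <Rg>` over the final quarter of the run.

**Assembly.**  The dimer is centred in a reflective cubic box (side 120 Å;
the printed reference geometry is dimensionally ambiguous and this package
adopts the all-atom-plausible reading of a 120 Å cube, config-exposed).
The plastic is placed with a uniformly random rotation and position at
least 12 Å from any dimer bead, or docked at contact against the charged
patch to prepare a pre-bound complex.  Counter-ions can be added to
neutralize the system for pulling runs.

## Campaigns

* `collapse_equilibrate()` — thermostatted run from the extended chain,
  recording Rg per frame.
* `binding_campaign()` — per replica: fresh random placement, dimer
  backbone immobilized (side chains free), Maxwell–Boltzmann initial
  velocities, fixed duration.  The binding frequency of residue *i* is
  the fraction of pooled (frame, replica) samples from the trailing 40%
  of each run in which any bead of that residue is within 0.65 nm of any
  plastic bead.
* `pulling_campaign()` — one domain's backbone immobilized except its
  swap segment; all non-swap beads of the other domain pulled by a
  constant force along that domain's residue-1 → C-terminus axis (the
  EC1→EC2 direction; EC2 itself is not part of the model, so this axis is
  the committed definition).  Replicas run in 0.1 ns chunks until the
  inter-domain contact count (0.65 nm cutoff, any bead to any bead) first
  reaches zero — the first transient zero counts, with no rebinding grace
  window — or are censored at the campaign duration.  The same 0.65 nm
  cutoff serves binding frequency and dissociation detection: one cutoff,
  one definition.

Paper-scale presets (30 × 50 ns binding; 30 × 100 ns pulling at 0/10/20
pN) ship in `campaign_preset("paper", ...)`; the desk-scale presets used
throughout the tests are 5–20 replicas of 1–2 ns, sizes chosen so the
full suite runs on a single CPU in minutes while still resolving the
qualitative contrasts of interest.

## What the synthetic systems do and do not show

The synthetic dimer preserves the architecture that the analysis stack
assumes — a two-domain dimer held by an interfacial swap patch, a charged
turn patch away from the interface, Gō-stabilized folds — but not cadherin
geometry: its helical domains, contact counts and patch placement are
constructions.  Tests passing on it demonstrate that the pipeline
measures what it claims to measure (enrichment at a charged patch,
interface binding of an uncharged polymer, force-accelerated dissociation,
earlier dissociation with a pre-bound anionic particle), not that the
model reproduces residue-level cadherin binding maps.  Likewise the
binding-selectivity checks run in a 70 Å box rather than the default
120 Å production box: with a single 20-mer the smaller box raises the
encounter rate so that a purely diffusive, short-range-attraction search
(the uncharged polymer has no long-range funnel) samples binding within
nanosecond-scale replicas.  Enrichment is a question of *where* the
polymer binds once it meets the dimer, which the box size does not bias.
Binding-site selectivity is reported as per-residue mean frequency over
the patch versus elsewhere; a contact within 0.65 nm of *any* bead of a
residue gives every patch visit a footprint spanning its sequence
neighbours, so summed frequency over a 4-residue patch against the sum
over all 40 remaining residues would measure patch size, not selectivity.

## Numerical choices

* Event times are exact quadratic roots; a pair classified on a boundary
  is disambiguated by its radial velocity, and the outermost wall of a
  bond window always classifies as inside (the wall is impenetrable).
  A pair found on the wrong side of an infinite wall through accumulated
  round-off transmits freely back — a self-healing rule that cannot
  inject energy.
* Tie-breaking is lexicographic on (time, kind, bead ids), which fixes the
  event order and hence bit-exact reproducibility for a given seed.
* The energy ledger (kinetic + step potential − steering work − thermostat
  increments) is recomputed from scratch at every frame; runs abort on
  event-time regression and flag any hard-core overlap.
* All randomness flows from one deterministic generator seeded per run;
  R-level builders use isolated seeds and restore the caller's RNG state.
* Degenerate inputs are rejected at construction (non-monotone edges,
  zero-width bond windows, empty selections, patches overlapping the
  swap segment).

## Known limitations

* Two beads per residue cannot reproduce all-atom binding hot-spot maps or
  hydrogen-bond chemistry; claims are qualitative contrasts at reduced
  scale.
* The thermostat provides no hydrodynamics; diffusion is ballistic between
  resamplings, so absolute binding kinetics are not transferable.
* Electrostatic screening parameters are effective, not fitted.
* Constant-velocity pulling, umbrella sampling and free-energy estimates
  are out of scope.
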