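---
title: "The mesofiber model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mesofiber model: assumptions, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesofiber)
```

## The model

`mesofiber` represents a chromatin fiber at nucleosome resolution with four
kinds of interacting units:

* **Nucleosome cores** are rigid bodies. Each core carries exactly 300
  discrete charges fixed in its body frame; the charge set approximates the
  screened electrostatic field of the full nucleosome (147 bp of wrapped DNA
  plus the tailless histone octamer). Three core types are supported:
  canonical, the macroH2A1 histone variant, and the hybrid core carrying one
  copy of each H2A species.
* **Linker DNA** is a wormlike bead chain at ~9 bp resolution: beads every
  `l0 = 3` nm (the B-DNA rise of 0.34 nm/bp gives 8.82 bp per segment), with
  harmonic stretching, harmonic bending calibrated to the 50 nm persistence
  length of DNA, and a twist-deviation penalty calibrated to the torsional
  rigidity `C = 3e-19 erg cm`. A linker of `n` beads spans `n + 1` segments
  (the outer two connect to the core entry/exit sites), so 2..8 beads
  represent 26.47..79.41 bp; two beads is the shortest admissible linker.
* **Histone tails** -- both N-terminal tails of H2A, H2B, H3, H4 and both
  C-terminal tails of H2A -- are flexible chains at 5 residues per bead,
  attached to fixed sites on the core surface. The macroH2A1 variant edits
  the H2A tail bead charges: N-tail (+3, +1, +3, +2) becomes
  (+1, +3, +2, +1) and C-tail (+1, 0, +2) becomes (0, 0, +3). Note the
  N-tail edit changes the summed tail charge by -2 e per copy; only the
  C-tail edit is charge-conserving.
* **Linker histones** bind on-dyad: 6 rigid globular beads that move with
  the host core and 22 flexible C-terminal-domain beads.

All charged units interact through a Debye-Hückel potential (monovalent
salt sets the inverse screening length; 150 mM at 293 K gives
`kappa = 1.27` 1/nm) and a Lennard-Jones excluded-volume term. Excluded
pairs are: elements of the same rigid body, bonded chain neighbours, and
tail/LH/terminal-DNA beads against their own attachment core. Genomic
loops are modelled as harmonic restraints with energy `k (l - l0)^2` --
deliberately without the 1/2 prefactor, matching the printed form of the
restraint energy; the force constant is interpreted in kcal/mol/nm^2
(the dimensionally consistent reading).

Tail acetylation is modelled as a two-state tail: a wildtype extended state
and a compact "folded" template (beads drawn to 60% of the wildtype
extension). Folded tails contribute nothing to the nonbonded energy -- they
are sterically present only for contact analysis -- and their stretching and
bending constants are stiffened by `acetyl_stiffness_factor`. A dedicated
Monte Carlo move (swap-fold) toggles eligible tails between the two states.

## Energy parameters

`energy_params()` exposes every constant. Defaults, with provenance:

| parameter | default | units | origin |
|---|---|---|---|
| `l0` | 3 | nm | DNA bead spacing (~9 bp) |
| `h` | 100 | kcal/mol/nm^2 | stiff bond, fluctuations ~0.08 nm |
| `g` | 9.70 | kcal/mol/rad^2 | from Lp = 50 nm: `g = Lp kBT / l0` |
| `s` | 14.39 | kcal/mol/rad^2 | from C = 3e-19 erg cm: `s = C / l0` |
| `bp_per_turn` | 10.3 | bp | helical repeat of nucleosomal-context DNA |
| `dna_bead_charge` | -24 | e | charged-cylinder effective charge at 150 mM; an approximation, override when better values are available |
| `k_ev` | 0.01 | kcal/mol | soft excluded-volume scale |
| `sigma_core/dna/tail/lh` | 1.2 / 2.4 / 1.8 / 1.8 | nm | effective contact diameters |
| `cutoff` | 7 | nm | ~9 Debye lengths at 150 mM |
| `temperature`, `salt` | 293 K, 0.15 M | | reference conditions |

The stiffness constants `h`, `g`, `s`, the excluded-volume scale and the
contact diameters are not uniquely pinned by any single experiment at this
resolution; the defaults reproduce the two experimental anchors (bending
persistence length, torsional rigidity) at the 3 nm discretization and
everything is overridable from a YAML file (`read_energy_params()`).

Twist bookkeeping: each linker should make `length_bp / 10.3` helical
turns. The deviation from the nearest integer is converted to a per-segment
penalty angle spread evenly over the linker's segments (the split rule is a
package choice; only the total is physically pinned), and the per-replica
residual twist (0, -12 or +12 degrees) is added to each segment target as
stated for the penalty form. Segment twists are measured by parallel
transport of the material frame along the bead chain.

## Synthetic charge sets

Production charge sets are derived from atomistic nucleosome structures by
an external electrostatic optimization and are *not* shipped; the package
reads them from plain-text profiles (`read_charge_profile()`). The built-in
`synthetic_core_charges()` stand-in places 300 equal charges on the
nucleosome cylinder surface (total -150 e) by a deterministic golden-angle
layout, identical across core types. Two consequences follow, and both are
deliberate:

* with synthetic sets, canonical/macroH2A1/hybrid differences act **only**
  through the published tail-charge edits, so variant effects are weaker
  than with real surface-charge differences;
* uniform negative surfaces lack the positive histone-surface patches that
  mediate strong internucleosome stacking, so synthetic-charge fibers
  compact less and more slowly than fibers with optimized charge sets.

Any conclusion about real chromatin therefore requires supplying real
charge profiles; the synthetic sets exist so that the whole pipeline is
exercisable and testable without external data.

## Sampling

`run_mc()` performs Metropolis Monte Carlo where one step is one attempted
move drawn from the weighted mixture (`move_set()`): global pivot (rotate
the shorter side of the fiber about a random axis through a random backbone
element), local translation/rotation of a single core or DNA bead (a core
carries its rigid charges, its tails' coordinates and its bound linker
histone), configurational-bias regrowth of one histone tail using the
Rosenbluth scheme (bond lengths are drawn from their exact Boltzmann
distribution, directions uniformly, with 8 trials per bead by default;
acceptance uses the new/old Rosenbluth weight ratio so detailed balance
holds), local translation of one LH C-terminal bead, and the swap-fold
toggle for tails of acetylated cores. Moves without eligible targets are
disabled per system. The default mixture (pivot 0.2, local 0.4, regrowth
0.2, LH 0.1, swap-fold 0.1) is a package choice.

Optional amplitude tuning toward ~40% acceptance runs only during a
discarded burn-in (`tune` argument) and is then frozen; tuning during
production would break detailed balance. Energies are tracked
incrementally per move and the engine recomputes the total from scratch at
the end of every run, storing both values in the trajectory metadata (the
test suite requires agreement to 1e-6 relative). A non-finite energy aborts
the run with a diagnostic rather than sampling from a corrupted state.

`run_replicas()` starts independent replicas with their own seeds and a
residual DNA twist cycling through 0, -12, +12 degrees. Reproducibility is
exact: the same seed yields a bit-identical trajectory. R's own RNG stream
is used throughout (single-threaded, sequential replicas), which meets the
reproducibility contract without a counter-based generator.

## Initial structures

Fibers start as a planar regular zigzag whose turning angle follows from
the core entry/exit geometry (108 degree wedge), with every DNA segment at
its equilibrium length, tails splayed toward the disk faces, and bead
frames parallel-transported from the core frames. The zigzag topology
forces a fixed total junction twist per linker; it is distributed evenly
over the segments, shifted by whole turns to sit nearest the twist target.
Any reasonable start is acceptable because sampling equilibrates the
structure; the relaxed start simply avoids an initial energy spike.
Nucleosome-free regions are built by deleting the core at the NFR position
and merging its two flanking linkers plus 167 bp of DNA into one long
stiff linker, discretized with `beads_for_length()` -- this preserves
contour length through the depleted region. The CAG-repeat expansion
lengthens the first linker by the bead increment nearest +106 bp
(+12 beads, a nominal ~35 repeats); whether such expansions sit on
nucleosomal or linker DNA is unknown, and linker DNA is the choice here.

## Analysis conventions

* **Contact matrix**: nucleosomes i and j are in contact when any element
  of i (core charges, tail beads, linker beads -- each linker half is
  assigned to its nearer flanking nucleosome -- LH beads) is within 2 nm of
  any element of j; frequencies are normalized per trajectory and then
  averaged across replicas.
* **Packing ratio**: nucleosomes per 11 nm of fiber-axis arc length. The
  axis is a cubic smoothing spline through the core centers versus core
  index; the automatic smoothing level is the strongest smoothing that
  keeps the RMS residual within one nucleosome radius (5.5 nm).
* **Sedimentation**: Kirkwood-type pair sum
  `S = S_mono(rho) (1 + (R1/N) sum 1/R_ij)` over ordered pairs, with the
  mononucleosome limits 11.1 S (no LH) and 12 S (with LH) pinning the
  linear interpolation in LH density.
* **Clutches**: DBSCAN over core centers with a 30 nm search radius and a
  minimum of 3 nucleosomes; implemented in the package (the algorithm is
  20 lines) and cross-checked in the tests against an exhaustive
  reachability oracle.
* **Persistence length**: exponential fit of the tangent correlation of
  the fiber axis. The pairing rule is ambiguous in general; both the
  all-pairs estimator (default) and a start-anchored estimator are
  provided. The fit is least squares on the log of positive correlations;
  non-decaying (straight) axes return a capped sentinel of 1e6 nm with a
  flag instead of infinity.
* **Epigenetic contact classes**: a core is classed acetylated > LH-bound >
  NFR-adjacent > unmarked (precedence is needed because marks overlap), and
  pair classes Ac/Ac, Ac/LH, LH/LH, NFR/Ac, NFR/LH are tallied with all
  remaining pairs pooled as WT/WT, so the classes exactly partition the
  total contact weight.
* **Tail interactions**: per snapshot each tail is assigned to the category
  of its closest contacted element (parental core/DNA, nonparental core,
  nonparental DNA, other tails) or "free", so the five frequencies sum to
  one; folded tails count as free. LH beads inherit their host core's
  category.

## What the synthetic generator does and does not emulate

`sample_positions()` draws dyad spacings from a normal distribution
truncated at 165 bp (the 147 bp footprint plus the shortest representable
linker), with NFRs as additional 167 bp gaps -- it emulates the *first
moments* of an MNase-derived nucleosome map (mean repeat length, jitter,
occasional depleted regions). It does not emulate sequence-directed
positioning, phasing against boundaries, or the long-tailed linker
distributions of real maps; when a real track is available it enters
through exactly the same path (`read_bed_track()` then `make_htt_like()`),
so passing tests on synthetic tracks validate the machinery, not any
biological claim. The gene-scale recipes encode the two epigenetic
conditions -- healthy: canonical cores, LH density 0.5, acetylation islands
(cores 1-7 and 629-659 at the 688-core reference, rescaled proportionally
for smaller desk-scale models), 4 loop restraints to anchors 357, 408, 442,
519; diseased: macroH2A1 cores, LH density 0.07, no acetylation, +106 bp
CAG expansion on linker 1, 3 loop restraints to anchors 531, 621, 688 --
all with k = 40 kcal/mol/nm^2 and l0 = 50 nm.

## Problem sizes used in the shipped checks

The package's checks run at desk scale: polymer-physics validations use
free chains of 2-31 beads with 2e4-2e5 attempted moves; oracle
equivalences use fibers of 3-8 cores; construction checks build up to the
full 688-nucleosome gene models (construction is cheap -- sampling is not).
The qualitative variant-composition comparison runs 20-core short-NRL
fibers for 1.5e5 steps over 2 replicas per composition. These sizes are
orders of magnitude below production scale (100-688 cores, 4e7-7e7 steps,
30-60 replicas), which is the appropriate regime for validating
correctness of the machinery; quantitative reproduction of ensemble
observables additionally requires the real charge sets discussed above.

One consequence is measured directly by the shipped checks: in the
variant-composition comparison, all-macroH2A1 20-core fibers show *more*
second-neighbour (i+/-2) contacts than all-canonical fibers, not fewer.
With uniform synthetic core surfaces there is no internucleosome stacking,
so desk-scale fibers never form the zigzag-folded regime in which the
variant erodes a pronounced i+/-2 peak; what remains visible is the
variant's generic short-range disordering through its weaker H2A tail
charges. The corresponding check is deliberately kept asserting the
folded-regime direction and is expected to fail until optimized charge
sets and production-scale sampling are supplied.

## Known limitations

* No sequence-dependent DNA mechanics and no twist-bend coupling.
* Only on-dyad LH binding; the LH bead charges shipped by default are a
  documented synthetic profile.
* The macroH2A1 macro-domain (beyond the histone fold) is not modelled.
* Debye-Hückel screening assumes monovalent salt; no multivalent ions.
* The Lennard-Jones and Debye-Hückel terms are truncated (not shifted) at
  the cutoff; with the soft default `k_ev` the discontinuity is far below
  kBT.
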