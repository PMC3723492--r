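---
title: "Multi-resolution modeling of peripheral membrane-protein anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution modeling of peripheral membrane-protein anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscale)
```

## The scientific problem

Water-soluble interfacial enzymes such as the calcium-independent
phospholipase A2 (iPLA2) become active only when anchored at a
phospholipid membrane surface.  Their membrane complexes are generally
invisible to crystallography and NMR, so structural models are built by a
dual-resolution strategy: the insertion process is simulated at
coarse-grained (CG) resolution, where four heavy atoms map to one
interaction bead and microsecond-scale association events are
reachable; the equilibrated CG complex is then mapped back to atomistic
coordinates for refinement; and the resulting pose is validated against
deuterium-exchange mass spectrometry (DXMS), which reports which protein
fragments lose solvent accessibility on membrane binding.

`memscale` implements that workflow as a reusable, testable toolkit: bead
mapping with an elastic network, a minimal CG molecular-dynamics engine,
rigid-body back-mapping, a membrane-insertion analysis suite, and a DXMS
consistency scorer.  Every step can be exercised on synthetic toy
systems generated by the fixtures module, so the full pipeline runs at
desk scale with no external data.

## Coarse-grained representation

`map_protein()` places one backbone bead per residue at the center of
mass of the backbone atoms (N, CA, C, O) and zero to two side-chain
beads at template-defined parent-atom centers of mass.  Bead masses are
parent-atom sums, so mass is conserved exactly; bead polarity classes
(P polar, N intermediate, C apolar, Q charged) follow side-chain
hydrophobicity and live in an editable YAML table rather than in code.
Placing the backbone bead at the backbone center of mass (not at the CA)
is our choice, consistent with the 4:1 mapping philosophy; the CA sits
about half an Angstrom from that center and the difference is absorbed
by the least-squares fit during back-mapping.

`map_lipid()` applies per-lipid templates; the packaged
phosphatidylcholine-like template uses 13 beads (a zwitterionic Q+/Q-
headgroup pair, two glycerol linkers, and 4+5 tail beads), while the
3-bead head--tail--tail `toy3` template is what the synthetic fixtures
use.  `map_water()` implements the standard 4:1 water mapping with a
floor.

To preserve secondary and tertiary structure during CG dynamics,
`build_elastic_network()` adds harmonic restraints
`E = 1/2 k (r - r0)^2` with `k = 10` kJ mol^-1 A^-2 between all backbone
beads within 7 A in the reference structure.  Two conventions required a
decision.  First, "force constant" is ambiguous by a factor of two; we
use the `1/2 k` convention throughout (bonds, angles, elastic network).
Second, sequence-adjacent backbone pairs are already restrained by their
bond term, so they are excluded from the network by default; passing
`include_bonded = TRUE` restores them, since the source protocol does
not state which reading was used.

## The CG engine

The engine (compiled, in `src/engine.cpp`) implements the standard
cutoff-based CG force model:

* 12-6 Lennard-Jones interactions with both the `r^-12` and `r^-6` terms
  taken through the standard shift polynomial over the 9--12 A window,
  so energy and force go continuously to exactly zero at 12 A.  For a
  `r^-p` term the shifted force is
  `F(r) = p/r^(p+1) + A (r-r1)^2 + B (r-r1)^3` on `r1 < r < rc`, with
  `A`, `B` fixed by `F(rc) = F'(rc) = 0` and the energy offset so
  `E(rc) = 0`.  The same polynomial with `p = 1` gives the Coulomb term,
  shifted over 0--12 A, with a uniform relative dielectric of 15 that
  stands in for the missing polarizability of chargeless CG water.
* harmonic bonds and angles; the elastic network enters as extra bonds.
* leapfrog integration at a 25 fs default timestep.
* the stochastic velocity-rescaling (canonical-sampling) thermostat with
  a single global coupling, default `tau` = 1 ps (the source protocol
  names the thermostat but not its coupling time) and 323 K target.
* an optional Berendsen barostat: each box axis is scaled by
  `mu = (1 - dt/tau_p * kappa * (P_ref - P_aa))^(1/3)` from the
  instantaneous pressure-tensor diagonal, with `tau_p` = 10 ps,
  `kappa` = 3e-5 bar^-1 and `P_ref` = 1 bar.  All three axes couple
  independently by default ("anisotropic"); a semi-isotropic x=y option
  exists because the convention is ambiguous for membrane work.  The
  per-step scaling factor is clamped to [0.995, 1.005] for stability.
* steepest-descent minimization (default 5000-step budget) with
  adaptive step size and component-wise force capping, so random boxes
  with overlapping beads have a finite initial gradient.

Units are Angstrom / fs / amu / kJ mol^-1 everywhere
(`mem_constants()` centralizes the conversions; 1 amu (A/fs)^2 is
exactly 1e4 kJ mol^-1).  Nonbonded interactions use a Verlet list built
from a cell decomposition with a 2 A skin, rebuilt when any bead has
moved more than half the skin; boxes too small for a 3x3x3 cell stencil
fall back to an all-pairs candidate sweep, which produces bit-identical
forces.  Coordinates are wrapped into the box at every rebuild so the
minimum image needs only a single branchless correction; bonded groups
are re-imaged on the analysis side (`memscale:::.unwrap_group`) where an
intact molecule is required.  Pairs joined by a bond (including elastic
bonds) or the outer pair of an angle are excluded from nonbonded
interactions.  Runs are bitwise reproducible given the integrator seed;
1-2 exclusions, thermostat noise and the barostat all draw from one
seeded generator.

The packaged force-field table is deliberately a reduced, configurable
4-class toy parameter set (well depths 2--5 kJ mol^-1, sigma 4.7 A)
rather than a reproduction of any published CG parameter set: behavior
(self-assembly, interfacial anchoring), not parameter values, is the
contract, and the table is data that can be swapped.

### Numerical choices worth knowing

* Energy conservation is assessed as MD engines report it: the slope of
  a linear fit to the total energy over the run, times the run length,
  per bead.  A symplectic integrator's energy fluctuates in a bounded
  band (here a few kJ mol^-1 for the 38-bead fixture at 25 fs); the
  fit averages that band out and exposes genuine secular drift.
* The thermostat acts on half-step leapfrog velocities; reported
  temperatures use on-step velocities (the average of adjacent
  half-steps).
* Minimization treats a trial step as accepted only if it lowers the
  energy; the step grows by 1.2x on acceptance and shrinks by 5x on
  rejection, terminating on a 1e-7 A underflow.

## Back-mapping

`kabsch_fit()` is the SVD solution of the orthogonal Procrustes problem
with determinant sign correction (never a reflection).
`fit_protein_to_cg()` moves a whole atomistic reference rigidly by the
CA-to-backbone-bead transform, pairing residues by id; internal geometry
is preserved to round-off.  The membrane patch has no point
correspondence with CG phosphates, so `fit_membrane_to_cg()` matches
the phosphate centroid (and thereby the bilayer midplane) by pure
translation.  `prune_lipids()` removes a lipid in full when any of its
atoms lies strictly within 0.6 A of any protein atom.
`solvate_and_ionize()` places lattice water outside an exclusion radius
and adds `round(conc * N_A * V_solvent)` ions per species -- 0.1 mol/L
default, read as "per species", which reproduces counts like 42+42 for
a ~7e5 A^3 solvent volume -- plus counter-ions to neutralize.
`water_exclusion_region()` emits a declarative z-slab (proximal
phosphate plane up to the protein's lower envelope, clipped to the
protein footprint) with a half-harmonic wall constant, serializable for
external atomistic engines; atomistic dynamics itself is out of scope.

## Insertion analysis

With the bilayer normal fixed to +z, `membrane_frame()` gives the lipid
center of mass and the two leaflet phosphate planes (2-means split of
phosphate z).  The insertion angle is the angle between a helix axis
(largest singular vector of centered CA coordinates, sign-folded into
[0, 90] because an insertion angle is orientationless) and its
projection on the membrane plane; the insertion depth is the unsigned
distance along the normal between a residue group's center of mass and
the bilayer center.  `residue_depth_table()` follows the convention of
published per-residue tables: side-chain center of mass per frame,
mean +/- population (divide-by-N) standard deviation -- the sd
convention is unstated in the sources this emulates, so it is fixed and
documented here -- with a whole-residue fallback for glycine and CA
traces.  `group_depth_summary()` averages row means and row sds per
class and rounds to one decimal, which is the precision such tables are
printed at.  `anchor_depth_reference()` packages literature-reported
per-residue depths for the iPLA2 anchor region (residues 710-724) as
the standard input for those summaries.

Hydrogen bonds use the common 3.5 A / 150 degree geometric criterion
(the sources give none); a heavy-atom-only distance mode exists for
models without hydrogens.  `density_profile()` gives mass-weighted,
unit-integral z-histograms about the bilayer center.  `ils_map()`
implements implicit-probe sampling for a single-site, LJ-only
(methane-like) probe: per voxel,
`F = -kB T log( mean over frames of exp(-dE/kB T) )` with `dE` the
shifted-LJ probe insertion energy within 12 A.  Orientational averaging
is omitted -- a spherical probe has none -- and grids finer than 0.1 A
are refused as a resource guard.

## DXMS consistency scoring

DXMS fragments are classified by their deuteration decrement on
membrane binding: `strong` at >= 70%, `weak` under 40%, `none` at zero,
and values in [40, 70) flagged `intermediate` (between the published
thresholds).  `burial_profile()` converts a trajectory into per-residue
buried-frame fractions (side-chain center of mass below the proximal
phosphate plane, or a sphere-point SASA criterion for atomistic
models).  The published comparisons of structure with DXMS are
qualitative; to obtain a reproducible number, `consistency_score()`
defines -- openly as this package's construction -- a fragment-level
match: strong fragments should be predicted protected (mean burial
fraction >= 0.5), no-decrement fragments exposed, and weak or
intermediate fragments count as half-weight matches when partially
buried, reflecting the interpretation that weak decrements arise from
transient occlusion (e.g. a phospholipid transiently occupying a
cavity) rather than stable burial.  Mapping burial to absolute
deuterium-exchange counts would require an exchange-rate model the
sources do not provide, and is deliberately not attempted.

## Fixtures: what the synthetic systems emulate

* `build_helix()` -- ideal helix (1.5 A rise, 100 degrees twist, 2.3 A
  radius: textbook values) as a CA trace with one radial side-chain
  pseudo-atom per non-Gly/Ala residue, numbered in full-protein
  coordinates so ranges like 710-724 are usable verbatim.
  `anchor_sequence()` reproduces the anchor-region composition: its six
  hydrophobic residues cluster on one helix face.
* `build_bilayer()` -- pre-assembled toy bilayer on two leaflet grids
  (default 28 A^2 per lipid, near close packing for a one-bead-wide
  sigma = 4.7 A lipid -- looser grids are unstable and collapse;
  phosphate planes +/- 12 A so the two straight 2-bead tails just meet
  at the midplane; the offset is a parameter, so head_offset = 19
  reproduces the phosphate-peak scale of a real PC bilayer when
  needed).
* `random_box()` -- seeded uniform lipid/water boxes for self-assembly,
  with a density guard and overlaps left to the clash-capped minimizer.
* `toy_protein()` -- a 40-residue helix-loop-helix miniature of the
  catalytic domain: anchor helix 710-724 lying interfacially
  (hydrophobic face down), a "long" helix rising at 67 degrees, in a
  membrane-bound or solution pose.  A full-size fold is unnecessary for
  exercising any operation.
* `synth_dxms(preset = "ipla2")` -- the published exchange pattern:
  strong protection at 708-730 and weak protection at 631-655, 658-664
  and 773-778.

Water in fixture systems is generated directly at CG resolution
(`solvate_fixture()`); whether published CG water counts came from 4:1
conversion of an atomistic box or direct CG solvation is not stated in
the protocols this emulates, and `map_water()` provides the ratio for
the former reading.

### Study conditions and problem sizes

The emergent-behavior experiments run at deliberately desk-scale sizes,
chosen once and fixed: self-assembly uses 64 toy lipids and 200 CG
water sites in a 36 A box for 1e5 steps of 25 fs at 323 K (NVT; the
constant-volume ensemble keeps the small box from drifting below twice
the cutoff during assembly), judged by `detect_bilayer()` -- one
distance-connected aggregate holding >= 90% of the lipids, tails
concentrated in a slab along one axis, heads outside the tails on both
sides.  Anchoring places the amphipathic helix in the water just above the
headgroup plane of a pre-formed 50-lipid bilayer with its anchor face
toward the membrane -- the fixture emulates a *productive* collision,
because in free runs the helix tumbles during its approach and the
random reorientation search is known to dominate the kinetics (most
collisions are unproductive); desk-scale runs cannot wait it out.  The
check compares hydrophobic versus polar side-chain distances from the
bilayer center over the last quarter of the run.  For the close-packed
toy head layer the equilibrium state is interfacial adsorption with the
hydrophobic face toward the lipids rather than deep wedging below the
phosphate plane; the ordering, not the absolute depth, is the
contract.  Relaxation runs the same system three times from one seed --
relaxed, 3 A too deep, and tilted 15 degrees -- and asks only that the
tense runs move toward the measured relaxed depth/tilt (or land inside
the relaxed run's own fluctuation band, since the observables of a
15-residue helix on a toy membrane are noisy), not for a rate.  These toy systems reproduce the qualitative physics --
hydrophobic-driven assembly, amphipathic interfacial anchoring,
relaxation from tense poses -- but none of the quantitative observables
of real lipids (areas per lipid, order parameters, microsecond
anchoring kinetics), so passing them validates the machinery, not any
real-membrane prediction.

## Known limitations

* The engine is cutoff-based by design (no Ewald electrostatics), serial,
  orthorhombic-box only, and makes no claim of force-field fidelity.
* Back-mapping stops at system construction; atomistic refinement needs
  an external engine.
* `detect_bilayer()` assumes a slab normal along a box axis; strongly
  tilted or curved aggregates (vesicles) are reported as not formed.
* DXMS scoring is fragment-level and threshold-based; it is a
  consistency check, not a kinetic exchange model.
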