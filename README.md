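# memscale

Multi-resolution modeling of peripheral membrane-protein anchoring in R.

Interfacial enzymes such as the calcium-independent phospholipase A2
(iPLA2) are water-soluble but act at phospholipid membranes, and their
membrane complexes usually cannot be solved experimentally.  The
standard computational route is dual-resolution: simulate the insertion
process with a coarse-grained (CG) model (~4 heavy atoms per bead, an
elastic network to hold the fold), map the equilibrated CG complex back
to atomistic coordinates by rigid-body least squares, and validate the
pose against deuterium-exchange mass spectrometry (DXMS), which reports
which protein fragments lose solvent accessibility on membrane binding.
`memscale` implements that workflow end to end for method developers
and structural modelers, with synthetic fixtures so everything runs at
desk scale.

## What is inside

* **structure_io** — PDB/GRO readers and writers, a shared
  atom/coordinate data model (Angstrom everywhere), trajectories
  (multi-MODEL PDB and a plain-text frame format), and a selection
  grammar (`"resid 710-724 and name CA"`).
* **cg_mapper** — 4:1 bead mapping for proteins (one backbone bead per
  residue at the N,CA,C,O center of mass, 0–2 side-chain beads),
  lipids (template-driven; a 13-bead phosphatidylcholine-like template
  and a 3-bead toy lipid are packaged) and water (4:1 with floor).
* **elastic_network** — harmonic restraints `E = ½k(r−r₀)²`,
  `k = 10 kJ mol⁻¹ Å⁻²`, between backbone beads within 7 Å.
* **cg_engine** — a minimal CG-MD engine (compiled core): 12-6 LJ and
  screened Coulomb (ε_r = 15) smoothly force-shifted to zero at 12 Å,
  leapfrog at 25 fs, stochastic velocity-rescaling thermostat (323 K),
  anisotropic Berendsen barostat (τ = 10 ps, κ = 3×10⁻⁵ bar⁻¹),
  steepest-descent minimization, periodic boundaries, bitwise-seeded
  reproducibility, plus bilayer and anchoring-event detectors.
* **backmapper** — Kabsch superposition, protein-onto-beads and
  membrane-patch alignment, 0.6 Å lipid clash pruning, lattice
  solvation with ~0.1 mol/L ionization, and a declarative
  water-exclusion region for the protein–membrane gap.
* **insertion_analysis** — membrane frame, insertion angle
  (helix axis vs membrane plane, 0–90°), insertion depth (|z-c.o.m.
  − bilayer center|), per-residue depth tables with class summaries,
  H-bond counts, RMSD/RMSF, z-density profiles, and an implicit-probe
  (methane-like) free-energy map.
* **dxms_compare** — fragment classification by exchange decrement
  (strong ≥ 70 %, weak < 40 %), per-residue burial profiles, and a
  fragment-level consistency score between model and DXMS data.
* **fixtures** — seeded generators: ideal/amphipathic helices, toy
  bilayers, random self-assembly boxes, a miniature anchor protein,
  synthetic DXMS tables.

## Worked example

Map an amphipathic anchor helix to beads, restrain it with an elastic
network, and summarize the published anchor-region depth table:

```r
library(memscale)

helix <- build_helix(anchor_sequence(), resid_start = 710)
cg <- with_elastic_network(map_protein(helix))
cg
#> <cg_model> 28 beads (15 backbone, 0 phosphate), 27 bonds, 0 angles, 36 elastic bonds

group_depth_summary(anchor_depth_reference())
#>         class mean_depth  mean_sd n_residues
#> 1 hydrophobic   16.01667 1.833333          6
#> 2       basic   18.65000 1.900000          2
#> 3       polar   19.36000 1.820000          5
```

The 15-residue anchor helix maps to 28 beads (one backbone bead per
residue plus 13 side-chain beads), held by 27 bonds and a 36-restraint
elastic network.  The class means say: the six hydrophobic anchor side
chains sit on average 16.0 Å from the bilayer center — about 3 Å deeper
than the basic (18.6 Å) and polar (19.4 Å) residues, which coincide
with the phosphate peak of the bilayer.  That ordering (hydrophobic face toward
the lipid tails, polar face among the headgroups) is the signature of
an amphipathic membrane anchor, and the package's toy simulations
reproduce it: a seeded self-assembly box forms a bilayer and a
fixture helix anchors hydrophobic-side-down
(`self_assembly_experiment()`, `anchoring_experiment()`).

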