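---
title: "Methods: contact, geometry and energetics analysis of nanodisc-binding trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, geometry and energetics analysis of nanodisc-binding trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`nanotraj` analyses trajectories of a peripheral membrane protein binding a
lipid nanodisc: a finite bilayer patch (here DOPC/DOPS) encircled by a
scaffold protein.  The motivating systems are discoidin-family C domains —
β-barrel membrane anchors carrying hydrophobic β-hairpin loops and basic
residues (the package's synthetic probe uses the blood-coagulation C-domain
residue numbering, 2021–2170 and 2171–2332, so selections like
`"resid 2021-2170 and protein"` address a domain directly).

The data model is deliberately small: a `Topology` (one row per atom: name,
element, residue, chain, segment class), a `Frame` (n × 3 coordinates in
ångström with an optional orthorhombic box), and a `Trajectory` (topology +
frame stack).  Multi-model PDB is the interchange format because it is
text-diffable; GRO (converted from nm on read/write) and plain XYZ streams
are also supported.  Coordinates are ångström everywhere internally.
Residue numbering is author numbering carried verbatim — the package never
re-indexes, so the field's residue names (R2163, F2093, …) map directly.
Atom indices are 1-based, following R convention.  Segment classes
(protein / lipid / scaffold / solvent / ion) are inferred from residue
names, with the scaffold chain configurable (default chain `"S"`); waters
and ions are recognised and excluded from analyses by default.

# Contacts and occupancy

A contact is an atom pair at distance strictly less than the cutoff
(default 4 Å); a pair at exactly the cutoff does not count.  The indicator
is a hard step function, not a smooth switching function — the step is the
definition the statistic is built on, and counting is exact.

Lipid atoms are partitioned into seven moiety classes by a packaged
(residue name, atom-name glob) table in the CHARMM36 dialect:
`chain_carbon`, `headgroup_carbon`, `ester_oxygen`, `amine_nitrogen`,
`phosphate`, `carboxylate` (DOPS only) and `other` (hydrogens).  Two table
choices were genuinely open and are made explicit (and overridable) rather
than implicit: the phosphate class is P plus its four bonded oxygens, so
the phosphate-ester oxygens O11–O14 stay with the phosphate rather than the
ester class; and the glycerol carbons C1–C3 are grouped with the headgroup
carbons.  Rows match first-to-last, so exact names shadow the chain globs
(`C2` glycerol before `C2*` = C22, C23, …).

Protein atoms are classified as hydrophilic probes (every N and O),
hydrophobic probes (every carbon of a residue in the hydrophobic set,
default ALA VAL LEU ILE MET PHE TRP PRO — the conventional apolar set, since
no canonical list is universal), or neither.  Hydrogens are excluded from
counting by default on both sides (heavy-atom indexing).

The per-(residue, moiety, lipid-type) *occupancy* is the fraction of frames
with count ≥ 1.  A count-weighted average is the other defensible reading
of "percent of the simulation"; the frame indicator was chosen because it
is the standard reading and is what a planted Bernoulli occupancy
reproduces exactly.  Replicate averaging is the arithmetic mean of
occupancies over trajectories with identical axes.

Counting uses a C++ cell list (cell edge ≥ cutoff, 27-cell scan); a brute
force all-pairs path and minimum-image counting for boxed systems are also
provided.  Property tests assert cell-list = all-pairs equality on random
systems, translation invariance, cutoff monotonicity of occupancy and
invariance under frame reordering.  Nanodiscs are finite in-plane, so
results must be (and are tested to be) insensitive to enabling PBC.

# Tilt geometry

Three scaffold alpha carbons (default residues 32, 93, 158) span the
membrane plane; the normal is the normalized cross product of the two
in-plane vectors, with a degenerate-plane error below a cross-product norm
of 1e-6.  The protein axis is the vector between two alpha carbons given
membrane-proximal endpoint first.  The tilt is `90° − arccos(n̂ · p̂)`,
signed, in [−90°, 90°]: folding to |tilt| would hide wide, sign-crossing
orientation distributions, which genuinely occur for weakly bound domains.
Because the cross product's sign depends on anchor order, the series
orients the normal once, at the first frame, toward the protein (positive
component along anchors-centroid → axis-centroid) and holds that sign.
Mean and sample standard deviation (n−1) accompany the per-frame series.

# SASA and ΔSASA

Shrake–Rupley with a deterministic golden-spiral point set (default 960
points; the analytic isolated-atom value is reproduced within 1 % and the
960 vs 3840 point difference is under 1 % on random clusters, which is why
960 is the default).  Probe radius 1.4 Å (water); vdW radii C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80, H 1.20 Å, editable.  A sphere point survives if it
is not strictly inside any other occluder's expanded sphere; atomic SASA is
the surviving fraction times the expanded-sphere area, and residue SASA is
the plain sum over its atoms (no relative-accessibility normalisation).
The quadrature is exactly invariant under translation and invariant under
rotation only up to the fixed point-set orientation (≈1–2 % at 960 points);
tests assert both at their respective tolerances.

ΔSASA per residue is mean unbound minus mean bound, so burial is positive.
The two "states" are the same protein coordinates with different occluder
sets — protein + lipids (bound) versus protein only (unbound) — which is
the reading that isolates membrane occlusion: removing lipids from the
bound occluders collapses ΔSASA to zero, and the tests assert exactly that
ablation.

# Superposition, RMSD, RMSF

Kabsch superposition via SVD of the weighted covariance, with the
determinant sign corrected so the rotation is always proper; collinear or
<3-point inputs are a degenerate-fit error.  The implementation is
cross-checked against bio3d's independent fitting routine.  RMSD series
superpose each frame on a reference (frame 1 by default; fitting can be
disabled to get raw displacement).  RMSF uses the common fit–average
convention: fit frames to frame 1, average, re-fit once to that average,
then take per-atom root-mean-square deviations from the mean structure;
residue values are unweighted means over backbone atoms N, CA, C, O.  No
mass weighting anywhere.  Note that RMSD over a binding trajectory measured
against a pre-binding reference includes rigid-body approach motion; the
reference frame and fit toggle are therefore explicit configuration rather
than hidden defaults.

# RDF and potential of mean force

`g(r)` is the histogram of reference–target distances over frames,
normalised by `N_ref · N_frames · 4πr²Δr · ρ`.  For the canonical use —
arginine guanidino nitrogens NE/NH1/NH2 against DOPS carboxylate oxygens
O13A/O13B — the "bulk density" ρ of a finite nanodisc in a box is not a
physical bulk, so two modes ship: `box_density` (ρ = N_target / V_box) and
`tail_unit` (rescale so the mean of g over the last 10 % of bins is 1).
The two differ by a constant factor, so PMF *depths* shift by a constant
while the well *location* is identical in both modes — outputs record the
mode, and depths are labelled effective/qualitative.  Defaults: bin width
0.02 Å, r_max 15 Å.

`PMF(r) = −RT ln g(r)` with R = 8.314462618×10⁻³ kJ·mol⁻¹·K⁻¹, default
T = 310 K; bins with g = 0 are undefined (NA), never −∞.  The minimum is
the most negative defined value, coinciding with the g maximum; ties break
toward smaller r.

# Interaction energy surrogate

The energy module is a documented surrogate, not a force-field energy: a
plain-truncation pair sum of Coulomb (`k q_i q_j / d`,
k = 1389.35458 kJ·mol⁻¹·Å·e⁻²) and Lennard-Jones
(Lorentz–Berthelot combining) over pairs closer than the cutoff (default
12 Å), with no PME/reciprocal-space, switching, bonded or solvent terms.
Its role is ordinal — ranking frames to select a lowest-energy pose and
resolving DOPC vs DOPS contributions — and every output records the cutoff
and truncation so values are never mistaken for absolute binding energies.
Parameters come from a TSV (residue name, atom name, charge, σ, ε);
distances under a 0.1 Å clash floor are an error naming the pair.  Ties in
the per-frame total resolve to the earliest frame.

# The synthetic generator and what it does (not) emulate

The generator is kinematic: posed rigid bodies plus scripted events, no
physics.  That is a deliberate design — exact planted ground truth is the
point, and only scripted placement makes occupancies, tilt distributions
and distance wells exactly known.

* **Nanodisc**: two leaflets on a jittered square lattice (default 64 DOPC
  + 16 DOPS per leaflet, i.e. a 20 % DOPS molar fraction; area per lipid
  70 Å², a standard fluid-phase value), DOPS positions drawn by seeded
  shuffle.  Lipids use a reduced CHARMM36-named atom set (~30 heavy atoms)
  covering every moiety class; an alpha-carbon scaffold ring (180 residues,
  chain S) supplies the plane anchors at residues 32, 93, 158.
* **Probe**: two rigid mini-domains with full backbones, hydrophobic loops
  (PHE/MET/LEU side-chain carbons) at the membrane-proximal end, arginines
  with guanidino nitrogens, lysines with NZ, numbered 2021–2332 so
  C-domain selections work.
* **Trajectory**: approach (20 % of frames), first-domain insertion
  (7.5 %), second-domain insertion (7.5 %), then a settled phase in which
  per-domain tilt is drawn i.i.d. from the planted normal (default
  68° ± 8° / 69° ± 9°), each planted residue's contact atom is placed
  2.8–3.4 Å from its designated moiety atom with the planted Bernoulli
  probability (else lifted ≥ 6 Å above the headgroups), and one arginine
  guanidino N–DOPS carboxylate O distance is drawn from the planted well
  (default 2.70 ± 0.15 Å).  Isotropic Gaussian jitter (default σ = 0.1 Å)
  is added last.  The frame stride metadata is 240 ps.  All randomness
  derives from one seed; identical inputs give byte-identical files.
* **Planted occupancies** default to the regime the analyses target:
  near-permanent (0.98–0.99) hydrophobic loop contacts with lipid chains
  and intermediate (0.45–0.62) polar contacts of basic/polar residues with
  phosphate, amine and carboxylate groups.

Lateral placements choose, once per planted pair, the azimuth that
maximises clearance from all other membrane atoms, so scripted positions
do not collide with neighbouring lipids.  The generator's default
nonbonded table puts CHARMM-flavoured partial charges on polar groups and
zero LJ ε on apolar atoms: the poses are not sterically relaxed, so the
binding signal is carried by electrostatics of the planted salt
bridges/polar contacts, and repulsive artifacts from posed overlaps are
excluded by construction.  These are generator parameters for exercising
the energy module, not force-field values.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: conformational dynamics and correlated
motion, membrane undulations and lipid diffusion, water/ions, realistic
rotamers (planted side chains stretch to their targets), force-field
energetics, and sampling autocorrelation (settled frames are i.i.d., so
real-data uncertainties will be larger at equal frame counts).

# Numerical choices and degenerate inputs

Strict `<` at every cutoff; ties at the boundary count as "no".  Collinear
plane anchors, zero-length axes, rank-deficient fits, single-frame RMSF,
all-zero g(r), unparameterised atoms, unknown lipid residues, overlapping
groups, and truncated records all raise typed errors naming the offender.
Empty target groups yield zero counts, not errors.  PDB coordinates
overflow fixed columns beyond ±9999.999 Å and are refused.  GRO files have
no chain column, so chains are re-opened wherever residue numbering
restarts, preserving the per-chain monotonicity invariant.

Problem sizes in the shipped validation: contact/energy checks run on
random 30–500-atom systems against all-pairs R oracles; tilt recovery uses
a 2005-frame trajectory (≈2000 settled frames); the end-to-end recovery
runs the full preset, two replicates of 1000 frames, with SASA evaluated on
a 20-frame stride of the settled phase (SASA is the costly stage and its
per-residue means stabilise well before that).

# Pipeline and outputs

`run_config()` validates everything up front (cutoffs positive, ≥ 32
sphere points, three anchors, named domains/axis pairs) and is echoed into
a manifest, so every default the analysis depends on is recorded alongside
the results.  `run_pipeline()` runs contacts (both channels plus their
union — whether a published per-residue map merges channels per cell is
usually unstated, so all three are reported), tilt, ΔSASA, RMSD/RMSF,
RDF/PMF and energies per replicate, averages occupancies across
replicates, writes tidy CSVs plus the lowest-energy frame, and
`render_report()` prints the summary.  The R function API is the package's
command surface; `scripts/acceptance.R` is the reproducibility entry point.

# Known limitations

Energies are short-range surrogates (above).  PMF depths are
normalisation-dependent for finite systems; only well locations are
comparable across modes.  Binary trajectory formats (XTC/DCD) are not
read — convert to multi-model PDB first.  The moiety table covers DOPC and
DOPS; other lipids require table rows.  SASA rotation invariance is
quadrature-limited (≈1–2 % at 960 points).  Occupancy confidence intervals
assume independent frames, which holds for the generator but not for real
MD, where block averaging over replicates (provided via
`average_replicates()`) is the honest uncertainty route.
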