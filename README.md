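# nanotraj

Analysis of molecular-dynamics trajectories of peripheral membrane proteins
binding lipid nanodiscs, written for systems like the tandem C domains of
blood-coagulation cofactors engaging an 80:20 DOPC:DOPS bilayer patch.

Given a trajectory (multi-model PDB, GRO or XYZ) of a protein plus a
nanodisc — a disc-shaped bilayer encircled by a scaffold protein — the
package computes the standard battery used to characterise peripheral
membrane binding:

* **Moiety-resolved contact occupancy maps.** Lipid atoms are classified
  into chemically defined moiety classes (acyl-chain carbons, headgroup
  carbons, ester oxygens, amine nitrogen, phosphate, and the DOPS serine
  carboxylate) via a packaged CHARMM36 atom-name table.  A contact between
  two atoms is a distance strictly below 4 Å.  The *occupancy* of a
  (residue, moiety, lipid type) cell is the fraction of frames with at
  least one contacting atom pair,

  `occ(i, m) = (1/T) * sum_t 1[ n_contacts(i, m, t) >= 1 ]`,

  computed per channel: hydrophilic (residue N/O atoms against polar lipid
  classes) and hydrophobic (carbons of hydrophobic residues against lipid
  carbons).  Counting is cell-list accelerated and verified against an
  all-pairs oracle.
* **Membrane tilt angles.** The membrane plane is anchored on the alpha
  carbons of three scaffold residues; with unit normal `n` and unit protein
  axis vector `p` (membrane-proximal endpoint first), the signed tilt is
  `90° − arccos(n · p)`, so an axis lying in the membrane plane scores 0°
  and one parallel to the normal scores 90°.
* **Shrake–Rupley SASA and ΔSASA.** Per-atom solvent-accessible surface
  area from a deterministic golden-spiral quadrature (default 960 points,
  1.4 Å probe), summed per residue; membrane burial is
  `ΔSASA_i = <SASA_i>_unbound − <SASA_i>_bound`, with lipids included among
  the occluders only in the bound state, so positive values mean burial.
* **Kabsch superposition, backbone RMSD and per-residue RMSF** (backbone =
  N, CA, C, O; RMSF about the fit-averaged mean structure).
* **RDF → potential of mean force.** The radial distribution function
  between, e.g., arginine guanidino nitrogens and DOPS carboxylate oxygens,
  and `PMF(r) = −RT ln g(r)` at 310 K; the reported well
  (depth, location) summarises the salt-bridge interaction.  Depths depend
  on the normalization convention for a finite nanodisc and are labelled
  effective/qualitative.
* **Interaction energies.** A documented cutoff-truncated Coulomb +
  Lennard-Jones pair sum between the protein and each lipid species
  (Lorentz–Berthelot combining, 12 Å cutoff, no long-range terms) used to
  rank frames and export the lowest-energy pose; it is a surrogate, not a
  force-field energy.

Because production nanodisc trajectories are large and rarely deposited,
the package ships a deterministic **synthetic generator**: a reduced-atom
DOPC/DOPS nanodisc (default 64 DOPC + 16 DOPS per leaflet), a two-domain
probe protein with C-domain-style residue numbering (2021–2332, hydrophobic
β-hairpin loops, membrane-facing arginines), and a scripted binding
trajectory with *planted ground truth*: per-residue contact occupancies,
per-domain tilt distributions, an arginine–carboxylate distance well and a
buried-residue set.  Every analysis stage is validated by recovering what
was planted.

## Worked example

```r
library(nanotraj)

preset  <- synthetic_preset(seed = 42, n_frames = 400, n_replicates = 1)
traj    <- preset$replicates[[1]]$trajectory
truth   <- preset$replicates[[1]]$truth
top     <- traj$topology
settled <- truth$settled_start:n_frames(traj)

# tilt of the first domain relative to the scaffold-anchored membrane plane
anchors <- atom_index(top, c(32, 93, 158), "CA", chain = "S")
axis_c1 <- atom_index(top, c(2093, 2145), "CA")
tilt_series(traj, anchors, axis_c1, frames = settled)
#> TiltSeries: 260 frames, tilt 68.3 +/- 8.4 degrees

# hydrophilic contact occupancies for three basic residues
ma <- assign_moieties(top)
cm <- contact_timeseries(traj, c(2090, 2092, 2163), ma, cutoff = 4,
                         mode = "hydrophilic", frames = settled)
df <- as.data.frame(cm)
df[df$occupancy > 0.2, ]
#>  residue_id residue_name       moiety lipid     channel occupancy
#>        2090          ARG ester_oxygen  DOPC hydrophilic 0.5461538
#>        2090          ARG    phosphate  DOPC hydrophilic 0.5615385
#>        2092          LYS    phosphate  DOPS hydrophilic 0.5961538
#>        2163          ARG  carboxylate  DOPS hydrophilic 0.4884615

# arginine guanidino N vs DOPS carboxylate O: RDF -> PMF well
ref <- select(top, "resid 2320 and name NE NH1 NH2")
tgt <- select(top, "resname DOPS and name O13A O13B")
pmf_from_rdf(rdf(traj, ref, tgt, bin_width = 0.1, frames = settled),
             temperature = 310)
#> PMFProfile (T = 310 K, box_density): minimum -13.24 kJ/mol at 2.65 A
```

The tilt (68.3° ± 8.4°) matches the generator's planted 68° ± 8°; the
occupancies sit within binomial noise of the planted 0.60/0.55/0.50 (the
arginine also grazes the ester oxygens of the same lipid, a real feature of
the pose, not an artefact); and the PMF well at 2.65 Å recovers the planted
2.70 Å arginine–carboxylate distance within one 0.1 Å bin.

`run_pipeline(run_config(...))` orchestrates all of the above over replicate
trajectories (with occupancy averaging across replicates) and writes tidy
CSV/JSON outputs plus the lowest-energy frame as PDB; `render_report()`
prints a one-page summary.

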