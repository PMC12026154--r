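---
title: "Methods: hydropathic scoring and flexibility analysis in hintmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydropathic scoring and flexibility analysis in hintmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hintmd)
```

# Scope and model

hintmd quantifies two consequences of a single-point mutation in a
globular protein, developed around the lipocalin allergen Mus m 1 (mouse
major urinary protein): the shift in the intramolecular *hydropathic*
interaction balance of a static structure, and the change in
*conformational flexibility* observed along a molecular-dynamics
trajectory.  The package deliberately stops at the boundary of the MD
engine: simulations (thermostats, barostats, PME, constraint solvers) are
produced elsewhere; hintmd consumes a structure in PDB format and a
trajectory as a multi-model PDB and computes everything downstream.

# The hydropathic score

## Formula and interpretation

Every admissible atom pair contributes

$$ b_{ij} = S_i\,a_i\,S_j\,a_j\,R_{ij}\,T_{ij}, \qquad
   R_{ij} = e^{-r_{ij}/\delta}, \qquad B = \sum_{i<j} b_{ij}. $$

* $S_i$ — solvent-accessible surface area of atom $i$ (Å²), computed on
  the whole protein, so buried atoms contribute almost nothing.  This is
  the solvent-modulated design of logP-based (HINT-family) scoring: an
  interaction only "counts" to the extent both partners still see
  solvent.
* $a_i$ — hydrophobic atom constant.  The sign carries polarity:
  aliphatic/aromatic carbons and thioether sulfur are positive, polar
  nitrogens and oxygens negative.  The product $a_i a_j$ therefore makes
  hydrophobic–hydrophobic and polar–polar contacts favorable and mixed
  contacts (desolvation) unfavorable.
* $T_{ij} \in \{+1, -1\}$ — a logic sign, $-1$ only for acid–acid and
  base–base pairs.  A bare product of two negative acid constants would
  call Coulombic repulsion favorable; the logic sign restores the
  physics.  This term is part of the HINT scoring tradition even where
  the compact published formula omits it, and we follow the substance:
  like-charge contacts enter the total as repulsive.
* $R_{ij}$ — exponential distance decay with $\delta = 1$ Å and a 9 Å
  cutoff (the conventional non-bonded cutoff, reused for consistency).

Pairs within covalent bond-graph distance ≤ 3 are excluded ("noncovalently
bonded pairs" plus standard 1-2/1-3/1-4 force-field practice).  The bond
graph is built from residue topology templates, peptide bonds between
consecutive residues, and disulfides auto-detected at SG–SG ≤ 2.5 Å, so no
CONECT records are needed.

Each pair is classified as hydrogen-bond, electrostatic-favorable,
hydrophobic, electrostatic-unfavorable, or desolvation.  Hydrogen bonds
require a donor/acceptor role pairing *and* geometry: a polar hydrogen on
the donor within 2.5 Å of the acceptor with a donor–H–acceptor angle
≥ 120°.  This angle test is a deliberate simplification of full
lone-pair/π directionality vectors; both parameters are fields of
`hint_params()`.  Components sum to the total exactly, and per-residue
totals attribute each pair half to each partner residue.

## Atom constants

The atom-constant table is our own open parameterisation, with values in
the spirit of published atomic logP fragment contributions and polarity
classes assigned by residue chemistry at neutral pH: Asp/Glu side-chain
oxygens (and C-terminal OXT) acid, Lys/Arg nitrogens base, histidine
neutral with amphoteric ring nitrogens.  The engine is therefore
"HINT-style": architecture and formula from the published scoring
framework, constants from open sources.  Absolute score magnitudes are
meaningful only within this parameter set; all comparisons the package
makes (wild type vs mutant, partner rankings) are internal to it.  The
table ships both in code (`default_hint_table()`) and as a TSV
(`inst/extdata/hint_params_default.tsv`) for external tools; a test pins
their equality.

## Semi-essential hydrogens

Only hydrogens that matter to hydropathic scoring are built: polar
hydrogens on N/O/S, hydrogens on unsaturated (sp²) carbons, and hydrogens
on carbons alpha to a heteroatom — including the backbone amide H and
alpha H.  Placement is deterministic ideal geometry (N–H 1.01, O–H 0.96,
S–H 1.34, C–H 1.09 Å; sp²/sp³ angles; staggered or anti dihedrals with
the reference neighbour chosen by lowest atom index).  Input hydrogens are
discarded first: crystal structures rarely carry them consistently, and
rebuilding guarantees the same hydrogen set for wild type and mutants.
Histidine is placed as the NE2-H tautomer.  N-terminal amines get three
hydrogens.  Water-mediated interactions are invisible to this model — a
known limitation: bridged hydrogen bonds (e.g. a tyrosine hydroxyl to a
threonine via a crystallographic water) cannot be reproduced by a
waterless scorer.

## Solvent accessibility

Shrake–Rupley with a deterministic golden-spiral lattice (default 256
points, probe 1.4 Å; van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å).  The lattice is oriented in a *canonical molecular frame* —
principal axes of the coordinates with rotation-covariant sign fixing
(third moments of the projections; the third axis from the cross product)
— so a rigidly moved molecule carries its lattice with it and all areas,
hence all scores, are invariant under rigid motion to numerical
precision.  The sign fix degenerates only for molecules with exactly
symmetric principal projections, which real proteins and our fixtures are
not; for fewer than three atoms the frame falls back to the identity
(the isolated-atom area does not depend on lattice orientation).

# Mutagenesis

Mutations are applied by side-chain truncation: allowed whenever the
target side chain is an atom subset of the source (after the C→S
SG→OG swap, with the new CB–OG bond rescaled to 1.41 Å — a standard C–O
single bond replacing the longer C–S).  Kept atoms never move; deleted
atoms are the set difference; stale hydrogens on the mutated residue are
dropped and rebuilt at scoring time.  This covers Y120F, Y120A, C138A,
C138S and any X→A/X→G, and makes mutant structures exactly reproducible —
no rotamer search, no minimisation.  Substitutions that would require
placing new heavy atoms (e.g. A→Y) are refused with a pointer to external
rotamer tools.  Scoring operates on the unminimised mutant: a
minimisation step would re-introduce an engine dependency and a source of
irreproducibility, at the cost that strained local geometry after
truncation is scored as-is.

# Trajectory observables

* **Superposition** — Kabsch (SVD) least-squares rigid fit with proper
  rotation enforced; collinear or coincident point sets are rejected.
* **RMSD** — per frame after fitting to a reference frame (default the
  first), Cα selection by default.
* **RMSF** — per-residue fluctuation about the time-average position.
  Frames are first fitted to the first frame, averaged, then fitted once
  to that average (one iteration; further iterations change the average
  by less than the fluctuation noise).  The fit reference is
  configurable (`fit = FALSE` skips superposition entirely, which is the
  correct setting for generators that add no rigid-body motion).  The
  variance uses the 1/n denominator — RMSF is a population moment of the
  sampled frames, not an estimator requiring Bessel correction; the
  cross-check against an independent implementation accounts for its
  n−1 convention.
* **Radius of gyration** — mass-weighted by default (standard atomic
  masses), unit weights optional.
* **SASA series** — per-frame Shrake–Rupley of a selection in the
  whole-protein context; identical to `compute_sasa()` frame by frame.
* **Helix–barrel distance** — an aggregated Cα pair distance.  The pair
  list is configuration, not inference: the barrel-interface residue
  ranges are known for the study system (His20–Ser26, Phe100–Lys109,
  Glu112–Gly121 for Mus m 1), but the helix pairing is not printed
  anywhere, so `default_interface_pairs()` pairs each barrel residue with
  its nearest helix Cα in the reference frame and this choice is flagged
  as a replication caveat.  `D_max`, `D_ave` ± SD summarise the series.
* **Essential-dynamics PCA** — eigendecomposition of the 3N×3N covariance
  of the fitted Cα coordinates; eigenvalues are clamped at zero and
  sorted, projections are exactly centred, and an `nm` toggle rescales
  projections for comparison with tools that report nanometres.

Trajectory-averaged scoring (`hint_trajectory()`) reports the mean ± SD of
the total and each component across frames — dispersion across frames,
not across replica simulations, which is the cheaper of the two
conventions and the one we implement.

# Flexibility comparison

`delta_rmsf()` subtracts wild-type from mutant RMSF per residue and flags
|Δ| ≥ 0.7 Å (inclusive on both sides, matching the "≥" wording of the
criterion it implements; the boundary value 0.70 flags, 0.69 does not).
Residues with wild-type RMSF ≥ 2.5 Å are marked highly flexible.  The
mutated position is matched by residue number although its name differs;
the mutant name is carried in its own column.  `annotate_epitopes()`
attaches the Discotope-predicted conformational epitope sets of
Mus m 1.0102 (13 residues in three epitopes) and summarises flagged
residues per epitope; annotation entries pointing at absent residues
warn rather than fail, so truncated constructs remain usable.

# The synthetic generator

The generators provide *known ground truth*, not physical realism:

* `make_toy_protein()` builds a lipocalin-like topology at toy scale —
  antiparallel strand Cα traces on a cylinder (3.4 Å spacing, side chains
  into the cavity) and an ideal helix trace (rise 1.5 Å, 100°/residue,
  Cα radius 2.3 Å) alongside.  Backbone N/C sit on the Cα–Cα segments
  with a small perpendicular kink, O and CB by ideal local geometry; the
  body is poly-Leu with poly-Ala caps so hydropathy assignment succeeds.
  One barrel strand is rotated so that a designated helix Cα and a strand
  Cα differ *exactly* by `helix_offset` along the barrel-normal; that
  matched pair is stored on the model.  Builds are fully deterministic
  and refuse geometries with any interatomic distance below 1.0 Å.
* `make_harmonic_trajectory()` displaces each residue rigidly by iid
  Gaussian noise (per-coordinate sd σ, the same draw for all atoms of a
  residue), so the per-residue RMSF ground truth is exactly σ√3.
  Residue-level rather than atom-level displacement keeps that ground
  truth exact for any atom selection.
* `make_breathing_trajectory()` displaces the helix rigidly along the
  barrel-normal by $A\sin(2\pi t/\text{period})$ plus optional Gaussian
  jitter, so the matched pair distance is exactly
  $d_0 + A\sin(2\pi t/\text{period}) + \text{jitter}$: D_ave recovers
  $d_0$ and D_max recovers $d_0 + A$ up to sine sampling and jitter.

Defaults are the study conditions: resting distance $d_0 = 4.25$ Å and
amplitude $A = 1.65$ Å, i.e. the contrast between a mutant whose helix
sits at ~4.25 Å from the barrel with strongly reduced oscillation and a
wild type whose helix swings out to ~5.9 Å.  The default fold (8 strands
× 9 residues + a 13-residue helix, ~85 residues) keeps full-pipeline runs
fast; odd segment lengths centre a residue on the barrel equator where
the matched pair sits.  What the generators do *not* emulate: real
backbone dihedral statistics, side-chain rotamers, anharmonic and
correlated motions, solvent effects.  Passing recovery tests therefore
demonstrates correctness of the estimators, not fidelity of any MD
simulation.

# Numerical choices and problem sizes

* Scoring tolerances: the engine is validated against an independently
  coded brute-force all-pairs sum to 1e-10 relative on systems of ≤ 50
  atoms; component sums close exactly by construction.
* Harmonic recovery uses 2000 frames, where the sampling error of RMSF is
  about 1%, comfortably inside the 5% acceptance band; breathing recovery
  uses 1000 frames over 10 full periods, where the integer-period sine
  grid makes the mean exact and the peak exact whenever the period is
  divisible by 4.  The acceptance script runs the breathing recovery with
  jitter disabled (its clean-recovery mode); unit tests also exercise the
  jittered generator against a 3-SEM band.
* PCA single-mode tests construct the collective vector orthogonal to the
  six rigid-body modes, so frame fitting cannot leak variance into other
  components.
* Degenerate inputs fail loudly: empty structures, mismatched multi-model
  atom sets (the offending model is named), insertion codes, missing
  backbone atoms, single-frame RMSF, empty selections, collinear
  superposition targets.
* Ties: hydrogen placement reference atoms and nearest-neighbour pairings
  resolve by lowest atom index; sorting of interaction partners is by
  descending |total|.

# Limitations

* Score magnitudes are parameter-set relative; no claim is made of
  numerical agreement with proprietary HINT outputs.
* No explicit water or ions: water-bridged hydrogen bonds are invisible.
* No pKa calculation: ionisation states are fixed neutral-pH defaults.
* Mutants are scored unminimised; strained post-truncation geometry is
  scored as-is.
* The multi-model PDB trajectory format is text and therefore bulky;
  binary trajectory adapters are intentionally out of the core.
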