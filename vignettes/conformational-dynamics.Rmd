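---
title: "Methods: conformational dynamics of an ABC transporter at Ca resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational dynamics of an ABC transporter at Ca resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cadyn` analyses the conformational dynamics of large membrane transporters
— it is built around mouse P-glycoprotein (Pgp), the polyspecific ABC
drug-efflux pump — from alpha-carbon coordinates: crystal structures, MD
trajectory exports, or its own synthetic trajectories with known ground
truth. This vignette records the models and the design decisions behind
each stage: the conventions chosen where the field has several, the
numerical tolerances, and what the synthetic generators do and do not
emulate.

## The data model

A **structure** is a tibble of atom records in file order (PDB author
numbering, never renumbered); a **trajectory** couples a fixed atom roster
with an `F x N x 3` coordinate array and a frame interval in picoseconds.
The default cadence is 10 ps/frame, so a 10 000-frame trajectory spans
100 ns and the default equilibrium window — the final 20% of frames — is
the 2000-frame last-20 ns ensemble used for all equilibrium averages.

PDB parsing covers the ATOM/HETATM/MODEL/ENDMDL subset. Alternate
locations keep the highest-occupancy conformer (ties to the first listed);
insertion codes are rejected explicitly rather than silently mangled —
they are absent from the structures this package targets. Multi-model
files with identical rosters become trajectories; mismatched rosters are a
hard error. The tab-separated frame table is the bulk format; it writes
doubles at full precision so the round trip is exact.

**Domain maps** name residue ranges: the two pseudo-symmetric halves
default to residues 40–626 (half1) and 691–1271 (half2). The bundled
`pgp_domain_map()` also carries TM1–TM12, NBD1/NBD2 and portal ranges;
these helix boundaries are package conventions (approximate limits chosen
so the standard landmark residues fall in their textbook helices), not
published values, and are meant to be overridden from a config file when
exact boundaries matter.

## Superposition, RMSD, RMSF, B-factors

Superposition is the Kabsch algorithm: SVD of the weighted cross
covariance with the determinant correction, so the rotation is always
proper. All headline statistics are computed on Ca atoms only — B-factor
profiles, correlation matrices and landmark angles are Ca-level
quantities, and heavy-atom detail enters only in contact detection.

RMSF uses a two-pass reference: frames are aligned to the first window
frame, averaged, re-aligned to that mean, and fluctuations are measured
about the re-averaged mean. The convention matters at the fraction-of-a-
percent level: superposition absorbs six rigid-body degrees of freedom,
deflating the measured fluctuation of an `N`-atom selection by roughly
`6/(3N)` in mean-square terms. B-factors use the crystallographic
conversion `B = 8 pi^2 RMSF^2` exactly.

The centre of mass of a domain is the unweighted Ca centroid. Residue
masses vary by less than a factor of two and domain centroids of hundreds
of residues shift by well under an Angstrom between the two conventions;
the `weights` argument provides mass weighting when wanted.

## Landmarks and group statistics

The named monitors are the standard set for this transporter: seven Ca
pair distances (three extracellular gates, two cavity pairs, and the two
ATP-site pairs joining Walker A to LSGGQ residues) and four Ca triplet
angles (the two NBD alignment angles, which approach 180 degrees in a
canonical ATP-sandwich dimer, and the front/back bilayer-portal opening
angles). Angles are interior angles at the middle residue, reported in
degrees; landmark resolution requires an unambiguous residue on the
roster, with an explicit chain override for two-molecule files.

Group comparisons use Welch's unequal-variance two-tailed t-test
(`var_equal = TRUE` switches to Student's pooled test), flagged at
p < 0.05. The observations are **per-run equilibrium means** — one number
per simulation, e.g. six apo runs against six drug-occupied runs — never
per-frame values: frames within a run are strongly autocorrelated, and
treating them as independent samples would inflate significance by orders
of magnitude. This is the package's reading of published per-group
p-values and it is fixed by design.

## Contacts

A protein residue is in contact with a partner group (drug, lipid) when
its minimum heavy-atom distance to any partner atom is at or below the
cutoff. The default cutoff is 3.0 Angstrom — the strict convention for
drug–domain interaction counting — and hydrogens are excluded; both are
arguments because distance conventions differ between studies. Detection
is a vectorised all-pairs scan; the test suite holds it equal to an
explicit brute-force double loop on every tested instance, so any future
spatial-indexing optimisation inherits a mandatory equivalence oracle.
Per-TM aggregation counts distinct contact residues per helix over a
window, pooling residues outside every TM under "other"; lipid analyses
are the same machinery with lipids as the partner group. The aromatic
census (PHE/TYR/TRP/HIS per region) covers portal and binding-cavity
composition; layer classifications are config-supplied residue groupings,
not a geometric classifier.

## Dynamical cross-correlation matrices

With displacements `dr_i` taken from the window-mean structure after the
same two-pass superposition as RMSF,
`C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`. The raw estimator is
reported — no smoothing or shrinkage. Atoms with zero fluctuation cannot
be normalised; their off-diagonal entries are zeroed with a warning.

One estimator property deserves emphasis: because each frame's best-fit
rigid motion is removed, any collective mode lying in the rigid-body
space is invisible. A whole-selection translation is the extreme case —
after superposition nothing remains of it. The
`compute_dccm(superpose = FALSE)` escape hatch exists for pre-aligned
input and for probing exactly such modes. The synthetic block generator
is designed around this: its flagship anti-phase design (below) plants a
coherent mode orthogonal to the rigid-body space, so the planted
correlations survive superposition.

## Anisotropic network model

`build_anm()` joins every Ca pair within the cutoff (default 15 Angstrom,
the conventional ANM choice) by a spring of uniform constant gamma
(default 1, arbitrary units). The off-diagonal 3x3 super-element for a
pair is `-gamma/|d|^2 d d^T`; diagonal super-elements enforce zero
super-row sums. The equivalent unit-direction form `gamma d^hat d^hat^T`
differs only in the units of gamma. Eigendecomposition is dense
(`eigen(symmetric = TRUE)`), run lazily and cached; a model of `N` nodes
has `3N` modes, and a connected, mechanically rigid network has exactly
six zero modes, detected with a relative threshold of `1e-8` times the
largest eigenvalue. Note that graph connectivity alone does not guarantee
six: a pendant node hanging on a single spring is free to swing, and such
under-constrained networks legitimately carry extra zero modes.

Analytic mean-square fluctuations are the traces of the diagonal 3x3
blocks of the Hessian pseudo-inverse (zero modes excluded), computed from
the eigenpairs rather than by forming the pseudo-inverse; the dense
pseudo-inverse is the oracle in tests. `analytic_dccm()` normalises the
pseudo-inverse blocks into the closed-form counterpart of the trajectory
DCCM, and `gen_anm_traj()` samples the model's Gaussian ensemble — the
bridge that lets the trajectory estimators be validated against the
model's analytic predictions. Mode animations displace sinusoidally along
one non-zero eigenvector and come back as ordinary trajectories.

A Pgp-sized model (1186 Ca nodes) has 3558 modes; the dense
decomposition is kept to `N <= ~600` in routine testing, and the
transporter-sized model is exercised for its Hessian structure and mode
count.

## The synthetic generators

The generators exist so that every analysis stage has at least one input
with exactly known ground truth. They are stand-ins for MD output at the
study cadence (10 ps/frame, 100 ns runs), not physical simulations: no
force field, no lipids, no solvent, no secondary-structure mechanics.
Passing their recovery tests demonstrates the estimators are correct, not
that real trajectories are this clean — real data add autocorrelation,
anharmonicity and slow drift that these models deliberately omit.

* `gen_helix_bundle()` builds ideal Ca helices (rise 1.5 Angstrom/residue,
  radius 2.3 Angstrom, 100 degrees/residue, hence consecutive Ca–Ca
  distances of ~3.83 Angstrom) on a ring, with a TM-per-helix domain map.
  The standard test article is a 4-helix, 80-residue bundle split into
  two 40-residue halves standing in for NBD1/NBD2.
* `gen_fluctuation_traj()` adds i.i.d. isotropic Gaussian jitter with
  per-residue sigma, so true RMSF is `sigma * sqrt(3)` (0.866 Angstrom at
  the default sigma = 0.5).
* `gen_correlated_traj()` plants a one-axis factor model: block factors
  displace whole blocks along the axis joining the block centroids, plus
  isotropic noise, calibrated so pairwise displacement correlations are
  exactly `rho_within` / `rho_between`. With
  `rho_between = -rho_within` and two equal blocks the coherent mode is a
  pure stretch — zero net translation, zero torque — so it is orthogonal
  to the rigid-body space and survives superposition; that anti-phase
  design (default -0.6) emulates the opposed NBD motions seen in
  domain-correlation analyses.
* `gen_closure_traj()` moves a rigid sub-structure so a monitored
  landmark follows a prescribed schedule exactly: angle schedules rotate
  about a hinge with the per-frame rotation solved by a bracketing scan
  plus root refinement (tolerance 1e-12 radians, following the branch
  continuous with the previous frame); centroid-distance schedules
  translate along the separation axis in closed form. Unreachable
  schedule values are a hard error, and optional Gaussian jitter sits on
  top of the exact rigid motion.
* `plant_ligand()` rejection-samples ligand atoms whose minimum distance
  to a target residue lies in a band (default 2.5–2.95 Angstrom) while
  staying farther than the band's top from every other residue, so a
  3.0 Angstrom contact cutoff recovers the planted set exactly and a
  cutoff below the band finds nothing. Infeasible geometry fails loudly
  after a bounded number of attempts.

Every generator is deterministic given its parameters and seed.

## Problem sizes and tolerances

Routine checks run on the 80-residue two-domain bundle; fluctuation
recovery uses 10 000 frames on a 300-residue bundle (measured RMSF within
2% of truth for at least 95% of residues); correlation recovery uses 5000
frames (planted -0.6 within 0.05); ANM analytic checks run at up to 200
nodes against the dense pseudo-inverse (1e-6 relative) with the
1186-residue model exercised for structure; contact detection is held
exactly equal to brute force on hundreds of random complexes; schedule
recovery is checked to 1e-6 (degrees / Angstrom). Power and size of the
group test are estimated over 1000 replicates of a six-vs-six run design
with a 25.4-degree planted difference and 8-degree run-to-run spread —
the estimate's binomial noise at 1000 replicates is small compared to the
margins checked (power at least 0.90, size at most 0.07 at nominal 0.05).

## Known limitations

* Ca-only analyses cannot see side-chain rearrangements; contacts are the
  only heavy-atom stage, and on Ca-only synthetic structures a "heavy
  atom" is the Ca itself.
* The deposited crystal structures of mouse Pgp (4M1M, 4M2S, 4M2T) are
  inputs, not bundled data: `crystal_geometry_report()` runs the
  molecule-split / shared-residue RMSD / portal-angle pipeline on any
  local copies, and the corresponding acceptance check requires those
  files under `inst/extdata/pdb/`.
* Sequence alignment for equivalencing non-identical chains is out of
  scope: the two molecules of one asymmetric unit share numbering, which
  is what the shared-residue matching relies on.
* The DCCM estimator is blind to rigid-body-like collective modes by
  construction (see above); this is a property of the method, not a bug,
  and the unsuperposed estimator is available when frames are already
  aligned externally.
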