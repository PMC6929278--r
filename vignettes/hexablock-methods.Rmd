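---
title: "Local sequence and spatial features for interface identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local sequence and spatial features for interface identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexablock)
```

## The problem

Two proteins that form a complex meet across an interface: the set of
residue pairs, one per subunit, whose atoms approach within 6 Å. Rigid-body
docking programs enumerate thousands of candidate relative placements
("poses" or "decoys") of the two subunits; the hard part is scoring — picking
the few near-native poses out of the pile. hexablock implements a scoring
pipeline built on two local, per-residue representations of evolutionary
profile information, one sequential and one spatial, pooled per pose and fed
to a support vector regression (SVR) trained against interface RMSD.

## Per-residue profiles

Residues are encoded two ways, always over the fixed alphabet
`A C D E F G H I K L M N P Q R S T V W Y`:

* **Physicochemical vectors.** Six properties per residue type
  (hydrophobicity, side-chain volume, polarity, polarizability,
  solvent-accessible surface area, side-chain net charge index), z-scored
  property-wise over the 20 types. We use the *population* standard
  deviation (denominator 20): the 20 amino-acid types are the entire
  population, not a sample from one. A `sample_sd` flag switches
  conventions; the two differ by a constant factor of
  `sqrt(19/20) ≈ 0.975` and change nothing downstream that a scale-aware
  model would notice.
* **Profile scores.** A per-position frequency profile ω (L×20, rows on the
  simplex) is projected through a 20×20 substitution matrix D:
  `PSSM[i,j] = Σ_k ω[i,k]·D[k,j]`. D defaults to the classic PAM250
  log-odds ("Dayhoff") matrix, taken from Biostrings and reordered; any
  20×20 matrix can be substituted. The product is then min–max normalized
  to [0,1] with the *global* matrix minimum and maximum — not per column —
  so one score scale is shared by all positions and residue types.
  PSI-BLAST ASCII profiles can be parsed directly; by default the log-odds
  block is used as the score matrix, and a flag instead takes the
  percent-frequency block (renormalized) as ω. Both routes are supported
  because raw PSI-BLAST output provides both blocks and either is a
  defensible input to the normalization.

Non-standard residue codes are remapped (B→N, Z→Q, U→C, O→K; X and anything
unknown gets the neutral column-mean vector); a strict mode rejects them.

## The sequential extractor (MLAB)

For a target residue R, the window holds the profile rows of R and its ten
sequential neighbors R⁻⁵…R⁺⁵ (11 slots; windows clip at chain termini — no
padding). Six overlapping blocks summarize the window at three scales:

| block | slots (R⁻⁵=1 … R⁺⁵=11) | role |
|-------|------------------------|------|
| A     | 1–11                   | global zone |
| B     | 1–6                    | bisection, up to and including R |
| C     | 6–11                   | bisection, R onward |
| D     | 1–4                    | trichotomy |
| E     | 5–8                    | trichotomy |
| F     | 9–11                   | trichotomy |

The feature is the per-block, per-column mean over the *present* rows
(`B_k` counts them), flattened block-major to 6×20 = 120 components. An
empty block (possible only at termini) contributes zeros plus an explicit
emptiness flag, keeping the vector length fixed — a requirement of the SVR
stage. The bisection overlaps at the target slot so both halves see R; the
trichotomy splits 4/4/3. These memberships are a design choice — the
three-scale structure (global/halves/thirds) is fixed, the exact slot
assignment is configurable and fingerprinted into any trained model, so a
model can never silently be applied to features from a different scheme.

## The spatial extractor (hexagon blocks)

Each residue gets a local right-handed frame: Cα at the origin, Cβ along
+y, backbone N in the x–y plane with positive x. Glycine (and any residue
without Cβ) gets a virtual Cβ from N, Cα, C by the tetrahedral rule
(bond 1.53 Å, both angles 110.5°, on the side given by the right-handed
normal — the L-amino-acid side). Space around the y-axis is split into six
60° azimuthal sectors, measured in the x–z plane from +x toward +z, each
sector the half-open wedge `[60(s−1)°, 60s°)` so boundary directions
resolve deterministically to the lower sector.

Per sector we take the nearest *non-local* Cα strictly within a cutoff
(default 10 Å — wide enough to enclose the first structural shell beyond
covalent neighbors, and configurable). Non-local means: on another chain,
or at least three residues away in sequence. The separation phrase admits
two readings (|Δ| ≥ 3 or |Δ| ≥ 4); we default to |Δ| ≥ 4 — "separated *by*
three residues" reads most naturally as three residues strictly between —
and expose `min_sep` for the other reading. Whether partner-chain residues
are eligible is likewise open; they are eligible by default
(`cross_chain`), which is what lets the spatial features react to the pose
geometry at the interface. Sequence positions use the 1-based rank within
the chain, so author numbering gaps and insertion codes cannot distort
locality.

The hexagon window holds the target row plus up to six neighbor rows
(slots: target = 1, sectors = 2–7), summarized by the same six-block mean
construction (A = all; B = target + sectors 1–3, C = target + sectors 4–6;
D/E/F = sector pairs), again 120 components with zero-filled flagged empty
blocks. Residues whose frame cannot be built (chain breaks, missing
backbone) yield a target-row-only window and are flagged rather than
dropped.

## CAPRI-style evaluation

Contacts use the strict rule: minimum inter-atomic distance < 6 Å. For a
pose against the native complex:

* `F_nat` — native contacts recovered / native contacts.
* `F_non-nat` — non-native predicted contacts / predicted contacts;
  undefined (NA) for a contact-free pose, and excluded from averages
  rather than forced to 0 or 1.
* `I_rmsd` — interface residues are fixed on the *native* complex at 6 Å
  (the same cutoff used everywhere here, rather than the 10 Å sometimes
  used elsewhere; configurable), their backbone atoms (N, Cα, C, O; atoms
  missing from either structure dropped pairwise) collected in matched
  order, and the pose interface optimally superposed on the native one by
  the Kabsch SVD construction with reflection excluded. The residual RMSD
  is `I_rmsd`.

Quality classes: Incorrect when `F_nat < 10%` or `I_rmsd > 4 Å`; otherwise
High / Medium / Acceptable by the `I_rmsd` bands (≤1, 1–2, 2–4 Å) with the
`F_nat` thresholds (50%, 30%, 10%) as *lower bounds*. Read verbatim, the
published band definitions are mutually exclusive on both measures and
leave gaps (e.g. `F_nat = 63%`, `I_rmsd = 3 Å` fits no band); the
lower-bound reading makes the classification total and monotone — raising
`F_nat` or lowering `I_rmsd` never demotes a pose — and matches common
usage. A `strict` mode reproduces the verbatim bands and returns
"Unclassified" in the gaps.

## Pose scoring and ranking

Per-pose features are built from pluggable *energy terms*, each a feature
group: the in-package groups are MLAB (group 6) and hexagon (group 7),
each pooled over the pose's interface residues by an element-wise mean
(permutation-invariant and size-normalized; `sum` and `max` are exposed as
alternatives). A contact-free pose pools to a flagged zero vector — itself
an informative "far from native" signature. Classical contact energies
(groups 1–5: pair potentials, secondary-structure preferences, dihedral
statistics, π–π terms) enter through the same plug-in contract; we ship
one simplified reference term, the sum of a 20×20 contact-propensity table
over interface pairs plus the contact count, and by default a
hydrophobicity-product table for it. It is a deliberately crude reference
group, not a reimplementation of any published potential.

The SVR (ε-regression, radial kernel, cost 1, ε = 0.1, γ = 1/dimension,
features standardized with training statistics) fits pooled features
against true `I_rmsd`. No hyperparameter search is built in: these are the
conventional defaults, recorded verbatim in the model object together with
the standardization constants, the feature-group layout and the block
schemes, and a layout mismatch at prediction time is an error. Ranking
orders poses by predicted `I_rmsd` ascending with ties broken by pose id
(stable, reproducible), selects the top 10 by default, and consensus
binding residues are those appearing in the interfaces of a majority
(`⌈n/2⌉` by default) of the selected poses — consensus over the top set,
rather than the single top pose, is the default because it is robust to a
single mis-ranked pose.

## The synthetic generators, and what they do (not) show

All tests and the acceptance script run on synthetic data:

* **Ideal chains.** Backbones (N, Cα, C, O, Cβ; glycine without Cβ) placed
  on a regular helix (radius 2.3 Å, 100°/residue, rise 1.5 Å/residue) or
  extended strand, with N/C split ±55.5° about the local axis-normal so
  the N-Cα-C angle is the physical 111° and every residue is
  frame-capable. The consecutive Cα–Cα distance follows in closed form
  from these constants, which `chain_geometry()` exposes for tests.
* **Toy complexes.** Two parallel ideal chains, the ligand slid along x by
  bisection until the closest inter-unit approach equals a target distance
  (default 4.5 Å — a realistic van-der-Waals contact separation), giving a
  native interface of a few dozen contacts.
* **Decoy ladders.** The ligand unit perturbed by seeded random rotations
  (uniform axis) about its centroid plus random-direction translations.
  The default ladder — translations 0.5/1/2/3/4 Å with 5°/Å rotations —
  was chosen to span the CAPRI quality range from High to Incorrect, and
  every decoy is labeled with its true CAPRI score at generation time.
* **Profiles.** Frequency rows from a symmetric Dirichlet scheme
  (concentration 0.5, moderately sharp positions), pushed through the
  Dayhoff projection and min–max normalization.

Randomness is controlled by one global seed; each generator derives its
own stream by a stable hash of (seed, generator name, call index), so
adding a generator never shifts another's draws, and generators restore
the caller's RNG state.

The synthetic experiments (25-residue chains, 5×100-decoy ladders, 100
train/held-out replicates at 60/40, and a 5×40 ladder for the ablation
table — sizes chosen to give stable statistics at desk scale) demonstrate
that the pipeline is *correct and informative*: the features respond to
pose geometry, the SVR recovers the perturbation ordering (held-out
Spearman, top-1/top-10 selection far below the random-pick baseline), and
the group-ablation design runs end to end. They do **not** demonstrate
benchmark-level docking accuracy: ideal-geometry decoys have no side
chains, no clashes, no conformational change, and synthetic profiles carry
no real conservation signal, so published benchmark figures cannot be —
and are not — reproduced here.

## Numerical choices and degenerate inputs

* Contacts: strict `<` at the cutoff; candidate residue pairs prefiltered
  by centroid distance plus radii before exact atom-pair minimization
  (exact, verified against brute force).
* Frames: orthonormality enforced by construction; collinear Cα/Cβ/N or
  missing atoms raise errors rather than returning garbage axes.
* Superposition: n ≥ 3 points required; rank-deficient (collinear) clouds
  rejected; reflection excluded via the determinant-corrected SVD.
* Altloc resolution: highest occupancy, ties by label order; insertion
  codes keep file order after their base residue number.
* Empty blocks/windows: zeros plus flags, never NA, never shortened
  vectors.
* Min–max normalization refuses constant matrices; z-scoring refuses
  constant columns (both are genuine degeneracies, not edge cases to
  mask).

## Known limitations

Single-model chains only (no mmCIF, no symmetry expansion, no hydrogens);
energy groups 1–5 are a plug-in surface, not reimplementations of the
published potentials; SVR hyperparameters are fixed defaults, not tuned;
pose enumeration is out of scope — poses come from the caller or from the
synthetic decoy generator.
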