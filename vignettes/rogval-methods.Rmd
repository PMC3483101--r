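---
title: "Methods: residue-based ROG validation of NMR ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-based ROG validation of NMR ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rogval)
```

## The validation model

An NMR deposition is an ensemble of M conformers of one molecule. Because
the experimental restraints are predominantly local, quality varies along
the sequence, and `rogval` therefore scores at the residue level. Every
scored entity carries an ordered three-level ROG state
(green < orange < red); parents take the worst state of their children.
Two deliberate asymmetries in the aggregation: only the *residue* critiques
cascade to the molecule score, and experimental-data critiques (restraints,
shifts, peaks) are reported with their own ROG but never change the
molecule's — a noisy peak list should not mask, or be masked by, a sound
structure.

The molecule score is computed from the percentages of green (%G) and red
(%R) residues within the well-defined range: red iff %G ≤ %R − 20, else
orange iff %G ≤ 20 + %R, else green. The red region is a strict subset of
the orange region (for any %G ≤ %R − 20, also %G ≤ 20 + %R), which the test
suite verifies over the integer grid. The denominators include orange
residues: %G and %R are fractions of *all* residues in the range, the only
reading under which the two inequalities partition sensibly.

## Dihedral machinery

All torsions use the right-handed convention (`dihedral_angle()`), with
values in [−180, 180); the planar trans arrangement is reported as −180.
Degenerate (collinear) geometries return an undefined marker rather than an
arbitrary angle. The virtual dihedral D1 of residue *i* spans
Cβ(i−1)–Cα(i−1)–Cα(i)–Cβ(i); D2(i) spans residues *i*, *i+1*, so
D2(i) = D1(i+1) is an exact identity (tested as such, not approximately).
For glycine the Hα3 proton substitutes for the missing Cβ. No protons are
ever built: a glycine lacking Hα3 simply has undefined D1/D2. Building
Hα3 from covalent geometry would be easy but would silently validate
coordinates that were never deposited.

Dispersion over models uses the circular variance
cv = 1 − mean resultant length, with the closed-form anchors cv({θ,θ,θ}) = 0,
cv({0°,180°}) = 1, cv({0°,90°}) = 1 − √2/2 frozen in the tests.

## Well-defined range selection

Per chain, in the stated order: (1) single-model ensembles and molecules
without amino acids use the full sequence; (2) keep residues with
max(cv(φ), cv(ψ)) ≤ 0.2; (3) re-include excluded interior gaps of ≤ 4
residues flanked on both sides by kept residues; (4) drop kept fragments of
≤ 4 residues; (5) reset to all residues if nothing survives. Two points
were genuinely open and decided here:

* the per-residue cv combines φ and ψ as their **maximum** — the
  conservative choice (a residue is only "ordered" if both angles are);
  termini with a single defined angle use that one. This is a config point,
  not a constant buried in code.
* gaps touching a chain terminus are **not** re-introduced: "flanked"
  is read as two-sided. Terminal disorder is the common case the selection
  exists to remove, so the asymmetric reading would defeat step (2).

The selection is idempotent on its own output and monotone in the cv cutoff
before gap-filling; both are property-tested.

## Superposition

Models are Kabsch-fitted (via `bio3d::fit.xyz`) to model 1, a mean
structure is formed, models are re-fitted to the mean, and the loop repeats
until the mean RMSD changes by < 1e−4 Å (at most 20 iterations — in
practice 2–3). Reported: per-model RMSD to the mean, mean ± SD, and the
conformer closest to the mean. Atom selections are `backbone` (N, Cα, C, O)
or `heavy`. RMSD is invariant under rigid motion of any input model
(tested to 1e−6 Å).

## Peirce's criterion

The rejection ratio R(n, k) solves Gould's fixed-point form of Peirce's
equations; the implementation evaluates every power in log space, so one
code path serves all n without overflow (R(500, 200) is as routine as
R(10, 1)), converging to 1e−10 in well under the 1000-iteration cap. The
iterative screening follows Ross: σ is the standard deviation of the *full*
sample at every iteration, never of the trimmed sample — implementations
differ here, so the choice is stated. The assumed outlier count k grows
while more than k points exceed R·σ, and the flagged set is capped below
half the sample. For angles, deviations are measured on the circle about
the circular mean. Tests pin the ratios against an independent
`uniroot()` solve of the transcendental system and the flagging against a
brute-force evaluation of the acceptance inequality for n ≤ 12.

## Restraint analytics

Effective distances over atom groups use r⁻⁶ summation,
(Σ_pairs d⁻⁶)^(−1/6) — the form under which k coincident pairs give
d·k^(−1/6) — matching common NOE ensemble-averaging practice; centre
averaging is available as an option. Dihedral-restraint bounds live on the
circle, so wrap-around intervals like [150°, −150°] are legal; the
violation is the circular excess beyond the nearer bound. ROG cutoffs
(distance max 0.3/0.5 Å, RMS 0.15/0.3 Å; dihedral max 3/10°, RMS 3/5°)
apply to lower-bound violations identically. A restraint with any
unresolved atom reference is red with undefined statistics — unresolved
references are carried as markers, never dropped, precisely so this rule
can fire.

Duplicates are defined on atom sets only (unordered contributions of
unordered group pairs), ignoring bounds; the retained member of a group is
the one with the most restrictive upper bound. Whether bounds-differing
restraints should count as duplicates is not settled usage; the atoms-only
rule is the stated hypothesis here.

NOE completeness is a simplified stand-in for a full completeness
analysis: observables are C/N-bound protons with methyls and fast-flipping
aromatic pairs collapsed; a pair is *expected* when its r⁻⁶ effective
distance is ≤ 4 Å in at least half the models (an approximation chosen
where the reference tool's internals are not public); *observed* when any
non-hydrogen-bond restraint links the groups. Completeness percentages
from this rule are comparable in spirit, not in digits, to the reference
implementation, which is why the benchmark tolerance on completeness is
wide.

## Chemical shifts, peaks, residue-specific checks

Shift Z-scores are (value − mean)/SD against a per-(residue type, atom)
reference table; |Z| > 3 flags the shift. The flag maps to orange by
default (configurable to red): the published criterion table gives the
single threshold without an unambiguous colour column, and "flagged" reads
as a warning. A shift assigned to an atom without coordinates is red.
Pseudo-atom/member and stereo-pair consistency use a tolerance of three
per-nucleus SDs (0.01 ppm ¹H, 0.15 ppm otherwise) — the same assumed SDs
used for peak-position Z-scores (orange ≥ 1, red ≥ 2).

Proline cis/trans is predicted from Δ = δ(Cβ) − δ(Cγ) with provisional
defaults cis ≥ 8.0 ppm, trans ≤ 6.0 ppm (chosen as round values bracketing
the literature consensus; both are configurable),
and compared against the geometric call from the ensemble ω angles. The ω
deviation itself is the ensemble average of each model's circular distance
to the nearer of the trans (179.7°) and cis (0°) references — nearest
reference per model, then average, since averaging first would blur mixed
cis/trans populations. Leucine χ2 consistency compares the sign of
δ(Cδ1) − δ(Cδ2) with the consensus rotamer (trans within 60° of 180°,
gauche+ within 60° of +60°, otherwise indeterminate and silent).

DSSP-style codes collapse to helix {G, H}, sheet {B, E}, other; mapping I
(π helix) to helix is an extension toggle defaulting off to keep the
published mapping literal. Consensus is the majority state; ties resolve
to "other", the least-claiming state.

## D1/D2 reference densities

The D1D2 residue criterion needs a reference density over (D1, D2). The
density is a pluggable input: a 2D histogram on a 10° grid with half-count
smoothing, and Z = (log-density at the observed point − density-weighted
mean log-density)/SD of log-density, averaged over models. The packaged
generator (`synthetic_d1d2_density()`) builds such densities from
generated ensembles and is explicitly synthetic — suitable for exercising
the machinery and for relative comparisons, not a substitute for a
database-derived reference. The published orange/red cutoffs for this row
(−1.0/−0.8) have red *less* extreme than orange; they are applied verbatim
(the calibration was manual), with a `d1d2_strict` switch to swap them.

## Interactions

Salt bridges follow the two-condition centroid + N–O rule at 4.0 Å (the
conventional criterion distance; configurable). Histidine is excluded from
the basic set — the enumeration is Arg/Lys × Glu/Asp — and "exactly one
condition" defines the weaker ionic-interaction class, which is the tested
reading of the salt-bridge/ionic distinction. Disulfides: Sγ–Sγ ≤ 2.5 Å is
bonded; otherwise Cβ–Cβ ≤ 4.5 Å with the Cβ–Sγ–Sγ′–Cβ′ dihedral magnitude
in 90 ± 30° is potential (Cβ distance alone when Sγ is absent). All
defaults are this package's own and configurable.

## The synthetic-data generator

`make_ensemble()` builds chains from ideal internal coordinates (N–Cα
1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å; canonical helix −57/−47, strand
−120/+130) and draws per-model φ/ψ as canonical value + Gaussian noise
with per-residue SD; ω stays trans with 1° noise. The controllable facts
are what the tests rely on: residues with noise SD ≈ 2° come out with
cv < 0.05, residues at 80° with cv > 0.2, so ordered/disordered segment
designs translate directly into expected range selections.
`make_restraints()` derives upper bounds from model-1 proton distances
plus padding, and injections set the bound to (ensemble maximum − δ), so
the maximum violation equals δ by construction; duplicates are appended
literally. `make_shifts()` draws mean + N(0, 0.2·SD) and forces listed
outliers to mean + z·SD exactly. Everything is reproducible bit-for-bit
from a seed.

What the generator does **not** emulate: packing, side chains beyond Cβ,
hydrogen-bond networks, realistic NOE density, correlated noise between
neighbouring residues, chemical-shift/structure coupling. Green tests on
synthetic data therefore demonstrate that the *rules* are implemented as
specified and that designed signals are recovered exactly — not that the
thresholds are well calibrated for experimental ensembles; that
calibration is inherited from the published cutoffs.

## Numerical choices and problem sizes

Superposition tolerance 1e−4 Å / 20 iterations; Peirce convergence 1e−10 /
1000 iterations; dihedral degeneracy guard at squared cross-product norm
1e−12; density smoothing half a count per bin. Coordinates are Å in the
PDB right-handed frame; sequence numbers follow the input verbatim (no
renumbering); the first altloc wins, with a record noting the drop. The
test and acceptance workloads use ensembles of 20–60 residues with 5–20
models — sizes at which every analysis, including the O(n²·M)
completeness scan, completes in seconds while still exercising multi-segment
range selection and hundreds of restraints. Hetero-entities (water, ions)
are loaded but excluded from residue criteria; nucleic acids are accepted
by the data model but carry no dihedral topology here.

## Known limitations

External per-residue metrics (Ramachandran/Janin Z, G-factor) are consumed
from tables, not computed; RDC restraints are not validated; no NEF or
mmCIF writing; the NMR-STAR reader covers only the assigned-chemical-shift
loop; uniform per-nucleus re-referencing offsets can be applied via the
reference table but are not estimated. The shipped reference shift table
and D1/D2 densities are synthetic stand-ins; for production use, supply
database-derived ones via `read_reference_shifts()` / `d1d2_density()`.
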