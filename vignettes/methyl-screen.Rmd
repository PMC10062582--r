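---
title: "Screening cryo-EM maps for 2'-O-methyl ribose modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cryo-EM maps for 2'-O-methyl ribose modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem and the method

High-resolution cryo-EM maps of ribosomes begin to resolve individual methyl
groups. In yeast 18S rRNA a set of adenosines carries a 2'-O-methyl group on
the ribose 2'-hydroxyl, deposited co-transcriptionally by snoRNA-guided
machinery. Given an atomic model and the map it was built into, one can ask
in an unbiased way: which residues show the little knob of extra density that
a 2'-O-methyl group would leave?

`ribomethscore` implements this question as a screen. Every candidate
residue (by default every adenosine with an intact C1'/C2'/O2' ribose edge)
is *hypothetically* methylated: a methyl carbon is constructed from internal
coordinates off the O2' atom, its torsion chosen to avoid steric clashes and
optionally settled into the local density. Two scores are then read off the
map by trilinear interpolation:

* **Sc_MapVal** — the map value at the hypothetical methyl carbon position.
  Where a methyl group is truly present (and modelled or not), the map holds
  density there; where it is absent, the position sticks out of the ribose
  envelope into weaker density.
* **Sc_FallOff** — Sc_MapVal divided by the map value at a probe placed on
  the same O2'→methyl line but at 2.4 Å from O2' (the carbon sits at
  1.43 Å). A genuine methyl peak falls off along this direction, giving a
  ratio above 1; flat density — for instance the broad blob of an
  unattributed ion — gives a ratio near 1. The screen flags candidates with
  Sc_FallOff strictly greater than 1.5.

Candidates are ranked by Sc_MapVal descending. The screen's output is the
full ranked table; the falloff flag and the top-N window are triage aids for
the manual inspection that necessarily follows any such screen.

## Geometry of the hypothetical methyl

The adduct is built with the natural-extension (NeRF) construction from the
C1', C2', O2' positions: bond length 1.43 Å, C2'–O2'–CM' angle 113°, and the
C1'–C2'–O2'–CM' dihedral as the single free parameter. The defaults follow
standard 2'-O-methyl nucleoside stereochemistry (wwPDB component A2M, whose
methyl carbon is named CM'); both are configuration fields of
`adduct_spec()`, as are the target residue codes, so other small adducts can
be screened with the same machinery.

Torsion selection scans the full turn in 5° steps and maximizes *clearance*:
the minimum over all heavy atoms — excluding atoms within two covalent bonds
of the adduct (O2' and C2') and any same-named atom already modelled in the
residue — of the interatomic distance minus the sum of van der Waals radii.
A placement counts as clash-free when clearance ≥ −0.6 Å, the conventional
allowed-overlap criterion. Ties break towards the smaller torsion, so the
scan is deterministic. Note that the 1–4 contacts to C1' and C3' are *not*
exempt: for an isolated nucleotide the best achievable clearance is about
−0.7 Å, so the clash flag is meaningful mainly as a relative signal (a caged
site scores far worse) rather than as an absolute chemistry verdict.

Treating hypothetical methylation as idempotent — ignoring an already-present
adduct atom of the same name in the clearance set — matters for validation:
synthetic fixtures contain truly methylated residues, and without this rule a
modelled methyl would repel its own hypothesis.

## Density-guided torsion refinement

The reference workflow settles the modified model into the map with a
map-weighted molecular-dynamics simulation. With the rest of the model held
rigid, the adduct's only internal degree of freedom is its torsion, so this
package replaces the settling step with a deterministic one-dimensional
optimization: maximize

J(τ) = map(adduct position(τ)) − λ · rms(map) · max(0, −clearance(τ)),

by a 5° coarse scan plus a 0.1° local scan, never returning a torsion whose
objective is below the input's. The clash penalty λ (default 2 per Å of
overlap) is expressed in units of the map's rms so that the optimum — and
therefore every Sc_FallOff and every rank — is invariant under rescaling the
map. The input torsion wins ties, so a uniform map leaves placements
untouched. Refinement can be disabled (`screen_config(refine = FALSE)`),
in which case the clash-scan torsion is scored directly.

Holding the environment rigid is a deliberate simplification: it isolates
the signal the method relies on (extra density at the methyl position) from
conformational confounds, at the cost of not reproducing any environment
relaxation a full simulation would allow.

## Map handling

MRC2014/CCP4 maps are read and written natively, including the two
conventions that diverge in the wild: the grid is reindexed to (x, y, z)
using the MAPC/MAPR/MAPS axis-correspondence words, and the origin is taken
from the ORIGIN record when present and non-zero, else from start indices ×
voxel size (with a warning when both are present and disagree; ORIGIN wins).
Probing uses trilinear interpolation, which is exact at grid nodes and exact
everywhere for affine fields — properties the test suite exploits as
closed-form oracles. Out-of-grid queries return a flagged zero, but scoring
treats a flagged probe as a hard error: a scored model must lie inside its
map. Raw map units are scored; no z-scoring or sharpening is applied, and
the scale invariance of Sc_FallOff and of the ranking makes units
immaterial.

One division hazard is guarded: cryo-EM maps hold near-zero and negative
values outside the molecular envelope, so when the falloff denominator's
magnitude is at most 0.05 × map rms the score is recorded as undefined
(never passing the flag) rather than exploding.

## The synthetic testbed

`make_toy_rna(n, frac, seed)` builds isolated adenosine nucleotides from an
idealized internal-coordinate template (ribose plus base heavy atoms, with
the 2'-OH on the correct sugar face), placed at random orientations with
pairwise O2'–O2' spacing ≥ 8 Å and no inter-residue interpenetration. A
chosen fraction receives a *real* methyl atom, built by the same placement
machinery at a random clash-free torsion — the density-guided refinement is
then responsible for re-finding that torsion at screen time, which keeps the
noise-free screen a controlled positive test of the scoring mathematics
rather than of geometry bookkeeping.

`simulate_map()` renders a model as a sum of isotropic Gaussian kernels with
σ = 0.425 × resolution proxy (FWHM ≈ nominal resolution; 1.275 Å at the 3 Å
proxy used throughout), on a 0.5 Å grid covering the model plus 6 Å padding,
with optional seeded i.i.d. Gaussian noise. All generator randomness is
seeded and bit-reproducible.

What the surrogate emulates: resolution-controlled blur, the presence or
absence of methyl density at O2', additive noise. What it does not emulate:
solvent flattening and sharpening (experimental maps are near zero with
noise outside the molecular envelope; the surrogate's envelope decays as
smooth Gaussian tails), ions and ligands, B-factor variation, chain
connectivity, and map–model misalignment. Passing tests therefore validate
the scoring logic and its invariances — not performance on experimental
maps.

One consequence deserves emphasis. On this surrogate the Sc_MapVal ranking
separates true sites from decoys cleanly (strict separation at zero noise;
8/8 in the top 10 at 10%-of-peak noise in the 40-residue validation screen).
Sc_FallOff, however, does *not* separate them: a decoy's probe pair rides
the steep outer tail of the ribose envelope, where the 1.43 → 2.4 Å ratio is
exp((2.4² − 1.43²)/(2σ²)) ≈ 3 at σ = 1.275 Å, while a true methyl's probe
sits at a kernel peak whose shoulder falls more gently (≈ 1.3–2 including
neighbours). Adding a methyl *flattens* the local falloff. In experimental
maps the falloff criterion earns its keep because decoy denominators sit in
flat solvent-level density; a sum-of-Gaussians surrogate cannot reproduce
that regime, and the package reports the discrepancy rather than papering
over it.

## Numerical choices and degenerate inputs

* Interpolable domain: the box spanned by the outermost grid nodes; queries
  at the boundary clamp the cell index and are exact.
* Collinear C1'/C2'/O2' reference geometry is rejected (no dihedral is
  defined there).
* Alternate conformations: the highest-occupancy conformer is kept at read
  time (ties to the alphabetically first altloc); the screen operates on a
  single conformation, and only the first model block of multi-model files
  is read. Either rule is a design choice, not derived from the reference
  workflow, which is silent on both.
* Ranking ties (equal Sc_MapVal) break by chain then residue number, making
  ranks independent of input order.
* Report numbers are written with fixed formats so identical screens yield
  byte-identical TSV files.

## Problem sizes

The validation screen uses 40 nucleotides with 8 methylated (seed 11), a
~60³ Å box at 0.5 Å voxels (~2 × 10⁶ voxels), and completes in a couple of
seconds per screen; unit tests use 1–20 nucleotide fixtures. These sizes
were chosen to exercise every code path at interactive speed while keeping
the recovery statistics stable across seeds.

## Known limitations

* The screen scores one rigid conformation; any real settling of the
  environment around a methyl is out of scope.
* Sc_FallOff discrimination against decoys cannot be demonstrated on the
  Gaussian surrogate (above); only its closed-form behaviour at peaks and
  on flat density is validated.
* No map–model fitting is performed: inputs must share a coordinate frame.
* Heavy atoms only; hydrogens are ignored throughout.
* The false-positive mechanism seen in practice (ion density adjacent to a
  ribose) is not simulated; the tool only flags and ranks, and manual
  inspection of top candidates remains part of the intended workflow.
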