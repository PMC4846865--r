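---
title: "Methods: quantifying binding-loop flexibility from structural ensembles"
author: "loopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying binding-loop flexibility from structural ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`loopdyn` analyzes structural ensembles — ordered coordinate frames sharing
one topology, typically snapshots of a molecular-dynamics simulation read
from a multi-model PDB — to characterize the flexibility of receptor binding
loops such as the six CDR loops of an αβ T cell receptor. This vignette
documents the models behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic validation does and does not
establish about real data.

## Ensembles, selections, superposition

Residue identity is the PDB author numbering plus insertion code throughout;
no renumbering is performed, so residues can be cross-referenced with
crystallographic literature directly. Alternate locations are reduced at read
time to the highest-occupancy conformer (ties broken by altloc letter), giving
a deterministic single-conformer model. Loop definitions are resolved from
one-letter sequence motifs that must occur exactly once in their chain — an
intentional strictness: a CDR sequence that matches twice means the loop table
and the structure disagree, and silently picking one match would corrupt every
downstream per-loop statistic.

Frames are superposed by the Kabsch rigid-body fit (rotation + translation,
with a determinant guard excluding reflections) of a user-chosen atom mask,
usually all α-carbons, onto reference coordinates. The fit minimizes mask
RMSD per frame; the test suite checks optimality against randomized rigid
placements. Masks with collinear reference atoms have no unique rotation and
are rejected.

One caveat the package deliberately surfaces rather than hides: global
superposition is itself an analysis choice. Fitting on *all* α-carbons when a
few loops are highly mobile lets those loops drag the fit, which attenuates
and mixes correlations (visible in the demo pipeline, where the planted
loop-pair correlation survives analysis of the raw generated frames but is
distorted after whole-molecule fitting). Validation statistics in the tests
therefore analyze synthetic ensembles in their generation frame, which is by
construction a common reference frame.

## Synthetic ensembles: the validation substrate

The generators define the controlled conditions for every oracle check.

* **Gaussian positional fluctuations.** Frames are `template + displacement`;
  each residue's displacement is a zero-mean Gaussian 3-vector, independent
  across frames and axes, with per-axis standard deviation σᵢ (Å) and
  inter-residue correlation ρᵢⱼ applied identically on each axis. All atoms of
  a residue move rigidly together. Closed forms: RMSF = σ√3; per-axis
  displacement covariance ρᵢⱼσᵢσⱼ; DCCM entry ρᵢⱼ; LMI −(3/2)ln(1−ρᵢⱼ²) for
  unit-variance pairs. Displacements carry no autocorrelation in time because
  every statistic in scope is ensemble-averaged, not time-correlated. The
  implied covariance must be positive semi-definite; sampling uses its
  eigendecomposition, so exactly singular specifications (ρ = 1) are legal.
* **Diffusion in a cone.** Unit vectors uniform on the spherical cap of
  half-angle θ₀ about +z, independent across frames;
  S² = [cos θ₀(1 + cos θ₀)/2]², cross-checked in the tests by numerical
  integration of the cap average of P₂(cos θ).
* **Two-state dihedral switching.** Bernoulli(p) state selection with
  wrapped-normal jitter (the simplest circular noise with controllable
  spread); all angles wrapped to (−180°, 180°].
* **Scripted hydrogen bonds.** A donor N–H / acceptor C=O pair whose per-frame
  geometry realizes a prescribed presence schedule; unbonded frames violate
  exactly one criterion each (distance 3.8 Å at a compliant angle, or angle
  100° at a compliant distance), so both halves of the detection rule are
  exercised.

Every generator takes a mandatory seed and restores the caller's RNG state;
identical spec + seed is bit-identical output.

What passing these checks shows: the estimators are implemented correctly —
they recover known moments, closed forms and planted structure at the stated
tolerances. What it does not show: real MD ensembles have autocorrelated,
anharmonic, multi-basin dynamics; convergence on real data is a sampling
question the package cannot answer for you.

## Fluctuations and B-factors

RMSF is computed about the **ensemble-mean** position (not frame 1): this is
the standard definition, and the reference choice matters only at second
order. B-factors interconvert with RMSF via B = (8π²/3)·RMSF², a strict
bijection on RMSF ≥ 0. Distance series use a **centered** running mean whose
window truncates at the series edges (an explicitly recorded choice; a
trailing window would lag transitions by half a window). Snapshot RMSD
matrices superpose every snapshot pair on the mask before measuring; block
averages over simulation pairs use the unweighted mean of cross pairs, and
distinct within-simulation pairs on the diagonal. Groove width defaults to
the Cα–Cα distance of the two marker residues, with the atom name
configurable, since marker-atom conventions vary.

## Order parameters (iRED)

The iRED matrix holds ⟨P₂(μ̂ᵢ·μ̂ⱼ)⟩ over frames for bond vectors Cα→Cβ
(Cα→Hα for glycine; a glycine without Hα is an error, never a silent skip).
Its eigenvalues are non-negative and sum to M; order parameters are
S²ᵢ = 1 − Σₘ λₘ e²ₘᵢ over all but the `n_excluded = 5` largest-eigenvalue
modes, the standard separation of overall reorientation. Degenerate
eigenvectors get a deterministic sign (first nonzero component positive), and
round-off S² in (−10⁻⁶, 0) is clamped to zero.

`n_excluded` is exposed because its effect is *not* negligible for internal
motions: when the vectors have no collective mode (independent residues), the
five discarded modes still carry internal amplitude of order (1 − S²)/M each,
biasing iRED S² upward by ≈ 5(1 − S²)/M relative to the direct second-rank
estimator S² = (3 Σₐᵦ ⟨μₐμᵦ⟩² − 1)/2. The tests measure this bias law
explicitly (M = 20 gives ≈ +0.21 at S² = 0.14) and validate the analytic cone
value with M = 300 vectors, where the bias (≈ 0.014) sits inside the 0.02
tolerance. For real proteins (M of hundreds of residues) the bias is small;
for short loops analyzed in isolation it is not, and the direct estimator is
reported alongside as a cross-check.

## Correlation and community networks

DCCM entries are normalized displacement covariances clamped to [−1, 1];
zero-variance residues produce *missing* entries rather than silent zeros.
Loop-pair averages are unweighted block means (off-diagonal pairs only on the
diagonal block). LMI is the Gaussian mutual information of two residues' 3D
displacements in **nats** (the 0.4 edge threshold is applied on that scale
and recorded in output); the diagonal is a divergent self-information
sentinel (`Inf`) excluded from filtering, and a singular joint covariance —
perfectly coupled motion — is reported as `Inf` with a warning rather than
a fabricated large number.

The network stage keeps edges with LMI ≥ 0.4 and ensemble-mean distance ≤ a
cutoff scanned over 8–10 Å in 0.5 Å steps (the scan step is the package's
choice; the range, threshold and the selection rule — fewest communities,
ties to the larger cutoff — are fixed by the protocol). Edges are unweighted:
the filter decides presence, not strength; inter-community connection weights
are retained-edge counts. Community detection is Girvan–Newman — iteratively
remove the edge of highest betweenness, tracking the connected-component
partition of maximum Newman–Girvan modularity on the original graph — with
betweenness ties broken by lexicographic endpoint order for determinism. The
implementation uses igraph primitives (betweenness, modularity, components)
but owns the removal protocol; tests cross-check it against igraph's
reference edge-betweenness clustering and against brute-force cutoff scans.

## Dihedrals and box occupancy

φ/ψ use the IUPAC sign convention (validated against an independent torsion
implementation on random quadruples) and wrap to (−180°, 180°]. Terminal
residues yield a defined-missing angle. Box occupancy counts frames with
circular distances |Δφ| ≤ 30° **and** |Δψ| ≤ 30° of the reference; edges are
inclusive (the boundary has measure zero in data but constructed inputs
should behave deterministically), and occupancies are reported to one decimal
in percent. Bound-state reference angles are inputs — taken from a crystal
structure or supplied in configuration — because they are properties of the
ligated complex, not of the ensemble under analysis.

## Hydrogen bonds

The criterion is donor–acceptor heavy-atom distance ≤ 3.5 Å and
donor–hydrogen–acceptor angle ≥ 120°, with a packaged donor/acceptor
chemistry table for the standard amino acids (backbone N donor except
proline; backbone O acceptor; side-chain donors of S/T/Y/N/Q/K/R/H/W and
acceptors of D/E/N/Q/S/T/Y/H). Hydrogens are located by covalent distance
(≤ 1.25 Å within the donor residue). Crystal structures usually lack
hydrogens, so a fallback mode — distance criterion plus an
antecedent–donor–acceptor angle proxy ≥ 90° — supports interloop counting on
heavy-atom models; fallback detections are flagged in output, never silent.
Occupancy maps report, per residue pair, the most persistent donor/acceptor
combination; the summary count uses a configurable occupancy floor
(default 10%), recorded in the output rather than baked in, because published
interface bond counts rarely state their floor.

## SASA and the flexibility regression

SASA is Shrake–Rupley with a 1.4 Å probe and 240 test points per atom placed
on a deterministic Fibonacci spiral (same probe and point budget as the
grid-based original, but exactly reproducible). Van der Waals radii come from
a single packaged element table (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å); an unknown element is an error. Because the point set is fixed in
space, rotating a structure changes the result at the ~1% discretization
level — the tests document this bound. Relative SASA divides by the residue
type's reference area from an extended (φ = −120°, ψ = 120°) Ala-X-Ala
tripeptide built by the package's internal-coordinate constructor and
measured with the same SASA engine. The constructor models residues at
backbone + Cβ resolution (no rotamer library), which exactly covers the
synthetic pseudo-residue alphabet; for real structures with full side chains,
supply a published maximum-accessibility table via the `reference` argument.

The flexibility model RMSF = a·(relative SASA) + b·(B-factor) + c is ordinary
least squares; coefficients are reported with explicit units (a: Å per
relative-SASA unit; b: Å/Å²; c: Å) because mixed unit conventions
(fractional vs percent relative SASA) change a by a factor 100. Collinear
predictors are rejected with the design-matrix condition number. Pearson R
between fitted and observed values is NA, with a warning, under zero
variance.

## Pipeline, demo conditions and problem sizes

`generate_demo_data()` builds two-chain toy receptors whose chains embed the
A6 and DMF5 CDR sequences between TS linkers, and Gaussian ensembles with a
planted contrast chosen to mirror the published loop-mobility profile: a
quiet σ = 0.25 Å baseline; for the A6-like toy, mobile uncorrelated
hypervariable loops (CDR3α σ = 1.7 Å, CDR3β σ = 2.9 Å, apex RMSF ≈ 3 and
5 Å); for the DMF5-like toy, quieter loops (σ = 1.15 / 0.58 Å ≈ 2 and 1 Å
RMSF) with a planted 0.42 CDR3α/CDR3β cross-correlation. Crystal B-factors
are set from the planted amplitudes, so the regression stage has a meaningful
signal. The default 300 frames keep a full two-receptor pipeline run around
ten seconds; validation statistics that need tighter Monte-Carlo error use
dedicated ensembles of 10⁴–5×10⁴ frames on small systems (2–60 residues,
300 vectors for the iRED cone check), sizes at which each check resolves its
stated tolerance with margin.

`run_pipeline()` executes stages in dependency order (read → superpose →
analyses), writes one CSV per stage and dataset, and records parameters,
package version, seed and per-stage status in `manifest.json`; a stage
failure aborts with the stage named and leaves a FAILED marker. All table
headers and the manifest carry the conventions in force (angle wrap, LMI log
base, occupancy floor, excluded mode count). A single global seed fans out to
named per-stage substreams so stage-level reproducibility does not depend on
stage order.

## Known limitations

* Multi-model PDB is the only bundled trajectory format; DCD/XTC readers are
  an extension point behind the same ensemble contract.
* No time-correlation analyses (Lipari–Szabo fits, autocorrelation decay):
  the synthetic generators are frame-independent by design.
* The Ala-X-Ala reference builder stops at Cβ; full-side-chain reference
  areas must be supplied externally for real proteins.
* No salt-bridge, π-interaction or water-mediated contact detection.
* Voronoi packing density is out of scope; relative SASA is the implemented
  accessibility measure.
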