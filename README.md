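# loopdyn

Conformational-ensemble flexibility analysis for receptor binding loops.

T cell receptors (TCRs) recognize peptide/MHC ligands through six
complementarity-determining-region (CDR) loops whose flexibility governs how
binding proceeds — by conformational selection (the free receptor already
samples the bound shape) or by induced fit (the ligand drives a rare
conformational change). Quantifying that flexibility from a structural
ensemble (for example, molecular-dynamics snapshots stored as a multi-model
PDB) takes a battery of standard analyses that are rarely available together
in one tested package. `loopdyn` provides them, for structural biologists and
simulators who have an ensemble and want the dynamics profile of a receptor:

- **Fluctuation profiles** — per-residue RMSF about the ensemble mean, with
  interconversion to crystallographic B-factors via `B = (8π²/3)·RMSF²`,
  inter-atom distance series with running averages, and
  snapshot-by-snapshot RMSD matrices with block averages.
- **Order parameters** — generalized order parameters `S²` of Cα–Cβ
  (Cα–Hα for glycine) bond vectors via isotropic reorientational eigenmode
  dynamics (iRED: eigendecomposition of the `⟨P2(μ̂ᵢ·μ̂ⱼ)⟩` matrix with the
  five largest reorientational modes excluded), cross-checked by a direct
  second-rank tensor estimator.
- **Correlation networks** — dynamic cross-correlation matrices
  (`Cᵢⱼ = ⟨Δrᵢ·Δrⱼ⟩ / √(⟨|Δrᵢ|²⟩⟨|Δrⱼ|²⟩)`) with loop-pair block averages;
  linear mutual information (`LMI = ½[ln det Σᵢ + ln det Σⱼ − ln det Σᵢⱼ]`,
  nats); and Girvan–Newman community detection after the edge filter
  *keep LMI ≥ 0.4 and mean distance ≤ cutoff*, scanning cutoffs over 8–10 Å
  and selecting the one that minimizes the community count (ties go to the
  larger cutoff).
- **Dihedral sampling** — backbone φ/ψ series and the fraction of frames
  inside a ±30° box around reference (e.g. bound-state) angles, with circular
  wrapping.
- **Hydrogen bonds** — detection at donor–acceptor distance ≤ 3.5 Å and
  donor–H–acceptor angle ≥ 120°, per-residue-pair occupancy maps across an
  interface, and interloop bond counting on crystal structures (with a
  flagged heavy-atom fallback when hydrogens are absent).
- **Surface regression** — Shrake–Rupley SASA (1.4 Å probe, 240 deterministic
  sphere points per atom), relative accessibility normalized to Ala-X-Ala
  tripeptide references, and the multilinear flexibility model
  `RMSF = a·(relative SASA) + b·(B-factor) + c` with Pearson-R reporting.

Every stage is validated against synthetic ensembles with known ground
truth, produced by the package's own generators: multivariate-Gaussian
positional fluctuations with prescribed amplitudes σ and correlations ρ
(RMSF = σ√3 exactly in expectation), diffusion-in-a-cone bond vectors
(`S² = [cos θ₀ (1 + cos θ₀)/2]²`), two-state circular dihedral switchers, and
scripted hydrogen-bond geometries.

## Worked example

```r
library(loopdyn)

# synthetic two-receptor demo dataset + configuration
dd <- generate_demo_data("demo", seed = 42, n_frames = 300)

# read the A6-like ensemble, superpose on alpha carbons
ens  <- read_ensemble(dd$receptors$A6$ensemble)
ca   <- selection_mask(ens, elety = "CA")
ens  <- superpose(ens, ca)

# resolve the six CDR loops from their sequences
loops <- resolve_loops(ens$topology, cdr_loop_table("A6"))
loops[[6]]
#> loop CDR3b (chain B): residues 18-31, ASRPGLAGGRPEQY (14 aa)

# per-loop fluctuation maxima
prof <- rmsf(ens, ca)
sapply(loops, function(lp)
  round(max(prof$rmsf[prof$chain == lp$chain & prof$resno %in% lp$resno]), 2))
#> [1] 0.92 0.85 2.87 0.92 1.03 4.58
```

The six numbers are the maximum Cα RMSF (Å) of CDR1α, CDR2α, CDR3α, CDR1β,
CDR2β, CDR3β: the hypervariable loops (2.9 and 4.6 Å) dominate the
germline loops (≤1 Å), reproducing the planted amplitude contrast of the
demo generator — the same ranking logic used to compare receptor loop
mobility in real simulations.

```r
# full pipeline over both demo receptors: one CSV per stage + manifest
run_pipeline(dd$config)
```

A thin command-line dispatcher over the same functions ships in
`inst/cli/loopdyn.R`
(`Rscript inst/cli/loopdyn.R rmsf --ensemble demo/a6_ensemble.pdb --out rmsf.csv`).

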