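---
title: "Methods: field-response observables and the synthetic ground-truth generator"
author: "eeftraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-response observables and the synthetic ground-truth generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeftraj)
```

## The problem

A static external electric field exerts a force `q·E` on every partial
charge of a protein. For a tubulin heterodimer the expected signature is
spatially structured: rigid helical cores barely move, while charged
flexible motifs — the α:H1-B2 loop, the β:M-loop, and the strongly
negative C-terminal tails — shift their mean positions along the field and
fluctuate more; at the dimer scale, the intradimer bend angle and the
monomer–monomer elongation redistribute. The package computes the standard
trajectory observables of that response (RMSD by secondary-structure
class, RMSF and ΔRMSF, endpoint displacement, fixed-charge dipoles, bend,
elongation, probe distances, salt bridges, MSD) and, because 50-ns
all-atom MD is not reproducible at desk scale, ships a synthetic
trajectory generator whose ground truth every estimator must recover.

## The generator

`build_synthetic_dimer()` constructs two identical monomers stacked along
+z (β below, α above), each with:

- a rigid core of ideal α-helix Cα geometry (rise 1.5 Å, 100°/residue,
  radius 2.3 Å), whose central three-quarters carry the `H7` region label;
- flexible segments H1-B2 (chain start), M-loop, H3 and C-terminus, placed
  as extended strands off the core; H1-B2 carries a +1e Lys-like probe
  (position 4, side atom NZ) and a −1e Asp-like probe (position 7, OD1);
- a net −5e C-terminal tail extending toward −x and descending along the
  monomer surface, so the built dipole (hence the positive transverse
  axis) points near +x, roughly perpendicular to the β→α longitudinal
  axis;
- one planted salt bridge per monomer: the last core residue is a surface
  Lys whose NZ sits exactly 3.0 Å from the first tail residue's Glu OE1,
  mimicking the contracted, surface-bound tail state.

`generate_trajectory()` then emits frames in a documented order. Per frame
*t*:

1. **Bend**: θ_t ~ N(bend_mean, bend_sd) degrees; the whole β monomer is
   rotated about the +y axis through the pivot at the midpoint of the two
   core centers of mass. The pivot choice is a self-consistency decision —
   only the rotation *angle* is ground truth.
2. **Elongation**: e_t ~ N(elong_mean, elong_sd); β is translated along
   the instantaneous core-COM axis so the helix-COM separation equals e_t.
3. **Field coupling**: while the field window is on, every flexible
   residue of net charge q shifts by `coupling · q · S` along the realized
   field direction (S in kV/cm). The shift is applied instantaneously at
   window start; relaxation is an observation for the analysis stages, not
   a generator feature.
4. **OU noise**: every atom gets independent per-coordinate
   Ornstein–Uhlenbeck noise with the exact discrete update
   `u(t+Δ) = u(t)·e^(−Δ/τ) + N(0, σ²(1 − e^(−2Δ/τ)))`, initialized at
   stationarity, so the stationary SD is exact at any frame interval.
5. **Drift**: a cumulative Brownian step N(0, 2DΔ) per coordinate on all
   atoms.

One seeded stream drives everything (θ, e, OU block atom-major with xyz
within atom, Brownian increment — frame-major), so fixtures are
bit-reproducible.

### Defaults and calibration

| parameter | default | rationale |
|---|---|---|
| residues/monomer, helix fraction | 64, 0.625 | 40-residue core (H7 = 30 residues) keeps helix-axis fits well conditioned at desk scale |
| ou_sigma_core | 0.41 Å | rigid-core Cα RMSD ≈ √6·σ ≈ 1 Å, the observed rigid-partition level |
| ou_sigma_loop | 1.0 Å | ambient flexible RMSD ≈ √6 ≈ 2.4 Å, inside the reported 2–3 Å ambient band |
| field widening | ×(1 + 0.5·S/750), charged ×(1 + |q|·S/750) | places flexible RMSD at ≈ 5.4 Å for S = 750, inside the reported 5–6 Å band, concentrated on charged residues |
| coupling | 0.004 Å/(e·kV/cm) | ±3 Å charged-loop shifts at 750 kV/cm; separable, strictly ordered probe-distance shifts at 50/100/200 |
| bend_mean, bend_sd | 5.9°, 2.0° | mean keyed per condition (below); spread a plausible few degrees |
| elong_mean, elong_sd | built separation (+ preset shift), 0.6 Å | self-consistent with the constructed geometry |
| ou_tau | 25 ps | loop relaxation of tens of ps; equal to the 25 ps frame interval |
| D | 5.9e-3 Å²/ps | a tubulin-scale translational diffusion coefficient |

The presets key the bend parameter to the two reported condition means:
5.9° unexposed and 8.2° for the negative-transverse condition at
750 kV/cm (interpolated linearly below 750), leave other directions at the
ambient value, and add a small elongation shift in every field direction
(largest for longitudinal fields). These defaults *are* the study
conditions; tests and the acceptance script do not adjust them.

### What the generator does and does not emulate

It reproduces the statistical shape of the MD observables: rigid/flexible
fluctuation contrast, charge-proportional field response, stationary
noise, frame-wise bend/elongation distributions, Brownian drift. It does
not model forces, solvent, electrostatic screening, secondary-structure
transitions (labels are static), bonded geometry beyond Cα pseudo-chains,
or any relaxation dynamics of the field response. Passing recovery tests
therefore validates the estimators, not any claim about real tubulin.

## Estimator choices

**Superposition.** Kabsch via SVD of the weighted covariance; a
reflection solution is corrected by sign-flipping the smallest singular
vector. Weights default to uniform (plain Cα convention); mass weighting
is a flag. Collinear point sets are rejected rather than silently
under-determined.

**Bend angle.** The study frame is anchored on the reference by the α:H7
atoms only, and "best fit line" means the first principal axis of the
centered atom cloud (total least squares, rotation invariant), with an
eigengap guard (relative gap > 1e-6) against isotropic clouds. Two modes
exist. `beta_only` (default) fits each structure's line through its β:H7
atoms: an applied intradimer rotation θ moves the β line by exactly θ, so
the estimator responds one-to-one to the generator's ground truth.
`combined` fits one line through αH7 ∪ βH7 per structure; since that line
mixes the anchored and the moving monomer, an applied rotation θ moves it
by c·θ with c = cov(z, lever)/var(z) < 1 (≈ 0.5 for symmetric helix
placement) — a structurally attenuated reading of the same motion. Both
are first-class and the pipeline reports them side by side; `beta_only` is
the default because it is the unbiased recovery estimator and matches the
monomer-axis convention of the curvature literature. Angles are folded to
[0°, 90°] (lines, not rays). One small geometric caveat, asserted in the
tests: a finite helix with a non-integer number of turns has its PCA axis
tilted ~0.3° off the geometric helix axis, which shows up as a
θ-proportional ~2e-5 relative offset — negligible against the statistical
error of any windowed mean.

**RMSF.** Alignment reference is the iterated mean structure (fit to the
plain frame average, re-average, fit again), the standard way to remove
rigid-body inflation. Windows are half-open `[t_start, t_end)` ps
everywhere, mapped by flooring on the frame interval. The RMSF window for
ΔRMSF defaults to the field-on window and the matching window of the
ambient run.

**Secondary structure.** The full-accuracy classifier (STRIDE-like,
hydrogen-bond based) needs full backbone geometry, out of scope here; the
`ca_geometry` mode uses P-SEA-style Cα pseudo-geometry (helix:
d(i,i+3) ∈ [4.8, 6.2] Å and d(i,i+4) ∈ [5.8, 7.2] Å over 4-residue runs;
sheet: d(i,i+2) ∈ [6.4, 7.4] Å over 3-residue runs with near-straight
pseudo-dihedrals), locked by tests on ideal geometries. `labels` mode
counts the static annotations.

**Dipoles.** The dimer is net-charged, so `μ` depends on the reference
point; it defaults to the mass-weighted COM and is always recorded in the
output. Conversion fixed at 1 e·Å = 4.80321 D. Histidine is excluded from
the salt-bridge basic set by default (δ-protonated, neutral His), and the
3.2 Å cutoff is inclusive.

**Distances and distributions.** Probe points default to the probe
residue's mass-weighted COM (`residue_com`); `sidechain_tip` and `ca` are
flags, since no atom convention is universal for named-residue distances.
Quartiles use the linear-interpolation (type 7) convention; histograms are
density-normalized.

**MSD.** Sliding time origins by default (single-origin by flag), fitted
with an intercept: frame-wise bend/elongation draws add an iid COM jitter
that contributes a constant offset to MSD at all lags ≥ 1, which the
intercept absorbs while the slope estimates 6D. The diffusion check fits
lags 1–10 (25–250 ps), where the sliding-origin estimator's variance is
lowest.

**Numerical conventions.** Coordinates are Å, times ps, fields kV/cm (a
converter handles V/Å and V/m exactly); PDB round-trips are exact to the
format's 3 decimals and annotations are exact through the TSV sidecar;
sub-1e-9 Å displacements after superposition are clamped to zero so strict
thresholds behave on identical inputs; selection resolution is
deterministic (ascending atom id) and empty resolutions are errors naming
the selection.

## Problem sizes and verification

Standard-scale recovery runs use 2000 frames (50 ns at 25 ps/frame) of the
140-atom dimer; distribution windows default to the last half ("last 5 ns
of exposure" convention scaled to the fixture length); tiny fixtures for
end-to-end pipeline checks use 50 frames across the 17-condition matrix.
At these sizes the ambient and negative-transverse bend means are
recovered within two standard errors of 5.9° and 8.2° (a ±2 SE check
carries its intrinsic ~5% false-alarm rate), per-residue fluctuation SDs
within 10%, the Einstein slope within 20%, and probe-distance shifts are
strictly ordered across 50/100/200 kV/cm with sign flip under field
reversal. Every such number stated here is computed by the test suite or
the acceptance script, not asserted.

## Limitations

- The generator's bend pivot and axis are conventions; only the angle
  distribution is ground truth, so cross-software comparison of absolute
  pivot-dependent quantities is out of scope.
- Dipole magnitudes of net-charged systems are reference-dependent; the
  package refuses to report them without recording the reference, and no
  claim is made of matching any particular published absolute dipole.
- `combined`-mode bend readings are attenuated by construction (above);
  compare them only against other combined-mode readings.
- The DCD reader is optional plumbing behind the same contract as the
  multi-model PDB dialect; PDB remains the required, human-writable
  fixture format.
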