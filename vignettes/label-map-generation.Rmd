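---
title: "Generating voxel-aligned label maps for cryo-EM map enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating voxel-aligned label maps for cryo-EM map enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryolabel)
```

## Scope and model

`cryolabel` turns a deposited experimental cryo-EM density map and its
atomic biological assembly into supervision targets for voxel-wise
learning: a density regression map, a three-class structure/background
classification map, and a six-class atom-type map, all sharing the
experimental grid voxel for voxel, plus an unmasked map-model FSC
validation of the result. The package assumes single-particle maps in
MRC2014 files and assemblies in fixed-column PDB format (`.pdb1`, possibly
multi-MODEL); mmCIF is not supported.

The method rests on three modeling choices:

* **Idealized density by real-space convolution.** The clean reference
  density is a sum of isotropic Gaussians centered on atoms. No electron
  scattering factors, B-factor blurring, or Fourier-space synthesis: the
  target is a geometric, noise-free representation of occupancy, not a
  physical scattering model. Uniform atom weights are the default; an
  atomic-number weighting is available (`amplitude_mode = "element"`).
* **Index mapping by truncation.** An atom at (x, y, z) maps to indices
  `i = floor((z - origin_z)/voxel_z)` (likewise j↔y, k↔x). Truncation
  loses up to one voxel of accuracy; the 6 Å neighborhood labeling exists
  precisely to compensate, so no rounding refinement is attempted.
* **Dual validation.** An atom contributes labels only when its index is
  valid in the experimental grid *and* its coordinate falls inside the
  simulated map's extent, guaranteeing labels describe regions present in
  both maps. When the simulated map is generated internally on the aligned
  grid (the `run_record()` path) the second check reduces to the first.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `voxel_target` | Å | 1.0 | common grid for learning across heterogeneous depositions; 2 Å Nyquist comfortably covers the 1–4 Å resolution window |
| `neighbor_radius` | Å | 6.0 | covers the density falloff around an atom at high resolution and absorbs the ≤1-voxel truncation error; configurable per run |
| `kernel resolution` | Å | 2.0 (fixtures) | FWHM of the Gaussian; for real entries pass the reported map resolution so model maps blur like the data |
| `kernel cutoff` | σ | 4 | keeps >99.8 % of kernel mass while bounding per-atom work |
| `res_min`, `res_max` | Å | 1, 4 | high-resolution selection window for curation |
| `origin_dialect` | — | `auto` | MRC ORIGIN record wins when nonzero, else start-indices × voxel; overridable because both dialects occur in the wild |

Distances for neighborhood membership are measured from the atomic
coordinate to voxel *centers*: coordinates are the only exact quantity in
the pipeline, and centers make membership independent of index
conventions.

## Numerical choices

* **Voxel-center inverse transform.** `indices_to_coords()` returns
  `origin + (index + 0.5) * voxel`, so the floor-based forward transform
  round-trips exactly on every in-bounds voxel — the invariant the test
  suite enforces grid-wide.
* **Unit-integral truncated kernel.** A Gaussian truncated radially at 4σ
  retains `pchisq(16, 3) ≈ 0.99887` of its mass, so the amplitude is
  divided by that factor; the truncated kernel then integrates to exactly 1
  and discrete sums conserve mass to lattice-aliasing error (≪ 1e-3 for
  σ ≥ 0.8 voxel). Kernels with σ below half the voxel size trigger an
  undersampling warning, not an error.
* **Resampling** interpolates trilinearly at output voxel centers; sample
  points outside the input's physical extent are zero-filled (solvent
  level), and the half-voxel ring between the boundary centers and the
  extent edge clamps to the edge value. Output dimensions are
  `ceiling(extent / target)`, so a trailing output voxel whose center lies
  past the input extent reads 0. Trilinear interpolation is exact on
  affine fields, which the suite exploits as an oracle.
* **Label precedence.** A direct atom voxel (class 1) is never demoted to
  neighbor (2) by nearby atoms. Atom-type collisions at one voxel resolve
  last-writer-wins except class 0 never overwrites a nonzero class — the
  simplest deterministic rule; the chemically ambiguous neighbor voxels
  carry no atom-type label at all.
* **Regression copying.** On the aligned grid the regression map is
  *identically* `simulated × (classification > 0)`. When a simulated map
  on a foreign grid is supplied, values are trilinear samples of that map
  at labeled voxel centers (both behaviors are exposed because published
  simulated maps need not share the experimental grid).
* **FSC shells** are one Fourier voxel wide (`1/(max(dim) · voxel)`) by
  default; the DC term is excluded and corner frequencies beyond Nyquist
  are discarded. Anisotropic voxels are rejected rather than approximated.
  Threshold crossing is linearly interpolated between shell centers; a
  curve that never drops below the threshold reports the Nyquist limit
  (2 × voxel), and one that starts below it reports `Inf` (unresolved).
* **Determinism.** MRC output contains no timestamps; all noise flows
  through a single integer seed. Reruns are byte-identical, which the
  suite checks by checksum.

## The synthetic fixtures

`make_helix()` builds an ideal poly-alanine α-helix (rise 1.5 Å, twist
100°, Cα radius 2.3 Å — giving the canonical 3.8 Å Cα–Cα spacing) with N,
C, O, Cβ at fixed ideal offsets in each residue's local frame.
`make_noisy_map()` layers two noise surrogates onto the clean simulated
map: seeded white Gaussian noise (for the shot/digital stages; default
σ = 0.05 density units against single-atom peaks of ≈ 0.10) and a few
wide Gaussian blobs placed preferentially away from the structure (for
structural noise with defined shape; default 3 blobs of σ = 2 Å, peak
0.1). These fixtures exercise every code path — resampling, labeling,
FSC — at desk scale.

What they do *not* emulate: CTF effects, projection/reconstruction
artifacts, resolution anisotropy, solvent flattening, conformational
heterogeneity, or nucleic acids (the labeler handles nucleotide O/N atoms,
but the fixture is protein-only). Passing tests therefore demonstrate the
correctness of the transforms and bookkeeping on realistic geometry, not
denoising performance on real micrograph-derived maps.

## Open design points, resolved

* **Resample sample points** use the voxel-center convention; whether the
  reference resampling in interactive tools samples centers or corners is
  undocumented, so exact parity with externally resampled maps is not
  claimed.
* **Hetero atoms** are included by default (`include_hetero = TRUE`):
  assemblies fully occupy their maps, and ions/ligands contribute real
  density; they can be excluded per run. Waters are dropped.
* **Curation redundancy** keys on `pdb_id`; the winner is the best
  (lowest) resolution, ties to the lexicographically smallest `emdb_id` —
  a documented choice, since the published selection rule among duplicates
  is unspecified.
* **Record contents.** `run_record()` writes the full five-map record
  (standardized experimental, simulated, three labels) plus a provenance
  sidecar, matching the published per-entry layout and naming.
* **Model maps for FSC** come from the same Gaussian kernel as the labels,
  not from a scattering-factor calculation; FSC values for real entries are
  therefore comparable to published ones only within a tolerance of a few
  tenths of an Ångström / one shell.

## Problem sizes

The shipped tests and the acceptance script run on 8–20-residue helices
(40–100 atoms) on grids up to 41×41×41 at 1 Å, with the FFT-vs-naive-DFT
oracle at 16³ and noise-monotonicity checks over 5 seeds × 4 noise levels
— sizes chosen so each property is exercised well inside a single-core
desk budget while keeping every count (neighbor sets, shell populations)
enumerable by brute force.

## Known limitations

Anisotropic target voxel sizes, Fourier-space (band-limited) resampling,
masked or half-map FSC, mmCIF input, and symmetry expansion from REMARK
records are out of scope. Big-endian MRC files are not read. Labels are
atom-centric: no per-residue or secondary-structure schemes, and no
soft/Gaussian class weighting.
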