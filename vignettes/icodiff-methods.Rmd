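---
title: "Difference mapping of icosahedral density maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference mapping of icosahedral density maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icodiff)
```

## Scope

`icodiff` quantifies where, and how strongly, substoichiometric proteins
occupy sites in icosahedrally averaged cryo-EM reconstructions, by
comparing a complete particle with deletion mutants. This vignette is the
package's own account of the model behind each stage, the tunable
parameters and their defaults, what the synthetic phantoms do and do not
emulate, and the numerical choices a maintainer should know about.

## Symmetry machinery

All geometry derives from the 60-element icosahedral rotation group *I*,
built by closure from a five-fold and a two-fold generator and stored in a
fixed **222 orientation**: the three mutually perpendicular two-fold axes
lie on the coordinate axes, so the five-fold axes point along cyclic
permutations of $(0, \pm 1, \pm\varphi)$ with $\varphi$ the golden ratio.
No convention is canonical for this symmetry; everything downstream is
covariant with the choice, so one fixed, documented setting keeps axis
positions reproducible. Axis direction sets are extracted from the group
elements themselves (eigenvectors of eigenvalue 1) rather than hard-coded:
12 five-fold, 20 three-fold and 30 two-fold directions, antipodal pairs
counted separately.

`symmetrize()` averages a map over the 60 rotations with trilinear
resampling about the grid center voxel (index `N %/% 2 + 1`; samples
falling outside the grid contribute 0). Trilinear interpolation is chosen
for simplicity and speed; its error on a feature of Gaussian width
$\sigma$ voxels is of order $1/(8\sigma^2)$ per pass, i.e. a few percent
for features two to three voxels wide. Consequently the symmetry
invariants (sphere invariance, mean preservation, idempotence) hold to
interpolation tolerance — percent-level — not to machine precision, and
the tests assert them at that level. Phantoms are built analytically
symmetric instead of being symmetrized, so this error never enters the
pipeline itself.

## Volumes, thresholds, normalization

Density units of single-particle reconstructions are arbitrary, so maps
must be placed on a common scale before subtraction. The package follows
the volume-matching strategy:

* The expected shell protein volume is
  $V = n \cdot m / (N_A \rho)$ — by default 120 copies of an 84 kDa
  protein at 1.41 g/cm³, about $1.19\times10^4$ nm³.
* `threshold_for_volume()` picks the density level whose enclosed volume
  is closest to $V$ (the $k$-th largest voxel value with
  $k = V / v_\mathrm{voxel}$, rounded). The achieved volume is reported;
  it can differ from the target by up to one voxel volume.
* Each map is standardized to mean 0, standard deviation 1 over the union
  of a **background annulus** and its **own** shell mask. Standardizing
  to 1 (the common value is not otherwise determined) makes σ-based
  contour levels directly interpretable. Using each map's own shell mask
  accommodates slight mask differences between mutants; an
  `"intersection"` option is available.
* Optional per-shell **radial scale factors** are the ratio of
  shell-masked radial averages against the reference (complete) map.
  Shells with undefined or near-zero masked means (below
  $10^{-6}\times$ the global density standard deviation) get factor 1.
  On phantoms with a shared shell construction the factors are all close
  to 1 and the difference maps change negligibly with or without them,
  which is why the stage is safe to leave on by default.

The annulus default is $[0.40, 0.47]\times$ the box edge — inside the box
but outside any reasonably sized particle, and clear of the apodized
boundary of a real reconstruction. These radii are configuration, not
science; they must be adapted to the particle at hand.

For grid-scaled-down phantoms the paper-scale mass budget exceeds the
phantom shell's entire volume, so `pipeline_config()` accepts an explicit
`target_volume_nm3`; `phantom_target_volume()` supplies the analytic
volume of the band $|r - R| \le \sigma_\mathrm{shell}$,
$4\pi R^2 \cdot 2\sigma_\mathrm{shell}$, which thresholds the phantom
shell at its one-sigma level.

## Difference maps and site detection

Subtraction is voxelwise on the normalized maps. The three maps obey the
exact algebraic identity
$(C-A) + (C-B) + (A+B-C) = C$; the package computes all three terms
(`subtract_maps()`, `composite_p14()`) and the test suite verifies the
identity to $10^{-9}$ — it is pure arithmetic and any violation indicates
a normalization bookkeeping bug.

`detect_axis_sites()` searches, for each axis direction, the
maximum-density voxel within a cylinder about the axis (default radius
0.15 × the outer band radius), restricted to a radial band (default
$[0.5, 0.95]\times$ the shell radius — the protein sites lie on or inside
the shell) and to that direction's hemisphere. A voxel inside two
cylinders is assigned to the angularly nearer axis; a winning peak within
1° of two axes raises a warning. The detection threshold is expressed in
multiples of a reference σ, by default the standard deviation of the
whole difference map — the same convention as a σ contour level in
isosurface rendering, where "2 σ" is the conventional difference-map
contour. The reference is overridable (`sigma = 1` gives absolute
normalized units). Counts are monotone non-increasing in the threshold by
construction.

Peak coordinates are recorded in full (not just the radial position)
because not every protein sits on its axis: the cofactor forms a ring of
three subunits around each three-fold axis, so its peaks lie 15–18 Å off
axis and the pipeline searches the cofactor difference map with a 1.5×
wider cylinder.

## Occupancy

Occupancy interpolates the site density between two anchors measured on
the normalized scale:

$$\mathrm{occ} = \frac{\bar\rho_\mathrm{site} - \bar\rho_\mathrm{bg}}
                      {\rho_\mathrm{P1,ref} - \bar\rho_\mathrm{bg}}$$

with $\rho_\mathrm{P1,ref}$ the mean of the top `reference_quantile`
(default 1%) of shell-mask densities — a robust reading of "the highest
density region of the fully occupied shell" — and the annulus mean as 0%.
The ratio of differences makes the estimate invariant under any affine
intensity transform applied jointly to the map(s).

Two design points matter in practice:

* **Where the site density is read.** In a full map the shell's radial
  tail contaminates sites that sit near it. The pipeline therefore reads
  complete-particle site densities from the *difference* maps, where the
  shell cancels exactly, while the 100% reference comes from the
  complete map (`reference_map` argument). Occupancies read directly off
  a mutant map are also reported but are cruder for exactly this reason.
* **Site masks.** The pipeline places small spheres (default radius 4 Å)
  at the detected difference-map peaks. Averaging over large
  threshold-derived blobs systematically underestimates peak-referenced
  occupancy (the mean of a Gaussian over its supra-threshold region is
  well below its peak).

The estimator is position-conditional: it counts density at the nominal
sites only and cannot see copies displaced elsewhere, so a mutant in which
a protein delocalizes will show reduced occupancy at the nominal site even
at unchanged stoichiometry. Estimates are deliberately not clipped to
$[0,1]$; values outside a small tolerance are flagged, since they signal
scaling or mask problems. `max_occupancy(available, total)` expresses the
complementary geometric bound: when only 12 of 20 visible sites can be
simultaneously occupied, occupancy cannot exceed 0.6.

Known limitation: low-pass filtering attenuates a blob of width
$\sigma_b$ by roughly $(\sigma_b/\sigma_\mathrm{eff})^3$, so proteins
small relative to the filter resolution are biased low by several percent
to ~15%. The polymerase (11 Å width at a 16 Å cutoff) loses a few
percent; a 6 Å feature would lose far more. This mirrors the real
situation — occupancy from filtered maps is a crude estimate — and is why
the validation tolerances below are ±0.10.

## Fourier shell correlation

`fsc_curve()` computes, per spherical frequency shell,
$\mathrm{FSC}(s) = \mathrm{Re}\sum F_a \bar F_b \big/
\sqrt{\sum |F_a|^2 \sum |F_b|^2}$, with shells assigned by
nearest-integer radius in frequency voxels (voxel counts recorded so
degenerate shells are visible; zero-power shells report `NA`).
`resolution_at_cutoff()` reads $1/f^\*$ at the first crossing below the
cutoff with linear interpolation between shells; a curve that never
crosses reports an explicit "better than Nyquist" outcome, and a curve
already below the cutoff at its first shell is an error. The conventional
0.5 cutoff is the default. Resolutions of real reconstructions depend on
the raw particle images, which this package does not process; the test
suite instead verifies the property that matters — half-maps built with a
known signal band recover the constructed resolution within one shell
width (±15% asserted over ten seeds).

## The phantom generator

`generate_procapsid()` emulates an icosahedrally averaged, unexpanded
procapsid map:

* a spherical shell with Gaussian radial cross-section (radius 80 Å,
  σ 8 Å at default scale) with **recessed five-fold vertices**
  (subtractive Gaussian dimples, depth 0.5 × shell amplitude) — the
  dodecahedral unexpanded architecture;
* a **motor blob** on each five-fold axis at the outer surface (88 Å);
* a **polymerase blob** on each three-fold axis inside the shell (60 Å,
  σ 11 Å — a realistic footprint for a ~75 kDa polymerase);
* **three cofactor blobs** ringing each three-fold axis (66 Å radius,
  15° off axis, σ 8 Å), placed as the 60-point group orbit of one seed
  point so the construction is exactly symmetric;
* an optional diffuse central Gaussian and white voxel noise (default
  0.1 × shell amplitude).

**Occupancy is amplitude.** In a symmetry-averaged map a site occupied in
a fraction $f$ of particles appears at $f$ times full density, so the
generator scales blob amplitudes by occupancy; blob amplitudes default to
the shell amplitude so full occupancy meets the estimator's 100%
reference. Default occupancies are 0.5 (polymerase), 0.57 (cofactor), 1
(motor) — the complete-particle regime this analysis targets.

`generate_mutant_triple()` derives the deletion mutants from one set of
noiseless components: the cofactor-minus particle drops the cofactor and
inflates the diffuse central density (×1.6, a delocalized polymerase);
the polymerase-minus particle drops the polymerase, halves the motor
density, reduces the cofactor to a third and the central density to 0.3 —
mirroring the qualitative interdependencies observed in such mutants.
Each map gets an independent noise realization seeded from the spec, so a
fixed seed is bit-reproducible.

What the phantoms do **not** emulate: projection imaging, CTF,
orientation error, structural noise correlated with the particle,
flexible or partially ordered density, RNA, and the expanded particle
state. Passing tests therefore demonstrate the correctness of the
analysis pipeline under controlled conditions, not the accuracy of
occupancy estimation on arbitrary experimental maps.

## Numerical choices and degenerate inputs

* **Filter roll-off.** The low-pass filter uses a raised-cosine edge of
  full width 0.5 × the cutoff frequency (transfer 1 below
  0.75 f_c, 0 above 1.25 f_c), which suppresses ringing in difference
  maps; a sharp cutoff is available. Whether any given historical
  pipeline used a sharp or apodized kernel is generally unknowable, so
  both are exposed. The DC term is never touched.
* **Grid conventions.** Cubic grids only; the center voxel is
  `N %/% 2 + 1` (1-based); radii are measured from it; even N supported.
* **MRC I/O.** MRC2014 mode 2 only (32-bit float), nx = ny = nz, voxel
  size from `cella/mx`. Malformed headers, non-cubic volumes and
  truncated files are hard errors. Densities round-trip bit-exactly once
  they are float32-valued.
* **Problem sizes.** The default phantom (96³) runs the full pipeline in
  a few seconds; the validation suite uses 96³ where the study
  conditions demand it and 48³–64³ phantoms with proportionally scaled
  geometry (and a proportionally scaled 10 Å filter) elsewhere.
* **Degenerate inputs.** Empty shells/masks warn or error explicitly;
  zero-variance scaling regions, inverted shell/background contrast,
  sub-Nyquist filter targets and oversized volume targets are errors;
  empty FSC shells and empty radial shells report `NA`, never silent 0.

## Validated properties

The test suite computes, among others: group order/closure and axis
counts (12/20/30); the decomposition identity to $10^{-9}$; exact
agreement of the volume-matched threshold with a sort-and-index oracle;
detection of exactly 20 polymerase sites on the fully occupied phantom
triple at the 2 σ contour (and of a seeded 12-of-20 subset at exactly the
chosen axes); FSC resolution recovery within ±15% over ten seeds; and
occupancy recovery at 0.25/0.5/0.75 within ±0.10 with correct ordering.
All quantitative statements in this vignette and the README are produced
by that code.
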