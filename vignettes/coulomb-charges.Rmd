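---
title: "Measuring charges and hydrogen positions in Coulomb potential maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring charges and hydrogen positions in Coulomb potential maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empot)
```

## The physics being exploited

Electrons are scattered by the electrostatic (Coulomb) potential of a
specimen, not by its electron density. Two consequences drive everything in
this package:

1. **Hydrogens are relatively strong electron scatterers.** In a
   sub-1.2 Å single-particle reconstruction, an Fo–Fc difference map
   against a hydrogen-omitted model shows positive peaks at most hydrogen
   sites, and the peak-to-parent distance carries chemical information: it
   sits near the internuclear distance (electrons feel the proton), whereas
   X-ray hydrogen peaks sit at the bond-polarized electron centroid,
   markedly closer to the parent atom.

2. **Charged atoms scatter very differently at low spatial frequency.**
   The electron scattering factor of an anion, obtained from the X-ray form
   factor through the Mott–Bethe relation
   \[
   f_e(s) = \frac{m_0 e^2}{8 \pi \varepsilon_0 h^2}\,
            \frac{Z - f_x(s)}{s^2},
   \]
   diverges toward $-\infty$ as $s \to 0$ for a net negative charge and
   converges to the neutral curve for $s \gtrsim 0.2$ Å$^{-1}$
   (resolutions better than about 2.5 Å). Deprotonated carboxylates
   therefore leave *negative* difference density that lives almost entirely
   in the low-resolution bands, which is the signature used to attribute
   negative densities to charge rather than radiation damage.

A partially charged atom with fractional charge $q$ ($|q| \le 1$) is
modelled as the linear combination
$f_q(s) = (1-|q|) f_{\text{neutral}}(s) + |q| f_{\text{ion}}(s)$.

## Scattering-factor tables and conventions

Neutral atoms use a published five-Gaussian parameterization of elastic
electron scattering factors; ionic curves are synthesized via Mott–Bethe
from tabulated ionic X-ray form factors (the oxygen anion row, the one
charged species the analyses need). Provenance is recorded in
`inst/extdata/scattering_factors.json`. Two numerical choices matter:

* The neutral X-ray rows are renormalized at load so $f_x(0) = Z$ exactly.
  The published fits carry residuals of order $10^{-3}$ electrons, which
  the $1/s^2$ in Mott–Bethe would otherwise blow up into a spurious
  divergence at very small $s$.
* Spatial frequency is $s = \sin\theta/\lambda = 1/(2d)$ throughout, and
  every public interface also accepts resolution $d$ in Å, so the axis
  convention can never be silently mixed up.
* For a *positive* fractional charge on an element with no tabulated
  cation (oxygen), the curve is extrapolated linearly in charge through
  the anion: the dominant term of the charged-minus-neutral difference is
  the net-charge Coulomb term $\propto -q/s^2$, which is odd in $q$, so
  charge reflection is the correct leading-order behaviour. This supports
  the antisymmetry property ($q \to -q$ flips the difference map's sign)
  and is a deliberate idealization, documented rather than hidden.

The Mott–Bethe route reproduces the tabulated neutral electron curves to
better than 1% for C, N and O over $s \in [0.05, 0.5]$ Å$^{-1}$. Hydrogen
is the known weak case (deviations up to ~25% at low $s$, because
$Z - f_x$ is a small difference of comparable numbers); hydrogen always
uses the electron table directly.

## From model to map

Structure factors on the reciprocal grid of a chosen voxel sampling are

\[
F(\mathbf h) = \sum_j o_j\, f_j(s_h)\, e^{-B_j d^{*2}/4}\,
               e^{2\pi i \mathbf h \cdot \mathbf u_j},
\]

with occupancy $o_j$, isotropic B-factor $B_j$, $d^* = 1/d$, and
fractional coordinates $\mathbf u_j$ in an orthogonal P1 box. Both the
Debye–Waller factor and the phase factorize along the three axes, so the
implementation evaluates per-axis vectors and outer-product indexing; a
naive double loop over reciprocal voxels and atoms serves as the test
oracle. Maps are synthesized by zeroing coefficients outside a resolution
band and inverse FFT.

Conventions, all of which are exercised by tests:

* **Grid:** node-centered voxels (value at $i \cdot \text{voxel}$ from the
  box corner), periodic box, default voxel $d_{\min}/4$ so that sub-voxel
  peak interpolation is accurate to well under 0.02 Å.
* **Bands** are half-open in $d^*$: $[1/d_{\text{low}}, 1/d_{\text{high}})$.
  A $d_{\text{low}} \ge 100$ Å means "all low frequencies"; the F(0) term
  is always excluded, so synthesized maps have zero mean and a
  well-defined σ.
* **σ** is the RMS deviation from the mean over *all* voxels of the box,
  with no mask. Contour-level statements (2σ, 4σ) depend on this choice,
  and a masked σ would change them.
* Nyquist planes of even-dimension grids are zeroed (they cannot carry a
  conjugate-symmetric pair), guaranteeing a real synthesis.

Difference maps are the unweighted Fourier difference
$\Delta(\mathbf h) = F_o(\mathbf h) - F_c(\mathbf h)$ over the band by
default. The production tools around the original analysis use a
likelihood-weighted difference; the charge and hydrogen signatures tested
here survive the simple scheme, and an optional per-shell weight
$w = \sigma^2_{\text{signal}} / (\sigma^2_{\text{signal}} +
\sigma^2_{\text{noise}})$ estimated from half maps is provided for noisy
data. Difference maps are stored in their own σ units with the absolute
scale retained (`sigma_raw`), because cross-band comparisons (the charge
trend) must be made on a common absolute scale while display conventions
are per-map σ.

## Hydrogen peaks and bond-type statistics

Peaks are 26-neighborhood local maxima at or above the threshold, refined
by a least-squares quadratic fit to the 3×3×3 neighborhood (Newton step,
clamped to half a voxel). Ties between equal neighboring voxels are broken
lexicographically so a plateau yields one peak. Against a dense-grid
argmax oracle the refined positions are accurate to a few 10⁻³ Å at the
default sampling — an order of magnitude inside the 0.02 Å budget.

Assignment to hydrogen sites replaces the original *manual* selection by a
deterministic rule: peaks are matched greedily in order of decreasing
height to the nearest ideal riding position within `max_offset` (default
0.5 Å, roughly half a C–H bond; large enough for noise-displaced peaks,
small enough not to cross to a neighboring site), one peak per site.
Distances are measured from the refined peak to the *parent* heavy atom.

Bond types follow residue-template lookup: aromatic-ring carbons →
`Caro-H`; sp³ carbons with 1/2/3 hydrogens → `Calk-H`/`C-H2`/`C-H3`;
nitrogens → `N-H` with lysine side-chain NZ flagged and excluded from
statistics (solvent-facing amines); hydroxyl oxygens → `O-H`; the
aggregate `C-H` is the union of `Calk-H` and `Caro-H`. The standard
deviation is the sample (n−1) convention and is reported only for n ≥ 2.

## The synthetic-data generator

The generator stands in for a deposited ~1.2 Å apoferritin map at desk
scale. It builds an extended polypeptide (idealized backbone geometry;
side chains grafted from idealized residue templates), places riding
hydrogens at either internuclear ("nuclear": C 1.09, C-aromatic 1.08,
N 1.02, O 0.98 Å) or electron-centroid ("electron": 0.97/0.93/0.86/0.84 Å)
reference distances, draws per-atom B-factors uniformly from a configurable
range, and synthesizes band-limited maps at 1.19 Å by default. Half-map
pairs add independent white Gaussian noise; dose (frame) series scale the
noise variance as $1/n_{\text{frames}}$ with the signal fixed, optionally
inflating B with accumulated dose to emulate damage.

Two B-factor ranges appear in the package's own validation, both taken
from the study conditions the generator emulates:

* **10–35 Å²** — the default, spanning the B values reported for ordered
  side chains in maps of this resolution.
* **10–20 Å²** — used for the hydrogen-distance recovery fixtures, because
  the hydrogen statistics in the emulated analysis are built from
  hydrogens riding on well-ordered parents (the original procedure retains
  hydrogens whose parent atoms average B ≤ 20 Å²).

What the generator does *not* emulate, and hence what passing tests do not
show about real data: reconstruction noise is colored, not white; real
maps are sharpened by post-processing while simulated maps are
unsharpened; there is no CTF, no Ewald curvature, no conformational
heterogeneity, and no solvent. Synthetic acceptance checks are therefore
either noiseless identities or sign/trend properties, never absolute σ
levels.

### A known systematic: peak coalescence of paired hydrogens

In an unsharpened band-limited map, the two (or three) hydrogens riding a
single parent (`C-H2`, `C-H3`, amide NH₂) are 1.6–1.8 Å apart and their
band-limited peaks pull each other inward. The bias grows steeply with B:
class means come out ~0.02 Å short at B ≈ 10–20 Å² and ~0.1 Å short by
B ≈ 30 Å². Isolated hydrogens (Cα–H, aromatic H, backbone amide H,
hydroxyl H) are unaffected at any B in range. Tests therefore assert
0.02 Å recovery for the isolated classes and the aggregate `C-H`, and a
slightly wider band for the paired classes, with this paragraph as the
explanation. Sharpened experimental maps resolve the pairs and do not show
the bias at the same magnitude.

The distance-vs-peak-height trend (lower peaks appearing farther from the
parent) is reproduced on noisy synthetic maps for isolated hydrogens: the
positional jitter of a low, broad peak inflates $|\mathbf r_{\text{true}} +
\boldsymbol\varepsilon|$ on average. For paired hydrogens the coalescence
pull dominates and the trend reverses — a caveat worth remembering when
interpreting per-class trend tables.

## Charge detection

`negative_density_metric` reports, per atom, the minimum map value within
a radius (default 1.0 Å, about a covalent bond length) and the integral of
values at or below −4σ (the display level at which the original analysis
contours negative densities). The resolution-series analysis applies this
across bands with a fixed high-resolution limit of 2.5 Å and low-resolution
limits of 100, 20, 10, 5 and 3.3 Å, plus the complementary 2.5–1.19 Å
band; on noiseless synthetic data with q = −0.3 carboxylate oxygens the
signal is strongly negative in the widest band, decreases monotonically as
low-resolution data are omitted, and is absent (below 1σ of the wide-band
map) in the high-resolution band. The dose-series variant checks that the
signal does not fade at lower accumulated dose, the control that
distinguishes charge from radiation damage. All charge analyses remain
qualitative (sign and trend), matching the scope of what difference-map
densities can support without conversion to electron density.

## Half-map model precision

The coordinate-uncertainty metric refits the same model independently into
each unfiltered half map and reports the RMSD between the two refits
(non-hydrogen atoms by default, matched by residue number and atom name,
no superposition since both refits live in the map frame). The original
procedure used restrained molecular-dynamics refinement per half map; this
package substitutes a deterministic local refit — each heavy atom moves to
the local maximum of the Fourier-interpolated density within `max_shift`
(default 0.5 Å) by damped Newton ascent with backtracking. The surrogate
preserves the metric's logic (independent fits to independent noise
realizations); it is *not* expected to reproduce the published 0.05–0.07 Å
value, which depends on restraints and the real data. Properties that do
hold and are tested: identical halves give exactly 0; the metric grows
monotonically with half-map noise; on well-separated atoms the refit is a
fixed point of its own noiseless map to <0.01 Å. In merged density
(bonded atoms at high B) the local maximum is displaced from the atom —
both refits displace identically, so the difference metric remains valid
even though individual refit positions are biased.

The Fourier shell correlation uses one reciprocal voxel as the default
shell width, excludes F(0) and Nyquist planes, drops shells with no power,
and interpolates threshold crossings (0.143 for the gold-standard half-map
criterion) linearly between shell centers.

## Micrograph proximity curation

Stage positions are scanned in acquisition order; a micrograph is removed
if it lies closer than 1.5 µm to *any* earlier acquisition, retained or
not — earlier exposures irradiate the area regardless of whether their
images were kept. The comparison is strict (< 1.5 µm removes). The
retained set is therefore well-separated only with respect to earlier
exposures, not necessarily mutually. Removal decisions depend on
acquisition order, and a constructed test demonstrates that permuting the
order changes the retained set.

## Problem sizes used in the validation suite

The recovery fixtures use a 20-residue chain (135 hydrogens, ~2 × 10⁵
voxels within the resolution cutoff), small charged peptides for the band
series, and 8-atom sparse models for refit properties — sizes chosen so
the full suite and the acceptance script each run in a couple of minutes
while every check exercises the same code paths as a full-size map.

## Known limitations

* Orthogonal P1 boxes only; no crystallographic or point-group symmetry.
* Isotropic B only; anisotropic displacement is out of scope.
* The unweighted difference map is a simplification of likelihood-weighted
  production maps; absolute σ levels of difference features will differ.
* Charge quantification is relative/qualitative; no absolute charge fits.
* Residue-template coverage is the standard amino acids shipped in
  `inst/extdata/residue_templates.json`; ligands would need new templates.
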