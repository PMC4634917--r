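---
title: "Backpropagation for full-view optical diffraction tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backpropagation for full-view optical diffraction tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difftomo)
```

## The physical model

A specimen with refractive index n(r) immersed in a medium of index
n~m~ is illuminated by a plane wave u~0~ = exp(i k~m~ z),
k~m~ = 2π n~m~/λ. Within scalar theory the field obeys the Helmholtz
equation, and the quantity the inverse problem targets is the object
function (scattering potential)

$$ f(\mathbf r) = k_m^2\left[\left(\frac{n(\mathbf r)}{n_m}\right)^2 - 1\right]. $$

The specimen rotates through a full turn; for each angle φ the complex
detector field u/u~0~ is recorded (the package stores fields
background-normalized, so u~0~ ≡ 1 at the detector). Three linearizations
connect the data to f:

* **Born** — the scattered field is a small additive perturbation,
  b = u/u~0~ − 1. Linear in f, no unwrapping, but the approximation fails
  once the total phase delay through the object approaches a radian.
* **Rytov** — the complex phase is the perturbation,
  φ~R~ = ln|u/u~0~| + i·unwrap(arg u/u~0~). The same linear inversion
  applies with φ~R~ in place of b; its validity is governed by the
  *gradient* of the refractive-index variation rather than the total phase
  delay, which is why it is the method of choice for cells.
* **Radon** — straight-ray phase projection, inverted by filtered
  backprojection. No diffraction; serves as the classical baseline.

The Fourier diffraction theorem states that the 1D (2D) transform of b at
angle φ samples the rotated object spectrum on the Ewald arc (cap)
$\mathbf k = (k_{Dx}[,k_{Dy}],\,\gamma - k_m)$,
$\gamma = \sqrt{k_m^2 - k_\perp^2}$, weighted by i/(2γ) and the propagation
phase to the detector plane. Frequencies with k~⊥~ ≥ k~m~ are evanescent —
they carry no far-field information and are cut, which is exactly a
numerical aperture of 1.

## The discrete backpropagation operator

Inverting the relation above over all angles, with the change of variables
from (φ, k~Dx~) to the frequency plane (Jacobian |k~Dx~| k~m~/γ, each point
covered twice over a full turn), gives the per-angle recipe implemented in
`backpropagate_2d()` / `backpropagate_3d()`:

1. pad the detector data and Fourier transform;
2. multiply by the ramp filter |k~Dx~| (only the x-frequency in 3D, since
   there is a single rotation axis y), the evanescent mask, and the depth
   kernel exp(i(γ − k~m~)(z′ − l~D~)) for every depth z′;
3. inverse transform each depth;
4. rotate the contribution into the laboratory frame (real-space bilinear
   interpolation, the same rotation helper the forward models use with the
   opposite sign) and accumulate with weight Δφ.

The global constant of the discrete sum, −i k~m~ Δφ/(2π) with
unitary-per-length FFT conventions, was derived from the package's own
forward convention (Weyl expansion of the free-space Green's function)
rather than transcribed from the literature, and is pinned by two
independent tests: a brute-force Green's-function summation must match the
FFT forward model to 1 % in L2, and weak-scattering round trips
(Δn = 10⁻³) must recover the phantom's mean contrast to within 5 % in both
2D and 3D. Because the DC frequency receives zero ramp weight, the
reconstruction loses a small uniform offset of order (object area)/(padded
area); at the default padding this stays well inside the 5 % calibration
band.

Sign conventions are fixed once: time convention exp(+i k~m~ z) for the
incident wave, rotation of the *object* by −φ in the forward direction, and
the grid center (= rotation axis) at 0-based index ⌊N/2⌋ on every axis for
even and odd N alike.

## Numerical choices

* **Units.** All lengths are in detector pixels (pixel pitch 1); the
  wavelength is supplied in pixels. `wavelengths_to_pixels()` converts
  object sizes quoted in wavelengths. Grids with fewer than two pixels per
  medium wavelength cannot carry the propagating spectrum and are rejected
  with guidance.
* **Padding.** Transforms that model propagation pad to the next power of
  two of twice the grid size. When the detector plane sits a distance l~D~
  from the volume center the padded length grows to cover 2N + 8|l~D~|:
  the FFT model is periodic, the scattered field spreads over ±l~D~ at
  NA = 1, and the cylindrical-wave tails of the periodic replicas decay
  only algebraically, so a generous margin is needed. For refocused data
  (l~D~ = 0, the default) this reduces to plain 2× padding.
* **Refocusing.** `propagate()` uses the angular spectrum on the field's
  own periodic grid (no padding), so propagation of band-limited fields is
  exactly unitary; evanescent components are zeroed. `autofocus()`
  minimizes the total forward-difference gradient of the field amplitude —
  a pure phase object in focus has a flat amplitude — over a 50-point
  coarse grid refined by golden-section search to λ/100. When the metric
  has several local minima in the interval the refined global grid minimum
  is returned and flagged.
* **Phase unwrapping.** 2D sinograms are unwrapped per projection with the
  simple cumulative-2π rule along the detector; 3D sinograms use
  quality-guided 2D unwrapping (reliability from wrapped second
  differences, edges sorted by reliability, groups merged with the integer
  2π offset that reconciles them — a noncontinuous path). Ties in edge
  reliability are resolved by the fixed enumeration order (horizontal
  edges column-major, then vertical), with a stable sort. The global 2π
  multiple is fixed by forcing the median phase on the detector border
  into (−π, π], since background pixels carry approximately zero phase.
* **Rotation.** Real-space bilinear interpolation about the grid center;
  values rotated in from outside the grid are filled with zero (forward
  models operate on f, which vanishes in the medium). Quarter-turn
  rotations are exact on the grid.
* **Degenerate inputs.** Reconstructed object functions can drive
  1 + Re(f)/k~m~² negative in artifact regions; `object_to_ri()` clamps
  the real part of the square-root argument at zero and reports the voxel
  count. Metrics reject a phantom uniformly equal to 1 (zero
  normalization).

## The error metrics

Reconstruction quality is summarized by two normalized errors over the
inscribed circle/sphere of radius N/2 (voxels outside it are not seen by
all projections and are excluded):

$$ E_{RMS} = \sqrt{\frac{\sum_{vol} (n_{ph} - n_{rec})^2}
                        {\sum_{vol} (n_{ph} - 1)^2}}, \qquad
   E_{TV} = \sqrt{\frac{\sum_{vol} \mathrm{TV}_{avg}(n_{ph} - n_{rec})}
                       {\sum_{vol} (n_{ph} - 1)^2}}, $$

with TV~avg~ the mean over axes of the absolute per-axis gradient. Both are
100 % when the residual is "as large as the phantom itself": E~RMS~ for
n~rec~ ≡ 1, E~TV~ when the averaged TV norm equals (n~ph~ − 1)² everywhere.
The common normalization makes 2D and 3D errors directly comparable, which
the suite verifies on extruded phantoms (slice-wise vs volumetric errors
within 5 percentage points).

Two conventions had to be fixed here. Gradients use per-pixel (not
per-wavelength) spacing — the only choice that keeps the TV ratio
dimensionless. And the forward difference at the final row/column
replicates the preceding difference instead of being set to zero: the
inscribed mask contains last-row pixels, and a forced zero gradient there
would make the 100 % anchor for a linear ramp unattainable; replicating the
difference is exact for ramps and identical everywhere else. TV gradients
are computed on the full grid before masking, so the mask boundary itself
contributes no spurious gradient.

## The phantom generator and what it does (not) emulate

`make_cell_phantom_2d()` / `make_cell_phantom_3d()` rasterize a
three-compartment cell: a cytoplasm disk/sphere of diameter 2a (default
17 λ), an ellipsoidal nucleus, and a small nucleolus, at refractive indices
1.365 / 1.360 / 1.387 in medium 1.333 — representative values for cells in
aqueous medium. Each voxel takes the index of the innermost compartment
containing its center, giving the piecewise-constant ground truth the
metrics need. The internal geometry beyond these published values is a
repository convention, chosen to be asymmetric and strictly nested and kept
fully configurable: nucleus semi-axes (0.6a, 0.55a, 0.55a) offset
(−0.1a, +0.08a, 0), nucleolus radius 0.12a centered at (2λ, 2λ, 2λ) for the
default cell and scaling proportionally with a. The minor semi-axes were
widened from an initial 0.5a because strict nucleolus-in-nucleus nesting —
which the constructor enforces by sampling the nucleolus surface — narrowly
fails at 0.5a with the nucleolus pinned at 2λ offsets. `ri_series(t)`
interpolates the compartment indices linearly from a uniform 1.334 (t = 0)
to (1.455, 1.435, 1.543) (t = 1) at fixed medium 1.333, covering and
exceeding the biological range.

The forward data are generated by the package's own scalar models:
`born_forward()` (Fourier-diffraction sampling, exact within first-order
scalar scattering on the grid), `rytov_forward()` (its exponentiation,
u/u~0~ = exp(b), for which the Rytov inversion is consistent), and
`radon_forward()` (ray integrals). A vectorial Maxwell solver is
deliberately out of scope. The consequences are worth stating plainly:
the simulated data contain no polarization effects, no multiple
scattering, no source bandwidth, and — unless `noise_sigma` is set — no
measurement noise. Reconstruction errors are therefore much smaller than
what FDTD- or experiment-referenced studies report at the same settings,
and passing tests demonstrate the correctness and internal consistency of
the reconstruction operators, not performance on real microscope data.
The optional noise model (circular complex Gaussian on the normalized
fields, seeded through R's RNG, off by default) emulates coherent
measurement noise without claiming any particular instrument's statistics.

## The quality studies at desk scale

`sweep_projections()`, `sweep_ri()` and `sweep_size()` rerun the three
systematic studies: one forward simulation per condition, all three data
filters applied to the same fields, each inverted with its matching
algorithm, both metrics recorded. Default problem sizes are chosen for
desk-scale runtimes — 2D grid 128 at λ = 4 px, 3D grid 48–64 at
λ = 3 px — rather than the FDTD-scale volumes of the original studies.
`plateau_onset()` finds the smallest sampled projection count from which on
every successive change of both metrics stays below a threshold (default
1 percentage point), with the first sample carrying no incoming change.

On clean Rytov-consistent data the projection-count curve of the default
phantom settles at about 100 projections (E~RMS~ ≈ 0.5–1.3 % throughout,
the plateau governed by E~TV~ alone), earlier than the ~160 projections
reported for FDTD-referenced data, whose model mismatch and coherent noise
keep per-step changes larger for longer. This is the expected signature of
approximation-consistent forward data and is reported as measured; the
generator's noise default was not changed to steer this number. The
ordering E~RMS~(Rytov) < E~RMS~(Born) and E~TV~(Rytov) < E~TV~(Radon), the
growth of errors with contrast and with object size at fixed volume, and
the 2D↔3D comparability all reproduce.

## Containers and interchange

Sinograms travel in a single-file container: a JSON header carrying the
full acquisition metadata (wavelength in pixels, medium index, detector
distance, approximation tag, shape, creator, optional seed) followed by
the raw angles and fields as little-endian IEEE-754 doubles — a
write/read round trip is bit-identical, and a missing attribute is
rejected by name. Volumes export as uncompressed 32-bit-float TIFF stacks
(one page per z slice, values unscaled); the package carries its own
minimal float-TIFF writer because the available R TIFF writers clamp
samples to [0, 1], and reads stacks back through `tiff::readTIFF` as an
independent cross-check.

## Known limitations

* Scalar, first-order forward models only; no vectorial effects, no
  multiple scattering, no exact Mie reference.
* Full-view, equally spaced sinograms only — no limited-angle or sparse
  variants, and no regularized or iterative reconstruction.
* Phase retrieval and rotation-axis alignment are upstream of this
  package: fields must arrive background-normalized with the rotation axis
  centered.
* Real-space bilinear rotation trades a small interpolation blur for
  robustness; quarter turns are exact, oblique angles agree with exact
  rotation at the few-percent level on sharp-edged objects.
* The single-axis geometry leaves the usual unsampled spectral region
  along the rotation axis; 3D reconstructions show the corresponding
  directional blur (apple-core artifact) by physics, not by defect.
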