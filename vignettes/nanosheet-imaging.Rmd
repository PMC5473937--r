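---
title: "Modeling interface-confined fluorescence excitation on a gold-nanoparticle sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interface-confined fluorescence excitation on a gold-nanoparticle sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lsprsheet` models why a two-dimensional sheet of small gold
nanoparticles, used as the substrate of a fluorescence microscope, images
the cell–substrate interface with far tighter axial confinement than TIRF
microscopy.  This vignette is the package's own account of the model: the
physics implemented, the parameters that matter and why their defaults
were chosen, what the synthetic data do and do not emulate, and the
numerical decisions a maintainer would want written down.

## 1. The three excitation fields

Three depth-response functions compete in this problem.

**Evanescent field.**  For light incident from glass (index $n_1$) onto a
water-side medium ($n_2 < n_1$) above the critical angle
$\theta_c = \arcsin(n_2/n_1)$, the transmitted intensity decays as
$I(z) = I_0\, e^{-z/d}$ with
$$d = \frac{\lambda}{4\pi\sqrt{n_1^2\sin^2\theta - n_2^2}}.$$
`penetration_depth()` implements this closed form; at
$\lambda = 561$ nm, $n_1 = 1.52$, $n_2 = 1.33$, $\theta = 65^\circ$ it
gives 124.37 nm, the conventional "$\sim$125 nm" TIRF sectioning depth.
No Fresnel transmission factor is applied at $z = 0$: all profiles are
relative to the interface intensity, which is how the comparison is
framed throughout.  Angles are degrees at every API boundary and radians
internally.

**Plasmonic near field.**  The sheet is a hexagonally close-packed
monolayer of spherical gold cores, diameter 12.6 nm, surface-to-surface
gap 2.6 nm (set by the interdigitated oleylamine ligands), i.e. a
center-to-center pitch of 15.2 nm.  Because the cores are two orders of
magnitude smaller than the wavelength, each is treated as a quasi-static
point dipole with polarizability
$\alpha = a^3(\varepsilon - \varepsilon_m)/(\varepsilon + 2\varepsilon_m)$,
$\varepsilon(\lambda)$ interpolated from the bundled Johnson & Christy
gold table and $\varepsilon_m = 1.33^2$ for water.  The dipoles couple
through the static dipole tensor
$\mathbf{K}(\mathbf{r}) = (3\hat{\mathbf{n}}\hat{\mathbf{n}}^\top - \mathbf{I})/r^3$
and the self-consistent system
$\mathbf{p}_i = \alpha\,(\mathbf{E}_0 + \sum_{j\neq i}\mathbf{K}_{ij}\mathbf{p}_j)$
is solved directly (one complex LU factorization, both in-plane
polarizations as right-hand sides).  The collective red shift of the
sheet's resonance emerges from this coupling; nothing is imposed.
Profiles are reported at the 488/561 nm laser lines, not at the
resonance peak, and the two in-plane polarizations are intensity-averaged
to emulate unpolarized epi-illumination.

The profile line follows the geometry used for the sheet's
intensity-versus-distance curve: the normal to the sheet through the
midpoint of two adjacent particles, with $D = 0$ in the plane of the
particle centers, so the nearest gold surface at $D = 0$ is half the gap
(1.3 nm) away.  On the default sheet at 561 nm the computed profile peaks
at roughly 150-fold intensity at the center plane and falls back below
the incident intensity near $D = 13$ nm — the quantities the test suite
and `scripts/acceptance.R` compute.

**Energy transfer.**  A fluorophore a distance $d$ from the nearest gold
surface transfers excitation to the metal at rate
$k = \tau_D^{-1}(d_0/d)^n$, with $n = 4$ for nanometal surface energy
transfer (NSET) and $n = 6$ for the Förster point-dipole law (both
supported; 4 is the default).  The surviving-fluorescence factor
$$\frac{I_d}{I_\infty} = \Bigl[1 + \bigl(d_0/d\bigr)^n\Bigr]^{-1}$$
is exactly $1/2$ at $d = d_0$.  The distance argument is always the
nearest-surface distance, also along the profile line — so the "LSPR
$\times$ SET" product combines two different distance variables on
purpose ($D$ along the line for the field, nearest surface for the
quenching).  Spectral-overlap-dependent transfer (PIRET) is not
modeled; the package works within the $d^{-4}$ description.

Because the characteristic distances of the curve family are not pinned
to single values experimentally, the profile study sweeps
$d_0 \in \{2, 5, 7, 10\}$ nm and labels outputs by $d_0$; the imaging
study uses $d_0 = 5$ nm, a mid-range value typical of dye–gold NSET
calibrations.

## 2. Patch size and other solver choices

The coupled-dipole patch is finite, and the profile's far tail is the
patch's most sensitive statistic: a uniformly polarized *infinite*
in-plane dipole sheet produces no net field above itself, but a finite
patch has edge depolarization that leaves the computed relative intensity
on a plateau below 1.  On a 13 × 13 patch that plateau sits near 0.85 for
$D$ = 12–50 nm, which distorts both the far-field limit and the
unity-crossing distance.  The default patch is therefore **21 × 21**
(452 particles; half-pitch-offset rows carry one extra particle so the
patch stays mirror-symmetric): the smallest odd patch for which the
profile is back within 10% of the incident intensity at three core
diameters and within 5% at 200 nm.  The convergence test compares the
21 × 21 and 25 × 25 peak statistics (they agree to a few percent); the
shallow unity crossing moves by $\sim$2 nm between successive patch
sizes, which is the honest uncertainty to attach to that number.

Other solver decisions:

* **Oracles, not FDTD.**  The solver is validated against the
  quasi-static single-sphere closed form (a one-particle patch must
  reproduce $|E/E_0|^2$ from
  $3\varepsilon/(\varepsilon+2\varepsilon_m)$-type expressions to better
  than 1%) and against a brute-force two-dipole system assembled
  independently in the tests (agreement to machine precision).  A
  time-domain grid solver would add nothing testable at this scale.
* **No substrate, no retardation.**  The host is uniform water; glass
  below the sheet and image-dipole corrections are neglected, as are
  retardation and radiative damping (cores $\ll \lambda$).  These limit
  absolute accuracy but not the relative depth profiles the package is
  about.
* **Material model.**  The solver interpolates the tabulated
  permittivity directly; the Drude fit (`fit_drude()`, window
  500–700 nm, residual recorded on the object) is provided for
  free-electron extrapolation and model checking, not used by the
  default solve — interband transitions make a pure Drude description of
  gold poor below $\sim$520 nm.

## 3. What the synthetic cell emulates

`generate_cell()` draws a fluorophore population mimicking a fixed,
actin-labeled adherent cell of $\sim$12 µm footprint:

| structure | geometry | z (nm) | default density |
|---|---|---|---|
| ventral layer | uniform disk | 5–50 | 50 µm⁻² |
| dorsal layer | uniform disk | 300–600 | 120 µm⁻² |
| stress fibers | 8 chords, 150 nm wide | 5–50 | 30 µm⁻¹ |
| focal adhesions | 30 spots, rim + center | 5–30 | 100 labels each |

Counts are Poisson (density × structure measure), positions follow the
configured geometry, brightness is log-normal, and a single integer seed
fixes everything.  Adhesions concentrate at the footprint rim and center
because that is where interface imaging of adherent cells localizes
them.  The dorsal density exceeds the ventral one because the 300 nm
dorsal slab integrates cortical plus cytoplasmic actin — this is exactly
the population that buries the interface detail in wide-field images, and
it is what makes the epi-versus-TIRF contrast in the simulated metrics.

z is measured from the top surface of the imaging substrate, positive
into the sample, for every modality.  For the sheet substrate a
fluorophore at height z is a distance $z + a + t_{cap} + t_{spacer}$ from
the plane of particle centers ($a$ = core radius, $t_{cap}$ = 1.3 nm
organic capping layer, $t_{spacer}$ = optional SiO₂ layer).  The spacer
enters only as this rigid offset: fluorophores cannot approach the gold
closer than the spacer allows.

Real cells are not this: there is no membrane, no receptor biology, no
fiber branching, no photophysics (blinking/bleaching), and absolute
ventral/dorsal z positions are assumptions (interface microscopy does not
measure them), all ranges being overridable.  Passing the imaging tests
therefore shows that the *optical orderings* follow from the geometry —
not that the generator reproduces any particular cell line.

## 4. Image formation and its metrics

Each fluorophore contributes `brightness × weight × exposure` expected
photons, spread by an *integrated* 2D Gaussian PSF of
$\sigma = 0.21\,\lambda_{em}/\mathrm{NA}$ (the Airy-core approximation;
pixel masses from `pnorm` differences, so the noise-free render conserves
photons to the $6\sigma$ kernel truncation, $\sim 10^{-9}$).  Poisson
shot noise, rounded Gaussian read noise, zero clipping and 16-bit
saturation follow.  Two practical notes: clipping biases *empty* pixels
upward by the positive half of the read noise ($\approx$ 0.6 counts at
1.5 rms), so mean-consistency checks run on pixels with real signal; and
at 160 nm pixels the PSF is near the sampling limit, so width estimates
are demonstrably poorer than at 65 nm — the package warns below
$\sigma = 0.1$ px.

Excitation weights per modality: epi and sub-critical oblique are
homogeneous (weight 1; oblique can carry an elevated uniform background
instead of a beam model); TIRF is $e^{-z/d}$; the sheet modality uses the
laterally averaged **bound** (scattered) near-field intensity
$|\mathbf{E}-\mathbf{E}_0|^2$ times the NSET attenuation, tabulated once
per height and interpolated.  Two deliberate choices here:

* **Lateral averaging.**  The lattice pitch (15.2 nm) is far below a
  65 nm pixel, so no camera pixel resolves the unit cell; the weight is
  the unit-cell average of the field at the fluorophore's height.
* **Bound field, not total field.**  The total relative intensity tends
  to 1 far from the sheet (the transmitted beam), which describes the
  *field*, but the depth-selectivity of the sheet as an imaging substrate
  comes from its surface-bound component; the uniform transmitted part is
  an epi-like background that real sheet images do contain to some
  degree.  The weight model therefore uses the bound intensity, and
  exposes the transmitted beam as a configurable `transmitted_fraction`
  (default 0).  Setting it to 1 recovers total-field behavior.  The
  profile curves of the profile study always use the total field.

Note the sheet weight is *not* monotone in z at contact: quenching wins
within a few nm of the gold, the weight peaks just beyond, then decays —
the same shape as the LSPR × SET product curves.  Monotonicity holds
beyond the quenching zone and is tested there.

Metrics: `ventral_fraction()` (share of total excitation reaching
ventral + fiber + adhesion tags) and `signal_to_background()`
((mean in-mask − mean out-of-mask)/sd out-of-mask, with the mask built
from the ground-truth adhesion/fiber positions dilated by the PSF
radius).  `compare_modalities()` runs both across setups and reports two
booleans: sheet metrics spread < 5% across illumination angles, and
glass metrics spread > 2× between sub- and super-critical illumination.

**Angles.**  The default study is in water ($n_2 = 1.33$,
$\theta_c = 61.0^\circ$), where a 65° arm is already evanescent; the
sub-critical oblique default is therefore 55°.  (In a glycerol-based
mounting medium, $n_2 = 1.46$, $\theta_c = 73.9^\circ$, 65° is oblique —
configure `optics$n2` and the angles accordingly.)  The sheet arms keep
0°/65°/75° because the bound excitation does not depend on the
illumination angle at all in this model; their metric spread across
angles comes only from per-image noise seeds.

## 5. Numerical details and degenerate inputs

* Singular coupled systems (driving a lossless synthetic material exactly
  at a collective resonance) error out with a message naming the
  resonant condition rather than returning garbage.
* Query points inside a core, TIRF below the critical angle, empty
  populations, all-zero densities, full/empty masks and zero background
  variance are rejected with directed messages.
* `fit_distance_exponent()` inverts the attenuation law through
  $\log(1/A - 1)$ and ordinary least squares; it requires $\geq 5$ points
  spanning $\geq 3\times$ in distance, returns a confidence interval, and
  recovers $n = 4$ and $n = 6$ exactly from noiseless curves (the
  perfect-fit warning from R's inferential summaries is suppressed as
  expected in that use).
* All randomness (cell, bead, shot/read noise) flows from integer seeds
  via `withr::with_seed`; pipeline runs are byte-reproducible, outputs
  are never overwritten without `overwrite = TRUE`, and logs go to
  stderr so they cannot perturb the artifacts.
* Problem sizes: the default 21 × 21 solve is a 1356² complex system
  (~1 s); the default cell is ~24k fluorophores and a 256² field of
  view (~1 s per render); the test suite holds smaller patches (9 × 9)
  and cells for end-to-end stages and keeps the full-size solve for the
  profile statistics.

## 6. Known limitations

Quasi-static CDA underestimates absolute enhancement in the gaps
(multipoles are truncated at the dipole) and carries finite-patch edge
effects in the profile tail; the substrate and emission-side physics
(Purcell factors, quantum-yield changes, enhancement spectra) are out of
scope — emission enhancement is a single configurable scalar gain.  The
oblique modality is homogeneous-plus-background, not a beam-propagation
model.  None of these affect the package's purpose: internally consistent,
oracle-checked *relative* depth profiles and modality orderings.
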