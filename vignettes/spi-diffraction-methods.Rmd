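---
title: "Models and methods for single-particle diffraction analysis"
author: "spidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-particle diffraction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidiff)
```

This vignette is the package's own account of the science it implements: the
measurement model, the statistics, the defaults and why they were chosen,
and what the synthetic-data tests do and do not demonstrate about real data.

## 1. The measurement chain

A single-particle imaging (SPI) experiment at an X-ray free-electron laser
records one detector exposure per femtosecond pulse.  Most frames are blank;
occasionally a single aerosolized particle (here: an icosahedral virus of
roughly 70 nm) intersects the focus in a random orientation, and rarely a
small cluster of particles does.  The raw data are analog-to-digital units
(ADU) per pixel; the analysis wants photons.  `spidiff` implements the chain

raw ADU → calibrated ADU → photon counts → {hit finding, radial profiles,
sphere size fit, model-validation z-score}

together with a generator that produces raw frames with known ground truth,
so every stage can be tested by parameter recovery rather than by eye.

## 2. Geometry and conventions

A detector is a flat monolithic pixel grid (`DetectorGeometry`): pixel counts,
pixel pitch $p$ (µm), distance $L$ (mm), a real-valued beam centre that may
sit outside the grid (offset detectors are common), and photon energy $E$
(keV) with $\lambda[\mathrm{\AA}] = 12.3984 / E$.  Panel gaps and bad
regions are represented by masks (logical, `TRUE` = bad, matching the
nonzero-is-bad convention of mask files), never by per-panel geometry.

For a pixel at radius $r$ from the beam centre, `buildPixelMap` records the
full scattering angle $\alpha = \arctan(r p / L)$, the momentum transfer
$q = (4\pi/\lambda)\sin(\alpha/2)$, the pixel solid angle
$(p/L)^2\cos^3\alpha$, and the resolution under the **half-period (speckle)
convention**

$$d = \frac{\lambda}{2\sin\alpha}.$$

The half-period convention was chosen deliberately: for a 7 keV beam, a
217.4 mm detector and 110 µm pixels it places the 6.67 Å resolution shell at
a radius of 264.75 px (rounding to 265), a self-consistent pair for this
instrument class, whereas the crystallographic convention
$d = \lambda/(2\sin(\alpha/2))$ would put roughly 13.3 Å there.  Coherent
imaging speaks the first convention; the package follows it everywhere.
No polarization or solid-angle flattening beyond $\cos^3\alpha$ is applied;
at the largest in-scope angle (~7.6°) the flat-Ewald error is below 1%.

## 3. Calibration and photonization

Per-pixel calibration constants (`CalibrationSet`) are pedestal (dark
offset), read noise, gain $\gamma$ (ADU/photon) and the bad-pixel mask.

* **Pedestal / read noise** — per-pixel mean and sample standard deviation
  over a stack of dark frames (`estimatePedestal`).
* **Common mode** — per readout panel, the median of unmasked pixels below a
  signal cut (default $0.5\gamma$, half a photon) is subtracted
  (`commonModeCorrect`).  The median is robust against genuine signal;
  panels with no sub-threshold pixels are left unchanged and flagged.  The
  correction region (per panel rather than per ASIC) and the cut are
  package choices; the underlying hardware effect is a correlated
  shot-to-shot offset.
* **Gain** — at low flat-field occupancy (≲ 0.5 photons/pixel/frame) the
  pedestal-subtracted per-pixel histogram is bimodal: a noise peak near 0
  and a single-photon peak near $\gamma$.  `estimateGain` least-squares fits
  a two-Gaussian model on 1-ADU bins over $[-5\sigma,\,2.5\gamma_0]$ and
  returns the separation of the fitted means.  The peak means are bounded
  ($|\mu_1| \le 3\sigma$, $\mu_2 \in [0.5, 1.5]\gamma_0$) so the fit cannot
  drift onto the small two-photon shoulder at $2\gamma$; fits with
  separation $< 3\sigma$, or pixels with under ten photon events, are
  returned as `NA` (masked).
* **Photonization** — the ceil rule
  $k_i = \lceil (A_i - 0.5\gamma)/\gamma \rceil$, i.e. thresholds at
  $(n - 0.5)\gamma$, applied after gain flattening with the
  detector-average $\gamma$.  Negative results (deep downward noise
  excursions) are clamped to zero: photon counts feed Poisson likelihoods
  and must be non-negative.  The formula is exactly scale-covariant
  ($cA, c\gamma$ gives the same counts) and, with zero read noise and exact
  gain, inverts the generator bit-exactly — both are tested.

## 4. Scattering models and the generator

**Homogeneous sphere.**  Expected photons per pixel at fluence $\Phi$
(photons/µm²):

$$n_i = \Phi\, r_e^2\, \Delta\Omega_i \,\bigl(N_e\, f(q_i R)\bigr)^2,
\qquad f(u) = \frac{3(\sin u - u\cos u)}{u^3},$$

with $r_e$ the classical electron radius and $N_e$ the total electron count
derived from the mass density (default 1.381 g/cm³, a packed-virus value)
and a protein-like **0.53 electrons per dalton**.  The composition ratio is a
convention, not a measured quantity, so the absolute fluence scale is one
too; everything downstream (size fits, z-scores) profiles or scans the
fluence and is insensitive to it.  $f$ is evaluated by series below
$u = 10^{-3}$, making $f(0) = 1$ exact.  The first zero of $f$ at
$u = qR = 4.4934$ puts the first fringe minimum of a 71 nm sphere at
77.8 px on the 2.4 m back-detector geometry — a geometric anchor the tests
verify two independent ways.

**Icosahedral blob shell.**  Twelve identical spherical blobs at the
vertices of a regular icosahedron, summed coherently on the flat Ewald
plane.  This is *not* a virus electron density; it is the minimal
orientation-dependent model carrying icosahedral symmetry, used to exercise
orientation grids in the surprise minimization.  Tests verify exact
invariance under the icosahedral rotation group and >1% pattern contrast
between unrelated orientations.

**The shot generator** (`simulateShot` / `simulateRun`) emulates, with
defaults chosen as the study conditions the analysis must survive:

| parameter | default | what it emulates |
|---|---|---|
| fluence | median $10^{11}$ ph/µm², log-normal, sdlog 0.3 | SASE pulse-energy jitter; gives ~9 photons/pixel just outside the beamstop |
| beam-centre drift | Gaussian, 0.5 px/axis | ~1 px centre-of-intensity wander from beamline pointing drift |
| class mix | 10% hits, 2% clusters (2–3 particles, coherent, touching), 5% darks, rest blanks | a realistic dilute-aerosol run |
| background | 0.05 photons/pixel, uniform | residual instrument scatter |
| beamstop | r < 20 px, transmission 0.01, masked | semi-transparent central stop |
| ADU rendering | pedestal 20 ± 2 ADU, read noise 3 ADU, γ = 33 ADU/photon ± 5% pixel-to-pixel | photon-counting hard X-ray detector at 7 keV |
| panels | 2 × 2, 2 px masked gaps | tiled readout |

Frames draw their randomness from per-frame substreams hashed from the run
seed and frame index, so a run is bit-reproducible and frames are
independent of simulation order.  What the generator does **not** model:
detector saturation, charge sharing and pile-up, water layers on the
particle, atomistic structure, per-panel metrology errors, Ewald curvature.
A passing test suite therefore demonstrates correctness of the analysis
under the stated statistical model, not robustness to every artifact of a
real beamline.

## 5. Sphere size fitting

`fitSphere` reduces a photon frame to 1-px radial bins about the beam
centre (half-open intervals, membership by pixel-centre radius; masked
pixels excluded).  Sums of independent Poisson counts are Poisson, so the
binned likelihood is exact, and the radial reduction matches the model's
symmetry while shrinking the problem ~200-fold.  At each candidate diameter
the fluence is profiled: with unit-fluence bin sums $m_b$ and a fixed
background sum $b_b$ per bin, the maximizer of
$\sum_b [k_b \log(\Phi m_b + b_b) - (\Phi m_b + b_b)]$ is the closed form
$\hat\Phi = \sum k_b / \sum m_b$ when $b_b = 0$ and otherwise the root of a
monotone score, found by `uniroot`.  The diameter is scanned on a 0.5 nm
grid over 40–120 nm and polished by golden-section search within one grid
step.

The **background term matters**: the generator's 0.05 photons/pixel, left
unmodelled, biases fits of 71 nm frames several percent low and inflates
the deviance by an order of magnitude — the uniform floor is brightest,
relative to the model, exactly where the sphere signal has died away.  The
rate is passed by the caller (in practice: estimated from blanks with
`averageBackground`).

**Single-particle classification** requires the fitted diameter inside a
closed window (default 60–85 nm, bracketing the ~71 nm particle and the
~76 nm solution-phase size estimates that motivate it) *and* deviance below
`2.5 × nBins`.  The factor 2.5 tolerates the up-to-twofold deviance
inflation that uncorrected ~1 px centre drift produces on 1 px bins, while
coherent clusters (deviance from ~2.3× to ~65× the bin count in simulation)
and fringe-free frames (~1000×) are rejected.  Notably, cluster frames often
*fit* to a diameter inside the window — the interference modulation averages
out radially — so the deviance test, not the window, is what rejects them.

## 6. The surprise statistic

Given expected photons $n_i$ and observed counts $k_i$ over $N$ unmasked
pixels, the surprise is the negative Poisson log-likelihood (natural log;
nats)

$$S = -\sum_{i=1}^{N} \log P(n_i, k_i),
\qquad P(n,k) = \frac{n^k e^{-n}}{k!}.$$

Its mean and standard deviation under the model are data-independent:
$\langle S\rangle = \sum_i H(n_i)$ with $H$ the Poisson entropy, and
$\sigma_S^2 = \sum_i \mathrm{Var}[\log P(n_i, k)]$.  The z-score
$z = (S - \langle S\rangle)/\sigma_S$ measures data–model consistency:
$|z| \gg 1$ means the frame is surprising under the model.  Per-pixel
moments are computed by truncated summation over $k = 0..K$ with
$K = \lceil n + 12\sqrt{n} + 30\rceil$ (omitted tail mass far below
$10^{-12}$), using the multiplicative recurrence
$p_{k+1} = p_k\, n/(k+1)$ rather than a density call per term; the tests
check agreement with a direct high-precision summation to $10^{-9}$
relative at $n$ from 0.01 to 100.  Single-pixel anchors:
$\langle S\rangle(n{=}1) = 1.3048$, $\sigma_S(n{=}1) = 0.6678$ nats.

Zero-rate pixels contribute nothing to $\langle S\rangle$ and $\sigma_S$,
and force $S = +\infty$ (flagged, never hidden) if they observed a photon.
An optional uniform floor can be added to a candidate model to represent
background; it is applied **after** fluence scaling
($n = \Phi n_0 + \mathrm{floor}$), because it is a rate, not part of the
scalable pattern.

`minimizeSurprise` scans a fluence grid × orientation grid.  When the floor
is zero the pattern is linear in $\Phi$ and $S(\Phi)$ separates into three
frame-level sufficient statistics, so the whole fluence grid costs one pass
over the pixels per orientation; with a floor the scan is direct.  The
z-score is evaluated *at the selected* $(\Phi, \Omega)$ — a post-selection
quantity, reported as such and not corrected (the selection bias is
negligible next to the mismatch signals of interest, and correcting it
would require a null ensemble per grid).  Ties go to the first grid point
in deterministic (fluence-major within orientation) order.

Calibration and sensitivity, both tested: frames sampled from their own
model give sample mean $z$ within ±0.1 and sd within [0.9, 1.1] over 1000
frames ($z$ has exactly mean 0 and variance 1 by construction; normality is
CLT); frames from a 71 nm sphere scored against an 80 nm model give median
$z \approx 19$ at the study fluence.  One behaviour worth knowing: with a
profiled fluence, a mismatched model can also drive $z$ strongly
*negative* (the data are "too regular": the model over-predicts rates over
wide low-signal areas whose entropy then exceeds the realized
cross-entropy).  Consistency means $|z|$ small, as the definition says —
the directional test above restricts to the signal-bearing radius range
where mismatch pushes $z$ up.

## 7. Hit finding and radial analysis

A frame is a hit when at least `minLitPixels` unmasked pixels hold
`≥ litThreshold` photons.  With a known background rate $b$ the blank lit
count is Poisson with mean $N_{\mathrm{pix}} P(k \ge t \mid b)$;
`suggestMinLitPixels` returns one count above its upper $1-10^{-6}$
quantile.  This matters: at $b = 0.05$ a full-size blank frame lights
~90 pixels at $k \ge 2$ and thousands at $k \ge 1$, so fixed thresholds
that work on a small test grid silently fail at scale.  At
(`litThreshold = 2`, budgeted `minLitPixels`) the simulated confusion
matrix reaches recall and precision ≥ 0.95.

`radialAverage` computes mean photons per pixel in 1-px annuli (exact
agreement with a brute-force double loop is a test), and
`signalResolutionLimit` compares hit and blank profiles on identical bins:
the limit is the outer edge of the last bin in a run of ≥ 3 consecutive
bins where hit > 1.2 × blank, converted to resolution through the geometry.
The factor 1.2 and run length 3 quantify "consistently elevated" and are
configurable; simulated post-sample apertures are recovered within 2 bins,
monotonically in the aperture radius.

## 8. I/O

CXI-flavoured HDF5 via `rhdf5`: the frame stack at
`/entry_1/instrument_1/detector_1/data` (chunked per frame; integer dtype
for photons, double for ADU), distance and pixel size in metres, source
energy in joules, per-frame identifiers at `/entry_1/experiment_identifier`,
an optional shared mask (nonzero = bad).  Missing optional metadata reads
as `NA`, never as a silent default; a missing `/entry_1` or data stack is a
hard `malformed-cxi` error.  Selections are a single 1-D `/timestamps`
dataset of fixed-width id strings compared lexically; standalone mask files
carry `/data/data`.  Simulated runs write a parallel truth file (class,
fluence, orientation quaternion, beam centre, true photon stack) for
parameter-recovery tests.

## 9. Problem sizes and numerical choices

The shipped tests run on reduced geometries — mostly a 185 × 388 px or
smaller back detector, tens to a few hundred frames per scenario, 150-point
orientation grids — sizes chosen so the whole suite completes in about a
minute while every statistical assertion retains comfortable margin (e.g.
the z-calibration bound uses 1000 frames where the standard error of the
mean is 0.032 against a ±0.1 acceptance band).  Scaling the same code to a
2.3 Mpix front detector changes run time, not logic: all kernels are
vectorized per frame.

Other numerical conventions collected in one place: pixel indices are
0-based with pixel centres at integers; radial bins are half-open
`[lo, hi)`; the resolution at the exact beam centre is `Inf` (undefined);
`resolutionToRadius`/`radiusToResolution` round-trip to $10^{-9}$ relative;
quaternions are canonicalized to a non-negative leading component; the gain
fitter's histogram uses 1-ADU bins, so a noiseless two-delta histogram
returns the gain exactly (both peak means land mid-bin, the offsets
cancel in the separation).

## 10. Known limitations

* The absolute fluence scale rests on the 0.53 e⁻/Da convention; only
  relative/profiled fluences are meaningful.
* The beamstop is a uniform-transmission disc, not a material attenuation
  model; its region is masked by default anyway.
* Centre refinement by centre-of-intensity is available but, with a masked
  beamstop and background, is noisy enough that the default pipeline relies
  on the nominal centre plus the drift-tolerant deviance threshold instead.
* The z-score at the best-fit grid point is a post-selection statistic
  (Section 6).
* The icosahedral blob shell is a symmetry stand-in, not a structural
  model; orientation-recovery results quantify the machinery, not
  attainable orientation accuracy for a real capsid.
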