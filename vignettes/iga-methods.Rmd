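---
title: "Iterative Gabor averaging: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative Gabor averaging: model, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(igaholo)
```

## The imaging problem

A digital in-line (Gabor) holographic microscope illuminates a mostly
transparent sample with a coherent quasi-monochromatic wave and records, at a
plane a few millimetres downstream, the intensity of the freely propagated
field — the in-line hologram. The sample is described by its complex
transmittance $t(x,y) = a(x,y)\,e^{i\varphi(x,y)}$; the phase
$\varphi = 2\pi\,\mathrm{OPD}/\lambda$ encodes the optical path difference,
the quantity of biological interest (it is proportional to optical
thickness). Because the camera records only $|U|^2$, a single
backpropagated hologram carries a *twin image*: the out-of-focus conjugate
replica of the object superimposed on the reconstruction. Under a low photon
budget the hologram is additionally dominated by Poisson shot noise and, for
dim signals, quantization noise from the few camera gray levels in use.

The two disturbances live in different spatial-frequency bands: the twin
image concentrates at low frequencies (it is a strongly defocused copy of
the object), while shot noise is white. That observation drives everything
in this package.

## Free-space propagation

All propagation uses the angular spectrum method: the field's 2-D spectrum
is multiplied by the unit-modulus transfer function

$$H(f_x, f_y; z) = \exp\!\left(i 2\pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2}\right),
\qquad f_x^2 + f_y^2 \le 1/\lambda^2,$$

and zero outside the propagating band. The hard evanescent cutoff (rather
than an exponentially decaying branch) is deliberate: at millimetre
distances the evanescent terms are numerically zero anyway, and the hard
zero keeps $|H| \in \{0, 1\}$, which makes unitarity exactly testable. One
operator serves both directions — backpropagation is the same kernel with
$-z$ — so forward simulation and reconstruction cannot drift apart in sign
conventions. Frequencies are laid out in the standard DFT order (zero
frequency first), and every filter in the package is built on the same
layout to avoid off-by-one shifts.

`propagate()` accepts `pad_factor = 2` (zero-padding, then cropping) to
suppress the DFT's periodic wrap-around, which is the right default for a
compact field in free space. Inside the simulator and the reconstruction
loops, however, the default is `pad_factor = 1`: the scenes of interest are
compact objects on a *uniform* background, and zero-padding such a scene
would surround it with an artificial dark frame whose edge diffraction
contaminates the hologram — with periodic boundaries an empty object records
an exactly uniform hologram, as it physically must. Wrap-around from the
weak diffracted component is confined to the image border and is the price
of that exactness; it is also what makes a hundred Gerchberg–Saxton cycles
on a megapixel stack affordable.

## Acquisition model

`record_hologram()` forms $U_0 = a\,\exp(i\varphi\,\lambda_{\rm ref}/\lambda)$
(the OPD, not the phase, is wavelength-invariant), propagates it by $+z$ and
records $I = |U|^2$ under unit illumination. Noise follows, then optional
quantization:

* **Poisson (shot) noise** is parameterized by its standard deviation `target_std`
  at unit mean intensity. That maps to a photon budget of
  $N = 1/\texttt{target\_std}^2$ photons per pixel at unit intensity, and the
  recorded value is $\mathrm{Poisson}(I N)/N$. A target std of 0.2 is a
  25-photon budget. This is the minimal mapping consistent with specifying
  noise only by its std.
* **Gaussian noise** adds i.i.d. $N(0, \sigma^2)$; it exists mainly for the
  two-plane convergence study.
* **Quantization** (`quantize()`) rounds $I \cdot \text{gain} \cdot
  \text{exposure}$ into $[0, 2^{\rm bits}-1]$. Noise is applied *before*
  quantization; the simulation studies are reported in continuous arbitrary
  units with quantization off, and quantization is exercised when emulating
  few-gray-level acquisitions.

Stacks are reproducible: each frame derives a distinct sub-seed
deterministically from the master seed, so frames are independent draws but
the stack is byte-identical across runs.

The packaged ground-truth artwork is a bitmap-font text object ("QPI" by
default) with phase in $[-0.4, 0.6]$ rad on a 256 px, 2 µm grid. Its glyph
fill factor is sized so that the noise-free hologram has mean 1 and contrast
$\Delta M \approx 0.09$ — the same order as real thin-sample acquisitions —
which puts the strongest simulated noise (std 0.2) below an SNR of 1.
Amplitude objects render as *absorbing* glyphs on a transmitting background:
an in-line hologram needs the unscattered background wave as its reference,
so the bright-background orientation is the physically meaningful one.

## The four reconstructors

With $A_k$ the normalized amplitude of frame $k$ (`normalize_hologram()`
divides by the mean intensity and takes the square root by default — cameras
record intensity; an `identity` mode is provided as a switch because
deposited implementations differ on this point):

* **GHR** — backpropagate a single $A_k$ with zero phase. Fast; twin image
  present by construction.
* **GS** — alternating projections: cycle the field through every
  measurement plane, replacing the amplitude with $A_k$ and keeping the
  phase, for $T$ full cycles, then backpropagate to the object plane. In
  wavelength multiplexing each inter-frame transfer passes through the
  object plane, where the phase is rescaled by $\lambda_j/\lambda_k$ (OPD
  invariance) before propagating at the next wavelength. GS suppresses the
  twin image on clean data but *fits the noise* when the frames disagree
  only through shot noise: its error grows with $T$ on noisy data.
* **GA** — average the $K$ complex backpropagations at the object plane.
  The in-focus object term is common to all frames; shot noise is
  uncorrelated, so the background noise falls as $1/\sqrt{K}$. The twin
  image is only partially averaged (it is deterministic per distance).
* **IGA** — route each band to the method that handles it: low-pass filter
  every recorded intensity with a Gaussian kernel of std $\sigma$ pixels and
  run GS on the filtered stack (twin-image-free, blurred, noise tamed by the
  filter); high-pass filter the GA field with the *same* kernel (sharp,
  noise-averaged); sum the two complex fields.

Initialization of GS is the textbook choice (first frame's amplitude, zero
phase, at the first frame's plane; frames visited in listed order, ascending
distance from the simulator). No object-plane constraint (support or
positivity) is applied between cycles — only amplitude substitution at the
measurement planes — and the output is taken after completing $T$ full
cycles. A single-frame stack degenerates exactly to GHR in both multiplex
modes.

Two deliberately surfaced conventions, switchable rather than guessed
silently: `hologram_to_amplitude` (`sqrt` default vs `identity`) and
`strict_band` (off by default: the GS-path output is *not* re-low-passed
before summation, the literal reading of the two-path scheme; on: the two
paths occupy exactly complementary bands).

### Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `iterations` ($T$) | cycles | 100 (10 for timing studies, 30 in the sweep) | twin-image suppression vs time, and noise amplification in GS |
| `sigma` ($\sigma$) | pixels | 2 | band split: larger favours the noise-robust GA path, weaker twin-image removal; values 1–4 behave similarly |
| `pad_factor` | — | 1 | periodic vs zero-padded propagation (see above) |
| `hologram_to_amplitude` | — | `sqrt` | intensity-to-amplitude convention |

The Gaussian filters are applied in the frequency domain with periodic
boundary, $G(f) = \exp(-2\pi^2\sigma^2 |f|^2)$ with $f$ in cycles/pixel, so
`lowpass + highpass` is exact to double precision — the band split loses
nothing. $\sigma$ is expressed in pixels of the hologram grid, making it
independent of the physical pitch.

## Evaluation metrics

* `rms_error()` removes the global piston for phase inputs before averaging:
  in-line holography cannot fix the global phase offset, so comparisons must
  be offset-invariant. For the amplitude-object convergence study, the truth
  is compared in the same energy normalization as the reconstruction
  (`truth / sqrt(mean(truth^2))`), since hologram normalization fixes the
  mean intensity at 1 rather than the background at 1.
* `ssim_index()` is the canonical SSIM (11×11 Gaussian window, std 1.5,
  $K_1 = 0.01$, $K_2 = 0.03$), averaged over all *complete* windows, with
  the dynamic range taken from the ground truth. The valid-window choice
  makes the value exactly reproducible by a direct per-window loop, which is
  how the test suite validates it.
* `background_std()` is the object-free-area std $S$; rectangles are 0-based
  and half-open everywhere in the package.
* `thickness_from_phase()` converts phase to physical thickness through
  $t = \varphi \lambda / (2\pi\,\Delta n)$; no unwrapping is performed
  anywhere since all in-scope objects satisfy $|\varphi| < \pi$.

## What the simulations do and do not show

The simulator reproduces coherent propagation, shot noise at a calibrated
photon budget, and gray-level quantization. It does **not** model partial
coherence, read noise, dark current, fixed-pattern noise, Bayer demosaicing,
aberrations, or spherical-wave magnification (unit magnification is assumed;
for lens-based systems supply the *effective* pixel pitch). Passing the
packaged tests therefore demonstrates the algorithmic claims — twin-image
suppression, $1/\sqrt{K}$ averaging, band fusion without blur — under ideal
coherent imaging, not end-to-end fidelity to any particular instrument. The
packaged text artwork also differs from any real lab target, so simulated
SSIM values characterize method *orderings* and trends, not absolute
figures for other scenes.

Problem sizes in the tests were chosen as the smallest that leave the
physics unambiguous: 256 px grids for the protocol replications (two-plane
GS over 100 cycles; the shot-noise sweep over six noise levels × three
seeds at $T = 30$), 64–128 px for unit properties, and a single
1000 px × 3-frame stack at $T = 10$ for the relative-cost check
(IGA ≈ GS + GA, compared as a ratio so the statement is hardware-free).

## Known limitations

* Twin-image residues below the $\sigma$ cut remain in IGA output (visible
  as low-frequency background fluctuation), exactly as in the GS path it
  inherits them from.
* $\sigma$ is manual; automatic adaptation to the measured noise spectrum is
  out of scope, as are alternative iterative engines (hybrid input–output,
  conjugate gradient), single-frame regularized twin-image removal,
  autofocus, and pixel super-resolution.
* GS in wavelength mode assumes dispersion-free OPD (phase strictly
  proportional to $1/\lambda$) and per-frame defocus distances taken at face
  value from the manifest.

## A minimal session

```{r, eval = FALSE}
g <- grid_spec(256, 256, pitch = 2e-6)
obj <- make_text_phase_object("QPI", g)
stack <- record_stack(obj, distances = c(2e-3, 3e-3, 4e-3),
                      noise = noise_spec("poisson", 0.1, seed = 1))
u <- reconstruct(stack, reconstruction_settings("iga", iterations = 100, sigma = 2))
evaluate_reconstruction(field_phase(u), obj$phase, roi = c(8, 58, 8, 58))
autoplot(u, "phase")

sweep <- sweep_noise_ssim(obj, iterations = 30, seeds = 1:3)
autoplot(sweep)
```
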