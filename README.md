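# igaholo

Multi-frame reconstruction for digital in-line (Gabor) holographic
microscopy under low photon budget.

## The problem

Quantitative phase imaging with in-line holography records, a few
millimetres behind the sample, the intensity $I = |U|^2$ of the freely
propagated object wave. Backpropagating the measured amplitude recovers the
complex field — and with it the phase $\varphi = 2\pi\,\mathrm{OPD}/\lambda$
that encodes the sample's optical thickness — but two disturbances fight the
reconstruction:

* the **twin image**, the conjugate out-of-focus replica that appears
  because the camera records no phase; it concentrates at low spatial
  frequencies;
* **shot noise**, which dominates when illumination is kept low to protect
  live samples (or exposure short for high-speed imaging); it is broadband.

Multi-frame stacks (several defocus distances, or the three channels of an
RGB snapshot at different wavelengths) make twin-image removal well-posed
via Gerchberg–Saxton (GS) alternating projections — but GS *fits the noise*
and its error grows with iterations on noisy data. Plain complex averaging
of the backpropagated frames (Gabor averaging, GA) suppresses noise as
$1/\sqrt{K}$ but leaves the twin image. **Iterative Gabor averaging (IGA)**
fuses the two: Gaussian-low-pass filter every hologram (std $\sigma$ px) and
run GS on the filtered stack for the twin-image-dominated low band; high-pass
filter the GA field with the same kernel for the noise-dominated high band;
sum the complex fields

$$U_{\rm IGA} = U_{\rm LP}^{\rm GS} + \left(U^{\rm GA} -
\mathcal{G}_\sigma * U^{\rm GA}\right).$$

The package implements the full chain for users of lensless and lens-based
in-line systems: angular-spectrum propagation, a calibrated hologram
simulator (Poisson/Gaussian noise, camera quantization), the four
reconstructors (GHR, GS, GA, IGA) for distance- and wavelength-multiplexed
stacks, evaluation metrics (RMS, SSIM, background std $S$, $M/\Delta M$/SNR,
phase↔thickness), TIFF/PNG stack IO with JSON manifests, and a CLI.

## Worked example

Simulate a three-distance stack of a phase object (phase −0.4…0.6 rad,
2 µm pixels, 500 nm) at a 100-photon budget (shot-noise std 0.1), then
reconstruct:

```r
library(igaholo)

g     <- grid_spec(256, 256, pitch = 2e-6)
obj   <- make_text_phase_object("QPI", g)
stack <- record_stack(obj, distances = c(2e-3, 3e-3, 4e-3),
                      noise = noise_spec("poisson", 0.1, seed = 1))

hologram_stats(stack$frames[[1]])
#> # A tibble: 1 × 3
#>       M delta_M   snr
#>   <dbl>   <dbl> <dbl>
#> 1  1.00   0.134    NA

u <- reconstruct(stack, reconstruction_settings("iga", iterations = 100, sigma = 2))
evaluate_reconstruction(field_phase(u), obj$phase, roi = c(8, 58, 8, 58))
#>      rms  ssim      S
#> 1 0.0536 0.595 0.0303
```

The hologram carries mean intensity `M = 1` (unit illumination, energy
conserved) and contrast `delta_M = 0.13`. Under the same conditions the
other methods give, for comparison (`rms` in rad against the ground truth,
piston-removed; `S` = std of the object-free corner):

| method | rms | ssim | S |
|---|---|---|---|
| GS (T = 100) | 0.152 | 0.056 | 0.149 |
| GA | 0.067 | 0.634 | 0.021 |
| IGA (T = 100, σ = 2) | 0.054 | 0.595 | 0.030 |

GS has amplified the shot noise (background std 0.149 rad); GA keeps the
background clean but its twin-image residue inflates the object error; IGA
has the lowest reconstruction error, combining GS-grade twin-image removal
with GA-grade noise. `autoplot(u, "phase")` shows the map;
`autoplot(sweep_noise_ssim(obj))` reproduces the full SSIM-vs-noise
comparison.

A shell entry point wrapping the same functions ships in
`inst/scripts/igaholo`:

```sh
Rscript inst/scripts/igaholo simulate --out sim --noise-kind poisson --noise-std 0.1 --seed 1
Rscript inst/scripts/igaholo reconstruct --manifest sim/stack_manifest.json \
        --output rec --method iga --iterations 100 --sigma 2
Rscript inst/scripts/igaholo evaluate --recon rec/reconstruction.json \
        --truth sim/ground_truth.json --out report.json
```

An annotated example manifest for describing externally acquired stacks is
in `inst/extdata/`.

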