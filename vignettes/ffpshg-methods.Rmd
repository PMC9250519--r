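---
title: "FF-PSHG analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FF-PSHG analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpshg)
```

## The measurement and the model

Polarization-resolved second harmonic generation (PSHG) microscopy probes
fibrillar collagen by recording SHG images while rotating the linear
excitation polarization. An acquisition here is a stack of ten 8-bit
grayscale frames at polarization angles 0° to 180° in 20° steps. Under the
single-axis molecule model — cylindrical symmetry about the fibril axis,
fibril lying in the image plane — the per-pixel intensity is

$$I(\alpha) = I_0\left[\sin^2 2(\varphi-\alpha) +
  \left(b\,\sin^2(\varphi-\alpha) + c\,\cos^2(\varphi-\alpha)\right)^2\right],$$

with $b = \chi_{31}/\chi_{15}$ and $c = \chi_{33}/\chi_{15}$ the two
independent ratios of the nonzero second-order susceptibility tensor
elements, $\varphi$ the in-plane fibril orientation and $\alpha$ the
excitation polarization. The signal is 180°-periodic and a finite cosine
series in $\Delta = \varphi - \alpha$:

$$I = I_0\left[c_0 + c_1\cos 2\Delta + c_2\cos 4\Delta\right],\qquad
  c_0 = \tfrac12 + \tfrac{v^2}{4} + \tfrac{u^2}{8},\;
  c_1 = \tfrac{uv}{2},\;
  c_2 = \tfrac{u^2}{8} - \tfrac12,$$

with $u = c - b$, $v = c + b$. Because the 20° step divides the 180°
period into nine equal parts, these two harmonics land exactly in bins 1
and 2 of the 9-point DFT of the endpoint-averaged series — that exact
aliasing is what makes the Fourier route to the parameters fast and
closed-form.

## The inversion

`fit_stack()` performs, per pixel:

1. **Endpoint averaging.** Frames at 0° and 180° are ideally identical;
   they are averaged in floating point, leaving 9 frames. (Whether to
   average before or after 8-bit rounding is a genuinely open choice; we
   average in floating point, which is the lower-noise option.)
2. **9-point DFT** with the forward convention
   $G_k = \sum_n x_n e^{-2\pi i k n/9}$.
3. **Orientation** from the phase of bin 1:
   $\varphi = -\arg G_1/2 \bmod 180°$. When the first harmonic vanishes
   ($b = c$, whose intensity is 90°-periodic), orientation falls back to
   bin 2, $\varphi = (\pi - \arg G_2)/4$, and is meaningful modulo 90°.
4. **Signed moments** $M_k$ by projecting bins 0–2 onto the recovered
   orientation, then the closed-form solution of
   $$I_0^2 + I_0(3M_2 - M_0) + \left(\tfrac{M_1^2}{4} - 2M_2M_0 +
   2M_2^2\right) = 0,$$
   followed by $u^2 = (8M_2+4I_0)/I_0$, $v^2 = 4(M_0-M_2-I_0)/I_0$.
5. **Pitch angle** $\theta_e = \arccos\sqrt{c/(2+c)}$, equivalently
   $\tan^2\theta_e = 2/c$, so $c = 2 \Rightarrow \theta_e = 45°$ exactly.
   (The fraction $c/(2+c)$ itself is dimensionless; reading it as
   $\cos^2\theta_e$ is the only interpretation consistent with the
   reported degree-valued pitch angles, e.g. $c = 1.79 \mapsto 46.6°$,
   and with the known $\tan^2\theta = 2/c$ relation.)

### Root selection and identifiability

The quadratic can have two admissible roots. Among real roots with
$I_0 > 0$, $u^2 \ge 0$, $v^2 \ge 0$, roots giving $b \ge 0$ are preferred
and ties are broken toward the smaller $|b - 1|$ — a Kleinman-symmetry
prior, since $\chi_{31}/\chi_{15}$ is expected near unity at these
excitation wavelengths. If only $b < 0$ roots exist the pixel is flagged
as having no physical solution (`NaN`).

One genuine degeneracy deserves emphasis: the model is *exactly*
invariant under $(b, c, \varphi) \to (c, b, \varphi + 90°)$, so the sign
of $c_1$ — equivalently, which ratio is which — cannot be determined from
the data. All fits and all phantom ground truth are reported in the
canonical representative $c \ge b$, which matches the physically expected
ordering for collagen ($b \approx 1$, $c \approx 1.8$–$2.2$). Users
comparing against externally fitted values should canonicalize those the
same way (`canonicalize_params()`).

### Numerical choices

Degeneracy is declared when both folded amplitudes $\hat c_1, \hat c_2$
fall below $10^{-9}\max(\hat c_0, \epsilon)$; tiny negative $u^2$, $v^2$
or discriminants within the same relative tolerance are clamped to zero.
Undefined pixels carry `NaN`, never 0, because 0 is a legal parameter
value. $\varphi$ is measured in degrees counterclockwise from the +x axis
of the image (the convention used by the original acquisition software is
not recoverable; this one is fixed and documented).

## Fitting-quality estimators

* **R²** $= 1 - SSR/SST$ over all **ten** originally acquired values,
  with predictions from the fitted model at all ten angles; `NaN` for a
  constant series.
* **ERR** $= \mathrm{mean}(\hat c_3, \hat c_4) /
  \mathrm{mean}(\hat c_0, \hat c_1, \hat c_2)$: with 9 samples the only
  harmonics beyond the model are 3 and 4 (two-sided bins 3–6), so the
  folded amplitudes $\hat c_3, \hat c_4$ are the noise term. Clean model
  data give ERR $\approx 0$; SHG-inactive noise pixels give ERR near 1.
* **SNR** $= 10\log_{10}[(|G_1|^2+|G_2|^2)/(|G_3|^2+|G_4|^2+|G_5|^2+|G_6|^2)]$
  in dB, capped at +99 (the value reported for noise-free pixels, where
  the noise bins are numerically zero). Bins 7–8 are the conjugates of
  2–1 and are excluded.

The DFT index convention needs one word: bins are 0-based frequency
indices of the 9-point transform. That is the only reading under which
the model's content sits in the "signal" set $\{1, 2\}$, clean data get
high SNR, and ERR $\approx 0$ — all three of which the estimators are
defined to produce.

An R² display threshold of 0.8 (optionally written as a binary mask by
`process_collection(..., r2_threshold = 0.8)`) is the conventional
good-fit filter for these maps; 0.9 is a stricter variant in use
elsewhere. The threshold only filters display/segmentation; it never
feeds back into the fit.

## Local dispersion maps

The five structural maps (CHI3115, CHI3315, CHI3331, FI, THETA) are
summarised by three estimators over six windows (square and circular, of
side/diameter 3, 7, 15), giving 90 maps per stack:

* **SD**: population standard deviation (divisor $n$).
* **MAD**: $\mathrm{median}(|x - \mathrm{median}(x)|)$, robust to
  outliers.
* **ENT**: Shannon entropy in bits of the occurrence-rate histogram after
  quantizing to 256 levels over a **fixed per-parameter range** — ratios
  clipped to $[0, 5]$, FI $[0, 180)$, THETA $[0, 90]$. Window-local
  ranges would make entropy scale-free and incomparable across an image,
  so they are not used.

"Circular" windows contain the offsets with
$dx^2 + dy^2 \le ((\mathrm{size}-1)/2)^2$: 5, 29 and 149 pixels for sizes
3, 7, 15. The published figures do not pin down the exact mask pixels, so
the convention is isolated in `window_mask()` where it can be swapped.
Windows are clipped at image borders without padding; a pixel's value is
`NaN` unless at least `min_valid_fraction` (default 0.5) of the *full*
mask is in-bounds and finite. Orientation (FI) is dispersed as plain
degrees by default, which matches the published maps but is biased at the
0/180 seam — a tight distribution straddling 0° shows a large linear SD.
The opt-in `circular_phi` mode measures axial distances to the window's
mean axis instead and removes the seam artifact.

## The phantom generator

`phantom_spec()`/`generate_stack()` emulate an acquisition from known
ground truth: disjoint collagen regions following the model exactly,
over an SHG-inactive background of constant mean. Defaults are chosen to
resemble the real 8-bit stacks: background mean 2 counts, Gaussian noise
with σ = 2 counts, and 8-bit quantization with the stack maximum scaled
to 255 (mimicking detector export). The real detector's noise statistics
are not published, so both Gaussian and Poisson options exist rather than
asserting one. Frames at 0° and 180° receive independent noise draws, so
endpoint averaging genuinely reduces noise in simulation as it does on
the instrument. Setting `bit_depth = NA` disables quantization for
machine-precision recovery experiments.

What the phantom does *not* emulate: spatially correlated speckle, fiber
crossings and partial-volume mixtures within a pixel, out-of-plane fiber
tilt, birefringence, depolarization, or any trigonal-symmetry deviation
from the single-axis model. Passing recovery tests on phantoms therefore
demonstrates the correctness of the inversion, not the adequacy of the
model for every tissue pixel.

## Problem sizes and verification

The package verifies itself on synthetic data at sizes a laptop handles
comfortably: a 64×64, 45-region noiseless sweep over
$b \in \{0.6, 1.0, 1.4\}$, $c \in \{1.2, 2.0, 2.8\}$,
$\varphi \in \{0°, 30°, 75°, 120°, 165°\}$ recovered to $10^{-13}$; 100
random clean pixels checked against an independent multi-start nonlinear
least-squares fit (agreement to $10^{-12}$); 1000 pure-noise pixels for
the ERR/SNR behaviour; and a 2-ROI end-to-end collection round trip
(simulate → fit → dispersion → validate at zero discrepancies). Real
512×512 stacks process in seconds for the fit; the MAD and entropy
windows are the slow path (per-pixel medians/histograms) and scale with
image area × window size.

## Known limitations

* The $c \ge b$ canonicalization is a convention; tissues genuinely
  violating Kleinman symmetry with $b > c$ would be reported swapped with
  $\varphi$ rotated by 90°.
* $\theta_e$ is only as meaningful as the single-axis model; for tissues
  better described by trigonal symmetry the pitch angle is biased.
* Entropy values depend on the fixed binning ranges; maps from other
  implementations with different binning are not directly comparable.
* The float-TIFF writer emits uncompressed single-strip files only — a
  deliberate minimal interface, readable by ImageJ and tifffile.
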