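# ffpshg

Pixel-wise collagen structure from polarization-resolved second harmonic
generation (PSHG) microscopy image stacks.

Fibrillar collagen generates strong SHG signal, and the way that signal
varies with the linear excitation polarization encodes molecular
organization. Given a stack of ten frames acquired at polarization angles
0°–180° in 20° steps, `ffpshg` recovers, per pixel and in closed form via
the harmonic content of the intensity-vs-polarization curve (the FF-PSHG
approach), the parameters of the single-axis collagen model

$$I(\alpha) = I_0\left[\sin^2 2(\varphi-\alpha) +
 \left(\tfrac{\chi_{31}}{\chi_{15}}\sin^2(\varphi-\alpha) +
 \tfrac{\chi_{33}}{\chi_{15}}\cos^2(\varphi-\alpha)\right)^2\right]$$

producing eight planar maps per stack — the susceptibility tensor ratios
χ31/χ15, χ33/χ15, χ33/χ31, the in-plane fibril orientation φ, the helical
pitch angle θe = arctan √(2 χ15/χ33), and three fitting-quality maps
(R², spectral error ratio ERR, signal-to-noise ratio SNR) — plus 90 local
dispersion maps (entropy, standard deviation, median absolute deviation of
the five structural maps over square and circular windows of size 3, 7,
15). It is aimed at microscopists and image-analysis developers working
with PSHG collections laid out like the PSHG-TISS tissue dataset: it reads
and writes that folder/nomenclature scheme, validates collection
inventories, and ships a synthetic phantom generator with known ground
truth for testing analysis code.

## Worked example

Fit a single clean pixel and read the parameters back:

```r
library(ffpshg)
p <- pshg_params(i0 = 100, chi3115 = 1, chi3315 = 2, phi = 30)
series <- shg_intensity(p, pshg_angles("processing"))
invert_spectrum(pixel_dft(series))
#> <collagen_fit> i0 = 100, chi31/chi15 = 1, chi33/chi15 = 2,
#>   chi33/chi31 = 2, phi = 30 deg, theta_e = 45 deg
```

χ33/χ15 = 2 corresponds to a pitch angle of exactly 45°; the ratio mode
of 1.79 typically reported for tissue collagen maps to

```r
theta_from_ratio(1.79)
#> [1] 46.58816
```

End to end on a simulated collection (two noisy collagen bands per
phantom over a dark background, 8-bit frames):

```r
td <- tempfile()
simulate_collection(td, n_roi = 1, height = 32, width = 32, seed = 1)
process_collection(td, r2_threshold = 0.8)   # writes Results/ maps + mask
fit <- read_parameter_maps(file.path(td, "phantom_1", "FSHG"))
fit
#> <pshg_maps> 32 x 32 pixels, maps: CHI3115, CHI3315, CHI3331, FI, THETA, R2, SNR, ERR
#>   fitted pixels: 1006/1024 (98.2%)
glance(fit)
#>   n_pixels n_fitted frac_good_fit median_r2 median_chi3115 median_chi3315 median_theta
#> 1     1024     1006     0.9860835 0.9998567      0.9735237       2.043333     44.69297
```

98.6% of fitted pixels clear the conventional R² ≥ 0.8 good-fit
threshold, the median χ31/χ15 sits near 1 (Kleinman symmetry), χ33/χ15
near its simulated value 2, and the median pitch angle near 45° — the
values the phantom was built from. `autoplot(fit)` draws the eight maps;
`dispersion_collection(td)` adds the 90 local-dispersion maps per stack;
`validate_collection(td)` then confirms the tree holds exactly the
expected inventory. A command-line front end with the same verbs lives at
`inst/cli/ffpshg.R`.

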