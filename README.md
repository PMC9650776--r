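# specpair

Low-dispersion spectrally resolved single-molecule localization microscopy
(sSMLM) in R.

## The problem this package addresses

SMLM reaches sub-50 nm resolution by fitting the point spread functions of
sparse blinking fluorophores, but acquiring *spectral* information per
emitter usually costs dearly: ratiometric dichroic schemes limit the usable
band, and conventional dispersive sSMLM smears each spectrum over 20–30
camera pixels, slashing signal-to-noise and the usable emitter density. A
low-dispersion alternative places a coarse blazed transmission grating
(70 lines/mm) millimetres from the camera chip: every emitter then produces
an undispersed 0th-order PSF plus a compact, slightly elongated 1st-order
pattern in the *same* field of view. Two observables per emitter carry the
spectroscopy:

* the **0th-to-1st-order distance** `d` encodes the intensity-weighted mean
  emission wavelength through a linear calibration
  `lambda = lambda0 + sd (d - d0)` with `sd ~ 0.21` nm of wavelength per nm
  of distance (~27 nm per pixel);
* the **1st-order width** obeys
  `sigma1 = sqrt(sigma_PSF^2 + (sigma_lambda / sd)^2)` and encodes the
  spectral width — enough to discriminate FRET states from donor-only
  emission in the joint `(d, sigma1)` plane.

Because both are differences of fitted positions, spectral precision is set
by localization precision. `specpair` implements the full chain for anyone
who wants to simulate, calibrate, or analyze such data: frame simulation
with exact photon accounting, Poisson-MLE sub-pixel fitting of both orders,
deterministic pair linking along the dispersion axis, distance-histogram
species classification, Monte-Carlo achievable-density comparison, and
smFRET state assignment/time-trace analysis.

## Worked example

Simulate ten frames of one CF660-like emitter, localize both diffraction
orders, link them, and read off the emission wavelength:

```r
library(specpair)
cfg <- optical_config()          # 70 l/mm, z = 6.9 mm, 126.4 nm px, PSF 150 nm
cal <- default_calibration()     # sd = 0.2137 nm/nm anchored at (3077 nm, 692 nm)
sp  <- dye_spectrum("CF660")     # synthetic stand-in, corrected mean 692 nm

em  <- emitter(x_nm = 2000, y_nm = 1500, spectrum = sp, photons = 2000)
sim <- simulate_frames(list(em), cfg, cal, noise_model(seed = 1),
                       fov_px = c(48, 24), n_frames = 10)
locs  <- localize_stack(sim$stack, cfg)
pairs <- link_orders(locs, cal)$pairs

nrow(pairs)                                      # 10
median(pairs$d_nm)                               # 3077.9
distance_to_wavelength(median(pairs$d_nm), cal)  # 692.2
median(pairs$sigma1_nm)                          # 160.5
```

Ten frames give ten linked pairs; the median 0th-to-1st-order distance of
3077.9 nm converts to a mean emission wavelength of 692.2 nm (truth:
692 nm), and the 1st order is mildly elongated (median 160.5 nm vs the
150 nm PSF) by the 13 nm spectral width of the dye. Per-pair `d` scatters
by ~10 nm — the combined localization uncertainty of the two fits — which
is ~2 nm in wavelength: enough to separate dyes whose corrected emission
means differ by 8–10 nm (ATTO647N/CF660/ATTO655/CF680 at
685/692/693/701 nm map to distances 3014/3077/3090/3128 nm).

Classification, FRET and density analyses follow the same pattern; see the
methods vignette (`vignettes/low-dispersion-ssmlm.Rmd`) and the CLI:

```sh
Rscript inst/cli/specpair.R run --config config.json --seed 1 --out out/
```

with subcommands `simulate`, `localize`, `pair`, `calibrate`, `classify`,
`render`, `fret-fit`, `fret-trace`, `density`, `run`.

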