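# silkpol

Quantitative characterization of wavelength-scale fibrous microstructure
from backscattering Mueller-matrix images, written for researchers who
probe textiles, tissue or other fibrous scattering media with imaging
polarimetry. The package covers the full computational chain for a
silk-washing study: reduction of 16-element Mueller images to frequency
distribution histograms (FDHs) and central moments, a dual-rotating-
retarder polarimeter model with full 16-element reconstruction, Lorenz-Mie
and tilted-infinite-cylinder single-scattering solutions, and a
polarized-photon Monte Carlo simulator for sphere-cylinder media that
produces the backscattering images the analysis consumes.

## The statistics at the core

Each m11-normalized element image is reduced to an FDH (400 bins, area
normalized to 1) and to the central moments of its pixel distribution:
mean `P1`, variance `P2` (population denominator), skewness `P3` and
non-excess kurtosis `P4`. Three derived parameters track a sample across
washes *i*:

    c1_p1  = |m22_P1 - m33_P1| / m22_P1          (anisotropy degree)
    d22_p1 = (m22_iP1 - m22_0P1) / m22_0P1       (m22 mean shift vs unwashed)
    d23_p2 = (m23_iP2 - m23_0P2) / m23_0P2       (m23 width change vs unwashed)

A large stable `c1_p1` (around 0.9 for well-ordered silk) means intact
anisotropy; a falling `c1_p1` with negative `d22_p1` signals fiber damage;
a strongly growing `d23_p2` signals disordering of the fiber orientations.

## Worked example

The published P1/P2 moment tables for silk washed 0-6 times with four
detergents ship with the package. Loading the color-stain-net series and
summarizing it:

```r
library(silkpol)
series <- load_paper_table("C")      # color stain net, washes 0..6
glance(series)
#>         detergent n_washes aniso_diff_0 aniso_diff_final c1p1_final d22p1_final
#> 1 color_stain_net        6        0.521            0.259      0.587      -0.205
#>   d23p2_final max_m22_p2_fold
#> 1        2.65            4.46
```

The m22 - m33 anisotropy difference collapses from 0.521 to 0.259 over
six washes, `c1_p1` falls to 0.587, `d22_p1` turns negative (-0.205), the
m23 distribution widens 3.6-fold (`d23p2 = 2.65`) and the m22 variance
grows 4.46-fold — the signature of fibers split into finer, disordered
strands. `series_report(series)` gives the full per-wash table;
`autoplot(series)` draws the three trajectories.

Simulating the corresponding backscattering measurement with the
sphere-cylinder Monte Carlo (1.5 um fibers along x with 15 degree spread
plus 0.2 um spheres, indices 1.56/1, 0.01 cm slab, 633 nm):

```r
sim <- run_simulation(medium_config(),
                      detector_config(grid = c(16, 16), extent = 0.4,
                                      acceptance_deg = 20),
                      n_photons = 5e4, seed = 42)
sim
#> SCSM simulation: 50000 photons/state, seed 42, detected fraction 0.0246
#> region-mean normalized Mueller matrix:
#>         c1      c2     c3      c4
#> r1  1.0000  0.3611 0.0475  0.0475
#> r2  0.3887  0.8263 0.1053  0.1433
#> r3  0.0050  0.0034 0.4527 -0.5075
#> r4 -0.0027 -0.0070 0.5049  0.3078
```

The aligned-fiber signature is visible directly: positive m12/m21,
near-zero m13/m31, and m22 well above m33. `sim$image` is the per-pixel
`mueller_image`, ready for `moment_set()`, `compute_fdh()` and
`autoplot()`. `simulate_wash_sweep()` and `end_to_end_demo()` run the
seven-step detergent-degradation parameter ladders and derive the
`c1p1`/`d22p1` trajectories.

The instrument model inverts its own forward simulation exactly; an air
(identity) scan is recovered at machine precision, far inside the 0.01
per-element calibration bound customary for such instruments:

```r
scan <- simulate_scan(mueller_matrix(diag(4)))   # 30-step rotation scan
max(abs(unclass(mueller_from_intensities(scan)) - diag(4)))
#> [1] 3.330669e-16
```

A thin command-line wrapper lives at `inst/cli/silkpol.R`
(subcommands `tables`, `simulate`, `analyze`, `reconstruct`, `demo`,
`phasefun`).

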