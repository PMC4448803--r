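# ppcf — periodic pair-correlation analysis with spectral bandwidth selection

`ppcf` quantifies spatial structure — clustering, segregation, or complete
spatial randomness — in point patterns extracted from two-dimensional
cell-biology images: nuclei or cell centroids marked on micrographs, or agent
centres from lattice simulations. It is aimed at quantitative biologists who
have coordinates (not raw images) and want an objective, reproducible summary
of *at which length scales* a population is aggregated or segregated, how big
the aggregates are, and how that changes as a population grows to confluence.

## The statistic

For a sample image of `X × X` pixels (`X` even) with `n` objects at integer
lattice sites, the periodic pair-distance of two coordinates is
`δ = min(|x₁ − x₂|, X − |x₁ − x₂|)`, appropriate because the image window is
cut from a much larger domain and its edges are not physical boundaries.
Counting the distances `c(δ)` over all unordered pairs of distinct objects in
the x-direction and scaling by the count expected for objects placed uniformly
at random on the lattice gives the directional pair-correlation

    P(δ) = c(δ) d(δ) (X² − 1) / (X n (n − 1)),   δ = 0, …, X/2,

with `d(δ) = 2` at the endpoints `δ ∈ {0, X/2}` and 1 otherwise (the origin
constant carries an additional exact-enumeration factor `X/(X−1)` so that the
expectation under randomness is exactly 1 at every distance). The isotropic
signal `f(δ)` averages the x- and y-direction statistics, and replicate images
are averaged with standard errors. `f ≈ 1` means random, `f > 1` aggregated,
`f < 1` segregated at that separation.

The practical difficulty is the box-kernel bandwidth `Δ` used to bin the
noisy signal `F(j) = (1/Δ) Σ f(δ)`. `ppcf` selects it spectrally: the signal
is reflected into an even, 2π-periodic function, transformed with a rescaled
DFT (`f̂_k`, `k = 0 … X/2`), and the dominant wavenumber `k₁` — the most
prominent interior peak of the power `|f̂_k|²` — defines a wavelength
`λ = X/k₁` whose nearest integer is the bandwidth, `Δ = [λ]`. One bin then
spans one period of the strongest fluctuation, which for crowded exclusion
patterns is set by the object size and for clustered patterns by the
cluster substructure.

Downstream, the unity crossing of the binned signal estimates the aggregate
size (crossing from above) or the object/segregation scale (from below), and
`fit_growth()` fits `n(t) = n₀ exp(αt)` to per-time mean counts.

The package also contains the generator of the synthetic study conditions: a
lattice exclusion process in which `s × s` agents (s odd) are placed without
overlap on a `4X × 4X` lattice — uniformly at random for spatially random
patterns, or sparsely seeded and grown by a random-sequential-update
proliferation mechanism (daughters placed `s` sites away in a random axis
direction, overlapping attempts aborted) for clustered patterns — and only
the centred `X × X` window is observed.

## Worked example

Simulate twenty replicate images of a sparse population grown for five
proliferation steps, then run the full spectral pipeline:

```r
library(ppcf)

cfg <- simulation_config(X = 100, s = 5, rho0 = 0.01, R = 1,
                         tau = 1, T = 5, N = 20, seed = 11)
ss <- simulate_ensemble(cfg)
ss
#> Sample set 'simulated ensemble'
#>   N = 20 samples on a 100 x 100 lattice
#>   objects per sample: mean 42.3 (range 20-83)

fit <- pcf_spectral(ss)
fit
#> Spectral pair-correlation analysis
#>   X = 100, N = 20 samples
#>   candidate bandwidths:
#>   k lambda bandwidth
#>  20  5.000         5
#>  39  2.564         3
#>   adopted bandwidth: 5

unity_crossing(bin_pcf(fit$pcf, 5))
#> Unity crossing (aggregation scale): delta* = 18.13 pixels  [bandwidth 5]
```

The two spectral peaks sit at the proliferation lattice scale: daughters are
placed exactly `s = 5` sites from their mothers, so cluster substructure
repeats with wavelength ≈ 5 pixels (`k ≈ 20` on a 100-pixel window) plus its
harmonic. The adopted bandwidth `Δ = 5` smooths the comb out of the signal,
leaving the biologically meaningful statement: aggregated below ≈ 18 pixels
(the typical cluster size, via the unity crossing), randomly arranged beyond.

Counts from a growth-to-confluence time series are fitted directly:

```r
t <- seq(0, 2000, by = 200)                      # minutes
counts <- 23.33 * exp(0.0443 * t) * exp(rnorm(11, 0, 0.03))
fit_growth(t, counts)
#> Exponential growth fit n(t) = n0 * exp(alpha * t)
#>   n0 = 25.3917, alpha = 0.04425 per minute, R^2 = 1
```

Pixel lengths convert to microns with `to_physical(25, 0.44)` → `11` μm.

Command-line wrappers live in `inst/scripts/`: `ppcf-simulate.R` writes a
sample-set directory (CSV per image + manifest), `ppcf-analyze.R` runs the
pipeline on such a directory and writes the signals and a JSON report.

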