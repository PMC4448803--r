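---
title: "Pair-correlation analysis of lattice point patterns: model, bandwidth selection, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-correlation analysis of lattice point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcf)
```

## The statistic and its assumptions

`ppcf` works with point patterns on an `X × X` integer pixel lattice —
typically object centroids marked on a microscope field. Three assumptions
shape every design choice:

1. **The window is not the world.** Images are cut from a much larger
   culture, so edges carry no physical meaning. The pair-distance is
   therefore *periodic*, `δ = min(|x₁−x₂|, X−|x₁−x₂|)`, which avoids the
   edge-correction machinery a bounded-domain statistic would need. `X` must
   be even so that the distance support `0:(X/2)` and the spectral grid both
   have an integral half-width.
2. **No directional bias.** Distances are counted per Cartesian axis and the
   x- and y-signals averaged into an isotropic `f(δ)`. Axis-wise counting
   (rather than radial annuli) keeps the normalization exact on the lattice
   and makes the statistic cheap: counts come from the per-column occupancy
   histogram in `O(X²)`, checked in the tests against a brute-force double
   loop.
3. **Replicates are identically prepared.** `N` images are averaged
   pointwise; the standard error of the mean,
   `σ(δ) = sqrt(Σᵢ (fᵢ−f̄)² / (N(N−1)))`, zero by convention at `N = 1`,
   propagates to binned signals and to the scalar total error `E = mean(σ)`.

### Normalization constants

The directional signal is `P(δ) = c(δ) d(δ) (X²−1) / (X n (n−1))` over
unordered pairs of distinct objects (self-pairs are never counted;
duplicate coordinates are legal data and contribute δ = 0 pairs). The
endpoint weights `d(0) = d(X/2) = 2` compensate the periodic distance map
being 1-to-1 there and 2-to-1 in the interior. Exact enumeration over
ordered pairs of distinct lattice sites shows the interior and `δ = X/2`
constants make the expectation under complete spatial randomness exactly 1,
while `δ = 0` retains a residual factor `(X−1)/X` (two objects sharing a
column must occupy different rows); the implementation folds the exact
`X/(X−1)` correction into `d(0)`. The test suite verifies the calibration by
Monte Carlo: over hundreds of uniform distinct-site patterns the mean signal
lies within three standard errors of 1 at ≥ 95 % of distances.

## Bandwidth selection in spectral space

The unbinned signal at `Δ = 1` is noisy enough to invite over-interpretation;
binned too coarsely it hides real structure. The selection rule is:

1. Reflect `f(δ)` into an even, 2π-periodic signal of length `X` (position
   `l` carries `f(|l − X/2|)`).
2. Transform: `f̂_k = (1/(X c_k)) Σ_l f̃(δ̃_l) e^(−ikδ̃_l)` on the grid
   `δ̃_l = −π + 2πl/X`, with `c_k = 2` at `k = X/2` and 1 otherwise.
   Internally this is `stats::fft()` rescaled by `(−1)^k/(X c_k)`; the
   rescaling, including the endpoint convention, is pinned by a test
   requiring `cos(m δ̃)` to transform to a single coefficient of exactly
   1/2 and by a direct-summation oracle. For even input all coefficients
   are real; the full mode set reconstructs the signal to numerical
   tolerance (also tested).
3. Find the dominant wavenumber `k₁` of the power `|f̂_k|²` (below).
4. Convert to a wavelength `λ = X/k₁` and take the bandwidth as the nearest
   integer, `Δ = [λ]`, halves rounding up. One bin then covers one period of
   the strongest fluctuation, which is why the binned signal stops
   oscillating without smearing longer-range features.

### Identifying dominant modes: prominence, not raw power

A subtlety dominates this step. Pair counts are conserved
(`Σ c(δ) = n(n−1)/2`), so any pattern that is segregated or aggregated at
short range must compensate elsewhere: the mean of the symmetrized signal is
pinned, and the short-range blip rides on a plateau slightly off unity. The
spectral image of that blip is a smooth envelope that decays monotonically
from `k = 1` and can rival — for crowded random patterns, deterministically
exceed — the oscillation peak in raw power. That envelope carries no
oscillatory length scale: selecting its edge would propose a bandwidth of
order `X`, larger than the signal support itself.

`dominant_wavenumbers()` therefore (i) considers only *strict interior*
local maxima of the power over `k = 1:(X/2)` — the monotone envelope has
none, and `k = 0` is the signal mean — and (ii) ranks peaks by
**topographic prominence**: a peak's height above the higher of the saddles
separating it from stronger peaks. Sampling noise riding on the envelope
shoulder does form interior local maxima, but their prominence is only the
noise height, while a genuine oscillation peak rising from a quiet region
keeps its full height. This mirrors what a trained eye calls "the" peak of
a spectrum plot. Ties break toward smaller `k` (longer wavelength); peaks at
floating-point jitter level are discarded, so a flat spectrum yields no
candidates and a warning. With the replicate counts used in the tests
(`N = 20`), prominence ranking makes the recovered `k₁` stable across seed
batches where raw-power ranking fragments among envelope-noise maxima.

When two modes are comparably prominent (clustered growth produces a
fundamental at the daughter-spacing scale plus a harmonic), all candidates
are reported with their implied bandwidths; `pcf_spectral()` adopts the most
prominent by default and a `bandwidth` argument overrides it — prior
knowledge of the object size is the natural tie-breaker.

### Numerical conventions

* Binning drops trailing distances that do not fill a complete bin
  (`⌊(X/2+1)/Δ⌋` bins); `Δ = 1` returns the input object unchanged.
* `Δ = [λ]` uses round-half-up (`floor(λ + 0.5)`): 5.88 → 6, 7.5 → 8,
  9.75 → 10. Wavelengths below 0.5 would give `Δ = 0` and are an error.
* The unity crossing interpolates linearly between *bin centres*
  `(j + ½)Δ − ½`. Centres (not left edges) are a convention, fixed here and
  in the tests; crossings are read from above (aggregate size) or below
  (object/segregation scale) and flagged accordingly. A signal that starts
  exactly at 1 or never crosses is an error, not a guess.
* Growth fitting is nonlinear least squares of `n₀ e^(αt)` on the counts
  (R² is reported on counts, not logs), initialised by the log-linear
  regression. If the initializer already fits to within `1e−10` relative,
  the refinement step is skipped — the zero-residual Jacobian would be
  degenerate — and the initializer is returned as the estimate, which is
  exact for noise-free exponentials.

## The simulator: what it emulates, and what it does not

`simulate_ensemble()` generates the two reference conditions used throughout
the tests, as an exclusion process of `s × s` square agents (s odd, centres
on lattice sites, overlap iff centre offsets are `< s` in both axes) on a
`4X × 4X` lattice with reflecting boundaries, observing only the centred
`X × X` window — so, as with real images, structure continues beyond the
window edge:

* **Random placement** (`R = 0`): `round(ρ₀ · (4X)²/s²)` agents by rejection
  sampling, giving expected window density `ρ₀`. Defaults mirror the study
  conditions exercised in the tests: `s = 5`, `ρ₀ = 0.5`, `X = 100`,
  `N = 20`. Near the jamming density of aligned squares the sampler aborts
  with advice rather than looping forever.
* **Proliferation growth** (`ρ₀` small, `R > 0`): per step of duration `τ`,
  `n` agents (`n` fixed at the step start) are selected uniformly *with
  replacement from the current population*; each divides with probability
  `R`, placing the daughter's centre exactly `s` sites away in a uniformly
  random axis direction; attempts that would overlap or cross the lattice
  boundary are aborted silently. "Adjacent" placement is site-based only
  for `s = 1`; offset-by-`s` (footprints touching) is this package's
  interpretation for larger agents. Because daughters land exactly `s`
  away, clusters live on an `s`-spaced sublattice — the pair-correlation
  comb and its spectral fundamental near `X/s` (plus harmonic) are a model
  property the spectral pipeline is expected to recover, with small
  downward shifts of the peaks from disorder at cluster boundaries.

The clustered defaults (`ρ₀ = 0.01, R = 1, τ = 1, T = 5`) start from about
four agents in the window on average; occasionally a realization's window
holds fewer than two agents, in which case the pair-correlation is
undefined and `average_pcf()` refuses the sample by name — ensemble-level
callers may drop such realizations explicitly (the tests do).

What the simulator does *not* emulate: agent motility (no displacement
events), cell-size variability (all agents are identical squares), adhesion,
multiple subpopulations, and off-lattice positions. Passing tests therefore
demonstrate that the estimator recovers known length scales of ideal
square-agent patterns; on real images, object-size variability broadens
spectral peaks and the recovered scale is an average.

Reproducibility: the config seed draws one sub-seed per realization, so
ensembles are identical across runs and machines for a given seed; every
stochastic test fixes its seed and asserts tolerance bands, with problem
sizes (`X = 100`, `N = 20` batches, a tenfold `N = 200` stability check,
error-decay comparisons at `N ∈ {5, 20, 80}`) chosen to keep the full suite
under a minute while leaving the stochastic checks comfortably inside their
bands.

## File formats and the MAT reader

Sample sets are directories of `x,y` CSVs plus a `manifest.json`
(`X`, `pixel_size_um`, `label`); coordinates are 1-based integers in
`1:X`, duplicates warn but load. `read_mat_coordinates()` is a best-effort
reader for MATLAB v5 coordinate files (numeric and cell arrays, plain or
zlib-compressed), since no installed R package parses the format; the
variable-to-sample mapping is heuristic by necessity — two-column numeric
arrays (or cells of them) are taken as per-image coordinates, non-integer
centroids are rounded with a warning, and anything ambiguous fails listing
the variables found.

## Known limitations

* The periodic distance slightly distorts scales approaching `X/2`; length
  scales near half the window are not trustworthy.
* The spectral rule proposes integer bandwidths only, and its resolution is
  limited to the wavenumber grid: neighbouring `k` differ by a full
  wavelength step `X/k − X/(k+1)`.
* Prominence ranking presumes the interesting scale appears as an isolated
  peak; patterns whose structure is genuinely broadband (e.g. fractal-like
  clustering) have no single dominant mode, and the candidate list — not
  the first entry — is the meaningful output.
* The growth fit assumes exponential growth throughout; it will happily fit
  early-confluence data where a logistic model would be honest.
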