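---
title: "Variance-slope patchiness analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-slope patchiness analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the statistic, the assumptions behind it, the synthetic data that stands
in for a basin-scale underway dataset, and the numerical decisions that
were genuinely open. Everything quantitative stated here is computed by
the package's test suite or by `scripts/acceptance.R`; nothing is quoted
from elsewhere.

## The variance slope

A transect leg is a vector of 500 per-minute samples (about 100 km of
track at the 0.21 km median step of a sailing vessel). For a window
length $L$ (in samples), partition the leg into consecutive
non-overlapping blocks of $L$ slots, discard the trailing remainder,
compute the variance within each block, and average over blocks: that is
the scale-dependent variance $V(L)$. Over 11 log-distributed window
lengths from 3 to 500 samples, $V(L)$ is close to a power law

$$V = L^{\Gamma},$$

and $\Gamma$ — the slope of an ordinary least-squares fit of
$\log_{10} V$ on $\log_{10} L$ — is the **variance slope**. It is a
sibling of the Fourier spectral slope: a red spectrum (steep power-law
decay of spectral density with wavenumber) gives a high $\Gamma$, white
noise gives $\Gamma \approx 0$. Its practical advantage is gap
tolerance: blocks that fall below a validity threshold simply do not
contribute, so records with up to about 20% missing data still yield a
slope, where a Fourier transform would need imputation.

Properties the implementation guarantees, each pinned by a test:

* **Affine invariance.** $\Gamma(ax+b) = \Gamma(x)$ exactly for $a \ne 0$:
  every block variance scales by $a^2$, which moves the log-log curve
  vertically without tilting it.
* **White-noise null.** With the default sample-variance estimator the
  expected $V(L)$ of i.i.d. noise is flat in $L$, so the ensemble-mean
  slope is statistically indistinguishable from zero.
* **Near log-invariance.** For a lognormal field, $\Gamma$ of the raw and
  of the log-transformed series agree closely (mean absolute difference
  below 0.05 at the package's chlorophyll-like default variability); the
  agreement is exact only for affine transforms and degrades as the
  lognormal coefficient of variation grows.
* **Closed forms.** The unit ramp $x_t = t$ has block population variance
  $(L^2-1)/12$ at every window, and an alternating $\pm 1$ series has
  population $V(3) = 8/9$ and $V(L_{\text{even}}) = 1$; the estimator
  reproduces these to machine precision under
  `var_method = "population"`.

### Numerical choices in the estimator

**Variance divisor.** The default block variance uses the sample divisor
$n-1$. The population divisor $n$ multiplies $V(L)$ by $(L-1)/L$, which
under the default window scheme tilts every fit by almost exactly +0.06 —
enough to push the white-noise null visibly off zero. The population
option is retained (`var_method = "population"`) because deterministic
closed forms such as the ramp's $(L^2-1)/12$ are population quantities;
the two options differ by a constant offset for any input, so comparative
statistics are unaffected by the choice.

**Block validity.** A block contributes if at least 80% of its slots are
valid (and at least 2), mirroring the leg-level 80% coverage rule: one
consistent constant rather than a second tunable. At the smallest window
(3 samples) this means any gap removes the block.

**Fit.** Log base 10, unweighted OLS over scales with positive,
non-missing variance. Weighting by the number of contributing blocks is
available (`weight_by_blocks`) but off by default: the conventional fit
treats each scale as one observation. Fewer than two usable scales flags
the fit invalid (`reason = "insufficient_scales"`) instead of erroring;
an all-constant leg yields a curve of zeros and the same flag.

**Windows.** `window_scheme()` places `n_windows` log-uniform points
between the endpoints, rounds to integers and deduplicates; the default
11 windows from 3 to 500 come out as 3, 5, 8, 14, 23, 39, 65, 108, 180,
300, 500 (consecutive ratios near $(500/3)^{1/10} \approx 1.67$).

## The Fourier side

`fourier_slope()` fits $\log_{10}$ periodogram power against
$\log_{10}$ wavenumber over the wavenumbers whose wavelengths lie inside
the window scheme's range. The default is the plain (untapered)
periodogram — the estimator practitioners usually mean by "the spectral
slope". A rectangular window leaks: spectra steeper than about $-2$
cannot be measured without tapering, so a Hann taper is available and is
what the package's own fidelity tests use when verifying that synthesized
fields carry their target exponents up to $-3$.

`gamma_slope_map()` regresses per-leg $\Gamma$ on the per-leg Fourier
slope across an ensemble and evaluates the fitted line anywhere. On
gapless 500-sample legs spanning spectral exponents 1–3, evaluation at
the classical inertial-subrange slope $-5/3$ gives a variance slope of
about 0.8 (recomputed by `scripts/acceptance.R`). Two finite-sample
effects shape this mapping, and both are deliberate features of the
study conditions rather than defects: a 500-sample window of a larger
field is not periodic, so untapered slope estimates of steep spectra
compress toward $-2$; and the residual scatter of the per-leg slope
estimates attenuates the regression. The mapping is therefore specific to
the estimator convention, which is why the package states it
operationally (fit, then evaluate) rather than as a universal constant.

## The synthetic-data module

The generators are first-class, tested code: they define the study
conditions under which every ensemble property above is verified.

**Power-law fields.** `gen_powerlaw_series()` synthesizes a Gaussian
field with power spectral density $\propto k^{-\beta}$ by random-phase
Fourier synthesis: amplitudes $k^{-\beta/2}$, independent uniform phases,
zero DC amplitude (so the mean is decoupled from the spectral shape),
inverse transform, then rescaling to the target mean and standard
deviation. Synthesis runs on a circle of `oversample` × `n_samples`
points (default 4) and returns a contiguous window. A strictly periodic
leg would have zero spectral leakage and no low-frequency excursions
across its ends — unlike any real transect, which is a window cut from a
basin-scale field. The oversampled window restores both effects; with
`oversample = 1` the exactly periodic series is still available.

**Marginals and noise.** The lognormal marginal is moment-matched:
$x = \exp(\mu + \sigma z)$ with $\mu, \sigma$ solved from the target mean
and standard deviation. This guarantees strict positivity and makes
$\log x$ exactly affine in the Gaussian precursor, which is what makes
the log-invariance property testable without confounding. The noise
floor adds i.i.d. variance as a stated fraction of signal variance —
additively for Gaussian marginals, on the log scale for lognormal ones
(preserving positivity). Gaps remove exactly
`round(gap_fraction * n_samples)` samples, either singly at random or in
geometric blocks of mean length 10, which better mimics instrument
dropouts.

**Default study conditions.** Chosen once, on realism grounds:

| variable | marginal | $\beta$ | mean | sd |
|---|---|---|---|---|
| temperature (°C) | gaussian | 2.0 | 18 | 1.5 |
| salinity (PSU) | gaussian | 2.0 | 35 | 0.5 |
| density (kg m⁻³) | gaussian | 2.0 | 1025 | 0.5 |
| chl-a (mg m⁻³) | lognormal | 1.5 | 0.25 | 0.075 |
| c_p(443) (m⁻¹) | lognormal | 1.5 | 0.10 | 0.03 |
| particle-size γ | gaussian | 1.5 | 0.9 | 0.15 |
| fCDOM (a.u.) | gaussian | 1.8 | 1.0 | 0.2 |

$\beta = 2$ for the physics puts the physical variance slope near 1, and
$\beta = 1.5$ puts the biogeochemical slope near 0.5 — the contrast
observed at sea. The chlorophyll within-leg coefficient of variation of
0.3 is typical of open-ocean 100-km legs away from blooms and fronts;
the log-invariance property tightens at lower variability and loosens
above it, so this default matters and is stated here rather than buried.

**Tracks and streams.** `gen_track()` draws lognormal step lengths with
an exact target median (0.21 km default) and AR(1) heading deviations,
advancing positions by spherical dead reckoning (per-step error relative
to a great circle is $O((d/R)^2)$, sub-millimetre here); all distances
elsewhere use the haversine formula on a 6371 km sphere.
`gen_underway_stream()` assembles per-minute columns on one track and can
impose a target correlation between variable pairs by Gaussian-copula
mixing of the spectral precursors. Mixing fluctuations necessarily mixes
spectra — a field built as $0.6 z_a + 0.8 z_b$ inherits part of $a$'s
spectral shape — so when an ensemble must combine correlated *values*
with *independent* spectral exponents (the decoupling property below),
the correlation is imposed on per-leg mean levels instead, which is also
what the real-ocean value correlations are: regional contrasts, not
minute-scale covariation.

**Raw optics.** `gen_acs_stream()` emulates an inline hyperspectral
absorption/attenuation meter at 4 Hz: dissolved (CDOM-like) baseline
decaying exponentially in wavelength; particulate absorption as a smooth
pigment baseline plus a Gaussian chlorophyll peak at 676 nm scaled by the
chlorophyll profile; particulate attenuation
$c_p(\lambda) \propto \lambda^{-\gamma}$ with a per-minute exponent; the
first 10 minutes of every hour carrying dissolved signal only; optional
positive whole-spectrum spikes (bubbles). The per-minute ground truth is
stored in the object so recovery through the processing chain is testable
to stated tolerances (particulate absorption to 2%, γ to ±0.05).

**What the generator does not emulate** — and therefore what passing
tests do and do not show about real data: no advection–reaction coupling
between variables, no 2D structure, no tides or diel cycles, no
instrument drift or biofouling beyond the filtered baseline, and
marginals that are exactly Gaussian or lognormal. Tests on this synthetic
ensemble validate the estimator and pipeline mechanics, not oceanic
mechanism.

## Processing chain decisions

**Minute binning.** Within each minute (and wavelength), samples strictly
outside the 2.5th–97.5th percentile interval (linear-interpolation
quantiles; boundary values retained) are dropped before averaging; the
standard deviation of the retained samples is the per-minute uncertainty.
An empty minute yields a missing marker, never an error. A trim this
width absorbs spike incidences up to roughly its own 2.5% capacity per
minute; beyond that, spikes begin to leak into the mean — visible in the
tests as a bounded worst-case error at a 1% spike rate.

**Baseline subtraction.** Each contiguous filtered-seawater period is
summarized by its median spectrum at its mid-time. Between periods the
baseline is linear in time, or — `method = "fcdom_scaled"` — varies
proportionally to the normalized fCDOM excursion between the bracketing
medians, falling back to linear when fCDOM is flat (so the two methods
coincide exactly in that limit). Before the first and after the last
period the nearest baseline is used: extrapolating a trend into
unobserved time would invent structure. The decomposition conserves
exactly: baseline + particulate = total at every minute and wavelength.

**Proxies.** Chlorophyll line height subtracts a linear baseline between
650 and 715 nm from the absorption at 676 nm (the peak wavelength is the
established convention; the baseline endpoints are configurable since
conventions differ). The particle-size exponent is fitted over
450–700 nm excluding 660–690 nm, because the power-law model describes
non-absorbing particulate shapes and the chlorophyll peak would
contaminate the fit; non-positive values (possible after baseline
subtraction) are excluded from the log-space fit, and fewer than 5 usable
wavelengths gives a missing value.

**Legs and quality control.** Legs are 500 consecutive stream rows.
Small gaps are `NA` cells in existing rows and count against the 80%
coverage rule; minutes wholly absent from the table stretch the leg's
elapsed time and are caught by the 16-hour rule. This division of labour
is why both rules exist; a design that padded every missing minute with
an empty row would make elapsed time constant at 8.3 h and the 16-hour
rule vacuous. "Distance traveled" is cumulative along-track path length
(30–150 km), not net displacement — a sailing vessel can tack a long
path through a small box, and path length is what "traveled" measures.
All rule violations are recorded per leg as reason codes
(`distance_short`, `distance_long`, `coverage`, `elapsed`), and
relaxing any criterion can only keep more legs (a tested monotonicity).

## Comparative layer

Correlations between per-leg variance slopes are Pearson on untransformed
slopes (Spearman available), pairwise-complete over legs where both fits
are valid, with two-sided p-values and no multiple-testing correction —
results are reported per comparison. Province aggregation takes
unweighted means per province and variable, keeps provinces with at
least 25 distinct legs, and joins user-supplied covariate tables by
province label; province geometry itself (point-in-polygon assignment)
is out of scope and arrives as a mapping table. The spatial
autocorrelogram bins all leg-centroid pairs by haversine distance into
10 logarithmic bins by default and reports the Moran-style pair
correlation per bin, flagging bins with fewer than 10 pairs; because
pairs share legs, its null fluctuations are wider than the
independent-pair $2/\sqrt{n}$ envelope.

The end-to-end decoupling property ties the layers together: an ensemble
whose temperature and chlorophyll mean levels are copula-correlated at
$r = 0.6$ but whose spectral exponents are drawn independently shows a
pooled value correlation well above the null while the slope–slope
correlation stays within it — correlated quantities, uncorrelated
patchiness.

## Problem sizes and tolerances

The test suite runs on ensembles sized to make each property decisive at
desk scale: 500-leg ensembles for the white-noise null (mean within 0.05
of zero and within three standard errors), 100 seeds per exponent for the
monotonicity of $\Gamma$ in $\beta$, 220-leg ensembles for the
$\Gamma$–spectral-slope map, 100-leg ensembles at 15% and 50 at 20% gaps
(ensemble median slope shift at most 0.1; no failures at 20%), and
machine-precision assertions (1e−10 to 1e−14) wherever a closed form
exists. `scripts/acceptance.R` regenerates the two headline numbers from
scratch with 250 and 500 legs respectively.

## Known limitations

* The $\Gamma \leftrightarrow$ spectral-slope mapping is convention
  dependent (taper, window scheme, leg length); treat its evaluation at
  $-5/3$ as a property of this pipeline's defaults, not a universal
  constant.
* Log-invariance is approximate and worsens with lognormal variability;
  comparisons of raw-space and log-space slopes at high coefficients of
  variation should use one convention throughout.
* No uncertainty is attached to a single leg's $\Gamma$ (a bootstrap
  over blocks would be a natural extension); ensemble spread is the
  package's working notion of uncertainty.
* Windows are non-overlapping; a sliding-window variant would use the
  data more efficiently at large scales at the cost of correlated block
  variances.
* The scheme converts windows to kilometres with the leg's median step;
  legs with highly variable speed blur the nominal 0.6–100 km range.
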