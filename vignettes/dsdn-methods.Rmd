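---
title: "Profiling non-stationarity and non-linearity in resting-state BOLD series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling non-stationarity and non-linearity in resting-state BOLD series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dsdn` asks, voxel by voxel, how far a resting-state BOLD time series
departs from the two assumptions that underlie most connectivity
analyses: stationarity (the statistics of the signal do not change over
the scan) and linearity (the dynamics can be captured by a linear
Gaussian process, possibly through a static transform). This vignette
documents the two statistics, every tunable that matters, the synthetic
data the package validates itself on, and the numerical and design
choices a maintainer should know about.

## The degree of stationarity (DS)

A voxel series `x(n)`, `n = 1..N`, is decomposed by empirical mode
decomposition (EMD) into `M` intrinsic mode functions `c_j` and a
residual `r_M`, with `x = sum_j c_j + r_M` holding exactly by
construction of the sifting recursion. Each IMF is extended to its
analytic signal, yielding an instantaneous amplitude `a_j(n)` and an
instantaneous frequency `w_j(n)` (the derivative of the unwrapped
analytic phase, in cycles/sample). Binning the frequencies on a uniform
grid over (0, 0.5] and accumulating amplitudes gives the Hilbert
spectrum `H(w, n)`; its time sum is the marginal spectrum
`h(w)`, and `B(w) = h(w) / N` is the average spectrum. The degree of
stationarity per frequency bin is

```
DS(w) = (1/N) * sum_n (1 - H(w, n) / B(w))^2
```

A process whose Hilbert spectrum carries only horizontal contours —
energy in each band constant over time — has `DS(w) = 0` identically;
any temporal redistribution of spectral energy makes `DS(w) > 0`. The
statistic is a pure function of the series: no randomness anywhere, so
identical inputs give bit-identical profiles.

**Collapsing DS(w) to one value per voxel.** The per-frequency profile
must be aggregated to a scalar for maps and tables, and the aggregation
is genuinely an open choice: empty bins carry no information, and bins
with trace energy carry noisy DS values. We use the
marginal-spectrum-weighted mean `sum_w h(w) DS(w) / sum_w h(w)` over
occupied bins, which weights the statistic where the signal actually has
energy. Absolute DS values therefore depend on this choice (and on the
bin count), and only *orderings* between voxel groups should be
interpreted — which is exactly how the package's own acceptance surface
uses them.

**EMD numerics.** Envelopes are cubic splines through the extrema,
mirror-extended by two extrema at each end; boundary effects otherwise
leak into the first/last IMF oscillations and corrupt DS at the series
edges. Sifting stops when the envelope-mean correction is small
(`sum(m^2)/sum(h^2) < 0.2`) *and* the defining IMF condition holds
(extrema and zero-crossing counts differ by at most one). The condition
is treated as binding: if it is still unmet after the soft cap of 100
sifts, sifting continues until it holds (hard cap 500). Decomposition
ends when the residual retains at most one interior extremum, so a
strictly monotone input yields zero IMFs. Flat segments contribute a
single extremum at their midpoint.

**Hilbert numerics.** The analytic signal comes from the FFT one-sided
method, which assumes periodicity; end effects are handled by trimming
the first and last 5% of timepoints (configurable, `hht_params(trim=)`)
before the DS statistic. Instantaneous frequency uses centred
differences (one-sided at the ends); negative estimates — a known
artefact of near-zero amplitude moments — are clipped to zero and
excluded from binning rather than polluting the lowest bin. The default
64 bins over (0, 0.5] resolve the BOLD band at `N = 256`, `TR = 2 s`
into roughly 20 occupied bins; DS is undefined (excluded, not
zero-filled) on empty bins.

## The degree of non-linearity (DN)

Delay vector variance (DVV) characterises predictability. With
embedding dimension `m`, the delay vectors `x(k) = [x_{k-m}, ...,
x_{k-1}]` each predict a target `x_k`. For a span threshold `tau_d`,
the neighbourhood of `x(k)` collects all delay vectors within `tau_d`
(including `x(k)` itself); the sample variance of their targets,
normalised by the series variance, averaged over all neighbourhoods
with at least `T0` members, is the unpredictability `sigma*^2(tau_d)`.
Spans run uniformly over `[max(0, mu_d - n_d sd_d), mu_d + n_d sd_d]`,
where `mu_d, sd_d` summarise the pairwise delay-vector distances — a
span cannot be a negative distance, hence the truncation at zero. At
the top of the span every neighbourhood contains every vector and
`sigma*^2` approaches 1; the shape of the descent at small spans
carries the signature of deterministic structure.

DN is the RMSE between the original curve and the average curve of an
iAAFT surrogate ensemble, over spans valid in both. iAAFT surrogates
keep the exact amplitude distribution (rank remapping) and converge the
amplitude spectrum to the original's; they are the null of "a monotone
static transform of a linear Gaussian process". Iteration stops early
at the exact rank fixed point, which leaves the result identical to
running the full iteration budget. The per-surrogate deviations from
the ensemble average form the null for a right-tailed test;
`p = (1 + #{d_s >= DN}) / (1 + S)`.

**Defaults.** `m = 3`, `n_d = 3`, 25 spans, `T0 = 30`, 25 surrogates of
at most 100 iterations — the established DVV practice; all are exposed
in `dvv_params()`. Series are standardised before embedding so spans
are comparable across voxels. Per-voxel surrogate seeds derive
deterministically from `(seed, voxel index)`, so maps are reproducible
and independent of evaluation order. Absolute DN values depend on every
one of these parameters; as with DS, only orderings are treated as
reproducible. The `O(N^2)` neighbourhood scan is compiled (Rcpp) with a
sort-and-prefix-sum scheme per reference vector; an exhaustive
double-loop R oracle guards it in the tests.

## Levels, overlap, reliability, similarity

Strong/medium/weak levels use quartile fences: with `Q1, Q3` by linear
interpolation of order statistics (the common type-7 convention —
documented because fence values shift between conventions), values in
`(Q3, Q3 + 1.5 IQR]` are strong, `(Q1, Q3]` medium, and at or below
`Q1` weak. A value exactly at a quartile belongs to the lower interval.
Values beyond the outer fences are counted and reported but stay
strong/weak — the DS distribution is long-tailed and the upper fence is
a fence, not an exclusion. The strong threshold is exposed as a
quantile parameter (default 0.75). Fences default to the group-average
map across all scans, with a per-scan option.

The DS-by-DN overlap map crosses the two strong sets into
`neither/ds_only/dn_only/both`. Because published overlap percentages
do not pin down their denominator, the package makes it explicit:
percentages are relative to the union of the two strong sets by default,
with a whole-mask option.

Test-retest reliability is the consistency ICC from a two-way ANOVA
with random subject and fixed session effects: the session sum of
squares is removed from error, `ICC = (BMS - EMS) / (BMS + (k-1) EMS)`,
`F = BMS/EMS` on `(n-1, (n-1)(k-1))` degrees of freedom. Negative ICCs
are reported as computed. No multiple-testing correction is applied to
the voxel-wise p-values by default (the p < 0.05 mask mirrors common
practice; a Benjamini-Hochberg adjustment is a one-liner on the
returned tibble). Between-network similarity correlates per-scan
network means across scans; slice similarity correlates DS against DN
within each axial plane. Welch's unequal-variance t is the default
two-sample test between networks, with the pooled variant behind a
flag.

Kernel densities for the distribution summaries are exact Gaussian
kernel sums on a 512-point grid spanning the data plus three
bandwidths (Silverman rule-of-thumb bandwidth by default) — exact
rather than binned, so the suite can hold it to a direct kernel-sum
oracle at 1e-10.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds a multi-subject, multi-session study on a
small grid: seven network blocks (slabs of the first axis, restricted
to the middle slices so a realistic fraction of the volume is
background), band-limited (0.009-0.08 Hz) unit-variance voxel series at
`TR = 2 s`, and additive Gaussian noise filtered with the signal at SNR
2. Four process classes plant the structure the estimators must
recover:

- `ar_linear` (DAN, FPN): stable Gaussian AR(2), coefficients
  (0.5, 0.2) — stationary and linear;
- `am_fm_nonstationary` (VN, SMN): a tone with full-depth amplitude
  modulation at 0.01 Hz and a 0.03-0.06 Hz frequency sweep —
  non-stationary but linear;
- `nonlinear_map` (LIMB, DMN): a bilinear AR process
  `x_t = a1 x_{t-1} + a2 x_{t-2} + b x_{t-1} e_{t-1} + e_t`, `b = 0.8`
  — stationary with genuinely dynamical non-linearity. A static cubic
  distortion and a logistic map are available alternatives, but neither
  is the default: a static monotone distortion lies *inside* the iAAFT
  null by construction, and the broadband logistic map loses most of
  its detectable determinism under band-pass filtering;
- `nonlinear_nonstationary` (VAN): the bilinear process under the same
  amplitude modulation.

Subject/session structure is planted on each kind's designated scalar
parameter (modulation depth, bilinear coupling, leading AR
coefficient): the per-voxel draw `b_iv + w_isv` with variances
`sigma_b2 = 0.6`, `sigma_w2 = 0.4` has population ICC 0.6 by
construction, independent of the DS/DN estimators, and enters the
signal through `exp(0.25 * draw)` to stay positive.

What passing tests on this generator show: the estimators order the
planted classes correctly (non-stationary above stationary for DS,
non-linear above linear for DN), the surrogate test is calibrated on
linear series, and the whole pipeline is deterministic and complete.
What they do not show: behaviour under hemodynamic convolution, head
motion, physiological noise, spatial smoothing or registration error —
none of which the generator models — so absolute DS/DN levels on real
scans are not predicted by these tests.

## Problem sizes and design scale

The package's own validation runs at desk scale, chosen so the full
suite exercises every stage: the end-to-end study uses an 8x8x4 grid
(112 in-mask voxels), 5 subjects x 3 sessions, `N = 256`; the
100-seed ordering study uses single scans with two voxels per network
at the same `N` and identical process parameters; ICC recovery uses
200 replicates of 50 x 10 panels. The statistics are insensitive to
grid size by construction (every voxel is processed independently); the
panel and seed counts set the Monte-Carlo resolution of the stated
tolerances.

## Known limitations

- DS depends on the EMD variant: ensemble or multivariate EMD (out of
  scope) would change absolute values.
- The instantaneous-frequency estimator is a simple phase difference;
  very low-frequency IMFs at short `N` produce few occupied bins, and
  their DS contribution is noisy (mitigated by marginal weighting).
- DVV with `T0 = 30` needs `N` of a few hundred; at `N < 100` many
  spans go invalid and DN rests on few points.
- The surrogate test inherits iAAFT's null: static monotone
  non-linearities are by design not detected.
- A heavy-tailed marginal distribution (e.g. from a cubic output
  distortion) inflates DS through amplitude bursts even when the
  process is second-order stationary; DS is a spectral-variability
  measure, not a formal stationarity test.
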