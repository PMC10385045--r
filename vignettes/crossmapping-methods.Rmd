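---
title: "Cross-mapping autonomic correlates onto facial skin temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-mapping autonomic correlates onto facial skin temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocm)
```

## The scientific question

Facial skin temperature is modulated by the autonomic nervous system
through two main effector pathways: vasomotor control of subcutaneous
blood flow (reflected in heart rate variability, HRV) and sweat gland
activity (reflected in electrodermal activity, EDA). Linear correlation
between a thermal time series and either autonomic correlate is typically
weak, yet the three signals may still be observations of one underlying
dynamical system. `thermocm` implements the nonlinear analysis that makes
this hypothesis testable: if two series are generated by the same system,
the delay embedding (shadow manifold) of one can be used to *estimate* the
other, and the rank correlation between the estimate and the observation
— written $\rho_{\hat Y Y}$ — quantifies the coupling. The package also
carries the full surrounding apparatus: preprocessing of cardiac and
electrodermal recordings into uniformly sampled 5 Hz, 150-s segments,
HRV/EDA feature extraction, permutation inference and group statistics.

Because raw human recordings of this kind are rarely shareable, every
stage is exercised against seeded synthetic generators with known ground
truth (coupled chaotic maps, a Lorenz system, ECG-like spike trains,
latent-driver triplets, split-plot cohorts). What the generators do and do
not emulate is discussed at the end.

## The cross-map estimator

For a predictor series $X$ and target $Y$, sampled simultaneously at the
same rate, the pipeline:

1. selects the embedding delay $\tau$ of each series at the first minimum
   of its automutual information (MI) curve;
2. selects the embedding dimension $m$ of each series with the false
   nearest neighbours (FNN) algorithm;
3. embeds the *predictor*: $\mathbf{x}_t = (x_t, x_{t-\tau},\dots,
   x_{t-(m_x-1)\tau})$;
4. for each point $\mathbf{x}_t$, finds its $k = \max(m_x, m_y)+1$
   nearest neighbours at times $t_1,\dots,t_k$ (nearest first), and
   estimates

$$
\hat Y_t = \sum_{i=1}^{k} \omega_i\, Y_{t_i},\qquad
\omega_i = \frac{u_i}{\sum_j u_j},\qquad
u_i = \exp\!\left(-\frac{\lVert \mathbf{x}_t-\mathbf{x}_{t_i}\rVert}
                        {\lVert \mathbf{x}_t-\mathbf{x}_{t_1}\rVert}\right);
$$

5. scores the estimate with the Spearman correlation
   $\rho_{\hat Y Y}$ over the valid (aligned) time range.

Each $\hat Y_t$ is a convex combination of observed target values, so the
estimate always lies inside the observed range. Two numerical corner
cases are fixed by convention: if the nearest neighbour distance is
exactly zero the weights collapse uniformly onto the zero-distance set
(the continuous limit of the formula), and neighbour ties at equal
distance are broken by the smaller time index so results are
deterministic. The query point itself and any point within a Theiler
window of $\tau$ samples are excluded from the neighbour search, which
prevents trivial temporal self-matching from inflating $\rho$; the window
is capped so that every query retains at least $k$ candidates on short
manifolds.

```{r}
cp <- gen_coupled_logistic(1000, rx = 3.8, ry = 3.55,
                           beta_xy = 0, beta_yx = 0.4, seed = 1)
x <- uniform_series(cp$x, fs = 5, label = "driver")
y <- uniform_series(cp$y, fs = 5, label = "driven")
cross_map_pair(y, x)   # driver recovered from the driven series
```

The direction is explicit throughout: in the thermal analysis the
physiological signal is always the predictor (its manifold is built) and
the thermal signal is the target being estimated.

## Embedding parameter selection

**Delay.** The MI curve is estimated with an equal-width 2-D histogram
(`ceiling(sqrt(N/5))` bins, capped at 32 — at the 750-sample segment
length this balances bias against resolution). The curve is smoothed with
a 5-point moving average and the selected lag is the first *prominent*
local minimum: the unique minimum within ±2 lags, followed within 15 lags
— and before any lower value — by a rise of at least 1.5% of MI(0). The
prominence requirement is what makes the selector robust: a flat noise
curve produces shallow single-sample dips that a bare "first strict local
minimum" rule would latch onto, while noiseless oscillatory signals
produce period-2 binning parity wiggles superposed on a broad basin; the
undercut veto walks past those wiggles to the true bottom. When the curve
has no internal minimum at all — map-like or noise-like data whose
dependence decays from the first lag — the fallback is $\tau = 1$, the
standard unit delay for discrete maps. (A fallback based on thresholding
the MI value itself was tried and rejected: binned MI of a deterministic
map stays high at lags that are already chaotically decorrelated, which
drags $\tau$ upward and collapses cross-map skill.)

**Dimension.** FNN fractions are computed for $m = 1..10$ with the
classical Kennel constants ($R_{tol} = 15$, $A_{tol} = 2$) on forward-lag
windows, testing the forward coordinate $x_{t+m\tau}$. The forward
direction matters: the package's manifolds use backward lags (so the
valid time range is a suffix, simplifying alignment), but the backward
test coordinate is a *preimage*, which is multivalued for non-invertible
maps — the logistic map would never unfold. The selected dimension is the
first $m$ whose fraction falls below 0.01, or failing that the first
flattening (drop below `change_threshold = 0.01`) at a fraction below
0.1; if neither occurs — as for noise, which has no finite-dimensional
attractor — `m_max` is returned with a warning. The 0.1 level guard is
needed because noise FNN curves flatten near 0.2 and would otherwise
satisfy the bare flattening rule.

```{r}
lor <- gen_lorenz(5000, dt = 0.01, seed = 1)
tau <- select_tau(lor$x)
m <- select_m_fnn(lor$x, tau)
c(tau = as.integer(tau), m = as.integer(m))
```

## Preprocessing

* **QRS detection** (`detect_r_peaks`) follows the adaptive-threshold
  recipe: 5–15 Hz zero-phase band-pass, derivative, squaring, 150 ms
  moving-window integration, then running signal/noise peak estimates
  with a search-back rule triggered when the gap since the last beat
  exceeds 1.66 times the running RR average. Constants are the classical
  published ones.
* **RR artifact correction** (`correct_rr_artifacts`) compares each
  interval to a 5-interval running median; absolute deviations above
  0.45 s (the lowest detection threshold) are flagged and replaced by
  cubic-spline interpolation over clean intervals, and beat times are
  rebuilt by cumulative summation from the first beat. The correction is
  idempotent.
* **Uniform resampling** (`rr_to_uniform`) attributes each RR value to
  its ending beat and interpolates with a piecewise cubic spline onto a
  5 Hz grid anchored at the first knot (the grid phase is a convention;
  nothing downstream depends on it).
* **Tonic/phasic EDA split** (`decompose_eda`) defines the tonic
  component spectrally as the sub-0.05 Hz content, extracted with a
  zero-phase 4th-order Butterworth low-pass; the phasic component is the
  residual, so the decomposition conserves the signal exactly. The
  decomposition is pluggable: any externally computed split (for example
  a convex-optimisation sparse decomposition) can be wrapped in
  `eda_decomposition()` and used downstream unchanged.
* **Zero-phase filtering** everywhere uses even (mirror) reflect padding
  of six periods of the lowest cutoff. Odd (point-symmetric) extension
  was evaluated and rejected: for oscillatory signals with non-zero
  endpoints it injects a DC step of twice the endpoint value into the
  extension, which a low-pass happily passes. The residual mirror-kink
  leakage is confined to roughly two filter periods at each edge; tests
  of stop-band attenuation therefore measure the interior of the
  segment.

## Features

HRV time-domain features (`meanHRV`, `stdHRV`, `RMSSD`, `pNN50`) are
computed on corrected, non-interpolated RR intervals; frequency-domain
features (`LF`, `HF` as percentages of 0–0.40 Hz power excluding DC, and
their ratio) on the 5 Hz interpolated series, matching standard HRV
practice. The spectral estimate is Welch's method with 60-s Hann-windowed
segments at 50% overlap — the longest segment that still averages
several periodograms within a 150-s record while resolving 0.04 Hz. EDA
features use non-overlapping 30-s (tonic) and 5-s (phasic) windows;
phasic peaks are local maxima above 0.01 signal units (a conventional
skin-conductance-response criterion; the threshold is a parameter).
`EDASymp` is the 0.04–0.25 Hz Welch band power of the reconstructed
conductance. Scale equivariance holds for all amplitude features;
`NPks` is scale-invariant provided peaks are not near the absolute
threshold.

## Inference

* **Block permutation test.** The significance of $\rho_{\hat Y Y}$ (and
  of the linear baseline $\rho_{XY}$) is assessed by cutting the observed
  target series into consecutive blocks of length $L$ equal to the target
  series' delay $\tau$, shuffling block order 1000 times, and recomputing
  the Spearman correlation against the *fixed* estimate; the two-sided
  p-value uses the add-one estimator on $|\rho|$. A final short block is
  kept (no data discarded), and the pipeline caps $L$ at a tenth of the
  series so the null always has at least 10 blocks. Re-estimating
  $\hat Y$ on every shuffle would be the more expensive reading of the
  procedure; the fixed-estimate reading is implemented. It is worth
  knowing that this reading is mildly anticonservative when $\tau = 1$
  reduces blocks to single samples, because the estimate is built from
  the target's own values; at the delays typical of slow physiological
  segments the effect is small (observed null rejection ~8–10% at
  $\alpha = 0.05$ in the zero-coupling synthetic triplets, against the
  nominal 5%).
* **Wilcoxon signed-rank** (rest vs stress, per feature): zero
  differences dropped, exact null up to 25 untied differences, normal
  approximation with tie and continuity correction otherwise.
* **Two-stage FDR.** Stage one runs the linear step-up at
  $q' = q/(1+q)$ to estimate the number of true nulls $\hat m_0$; stage
  two runs the step-up at $q\,m/\hat m_0$. With this stage-two level the
  rejection set always contains the single-stage step-up rejections at
  $q$ (the variant with $q'$ in stage two — as in the original two-stage
  formulation — does not have that property; the package adopts the
  dominating variant and its empirical FDR stays below $q + q^2$).
* **Split-plot ANOVA** (`spanova`): one between-subjects factor (gender)
  tested against subjects-within-groups, one within-subjects factor
  (condition, two levels) and their interaction tested against the
  condition-by-subjects residual. Unbalanced group sizes are handled
  with Type-II sums of squares via nested model comparison; with two
  within-subject levels sphericity holds automatically, so p-values come
  straight from the F distribution.

## The synthetic generators

`gen_physio_triplet` emulates the co-recorded study segments: 150 s at
5 Hz, three channels tied to one latent driver (low-pass-filtered
Gaussian noise, cutoff 0.05 Hz, unit variance) through channel-specific
monotone, lagged transforms — thermal: negated driver lagged 2 s (a
vasoconstriction-like inverse relation); RR: `tanh` of the driver lagged
1 s around a 0.85 s baseline; tonic EDA: softplus of the driver lagged
0.6 s. Each channel adds a small linear baseline trend (±0.02 units per
segment) and white observation noise (default sd 0.05). The couplings
are the ground truth: zero detaches a channel from the driver entirely.
This is deliberately a *minimal* realisation of shared-system coupling,
not a mechanistic thermoregulation model: real thermal series have
motion and perspiration artifacts, circadian drift, and nonstationary
coupling that the generator does not emulate, so passing tests
demonstrate correctness of the estimators, not validity of any
physiological claim.

`gen_coupled_logistic` provides the standard cross-mapping benchmark
$x_{t+1} = x_t(r_x - r_x x_t - \beta_{xy} y_t)$ with a 300-iteration
burn-in. Initial values are drawn in (0.2, 0.8); after one step the
state obeys $x \le r_x/4$, which provably confines moderately coupled
regimes (e.g. $\beta = 0.4$ with $r_x = 3.55$, $r_y = 3.8$) to $[0,1]$,
while regimes that do escape raise an explicit divergence error. The
ECG generator renders beats from an AR(1) RR process (gaps clamped to
(0.3, 2.0) s) as narrow Gaussian spikes — enough to exercise detection
and artifact logic, with no P/T-wave morphology. The cohort generator
produces balanced-within split-plot data with effect-coded gender,
condition and interaction effects plus a subject random intercept
(sd 1 by default).

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at the study's
native scale (750-sample segments) or the benchmark scales quoted above:
convergence over 25 paired seeds at $N \in \{200, 2000\}$, permutation
calibration over 200 runs of 200 permutations, FDR over 500 replicates of
100 hypotheses, ANOVA calibration over 200 cohorts, and a 30-subject
end-to-end study reproduced twice byte-for-byte from one master seed.
Per-subject seeds derive from the master seed by a stable counter scheme,
so any subject's results can be regenerated in isolation; the output
manifest records the seed and a hash of the scientific configuration
(output paths excluded, so the same analysis is byte-identical wherever
it is written).

## Known limitations

* The tonic/phasic split is a spectral stand-in; sparse deconvolution
  methods attribute slow skin-conductance recovery differently.
* The fixed-estimate permutation null inherits the mild anticonservatism
  discussed above; where exactness matters at $\tau = 1$, a
  surrogate that re-estimates $\hat Y$ per shuffle would be needed.
* FNN-based dimension selection returns `m_max` with a warning on
  noise-dominated channels; cross-map scores for such channels are valid
  but their embedding is not a meaningful attractor reconstruction.
* The estimator targets fixed-length segments; no library-length sweep
  API is provided beyond what the convergence tests construct directly.
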