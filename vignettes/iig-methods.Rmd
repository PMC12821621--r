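---
title: "Directed connectivity from voxel states: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity from voxel states: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iigfc)
```

This vignette documents the statistical model behind `iigfc`, the
tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where more than one reasonable choice existed.

## The IIG causality test

A region's state at volume $t$ is the vector of its voxel values
$X_t \in \mathbb{R}^{V}$. For two distance matrices $d_A, d_B$ over the
same $N$ instances, the *information imbalance*

$$\Delta(A \to B) \;=\; \frac{2}{N}\,\big\langle\, r_B(i,\,\mathrm{nn}_A(i)) \,\big\rangle_i$$

averages, over instances $i$, the rank (in $i$'s row of $d_B$, nearest
$= 1$, self excluded) of $i$'s nearest neighbour under $d_A$. If the
neighbourhood structure of $A$ fully determines that of $B$,
$\Delta = 2/N$; if the two geometries are unrelated, the expected rank
is about $N/2$ and $\Delta \approx 1$.

To test whether region $X$ drives region $Y$ at lag $\ell$ volumes,
instances are the (present, future) pairs $t \to t + \ell$, built
within epochs only (analysis windows are treated as independent
epochs; lagged pairs never straddle a window boundary). The test
statistic is the *gain*

$$G \;=\; \Delta\!\big(d_{Y_t} \to d_{Y_{t+\ell}}\big) \;-\;
         \Delta\!\big(d_{(X_t, Y_t)} \to d_{Y_{t+\ell}}\big),$$

with the combined distance $\sqrt{d_X^2 + d_Y^2}$, i.e. the Euclidean
distance on the concatenated voxel states. $G > 0$ indicates that the
source's present state carries predictive information about the
target's future beyond the target's own past. Significance is assessed
against a permutation null: the time indices of $X$'s instances are
randomly permuted (within epochs, whole voxel patterns moving
together), the gain recomputed for each of `n_permutations` draws
(default 100), and the observed gain expressed as a Z-score against
the null's mean and standard deviation. Aggregation over
(subject, hemisphere) units uses Stouffer's
$\tilde Z = \sum_i Z_i / \sqrt{k}$.

Assumptions worth keeping in mind: distances are Euclidean on
(by default) per-voxel z-scored series; the test conditions only on
the target's *single-volume* present state, not its full history; and
the permutation null destroys *all* temporal structure of the source,
so any reproducible temporal alignment between the regions — causal or
not — can contribute to the observed deviation.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `lag_volumes` | 1 | prediction lag, in volumes (3 s at TR 3 s); matches the lag used by the MI baseline |
| `n_permutations` | 100 | permutation-null size; Z-score resolution scales as $1/\sqrt{B}$ |
| `k` | 1 | neighbours averaged in the imbalance; $k=1$ is the most sensitive and the conventional choice |
| `weight` | 1 | weight of $d_X$ inside the combined distance; 1 is the plain concatenation formula, 0 recovers the target-only distance. Exposed because variants of the test scan this weight; the default performs no scan |
| `standardize` | TRUE | z-score each voxel over the analysed segment before distances |

Rank ties are broken by ascending instance index after a stable sort —
deterministic, and measure-zero for continuous data. An optional guard
excludes temporally adjacent instances from the nearest-neighbour
search (off by default; it addresses autocorrelation concerns but is
not part of the core definition). Instances from different task blocks
are pooled into one ranking problem, with lags epoch-restricted; this
uses all available volume pairs at the cost of mixing block contexts,
and is the package default.

### Why voxel series are standardized

BOLD offsets and per-voxel gains are scanner- and tissue-dependent and
carry no information about coupling; without standardization,
high-variance voxels would dominate every distance. Standardization is
per voxel *over the analysed segment*, so that condition-restricted
analyses are self-contained. It can be disabled (`standardize =
FALSE`) for data already normalized upstream. No hemodynamic-delay
shift is applied when mapping task blocks to volume windows; an
integer-volume shift is exposed (`shift_volumes` in
`segment_by_condition()`, default 0) for users who want one.

## Baseline metrics

Both baselines operate on the region-mean series (voxel average per
volume) — their sample-size requirements rule out voxel-level use at
80 volumes.

**Lagged mutual information.** $I(y_t;\, x_{t-\ell})$ in nats,
estimated by a plug-in with uniform ("box") kernels of half-width
$h = 0.2$ on z-scored series: marginal and joint densities are
evaluated at the sample points and averaged as
$\langle \log \hat f_{xy} / (\hat f_x \hat f_y) \rangle$. Densities
are evaluated *leave-one-out* (the evaluation point is excluded from
its own kernel sums): the self-inclusive plug-in carries a positive
bias of order $1/(n h^2)$ — about $+0.06$ nats at $n = 2000$ — that
would swamp the independence limit, while the LOO estimate is unbiased
to leading order and still recovers $\ln 2$ within 2% on a balanced
lagged-copy sequence. Negative plug-in values are clipped at 0 (the
raw value is retained); a degenerate (constant) input yields 0 with a
flag. Significance comes from permuting the source series
(`p = (1 + \#\{null \ge obs\}) / (1 + B)`, one-sided add-one
estimator, never exactly 0).

**Granger causality.** Ordinary least squares of $y_t$ on its own
`order` lags (restricted) and additionally on the source's lags
(unrestricted), both with intercept;
$F = \frac{(RSS_r - RSS_u)/p}{RSS_u/(n - 2p - 1)}$ with the upper-tail
F probability. The models are pure autoregressions of configurable
order (default 1): a moving-average component is unidentifiable at 80
volumes, and AR-based testing is standard practice. The implementation
is checked in the test suite against an independent implementation
(`lmtest::grangertest`) and a normal-equations oracle.

Aggregated MI/GC results are reported as $\log_{10}$ of the Fisher
combined p-value ($-2\sum \ln p_i \sim \chi^2_{2k}$), floored at $-16$;
values below $-2$ / $-3$ mark significance at $\alpha = 0.01$ / 0.001.
Fisher's independence assumption is taken at face value; no dependence
correction is applied.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not scanner physics. Per hemisphere, each region $r$ has a latent
neural signal on a fine grid (step `dt_s`, default 0.5 s):

$$n_r(t) \;=\; \beta_r(t) \;+\; \sum_{e:\, \mathrm{src}\to r} a_e\, n_{\mathrm{src}}(t - \lambda_e) \;+\; \eta_t,
\qquad \eta_t \sim \mathcal N(0, \sigma_n^2),$$

where $\beta_r(t)$ is the task drive: `beta_contra` (default 1) during
blocks contralateral to the region's hemisphere, `beta_ipsi` (default
0.4) during ipsilateral blocks. The latent signal is convolved with a
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
unit dispersions, undershoot ratio 1/6 — the conventional
parameterization; the kernel is normalized inside the simulator so a
sustained unit drive plateaus at 1), sampled at the TR, and projected
to voxels: voxel $v$ = loading$_v$ · BOLD + drift + observation noise,
with loadings uniform on $[0.5, 1.5]$, optional sinusoidal drift
(period 120 s, amplitude default 0 so oracle tests stay exact), and
white observation noise `sigma_obs` (default 0.3). White-matter sulcal
voxels (8 of 30 by default) instead carry a convex mixture
(`wm_mixture`, default 0.5) of the precentral and postcentral BOLD —
the fibre-passing signal that motivates the cortex-only sulcus
analysis. A 30 s burn-in is discarded; per-subject seeds are
`master seed + subject index`.

Default amplitudes were chosen once for realism at 1.5 T: after
haemodynamic smoothing the neural noise contributes regional
fluctuations of roughly a quarter of the task plateau, and task,
regional noise and voxel noise contribute variance of the same order —
block-design task responses and spontaneous fluctuations are
comparable in real BOLD.

Scenario presets (`scenario_graph()`): *mediated* — both gyri feed the
sulcus (gain 0.8, lag 1 TR) and the sulcus relays back at a sub-TR lag
of one simulation step; *direct* — gyri feed the sulcus and the
postcentral gyrus drives the precentral gyrus, all at 1 TR; *null* —
no edges. The relay edges default to gain 0.4 rather than 0.8: the two
feed-forward/relay loops share the sulcus, so the total loop gain is
$2 \cdot 0.8 \cdot g_{\mathrm{relay}}$, and 0.8 everywhere would give
1.28 — a divergent recursion (the simulator detects divergence and
rejects the graph). 0.4 keeps the loop at 0.64 with a healthy
stability margin.

**What the generator does not emulate:** spatial autocorrelation of
voxel noise, physiological (cardiac/respiratory) structure, motion
artifacts, nonlinear haemodynamics (balloon-type models),
between-region HRF variability, and scanner drift beyond a single
sinusoid. Passing tests on simulated cohorts therefore demonstrate the
*statistical* correctness of the pipeline — calibration under the
null, recovery of planted coupling, robustness to voxel-count
asymmetry — not performance under all real-data artifacts.

## Calibration properties and a limitation worth knowing

On cohorts of truly independent regions (task amplitudes 0), per-unit
IIG Z-scores are well calibrated (mean within $\pm 0.5$, sd within
$[0.6, 1.5]$ across replicate cohorts) and voxel-count asymmetry
(100-voxel source vs 10-voxel target) does not create spurious
aggregate causality. With the task drive on, regions share a common
time-locked component even without coupling; the per-unit Z acquires a
small positive bias (of order $+0.2$–$0.3$ in the default
configuration), which is visible but stays below the aggregate
significance threshold for 9-subject cohorts. The shuffled-source
control (`shuffle_control = TRUE`) is the appropriate negative control
on real data, since it preserves both marginals exactly.

A structural limitation surfaced by the simulator: *sub-TR feedback is
not invisible*. One might expect coupling faster than the sampling
resolution to appear only as instantaneous correlation and thus escape
a predictive-causality test. That holds in discrete-time dynamics at
the TR scale, but not under a latent continuous-time model with
haemodynamic convolution: a relay of even a fraction of the TR spreads
into subsequent volumes through the HRF, and because single-volume
voxel states are a noisy, effectively rank-one reading of the regional
signal, the source's instantaneous state genuinely improves
nearest-neighbour prediction of the target's future (a denoising
effect). In the mediated preset the sub-TR relay edges are accordingly
detected at intermediate aggregate strength (Stouffer $\tilde Z
\approx 3$–5 for 9-subject cohorts) rather than suppressed. Directed
conclusions about fast feedback loops should therefore lean on the
shuffled control and on converging evidence, not on the absence of a
detection threshold.

Because all aggregate cells are examined jointly, negative controls
should also be read with multiple comparisons in mind: across the six
directed cells of a calibrated Z table, the probability that *all*
stay within $|\tilde Z| < 2$ is about $0.95^6 \approx 0.75$ per run,
and similarly for p-value tables; occasional single-cell excursions in
a shuffled control are expected and not evidence of residual coupling.

## Numerical choices and degenerate inputs

* Volumes are 0-based and windows half-open $[start, end)$, making
  concatenation and splitting unambiguous; odd-length runs split at
  $\lfloor T/2 \rfloor$.
* The gain is the raw difference of imbalances (not a ratio): the
  permutation Z-score already normalizes scale.
* A degenerate permutation null (sd 0) is an error, not a silent 0.
* Constant voxels become all-zero after standardization rather than
  NaN; a constant source gives gain exactly 0 and MI exactly 0 (with a
  degeneracy flag); a constant regressor in the Granger design is
  rejected by a rank check naming the regressor.
* In rare permutation draws at small sample sizes, every point's
  leave-one-out joint kernel count can be zero; the MI plug-in then
  returns 0 (no reusable joint mass) instead of propagating NaN.
* Simulated recursions are validated by a divergence guard
  (burn-in plus run must stay bounded), and coupling lags below one
  simulation step are rejected rather than silently rounded to zero.

## Problem sizes used by the test suite

The suite exercises the pipeline at the paradigm's native scale —
80 volumes, 30 voxels per region, 100 permutations, 9-subject cohorts
(18 analysis units) — with 10–20 replicate cohorts for calibration
properties and reduced cohorts (2–3 subjects, 8 voxels) for structural
and determinism checks; these sizes keep the full suite in the
minutes range on a single CPU while leaving every statistical check at
the scale the defaults target.
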