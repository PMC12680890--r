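---
title: "Methods: ultrasonic cell-count estimation with compact neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasonic cell-count estimation with compact neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sonoyeast)
```

This vignette is the package's account of its science: the generative model
behind the simulator, the signal-processing and modeling choices, where the
design was genuinely open and how it was settled, and what the synthetic
results do and do not say about real measurements.

## The measurement and its generative model

A pulse-echo cell consists of a 2 MHz transducer coupled to a buffer rod
(diameter 17 mm) that acts as an acoustic delay line, a sample chamber of
diameter $d = 37.5$ mm holding the yeast suspension, and a parallel
reflector. One excitation produces three echoes:

* $E_1$ — the reflection at the buffer-rod/sample interface. It never
  enters the suspension, so its features characterize the interface
  impedance contrast and serve as an internal amplitude reference.
* $E_2$ — the reflection at the sample/reflector interface, which crosses
  the suspension twice (path $2d$).
* $E_3$ — a further reverberation with an accumulated sample path of $4d$,
  hence stronger attenuation and sensitivity to multiple scattering.

`synth_ascan()` models the recorded waveform as a sum of Gaussian-windowed
tonebursts plus white recording noise:

$$x_0(t) = \sum_{i=1}^{3} A_i\,
  e^{-(t - t_i)^2 / 2\sigma^2} \sin\!\big(2\pi f_0 (t - t_i)\big)
  + \varepsilon(t), \qquad \varepsilon(t) \sim \mathcal N(0, \sigma_n^2)$$

with arrival times $t_1$ (fixed by the buffer rod), $t_2 = t_1 + 2d/c$, and
$t_3 = t_2 + \Delta_3$, and amplitudes

$$A_1 = A_0 r_1, \qquad
  A_2 = A_0\, g_2(\text{strain})\, e^{-2\alpha d}, \qquad
  A_3 = A_0\, g_3\, e^{-4\alpha d}.$$

Two material laws tie the echoes to the suspension:

* attenuation $\alpha = \alpha_0(\text{wort}) +
  k_\alpha(\text{strain})\cdot y$ (Np/m), $y$ the yeast mass fraction in
  wt% — denser suspensions absorb and scatter more, so $A_2$ and $A_3$ fall
  exponentially in $y$;
* sound velocity $c = c_0 + s_w (\text{wort} - 12) + s_y(\text{strain})\, y$
  (m/s) — dissolved extract and cells stiffen the medium, so echoes arrive
  earlier at higher concentrations.

The cell-count label emulates a manual hemocytometer determination:
$N = N_1(\text{strain})\cdot y$ cells/mL with a multiplicative Gaussian
counting error (CV 5%), truncated at zero, and exactly zero for blank
suspensions.

### Default parameters and why

All defaults live in `acoustic_params()` / `vessel_geometry()` /
`sim_config()` and were fixed once, before any model tuning:

| parameter | default | rationale |
|---|---|---|
| $f_0$, $\sigma$ | 2 MHz, 500 ns | transducer centre frequency; a 500 ns Gaussian approximates a four-cycle burst |
| $t_1$ | 12,500 ns | centre of the $E_1$ gate |
| $c_0$ | 1500 m/s | water-like wort at 20 °C; puts $2d/c_0 = 50$ µs, the centre of the $E_2$ gate |
| $s_w$ | 4 m/s per wt% | typical extract dependence of sound velocity in sugar solutions |
| $s_y$ | 8 / 12 / 5 m/s per wt% | strain-dependent cell compressibility/size effects |
| $\alpha_0$ | 6 / 7 / 8 Np/m (10/12/14 wt%) | mild background absorption rising with extract |
| $k_\alpha$ | 9 / 12 / 6 Np/m per wt% | strain-dependent scattering (cell size, flocculation) |
| $r_1$, $g_2$, $g_3$ | 0.25; 0.50/0.55/0.60; 0.35 | interface gains; $g_2$ is strain-dependent so that strain identity remains identifiable even in blank suspensions |
| $\Delta_3$ | 12,000 ns | see "the third echo" below |
| $\sigma_n$ | 0.01 (1% of $A_0$) | oscilloscope-grade noise floor; after 5-signal averaging the effective noise is $\approx 0.45$% |
| $N_1$ | 245/315/165 $\times 10^6$ cells/mL | the strains' maximum counts at 1.0 wt% |
| count CV | 0.05 | plausible hemocytometer repeatability; no published error model exists |

**The third echo.** A literal second round trip would place $E_3$ about
$2d/c \approx 50$ µs after $E_2$, yet its gating window starts only 7 µs
after the $E_2$ window ends. The geometric origin of this early arrival is
not resolved; the simulator therefore uses an explicit reverberation delay
$\Delta_3$ (default 12 µs, centring $E_3$ in its gate) while keeping the
$4d$ attenuation path for its amplitude. The fixed gating windows are
treated as the authoritative constraint; $\Delta_3$ is a stand-in, not an
interpretation.

**Strain separability.** $k_\alpha$, $s_y$, and $g_2$ differ by strain so
that classification is learnable — these are modeling choices of the
simulator, not measured constants. In particular, a strain-dependent $g_2$
is what makes blank (0 wt%) suspensions classifiable at all; with a shared
$g_2$ the three strains would be physically identical at $y = 0$ and
classification accuracy would be capped near 89% on this design.

### What the simulator does and does not emulate

It reproduces the study design (3 strains × 3 worts × 6 levels × 3
replicates, 50 shots per measurement in 0.5 s intervals), the echo
structure and gating windows, concentration-dependent attenuation and
velocity, measurement noise, and label noise. It does **not** model full
wave propagation, frequency-dependent attenuation, multiple scattering,
temperature drift, CO₂/ethanol compositional changes, transducer impulse
response, or fouling. Passing tests on synthetic data therefore demonstrate
that the pipeline and models are correct and recover known structure; they
do not certify performance on real fermentation data.

## Signal processing

* **Filter.** The stated "eighth-order bandpass, zero phase" is realized as
  a fourth-order Butterworth (maximally flat; no family was mandated)
  applied forward and backward: effective magnitude order eight, exactly
  zero phase. At a normalized band of 0.003–0.005 (1.5–2.5 MHz at 1 GHz)
  transfer-function polynomials are numerically unusable, so the design
  stays in zero-pole-gain form and is executed as a cascade of second-order
  sections, each filtered with `signal::filtfilt`. Zero phase matters
  because two of the nine features are echo arrival times.
* **Averaging.** Non-overlapping blocks of five consecutive filtered
  signals are averaged (filtering first, as the processing chain is
  presented); 50 shots become 10 averaged signals.
* **Envelope.** $e(t)$ is the maximum of $|x|$ over a centred moving window
  of 1000 ns (1000 samples at 1 GHz, converted per rate, i.e. an odd window
  of $2\lfloor W/2\rfloor + 1$ samples), with shrinking windows at the
  record edges. This moving-maximum envelope — not a Hilbert transform — is
  what the feature definitions assume. Note that a moving maximum is not
  idempotent (re-application widens plateaus), so the envelope is computed
  exactly once.
* **Features.** Gates are converted ns→index by `round(t · rate / 1e9)`,
  endpoints inclusive. `t_max` ties break to the earliest sample;
  `A_sum` is computed on the filtered, averaged signal (not the envelope)
  and is deliberately not normalized by window length.

## Dataset assembly

* **Row unit.** Each averaged signal is one model row (10 per measurement)
  sharing its measurement's labels: this maximizes training data in the
  spirit of the 50-shot acquisition. `collapse_features()` provides the
  one-row-per-measurement alternative.
* **Splitting.** Because the 10 rows of one measurement are near
  duplicates, the default split is group-aware: a measurement's rows stay
  together across the 80:20 split and across the five CV folds, stratified
  by strain. `make_split(..., group_aware = FALSE)` reproduces a literal
  row-level random split; with it, test metrics are optimistic, which is
  exactly the leakage the default prevents.
* **Standardization.** Means and SDs of the nine echo features are fitted
  on the training rows only — and refitted inside every CV fold on that
  fold's training part — then applied unchanged to validation/test rows.
  One-hot and ordinal columns pass through.

## The network and its training

Architecture and hyperparameters are fixed for all five approaches: input
width 9/12/13 by approach, hidden layers 5 and 3 (ReLU), linear output for
regression, three-way softmax for classification; loss MSE or categorical
cross-entropy plus $\lambda \sum \lVert W\rVert^2$ with $\lambda = 0.001$
(biases unpenalized); Glorot uniform initialization; full-batch L-BFGS.

Numerical choices:

* **Optimizer.** L-BFGS (memory 10, two-loop recursion) with a strong-Wolfe
  line search ($c_1 = 10^{-4}$, $c_2 = 0.9$, bracket/zoom) is implemented
  in the package, because early stopping requires scoring a validation set
  after every optimizer iteration and restarting an external optimizer
  per iteration would destroy its curvature memory. The line-search quality
  is not cosmetic: with a cruder backtracking search the validation loss is
  noisy enough to trigger early stopping prematurely and measurably degrade
  the classifier.
* **Early stopping.** "Epoch" for a full-batch method is one L-BFGS
  iteration. An inner 10% of the training rows (drawn deterministically
  from the seed before optimization; the CV fold itself is never touched)
  is scored each iteration; training stops after 6 iterations without
  improvement (or at 500 iterations), and the weights of the
  best-validation iteration are returned.
* **Scaling.** Regression targets are trained in units of $10^6$ cells/mL
  so MSE magnitudes are $O(10^2)$; predictions are reported in cells/mL.
* **ReLU subgradient** at 0 is taken as 0; softmax is computed with
  row-max subtraction; cross-entropy clamps probabilities at $10^{-300}$.
* **Determinism.** All randomness (waveform noise, counting error, splits,
  validation subsets, initialization) derives from one root seed through
  fixed arithmetic substreams, so every run is bit-reproducible.

## Evaluation

$R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2$, RMSE, and
MAE for regression; confusion matrices (rows = true, columns = predicted)
with per-class precision, recall and F1 in percent and overall accuracy for
classification. The cross-validation figure is the unweighted mean over the
five folds; classification additionally pools out-of-fold predictions into
one CV confusion matrix. Percentages are displayed to one decimal; full
precision is retained in all returned objects and JSON exports. F1 is
computed from unrounded precision and recall. A class that is never
predicted reports precision as `NA` rather than dividing by zero.

## Problem sizes

The package's study configuration is the full design — 162 measurements,
50 signals each — sampled at 100 MHz with all time quantities specified in
ns and converted per rate, which preserves the echo structure of the 1 GHz
production rate at a fraction of the memory and runtime; 1 GHz remains the
default of `sim_config()` for realism. Waveforms are synthesized and
processed one measurement at a time, so peak memory stays at a few
megabytes either way. End to end (simulation, filtering, feature
extraction, training of three approaches with fivefold CV) takes on the
order of three minutes on one CPU at 100 MHz.

## Known limitations

* The acoustic model is parametric and additive; it contains no physical
  scattering theory, so absolute feature values are not comparable to a
  real instrument — only their structure is.
* Strain separability at zero yeast content is injected via $g_2$; real
  blank worts would not carry strain information.
* The hemocytometer error model (multiplicative Gaussian, CV 5%) is an
  assumption; it bounds the attainable regression accuracy at roughly
  $R^2 \approx 0.99$ on this design.
* Early stopping with patience 6 on a 10% validation subset is sensitive to
  the validation draw for very small datasets (approach 1 on a single
  strain uses ~430 training rows; below that, expect variance between
  seeds).
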