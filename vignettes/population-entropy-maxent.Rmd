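---
title: "Population pattern entropy and maximum-entropy models of hippocampal ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pattern entropy and maximum-entropy models of hippocampal ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcode)
```

## The scientific problem

Amyloid-beta pathology degrades synapses long before neurons die, and the
interesting question is what that does to the *population code*: not to
single-cell firing rates, but to the repertoire of joint activity patterns a
network of dorsal-CA1 neurons can produce. `popcode` implements the analysis
chain needed to ask that question from multi-channel extracellular
recordings in head-fixed, wheel-running mice — spike sorting, behavioural
state segmentation, pairwise correlations, pattern entropy, and pairwise
maximum-entropy (Ising) modelling — together with a synthetic-data module
that generates every input with known ground truth, so the whole chain is
testable without access to recorded data.

## Models and estimators

### Binary population patterns

Spike trains are binarized in non-overlapping 10 ms bins (1 if the unit
fired at least once in the half-open bin). The joint state of an N-unit
ensemble in one bin is a *pattern* (or word), encoded as an integer in
`0..2^N - 1` with unit 1 as the least-significant bit. The default ensemble
size is 10 units, giving 1024 possible patterns; ensembles are drawn as
random subsamples of the sorted population (uniformly without replacement
within a draw; unit sets may repeat across the 1000 default draws, since
with, say, 50 units there are ~10^10 possible ensembles and collisions are
immaterial).

### Plug-in entropy

The diversity of the pattern repertoire is measured by the Shannon entropy
of the empirical pattern distribution,

$$H = -\sum_{k} p_k \log_2 p_k \quad \text{(bits)},$$

computed directly from relative frequencies (the plug-in estimator, with
$0\log 0 = 0$). No bias correction is applied — the estimator is kept
deliberately simple, and comparisons are always between conditions
estimated from comparable sample sizes. The plug-in estimator is biased
downward by approximately $(K-1)/(2\ln 2\, n)$ bits for support size $K$ and
$n$ bins; the test suite uses this known bias as an oracle (the measured
bias on independent-Bernoulli ensembles must sit within a factor of two of
the asymptotic value), which is a sharper check than merely observing
convergence.

### Maximum-entropy models

Two nested models are fitted to each ensemble's pattern distribution over
binary states $\sigma_i \in \{0, 1\}$:

$$P(\sigma) = \frac{1}{Z} \exp\Big(\sum_i h_i \sigma_i\Big)
\qquad\text{(independent, order 1)}$$

$$P(\sigma) = \frac{1}{Z} \exp\Big(\sum_i h_i \sigma_i +
\tfrac{1}{2}\sum_{i \ne j} J_{ij}\, \sigma_i \sigma_j\Big)
\qquad\text{(pairwise, order 2)}$$

with $J$ symmetric and zero-diagonal and $Z$ the partition function. The
$\tfrac12\sum_{i\ne j}$ convention double-counts each unordered pair, so it
is equivalent to $\sum_{i<j} J_{ij}\sigma_i\sigma_j$; the convention is
written into every serialized model file because the alternative
($J \to 2J$) rescaling is a classic source of cross-toolbox confusion.

Everything is exact: for $N \le 20$ the $2^N$ states are enumerated
(in chunks, to bound memory), so `logZ`, pattern probabilities, moments and
entropy involve no Monte Carlo and no mean-field approximation. Sampling
from a model is exact categorical sampling over the enumerated
distribution — there are no Markov-chain mixing questions.

**Fitting.** The order-1 fit is the closed-form logit of the marginals,
$h_i = \ln\big(m_i/(1-m_i)\big)$, with marginals clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 1/(2n)$, so that a unit that
never fires in $n$ bins gets a finite bias term consistent with "less than
one spike in $2n$ bins". The order-2 fit maximizes likelihood, which for an
exponential family is equivalent to matching the empirical first and second
moments. The negative log-likelihood is convex with gradient
(empirical − model moments) and Hessian equal to the model's feature
covariance, both computed exactly by enumeration, so the fit uses a damped
Newton iteration with backtracking line search. This converges in tens of
iterations to a moment mismatch below $10^{-6}$ (the convergence criterion
is defined on the moment mismatch — the sufficient statistics — not on
parameter change); a first-order ascent on the same gradients needs orders
of magnitude more iterations once some pattern probabilities are small,
which is the normal situation at 10 ms bins. Empirical second moments are
clipped with the same $\varepsilon$ rule, so pairs never observed together
get large negative, but finite, couplings.

**Model evaluation.** Fit quality is the Kullback–Leibler divergence

$$D(\hat p \,\|\, p_{\text{model}}) = \sum_k \hat p_k
\log_2 \frac{\hat p_k}{p_{\text{model},k}} \quad \text{(bits)},$$

taken empirical-first. This is the likelihood-based direction: it equals
the per-bin log-likelihood shortfall of the model, which makes the nesting
inequality $D(\hat p\|\text{pairwise}) \le D(\hat p\|\text{independent})$
an exact theorem rather than an empirical tendency, and it is always finite
because maximum-entropy probabilities are strictly positive. The
`coactivity_spectrum()` view aggregates pattern probabilities by the number
of co-active units, which is where pairwise models visibly under-predict
highly coactive events in strongly coupled populations.

### Correlations and behavioural conditioning

Pairwise correlations are product-moment correlations of z-scored
instantaneous firing rates: sliding-window spike counts (100 ms window,
10 ms steps — the window width is a free parameter of this analysis and is
exposed in every relevant function signature) z-scored once over the full
recording. Behavioural conditioning subsets the *samples* of these
already-normalized series by epoch label; z-scores are not recomputed
within state, so a rate change between states shows up in the conditioned
series rather than being normalized away. Windows are centred and
truncated at the recording edges.

Running epochs are the samples where |velocity| exceeds 1 cm/s (the wheel
is bidirectional, so the threshold is applied to speed), with velocity
decoded from the 2-bit quadrature encoder state machine, converted to cm/s
and averaged over a centred 150 ms window at 10 ms steps. No minimum epoch
duration or gap-merging is applied.

### Null models and inference procedures

State effects are tested against a *firing-rate-matched shuffle*: each
unit's spikes are redistributed uniformly over the recording (equivalently,
at raster level, each unit's bins are randomly permuted), preserving the
spike count of that realization exactly while destroying all temporal and
cross-unit structure. Preserving the exact count is stronger than
preserving the expected rate and makes the null tighter. The empirical
running-minus-stationary change in correlation (per pair) or entropy (per
ensemble) is compared with the distribution of the same statistic over
1000 shuffles by default.

The shuffle null is exactly calibrated when units are independent and
homogeneous; when genuine correlations exist the shuffle removes them in
the null, making the test conservative for correlation-born entropy
differences. The calibration tests in this package therefore use
independent generative models — that is the regime in which central-95%
coverage should be, and is, ~95%.

Animal-level inference uses a subsampled bootstrap: per repetition, 250
entropy samples are drawn without replacement per animal, averaged within
animal, and group means compared; 5000 repetitions give the distribution of
the group difference.

Group hypothesis tests are two-sided Wilcoxon rank-sum tests
(`stats::wilcox.test`: exact for small untied samples, normal approximation
with tie correction otherwise), with the rank-biserial correlation reported
as effect size. Unit-, pair- and ensemble-level statistics are pooled
across animals within group, mirroring the convention of reporting n as
units / unit-pairs / subsamples; per-animal summaries are also emitted.

## Spike sorting

The sorter follows the classical threshold-and-cluster chain:

1. **Common mean reference** — subtract the across-channel mean per sample.
2. **Detection** — tag contiguous excursions of |voltage| beyond 8 noise
   SDs, either polarity, peak at the extremal sample. The noise SD is
   estimated per channel with the MAD (scaled to SD) so the spikes
   themselves do not inflate the threshold.
3. **Artifact removal** — samples where ≥ 90% of channels are
   simultaneously supra-threshold mark array-wide artifacts; events within
   2 ms are discarded. The 90% criterion is the automated surrogate for
   what would otherwise be a visual judgement of "nearly all channels".
4. **Consolidation** — events on one channel within 1 ms collapse to the
   largest-amplitude peak (biphasic waveforms cross the threshold twice).
5. **Clustering** — per detecting channel, snippets (1 ms pre / 2 ms post
   peak, peak-aligned) are concatenated across the channel and its 8
   nearest neighbours, projected onto the smallest principal subspace
   explaining > 80% of variance, and split by a Gaussian-mixture model.
   The component count is chosen by BIC over k = 1..10 (`mclust`), since
   no selection rule is canonical and BIC is the standard default.
6. **Curation** — an automated, deterministic stand-in for two-reviewer
   waveform inspection: clusters whose mean waveform peaks below 8 SD, or
   whose positive and negative peaks agree within 10% (symmetric waveforms
   are characteristic of noise, not extracellular spikes), are rejected.
7. **Duplicate merging** — if ≥ 50% of a smaller unit's spikes fall within
   0.5 ms of another unit's spikes, the smaller unit is dropped (the same
   neuron detected on two channels). The 0.5 ms / 50% thresholds
   operationalize "highly overlapping spike times".
8. **QC** — units need ≥ 50 spikes and ≤ 10% of inter-spike intervals
   below 3 ms.

On synthetic 16-channel traces (3 units at 12-SD amplitude, 1–3 Hz,
300 s) the chain recovers ≥ 95% of ground-truth spikes with < 2% false
positives and adjusted-Rand agreement ≥ 0.95 — the regime of
well-separated units the generator is designed to produce. The sorter has
no drift correction or overlap decomposition, so heavily overlapping or
drifting units on real probes are out of its scope.

## What the synthetic data emulates — and what it does not

The generators are the package's study conditions, not tuning knobs:

* **Poisson trains** at specified rates (also the generative primitive
  behind the shuffle null).
* **Exact Ising rasters**: i.i.d. bins from an enumerated model
  distribution, so every sample statistic has an exact oracle.
* **Raw traces**: band-limited (500–3500 Hz Butterworth-filtered, rescaled
  to the target SD) Gaussian noise, biphasic waveform templates inserted
  at Poisson times on a peak channel with decaying amplitude on
  neighbours, and broadband artifacts hitting 95% of channels at 12 SD.
* **Behaviour**: alternating stationary / running bouts with exponential
  durations. No distributional form is established for real run bouts;
  the exponential is a declared stand-in. The mean bout length of 1.15 s
  follows from jointly matching a ~6% running fraction and a ~18 s mean
  inter-run interval, the reported summary statistics of this behaviour.
* **Cohorts**: 50-unit populations built from independent blocks of 10
  units, each block a pairwise model with h drawn from N(−5.96, 1.65²)
  (control-like) or N(−6.26, 1.56²) (amyloid-like) and within-block J from
  N(−0.02, 1.15²) vs N(−0.25, 1.04²) — the fitted parameter distributions
  reported for the two conditions, used here as generative truth. Running
  raises every bias term by +0.5 (control-like) or +0.3 (amyloid-like),
  values fixed once to reproduce the reported direction and rough size of
  the stationary-to-running entropy increase in each group.

Real data differ in ways the generator deliberately ignores: couplings are
not block-structured, rates are non-stationary within state, electrodes
drift, spikes overlap, and the amyloid phenotype includes hyper- and
hypo-active subpopulations rather than a clean mean shift. Passing tests
on synthetic cohorts therefore validate the *estimators and inference
machinery* — that the chain recovers known ground truth and reproduces the
qualitative control-vs-pathology signature (lower correlations, lower
entropy in both states, smaller entropy gain with running, lower KLD for
both models in the amyloid-like group) — not the biological claims
themselves.

One caveat worth stating: the *fitted* J values on 10-unit ensembles
subsampled across blocks do not average to the generative within-block
J mean — most sampled pairs span blocks (true coupling 0) and finite
samples at 10 ms bins estimate rare coincidences noisily. Group
*differences* in fitted parameters remain interpretable; absolute fitted
means should not be read as recovering the generative ones.

## Numerical choices and degenerate inputs

* Pattern encoding is fixed (unit 1 = least-significant bit) and written
  into serialized files.
* Bins are half-open `[t0 + k w, t0 + (k+1) w)`; a spike exactly at a bin
  edge belongs to the later bin; epoch membership of a bin is decided by
  its centre, so partial edge bins are excluded from conditioned analyses.
* Zero-spike units have undefined z-scores; their rate series is returned
  as all-zero with a `constant` flag, and correlations involving them are
  `NA` and excluded (with counts) from summaries.
* `logZ` is validated against direct enumeration after every fit
  (to 1e-10); fitted moments are validated against their targets.
* Non-convergent pairwise fits (moment mismatch above tolerance at the
  iteration cap) return the best parameters with `converged = FALSE`
  rather than erroring.
* The firing-rate-matching procedure for entropy comparisons
  (`rate_matched_entropy`) is a one-sided random-deletion surrogate —
  units paired by rate rank, 1-bins deleted from the faster partner — and
  is labelled non-canonical: the original correction it stands in for is
  not fully specified anywhere, so its results are qualitative.

## Problem sizes used in the shipped tests

The packaged test-suite and acceptance script run at sizes chosen to make
every statistical check sharp yet quick on a laptop: cohorts of 4 + 4
animals × 50 units × 30 simulated minutes, 200 entropy subsamples and 40
maximum-entropy fits per animal, shuffle nulls at 200 repetitions, sorting
at 16 channels × 300 s, and parameter-recovery fits at up to 10^6 samples.
Full-scale analyses (1000 subsamples, 1000 shuffles, 5000 bootstrap
repetitions) use the same code paths — those are simply the function
defaults.
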