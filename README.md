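# popcode

Population-coding analysis of multi-channel hippocampal recordings:
spike sorting, behaviour segmentation, pairwise correlations, pattern
(word) entropy, and exact maximum-entropy (Ising) models of binary
population activity — with a synthetic-data module that generates every
input with known ground truth.

`popcode` is aimed at systems neuroscientists asking how a disease state
(here, amyloid pathology in the APP/PS1 mouse model) changes what a
*population* of dorsal-CA1 neurons can represent, beyond what single-cell
rates show. The pipeline runs from raw voltage traces to a group-level
statistical report, and every stage can be validated end-to-end on
generated data because no recorded dataset ships with the package.

## The core quantities

Spike trains are binarized in 10 ms bins; the joint state of an N-unit
ensemble in one bin is a binary **pattern** (word), and the diversity of
the pattern repertoire is its plug-in Shannon entropy

    H = - sum_k p_k log2 p_k   (bits),

estimated over random ensembles (default: 1000 subsamples of 10 units).
Each ensemble's pattern distribution is then modelled by two nested
maximum-entropy models over states sigma_i in {0, 1}:

    independent:  P(sigma) = exp( sum_i h_i sigma_i ) / Z
    pairwise:     P(sigma) = exp( sum_i h_i sigma_i
                                  + 1/2 sum_{i!=j} J_ij sigma_i sigma_j ) / Z

fitted exactly by enumeration of all 2^N states (closed-form logit for the
independent model; damped Newton on the convex likelihood for the pairwise
model, converged when model and empirical moments agree to 1e-6). Fit
quality is the Kullback-Leibler divergence D(empirical || model) in bits.
Behavioural state (running vs stationary, |velocity| > 1 cm/s) conditions
every statistic, and firing-rate-matched shuffle nulls calibrate the
state-change tests.

## Worked example

Fit and evaluate maximum-entropy models on a sampled 3-unit ensemble with
one strong positive and one negative coupling:

```r
library(popcode)

m <- maxent_model(h = c(-2.5, -2.0, -1.5),
                  J = matrix(c(0, 0.8, 0,  0.8, 0, -0.4,  0, -0.4, 0), 3))
m
#> maxent_model: order 2, N = 3, logZ = 0.410472
#>   mean h = -2.000, mean J (off-diag) = 0.133

r <- sample_model(m, n_bins = 50000, seed = 1)   # exact i.i.d. sampler
d <- pattern_distribution_of(r)
shannon_entropy(d)
#> [1] 1.623841

fit_i <- fit_independent(d)
fit_p <- fit_pairwise(d)
kld(d, model_pattern_probs(fit_i$model))
#> [1] 0.00629002
kld(d, model_pattern_probs(fit_p$model))
#> [1] 2.719992e-05
fit_p$model$J[1, 2]
#> [1] 0.7841166
```

The independent model misses the correlation structure (KLD ~6.3e-3 bits);
the pairwise model absorbs it (KLD ~2.7e-5 bits, three orders of magnitude
smaller) and recovers the generating coupling J12 = 0.8 to within sampling
error. The nesting `kld(pairwise) <= kld(independent)` holds for every
dataset by construction.

A full group analysis runs the same way from a synthetic cohort:

```r
animals <- gen_cohort(n_per_group = 4, n_units = 50, duration = 1800, seed = 1)
report  <- run_pipeline(animals, n_subsamples = 200,
                        n_maxent_subsamples = 40, seed = 2)
report   # medians, means, rank-sum p per measure, control-like vs amyloid-like
```

The amyloid-like group shows the expected signature: lower median pairwise
correlation, lower pattern entropy in both behavioural states, a smaller
entropy gain with running, and lower KLD for both models.

## Layout

| Path | Contents |
|---|---|
| `R/synthetic.R`, `R/cohort.R` | ground-truth generators (Poisson trains, exact Ising rasters, raw traces, behaviour, cohorts) |
| `R/sorting.R` | threshold + PCA + Gaussian-mixture spike sorting with QC |
| `R/behavior.R` | quadrature decoding, velocity, epoch segmentation |
| `R/popstats.R` | rates, z-scored rate series, conditioned correlations, shuffle nulls |
| `R/entropy.R` | binarization, pattern distributions, subsample entropy, bootstrap |
| `R/maxent.R` | Ising models: enumeration, fitting, KLD, coactivity, sampling |
| `R/pipeline.R` | per-animal analysis, group comparison (Wilcoxon rank-sum) |
| `vignettes/` | methods vignette: models, assumptions, design choices |
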