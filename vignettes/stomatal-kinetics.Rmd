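---
title: "Modelling stomatal conductance kinetics with stomkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stomatal conductance kinetics with stomkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomkin)
```

# The modelling problem

When light intensity steps up or down, stomatal conductance
($g_s$, mol m$^{-2}$ s$^{-1}$) relaxes toward a new steady state over
minutes. Two traits summarize the speed of that relaxation: the time
constant $\tau$ (s), the time to complete $1 - e^{-1} \approx 63.2\%$ of
the total change $\Delta g_s = g_f - g_i$, and the maximum slope
$Sl_{max}$ (mol m$^{-2}$ s$^{-2}$), the steepest instantaneous rate of
change. $\tau$ is a relative measure, independent of the magnitude of the
response; $Sl_{max}$ scales with $\Delta g_s$ and depends strongly on the
assumed curve shape. Comparing speed across studies therefore requires a
model family that accommodates both the exponential responses common in
many species and the sigmoidal, lagged responses seen in others.

## The four response models

`stomkin` implements four extraction methods behind one interface
(`kinetic_params()`, `predict_gs()`, `slmax()`, `t63()`):

1. **Empirical $t_{63}$** (`t63_empirical()`): a cubic smoothing spline is
   fitted to the raw trace, plateaus are read off the spline, and the
   first crossing of $g_i + (1 - e^{-1})\,\Delta g_s$ is located
   numerically. No shape assumption, but sensitive to plateau estimation
   and noise.
2. **Exponential**: $g_s(t) = g_f + (g_i - g_f)e^{-t/\tau}$, with
   $Sl_{max} = |\Delta g_s|/\tau$ at $t = 0$ and $t_{63} = \tau$. Cannot
   represent an initial lag.
3. **Sigmoidal (Gompertz)**:
   $g_s(t) = g_i + \Delta g_s \exp(-\exp((\lambda - t)/\tau + 1))$, where
   $\lambda$ (s) is a lag constant. With $\lambda = 0$ the response at
   $t = \tau$ has completed $e^{-1} \approx 37\%$ of $\Delta g_s$;
   $Sl_{max} = |\Delta g_s|/(e\tau)$ at $t = \lambda + \tau$, and
   $t_{63} = \lambda + \tau(1 - \ln(-\ln(1 - e^{-1})))
   \approx \lambda + 1.7793\,\tau$. Fits lagged responses but distorts
   lag-free exponential ones.
4. **Weibull CDF** ("CDWeibull"):
   $g_s(t) = g_f + (g_i - g_f)\exp(-(t/\tau)^{\lambda})$ with a
   dimensionless shape $\lambda$. At $\lambda = 1$ it *is* the
   exponential model (exact algebraic collapse, tested to $10^{-12}$); at
   $\lambda > 1$ it develops a sigmoidal lag. Crucially,
   $g_s(\tau)$ always completes exactly $1 - e^{-1}$ of $\Delta g_s$,
   whatever $\lambda$: $\tau$ and $t_{63}$ coincide for every shape, so
   time constants are directly comparable across species with and without
   lags. For $\lambda > 1$,
   $Sl_{max} = |\Delta g_s|\,(\lambda/\tau)\,q^{q}e^{-q}$ with
   $q = (\lambda-1)/\lambda$, attained at $t^\ast = \tau q^{1/\lambda}$.

The printed forms of the sigmoidal $t_{63}$ and the Weibull $Sl_{max}$ are
fixed by internal-consistency requirements (the 37% anchor at
$t = \tau$ with no lag, $Sl_{max} = \Delta g_s/(e\tau)$, and
$\lambda$-independence of the 63.2% point) and verified against bisection
and dense finite-difference oracles in the test suite.

**Numerical edge cases.** For $\lambda < 1$ the Weibull derivative is
unbounded as $t \to 0^+$; `slmax()` then reports the slope at a
configurable minimum time $\varepsilon$ (default 1 s) with a `boundary`
flag rather than an infinite supremum. $\Delta g_s = 0$ makes $t_{63}$
undefined and raises a typed condition. The smoothing factor of the
empirical method is passed to `stats::smooth.spline` as `spar`
(default 0.005, close to interpolation); smoothing-parameter semantics
differ between spline implementations, so the value is exposed rather
than hard-coded.

# Curation of gas-exchange time courses

Raw traces need three repairs before fitting, automated in
`curate_timecourse()`:

* **Segmentation** (`detect_light_steps()`, `extract_segment()`): each
  response runs from a light switch to the next switch or the series end.
  If a steady state is reached earlier (rolling slope below
  $10^{-5}$ mol m$^{-2}$ s$^{-2}$ over 5 min), later secondary drifts are
  cut and the steady tail is trimmed to about 5 min.
* **Transient stripping** (`strip_transients()`): a light switch perturbs
  cuvette temperature and vapour-pressure deficit, producing spurious
  $g_s$ spikes. Points are excluded up to the first point within 10% of
  $|\Delta g_s|$ of the pre-switch steady value (median of the last 5 min
  before the switch) that is followed by a run of $\ge 3$ samples with no
  counter-movement beyond half that tolerance. The exclusion set is always
  a prefix of the post-switch points, and curation is idempotent.
* **Review flags**: segments that never recover from a transient, are too
  short, or never reach steady state are flagged (`usable = FALSE`)
  rather than silently dropped — the original curation of such data was
  partly a manual judgement, and automated rules should surface their
  failures for human review.

The tolerance, run length, slope threshold and window lengths are exposed
in the function signatures; the defaults above were chosen once as the
smallest rules that reject oscillating artifacts on the synthetic fixtures
and were not tuned afterwards.

# Hierarchical Bayesian set fitting

Curves from one source, genotype and direction form a *set*; a set of
$\ge 3$ curves is fitted jointly (`fit_set()`) with a **shared**
$\tau$ (and $\lambda$) and **per-curve** endpoints $g_i, g_f$, under a
homoscedastic Gaussian residual with sd $\sigma$ shared across the set.
Sharing the time constant pools information across replicates while
letting magnitudes differ; per-curve endpoints may alternatively be
pinned to the data plateaus (`endpoints = "fixed"`).

**Priors** (all overridable in `fit_config()`): $\tau \sim$
LogNormal$(\ln 600, 1)$ s, covering the observed 1–100 min range without
dominating the data; Weibull shape $\lambda \sim$ LogNormal$(0, 0.5)$;
sigmoidal lag $\lambda \sim$ HalfNormal$(300)$ s; endpoints
$\sim$ Normal(data plateau medians, $0.05$) truncated at 0;
$\sigma \sim$ HalfNormal$(0.01)$.

**Sampler.** The convergence contract is diagnostic, not algorithmic:
every parameter must reach an effective sample size above 100 (sufficient
to describe 95% probability intervals) and split $\hat R < 1.05$. The
backend is an adaptive random-walk Metropolis sampler (4 chains, 2000
warm-up + 1000 sampling iterations by default) preconditioned with the
Laplace covariance at the posterior mode: parameter scales in these fits
span four orders of magnitude, which defeats unpreconditioned proposals,
while mode-plus-curvature preconditioning gives effective sample sizes of
a few hundred per fit in about a second. Sets that fail the gate are
escalated — warm-up raised to 3000 and sampling iterations doubled, twice
if needed — and sets still failing are returned with `converged = FALSE`
and excluded from downstream analysis. A random-walk sampler has no
divergent-transition diagnostic, so `n_divergent` is 0 by construction
and the gate rests on ESS/$\hat R$ plus an identifiability check: a
posterior for $\log\tau$ nearly as wide as its prior (ratio $> 0.8$)
marks the set as carrying no response information (e.g. constant $g_s$).
Every fit derives its chain seeds from the configured seed and is
bit-reproducible.

**Model comparison.** `loo_compare()` computes pointwise log-likelihood
matrices over the posterior draws and ranks models by PSIS-LOO
(Pareto-smoothed importance sampling; the largest 20% of importance
ratios per observation are replaced by expected order statistics of a
generalized Pareto fit, with shape $\hat k > 0.7$ on more than 10% of
points flagging the estimate unreliable). Models within twice the
standard error of the pointwise LOOIC difference of the best model are
flagged equivalent. On synthetic data this reproduces the expected
pattern: the Weibull-CDF model decisively beats the exponential on
sigmoidal-truth data and is statistically equivalent to it on
exponential-truth data despite its extra parameter.

# Species traits and the composite leaf

`derive_metrics()` turns a converged opening fit and closing fit into the
species/genotype traits used downstream — $\tau_{open}$, $\tau_{close}$
(reported in minutes; seconds internally), $Sl_{max}$ per direction from
the set-mean $\Delta g_s$, $t_{63}$, and the asymmetry ratio
$\tau_{open}/\tau_{close}$ — using posterior means.

Anatomy tables record guard-cell length SSl (the size proxy, averaged
over surfaces; less aperture-sensitive than width), per-surface stomatal
densities summed into SD, and the adaxial/abaxial ratio
rSD $=$ SD$_{ad}$/SD$_{ab}$. Because rSD is zero-inflated (hypostomatous
species), it is binned into four ordered classes
($0$, $(0, 0.5]$, $(0.5, 1]$, $> 1$) for use in regressions
(`classify_rsd()`).

`simulate_composite_leaf()` models an amphistomatous leaf as the weighted
average of two independent surface responses, with weights proportional
to per-surface stomatal counts: $w_{ad} = rSD/(1 + rSD)$,
$w_{ab} = 1/(1 + rSD)$ (the unique choice with count-proportional
weights; $w_{ad} + w_{ab} = 1$ exactly and $rSD = 0$ reproduces the
abaxial curve). The composite $t_{63}$ is located numerically on the
weighted curve and is bounded by the two surface values whenever the
surfaces share direction and endpoints.

# Comparative statistics

Standardized major axis regression (`sma_fit()`) handles the symmetric
trait–trait relationships (slope $\mathrm{sign}(r)\,s_y/s_x$, CI via the
standard $B$-construction, significance from the correlation); both axes
are natural-log transformed by default for allometric pairs such as SD
vs SSl, with a raw-scale option. Ordered rSD classes are compared by
Kruskal–Wallis with Dunn post hoc z-tests (`kruskal_dunn()`), unadjusted
by default (the common Dunn-test default) with Benjamini–Hochberg
available, and summarized as compact letter displays. PCA
(`pca_traits()`) runs on z-scored complete cases, separately per
guard-cell type, with loadings sign-fixed (largest-magnitude loading
positive) for determinism; stability is assessed by leave-one-out
refitting with symmetric Procrustes alignment (`pca_stability()`).

# Exhaustive phylogenetic regression

Candidate models predicting a log kinetic trait from anatomy are all
$2^{11} - 1 = 2047$ non-empty subsets of eleven terms: SD, SSl, rSD
(orthogonal polynomial contrasts over the four ordered classes), GC
(guard-cell type, treatment-coded), their six two-way interactions, and
`lineage`. Non-hierarchical subsets are allowed. `lineage` toggles the
phylogenetically structured species effect: with one (species-averaged)
row per species, the species random effect is absorbed into the residual,
whose correlation is the Brownian-motion matrix of the phylogeny
(shared root-to-ancestor path length, normalized) when `lineage` is
present and the identity otherwise — so `lineage` is interpreted as the
phylogenetic-covariance toggle, matching its role as one switchable model
term. Zero-length branches are raised to the minimum nonzero branch
length before the correlation is computed (`prepare_tree()`).

Fits are maximum-likelihood GLS (`fit_candidate()`) — fast, deterministic,
and exact — rather than a sampled multiresponse model: the deposited form
of such compilations is species-averaged, which removes the information a
multiresponse missing-data model would exploit, so the package fits each
response separately on complete cases. Model quality is summarized by a
pseudo-$R^2$ in the Bayesian-$R^2$ sense,
$\mathrm{var}(\hat y)/(\mathrm{var}(\hat y) + \mathrm{var}(e))$, and
candidates are ranked (`loo_rank()`) by **exact case-deletion LOO**: for
each observation the model is refitted without it and the log predictive
density of the held-out point is evaluated under the conditional Gaussian
given the remaining observations (accounting for both the correlation
structure and coefficient uncertainty). For identity correlation this
reduces to the classical hat-matrix formulas, which serve as an
independent oracle in the tests. Reporting mirrors the three-row
convention: global best model, most parsimonious equivalent with
phylogeny, most parsimonious without (`select_models()`), with
equivalence again defined by the 2-SE rule.

# The synthetic-data generator

`synth_config()` fixes the study conditions; all generators are pure
functions of (configuration, seed). Defaults emulate a multi-study
compilation: a light schedule of 30 min at 100 µmol m$^{-2}$ s$^{-1}$,
60 min at 1000, 60 min at 100, sampled every 30 s — long enough for
steady state at the slowest default time constants; Weibull-CDF
trajectories with asymmetric opening/closing $\tau$ clamped to
[60, 3600] s opening and [40, 3600] s closing; shapes in [0.8, 3];
Gaussian noise of sd 0.005 mol m$^{-2}$ s$^{-1}$ (typical infra-red gas
analyser scatter); optional 2-sample post-switch spike artifacts of
0.05 mol m$^{-2}$ s$^{-1}$ whose indices are recorded as ground truth.
Species anatomy draws log SSl and log SD jointly normal with correlation
$-0.6$ (the size–density trade-off), rSD zero-inflated with a 0.29 point
mass at zero and positive part up to 2.16, and a dumbbell guard-cell
clade covering about 30% of species (grass-like lineage clustering, with
dumbbell intercepts several-fold faster: opening 7 vs 28 min, closing
8.9 vs 20 min on the log scale). Kinetic traits are linear in log anatomy
plus a Brownian phylogenetic deviation (Pagel's $\lambda$ scaled,
default 1) and iid noise. Trees are pure-birth and ultrametric
(`gen_phylogeny()`).

What the generator does **not** emulate: cuvette gas-mixing delays and
micro-climate physics, instrument drift, heteroscedastic noise,
non-stationary lags, or real phylogenetic imbalance. Passing tests
therefore demonstrate that the machinery recovers known structure under
its own assumptions — parameter recovery, ranking behaviour, type-I error
— not that those assumptions hold for any particular instrument or
species set.

# Problem sizes and reproducibility

The test suite and the acceptance script were sized for a desk run:
parameter recovery uses 50 three-curve sets of 121 points per curve with
measurement windows scaled to $5\tau$ (capped at 5 h); model-ranking
checks use single representative sets of 121-point curves; the
Kruskal–Wallis size check uses 1000 null simulations of 3 × 10
observations; descriptive-structure checks use 200 synthetic species; the
pipeline test runs 4 species end to end. Every stochastic step takes an
explicit seed, pipeline outputs carry a manifest with configuration hash
and per-file MD5 sums, and refitting with the same seed is
bit-reproducible.

# Known limitations

* The random-walk backend is slower per effective sample than a
  gradient-based sampler and relies on the Laplace preconditioner; very
  flat or multimodal posteriors (e.g. steady state never reached) fall
  back to covariance learning during warm-up and will usually, and
  correctly, fail the diagnostic gate.
* Exact case-deletion LOO refits each candidate $n$ times; for the full
  2047-candidate sweep on large species sets this is the dominant cost
  (still seconds at $n \approx 100$).
* The empirical $t_{63}$ method inherits the plateau-estimation
  sensitivity it is known for; it is provided for comparison, not as the
  primary estimator.
* Group summaries average across species means by default (each species
  counts once); per-observation averaging is available but changes the
  interpretation when replication is unbalanced.
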