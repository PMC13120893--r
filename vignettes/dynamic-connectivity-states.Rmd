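---
title: "Dynamic connectivity states, topological variability and a subject covariate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states, topological variability and a subject covariate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The model and its assumptions

`dynconn` analyses multivariate brain time series (nodes are ICA component
time courses) under the working model that whole-brain functional
connectivity is piecewise stationary: at any moment the brain occupies one
of a small number of recurring connectivity configurations ("FC states"),
and subjects differ in how long and how often they occupy each state. Two
complementary summaries are computed and related to a subject-level
covariate (BMI throughout):

* **State dynamics** — fractional window (FW, the percentage of windows a
  subject spends in each state), mean dwell time (MDT, the mean length of
  maximal runs in a state, in windows) and number of transitions (NT).
* **Topological variability** — the coefficient of variation across
  windows of each node's efficiency metrics, i.e. how much a node's role
  in the network reorganises over time.

The estimation chain assumes the node time series are already unmixed
(ICA is out of scope), that a 70-TR window is short enough to track state
switching yet long enough to estimate a 43-node covariance when
regularised, and that windowed observations are approximately Gaussian so
the graphical lasso's penalised likelihood and the cross-validated
held-out log-likelihood are meaningful.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `n_drop` | 10 | frames | initial transient removal |
| `detrend_order` | 3 | — | joint projection on orders 0–3 |
| `despike_c1`, `despike_c2` | 2.5, 4.0 | MAD units | onset and saturation of tanh compression |
| `lowpass_hz` | 0.15 | Hz | order-5 Butterworth, forward–backward |
| `standardize` | TRUE | — | unit-variance nodes after filtering |
| `L`, `sigma` | 70, 3 | TR | taper: rectangle convolved with a Gaussian |
| `step` | 1 | TR | window stride |
| `lambda_grid` | 10 points, 0.03–1 (log) | covariance scale | per-subject CV, 5 contiguous folds |
| `k_range` | 2–10 | — | elbow on within/between dispersion ratio |
| `n_replicates` | 100 | — | k-means restarts (20 during the elbow scan) |
| `sparsity_grid` | 0.10–0.34 by 0.01 | edge fraction | binarization thresholds |
| `cv_ddof` | 1 | — | sample SD in the CV |
| `fd_threshold` | 0.25 | mm | cohort head-motion exclusion |

The despike thresholds, filter family/order, CV fold count, λ grid,
sparsity range and the CV's degrees of freedom are not pinned down by the
literature this pipeline follows; each is therefore an explicit,
configurable default, and results should always be reported together with
the values used.

## Numerical choices

* **Detrending** is one joint least-squares projection onto an
  orthonormal polynomial basis (intercept plus `stats::poly`), so it is
  idempotent and order-independent, unlike sequential regression.
* **Low-pass filtering** applies `signal::filtfilt` after odd-symmetric
  edge padding whose length scales with the inverse normalised cutoff;
  without padding the filter's edge transient reaches 0.4 on a constant
  input, with it the error is below 1e-6.
* **Despiking** fits a cubic baseline, scales residuals by
  1.4826·MAD, and compresses only samples beyond `c1` scaled units with a
  tanh map saturating at `c2`, the 1-D restriction of the scheme used by
  the standard fMRI despiking tools.
* **Graphical lasso** is block coordinate descent on the working
  covariance with the penalty on off-diagonal entries only; convergence is
  declared when the largest working-covariance update falls below 1e-7,
  and non-convergence is an error, never a silent result. At λ = 0 the
  solution agrees with direct inversion to ~1e-8; at
  λ ≥ max|off-diagonal(S)| the precision is exactly diagonal.
* **Correlation clipping** at |r| ≤ 1 − 1e-7 precedes the Fisher
  transform, so z-values are always finite.
* **L1 k-means** breaks assignment ties toward the lower centroid index,
  updates centroids by the component-wise median (the exact L1 minimiser),
  and re-seeds an emptied cluster at the point farthest from its current
  centroid. All restarts draw their initial centroids from R's RNG, so a
  seed fixes the full trajectory.
* **Elbow selection** maximises the discrete second difference of the
  validity curve CVI(k) = mean within-cluster L1 dispersion / mean
  between-centroid L1 distance; ties and flat curves resolve toward the
  smallest k (with a warning when there is no curvature at all).
* **Final window assignment** is a single nearest-centroid pass from the
  exemplar-derived centroids (no further centroid updates); full k-means
  refinement over all windows is available behind `refine = TRUE`.
* **Binarization** ranks edges by |z| (signed ranking is a flag), keeps
  `floor(s·E)` edges, and breaks ties deterministically in upper-triangle
  index order; an all-zero window is flagged once and falls back to the
  tie rule. Disconnected node pairs contribute zero efficiency (the
  infinite-distance convention), and AUC aggregation uses the trapezoid
  rule.
* **Unvisited states** yield undefined MDT; such subject–state pairs are
  dropped pairwise from the affected test only, which mirrors the unequal
  per-state Ns seen in group-level state analyses.

## Design choices that were genuinely open

* **Precision to connectivity.** The windowed precision matrix is
  inverted back to a covariance and normalised to correlations before the
  Fisher transform (the convention of the GIFT dFNC tooling this chain
  follows); reading partial correlations directly off the precision is a
  deliberate non-default alternative.
* **Variance normalisation.** Each node's series is scaled to unit
  variance at the end of preprocessing (the dFNC convention). Low-pass
  filtering shrinks the variance scale, and the graphical-lasso penalty
  acts on the covariance scale, so without this step one λ grid cannot be
  meaningful across subjects or preprocessing choices. It can be disabled
  (`standardize = FALSE`).
* **λ selection.** Cross-validation is per subject on the full
  (unwindowed) preprocessed series with 5 contiguous folds — contiguous
  because fMRI samples are serially dependent and shuffled folds would
  leak. The grid is log-spaced 0.03–1.0. When state dwells are long
  relative to a fold (as in the desk-scale studies), fold covariances
  differ in state composition and the held-out likelihood rewards extra
  shrinkage, so selected λ varies across subjects (0.03–0.46 in the
  shipped recovery study); occasionally a weak-connectivity window then
  becomes fully sparse (all-zero z) — such windows are flagged and survive
  through the tie-rule binarization rather than being dropped. More folds
  do not help at these series lengths (they destabilise the elbow), so
  the study keeps the 5-fold default and, where an analysis needs
  cross-subject comparability of pattern sharpness (the pure-window
  labelling check), uses one mild shared penalty instead.
* **FDR families.** FW and MDT across states are corrected jointly (one
  family of 2k tests) by default, with a `separate` mode (k + k); each
  topology metric is its own family across nodes; NT is a single
  uncorrected test. The family definitions travel with the results.
* **Group contrasts** use Welch's t-test (no equal-variance assumption),
  two-sided, healthy-weight vs overweight and vs obese only; underweight
  subjects stay in the correlation analyses but not the three-group
  contrasts. BMI groups use half-open intervals [18.5, 25), [25, 30),
  [30, ∞) so that values such as 24.95 are classified (healthy) rather
  than falling in a gap.
* **Group-level centroid consistency** uses Pearson pattern correlation
  of group-averaged subject centroids; ICC variants are possible but not
  asserted as the canonical choice.

## What the synthetic generator emulates — and what it does not

Each simulated subject follows a K-state first-order Markov chain over
block-structured covariance states (three node blocks standing in for
visual, sensorimotor and association networks). State 3 is
visual-dominant: strong positive intra-visual correlation (0.70), positive
visual–sensorimotor coupling (0.40) and negative visual–association
coupling (−0.25). The BMI-like covariate (truncated normal, mean 26.5,
SD 5, range 16–46 kg/m²) shifts that state's self-transition probability
on the log-odds scale (0.15 per kg/m² by default, base 0.995) with the
remaining row mass renormalised proportionally — so higher-BMI subjects
dwell longer in the visual-dominant state, which also (emergently)
suppresses the temporal variability of visual-node efficiency. Age is
uniform over 22–37, gender Bernoulli(0.52), observations Gaussian with
additive isotropic noise (SD 0.2) and optionally AR(1) innovations.

A first design draft used a base self-transition of 0.99 and two states
sharing the association-block signature; at the desk-scale study sizes the
mean dwell (~100 TR) was too close to the 70-TR window and the elbow
merged the two similar states. The frozen design lengthens dwelling
(0.995, mean dwell ~200 TR) and gives every state a distinct block
signature, which is the regime the recovery study is meant to probe.

The generator does **not** emulate hemodynamics, realistic fMRI noise
spectra (1/f, physiological cycles), spatial maps, scanner drift beyond
what detrending removes, or motion artefacts. Passing the recovery tests
therefore shows the estimation chain is correct and well calibrated under
its own working model — piecewise-stationary Gaussian states — not that
real resting-state data satisfies that model.

## Study sizes used in the shipped analyses

The recovery study uses 60 subjects × 10 nodes × 800 time points with
K = 4 planted states (elbow scan k = 2..10, 20 restarts per k, 100 at the
final k); the association study uses 150 subjects from the same model; the
null calibration re-draws 200 cohorts of 40 subjects with zero dwell
coupling at the latent-chain level, since the calibration of the
partial-correlation + FDR stage does not depend on the observation model.
These sizes were chosen so every stage's behaviour (elbow position,
centroid recovery above 0.9, planted-association detection, null
false-positive rate) is measurable in minutes on one core while keeping
the window length, taper, sparsity grid and statistical machinery at their
full-scale values.

## Known limitations

* Piecewise-stationary Gaussian states are a simplification; HMM or
  change-point models (explicit non-goals here) may suit gradual
  transitions better.
* The graphical-lasso penalty acts on the covariance scale; with
  `standardize = FALSE` the selected λ is not comparable across
  preprocessing choices that rescale variance.
* Group-level clustering assumes a shared state space across subjects;
  subject-specific state models are out of scope.
* MDT is reported in windows; multiply by TR × step for seconds (50.4 s
  per 70-TR window at TR = 720 ms).
* The elbow criterion needs a validity curve over at least three k values
  and resolves genuinely flat curves to the smallest k — a warning, not an
  answer, in that case.
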