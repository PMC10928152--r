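---
title: "Latent brain-state dynamics across cognitive tasks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent brain-state dynamics across cognitive tasks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A recurring observation in cognitive neuroscience is that very different
demanding tasks — working memory, task switching, response inhibition,
interference resolution, relational reasoning — engage a common
frontoparietal/cingulo-opercular "multiple-demand" system. Activation overlap
alone, however, cannot show that the same *dynamic process* operates across
tasks. `mdstates` implements the model-based route to that question: fit a
latent-state model to multi-ROI fMRI time series independently per task,
then ask, quantitatively, whether a state discovered in one task recurs in
another, whether its moment-to-moment engagement predicts each task's
cognitive-control index, and which regions carry the cross-task similarity.

The package operates on per-run matrices of T timepoints by D regions of
interest (default D = 11: bilateral anterior insula, middle frontal gyrus,
frontal eye field, intraparietal sulcus, plus DMPFC, VMPFC and PCC). All
pipeline stages run equally on real extracted time series or on the
package's synthetic cohorts.

## The state model

Each run is modeled as a hidden Markov chain over K latent brain states.
State k is a multivariate Gaussian with mean vector `mu_k` (the state's
activation profile, in z-units) and covariance `Sigma_k` (its functional
connectivity). The chain has initial probabilities `p(i)` and a transition
matrix `A(i, j)`; the temporal posterior probability (TPP) matrix gives, for
every timepoint, the probability of each state given the whole run.

Fitting is variational-Bayes EM over all runs of a task jointly (one group
model per task), with the chain restarting from `p(i)` at every run
boundary:

* **Priors.** Symmetric Dirichlet priors with small concentration
  (`alpha0 = eps0 = 0.01`) on `p(i)` and on each row of `A`; a
  Normal–Wishart prior on each `(mu_k, Lambda_k)` with `m0 = 0`,
  `beta0 = 1e-3`, `nu0 = D + 2` and `W0 = I / nu0`, so the prior expected
  precision is the identity — the natural scale for z-scored inputs.
* **Inference.** The E-step is an exact forward–backward pass (compiled
  code) under the Dirichlet expected-log parameters and the Normal–Wishart
  expected emission log-densities; the M-step applies the standard
  conjugate updates. The evidence lower bound (ELBO) is the structured
  variational bound — the forward-pass log-normalizer minus the Dirichlet
  and Normal–Wishart KL terms — and is non-decreasing over iterations.
  Convergence: relative ELBO change below `1e-6` or 500 iterations.
* **Initialization.** k-means on the concatenated data with `K_init`
  centers (default 15, deliberately over-complete); `n_restarts` (default
  5) seeded initializations, best final ELBO wins. Every fit is a pure
  function of its seed.
* **ARD pruning.** The sparse Dirichlet priors starve states that the data
  do not support; after convergence, states with expected usage below
  `1 / (10 * K_init)` of total time are removed and the model re-converged,
  repeating until stable. The effective state count is therefore learned.
* **Merge pass.** Usage-based pruning cannot escape the local optimum in
  which two components split one true state — both halves keep substantial
  usage. After pruning, the fitter therefore proposes merging the two
  closest surviving states (smallest symmetrized KL), re-converges, and
  accepts the merge only if the ELBO improves, repeating until no merge
  helps. This is an ELBO-guided model move in the split-and-merge EM
  tradition; because acceptance requires a higher bound, it never degrades
  the fit.
* **Numerical guards.** Covariances are jittered by
  `1e-6 * trace/D` on the diagonal whenever the smallest eigenvalue falls
  below `1e-8`; emission likelihood rows are max-shifted before
  exponentiation; `elbo_trace` holds the (monotone) trace of the final
  converged stage and `elbo_history` the full multi-stage history.

### Global-variable transfer

The model's parameters divide into *global* latent variables — `p(i)`, `A`,
the state Gaussians — and *local* ones, the per-timepoint posteriors.
`apply_state_model()` transfers a fitted model to new runs by holding the
global variables fixed and running a single exact forward–backward pass.
This is what lets a reference task's states be tracked inside another
task's data.

## Cross-task state matching

Two deliberately different metrics, which should agree when a state is
genuinely shared:

* **State space closeness** `c = 1 / divergence` between two states'
  Gaussians. The divergence defaults to the symmetrized (Jeffreys) KL,
  `KL(a||b) + KL(b||a)`, because no directed convention is privileged; both
  directed values are always reported, and the matched state (the argmax of
  `c`) is insensitive to the choice in all tested regimes. Identical states
  give infinite closeness, reported with a flag.
* **State temporal closeness** `r`: the Pearson correlation between the
  reference state's transferred TPP time course and each target state's own
  TPP time course on the same runs, concatenated in subject order (a
  per-subject correlation array is retained so a few subjects cannot
  dominate silently).

**Permutation significance.** The null distribution draws `n_perm`
(default 100) state pairs uniformly from the pooled inventories of the two
models — same-task and cross-task draws both allowed, the observed pair
excluded — and recomputes the statistic. The p-value is the exceedance
fraction with a `< 1/n_perm` floor; raw exceedance counts are always kept.
With the observed pair drawn exchangeably with the pool, these p-values are
uniform, which the test suite verifies by KS test; the p-value attached to
a *selected* best match is, as in any post-selection test, conservative to
interpret and is reported with its construction.

`match_states()` assembles the full report: per-candidate `c` and `r`,
permutation p-values for the best of each, the matched state (argmax `c`,
ties broken by `r` and flagged), and the consistency verdict
(`argmax c == argmax r`), which is the pipeline's central empirical check.

## Dynamics, lesions, behavior

**Occupancy.** The primary occupancy rate is the fraction of timepoints at
which a state attains the maximum posterior (ties go to the lowest index
and are counted); the mean-posterior variant is always computed alongside,
since soft occupancy is the natural covariate for symptom analyses. Both
sum to one per run.

**Leave-one-ROI-out lesions.** For each ROI, both states are marginalized
over that ROI (exact for Gaussians: drop the mean entry and the covariance
row/column) and `delta = |divergence(full) − divergence(lesioned)|` is
recorded with impact `1/delta`. A small delta means the removed region was
*not* the locus of the states' discrepancy — its features carry shared
structure — so the top-ranked (largest `1/delta`) ROI contributes most to
the similarity. Both `delta` and `1/delta` are emitted so either reading is
recoverable; deltas below `1e-12` cap the impact at a flagged ceiling.

**Behavioral indices.** One scalar of cognitive control per task, always
oriented so larger = better control: the z-scored AY–BX reaction-time
contrast (AX-CPT), the negative congruency cost (cued task switching,
Stroop; raw signed cost attached), z-scored accuracy/RT efficiency on the
demanding condition (Sternberg, relational processing), and `1000 / SSRT`
(stop-signal task). SSRT uses the race-model integration method: the go-RT
order statistic at rank `ceiling(P(respond|stop) * n)`, with go omissions
replaced by the maximum go RT, minus the mean stop-signal delay; a mean
method is available behind a flag. Paired condition contrasts report the
paired t, two-tailed p, and Cohen's `d_z = mean(diff)/sd(diff)` (pooled-sd
variant behind a flag).

**Brain–behavior statistics.** Canonical correlation between the
subjects-by-states occupancy matrix and the behavioral measures, computed
by a whitening-plus-SVD solve with automatic ridge regularization (flagged)
on near-singular blocks. The analyzed component is the one whose behavioral
variate aligns best (absolute correlation, sign-flipped positive) with the
task's control index; this operationalizes "the component that best
represents cognitive control", and all components' statistics are emitted.
Significance is a permutation test of subject rows (1000 draws) against the
permuted *maximum* canonical correlation — a conservative null for a
selected component. Predictive validity uses leave-one-out CCA: weights are
re-fit without each subject (standardization inside the fold), the held-out
subject is projected, folds are sign-aligned with the full-sample solution,
and the held-out brain and behavior scores are correlated. Univariate
analyses are two-tailed Pearson correlations; the specificity screen runs
one per state and flags whether exactly one state is significantly
positively associated. P-values are unadjusted by default (matching the
analysis convention this pipeline follows), with a Benjamini–Hochberg
option.

## The synthetic cohort generator

`generate_multitask_cohort()` draws a ground truth and emits everything the
pipeline consumes: per-(subject, task) runs, motion files, a behavioral
table, and the truth itself for testing. The generative process is exactly
the model's own: first-order Markov chains with Gaussian emissions. Default
study conditions: 2 tasks, 40 subjects, T = 300 at TR 0.72 s, 4 states per
task over the 11 multiple-demand ROIs, one shared state planted at a
seed-determined inventory position in every task, sticky dynamics
(self-transition 0.85), state-mean separation 1.0 z-units (pairwise state
distances of several z-units at D = 11, i.e. well-separated), and a
behavioral index coupled to each subject's realized shared-state occupancy
at population correlation 0.5 — on the order of the strongest
brain-behavior correlations plausible in task fMRI. Per-subject occupancy
heterogeneity comes from a log-tilt of transition mass into the shared
state (sd 0.5), chosen to give occupancy spreads wide enough to detect the
coupling at n = 40–50; within- vs between-subject variance partitioning is
not otherwise constrained by the study design, so it is exposed in the
config. Optional linear drift and motion-mixed random-walk nuisance (off by
default; the preprocessing stage removes both when enabled), a perturbation
sd for the shared state's mean (default 0) to probe matching robustness,
and no hemodynamic convolution — states are defined on the observed series,
and a convolution step would only blur run-internal transitions without
changing any cross-task contract. Null cohorts (`shared = FALSE`) omit the
planted state and refuse a behavioral coupling.

What passing on this generator does and does not show: the generator is the
model's own data-generating process, so recovery tests validate inference,
matching, lesion and behavioral machinery — not the adequacy of Gaussian
HMMs for real BOLD, which exhibits autocorrelation within states,
non-Gaussian tails, and hemodynamic smoothing that these tests do not
emulate.

## Preprocessing

Cleaning follows the standard ROI pipeline: regression of the 6 rigid-body
realignment parameters, linear detrending, z-scoring (sample sd, T − 1
divisor; z-scoring is the assumed reading of "normalization", flagged here
because alternatives exist). The exported steps are individually available
in that order; the composed `preprocess_run()` projects intercept, trend
and motion out in a single joint least-squares step. The sequential and
joint forms coincide when the regressors are mutually orthogonal, but
motion drifts, and only the joint projection satisfies both contracts that
matter downstream — exact residual orthogonality to every regressor and
idempotence of the chain. An intercept is always included so residuals
carry no mean structure.

## Problem sizes used by the test suite

The suite exercises full study-scale recovery once (40 subjects x T = 300,
D = 11, K_init = 15, 2 restarts) and uses reduced replicates elsewhere
(two-task matching at 8 subjects x T = 150 with K_init = 6 over 40
replicates; 500 null-calibration replicates at the state-inventory level;
200 null LOO-CCA replicates at n = 100). These sizes were chosen as the
smallest at which the tested properties are stable across seeds.

## Known limitations

* The model operates in observed ROI space; no learned low-rank latent
  subspace is fitted, and emission Gaussians are conditionally independent
  in time within a state.
* Matching assumes both models share one ROI set in one order.
* The permutation null for a best match is selection-naive (see above);
  raw counts are reported for any pooled reanalysis.
* Real-data behavioral ingestion expects per-subject summary tables (or
  trial tables for the stop-signal task); trial-level modeling beyond the
  race model is out of scope.
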