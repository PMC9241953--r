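---
title: "Scoring AP-MS interactors with a bait-normalized Gaussian mixture"
author: "apmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AP-MS interactors with a bait-normalized Gaussian mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmix)
```

## The model

An affinity-purification mass-spectrometry (AP-MS) experiment recovers a
tagged bait protein together with everything bound to it — and everything
that sticks nonspecifically to beads, tag, or tube. Peptide counts are the
abundance currency, but raw counts are confounded by protein length and by
how efficiently each individual pulldown worked. `apmix` removes both
confounders with a two-step normalization and then lets a mixture model
draw the line between background and bound.

For protein $p$ with length $L_p$ and summed peptide count $c_{pa}$ in
assay $a$, the bait-relative abundance is

$$
r_{pa} \;=\; \frac{c_{pa}/L_p}{c_{ba}/L_b},
$$

where $b$ is the bait. Dividing by length corrects for longer proteins
producing more detectable peptides (the same correction that underlies
spectral-abundance factors); dividing by the bait's length-normalized
value within the same assay makes values comparable across pulldowns of
different efficiency, because every protein is now expressed as a fraction
of whatever amount of bait that particular pulldown captured. The bait
maps to exactly 1 in every assay by construction.

The $\log_2 r_{pa}$ values of all replicate assays are pooled as separate
observations — a protein detected in three assays contributes three points
— and modelled as a $k$-component univariate Gaussian mixture fitted by
expectation-maximization (EM). With the default $k = 2$ the components
have a direct reading: a heavy low-mean component of nonspecific
background and a light high-mean component of bait-bound preys. The
assumption being made is that on the log scale each population is roughly
Gaussian; pooling assays treats replicates as exchangeable draws from the
same two populations.

Each protein then receives one score — the arithmetic mean of its pooled
$\log_2$ observations — and one posterior: the Bayes-rule probability that
this score came from the high-mean component,

$$
P(\text{bound} \mid x) =
  \frac{w_h\,\varphi(x;\mu_h,\sigma_h^2)}
       {\sum_j w_j\,\varphi(x;\mu_j,\sigma_j^2)} .
$$

The final call is deliberately dual: a protein is in complex with the bait
iff its posterior **strictly** exceeds 0.5 *and* its raw peptide counts
summed over all assays are at least 5. The posterior captures relative
enrichment; the count floor stops proteins seen in one or two stray
spectra — whose normalized value can be high purely by chance, especially
for short proteins — from being called on no real evidence.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 2 | components | background vs bound; BIC selection over 1–3 via `select_k_by_bic` |
| `posterior_threshold` | 0.5 | probability | strict lower bound on the high-component posterior |
| `count_threshold` | 5 | peptide counts | inclusive floor on counts summed across assays |
| `tol` | 1e-8 | log-likelihood | EM convergence: absolute change per iteration |
| `max_iter` | 2000 | iterations | EM budget per restart |
| `n_restarts` | 5 | — | quantile start plus 4 seeded perturbations |
| `var_floor` | 1e-6 | log₂² | lower bound on component variances |
| `pseudocount` | 0 | counts | optional additive count offset (off) |
| `min_obs` | 10 | observations | minimum pooled points to attempt a fit |

All randomness flows from one integer seed that is recorded in the fit and
in the run record, so a run is a pure function of its configuration.

## Design choices where the design was open

**The count filter sums across assays.** Classification happens after the
assays are merged, so "raw peptide counts of at least five" is applied to
the per-protein total over all assays. A per-assay reading would be
stricter; the summed form matches the merged, per-protein result the rule
qualifies.

**One posterior per protein, evaluated at its mean score.** The mixture is
trained on pooled per-assay observations, but the verdict is per protein.
The package collapses a protein's observations to their arithmetic mean
and evaluates the posterior there. The alternative — multiplying per-assay
posteriors — compounds assay noise and penalizes proteins detected in more
assays; it was noted and not adopted.

**Zero cells are excluded, not pseudocounted.** $\log_2 0$ is undefined,
and any pseudocount choice would silently shape the background component.
Zero (protein, assay) cells are therefore dropped from training and logged
with a reason, and the pooled-observation count obeys the exact identity
*(proteins − 1) × assays − zero cells*, which the run record exposes for
audit. A `pseudocount` option exists for users who prefer to keep dropout
cells, but it defaults to off. Proteins with *all* counts zero never enter
training and are reported with posterior 0.

**The bait is excluded from training.** Its value is identically 0 on the
log₂ scale by construction; leaving it in would plant an artificial point
at the top of the scale in every assay and bias the high component. The
bait is reported first in the calls table with a sentinel posterior of 1
and an `is_bait` flag.

**One mixture per run.** A run scores one bait in one condition (its
replicate assays). Comparing conditions means running the pipeline once
per condition; the package does not pool conditions into a joint model,
because nothing in the two-population reading justifies sharing components
across conditions with possibly different backgrounds.

**Proteins detected in only some assays contribute only those assays.**
No imputation: a missing observation is information about dropout, not a
value to invent.

## Numerical choices

The E-step works entirely in log space: component log-densities plus log
weights, normalized by a log-sum-exp with the row maximum factored out, so
posteriors are stable even hundreds of standard deviations into a tail.
Posteriors are computed as a softmax of the log joint terms, which returns
exactly 0.5 at the exact midpoint of two equal-weight, equal-variance
components — the classification boundary behaves exactly, not just
approximately.

Initialization is deterministic by default: component means at the
$(2j-1)/(2k)$ sample quantiles, equal weights, pooled sample variance.
Additional restarts perturb the quantile means with a seeded normal
deviate ($\mathrm{sd} = s_x/2$), and the restart with the best final
log-likelihood wins. Convergence is declared on an absolute log-likelihood
change below `tol`; the per-iteration likelihood trace is kept in the fit
object, and the suite asserts it never decreases — the EM monotonicity
guarantee is checked, not assumed. The budget of 2000 iterations reflects
that at `tol = 1e-8` well-separated fits converge in tens to hundreds of
iterations, while poorly separated components can legitimately need more
than a thousand; a tighter budget would reject exactly the hard fits.

A variance floor of 1e-6 log₂² prevents the classic EM degeneracy of a
component collapsing onto a single point with unbounded likelihood.
Canonical form stores means in ascending order; the "high" component is
the largest mean, with ties broken by larger weight and then lowest index.
Degenerate inputs — fewer than $5k$ observations, or all observations
identical — are rejected before fitting rather than producing a
meaningless fit.

Model-order selection, when requested, minimizes
$\mathrm{BIC} = (3k-1)\ln n - 2\ell$ over $k \in \{1,2,3\}$, counting
$k-1$ free weights, $k$ means and $k$ variances. On real pooled counts BIC
will sometimes prefer $k = 3$ — log counts are not exactly Gaussian — which
is why the pipeline default stays at the interpretable $k = 2$.

## What the synthetic generator emulates — and what it does not

`simulate_pulldown()` produces the data structure the model assumes, with
ground truth: a dominant bait (negative-binomial counts, mean 400 per
assay), a small interactor population whose latent bait-relative log₂
abundance is drawn from $N(-2, 0.8^2)$, a large background population from
$N(-7, 1.2^2)$ (five log₂ units of separation), protein lengths uniform on
100–3000 residues, three independent assays, overdispersed
negative-binomial counts (size 5), and 15% per-assay dropout of background
proteins. Latent abundances live directly on the bait-relative log₂ scale,
so the expected count is constructed so that the pipeline's own
normalization chain recovers the latent value in expectation — parameter
recovery is then a direct test of the model, not of a translation layer.
Interactors are exempt from the dropout coin-flip, mirroring the
reproducible detection of genuine complex partners across replicates
(count noise can still produce an occasional interactor zero).

What it deliberately does not simulate: peptide-level identification
error, shared peptides between proteins, retention-time or spectral
artifacts, control pulldowns, and correlated contamination (the same sticky
proteins appearing in every assay at correlated levels). Passing tests on
this generator therefore demonstrate that the statistical machinery is
correct under the model's own assumptions — not that the assumptions hold
for any particular instrument or purification protocol.

The validation problem sizes are modest by choice: the standard study is
311 proteins × 3 assays (about 620 pooled observations), mixture recovery
uses 2,000 draws with 20 replicates, and end-to-end recovery averages over
10 simulation seeds — large enough for stable estimates of the recovered
means and error rates, small enough that the entire suite re-runs in well
under a minute per property.

## Known limitations

- With two planted populations 5 log₂ units apart, the fitted
  high-component mean tracks the planted interactor mean as an average
  across replicate studies, but individual studies can wander by up to a
  log₂ unit when the high component absorbs part of the background's upper
  tail — a small-sample property of fitting a 4%-weight component to ~600
  points, visible directly in the acceptance output.
- Bait normalization assumes the bait is quantified reliably; a pulldown
  in which the bait itself is marginal (a handful of counts) propagates
  that noise into every prey of that assay. The validator rejects
  bait-free assays outright but cannot rescue a weak one.
- Spectral counts are integers with strong mean–variance coupling; the
  Gaussian-on-log₂ model is an approximation that the overdispersed
  generator stresses but cannot fully license.
- No control-pulldown subtraction or contaminant-repository filtering is
  performed; preys that bind the tag rather than the bait will score as
  interactors if they are enriched to bait-comparable levels.
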