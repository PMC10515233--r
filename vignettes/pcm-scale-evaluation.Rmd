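---
title: "Evaluating polytomous rating scales with the partial credit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating polytomous rating scales with the partial credit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmeval)
```

# The measurement problem

Questionnaires like the Perceived Stress Scale (PSS) produce ordinal item
scores (0 "Never" ... 4 "Very often") that are routinely summed and treated
as interval measurements. Whether that is defensible is an empirical
question with five classical parts: is the item set **unidimensional**; do
the **response categories** function as intended; are item difficulties
**invariant** across groups (no differential item functioning, DIF); are the
items well **targeted** to the persons; and over which range is the score
**reliable**? `pcmeval` implements this whole evaluation under the Rasch
partial credit model (PCM), ships item-subset presets for the 14-, 10- and
4-item PSS versions and their negative/positive wording subscales, and
includes a synthetic-data generator so that every stage of the pipeline can
be exercised and validated without any particular data set.

# The model and its estimation

For person location $\theta$ (logits) and an item with ordered categories
$0,\dots,m_i$ and step thresholds $\delta_{i1},\dots,\delta_{im_i}$, the PCM
gives

$$P(X_i = x \mid \theta) \propto \exp\Big(\sum_{k \le x} (\theta - \delta_{ik})\Big),$$

with an empty sum for $x = 0$. The threshold $\delta_{ik}$ is the location
where categories $k-1$ and $k$ are equally probable; the item location is
the mean of its thresholds.

**Conditional maximum likelihood (CML).** The raw sum score
$R = \sum_i X_i$ is sufficient for $\theta$, so conditioning on it removes
the person parameters entirely: the conditional pattern probability is
$\prod_i \psi_{i x_i} / \gamma_r$, where
$\psi_{ix} = \exp(-\sum_{k\le x}\delta_{ik})$ and $\gamma_r$ is the
elementary symmetric function of order $r$ — the sum of
$\prod_i \psi_{ix_i}$ over all patterns with total $r$. Item estimates are
therefore free of assumptions about the person distribution; the package
verifies this invariance by simulation (shifting the generating person mean
leaves the estimates unchanged up to Monte Carlo error). The
$\gamma_r$ are computed by item-by-item convolution carried out entirely in
log space, so the recursion cannot overflow for any threshold magnitudes;
it is tested against exhaustive pattern enumeration to $10^{-10}$ in log
space. Persons are grouped by their observed item subset, giving each group
its own conditional likelihood — this is how missing responses are handled
— and persons with extreme raw scores (zero or maximum) drop out because
they carry no conditional information.

The conditional log-likelihood is convex. One direction is unidentified (a
uniform shift of all thresholds), so optimization runs on a reduced
parameter vector with the shift direction removed, using BFGS with the
analytic gradient followed by Newton polishing until the gradient norm
falls below `tol` (default `1e-8`, default cap 200 iterations; in practice
a 14-item, n = 2000 fit converges to gradient norms near `1e-12` in a few
seconds). The reported solution is re-anchored so the **item locations sum
to zero**, and the constraint is recorded on the `item_parameters` object
so reports can re-anchor differently.

**Null categories.** A category observed zero times has no information
about its step parameter (the estimate would diverge), so such categories
are collapsed into their lower neighbour (the lowest category merges
upward) and the recoding is recorded on the result and reapplied
automatically when the parameters meet new data.

**Person estimation.** The default is Warm's weighted likelihood estimate
(WLE), which is bias-reduced and — crucially for targeting displays and
coverage percentages — finite for extreme raw scores. For the PCM the WLE
solves $r - E[R\mid\theta] + I'(\theta)/(2I(\theta)) = 0$ with
$I(\theta)$ the test information (the conditional variance of $R$) and
$I'$ its derivative (the third central moment). Plain ML is available for
comparison; it maps extreme scores to $\pm\infty$. Standard errors are
$1/\sqrt{I(\hat\theta)}$. Because the raw score is sufficient, estimates
are solved once per distinct (item subset, raw score) pair.

# Item fit

Standardized residuals are $z_{pi} = (x_{pi} - E[X_{pi}])/\sqrt{\mathrm{Var}(X_{pi})}$.
By default the moments are those of item $i$'s distribution **conditional
on the person's raw score** over their observed items, computed from the
same elementary symmetric functions as the estimation. Under the model this
makes $E[z] = 0$ and $E[z^2] = 1$ hold exactly, so the mean-square
statistics are centred at 1 for any test length. The often-seen alternative
— unconditional moments evaluated at the estimated $\hat\theta$
(`moments = "theta"`) — is also provided; it deflates the null mean squares
by roughly $1 - V_i/\mathrm{TIF}$ (about $1 - 1/I$ for comparable items,
e.g. $\approx 0.86$ for a 7-item scale), because the person estimate
absorbs part of each response. That deflation is a property of the
estimator, not of the data, which is why the conditional version is the
default.

Outfit is the unweighted mean of $z^2$ per item; infit weights by the
conditional variance, $\sum (x-E)^2 / \sum \mathrm{Var}$. Standardized
versions (ZSTD) use the Wilson–Hilferty cube-root transform
$z = (u^{1/3}-1)\,3/q + q/3$ with model-based variance $q^2$ from fourth
conditional moments: $q^2_{\text{outfit}} = \sum (\mu_4/V^2)/N^2 - 1/N$ and
$q^2_{\text{infit}} = \sum(\mu_4 - V^2)/(\sum V)^2$. Since ZSTD grows
without bound with the sample size under even trivial misfit,
`subsampled_zstd()` averages the statistic over `k = 40` seeded subsamples
of `n_sub = 300` persons, item parameters held fixed from the full fit (a
switch allows per-subsample refitting). Flagging uses mean squares outside
[0.7, 1.3] or |ZSTD| above 2.0, with **inclusive boundaries**: a mean
square of exactly 0.7 is acceptable.

# Dimensionality

`residual_pca()` eigen-decomposes the item-by-item correlation matrix of
standardized residuals (pairwise-complete; the correlation matrix, not the
covariance, so eigenvalues sum to the item count). A first eigenvalue at or
above 2.0 signals a second dimension; the loadings on the first contrast
(leading eigenvector scaled by the root eigenvalue) then typically split
the items into clusters by sign, which `plot_first_contrast()` displays
against item location. `residual_correlations()` screens item pairs with a
Q3-type statistic against a **relative** cutoff: 0.2 above the mean of all
pairwise residual correlations (the estimator is labelled in the output,
since different packages compute "residual correlations" differently). The
combined verdict (`assess_unidimensionality()`) is *multidimensional* iff
any eigenvalue reaches 2.0 or any pair exceeds the cutoff, with the
triggering values listed. On two-trait synthetic data the verdict flips
from unidimensional at trait correlation $\rho = 1.0$ to multidimensional
at $\rho = 0.3$ (n = 2000), which is the package's operational check that
the rule has power where it should.

Note one visible consequence of the conditional residual moments: within a
person, conditional residuals are negatively coupled across items (their
weighted sum is fixed), so the smallest eigenvalues of the residual
correlation matrix sit closer to zero than under $\hat\theta$-based
residuals. The verdict thresholds act on the top of the spectrum, which is
unaffected.

# Differential item functioning

`dif_two_group()` fits the model separately per group (after collapsing
categories identically in both groups so the likelihoods share a support)
and compares item locations on an equated metric, with DIF size = absolute
location difference in logits and the conventional 0.5-logit criterion.
Equating needs anchors, and anchors should not themselves carry DIF. Each
group's own fit is centred (locations sum to zero), which attenuates a
single shifted item's raw location difference by $(I-1)/I$ — enough to keep
a true 0.5–0.6 logit shift below the flagging cutoff if all items anchor
the metric. The package therefore seeds the anchor set by **leave-one-out
equating** (each item judged against the mean difference of the *other*
items, which is unbiased under single-item DIF), then runs up to three
standard purification rounds equating on the mean of the current anchors,
so the final reported metric has mean anchor difference zero. Injection
tests recover a 0.6-logit shift within 0.1 and keep the null flag rate at
zero. A global likelihood-ratio test (group-specific vs joint parameters)
accompanies the table.

`dif_split_search()` scans all cut points of an ordered covariate that
leave at least `min_group` persons on each side, computes the LR statistic
at each, and reports the maximizing cut with a Bonferroni adjustment over
the number of candidates. This is deliberately a *single-level* split
search rather than a full model-based recursive partition: the evaluation
design only ever interprets one split per covariate, and the exhaustive
scan with a multiplicity correction is transparent about what was searched.
Age dichotomizations at 31 and at 20 are available as presets.

# Targeting, reliability and score conversion

Targeting compares the person distribution with the item threshold
distribution on the shared logit scale (`targeting_summary()`,
`plot_wright_map()`); thresholds here are the PCM step parameters, not
Thurstonian thresholds (documented, switchable by supplying other values).
Disordered thresholds — $\delta_{i,k} > \delta_{i,k+1}$ — are flagged per
adjacent pair with the gap size.

Reliability is reported conditionally, not as a point estimate: the test
information function $\mathrm{TIF}(\theta) = \sum_i \mathrm{Var}(X_i\mid\theta)$
is evaluated on a grid ($[-6, 6]$ in steps of 0.01, extended to cover the
person estimates), converted to a conditional person separation index via

$$\mathrm{PSI}(\theta) = 1 - 1/\mathrm{TIF}(\theta),$$

clipped at zero below TIF = 1. PSI 0.7 and 0.8 correspond to test
information 10/3 and 5. The interval where PSI reaches the threshold is
found on the grid with linearly interpolated endpoints, and the share of
persons below / inside / above it is reported (summing to 100), along with
the share beyond the most extreme item thresholds. Extreme-score persons
participate through their finite WLE locations, flagged as such — excluding
them would silently understate floor and ceiling shares.

`score_to_theta_table()` converts raw sum scores to interval measures for a
complete item subset: interior scores solve $E[R\mid\theta] = r$ by
monotone root-finding (these coincide with ML scoring to $10^{-6}$, which
the tests assert), extreme scores use the WLE (finite and consistent with
person estimation elsewhere), and standard errors are
$1/\sqrt{\mathrm{TIF}}$. Output stays in logits; no rescaling rule is
imposed.

# The synthetic-data generator

`simulate_pcm()` draws category responses from the model at each person's
trait value; `pss_like_preset()` encodes the study-like conditions the
package is configured for: 793 persons, 14 five-category items split 7/7
into negatively and positively worded clusters answering two traits with
correlation 0.5, person distribution $N(0.88, 1.57^2)$ per trait, MCAR
missingness off by default, and a mandatory seed (generation is
bit-reproducible). Negative-item locations average 0.58 logits with items
1 and 11 on top; positive-item locations and the step spreads are not
published anywhere, so they were fixed once to reproduce the instrument's
known response-category totals (roughly 6/20/32/28/14 percent across
categories 0–4) and threshold geometry (top negative step near 3.2; items
4, 5, 9, 10 with clearly separated thresholds, spread 1.8 vs 1.2). Group
covariates (gender ~2:1 female, a right-skewed adult age distribution) are
generated alongside so DIF scenarios can condition on them; `inject_dif()`
shifts a target item's thresholds for a covariate-defined group before
sampling. Responses are generated already oriented in the distress
direction — i.e. *after* the reverse-coding step that real PSS data would
need — so pipelines on synthetic data should run with
`reverse_positive = FALSE`.

What the generator does *not* emulate: response styles (e.g. extreme or
midpoint preference), informative missingness, local dependence beyond the
two-trait structure, discrimination differences between items, or guessing.
Passing tests on this data therefore demonstrate that the statistical
machinery is correct and has power under the model's assumptions — not that
any particular real instrument satisfies them.

# Numerical and design choices, in one place

* ESF recursion in log space (log-sum-exp convolutions); leave-one-out
  tables via prefix/suffix convolutions for the analytic CML gradient.
* Identification: sum of item locations = 0, recorded on the object;
  optimization removes the flat direction by parameter reduction first.
* Convergence: gradient norm below `1e-8` (BFGS + Newton polish); a fit
  that cannot reach within two orders of magnitude of the tolerance raises
  an error naming the gradient norm.
* Residual moments conditional on the raw score by default;
  `moments = "theta"` for the conventional plug-in version.
* Fit-flag boundaries inclusive; Q3 cutoff is *strictly greater than*
  mean + 0.2.
* Subsample ZSTD holds item parameters fixed by default (`refit = TRUE`
  to re-estimate per subsample); all draws flow from one seed.
* DIF anchors seeded by leave-one-out equating, then mean-anchor
  purification (max 3 rounds); split-search p-values Bonferroni-adjusted
  over candidate cuts.
* Reliability grid $[-6,6]$ step 0.01 with linear interpolation at the PSI
  crossings; coverage counts WLE-located extreme persons.
* Degenerate inputs: items with fewer than two observed categories are
  rejected with a pointer to preprocessing; persons with no observed items
  are rejected; single-person targeting warns that the SD is undefined.

Simulation-based checks in the test suite use n = 2000 (person recovery,
fit-statistic null behaviour, DIF injection, dimensionality verdicts) and
n = 3000 (person-distribution invariance), sizes at which the Monte Carlo
error of the checked quantities is comfortably below the asserted margins.

# Limitations

The package fits the PCM by CML only — no rating scale model, no joint or
marginal ML, no Bayesian estimation, and no multidimensional IRT: the
dimensionality stage *diagnoses* structure but does not model it. Fit
statistics are item-level (no person fit), and their null distributions are
handled by the subsample protocol rather than bootstrapping. The DIF stage
covers two-group comparisons and one-level covariate splits, not trees over
covariate combinations or uniform/non-uniform decompositions. Score
conversion tables require complete responses on the subset.
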