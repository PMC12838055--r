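---
title: "Anchor-based semantic scoring and its evaluation battery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based semantic scoring and its evaluation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Open-response instruments ask people to produce their own descriptor terms
rather than endorse fixed items. To place such responses on the metric of an
established trait taxonomy (here the five-domain, thirty-facet Big Five
hierarchy), `semanchor` scores each respondent term against a curated *anchor
lexicon*: every facet is represented by a set of anchor phrases, all text is
embedded in a shared semantic vector space, and a term's score on facet $f$
is the mean cosine similarity to $f$'s anchors,

$$s_{t,f} = \frac{1}{|A_f|}\sum_{a \in A_f}\cos(e_t, e_a).$$

Person-level facet composites average $s_{t,f}$ over the person's retained
terms, $x_{if} = \mathrm{mean}_{t \in T_i}\, s_{t,f}$, and are standardized
per facet across persons, $z_{if} = (x_{if}-\bar x_f)/s_f$ (sample sd,
denominator $n-1$). Because each $s_{t,f} \in [-1,1]$, every raw composite is
bounded in $[-1,1]$; the package asserts this invariant on every run.

The anchor lexicon *defines* the score space: the transformation aligns
open-response output with an existing trait language rather than discovering
structure inductively. Everything downstream — reliability, network
stability, convergence, configuration alignment — evaluates the behavior of
these predefined composites.

## Quality control

Raw terms are normalized (lowercase, trimmed, internal whitespace collapsed;
a minimal superset of "lowercase, trim whitespace"), junk tokens on a
configurable stop list (`nan`, `n/a`, empty strings, boilerplate) are flagged
as noise, and within-person repeats of the same normalized term beyond the
first are flagged as duplicates. Deduplication is idempotent: adding a copy
of an existing term changes no score. Persons left with zero retained terms
are excluded with a warning and listed in the composite matrix's exclusion
set; zero-variance facet columns are flagged and zeroed rather than dropped,
so matrix shapes are stable across resamples.

The two term categories (personal / professional prompts) are pooled for
scoring — the composite definition does not distinguish them — but the
category field is retained and per-category scoring is available by
subsetting records before `build_composites()`.

## Embedding backends

`embedding_provider()` is a deterministic contract: same text, same unit
vector. Any sentence encoder can be wrapped in it. The package's default
backend, `make_embedding_space()`, is a *geometric construction with planted
structure*: domain directions are drawn on the unit sphere, facet centroids
mix their domain direction with a facet-specific direction using weight
`domain_cohesion` (loading parametrization: within-domain centroid cosine is
approximately `domain_cohesion^2`), and every vocabulary term or anchor
phrase is the centroid plus Gaussian noise with expected displacement norm
`anchor_concentration` (the noise is scaled by $1/\sqrt d$ so the parameter
has the same meaning at any embedding dimension). Out-of-vocabulary strings
map to seeded-hash unit vectors, so arbitrary text stays embeddable.

This backend exists so that every downstream statistic can be validated
against known ground truth without downloading model weights. It emulates
the *geometry* real sentence encoders induce over trait language — tight
facet clusters nested in broader domain regions — but not their lexical
semantics: synonyms invented at test time do not land near each other unless
the generator placed them there. Passing tests therefore demonstrate that
the pipeline measures planted structure faithfully, not that any particular
pretrained encoder yields valid trait scores.

## The synthetic cohort

`simulate_cohort()` generates the full study situation. Latent domain scores
are standard normal; latent facet scores are
$a\,\theta_{d(f)} + \sqrt{1-a^2}\,\varepsilon$ with `facet_loading_a = 0.8`
by default. Each person emits 20 terms (alternately tagged professional /
personal, mirroring a 10 + 10 prompt design): a facet is sampled with
probability proportional to $\exp(\eta_{if}/\tau)$, then an unused
vocabulary term of that facet, so that with duplicate injection disabled no
accidental repeats occur. With probability `dup_rate` (default 0.126,
matching a realistic within-person duplicate rate for open-response
exports) a slot repeats a uniformly chosen earlier term, and with
probability `noise_rate` (default 0.02) it emits a stop-list token.
Questionnaire facet scores are
$c\,\eta_{if} + \sqrt{1-c^2}\,\epsilon$ rescaled to a T-score metric
(mean 50, sd 10); `b5_convergence_c` is the convergence dial that the
person-level validity analyses must recover. The T-scaling is cosmetic —
downstream analyses standardize — but mirrors how questionnaire reports
arrive in practice.

Simulated expert ratings follow a two-way random-effects generating model:
`rating = clamp(round(true + rater_bias + error), 1, 5)` with the latent
true scores centered at the scale midpoint. The returned matrix carries the
latent scores so recovery can be tested. Note that the 1–5 discretization
attenuates ICC estimates by roughly 0.05 relative to the continuous-scale
analytic value $\sigma^2_t/(\sigma^2_t+\sigma^2_b+\sigma^2_e)$ (rounding
contributes variance close to 1/12, clamping a little more); the estimator
itself is unbiased in the continuous limit, which the test suite verifies
separately.

All randomness flows from a single integer seed; replicate seeds for every
bootstrap are derived from the master seed *by counter*, not by execution
order, so replicate $b$ is reproducible in isolation and results are
byte-identical across reruns.

## Reliability

Omega total is computed from a minimum-residual (minres) factor solution:
the uniquenesses are optimized by L-BFGS-B to minimize the off-diagonal
residuals of $R - \Lambda\Lambda'$, with loadings recovered from the reduced
matrix's eigendecomposition. For parallel items omega equals standardized
alpha, a closed-form cross-check in the tests.

Omega hierarchical uses a Schmid–Leiman orthogonalization: group factors by
minres, oblique rotation, a single higher-order factor fitted to the
group-factor correlation matrix, and loadings split into a general part
($\lambda g$) and orthogonal group parts ($\lambda\sqrt{1-g^2}$). The
rotation is promax; the more common oblimin criterion would serve equally,
but promax is available in base R, is standard practice for this
decomposition, and the Schmid–Leiman contract (communality preserved,
$\omega_h \le \omega_t$) is independent of the oblique criterion chosen.
When the rotation degenerates — effectively one common factor, so the
group-factor correlation matrix is singular — all common variance is
assigned to the general factor, which reproduces the correct limit
$\omega_h = \omega_t$. Hierarchical partitioning is refused outright for
fewer than two group factors, and the pipeline refuses it for domains with
$k < 3\times$ the group count, generalizing the instability of hierarchical
estimates for very small indicator sets.

Bootstrap confidence intervals resample persons (not indicators) with
replacement — the standard choice when rows are the exchangeable unit — and
use percentile bounds. Failed resamples are dropped and counted; more than
10% failures aborts.

ICC uses the classical two-way random-effects ANOVA decomposition for
absolute agreement. Both ICC(A,1) and ICC(A,k) are computed; ICC(A,1) is the
headline because single-rater agreement is the conservative claim when the
variant is unreported.

## Networks

The partial-correlation network is a graphical lasso applied to the Spearman
correlation matrix (rank-based, robust to zero inflation), repaired to
positive definite by eigenvalue clipping at $10^{-6}$ with rescaling to unit
diagonal (a no-op on PD input). The lasso path runs from $\lambda_{max}$
(smallest penalty giving an empty graph) down to $0.01\,\lambda_{max}$ over
log-spaced points, with warm starts. Model selection uses the extended BIC,
$-2\ell + E\log n + 4 E \gamma \log p$ with $\gamma = 0.5$ (the conventional
default; $\gamma = 0$ reduces to BIC, asserted as an identity in the tests).
One numerical choice deserves emphasis: the log-likelihood entering the EBIC
is that of the *constrained maximum-likelihood refit* on each candidate
support (zero penalty on active edges, prohibitive elsewhere), not of the
shrunken estimate. Scoring the shrunken estimate lets the shrinkage bias of
strong edges masquerade as fit improvement and systematically over-selects
density; with the refit, the selected support matches planted sparse
structures with high sensitivity and near-zero false positives. At the
refit optimum $\mathrm{tr}(S\Theta) = p$, so the likelihood reduces to
$-(n/2)(\log\det W + p)$ with $W$ the completed covariance — the form used,
because it stays finite where a near-singular precision reconstruction
would not. Reported edge weights are the standardized negative precision
off-diagonals of the penalized solution at the selected $\lambda$, as is
conventional.

Strength centrality sums absolute edge weights; betweenness and closeness
use edge lengths $1/|w|$ (stronger edge, shorter path) with harmonic
closeness so disconnected pairs contribute zero. The CS coefficient follows
the case-dropping bootstrap: the largest drop proportion at which subsample
centralities correlate at least 0.7 with the full-sample centralities in at
least 95% of resamples, on a 0.05–0.75 grid, truncated so every subsample
keeps at least $3p$ cases. Louvain community detection runs on absolute
weights with 20 seeded restarts, best by modularity. The five-domain
organization of a lexicon's semantic space is assessed on the facet–facet
cosine similarity graph (`facet_similarity_network()`), which is where
modular structure of the *trait language* lives; the person-score network
recovers the same partition when the planted structure is strong.

## Alignment

Configuration-level alignment treats each facet as a point (the mean of its
anchor embeddings) and compares two lexicons' configurations with five
indices: first canonical correlation after PCA reduction, RV coefficient,
Procrustes similarity ($1 - m^2$ after optimal translation, isotropic
scaling, rotation/reflection), distance correlation, and a one-sided Mantel
permutation test on cosine-distance matrices with the $+1$ small-sample
correction. Embedding-based configurations are the primary path (this is
what "semantic-space alignment" means); a score-based alternative — facet
correlation structure over persons — can be obtained by passing score
matrices to the same index functions.

Two degeneracy rules matter. When the two configurations' retained ranks sum
to at least the number of rows, the first canonical correlation equals 1 for
generic data as a matter of linear algebra; the package computes it anyway
and attaches a machine-readable flag, because silently suppressing the value
would hide behavior a reader needs to see (it is reported descriptively, as
such values should be). And the Mantel permutation scheme permutes row/column
*labels* simultaneously, never resampling entries, so each permuted matrix
has exactly the original distance multiset — asserted in tests.

Person-level convergence uses pairwise-complete Pearson and Spearman
cross-correlations of domain composites (means of six facet composites per
domain), matched-diagonal summaries, and a facet-level scan that reports the
largest absolute correlation among cells with pairwise $n \ge 10$.

## Problem sizes and runtime choices

The analysis scripts use 1000 bootstrap resamples for reliability CIs and
500 for network stability; the acceptance script uses 120 and a 25-point
lambda path, and the test suite smaller sizes still (down to 15 resamples in
pipeline smoke tests). These are accuracy/runtime trade-offs chosen so the
full battery runs in minutes on one core; the statistics themselves are
insensitive to these counts well before the chosen values, which the
seed-determinism and stability tests exercise.

## Known limitations

* The geometric embedding backend validates the pipeline, not any particular
  pretrained encoder; conclusions about real instruments require plugging in
  the instrument's actual encoder and lexicon.
* Polychoric input correlations are not supported; Pearson (reliability) and
  Spearman (networks) are the implemented choices.
* The generator draws a fixed number of terms per person; it does not model
  the heavy-tailed term-count distributions real exports show.
* Non-English responses and foil-prompt manipulation detection are out of
  scope; records carrying such labels pass through untouched.
* CS coefficients are capped by the grid truncation rule at small $n/p$
  ratios; with 176 persons and 30 nodes the maximum observable CS is 0.45.
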