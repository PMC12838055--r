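# semanchor

Psychometric evaluation of anchor-based semantic scoring for open-response
descriptor terms.

## The problem

Open-response instruments ask respondents to produce their own descriptor
terms (e.g. 10 "professional" and 10 "personal" attributes) instead of
rating fixed items. To analyze such output with classical psychometrics, the
terms must first be placed on the metric of an established trait taxonomy.
`semanchor` implements the full measurement-and-evaluation battery for that
setting, aimed at researchers validating expressive-semantic instruments
against the Big Five facet hierarchy (5 domains × 6 facets):

1. **Scoring.** Every facet *f* is represented by an anchor lexicon
   *A<sub>f</sub>* of facet-language phrases. With all text embedded in a
   shared semantic space, a term *t* scores
   *s<sub>t,f</sub>* = (1/|A<sub>f</sub>|) Σ<sub>a∈A<sub>f</sub></sub>
   cos(e<sub>t</sub>, e<sub>a</sub>). Person-level composites
   *x<sub>if</sub>* = mean<sub>t∈T<sub>i</sub></sub> *s<sub>t,f</sub>* over
   the person's QC-retained terms are standardized per facet to
   *z<sub>if</sub>*.
2. **Reliability.** McDonald's ω per domain with percentile bootstrap CIs,
   ω<sub>h</sub> via a Schmid–Leiman decomposition (minres extraction,
   oblique rotation, higher-order factor, orthogonalization), corrected
   indicator–total correlations, leave-one-out Δω, and two-way
   random-effects ICC for expert-rater agreement.
3. **Network structure and stability.** EBIC-selected graphical-lasso
   partial-correlation networks on Spearman matrices (the graphical lasso is
   implemented in compiled code, with the EBIC scored on constrained
   maximum-likelihood refits of each candidate support), strength /
   betweenness / closeness centralities, case-dropping CS coefficients,
   edge-weight bootstraps, Louvain communities, and global
   connectivity metrics.
4. **Convergence and alignment.** Person-level convergent/discriminant
   correlation matrices against questionnaire composites, and
   configuration-level alignment between two facet lexicons: first canonical
   correlation (with rank-degeneracy flags), RV coefficient, Procrustes
   similarity, distance correlation, and a Mantel permutation test on
   cosine-distance matrices.

Because real cohorts of this kind are typically proprietary, the package
ships a first-class synthetic-data module: a geometric embedding space with
planted facet/domain structure, cohort simulation with injected duplicate
and junk terms, questionnaire scores with a configurable convergence dial,
and ordinal rater panels with known variance components. Every downstream
statistic is validated against this ground truth.

## Worked example

The repository is organized as a numbered analysis workflow over the
package; each stage prints its findings and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic study inputs
Rscript analysis/02_score.R        # QC + anchor scoring
Rscript analysis/03_reliability.R  # omega battery + ICC
Rscript analysis/04_network.R      # glasso network + stability bootstraps
Rscript analysis/05_alignment.R    # convergence + configuration alignment
```

Output from a run at the default configuration (176 persons, seed
20260923):

```
persons: 176
term records: 3520
retention rate: 86.7% (duplicates 11.0%, noise 2.3%)

per-domain reliability (1000 bootstrap resamples):
 domain k omega omega_h ci_low ci_high mean_r_it max_abs_delta_omega
  dom01 6 0.987   0.917  0.984   0.990     0.956             0.00519
  dom02 6 0.994   0.928  0.992   0.995     0.979             0.00232
  ...
rater agreement: ICC(A,1) = 0.744, ICC(A,3) = 0.897

network: 30 nodes, density 0.398, global strength 18.30
communities: 5 (Q = 0.549, ARI vs planted domains = 1.000)
CS: strength 0.45, betweenness 0.40, closeness 0.40 (500 resamples)
edges: mean retention 0.842, median weight correlation 0.964

person-level: matched-domain mean |r| = 0.540 (range 0.472 to 0.582, n = 176)
configuration alignment: CCA r1 = 1.000 [flagged degenerate], RV = 0.993,
Procrustes = 0.988, dcor = 0.998
Mantel: r = 0.990, p = 0.0002 (5000 permutations)
```

Reading these numbers: the QC stage catches the duplicate/junk rates the
generator injected; ω ≈ 0.99 with ω<sub>h</sub> ≈ 0.92 says each domain's
six facet composites share a strong common component; Louvain on the
partial-correlation network recovers exactly the five planted domains
(ARI = 1); the CS coefficient of 0.45 is the grid maximum allowed at
n = 176 with 30 nodes (subsamples must keep ≥ 3p cases); the matched-domain
mean |r| ≈ 0.54 reflects the generator's convergence dial c = 0.6 after
attenuation through both instruments; and the CCA r1 = 1.00 is flagged as
rank-degenerate (two 64-dimensional configurations of 30 points), which is
why the permutation-based Mantel test and the RV/Procrustes/dcor indices
carry the inferential weight.

The same machinery is available programmatically:

```r
library(semanchor)
cohort <- simulate_cohort(sim_config(n_persons = 200, seed = 1))
cm  <- build_composites(cohort$term_records, cohort$anchor_lexicon, cohort$embedding)
net <- estimate_network(cm$Z)
louvain_communities(net, seed = 1)$Q
```

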