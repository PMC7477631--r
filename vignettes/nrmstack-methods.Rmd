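---
title: "Methods: neighbor-recommender stacking for drug-combination prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbor-recommender stacking for drug-combination prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrmstack)
```

## The problem and the model

Known drug combinations form a sparse undirected network over a drug
universe: nodes are drugs, edges are clinically validated pairs. The
prediction task is link prediction on this network, using side information:
per-drug annotation sets in several *channels* (protein targets, disease
indications, expression-signature genes, co-indication modules), plus
optionally precomputed similarity matrices (e.g. structural fingerprints).

Everything rests on one assumption: **similar drugs have similar
combination behavior**. The package operationalizes it in two ways.

### Per-channel Tanimoto similarity

For drugs $A$, $B$ with annotation sets of sizes $N_A$, $N_B$ and shared
count $N_{AB}$,

$$ S(A,B) = \frac{N_{AB}}{N_A + N_B - N_{AB}} \in [0, 1]. $$

Tokens are compared by exact string equality after whitespace trimming; any
fuzzy unification of identifiers (e.g. disease-name normalization) is
assumed to have happened upstream. The $0/0$ case (two annotation-free
drugs) is *undefined*: an annotation-free drug carries no evidence of
similarity. The default policy records the pair as undefined and stores 0;
a strict mode raises an error instead.

### Neighbor recommender scoring

Given a channel's similarity matrix $S$ and the binary adjacency $a$,

$$ Y_{ij} = \frac{\sum_{k \ne j} S_{ik}\, a_{kj}}{\sum_{k \ne j} S_{ik}},
\qquad \mathrm{score}_{ij} = \mathrm{score}_{ji} = Y_{ij} + Y_{ji}, $$

the similarity-weighted fraction of $i$'s neighborhood already known to
combine with $j$, symmetrized. Two deliberate deviations from the literal
formula, both switchable (`exclude_self`, and thresholding the raw score):

* **Self-exclusion (default `TRUE`).** The literal sum runs over all
  $k \ne j$, which includes $k = i$; since $S_{ii} = 1$, the term
  $S_{ii}a_{ij}$ injects the *label being predicted* into its own score and
  silently invalidates cross-validation. The default also drops $k = i$; a
  strict mode keeps it for replication.
* **Probability $= \mathrm{score}/2$.** The score is a sum of two
  quantities each in $[0,1]$, yet a probability threshold of $0.5$ is the
  conventional decision rule. Halving the score makes "probability
  $\ge 0.5$" well defined; strict mode thresholds the raw score.

A zero denominator (an isolated drug with no similarity mass) yields score
0 with a degeneracy flag rather than an error, so such drugs rank last
instead of aborting a scan.

### Stacked ensemble

One NRM base predictor per selected channel; a logistic-regression
meta-classifier combines the base probabilities. Base predictions fed to
the meta-fit are **out-of-fold**: each pair's base scores are computed with
its own fold's positive edges masked from the network. This is standard
stacking hygiene — in-sample base predictions are optimistically biased
because every training edge contributes to its own score. An in-sample
mode exists (`folds = NULL`) for replication of the simpler protocol, with
this caveat. The meta-model is unregularized (`glm`, binomial); perfectly
collinear base columns are tolerated with a warning, dropping the redundant
coefficient, which leaves predictions unchanged.

### Baseline classifiers

For comparison, each labeled pair can be represented by its vector of
per-channel similarities and fed to logistic regression, Gaussian naive
Bayes, or an RBF-kernel SVM. Because the pre-installed stack has no SVM or
random-forest library, both are implemented in compiled code in this
package: the SVM by simplified SMO with Platt-scaled probabilities, the
forest as CART with Gini-impurity splits. The naive Bayes event model is
Gaussian per feature (the features are continuous Tanimoto values, and
variances are floored at $10^{-9}$ against degenerate columns). Note one
consequence verified in the unit tests: on a balanced binary toy where
$P(\mathrm{pos}\mid x{=}1) = 0.9$, a *Bernoulli* NB would return 0.9, but
the Gaussian model returns the Gaussian-likelihood posterior
($\approx 0.988$); the tests freeze the Gaussian closed form, which is the
documented model. SVM hyperparameters default to $C = 1$,
$\gamma = 1/\text{channels}$ with an optional small grid search
(`grid = TRUE`), since no canonical values exist for this representation.

## Feature assessment and selection

A channel is informative when positive pairs are more similar than negative
pairs. Three statistics per channel, computed on the **full** non-edge set
(not a downsample):

* **Welch t-test** p-value (unequal variances — with $\sim$150:1 class
  imbalance the equal-variance assumption is indefensible);
* **signed KS statistic** $d = \big(F_{\mathrm{neg}} -
  F_{\mathrm{pos}}\big)$ at the point of maximum absolute difference, so
  $d > 0$ when positives are stochastically larger ($d \in [-1, 1]$; the
  subtraction order is a convention the package documents and keeps fixed);
* **random-forest mean-decrease-Gini** importance, computed on a 1:1
  downsampled pair set (so both classes carry weight), 500 trees,
  $\sqrt{C}$ candidate features per split, then min–max normalized to
  $[0,1]$ across channels.

The selection rule is `t_p < alpha` **or** `t_p <= marginal`
(defaults $\alpha = 0.05$, marginal band $0.1$). The band formalizes the
common practice of retaining a borderline channel by judgement.

**A caveat the user should understand:** raw per-channel thresholds have
exactly the textbook false-positive rate. With $C_0$ truly uninformative
channels, the probability that the selected set equals the informative set
is $\approx (1 - 0.1)^{C_0}$ per dataset. On synthetic nulls we observe
precisely this (uniform p-values on noise channels; occasional 5%-level
admissions). If exact support recovery matters more than per-channel power,
tighten `alpha` toward a Bonferroni-corrected level (`alpha = 0.05 / C`,
`marginal = alpha`); the package keeps the conventional raw default because
that is the established practice in this literature, and because a
spuriously admitted noise channel costs the stacked ensemble little (its
meta-coefficient shrinks toward zero — the planted-signal tests confirm the
out-of-fold ensemble stays within 0.02 AUROC of the best single channel).

## Evaluation harness

* **Downsampling.** All positives plus `ratio` $\times$ positives negatives
  drawn uniformly without replacement from the non-edge pool.
* **Folds.** Stratified by default (per-fold class counts within one pair
  of proportionality); any $k \ge 2$, with 3/5/10 the conventional values.
* **Link masking.** For network models (NRM, ensemble), CV folds partition
  the *labeled pairs*, and scoring a test fold removes that fold's positive
  edges from the adjacency first. This is the central correctness decision:
  no test edge may influence any training-time quantity. It is enforced in
  code (masking happens before any $Y$ is computed) and by tests that
  toggle masked edges and require bit-identical scores.
* **Protocol composition.** Baseline classifiers are cross-validated on the
  downsampled set (matching the conventional presentation of such results);
  a leakage-free alternative — downsample within each training fold — is
  the better choice when negatives are informative, and is what we
  recommend for new studies. Network models are evaluated on the full pair
  universe without downsampling.
* **Metrics.** Recall, precision, F1 from thresholded counts
  (threshold applied as $\ge$); AUROC via midranks (ties share average
  rank, equal to the Mann–Whitney statistic); AUPR by step integration of
  the precision–recall curve over distinct thresholds. Zero predicted
  positives make precision undefined: reported as 0 with a degeneracy flag
  (this matters in high-ratio sweeps). Repeats re-randomize both the
  negative sample and the folds; fold metrics are averaged within repeat,
  then mean $\pm$ sd taken over repeats. Every repeat/fold seed is derived
  deterministically from the master seed, so any run is bit-reproducible.
* **Leave-one-drug-out.** All edges touching the target are hidden; the
  ensemble is trained on the remaining pairs (out-of-fold); every
  (target, other) candidate is scored on the target-free network and
  ranked. Under heavy imbalance the meta-probabilities are conservative, so
  a threshold below 0.5 is often appropriate for candidate *lists* even
  though ranking quality is unaffected.

## The synthetic world

`generate_world()` emulates the features the method exploits, nothing more:

* `n_drugs = 120` in `n_clusters = 4` balanced latent clusters — large
  enough for stable AUROC estimates, small enough for fast tests;
* 4 channels, the first 2 informative. Each cluster owns 30 signature
  tokens; a drug carries each signature token of its own cluster with
  probability 0.6 and each of 60 shared background tokens with probability
  0.05. Expected within-cluster Tanimoto $\approx 0.35$ vs
  $\approx 0.005$ between — a strong, realistic annotation signal. Noise
  channels draw all tokens independently at rate 0.12, matching the
  expected set size ($\approx 21$) so set-size artifacts cannot separate
  the channel types;
* edges are Bernoulli with probability
  $\mathrm{logit}^{-1}(-4 + 4 \cdot \mathbb{1}[\text{same cluster}])$:
  $\approx 50\%$ within clusters, $\approx 1.8\%$ between, i.e. a strongly
  assortative network at $\approx 13\%$ overall density. All parameters
  were fixed once from this expected-value arithmetic, before any test was
  run. For the negative-ratio sweep (which must draw $12\times$ positives
  from the non-edge pool) the tests use a sparser variant
  (`edge_base = -5`, `edge_coef = 3.5`) because at default density the pool
  is arithmetically too small for ratio 12 — a feasibility constraint, not
  a tuning choice.

What the generator does **not** emulate: real marginal distributions of
annotation-set sizes (heavy-tailed in practice), hub drugs and
degree heterogeneity, correlated channels, missing-channel drugs, or the
$\sim 0.7\%$ edge density of curated combination data. A green test on this
world therefore establishes *mechanical correctness and signal recovery
under the model's own assumption*, not expected performance on any real
dataset. Typical default-world numbers, all recomputed by the tests and the
acceptance script rather than asserted as constants: out-of-fold per-channel
NRM AUROC $> 0.8$ on informative channels and $< 0.6$ on noise channels;
stacked AUROC $\approx 0.85$–$0.9$.

The latent cluster assignment is written only to a `truth_*` sidecar file
that no prediction-path reader consumes (the end-to-end CLI test deletes it
before running).

## Numerical and format choices

* Similarity matrices are symmetrized by averaging, with asymmetry beyond
  $10^{-6}$ treated as a data error (tolerates float-formatted exports
  without hiding real problems); diagonals are forced to 1 with a warning.
  Percent-scaled inputs (0–100) are divided by 100 on read.
* Pairs are stored with the lexicographically smaller id first; all pair
  keys are unordered; self-pairs are rejected everywhere with the offending
  line/id named.
* Missing similarity (drug absent from a channel): default policy scores 0
  and flags the pair (`missing_any`); a complete-cases policy drops it.
* Matrix writes use 17 significant digits, so read–write round trips are
  exact to $10^{-9}$ and better.
* Report files render `mean ± sd` cells at 3 decimals alongside
  full-precision columns; every output carries a `# seed=... config=...`
  header (32-bit deterministic hash of the run configuration).

## Known limitations

* The t/KS tests treat pair-level similarity values as independent
  samples; pairs sharing a drug are in fact dependent. P-values should be
  read as screening scores, not calibrated error rates (the selection-rule
  caveat above compounds this).
* Platt scaling is fit on in-sample decision values, which can make SVM
  probabilities overconfident on small training sets; rankings (AUROC/AUPR)
  are unaffected.
* The SMO solver targets small dense problems (thousands of pairs); for the
  full 183k-pair universe use the network models, which are vectorized.
* `exclude_self = FALSE` (the literal scoring formula) is provided for
  replication only; do not use it with cross-validation on the same
  network it is scored against.
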