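# nrmstack

Similarity-based prediction of synergistic **drug combinations** in R.

Finding drug pairs worth combining by wet-lab screening is slow and
expensive. A well-established computational shortcut starts from the
assumption that *similar drugs combine similarly*: if drug *i* resembles
drugs that are known combination partners of drug *j*, then (*i*, *j*) is a
promising candidate. `nrmstack` implements that idea end to end for anyone
with (a) set-valued drug annotations (targets, indications,
expression-signature genes, modules, ...) and/or precomputed similarity
matrices, and (b) a list of known positive drug pairs.

## The method

1. **Per-channel Tanimoto similarity.** For each feature channel, drug
   similarity is the set-overlap (Jaccard/Tanimoto) coefficient

   ```
   S(A, B) = N_AB / (N_A + N_B - N_AB)
   ```

   where `N_A`, `N_B` are annotation-set sizes and `N_AB` the shared count.
   Precomputed matrices (e.g. 2D structural similarity on a 0-100 scale)
   are read directly.

2. **Neighbor recommender scoring (NRM).** Given a similarity matrix `S`
   and the known-combination adjacency `a`, a candidate pair is scored

   ```
   Y_ij = Σ_k S_ik a_kj / Σ_k S_ik     (k ≠ j, and k ≠ i by default)
   score_ij = score_ji = Y_ij + Y_ji,   probability = score / 2
   ```

   i.e. the similarity-weighted fraction of `i`'s neighborhood that is
   already known to combine with `j`, symmetrized.

3. **Feature assessment and selection.** Channels are screened by comparing
   similarity values of positive vs negative pairs: Welch t-test, signed
   two-sample Kolmogorov–Smirnov D, and random-forest mean-decrease-Gini
   importance (min–max normalized).

4. **Stacked ensemble.** The selected per-channel NRM predictors are
   combined by a logistic-regression meta-classifier trained on
   *out-of-fold* base predictions.

5. **Imbalance-aware evaluation.** Known-pair data are extremely
   imbalanced (e.g. 1,196 positives vs 182,119 candidate negatives among
   606 drugs). The harness supports negative downsampling at a chosen
   ratio, stratified k-fold cross-validation with *link masking* (test-fold
   edges are removed from the network before any score is computed),
   repeated sampling, and recall / precision / F1 / AUROC / AUPR reporting
   as `mean ± sd`.

A synthetic-data generator with planted latent clusters makes the whole
pipeline testable offline, and a CLI (`simulate`, `similarity`, `nrm`,
`assess-features`, `ensemble`, `evaluate`, `predict`) drives everything
from plain TSV files.

## Worked example

```r
library(nrmstack)

world <- generate_world(generator_config(seed = 42))   # 120 drugs, 4 channels
world$network
#> <combination_network> 120 drugs, 955 known combinations

a <- assess_features(world$matrices, world$network, seed = 42, ntree = 150)
a
#>    channel       t_p    ks_d   ks_p gini gini_norm selected
#> 1 channel1 2.96e-323  0.7353 0.0000  327     0.930     TRUE
#> 2 channel2 1.82e-320  0.7356 0.0000  343     1.000     TRUE
#> 3 channel3  6.12e-01 -0.0357 0.2437  120     0.022    FALSE
#> 4 channel4  2.15e-02  0.0545 0.0146  115     0.000     TRUE
```

Channels 1–2 carry the planted signal (vanishing p-values, large positive
KS D, dominant Gini importance) and are selected; channel 4 is a textbook
5%-level false positive of the raw-threshold selection rule — see the
vignette for why that is expected behavior.

```r
sel <- select_channels(a)
rep <- run_experiment(world$network, world$matrices[sel],
                      list(type = "ensemble"),
                      run_config(k = 5, repeats = 5, seed = 42))
rep
#> <evaluation_report> model 'ensemble', k = 5, 5 repeat(s)
#>   recall    0.312 ± 0.014
#>   precision 0.470 ± 0.010
#>   f1        0.374 ± 0.013
#>   auroc     0.865 ± 0.003
#>   aupr      0.448 ± 0.009
```

AUROC/AUPR are threshold-free ranking metrics; recall/precision/F1 use the
0.5 probability threshold, which is deliberately conservative on the full
(≈13% positive) pair universe — hence high AUROC with modest recall.

Candidate partners for one held-out drug (all of its edges hidden during
training):

```r
cand <- leave_one_drug_out(world$network, world$matrices[sel], "D007",
                           threshold = 0.3, seed = 42)
head(cand, 5)
#>   Rank Drug1 Drug2 Possibility
#> 1    1  D007  D059   0.4167858
#> 2    2  D007  D047   0.3371696
#> 3    3  D007  D075   0.3371470
#> 4    4  D007  D055   0.3357932
#> 5    5  D007  D023   0.3151488
```

Four of these five top-ranked partners are true (hidden) combinations of
`D007` in the generating network.

## Command line

```sh
Rscript inst/cli/nrmstack simulate --n-drugs 120 --seed 7 --out fixtures/
Rscript inst/cli/nrmstack evaluate \
    --matrices c1=fixtures/similarity_channel1.tsv,c2=fixtures/similarity_channel2.tsv \
    --pairs fixtures/known_pairs.tsv --model ensemble --k 5 --repeats 20 \
    --seed 7 --out report.tsv
Rscript inst/cli/nrmstack predict --matrices ... --pairs ... --target D007
```

(After installation the launcher is at
`system.file("cli", "nrmstack", package = "nrmstack")`.)

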