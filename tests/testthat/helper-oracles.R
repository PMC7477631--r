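# Independent oracles and small instance builders shared across tests.
# These deliberately re-derive quantities by the most literal route
# (double loops, pairwise comparisons) so they stay independent of the
# vectorized implementations they check.

# Random symmetric similarity matrix over n drugs, entries in [0,1], unit
# diagonal.
rand_similarity <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("d%02d", seq_len(n))
  m <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  similarity_matrix(m, channel = "rand")
}

# Random combination network over the same ids at a given edge density.
rand_network <- function(n, seed, density = 0.25) {
  set.seed(seed + 1)
  ids <- sprintf("d%02d", seq_len(n))
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < density
  if (!any(keep)) keep[1] <- TRUE
  combination_network(
    data.frame(a = ids[ut[keep, 1]], b = ids[ut[keep, 2]]),
    drugs = drug_set(ids))
}

# Literal per-pair neighbor-recommender Y: explicit loop over neighbors k.
naive_nrm_y <- function(S, adj, i, j, exclude_self = TRUE) {
  ids <- rownames(S)
  num <- 0; den <- 0
  for (k in seq_along(ids)) {
    if (ids[k] == j) next
    if (exclude_self && ids[k] == i) next
    s <- S[i, ids[k]]
    num <- num + s * adj[ids[k], j]
    den <- den + s
  }
  if (den <= 1e-12) 0 else num / den
}

naive_nrm_score <- function(S, adj, i, j, exclude_self = TRUE) {
  naive_nrm_y(S, adj, i, j, exclude_self) +
    naive_nrm_y(S, adj, j, i, exclude_self)
}

# AUROC as the literal probability that a random positive outranks a random
# negative (ties count one half).
brute_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Classical unsigned two-sample KS statistic by brute force over the pooled
# grid.
brute_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Out-of-fold stacked-ensemble probabilities for all labeled pairs of a
# world; returns list(labels, prob, base).
oof_ensemble <- function(world, channels = names(world$matrices), k = 5,
                         seed = 1) {
  pairs <- nrmstack:::all_labeled_pairs(world$network)
  folds <- make_folds(pairs, k = k, seed = seed)
  base <- base_prediction_matrix(world$matrices[channels], world$network,
                                 pairs, folds)
  prob <- rep(NA_real_, nrow(pairs))
  for (f in seq_len(k)) {
    te <- folds == f
    meta <- fit_ensemble(base[!te, , drop = FALSE], pairs$label[!te])
    prob[te] <- ensemble_predict(meta, base[te, , drop = FALSE])
  }
  list(labels = pairs$label, prob = prob, base = base, folds = folds,
       pairs = pairs)
}
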