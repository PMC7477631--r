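# Which similarity channels are worth feeding to the ensemble? Positive
# pairs (known combinations) should be systematically more similar than
# negative pairs in an informative channel. Assessed with a Welch two-sample
# t-test, a signed two-sample Kolmogorov-Smirnov statistic, and
# random-forest Gini importance (min-max normalized across channels).

#' Split a channel's similarity values by combination label
#'
#' @param matrix A [similarity_matrix()].
#' @param network A [combination_network()] over the same drug set.
#' @return List with `pos` (values over edges) and `neg` (values over
#'   non-edges, upper triangle).
#' @export
split_by_label <- function(matrix, network) {
  adj <- network$adjacency
  if (!identical(rownames(adj), rownames(matrix))) {
    stop("matrix and network index different drug sets", call. = FALSE)
  }
  S <- unclass(matrix)
  ut <- upper.tri(adj)
  list(pos = S[ut & adj == 1L], neg = S[ut & adj == 0L])
}

#' Welch two-sample t-test p-value
#'
#' @param pos,neg Numeric vectors, each of length >= 2.
#' @return Two-sided p-value (unequal-variance Welch variant; robust to the
#'   extreme class-size imbalance of combination data). Identical constant
#'   samples, where the statistic is 0/0, return p = 1.
#' @export
ttest_pvalue <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  if (stats::var(pos) + stats::var(neg) == 0) {
    return(if (mean(pos) == mean(neg)) 1 else 0)
  }
  stats::t.test(pos, neg, var.equal = FALSE)$p.value
}

#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' D is the vertical difference `ECDF(neg) - ECDF(pos)` evaluated where its
#' absolute value is maximal, so `d > 0` when positive values are
#' stochastically larger (their ECDF lags behind). Ranges over [-1, 1];
#' swapping the samples flips the sign. The p-value is the standard
#' two-sample KS p for |d|.
#'
#' @param pos,neg Nonempty numeric vectors.
#' @return List with `d` (signed) and `p`.
#' @export
kstest_signed <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("each sample must be nonempty", call. = FALSE)
  }
  grid <- sort(unique(c(pos, neg)))
  ecdf_pos <- vapply(grid, function(x) mean(pos <= x), 0)
  ecdf_neg <- vapply(grid, function(x) mean(neg <= x), 0)
  diffs <- ecdf_neg - ecdf_pos
  d <- diffs[which.max(abs(diffs))]
  p <- suppressWarnings(stats::ks.test(pos, neg, exact = FALSE)$p.value)
  list(d = d, p = p)
}

#' Random-forest Gini importance of the similarity channels
#'
#' Trains a CART random forest (Gini impurity splits, `sqrt(C)` candidate
#' features per split, bootstrap resampling) on the pair dataset and returns
#' the raw mean decrease in Gini impurity per channel, averaged over trees.
#' Deterministic given the seed.
#'
#' @param dataset A [pair_dataset()] with both classes.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @return Named numeric vector of raw importances (one per channel).
#' @export
rf_importance <- function(dataset, seed = 1L, ntree = 500L) {
  X <- pair_features(dataset)
  y <- dataset$label
  if (length(unique(y)) < 2) {
    stop("importance needs both classes", call. = FALSE)
  }
  mtry <- max(1L, floor(sqrt(ncol(X))))
  imp <- rf_gini_importance(X, as.integer(y), as.integer(ntree), mtry,
                            as.integer(seed))
  stats::setNames(as.numeric(imp), attr(dataset, "channels"))
}

#' Min-max normalization to [0, 1]
#'
#' `x -> (x - min(x)) / (max(x) - min(x))`; the minimum maps to 0 and the
#' maximum to 1. All-equal input is a division by zero and errors.
#'
#' @param values Numeric vector with >= 2 values, not all equal.
#' @return Normalized vector (names preserved).
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  r <- range(values)
  if (r[1] == r[2]) {
    stop("all values equal: min-max normalization undefined", call. = FALSE)
  }
  (values - r[1]) / (r[2] - r[1])
}

#' Assess every similarity channel against the combination labels
#'
#' @param matrices Named list of [similarity_matrix()] objects.
#' @param network A [combination_network()].
#' @param seed Seed for the random-forest importance (which is computed on a
#'   1:1 downsampled pair dataset, so the two classes carry equal weight).
#' @param ntree Trees for the forest.
#' @param alpha,marginal Selection cutoffs, see [select_channels()].
#' @return A `feature_assessment` data frame: one row per channel with
#'   `t_p`, `ks_d`, `ks_p`, `gini`, `gini_norm` and `selected`.
#' @export
assess_features <- function(matrices, network, seed = 1L, ntree = 500L,
                            alpha = 0.05, marginal = 0.1) {
  channels <- names(matrices)
  rows <- lapply(channels, function(ch) {
    sp <- split_by_label(matrices[[ch]], network)
    ks <- kstest_signed(sp$pos, sp$neg)
    data.frame(channel = ch, t_p = ttest_pvalue(sp$pos, sp$neg),
               ks_d = ks$d, ks_p = ks$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  labeled <- downsample_negatives(network, ratio = 1L, seed = seed)
  ds <- assemble_pair_features(matrices, labeled)
  out$gini <- as.numeric(rf_importance(ds, seed = seed, ntree = ntree))
  out$gini_norm <- if (nrow(out) >= 2 && diff(range(out$gini)) > 0) {
    minmax_normalize(out$gini)
  } else {
    rep(NA_real_, nrow(out))
  }
  out$selected <- selection_rule(out$t_p, alpha, marginal)
  class(out) <- c("feature_assessment", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "marginal") <- marginal
  out
}

selection_rule <- function(t_p, alpha, marginal) {
  t_p < alpha | t_p <= marginal
}

#' Select channels from a feature assessment
#'
#' A channel is kept when its t-test p-value is below `alpha`, or within the
#' marginal-keep band (`t_p <= marginal`); the band mirrors the practice of
#' retaining a borderline channel (e.g. expression similarity at p = 0.1)
#' on judgement. The selection is a pure function of the recorded
#' statistics.
#'
#' @param assessment Output of [assess_features()].
#' @param alpha Significance cutoff (default 0.05).
#' @param marginal Marginal-keep cutoff (default 0.1); set to `alpha` to
#'   disable the band.
#' @return Character vector of selected channel names; empty selection
#'   errors with advice to pass a manual channel list.
#' @export
select_channels <- function(assessment, alpha = 0.05, marginal = 0.1) {
  sel <- assessment$channel[selection_rule(assessment$t_p, alpha, marginal)]
  if (!length(sel)) {
    stop("no channel passed selection; supply channels manually",
         call. = FALSE)
  }
  sel
}
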