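# Imbalance-aware evaluation: negative downsampling at a chosen
# negative:positive ratio, stratified k-fold cross-validation with link
# masking for the network-based models, repeated sampling, threshold and
# threshold-free metrics, and the leave-one-drug-out prediction protocol.

#' Downsample negatives to a fixed negative:positive ratio
#'
#' Keeps every positive pair and draws `ratio x n_positive` negative pairs
#' uniformly without replacement from the non-edge pool. Reproducible per
#' seed.
#'
#' @param network A [combination_network()].
#' @param ratio Integer >= 1.
#' @param seed Integer seed.
#' @return Data frame `drug_a, drug_b, label`.
#' @export
downsample_negatives <- function(network, ratio = 1L, seed = 1L) {
  ratio <- as.integer(ratio)
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  pos <- network$positive_pairs
  if (!nrow(pos)) stop("network has no positive pairs", call. = FALSE)
  pool <- non_edges(network)
  need <- ratio * nrow(pos)
  if (nrow(pool) < need) {
    stop("insufficient negatives: need ", need, ", pool has ", nrow(pool),
         call. = FALSE)
  }
  set.seed(seed)
  neg <- pool[sample.int(nrow(pool), need), , drop = FALSE]
  out <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  rownames(out) <- NULL
  out
}

#' Stratified fold assignment
#'
#' @param pairs Data frame with a `label` column.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Keep per-fold class proportions within one pair of the
#'   global proportions (default).
#' @return Integer vector of fold indices in `1..k`, one per pair.
#' @export
make_folds <- function(pairs, k = 5L, seed = 1L, stratified = TRUE) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- nrow(pairs)
  if (n < k) stop("fewer pairs than folds", call. = FALSE)
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(pairs$label)) {
      idx <- which(pairs$label == cl)
      if (length(idx) < k) {
        stop("stratified folds need >= k pairs per class", call. = FALSE)
      }
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Classification and ranking metrics for scored pairs
#'
#' Thresholded confusion counts give recall, precision and F1; AUROC is the
#' midrank (Mann-Whitney) statistic; AUPR is the step integral of the
#' precision-recall curve over distinct score thresholds. With zero
#' predicted positives, precision is undefined and reported as 0 with
#' `precision_degenerate = TRUE`.
#'
#' @param labels 0/1 vector, both classes present.
#' @param scores Scores/probabilities in [0, 1].
#' @param threshold Decision threshold (label 1 iff `score >= threshold`).
#' @return List: `recall, precision, f1, auroc, aupr, precision_degenerate`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("metrics need both classes", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  recall <- tp / (tp + fn)
  degenerate <- (tp + fp) == 0L
  precision <- if (degenerate) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  r <- rank(scores)  # midranks: ties share the average rank
  auroc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(recall = recall, precision = precision, f1 = f1, auroc = auroc,
       aupr = aupr(labels, scores), precision_degenerate = degenerate)
}

# Step integral of precision over recall, walking distinct thresholds from
# the highest score down: AP = sum over threshold steps of
# (R_t - R_{t-1}) * P_t.
aupr <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  keep <- c(diff(sc) != 0, TRUE)  # last index of each distinct score
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels == 1L)
  sum(diff(c(0, rec)) * prec)
}

metric_names <- c("recall", "precision", "f1", "auroc", "aupr")

#' Run a full repeated cross-validation experiment
#'
#' For each repeat (all seeds derived from the master seed): baseline
#' classifiers (`glm`/`nb`/`svm`) draw a fresh downsampled pair set at the
#' configured ratio and are cross-validated on it; network models (`nrm`,
#' `ensemble`) are cross-validated on the full labeled pair universe with
#' the test fold's positive edges masked out of the network during scoring.
#' Fold metrics are averaged within a repeat, then mean and sd are taken
#' over repeats.
#'
#' @param network A [combination_network()].
#' @param matrices Named list of [similarity_matrix()] objects.
#' @param model Model spec: list with `type` in
#'   `c("nrm", "ensemble", "glm", "nb", "svm")`, optional `channels`
#'   (default: all matrices; for `"nrm"`, the single channel to score) and
#'   `hyperparams`.
#' @param config A [run_config()].
#' @return An `evaluation_report`: `metrics` (per repeat), `summary`
#'   (mean/sd per metric), `config`, `model`.
#' @export
run_experiment <- function(network, matrices, model, config = run_config()) {
  type <- match.arg(model$type, c("nrm", "ensemble", "glm", "nb", "svm"))
  channels <- model$channels %||% names(matrices)
  mats <- matrices[channels]
  per_repeat <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    rep_seed <- derive_seed(config$seed, r)
    fold_metrics <- if (type %in% c("glm", "nb", "svm")) {
      eval_baseline_repeat(network, mats, type, model$hyperparams %||% list(),
                           config, rep_seed)
    } else {
      eval_network_repeat(network, mats, type, config, rep_seed)
    }
    m <- colMeans(fold_metrics)
    per_repeat[[r]] <- data.frame(model = type, k = config$k, rep = r,
                                  t(m), stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, per_repeat)
  summary <- do.call(rbind, lapply(metric_names, function(mn) {
    data.frame(model = type, k = config$k, metric = mn,
               mean = mean(metrics[[mn]]), sd = stats::sd(metrics[[mn]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, summary = summary, config = config,
                 model = model),
            class = "evaluation_report")
}

eval_baseline_repeat <- function(network, matrices, type, hyperparams,
                                 config, rep_seed) {
  labeled <- downsample_negatives(network, config$ratio, seed = rep_seed)
  ds <- assemble_pair_features(matrices, labeled,
                               missing_policy = config$missing_policy)
  folds <- make_folds(ds, k = config$k, seed = derive_seed(rep_seed, 1))
  t(vapply(seq_len(config$k), function(f) {
    train <- ds[folds != f, , drop = FALSE]
    test <- ds[folds == f, , drop = FALSE]
    fit <- fit_pair_classifier(train, type, hyperparams,
                               seed = derive_seed(rep_seed, 2, f))
    p <- predict_pairs(fit, test)
    unlist(compute_metrics(test$label, p, config$threshold)[metric_names])
  }, stats::setNames(numeric(5), metric_names)))
}

all_labeled_pairs <- function(network) {
  adj <- network$adjacency
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  data.frame(drug_a = rownames(adj)[idx[, 1]],
             drug_b = colnames(adj)[idx[, 2]],
             label = adj[idx], stringsAsFactors = FALSE)
}

eval_network_repeat <- function(network, matrices, type, config, rep_seed) {
  pairs <- all_labeled_pairs(network)
  folds <- make_folds(pairs, k = config$k, seed = rep_seed)
  base <- base_prediction_matrix(matrices, network, pairs, folds)
  t(vapply(seq_len(config$k), function(f) {
    test <- folds == f
    p <- if (type == "nrm") {
      base[test, 1]
    } else {
      meta <- fit_ensemble(base[!test, , drop = FALSE], pairs$label[!test])
      ensemble_predict(meta, base[test, , drop = FALSE])
    }
    unlist(compute_metrics(pairs$label[test], p,
                           config$threshold)[metric_names])
  }, stats::setNames(numeric(5), metric_names)))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> model '", x$model$type, "', k = ", x$config$k,
      ", ", x$config$repeats, " repeat(s)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f ± %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Leave-one-drug-out candidate prediction
#'
#' Hides every edge touching `target` from the network, trains the stacked
#' ensemble on all pairs *not* involving the target (out-of-fold base
#' predictions), then scores every (target, other) candidate with base NRM
#' features computed on the target-free network. Candidates at or above the
#' threshold are returned ranked by predicted probability.
#'
#' @param network A [combination_network()].
#' @param matrices Named list of [similarity_matrix()] objects (selected
#'   channels).
#' @param target Drug id to hold out.
#' @param threshold Decision threshold (default 0.5).
#' @param k Folds for the out-of-fold base predictions (default 5).
#' @param seed Integer seed.
#' @return Data frame with columns `Rank, Drug1, Drug2, Possibility`, sorted
#'   by decreasing possibility; attribute `all_candidates` holds the full
#'   scored table (used for rank diagnostics).
#' @export
leave_one_drug_out <- function(network, matrices, target, threshold = 0.5,
                               k = 5L, seed = 1L) {
  ids <- as.character(network$drugs)
  if (!(target %in% ids)) stop("unknown drug: ", target, call. = FALSE)
  pp <- network$positive_pairs
  keep <- pp$drug_a != target & pp$drug_b != target
  train_net <- combination_network(pp[keep, , drop = FALSE],
                                   drugs = network$drugs)
  others <- setdiff(ids, target)
  train_pairs <- all_labeled_pairs(train_net)
  train_pairs <- train_pairs[train_pairs$drug_a != target &
                               train_pairs$drug_b != target, , drop = FALSE]
  folds <- make_folds(train_pairs, k = k, seed = seed)
  base <- base_prediction_matrix(matrices, train_net, train_pairs, folds)
  meta <- fit_ensemble(base, train_pairs$label)
  cand <- data.frame(drug_a = pmin(target, others),
                     drug_b = pmax(target, others),
                     stringsAsFactors = FALSE)
  cand_base <- base_prediction_matrix(matrices, train_net,
                                      cbind(cand, label = 0L), folds = NULL)
  prob <- ensemble_predict(meta, cand_base)
  o <- order(prob, decreasing = TRUE)
  all_cand <- data.frame(Drug1 = cand$drug_a[o], Drug2 = cand$drug_b[o],
                         Possibility = prob[o], stringsAsFactors = FALSE)
  hits <- all_cand[all_cand$Possibility >= threshold, , drop = FALSE]
  out <- cbind(Rank = seq_len(nrow(hits)), hits)
  rownames(out) <- NULL
  attr(out, "all_candidates") <- all_cand
  out
}
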