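# Stacked ensemble: one NRM base predictor per selected similarity channel,
# combined by a logistic-regression meta-classifier. Base predictions are
# out-of-fold by default (each pair's base scores come from a network with
# that pair's fold masked), which is what makes stacking legitimate; an
# in-sample mode exists for replication but leaks the training labels into
# the meta-features.

#' Out-of-fold base prediction matrix
#'
#' Column c holds, for every labeled pair, the NRM probability from channel
#' c computed with the pair's own fold masked out of the combination
#' network. Equivalent to running a standalone masked NRM per channel and
#' collating the columns.
#'
#' @param matrices Named list of [similarity_matrix()] objects (selected
#'   channels, in order).
#' @param network A [combination_network()].
#' @param pairs Data frame `drug_a, drug_b, label`.
#' @param folds Integer fold assignment per pair (from [make_folds()]), or
#'   `NULL` for in-sample base predictions (no masking; leaks labels).
#' @param exclude_self See [nrm_y()].
#' @return Numeric matrix, `nrow(pairs)` x `length(matrices)`.
#' @export
base_prediction_matrix <- function(matrices, network, pairs, folds = NULL,
                                   exclude_self = TRUE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  base <- matrix(NA_real_, nrow(pairs), length(matrices),
                 dimnames = list(NULL, names(matrices)))
  if (is.null(folds)) {
    for (c in seq_along(matrices)) {
      base[, c] <- score_pairs(matrices[[c]], network, pairs,
                               exclude_self = exclude_self)$probability
    }
    return(base)
  }
  if (length(folds) != nrow(pairs)) {
    stop("folds must assign every pair", call. = FALSE)
  }
  for (f in sort(unique(folds))) {
    test <- folds == f
    masked <- pairs[test, c("drug_a", "drug_b")]
    for (c in seq_along(matrices)) {
      base[test, c] <- score_pairs(matrices[[c]], network,
                                   pairs[test, , drop = FALSE],
                                   masked = masked,
                                   exclude_self = exclude_self)$probability
    }
  }
  base
}

#' Fit the logistic meta-classifier over base predictors
#'
#' Plain unregularized logistic regression ("default parameters") on the
#' base probability columns. Perfectly collinear base columns produce a
#' rank-deficient fit; the fit proceeds with a warning and the redundant
#' coefficient dropped.
#'
#' @param base Base prediction matrix from [base_prediction_matrix()].
#' @param labels 0/1 labels, both classes present.
#' @return An `ensemble_model` holding the GLM and the channel order.
#' @export
fit_ensemble <- function(base, labels) {
  if (length(unique(labels)) < 2) {
    stop("ensemble training needs both classes", call. = FALSE)
  }
  if (ncol(base) > 1 && qr(cbind(1, base))$rank < ncol(base) + 1) {
    warning("collinear base predictor columns; redundant columns dropped",
            call. = FALSE)
  }
  df <- data.frame(.label = labels, base, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.label ~ ., data = df, family = binomial()))
  structure(list(fit = fit, channels = colnames(base)),
            class = "ensemble_model")
}

#' Predict with a fitted ensemble
#'
#' @param model An `ensemble_model`.
#' @param base Base prediction matrix with columns in the training channel
#'   order (enforced by name).
#' @return Probabilities in [0, 1].
#' @export
ensemble_predict <- function(model, base) {
  if (!identical(colnames(base), model$channels)) {
    stop("base predictor channel order mismatch: expected (",
         paste(model$channels, collapse = ", "), ")", call. = FALSE)
  }
  df <- as.data.frame(base)
  names(df) <- colnames(base)
  p <- as.numeric(suppressWarnings(
    stats::predict(model$fit, newdata = df, type = "response")))
  pmin(pmax(p, 0), 1)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> logistic stack over: ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize an ensemble model to JSON
#' @param model An `ensemble_model`.
#' @param path Output path.
#' @export
write_ensemble <- function(model, path) {
  co <- stats::coef(model$fit)
  co[is.na(co)] <- 0
  jsonlite::write_json(list(channels = model$channels,
                            intercept = unname(co[1]),
                            coefficients = as.list(co[-1])),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
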