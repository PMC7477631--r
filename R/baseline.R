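# Feature-vector baselines: each labeled drug pair becomes one row whose
# features are the per-channel similarities S_c[i, j], and a conventional
# classifier (logistic regression, Gaussian naive Bayes, or an RBF-kernel
# SVM) is trained on those rows.

#' Assemble per-pair similarity feature vectors
#'
#' The feature vector of pair (i, j) is `(S_1[i,j], ..., S_C[i,j])` in the
#' declared channel order. A drug missing from some channel's matrix is
#' handled by the missing-value policy: `"zero"` scores the pair 0 in that
#' channel and flags it (column `missing_any`), `"complete"` drops the pair.
#'
#' @param matrices Named list of [similarity_matrix()] objects (the declared
#'   channel order).
#' @param pairs Data frame with columns `drug_a, drug_b, label`.
#' @param missing_policy `"zero"` or `"complete"`.
#' @return A [pair_dataset()].
#' @export
assemble_pair_features <- function(matrices, pairs,
                                   missing_policy = c("zero", "complete")) {
  missing_policy <- match.arg(missing_policy)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  channels <- names(matrices)
  if (is.null(channels) || any(!nzchar(channels))) {
    stop("'matrices' must be a named list (channel names)", call. = FALSE)
  }
  feats <- matrix(NA_real_, nrow(pairs), length(channels),
                  dimnames = list(NULL, channels))
  for (c in seq_along(matrices)) {
    S <- matrices[[c]]
    ia <- match(pairs$drug_a, rownames(S))
    ib <- match(pairs$drug_b, rownames(S))
    ok <- !is.na(ia) & !is.na(ib)
    feats[ok, c] <- unclass(S)[cbind(ia[ok], ib[ok])]
  }
  miss <- rowSums(is.na(feats)) > 0
  if (missing_policy == "complete") {
    pairs <- pairs[!miss, , drop = FALSE]
    feats <- feats[!miss, , drop = FALSE]
    miss <- miss[!miss]
  } else {
    feats[is.na(feats)] <- 0
  }
  out <- pair_dataset(pairs, feats, channels)
  out$missing_any <- miss
  out
}

#' Fit a baseline pair classifier
#'
#' @param dataset A [pair_dataset()] containing both classes.
#' @param algorithm `"glm"` (logistic regression), `"nb"` (Gaussian naive
#'   Bayes) or `"svm"` (RBF-kernel SVM trained by SMO, probabilities via
#'   Platt scaling).
#' @param hyperparams List; for the SVM, `cost` (default 1) and `gamma`
#'   (default `1/n_channels`). `grid = TRUE` runs a small internal
#'   cross-validated grid over `cost` in {0.5, 1, 2, 4} and `gamma` in
#'   {0.5, 1, 2}/n_channels.
#' @param seed Integer seed (SVM working-set shuffling; GLM and NB are
#'   deterministic).
#' @return A `pair_model` with a [predict_pairs()] method.
#' @export
fit_pair_classifier <- function(dataset, algorithm = c("glm", "nb", "svm"),
                                hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  channels <- attr(dataset, "channels")
  X <- pair_features(dataset)
  y <- dataset$label
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("constant feature column(s): ", paste(channels[const],
            collapse = ", "), call. = FALSE)
  }
  fit <- switch(algorithm,
    glm = {
      df <- data.frame(.label = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(.label ~ ., data = df, family = binomial()))
    },
    nb = gnb_fit(X, y),
    svm = svm_fit(X, y, hyperparams, seed))
  structure(list(algorithm = algorithm, fit = fit, channels = channels,
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "pair_model")
}

#' Predict combination probabilities for drug pairs
#'
#' @param model A `pair_model` from [fit_pair_classifier()].
#' @param dataset A [pair_dataset()] whose channels match the training
#'   channel order (enforced).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_pairs <- function(model, dataset) {
  channels <- attr(dataset, "channels")
  if (!identical(channels, model$channels)) {
    stop("channel order mismatch: model was trained on (",
         paste(model$channels, collapse = ", "), ")", call. = FALSE)
  }
  X <- pair_features(dataset)
  p <- switch(model$algorithm,
    glm = {
      df <- as.data.frame(X)
      names(df) <- colnames(X)
      as.numeric(suppressWarnings(
        stats::predict(model$fit, newdata = df, type = "response")))
    },
    nb = gnb_predict(model$fit, X),
    svm = svm_predict_prob(model$fit, X))
  pmin(pmax(p, 0), 1)
}

#' @export
print.pair_model <- function(x, ...) {
  cat("<pair_model> ", toupper(x$algorithm), " on channels: ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Gaussian naive Bayes ------------------------------------------------------
# Continuous Tanimoto features; per-class, per-feature normal likelihoods
# with a variance floor so degenerate (constant) features cannot produce
# infinite densities.

gnb_fit <- function(X, y, var_floor = 1e-9) {
  classes <- sort(unique(y))
  stats_by_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(mean = colMeans(Xc),
         var = pmax(apply(Xc, 2, stats::var), var_floor),
         prior = nrow(Xc) / nrow(X))
  })
  names(stats_by_class) <- as.character(classes)
  list(classes = classes, stats = stats_by_class)
}

gnb_predict <- function(fit, X) {
  loglik <- vapply(as.character(fit$classes), function(cl) {
    st <- fit$stats[[cl]]
    ll <- rep(log(st$prior), nrow(X))
    for (c in seq_len(ncol(X))) {
      ll <- ll + stats::dnorm(X[, c], st$mean[c], sqrt(st$var[c]), log = TRUE)
    }
    ll
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) loglik <- matrix(loglik, nrow = 1)
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  post[, as.character(fit$classes) == "1"]
}

## RBF-kernel SVM (simplified SMO + Platt scaling) ---------------------------
# The pre-installed stack has no SVM library, so the dual problem is solved
# with a compiled simplified-SMO routine; probabilities come from a logistic
# (Platt) fit on the training decision values.

svm_fit <- function(X, y, hyperparams = list(), seed = 1L) {
  cost <- hyperparams$cost %||% 1
  gamma <- hyperparams$gamma %||% (1 / ncol(X))
  if (isTRUE(hyperparams$grid)) {
    gs <- svm_grid_search(X, y, seed)
    cost <- gs$cost; gamma <- gs$gamma
  }
  ypm <- ifelse(y == 1, 1, -1)
  sm <- svm_smo_train(X, ypm, cost, gamma, 1e-3, 20L, as.integer(seed))
  dec <- svm_decision(X, ypm, sm$alpha, sm$b, gamma, X)
  platt <- suppressWarnings(
    stats::glm(y ~ dec, family = binomial(),
               data = data.frame(y = y, dec = dec)))
  list(X = X, y = ypm, alpha = sm$alpha, b = sm$b, cost = cost, gamma = gamma,
       platt = platt)
}

svm_decision_values <- function(fit, Xnew) {
  svm_decision(fit$X, fit$y, fit$alpha, fit$b, fit$gamma, Xnew)
}

svm_predict_prob <- function(fit, Xnew) {
  dec <- svm_decision_values(fit, Xnew)
  as.numeric(stats::predict(fit$platt, newdata = data.frame(dec = dec),
                            type = "response"))
}

svm_grid_search <- function(X, y, seed, costs = c(0.5, 1, 2, 4),
                            gammas = c(0.5, 1, 2) / ncol(X), k = 3L) {
  folds <- make_folds(data.frame(label = y), k = k, seed = seed)
  best <- list(auroc = -Inf, cost = costs[1], gamma = gammas[1])
  for (cost in costs) {
    for (gamma in gammas) {
      aucs <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
          return(NA_real_)
        }
        fit <- svm_fit(X[tr, , drop = FALSE], y[tr],
                       list(cost = cost, gamma = gamma), seed)
        compute_metrics(y[!tr],
                        svm_predict_prob(fit, X[!tr, , drop = FALSE]))$auroc
      }, 0)
      a <- mean(aucs, na.rm = TRUE)
      if (is.finite(a) && a > best$auroc) {
        best <- list(auroc = a, cost = cost, gamma = gamma)
      }
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
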