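# GLM / Gaussian NB / RBF-SVM baselines on per-pair similarity vectors.

sep_dataset <- function(n = 60, seed = 1) {
  # linearly separable in channel c1
  set.seed(seed)
  label <- rep(c(1L, 0L), each = n / 2)
  x1 <- ifelse(label == 1, runif(n, 0.7, 1), runif(n, 0, 0.3))
  x2 <- runif(n)
  pair_dataset(data.frame(drug_a = sprintf("a%d", 1:n),
                          drug_b = sprintf("b%d", 1:n), label = label),
               cbind(x1, x2), c("c1", "c2"))
}

null_dataset <- function(n = 1000, seed = 2) {
  set.seed(seed)
  pair_dataset(data.frame(drug_a = sprintf("a%d", 1:n),
                          drug_b = sprintf("b%d", 1:n),
                          label = rep(c(1L, 0L), n / 2)),
               cbind(runif(n), runif(n)), c("c1", "c2"))
}

test_that("assemble_pair_features builds vectors in declared channel order", {
  w <- generate_world(generator_config(n_drugs = 12, seed = 9))
  pairs <- downsample_negatives(w$network, 1, 3)
  ds <- assemble_pair_features(w$matrices, pairs)
  expect_identical(attr(ds, "channels"), names(w$matrices))
  expect_equal(ncol(pair_features(ds)), 4)
  i <- 5
  for (ch in names(w$matrices)) {
    expect_equal(ds[[ch]][i],
                 w$matrices[[ch]][ds$drug_a[i], ds$drug_b[i]])
  }
  # 2-channel case with known entries
  m <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  ds2 <- assemble_pair_features(
    list(u = similarity_matrix(m), v = similarity_matrix(m2)),
    data.frame(drug_a = "A", drug_b = "B", label = 1))
  expect_equal(unname(pair_features(ds2)[1, ]), c(0.2, 0.7))
  # self-pairs rejected
  expect_error(assemble_pair_features(
    list(u = similarity_matrix(m)),
    data.frame(drug_a = "A", drug_b = "A", label = 1)), "self")
})

test_that("missing-channel drugs follow the missing-value policy", {
  m <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m3 <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pairs <- data.frame(drug_a = c("A", "A"), drug_b = c("B", "C"),
                      label = c(1, 0))
  mats <- list(u = similarity_matrix(m), v = similarity_matrix(m3))
  dz <- assemble_pair_features(mats, pairs, missing_policy = "zero")
  expect_equal(nrow(dz), 2)
  expect_equal(dz$u[2], 0)           # missing similarity scored 0
  expect_true(dz$missing_any[2])     # ... and flagged
  dc <- assemble_pair_features(mats, pairs, missing_policy = "complete")
  expect_equal(nrow(dc), 1)          # incomplete pair dropped
})

test_that("SVM separates a separable toy perfectly in-sample", {
  ds <- sep_dataset()
  fit <- fit_pair_classifier(ds, "svm", seed = 1)
  p <- predict_pairs(fit, ds)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(compute_metrics(ds$label, p)$auroc, 1)
})

test_that("all classifiers are near chance on label-independent features", {
  ds <- null_dataset()
  half <- seq_len(nrow(ds)) <= nrow(ds) / 2
  for (alg in c("glm", "nb", "svm")) {
    fit <- fit_pair_classifier(ds[half, ], alg, seed = 3)
    auc <- compute_metrics(ds$label[!half],
                           predict_pairs(fit, ds[!half, ]))$auroc
    expect_gt(auc, 0.4)
    expect_lt(auc, 0.6)
  }
})

test_that("Gaussian NB posterior matches the closed-form Bayes computation", {
  # balanced binary feature: x=1 is 90% positive, x=0 is 10% positive
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1L, 90), rep(0L, 10), rep(1L, 10), rep(0L, 90))
  ds <- pair_dataset(data.frame(drug_a = sprintf("a%d", 1:200),
                                drug_b = sprintf("b%d", 1:200), label = y),
                     cbind(c1 = x), "c1")
  fit <- fit_pair_classifier(ds, "nb")
  p1 <- predict_pairs(fit, ds[1, ])
  # closed form under the documented Gaussian event model, from dnorm
  m1 <- mean(x[y == 1]); v1 <- var(x[y == 1])
  m0 <- mean(x[y == 0]); v0 <- var(x[y == 0])
  num <- dnorm(1, m1, sqrt(v1)) * 0.5
  den <- num + dnorm(1, m0, sqrt(v0)) * 0.5
  expect_equal(p1, num / den, tolerance = 1e-9)
})

test_that("fit rejects single-class data, warns on constant features", {
  ds <- sep_dataset()
  expect_error(fit_pair_classifier(ds[ds$label == 1, ], "glm"),
               "both classes")
  dsc <- ds
  dsc$c2 <- 0.5
  expect_warning(fit_pair_classifier(dsc, "glm"), "constant")
})

test_that("predict enforces channel order and ignores row order", {
  ds <- sep_dataset()
  fit <- fit_pair_classifier(ds, "glm")
  swapped <- ds
  attr(swapped, "channels") <- c("c2", "c1")
  expect_error(predict_pairs(fit, swapped), "channel order")
  set.seed(5)
  perm <- sample(nrow(ds))
  p <- predict_pairs(fit, ds)
  expect_equal(predict_pairs(fit, ds[perm, ]), p[perm])
})

test_that("GLM ranking is invariant to affine rescaling of a feature", {
  ds <- sep_dataset(n = 80, seed = 6)
  fit1 <- fit_pair_classifier(ds, "glm")
  ds2 <- ds
  ds2$c1 <- ds$c1 / 2 + 0.1  # affine map, still in [0,1]
  fit2 <- fit_pair_classifier(ds2, "glm")
  a1 <- compute_metrics(ds$label, predict_pairs(fit1, ds))$auroc
  a2 <- compute_metrics(ds2$label, predict_pairs(fit2, ds2))$auroc
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("SVM fits are deterministic given seed and honor hyperparameters", {
  ds <- sep_dataset(n = 40, seed = 7)
  f1 <- fit_pair_classifier(ds, "svm", list(cost = 2, gamma = 1), seed = 11)
  f2 <- fit_pair_classifier(ds, "svm", list(cost = 2, gamma = 1), seed = 11)
  expect_identical(predict_pairs(f1, ds), predict_pairs(f2, ds))
  expect_equal(f1$fit$cost, 2)
  expect_equal(f1$fit$gamma, 1)
})
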