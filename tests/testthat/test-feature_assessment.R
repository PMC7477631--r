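# Channel assessment: label split, Welch t, signed KS, forest importance,
# min-max normalization and the selection rule.

test_that("split_by_label partitions the upper triangle by edge status", {
  ids <- c("A", "B", "C", "D")
  m <- matrix(runif(16), 4, dimnames = list(ids, ids))
  S <- similarity_matrix((m + t(m)) / 2 * 0 + 0.3 + diag(4) * 0.7)
  net <- combination_network(data.frame(a = c("A", "C"), b = c("B", "D")),
                             drugs = drug_set(ids))
  sp <- split_by_label(S, net)
  expect_length(sp$pos, 2)
  expect_length(sp$neg, 4)  # C(4,2) - 2
  empty <- combination_network(net$positive_pairs[0, ], drugs = net$drugs)
  expect_length(split_by_label(S, empty)$pos, 0)
})

test_that("Welch t-test matches the textbook computation on a fixed toy", {
  pos <- c(0.52, 0.61, 0.48, 0.55, 0.66)
  neg <- c(0.31, 0.42, 0.29, 0.38, 0.33)
  # hand-rolled Welch: t, Welch-Satterthwaite df, two-sided p
  s1 <- var(pos) / 5; s2 <- var(neg) / 5
  tstat <- (mean(pos) - mean(neg)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / 4 + s2^2 / 4)
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(ttest_pvalue(pos, neg), p_hand, tolerance = 1e-12)

  expect_equal(ttest_pvalue(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  set.seed(1)
  expect_lt(ttest_pvalue(rnorm(100, 1, 0.01), rnorm(100, 0, 0.01)), 1e-10)
  expect_error(ttest_pvalue(1, c(1, 2)), ">= 2")
})

test_that("signed KS statistic: sign convention, extremes, antisymmetry", {
  expect_equal(kstest_signed(c(0.1, 0.2), c(0.1, 0.2))$d, 0)
  expect_equal(kstest_signed(c(0.8, 0.9), c(0.1, 0.2))$d, 1)   # pos larger
  expect_equal(kstest_signed(c(0.1, 0.2), c(0.8, 0.9))$d, -1)  # flipped
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(20); b <- runif(15) + 0.1
    ks <- kstest_signed(a, b)
    expect_equal(abs(ks$d), brute_ks_stat(a, b))
    expect_equal(kstest_signed(b, a)$d, -ks$d)
    # |d| agrees with the classical statistic
    expect_equal(abs(ks$d),
                 unname(suppressWarnings(ks.test(a, b)$statistic)))
  }
  expect_error(kstest_signed(numeric(0), 1), "nonempty")
})

test_that("forest importance finds a planted signal and is seed-stable", {
  set.seed(10)
  n <- 600
  x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
  y <- as.integer(x1 > 0.5)
  ds <- pair_dataset(data.frame(drug_a = sprintf("a%d", 1:n),
                                drug_b = sprintf("b%d", 1:n), label = y),
                     cbind(c1 = x1, c2 = x2, c3 = x3), c("c1", "c2", "c3"))
  imp <- rf_importance(ds, seed = 4, ntree = 100)
  expect_identical(names(which.max(imp)), "c1")
  expect_true(all(imp >= 0))
  expect_identical(rf_importance(ds, seed = 4, ntree = 100), imp)
  expect_false(identical(rf_importance(ds, seed = 5, ntree = 100), imp))
  expect_error(rf_importance(ds[ds$label == 1, ]), "both classes")
})

test_that("planted two-channel signals of unequal strength rank correctly", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 2000
    x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
    logit <- 3.0 * (x1 - 0.5) + 1.0 * (x2 - 0.5)
    y <- as.integer(runif(n) < plogis(4 * logit))
    ds <- pair_dataset(data.frame(drug_a = sprintf("a%d", 1:n),
                                  drug_b = sprintf("b%d", 1:n), label = y),
                       cbind(c1 = x1, c2 = x2, c3 = x3),
                       c("c1", "c2", "c3"))
    imp <- rf_importance(ds, seed = seed, ntree = 150)
    if (imp["c1"] > imp["c2"] && imp["c2"] > imp["c3"]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("minmax_normalize maps to [0,1], preserves order, is idempotent", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)  # attained bounds: unchanged
  expect_error(minmax_normalize(c(5, 5, 5)), "equal")
  expect_error(minmax_normalize(3), ">= 2")
  set.seed(2)
  v <- rnorm(20)
  nv <- minmax_normalize(v)
  expect_identical(order(nv), order(v))
  expect_equal(minmax_normalize(nv), nv)
})

test_that("selection keeps significant channels plus the marginal band", {
  a <- data.frame(channel = c("target", "indication", "structure",
                              "expression", "module"),
                  t_p = c(1e-17, 1e-17, 0.012, 0.1, 0.4))
  expect_identical(select_channels(a, alpha = 0.05, marginal = 0.1),
                   c("target", "indication", "structure", "expression"))
  expect_identical(select_channels(a, alpha = 1, marginal = 0),
                   a$channel)  # everything below alpha = 1
  a$t_p <- rep(1, 5)
  expect_error(select_channels(a), "manually")
})

test_that("assess_features records coherent statistics on a planted world", {
  w <- generate_world(generator_config(n_drugs = 60, seed = 21))
  a <- assess_features(w$matrices, w$network, seed = 3, ntree = 100)
  expect_setequal(a$channel, names(w$matrices))
  expect_true(all(a$ks_d >= -1 & a$ks_d <= 1))
  # normalized importance attains 0 and 1
  expect_equal(min(a$gini_norm), 0)
  expect_equal(max(a$gini_norm), 1)
  # informative channels dominate noise in every statistic
  inf <- a$channel %in% c("channel1", "channel2")
  expect_true(max(a$t_p[inf]) < min(a$t_p[!inf]))
  expect_true(min(a$ks_d[inf]) > max(a$ks_d[!inf]))
  expect_true(min(a$gini[inf]) > max(a$gini[!inf]))
  # selection is a pure function of recorded statistics
  expect_identical(a$selected,
                   a$t_p < attr(a, "alpha") | a$t_p <= attr(a, "marginal"))
})
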