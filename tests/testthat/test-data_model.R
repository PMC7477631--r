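# Domain types and file formats.

test_that("drug_set enforces uniqueness, size and fixed order", {
  expect_error(drug_set("A"), "at least 2")
  expect_error(drug_set(c("A", "B", "A")), "duplicate")
  ds <- drug_set(c("B", "A", "C"))
  expect_identical(as.character(ds), c("B", "A", "C"))  # order preserved
})

test_that("combination_network canonicalizes unordered pairs", {
  net <- combination_network(data.frame(a = c("A", "B", "A"),
                                        b = c("B", "A", "C")))
  expect_equal(nrow(net$positive_pairs), 2)  # "A B" == "B A"
  expect_true(all(net$adjacency == t(net$adjacency)))
  expect_true(all(diag(net$adjacency) == 0))
  expect_error(combination_network(data.frame(a = "A", b = "A")),
               "self-pair")
  expect_error(
    combination_network(data.frame(a = "A", b = "Z"),
                        drugs = drug_set(c("A", "B"))),
    "Z")
})

test_that("read_pair_list dedups, infers drugs, rejects self-pairs by line", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tC"))
  net <- read_pair_list(f)
  expect_equal(nrow(net$positive_pairs), 2)
  expect_identical(as.character(net$drugs), c("A", "B", "C"))

  f2 <- withr::local_tempfile(lines = "A\tA")
  expect_error(read_pair_list(f2), "line 1")

  f3 <- withr::local_tempfile(lines = c("drug1\tdrug2", "A\tB"))
  expect_equal(nrow(read_pair_list(f3)$positive_pairs), 1)

  f4 <- withr::local_tempfile(lines = "A\tB")
  expect_error(read_pair_list(f4, drugs = drug_set(c("A", "C"))), "B")
})

test_that("read_profile handles long and GMT-like layouts with set semantics", {
  f <- withr::local_tempfile(lines = c("D1\tt1", "D1\tt2", "D2\tt1"))
  p <- suppressMessages(read_profile(f, "target"))
  expect_identical(p$members$D1, c("t1", "t2"))
  expect_identical(p$members$D2, "t1")

  g <- withr::local_tempfile(lines = c("D1\tt1\tt2", "D2\tt3", "D3"))
  p2 <- suppressMessages(read_profile(g, "target"))
  expect_identical(p2$members$D1, c("t1", "t2"))
  expect_identical(p2$members$D3, character(0))  # recorded emptiness

  d <- withr::local_tempfile(lines = c("D1\tt1", "D1\tt1", "D2\tt2", "D2\tt3"))
  expect_warning(p3 <- suppressMessages(read_profile(d, "x")), "duplicate")
  expect_identical(p3$members$D1, "t1")

  e <- withr::local_tempfile(lines = character(0))
  expect_error(suppressMessages(read_profile(e, "x")), "empty")
})

test_that("read_similarity_matrix scales, validates and symmetrizes", {
  write_m <- function(m) {
    f <- withr::local_tempfile(.local_envir = parent.frame())
    writeLines(c(paste(c("drug", colnames(m)), collapse = "\t"),
                 paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                       sep = "\t")), f)
    f
  }
  m <- matrix(c(100, 25, 25, 100), 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  s <- read_similarity_matrix(write_m(m), scale = "percent")
  expect_equal(s["A", "B"], 0.25)

  id <- diag(3); dimnames(id) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unclass(read_similarity_matrix(write_m(id)))[, ],
               id, ignore_attr = TRUE)

  bad <- matrix(c(100, 101, 101, 100), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(read_similarity_matrix(write_m(bad), scale = "percent"),
               "out of \\[0,1\\]")

  asym <- matrix(c(1, 0.2, 0.4, 1), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(similarity_matrix(asym), "asymmetry")
  expect_error(similarity_matrix(matrix(0.5, 2, 3)), "square")
  d0 <- matrix(c(0.5, 0.2, 0.2, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(sm <- similarity_matrix(d0), "diagonal")
  expect_equal(diag(unclass(sm)), c(A = 1, B = 1))
})

test_that("readers and writers round-trip all three formats", {
  w <- generate_world(generator_config(n_drugs = 12, seed = 5))
  dir <- withr::local_tempdir()

  mp <- file.path(dir, "m.tsv")
  write_similarity_matrix(w$matrices[[1]], mp)
  back <- read_similarity_matrix(mp)
  expect_lt(max(abs(unclass(back) - unclass(w$matrices[[1]]))), 1e-9)

  pp <- file.path(dir, "p.tsv")
  write_profile(w$profiles[[1]], pp)
  backp <- suppressMessages(read_profile(pp, w$profiles[[1]]$channel))
  expect_identical(backp$members, w$profiles[[1]]$members)

  lp <- file.path(dir, "l.tsv")
  write_pair_list(w$network, lp)
  backn <- read_pair_list(lp, drugs = w$drugs)
  expect_identical(backn$adjacency, w$network$adjacency)
})

test_that("networks and matrices are symmetric regardless of input order", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("d%d", 1:8)
    pr <- data.frame(a = sample(ids, 10, TRUE), b = sample(ids, 10, TRUE))
    pr <- pr[pr$a != pr$b, ]
    net <- combination_network(pr)
    expect_identical(net$adjacency, t(net$adjacency))
    S <- rand_similarity(8, seed)
    expect_identical(unclass(S), t(unclass(S)))
  }
})

test_that("write_report renders mean ± sd rows and round-trips", {
  summ <- data.frame(model = "svm", k = 5,
                     metric = c("recall", "precision", "f1", "auroc", "aupr"),
                     mean = c(0.684, 0.770, 0.724, 0.795, 0.785),
                     sd = c(0.005, 0.009, 0.006, 0.006, 0.010))
  f <- withr::local_tempfile()
  write_report(summ, f)
  back <- read_report(f)
  expect_equal(nrow(back), 5)  # one row per metric for one (model, k)
  expect_identical(back$cell[back$metric == "auroc"], "0.795 ± 0.006")
  expect_equal(back$mean, summ$mean)
  expect_equal(back$sd, summ$sd)

  f2 <- withr::local_tempfile()
  write_report(summ[0, ], f2)
  expect_equal(nrow(read_report(f2)), 0)  # header-only
})

test_that("run_config validates fields and is hashed deterministically", {
  expect_error(run_config(k = 1), "k")
  expect_error(run_config(ratio = 0), "ratio")
  expect_error(run_config(threshold = 1), "threshold")
  c1 <- run_config(seed = 7)
  expect_identical(nrmstack:::config_hash(c1),
                   nrmstack:::config_hash(run_config(seed = 7)))
  expect_false(identical(nrmstack:::config_hash(c1),
                         nrmstack:::config_hash(run_config(seed = 8))))
})

test_that("pair_dataset rejects self-pairs, duplicates and bad features", {
  p <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "C"),
                  label = c(1, 0))
  expect_s3_class(pair_dataset(p, matrix(0.5, 2, 2), c("c1", "c2")),
                  "pair_dataset")
  expect_error(pair_dataset(data.frame(drug_a = "A", drug_b = "A", label = 1),
                            matrix(0.5, 1, 1), "c1"), "self")
  dup <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "A"),
                    label = c(1, 0))
  expect_error(pair_dataset(dup, matrix(0.5, 2, 1), "c1"), "duplicate")
  expect_error(pair_dataset(p, matrix(1.5, 2, 1), "c1"), "\\[0,1\\]")
})
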