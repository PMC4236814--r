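test_that("discriminant fit separates classes and matches MASS::lda", {
  # complete separation on one SNP
  X <- matrix(c(rep(0, 6), rep(2, 6)), ncol = 1,
              dimnames = list(NULL, "s1"))
  lab <- rep(c("A", "B"), each = 6)
  f <- suppressWarnings(fda_fit(X, lab))
  expect_equal(f$accuracy, 1.0)
  # identical class distributions: accuracy near the majority rate
  set.seed(23)
  Xn <- matrix(rbinom(40, 2, 0.5), ncol = 1)
  labs <- rep(c("A", "B"), each = 20)
  fn <- fda_fit(Xn, labs)
  expect_lte(fn$accuracy, 0.8)
  # agreement with the reference implementation on its predictions
  set.seed(24)
  Xm <- cbind(s1 = rbinom(60, 2, c(0.2, 0.7)[rep(1:2, each = 30)]),
              s2 = rbinom(60, 2, 0.5),
              s3 = rbinom(60, 2, c(0.3, 0.6)[rep(1:2, each = 30)]))
  labm <- rep(c("A", "B"), each = 30)
  fm <- fda_fit(Xm, labm)
  ref <- MASS::lda(Xm, grouping = labm)
  expect_equal(as.character(fm$predictions),
               as.character(predict(ref, as.data.frame(Xm))$class))
  expect_error(fda_fit(Xm, rep("A", 60)), "2 classes")
})

test_that("null-genotype discriminant accuracy stays near chance", {
  set.seed(25)
  acc <- replicate(200, {
    X <- matrix(rbinom(90, 2, 0.5), ncol = 1)
    fda_fit(X, sample(rep(c("A", "B"), each = 45)))$accuracy
  })
  # 99th percentile of the null training accuracy on one null SNP
  expect_lte(quantile(acc, 0.99), 0.67)
})

test_that("sum-of-squares ratio matches hand computations", {
  expect_equal(sums_of_squares_ratio(c(0, 0, 0, 2, 2, 2),
                                     rep(c("A", "B"), each = 3)), 0)
  expect_equal(sums_of_squares_ratio(c(0, 1, 1, 2),
                                     rep(c("A", "B"), each = 2)), 1.0)
  expect_equal(sums_of_squares_ratio(c(0, 2, 0, 2),
                                     rep(c("A", "B"), each = 2)), Inf)
})

test_that("forward selection is greedy with the documented tie-breaks", {
  set.seed(26)
  n <- 40
  lab <- rep(c("A", "B"), each = n / 2)
  sep <- c(rep(0, n / 2), rep(2, n / 2))               # perfect separator
  noise <- rbinom(n, 2, 0.5)
  X <- cbind(zz_sep = sep, aa_noise = noise)
  fs <- suppressWarnings(forward_select(X, lab))
  expect_equal(fs$panel, "zz_sep")
  expect_equal(tail(fs$trace, 1), 1.0)
  # trace is non-decreasing by construction
  expect_true(all(diff(fs$trace) >= 0))
  # tie on accuracy -> smaller SS ratio wins; both candidates misclassify
  # exactly 4 of 40 but differ in within-class spread
  x_loose <- c(rep(0, 18), rep(2, 2), rep(2, 18), rep(0, 2))
  x_tight <- c(rep(0, 17), rep(1, 2), 2, rep(2, 17), rep(1, 2), 0)
  acc_tight <- fda_fit(cbind(x_tight), lab)$accuracy
  acc_loose <- fda_fit(cbind(x_loose), lab)$accuracy
  expect_equal(acc_tight, acc_loose)                   # constructed tie
  expect_lt(sums_of_squares_ratio(x_tight, lab),
            sums_of_squares_ratio(x_loose, lab))
  Xt <- cbind(loose = x_loose, tight = x_tight)
  fs_t <- suppressWarnings(forward_select(Xt, lab))
  expect_equal(fs_t$panel[1], "tight")
  # residual tie -> lexicographic order
  Xl <- cbind(bbb = x_tight, aaa = x_tight)
  fs_l <- suppressWarnings(forward_select(Xl, lab))
  expect_equal(fs_l$panel[1], "aaa")
  # a sub-threshold best increment halts without adding
  Xn <- matrix(rbinom(n, 2, 0.5), ncol = 1,
               dimnames = list(NULL, "flat"))
  Xn[, 1] <- rep(c(0, 1, 2, 1), each = 10)             # symmetric in classes
  fs_n <- forward_select(Xn, lab)
  if (length(fs_n$panel) == 0) expect_length(fs_n$trace, 0)
})

test_that("nested cross-validation picks the best fold-model, reproducibly", {
  set.seed(27)
  n <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  # fully separable populations
  Xsep <- cbind(s1 = c(rep(0, n / 2), rep(2, n / 2)),
                s2 = rbinom(n, 2, 0.5))
  res <- suppressWarnings(nested_cv_classify(Xsep, lab, k = 10, seed = 3))
  expect_equal(res$test_accuracy, 1.0)
  expect_true("s1" %in% res$panel)
  expect_equal(res$fold_results$test_accuracy[res$chosen_fold],
               max(res$fold_results$test_accuracy))
  # determinism
  res2 <- suppressWarnings(nested_cv_classify(Xsep, lab, k = 10, seed = 3))
  expect_identical(res$panel, res2$panel)
  expect_identical(res$fold_results, res2$fold_results)
  # labels independent of genotypes: the best-of-10-folds accuracy is
  # noisy on 9-sample test folds, so the null bound is asserted on the
  # median over replicates
  set.seed(28)
  accs <- replicate(11, {
    Xnull <- matrix(rbinom(90 * 100, 2, 0.5), 90, 100,
                    dimnames = list(NULL, sprintf("n%03d", 1:100)))
    labn <- sample(rep(c("A", "B"), each = 45))
    suppressWarnings(nested_cv_classify(Xnull, labn, k = 10,
                                        seed = 4))$test_accuracy
  })
  expect_lte(median(accs), 0.80)
})

test_that("candidate set algebra mirrors the union/intersection/specific rules", {
  sets <- list(CHB = c("s1", "s2", "s3"), JPT = c("s2", "s3", "s4"))
  expect_equal(eqtl_candidate_set(sets, "union"), c("s1", "s2", "s3", "s4"))
  expect_equal(eqtl_candidate_set(sets, "intersection"), c("s2", "s3"))
  expect_equal(eqtl_candidate_set(sets, "specific"), c("s1", "s4"))
})
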