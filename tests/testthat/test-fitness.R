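test_that("stratified folds preserve class proportions to within one", {
  labels <- rep(c(0L, 1L), each = 40)
  folds <- make_stratified_folds(labels, 5, fold_seed = 2)
  for (f in folds) {
    expect_length(f, 16)
    expect_equal(sum(labels[f] == 0), 8)
    expect_equal(sum(labels[f] == 1), 8)
  }

  labels2 <- c(rep(0L, 14), rep(1L, 7))
  folds2 <- make_stratified_folds(labels2, 7, fold_seed = 1)
  for (f in folds2) {
    expect_equal(sum(labels2[f] == 0), 2)
    expect_equal(sum(labels2[f] == 1), 1)
  }

  # partition: disjoint, covering all indices; deterministic under the seed
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))
  expect_identical(folds, make_stratified_folds(labels, 5, fold_seed = 2))
  expect_false(identical(folds, make_stratified_folds(labels, 5, fold_seed = 3)))

  expect_error(make_stratified_folds(c(0, 0, 0, 1), 3), "fewer than k")
})

test_that("feature tables have one row per sample in order", {
  ds <- generate_dataset(synth_config(n_per_class = 3, seed = 8))
  samples <- preprocess_samples(ds$train)
  bank <- bank_fixture("median")
  tab <- build_feature_table(samples, bank)
  expect_equal(dim(tab), c(length(samples), 10))  # id + 8 features + label
  expect_identical(names(tab)[2:9],
                   paste0(rep(c("mu", "sigma"), 4), rep(1:4, each = 2)))
  for (i in seq_along(samples)) {
    expect_equal(unlist(tab[i, 2:9]),
                 extract_features(samples[[i]]$image, bank),
                 ignore_attr = TRUE)
  }
  # identical images give identical rows
  twin <- list(samples[[1]], samples[[1]])
  ttab <- suppressWarnings(build_feature_table(twin, bank))
  expect_equal(ttab[1, 2:9], ttab[2, 2:9], ignore_attr = TRUE)
  expect_warning(build_feature_table(twin, bank), "single class")
})

test_that("cross-validated error is zero for separated clouds and the
           majority error for identical features", {
  sep <- separable_table(n_per_class = 20)
  rec <- evaluate_error(sep, cv_config(folds = 5, fold_seed = 1))
  expect_equal(rec$error, 0)
  expect_equal(rec$fold_accuracies, rep(1, 5))

  # identical feature vectors: the SVM degenerates to a majority vote,
  # so with a 60/40 split each stratified fold scores 0.6
  flat <- data.frame(id = as.character(1:50), f1 = 0, f2 = 0,
                     label = c(rep(0L, 30), rep(1L, 20)))
  rec2 <- evaluate_error(flat, cv_config(folds = 5, fold_seed = 3))
  expect_equal(rec2$error, 0.4)
  expect_equal(rec2$fold_accuracies, rep(0.6, 5))

  expect_true(rec2$error >= 0 && rec2$error <= 1)
  expect_identical(rec2, evaluate_error(flat, cv_config(folds = 5,
                                                        fold_seed = 3)))
})

test_that("error is invariant to row order under a fixed partition", {
  tab <- separable_table(n_per_class = 10, gap = 2, sd = 1, seed = 4)
  cv <- cv_config(folds = 5, fold_seed = 6)
  folds <- make_stratified_folds(tab$label, 5, 6)
  e1 <- evaluate_error(tab, cv, folds)$error

  set.seed(9)
  perm <- sample.int(nrow(tab))
  tabp <- tab[perm, ]
  foldsp <- lapply(folds, function(f) match(f, perm))
  e2 <- evaluate_error(tabp, cv, foldsp)$error
  expect_equal(e1, e2)
})

test_that("degenerate folds are reported with their index", {
  tab <- data.frame(id = as.character(1:12), f1 = rnorm(12),
                    label = c(rep(0L, 9), rep(1L, 3)))
  # positives spread across folds: every training split keeps both classes
  folds <- list(c(1:3, 10), c(4:6, 11), c(7:9, 12))
  expect_silent(evaluate_error(tab, cv_config(folds = 3), folds))
  # a fold holding every positive leaves its training split single-class
  folds_bad <- list(10:12, 1:5, 6:9)
  expect_error(evaluate_error(tab, cv_config(folds = 3), folds_bad),
               "degenerate fold 1")
})

test_that("the optimizer fitness closure reuses one partition", {
  ds <- generate_dataset(synth_config(n_per_class = 5, seed = 21))
  samples <- preprocess_samples(ds$train)
  cv <- cv_config(folds = 2, fold_seed = 13)
  fitness <- make_cv_fitness(samples, cv)
  v <- encode_bank(gabor_bank(gabor_params(7, 2, 1.4, 6, 0.5, 0)))

  labels <- vapply(samples, `[[`, integer(1), "label")
  folds <- make_stratified_folds(labels, 2, 13)
  tab <- build_feature_table(samples, decode_vector(v))
  expect_equal(fitness(v), evaluate_error(tab, cv, folds)$error)
  expect_equal(fitness(v), fitness(v))
})

test_that("a constant-response bank scores exactly the majority-vote error", {
  # odd windows with zero phase give zero-sum kernels, so on any images the
  # responses collapse and every sample gets an identical feature vector
  ds <- generate_dataset(synth_config(n_per_class = 10, noise_sd = 0,
                                      seed = 33))
  samples <- preprocess_samples(ds$train)
  # unbalance the classes: drop half the positives
  pos <- which(vapply(samples, `[[`, integer(1), "label") == 1L)
  samples <- samples[-pos[1:4]]
  labels <- vapply(samples, `[[`, integer(1), "label")
  const_imgs <- lapply(samples, function(s) {
    s$image <- matrix(128, 16, 16); s
  })
  bank <- gabor_bank(gabor_params(9, 3, 0.7, 5, 0.5, 0))
  tab <- build_feature_table(const_imgs, bank)
  expect_true(all(abs(unlist(tab[, 2:3])) < 1e-9))
  cv <- cv_config(folds = 2, fold_seed = 5)
  rec <- evaluate_error(tab, cv)
  folds <- make_stratified_folds(labels, 2, 5)
  maj_err <- mean(vapply(folds, function(f) {
    mean(labels[f] != 0)  # majority class is 0 in every training split
  }, numeric(1)))
  expect_equal(rec$error, maj_err)
})
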