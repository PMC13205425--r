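# Wrapper fitness: a candidate bank is scored by the stratified K-fold
# cross-validated error of a linear SVM on its feature table. Folds are built
# once per run (per fold_seed) and reused for every candidate so that all
# candidates are compared on identical partitions.

#' Cross-validation / SVM configuration
#'
#' Defaults follow the study protocol: stratified 5-fold cross-validation and
#' a linear-kernel SVM with regularization `C = 1`. Features are z-scored
#' with statistics fitted on the training folds only; raw Gabor means can
#' reach hundreds while phase-related features stay near zero, and a `C = 1`
#' linear SVM is scale-sensitive.
#'
#' @param folds number of folds `K`.
#' @param svm_cost SVM regularization parameter `C`.
#' @param standardize z-score features on training statistics.
#' @param fold_seed seed for the fold partition.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(folds = 5L, svm_cost = 1, standardize = TRUE,
                      fold_seed = 1L) {
  stopifnot(folds >= 2L, svm_cost > 0)
  structure(list(folds = as.integer(folds), svm_cost = svm_cost,
                 standardize = isTRUE(standardize),
                 fold_seed = as.integer(fold_seed)),
            class = "cv_config")
}

#' Build the feature table of a sample set under a bank
#'
#' One row per sample, in input order: `id`, the `2 * Nf` Gabor features, and
#' `label`.
#'
#' @param samples list of samples (`image`, `label`, optional `id`).
#' @param bank a `gabor_bank`.
#' @return data frame with feature columns `mu1, sigma1, ...`.
#' @export
build_feature_table <- function(samples, bank) {
  stopifnot(length(samples) >= 1L)
  feats <- t(vapply(samples, function(s) extract_features(s$image, bank),
                    numeric(2L * length(bank$filters))))
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  ids <- vapply(samples, function(s) as.character(s$id %||% NA_character_),
                character(1))
  if (length(unique(labels)) < 2L) {
    warning("feature table contains a single class; CV error is undefined")
  }
  cbind(data.frame(id = ids, stringsAsFactors = FALSE),
        as.data.frame(feats),
        data.frame(label = labels))
}

#' Stratified K-fold partition
#'
#' Shuffles indices within each class (seeded) and deals them round-robin
#' across folds, so per-fold class counts differ from perfect
#' proportionality by at most one.
#'
#' @param labels vector of 0/1 class labels.
#' @param k number of folds.
#' @param fold_seed RNG seed for the shuffle.
#' @return list of `k` disjoint integer index vectors covering all samples.
#' @export
make_stratified_folds <- function(labels, k, fold_seed = 1L) {
  stopifnot(k >= 2L)
  set.seed(fold_seed)
  folds <- vector("list", k)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has ", length(idx),
           " members, fewer than k = ", k)
    }
    idx <- idx[sample.int(length(idx))]
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

# z-score statistics from training rows; zero-variance features get scale 1
standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(m) sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/"))
}

feature_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), c("id", "label")), drop = FALSE])
}

fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)), kernel = "linear",
             cost = cost, scale = FALSE)
}

#' Cross-validated SVM error of a feature table
#'
#' For each fold, fits a linear SVM on the remaining folds (standardization
#' statistics fitted on those training folds only) and scores accuracy on the
#' held-out fold. The fitness is the complement of the mean fold accuracy,
#' `E = 1 - mean(Acc_k)`.
#'
#' @param table feature table from [build_feature_table()].
#' @param cv a `cv_config`.
#' @param folds optional precomputed fold partition (so an optimizer can
#'   reuse one partition across candidates); built from `cv$fold_seed`
#'   otherwise.
#' @return object of class `fitness_record`: `error` and `fold_accuracies`.
#' @export
evaluate_error <- function(table, cv = cv_config(), folds = NULL) {
  x <- feature_matrix(table)
  y <- table$label
  if (is.null(folds)) folds <- make_stratified_folds(y, cv$folds, cv$fold_seed)
  acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    if (length(unique(y[train_idx])) < 2L) {
      stop("degenerate fold ", f, ": training split contains one class only")
    }
    xtr <- x[train_idx, , drop = FALSE]
    xte <- x[test_idx, , drop = FALSE]
    if (cv$standardize) {
      z <- standardizer(xtr)
      xtr <- z$apply(xtr)
      xte <- z$apply(xte)
    }
    fit <- fit_linear_svm(xtr, y[train_idx], cv$svm_cost)
    pred <- as.integer(as.character(predict(fit, xte)))
    acc[f] <- mean(pred == y[test_idx])
  }
  structure(list(error = 1 - mean(acc), fold_accuracies = acc),
            class = "fitness_record")
}

#' Fitness closure for the optimizer
#'
#' Precomputes the stratified fold partition once (from `cv$fold_seed`) and
#' returns a function mapping a decision vector to its cross-validated error,
#' evaluating every candidate on the same partition.
#'
#' @param samples preprocessed labeled samples.
#' @param cv a `cv_config`.
#' @return function: numeric decision vector -> error in `[0, 1]`.
#' @export
make_cv_fitness <- function(samples, cv = cv_config()) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  folds <- make_stratified_folds(labels, cv$folds, cv$fold_seed)
  force(samples)
  function(v) {
    bank <- decode_vector(v)
    table <- build_feature_table(samples, bank)
    evaluate_error(table, cv, folds)$error
  }
}

#' Train on one table, evaluate on another
#'
#' The second-stage path: a single linear SVM fit on the full training table
#' (no cross-validation), evaluated on a held-out table. Standardization
#' statistics come from the training table only.
#'
#' @param train_table,test_table feature tables with identical feature
#'   columns.
#' @param svm_cost SVM regularization parameter.
#' @param standardize z-score on training statistics.
#' @return list with `predictions` (0/1 vector for the test rows), `counts`
#'   (a `confusion_counts`), `metrics` (a `metrics_report`), and `collapse`
#'   (`TRUE` when all predictions are one class).
#' @export
train_and_evaluate <- function(train_table, test_table, svm_cost = 1,
                               standardize = TRUE) {
  xtr <- feature_matrix(train_table)
  xte <- feature_matrix(test_table)
  if (ncol(xtr) != ncol(xte)) {
    stop("feature-length mismatch: train has ", ncol(xtr),
         " columns, test has ", ncol(xte))
  }
  if (standardize) {
    z <- standardizer(xtr)
    xtr <- z$apply(xtr)
    xte <- z$apply(xte)
  }
  fit <- fit_linear_svm(xtr, train_table$label, svm_cost)
  pred <- as.integer(as.character(predict(fit, xte)))
  counts <- confusion_counts(test_table$label, pred)
  list(predictions = pred,
       counts = counts,
       metrics = compute_metrics(counts),
       collapse = length(unique(pred)) == 1L)
}
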