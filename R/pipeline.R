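# The two-stage experimental protocol. Stage 1 runs repeated, independently
# seeded DE optimizations on the training set only and selects the best,
# median and worst runs by final cross-validated error. Stage 2 refits a
# single linear SVM on the whole training set with a chosen descriptor and
# reports held-out metrics. The test set is never touched in stage 1.

#' Stage 1: repeated DE optimization on the training set
#'
#' Runs `n_runs` independent optimizations with run seeds
#' `base_seed + 1, ..., base_seed + n_runs`. Each run uses its own seed both
#' for the DE stream and for the fold partition (folds are fixed within a
#' run, differ across runs). Returns all runs, descriptive statistics of the
#' final fitnesses, and the best/median/worst representative runs.
#'
#' @param train_samples preprocessed labeled samples (training set only).
#' @param de a `de_config` (its `seed` field is overridden per run).
#' @param cv a `cv_config` (its `fold_seed` is overridden per run).
#' @param n_runs number of independent runs.
#' @param base_seed base of the per-run seed sequence.
#' @param verbose print one line per completed run.
#' @return object of class `stage1_result`: `runs`, `summary` (from
#'   [summarize_runs()]), `representatives` (from [pick_representatives()]).
#' @export
run_stage1 <- function(train_samples, de = de_config(), cv = cv_config(),
                       n_runs = 31L, base_seed = 0L, verbose = FALSE) {
  stopifnot(n_runs >= 1L)
  labels <- vapply(train_samples, function(s) as.integer(s$label), integer(1))
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < cv$folds)) {
    stop("each class needs at least ", cv$folds,
         " training samples for stratified CV; have ",
         paste(counts, collapse = "/"))
  }
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    seed_i <- base_seed + i
    de_i <- de; de_i$seed <- as.integer(seed_i)
    cv_i <- cv; cv_i$fold_seed <- as.integer(seed_i)
    fitness <- make_cv_fitness(train_samples, cv_i)
    runs[[i]] <- run_de(fitness, de_i)
    if (verbose) {
      message(sprintf("run %d/%d (seed %d): best E = %.4f after %d generations",
                      i, n_runs, seed_i, runs[[i]]$best$fitness,
                      runs[[i]]$generations))
    }
  }
  structure(list(runs = runs,
                 summary = summarize_runs(
                   vapply(runs, function(r) r$best$fitness, numeric(1))),
                 representatives = pick_representatives(runs)),
            class = "stage1_result")
}

#' @export
print.stage1_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Stage 1: %d runs | final CV error min %.4f, median %.4f, mean %.4f, max %.4f, sd %.4f\n",
    s$n, s$min, s$median, s$mean, s$max, s$sd))
  invisible(x)
}

#' Stage 2: held-out evaluation of a descriptor
#'
#' Extracts features for the train and test sets with the given bank, fits a
#' single linear SVM on the full training table (no cross-validation), and
#' reports confusion-matrix metrics on the test set, including a collapse
#' flag when the model predicts a single class for every test sample.
#'
#' @param train_samples,test_samples preprocessed labeled samples.
#' @param bank a `gabor_bank` (e.g. a stage-1 representative's `best_bank`).
#' @param svm_cost SVM regularization parameter.
#' @param standardize z-score features on training statistics.
#' @return object of class `stage2_result`: `metrics`, `counts`,
#'   `predictions`, `collapse`.
#' @export
run_stage2 <- function(train_samples, test_samples, bank, svm_cost = 1,
                       standardize = TRUE) {
  train_table <- build_feature_table(train_samples, bank)
  test_table <- build_feature_table(test_samples, bank)
  res <- train_and_evaluate(train_table, test_table, svm_cost, standardize)
  structure(res, class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  print(x$metrics)
  if (x$collapse) cat("WARNING: constant predictions (model collapse)\n")
  invisible(x)
}

#' Save / load an optimized descriptor
#'
#' A descriptor file is the JSON bank serialization of [write_bank()] with
#' provenance metadata (run seed, final fitness, termination reason).
#' Loading revalidates all parameter domains.
#'
#' @param run a `de_result` (or a `gabor_bank`, saved without fitness
#'   provenance).
#' @param path file path.
#' @return `load_descriptor` returns a `gabor_bank` with a `"metadata"`
#'   attribute.
#' @export
save_descriptor <- function(run, path) {
  if (inherits(run, "gabor_bank")) {
    return(write_bank(run, path))
  }
  stopifnot(inherits(run, "de_result"))
  write_bank(run$best_bank, path, metadata = list(
    seed = run$seed,
    fitness = run$best$fitness,
    generations = run$generations,
    termination_reason = run$termination_reason))
}

#' @rdname save_descriptor
#' @export
load_descriptor <- function(path) read_bank(path)

#' Batch feature extraction to a data frame / CSV
#'
#' Extracts the feature table of a sample set under a bank and optionally
#' writes it as CSV (columns `id`, `mu1`, `sigma1`, ..., `label`).
#'
#' @param samples preprocessed labeled samples.
#' @param bank a `gabor_bank`.
#' @param path optional CSV output path.
#' @return the feature table, invisibly when `path` is given.
#' @export
extract_feature_table <- function(samples, bank, path = NULL) {
  table <- build_feature_table(samples, bank)
  if (!is.null(path)) {
    write.csv(table, path, row.names = FALSE)
    return(invisible(table))
  }
  table
}
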