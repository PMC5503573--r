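# Confusion counts, percentage metrics, stratified k-fold CV and the
# end-to-end simulate -> screen -> tree -> evaluate pipeline.

#' Confusion counts for a two-class prediction
#'
#' The case class is the positive class: `tp` counts case samples predicted
#' case, `tn` control samples predicted control.
#'
#' @param truth,predicted Character vectors of `"case"`/`"control"` labels.
#' @return Named integer vector `(tp, fn, tn, fp)`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(tp = sum(truth == "case" & predicted == "case"),
    fn = sum(truth == "case" & predicted == "control"),
    tn = sum(truth == "control" & predicted == "control"),
    fp = sum(truth == "control" & predicted == "case"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Sensitivity is the probability that a case sample is predicted case,
#' specificity the probability that a control sample is predicted control,
#' accuracy the overall probability of a correct prediction.  All three are
#' percentages; the unrounded values are carried in the object and the
#' display convention is 2 decimals, halves rounding up.
#'
#' @param counts Named vector with elements `tp`, `fn`, `tn`, `fp` (e.g.
#'   from [confusion_counts()]); both classes must be represented.
#' @return Object of class `"class_metrics"`: list with unrounded
#'   `accuracy`, `sensitivity`, `specificity` (percent) and the `counts`.
#' @examples
#' compute_metrics(c(tp = 23, fn = 9, tn = 13, fp = 2))
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  tn <- counts[["tn"]]; fp <- counts[["fp"]]
  if (any(c(tp, fn, tn, fp) < 0)) ms_stop("counts must be nonnegative", "argument_error")
  if (tp + fn == 0 || tn + fp == 0) {
    ms_stop("metrics undefined: need at least one case and one control sample",
            "argument_error")
  }
  structure(list(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (tp %d, fn %d, tn %d, fp %d)\n",
              round_half_up(x$accuracy), round_half_up(x$sensitivity),
              round_half_up(x$specificity),
              x$counts[["tp"]], x$counts[["fn"]], x$counts[["tn"]],
              x$counts[["fp"]]))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Shuffles each group under the seed and deals samples into `k` folds
#' round-robin, so per-fold class counts differ by at most one; 55 case and
#' 50 control samples with `k = 5` give five folds of exactly 11 case + 10
#' control.
#'
#' @param groups Character vector of `"case"`/`"control"` labels.
#' @param k Number of folds; must not exceed the smaller group.
#' @param seed Integer seed.
#' @return Integer fold assignment in `1..k`, parallel to `groups`.
#' @export
stratified_kfold <- function(groups, k, seed = 1L) {
  stopifnot_scalar_count(k, "k", 1L)
  if (k > min(table(groups))) {
    ms_stop("k exceeds the size of the smaller group", "argument_error")
  }
  folds <- integer(length(groups))
  with_seed(seed, {
    for (g in unique(groups)) {
      idx <- sample_vec(which(groups == g))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the decision tree
#'
#' For each fold a tree is fitted on the remaining folds and evaluated on
#' the held-out fold.  The feature set (`ions`) is fixed in advance --
#' typically the candidates screened on the full training split -- so the
#' CV measures the stability of the tree given those features, mirroring
#' the screen-once protocol.  Set `nested = TRUE` to re-run the screening
#' cascade inside each training fold instead (honest generalisation
#' estimate; needs the full matrix).
#'
#' Both the population and the sample SD of the per-fold metrics are
#' computed; `sd_convention` picks which one `print` reports (sample is the
#' default).
#'
#' @param matrix Feature matrix (all ions; it is subset internally).
#' @param samples Sample table; only training-split rows enter the CV.
#' @param ions Candidate ion labels used as tree features (ignored when
#'   `nested = TRUE`).
#' @param tree_cfg A [tree_config()].
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param nested Re-screen inside each fold? Default `FALSE`.
#' @param screen_cfg [screen_config()] used when `nested = TRUE`.
#' @param sd_convention `"sample"` (default) or `"population"`.
#' @return Object of class `"cv_result"`: per-fold metrics, per-metric mean
#'   and both SDs, and the pooled out-of-fold confusion counts.
#' @export
cross_validate <- function(matrix, samples, ions, tree_cfg = tree_config(),
                           k = 5L, seed = 1L, nested = FALSE,
                           screen_cfg = screen_config(),
                           sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  tr <- samples[samples$split == "train", , drop = FALSE]
  folds <- stratified_kfold(tr$group, k, seed)
  per_fold <- vector("list", k)
  pooled <- c(tp = 0L, fn = 0L, tn = 0L, fp = 0L)
  for (f in seq_len(k)) {
    fit_samples <- tr[folds != f, , drop = FALSE]
    hold <- tr[folds == f, , drop = FALSE]
    feat <- if (nested) {
      sub_samples <- fit_samples
      scr <- screen_markers(matrix[sub_samples$sample_id, , drop = FALSE],
                            sub_samples, screen_cfg)
      candidates(scr)$ion
    } else ions
    if (!length(feat)) {
      ms_stop("no candidate ions available for tree fitting", "state_error")
    }
    tree <- c45(matrix[, feat, drop = FALSE], fit_samples, tree_cfg)
    pred <- predict(tree, matrix[hold$sample_id, feat, drop = FALSE])
    cnt <- confusion_counts(hold$group, pred)
    pooled <- pooled + cnt
    per_fold[[f]] <- compute_metrics(cnt)
  }
  metric_mat <- vapply(per_fold, function(m) {
    c(accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity)
  }, numeric(3))
  mean_v <- rowMeans(metric_mat)
  sd_sample <- apply(metric_mat, 1L, stats::sd)
  sd_population <- sqrt(rowMeans((metric_mat - mean_v)^2))
  structure(list(per_fold = per_fold, folds = folds, k = k,
                 mean = mean_v, sd_sample = sd_sample,
                 sd_population = sd_population,
                 sd_convention = sd_convention,
                 pooled_counts = pooled),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (SD convention: %s)\n",
              x$k, x$sd_convention))
  tab <- data.frame(
    fold = seq_len(x$k),
    accuracy = vapply(x$per_fold, function(m) round_half_up(m$accuracy), numeric(1)),
    sensitivity = vapply(x$per_fold, function(m) round_half_up(m$sensitivity), numeric(1)),
    specificity = vapply(x$per_fold, function(m) round_half_up(m$specificity), numeric(1))
  )
  print(tab, row.names = FALSE)
  sds <- if (x$sd_convention == "sample") x$sd_sample else x$sd_population
  cat(sprintf("mean: %.2f%% +/- %.2f | %.2f%% +/- %.2f | %.2f%% +/- %.2f\n",
              round_half_up(x$mean["accuracy"]), round_half_up(sds["accuracy"]),
              round_half_up(x$mean["sensitivity"]), round_half_up(sds["sensitivity"]),
              round_half_up(x$mean["specificity"]), round_half_up(sds["specificity"])))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration and seed for [run_pipeline()].
#'
#' @param cohort A [cohort_config()] for the simulated cohort (ignored when
#'   data are supplied to [run_pipeline()] directly).
#' @param n_case_train,n_control_train Training-split sizes per group.
#' @param screen A [screen_config()].
#' @param tree A [tree_config()].
#' @param cv_k CV folds (default 5).
#' @param split_seed,cv_seed Seeds for the train/test split and the fold
#'   assignment.
#' @param nested_cv Re-screen inside CV folds? Default `FALSE`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            n_case_train = 55L, n_control_train = 50L,
                            screen = screen_config(), tree = tree_config(),
                            cv_k = 5L, split_seed = 1L, cv_seed = 1L,
                            nested_cv = FALSE) {
  structure(list(cohort = cohort, n_case_train = as.integer(n_case_train),
                 n_control_train = as.integer(n_control_train),
                 screen = screen, tree = tree, cv_k = as.integer(cv_k),
                 split_seed = as.integer(split_seed),
                 cv_seed = as.integer(cv_seed),
                 nested_cv = isTRUE(nested_cv)),
            class = "pipeline_config")
}

#' Run the full marker-discovery and evaluation pipeline
#'
#' Simulate (or accept) a cohort, hold out a stratified test set, screen
#' candidate ions on the training split, cross-validate the decision tree
#' on the training split, fit the final tree on the whole training split
#' and evaluate it on the held-out test set.
#'
#' @param config A [pipeline_config()].
#' @param matrix,samples Optional observed data; when omitted, a cohort is
#'   simulated from `config$cohort` and split with
#'   `config$n_case_train`/`config$n_control_train`.
#' @return Object of class `"pipeline_report"` with elements `screen`
#'   (the `"marker_screen"` table), `candidates`, `cv` (`"cv_result"`),
#'   `tree` (`"c45"`), `test_metrics` (`"class_metrics"`), `truth` (when
#'   simulated) and `recovered` (planted markers among the candidates).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_config(n_ions = 500, seed = 7))
#' rep <- run_pipeline(cfg)
#' rep
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), matrix = NULL,
                         samples = NULL) {
  truth <- NULL
  if (is.null(matrix)) {
    cohort <- simulate_cohort(config$cohort)
    matrix <- cohort$matrix
    samples <- split_train_test(cohort$samples, config$n_case_train,
                                config$n_control_train,
                                seed = config$split_seed)
    truth <- cohort$truth
  }
  validate_feature_matrix(matrix)
  validate_sample_table(samples, matrix)

  scr <- screen_markers(matrix, samples, config$screen)
  cand <- candidates(scr)
  if (!nrow(cand)) {
    ms_stop("screening produced no candidate ions; nothing to model",
            "state_error")
  }
  cv <- cross_validate(matrix, samples, cand$ion, config$tree,
                       k = config$cv_k, seed = config$cv_seed,
                       nested = config$nested_cv,
                       screen_cfg = config$screen)
  tree <- c45(matrix[, cand$ion, drop = FALSE], samples, config$tree)
  te <- samples[samples$split == "test", , drop = FALSE]
  test_metrics <- NULL
  if (nrow(te)) {
    pred <- predict(tree, matrix[te$sample_id, cand$ion, drop = FALSE])
    test_metrics <- compute_metrics(confusion_counts(te$group, pred))
  }
  recovered <- if (!is.null(truth)) intersect(truth$ion, cand$ion) else NULL
  structure(list(screen = scr, candidates = cand, cv = cv, tree = tree,
                 test_metrics = test_metrics, truth = truth,
                 recovered = recovered, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Marker discovery pipeline report ==\n")
  print(x$screen)
  if (!is.null(x$truth) && nrow(x$truth)) {
    cat(sprintf("Planted markers recovered: %d of %d\n",
                length(x$recovered), nrow(x$truth)))
  }
  cat("\n")
  print(x$cv)
  cat("\nFinal tree (fitted on the full training split):\n")
  print(x$tree)
  if (!is.null(x$test_metrics)) {
    cat("\nIndependent test: ")
    print(x$test_metrics)
  }
  invisible(x)
}

#' Deterministic text rendering of a pipeline report
#'
#' Captures the printed report as a character vector; two runs under the
#' same configuration produce identical output, which makes end-to-end
#' determinism directly checkable.
#'
#' @param x A `"pipeline_report"`.
#' @param ... Unused.
#' @return Character vector of report lines.
#' @export
format.pipeline_report <- function(x, ...) {
  utils::capture.output(print(x))
}
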