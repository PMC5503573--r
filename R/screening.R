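#' Screening configuration
#'
#' Thresholds for the four-stage candidate-ion screening cascade:
#' \enumerate{
#'   \item detection: keep ions detected (nonzero) in strictly more than
#'     half of the training samples, pooled over both groups;
#'   \item fold change: fit a three-parameter Gaussian to the histogram of
#'     per-ion log10 fold changes and keep ions with positive log ratio
#'     lying more than `sd_multiplier` fitted SDs above the fitted mean
#'     (down-regulated ions are never kept);
#'   \item rank-sum: two-sided Wilcoxon rank-sum p-value below `alpha`;
#'   \item AUC: case-vs-control ROC area at least `auc_min`.
#' }
#'
#' @param sd_multiplier SD multiplier for the fold-change filter (default 1).
#' @param alpha Rank-sum significance level (default 0.05); no
#'   multiple-testing correction is applied, mirroring the screening design
#'   this cascade implements.
#' @param auc_min Minimum ROC AUC (default 0.7).
#' @param histogram_bins Number of equal-width histogram bins for the
#'   Gaussian fit (default 100).
#' @param zero_in_means If `TRUE` (default) group means in the fold change
#'   include non-detected (zero) intensities; set `FALSE` for a
#'   detected-only sensitivity analysis.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(sd_multiplier = 1, alpha = 0.05, auc_min = 0.7,
                          histogram_bins = 100L, zero_in_means = TRUE) {
  if (alpha <= 0 || alpha >= 1) ms_stop("alpha must lie in (0, 1)", "config_error")
  # auc_min above 1 is allowed so an impossible threshold can be expressed
  if (auc_min < 0.5) ms_stop("auc_min must be at least 0.5", "config_error")
  if (sd_multiplier <= 0) ms_stop("sd_multiplier must be positive", "config_error")
  stopifnot_scalar_count(histogram_bins, "histogram_bins", 5L)
  structure(list(sd_multiplier = sd_multiplier, alpha = alpha,
                 auc_min = auc_min, histogram_bins = as.integer(histogram_bins),
                 zero_in_means = isTRUE(zero_in_means)),
            class = "screen_config")
}

train_ids <- function(samples) samples$sample_id[samples$split == "train"]

#' Stage 1: detection filter
#'
#' Keeps ion `i` iff the number of training samples (both groups pooled)
#' with intensity strictly greater than zero exceeds half the training-set
#' size strictly: with 105 training samples an ion needs at least 53
#' detections.
#'
#' @param matrix Feature matrix.
#' @param samples Sample table.
#' @return Character vector of retained ion labels.
#' @export
detection_filter <- function(matrix, samples) {
  ids <- train_ids(samples)
  if (!length(ids)) ms_stop("training split is empty", "state_error")
  sub <- matrix[ids, , drop = FALSE]
  keep <- colSums(sub > 0) > nrow(sub) / 2
  colnames(sub)[keep]
}

#' Stage 2 statistic: per-ion fold change
#'
#' Fold change is the ratio of the training case-group mean intensity to the
#' training control-group mean; non-detected zeros are included in the means
#' (set `zero_in_means = FALSE` in the config for detected-only means).  The
#' log ratio is `log10(ratio)`.  Ions whose control mean is zero have no
#' defined ratio and are returned as `NA` with a warning.
#'
#' @param matrix Feature matrix (optionally restricted to stage-1 survivors).
#' @param samples Sample table.
#' @param zero_in_means Include zeros in group means?
#' @return data.frame with columns `ion`, `ratio`, `log_ratio`.
#' @export
fold_change <- function(matrix, samples, zero_in_means = TRUE) {
  tr <- samples[samples$split == "train", ]
  case <- matrix[tr$sample_id[tr$group == "case"], , drop = FALSE]
  ctrl <- matrix[tr$sample_id[tr$group == "control"], , drop = FALSE]
  gmean <- function(m) {
    if (zero_in_means) colMeans(m)
    else apply(m, 2L, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  }
  mc <- gmean(case)
  mh <- gmean(ctrl)
  ratio <- ifelse(mh > 0, mc / mh, NA_real_)
  if (anyNA(ratio)) {
    warning(sprintf("%d ion(s) excluded from fold-change: control mean is zero",
                    sum(is.na(ratio))), call. = FALSE)
  }
  data.frame(ion = colnames(matrix), ratio = ratio,
             log_ratio = log10(ratio), stringsAsFactors = FALSE)
}

#' Three-parameter Gaussian fit to a log-ratio histogram
#'
#' Bins the finite log ratios into `bins` equal-width bins over their range
#' and least-squares fits `A * exp(-(x - mu)^2 / (2 sigma^2))` to the
#' (bin-center, count) pairs, via Levenberg-Marquardt.  If the optimisation
#' fails (e.g. a degenerate histogram) the sample mean and SD of the log
#' ratios are returned with `fallback = TRUE` and a warning.
#'
#' @param log_ratios Numeric vector of log10 fold changes; at least 10
#'   finite values required.
#' @param bins Number of histogram bins.
#' @return List of class `"gaussian_fit"`: `amplitude` (count units),
#'   `mean`, `sd` (log10-ratio units, `sd > 0`), `fallback` flag.
#' @examples
#' fit <- fit_gaussian_log_ratios(rnorm(5000, 0.1, 0.4), bins = 60)
#' c(fit$mean, fit$sd)
#' @export
fit_gaussian_log_ratios <- function(log_ratios, bins = 100L) {
  x <- log_ratios[is.finite(log_ratios)]
  if (length(x) < 10L) {
    ms_stop("need at least 10 finite log ratios for the Gaussian fit",
            "argument_error")
  }
  stopifnot_scalar_count(bins, "bins", 2L)
  fallback <- function() {
    warning("Gaussian histogram fit failed; falling back to sample mean/SD",
            call. = FALSE)
    structure(list(amplitude = NA_real_, mean = mean(x),
                   sd = max(stats::sd(x), .Machine$double.eps),
                   fallback = TRUE),
              class = "gaussian_fit")
  }
  rng <- range(x)
  if (diff(rng) == 0) return(fallback())
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  fit_gaussian_curve(h$mids, h$counts, fallback)
}

# least-squares Gaussian A*exp(-(x-mu)^2/(2 s^2)) through (x, y) points;
# moment-based start values
fit_gaussian_curve <- function(xs, ys, fallback = NULL) {
  w <- ys / sum(ys)
  mu0 <- sum(w * xs)
  s0 <- sqrt(max(sum(w * (xs - mu0)^2), diff(range(xs))^2 / 1e6))
  a0 <- max(ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - m)^2 / (2 * s^2)),
      data = data.frame(x = xs, y = ys),
      start = list(A = a0, m = mu0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    if (is.null(fallback)) ms_stop("Gaussian curve fit failed", "state_error")
    return(fallback())
  }
  cf <- coef(fit)
  structure(list(amplitude = unname(abs(cf["A"])), mean = unname(cf["m"]),
                 sd = unname(abs(cf["s"])), fallback = FALSE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit%s: amplitude %.4g, mean %.4g, sd %.4g\n",
              if (x$fallback) " (moment fallback)" else "",
              x$amplitude, x$mean, x$sd))
  invisible(x)
}

#' Stage 2: fold-change filter
#'
#' Keeps an ion iff its log ratio is positive and lies more than
#' `sd_multiplier` fitted SDs above the fitted mean of the log-ratio
#' distribution.  Down-regulated ions (log ratio <= 0) are never kept: a
#' zero intensity cannot distinguish absence from missed detection, so only
#' up-regulation is trusted.
#'
#' @param stats data.frame from [fold_change()].
#' @param fit `"gaussian_fit"` for the log-ratio distribution.
#' @param sd_multiplier Number of SDs beyond the mean required.
#' @return Character vector of retained ion labels.
#' @export
fold_filter <- function(stats, fit, sd_multiplier = 1) {
  lr <- stats$log_ratio
  keep <- !is.na(lr) & lr > 0 & (lr - fit$mean) > sd_multiplier * fit$sd
  stats$ion[keep]
}

#' Stage 3 statistic: two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution when the pooled size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param case_values,control_values Numeric intensity vectors; both must be
#'   non-empty.
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
#' @export
rank_sum_test <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values)) {
    ms_stop("both groups must be non-empty", "argument_error")
  }
  ties <- anyDuplicated(c(case_values, control_values)) > 0L
  exact <- (length(case_values) + length(control_values) <= 12L) && !ties
  suppressWarnings(
    wilcox.test(case_values, control_values, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Stage 4 statistic: ROC area (Mann-Whitney AUC)
#'
#' `AUC = (#{case > control pairs} + 0.5 * #{tied pairs}) / (n1 * n2)`,
#' oriented so that a perfectly case-high ion scores 1.  Computed through
#' midranks, which is algebraically identical to the pair count.
#'
#' @param case_values,control_values Numeric intensity vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(5, 6, 7), c(1, 2, 3)) # 1
#' @export
auc <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (!n1 || !n2) ms_stop("both groups must be non-empty", "argument_error")
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Run the four-stage marker screening cascade
#'
#' Applies the detection, fold-change, rank-sum and AUC filters in order on
#' the training split and returns one row per stage-1 survivor with its
#' detection counts (computed on the training split per group), fold change,
#' p-value, AUC and the last stage it passed.  Final candidates
#' (`passed_stage == 4`) sort first, by ascending p-value.
#'
#' @param matrix Feature matrix.
#' @param samples Sample table.
#' @param config A [screen_config()].
#' @return data.frame of class `"marker_screen"` with columns `ion`,
#'   `n_detect_case`, `n_detect_control`, `ratio`, `log_ratio`, `p_value`,
#'   `auc`, `passed_stage`; the Gaussian fit is attached as attribute
#'   `gaussian_fit` and the stage survivor counts as attribute `funnel`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_case = 30, n_control = 30,
#'                                         n_ions = 300, n_markers = 3,
#'                                         marker_fold_range = c(10, 10)))
#' scr <- screen_markers(cohort$matrix, cohort$samples)
#' candidates(scr)
#' @export
screen_markers <- function(matrix, samples, config = screen_config()) {
  validate_feature_matrix(matrix)
  validate_sample_table(samples, matrix)
  if (!inherits(config, "screen_config")) {
    config <- do.call(screen_config, as.list(config))
  }
  tr <- samples[samples$split == "train", ]
  if (!nrow(tr)) ms_stop("training split is empty", "state_error")
  case_ids <- tr$sample_id[tr$group == "case"]
  ctrl_ids <- tr$sample_id[tr$group == "control"]
  if (!length(case_ids) || !length(ctrl_ids)) {
    ms_stop("both groups must be present in the training split", "state_error")
  }

  stage1 <- detection_filter(matrix, samples)
  sub <- matrix[, stage1, drop = FALSE]
  fc <- fold_change(sub, samples, zero_in_means = config$zero_in_means)
  fit <- if (sum(is.finite(fc$log_ratio)) >= 10L) {
    fit_gaussian_log_ratios(fc$log_ratio, bins = config$histogram_bins)
  } else {
    structure(list(amplitude = NA_real_,
                   mean = mean(fc$log_ratio[is.finite(fc$log_ratio)]),
                   sd = max(stats::sd(fc$log_ratio[is.finite(fc$log_ratio)]),
                            .Machine$double.eps, na.rm = TRUE),
                   fallback = TRUE), class = "gaussian_fit")
  }
  stage2 <- fold_filter(fc, fit, config$sd_multiplier)

  case_m <- sub[case_ids, , drop = FALSE]
  ctrl_m <- sub[ctrl_ids, , drop = FALSE]
  p <- vapply(seq_along(stage1), function(j) {
    rank_sum_test(case_m[, j], ctrl_m[, j])
  }, numeric(1))
  a <- vapply(seq_along(stage1), function(j) {
    auc(case_m[, j], ctrl_m[, j])
  }, numeric(1))

  in2 <- fc$ion %in% stage2
  in3 <- in2 & p < config$alpha
  in4 <- in3 & a >= config$auc_min
  out <- data.frame(
    ion = fc$ion,
    n_detect_case = colSums(case_m > 0),
    n_detect_control = colSums(ctrl_m > 0),
    ratio = fc$ratio,
    log_ratio = fc$log_ratio,
    p_value = p,
    auc = a,
    passed_stage = 1L + in2 + in3 + in4,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$passed_stage, out$p_value, out$ion), ]
  rownames(out) <- NULL
  attr(out, "gaussian_fit") <- fit
  attr(out, "funnel") <- c(input = ncol(matrix), detection = length(stage1),
                           fold = sum(in2), rank_sum = sum(in3),
                           auc = sum(in4))
  class(out) <- c("marker_screen", "data.frame")
  out
}

#' Final candidates of a screening run
#'
#' @param x A `"marker_screen"` result.
#' @return The rows with `passed_stage == 4`, sorted by ascending p-value.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "marker_screen"))
  out <- x[x$passed_stage == 4L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.marker_screen <- function(x, digits = 3, ...) {
  funnel <- attr(x, "funnel")
  cat("Four-stage marker screening\n")
  cat(sprintf("  ions in: %d | detected: %d | fold: %d | rank-sum: %d | AUC: %d\n",
              funnel["input"], funnel["detection"], funnel["fold"],
              funnel["rank_sum"], funnel["auc"]))
  fit <- attr(x, "gaussian_fit")
  cat(sprintf("  log-ratio Gaussian: mean %.3f, sd %.3f%s\n", fit$mean, fit$sd,
              if (fit$fallback) " (moment fallback)" else ""))
  cand <- candidates(x)
  if (nrow(cand)) {
    cat(sprintf("Candidate ions (%d):\n", nrow(cand)))
    disp <- data.frame(ion = cand$ion,
                       `#case` = cand$n_detect_case,
                       `#control` = cand$n_detect_control,
                       ratio = round(cand$ratio, 2),
                       p = signif(cand$p_value, 3),
                       AUC = round(cand$auc, 2),
                       check.names = FALSE)
    print(disp, row.names = FALSE)
  } else {
    cat("No ions passed all four stages.\n")
  }
  invisible(x)
}

#' Write screening statistics to a tab-delimited file
#'
#' @param x A `"marker_screen"` result.
#' @param path Output path (conventionally `ionstats.tsv`).
#' @return `path`, invisibly.
#' @export
write_ionstats <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
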