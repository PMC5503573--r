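#' Configuration for the synthetic cohort generator
#'
#' Describes a two-group (case/control) untargeted LC-MS cohort with
#' zero-inflated log-normal ion intensities and a small set of planted
#' up-regulated marker ions.  Defaults emulate a bladder-cancer vs hernia
#' urine study design: 87 case and 65 control subjects, a few thousand
#' aligned spectral ions, six markers up-regulated several-fold in cases.
#'
#' Per ion, a base log10 mean and log10 SD are drawn once from the
#' configured ranges; intensities are `10^Normal(mu, sigma)`.  Marker ions
#' get a case-group mean shifted by `log10(fold)` with the fold drawn from
#' `marker_fold_range`.  Each observation is independently zeroed ("not
#' detected") with the ion's dropout probability, drawn from
#' `dropout_prob_range` for background ions and fixed at
#' `marker_dropout_prob` for markers (markers are, by construction,
#' reliably detected ions).
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_ions Number of spectral ions.
#' @param n_markers Number of planted up-regulated marker ions
#'   (`n_markers <= n_ions`).
#' @param marker_fold_range Length-2 numeric, linear fold-change range for
#'   markers; minimum must exceed 1.
#' @param base_log10_mean_range,base_log10_sd_range Ranges the per-ion base
#'   log10 mean and SD are drawn from.
#' @param dropout_prob_range Range of per-ion non-detection probability for
#'   background ions.
#' @param marker_dropout_prob Non-detection probability for marker ions.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_case = 87L,
                          n_control = 65L,
                          n_ions = 5000L,
                          n_markers = 6L,
                          marker_fold_range = c(5, 15),
                          base_log10_mean_range = c(3, 6),
                          base_log10_sd_range = c(0.15, 0.35),
                          dropout_prob_range = c(0.05, 0.6),
                          marker_dropout_prob = 0.05,
                          seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_ions = as.integer(n_ions), n_markers = as.integer(n_markers),
              marker_fold_range = as.numeric(marker_fold_range),
              base_log10_mean_range = as.numeric(base_log10_mean_range),
              base_log10_sd_range = as.numeric(base_log10_sd_range),
              dropout_prob_range = as.numeric(dropout_prob_range),
              marker_dropout_prob = as.numeric(marker_dropout_prob),
              seed = as.integer(seed))
  stopifnot_scalar_count(cfg$n_case, "n_case", 1L)
  stopifnot_scalar_count(cfg$n_control, "n_control", 1L)
  stopifnot_scalar_count(cfg$n_ions, "n_ions", 1L)
  stopifnot_scalar_count(cfg$n_markers, "n_markers", 0L)
  if (cfg$n_markers > cfg$n_ions) {
    ms_stop("n_markers exceeds n_ions", "config_error")
  }
  rng2 <- function(x, name) {
    if (length(x) != 2L || anyNA(x) || x[1L] > x[2L]) {
      ms_stop(sprintf("'%s' must be an ordered (min, max) pair", name),
              "config_error")
    }
  }
  rng2(cfg$marker_fold_range, "marker_fold_range")
  rng2(cfg$base_log10_mean_range, "base_log10_mean_range")
  rng2(cfg$base_log10_sd_range, "base_log10_sd_range")
  rng2(cfg$dropout_prob_range, "dropout_prob_range")
  if (cfg$n_markers > 0L && cfg$marker_fold_range[1L] <= 1) {
    ms_stop("marker_fold_range minimum must exceed 1", "config_error")
  }
  if (any(cfg$dropout_prob_range < 0) || any(cfg$dropout_prob_range > 1) ||
      cfg$marker_dropout_prob < 0 || cfg$marker_dropout_prob > 1) {
    ms_stop("dropout probabilities must lie in [0, 1]", "config_error")
  }
  if (any(cfg$base_log10_sd_range < 0)) {
    ms_stop("base_log10_sd_range must be nonnegative", "config_error")
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a two-group LC-MS cohort
#'
#' Generates a feature matrix, a sample table (all samples marked `train`;
#' use [split_train_test()] to hold out a test set) and the ground truth for
#' the planted markers.  Ion labels follow the canonical
#' `"(R min: M m/z)"` convention with retention times drawn uniformly in
#' 0.5-30 min and m/z uniformly in 50-1000, mirroring a typical reversed
#' phase positive-mode acquisition range.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cohort"` with elements `matrix` (feature
#'   matrix), `samples` (sample table) and `truth` (data.frame with columns
#'   `ion_index`, `ion`, `true_fold`, `true_log_fold`).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_case = 20, n_control = 20,
#'                                         n_ions = 50, n_markers = 2))
#' dim(cohort$matrix)
#' cohort$truth
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  with_seed(config$seed, {
    n_ions <- config$n_ions
    n_case <- config$n_case
    n_ctrl <- config$n_control
    n <- n_case + n_ctrl

    # unique canonical labels: redraw collisions at display precision
    rt <- runif(n_ions, 0.5, 30)
    mz <- runif(n_ions, 50, 1000)
    labels <- ion_label(rt, mz)
    while (anyDuplicated(labels)) {
      dup <- which(duplicated(labels))
      rt[dup] <- runif(length(dup), 0.5, 30)
      mz[dup] <- runif(length(dup), 50, 1000)
      labels <- ion_label(rt, mz)
    }

    mu <- runif(n_ions, config$base_log10_mean_range[1L],
                config$base_log10_mean_range[2L])
    sigma <- runif(n_ions, config$base_log10_sd_range[1L],
                   config$base_log10_sd_range[2L])
    dropout <- runif(n_ions, config$dropout_prob_range[1L],
                     config$dropout_prob_range[2L])

    marker_idx <- integer(0)
    fold <- numeric(0)
    if (config$n_markers > 0L) {
      marker_idx <- sort(sample.int(n_ions, config$n_markers))
      fold <- runif(config$n_markers, config$marker_fold_range[1L],
                    config$marker_fold_range[2L])
      dropout[marker_idx] <- config$marker_dropout_prob
    }

    group <- rep(c("case", "control"), c(n_case, n_ctrl))
    shift <- matrix(0, nrow = n, ncol = n_ions)
    if (length(marker_idx)) {
      shift[group == "case", marker_idx] <-
        rep(log10(fold), each = n_case)
    }
    logx <- matrix(rnorm(n * n_ions, mean = mu, sd = sigma),
                   nrow = n, ncol = n_ions, byrow = TRUE) + shift
    x <- 10^logx
    detected <- matrix(runif(n * n_ions), nrow = n, ncol = n_ions) >=
      rep(dropout, each = n)
    x[!detected] <- 0

    ids <- sprintf("%s_%03d", ifelse(group == "case", "case", "ctrl"),
                   c(seq_len(n_case), seq_len(n_ctrl)))
    dimnames(x) <- list(ids, labels)

    samples <- data.frame(sample_id = ids, group = group, split = "train",
                          stringsAsFactors = FALSE)
    truth <- data.frame(ion_index = marker_idx,
                        ion = labels[marker_idx],
                        true_fold = fold,
                        true_log_fold = log10(fold),
                        stringsAsFactors = FALSE)
    structure(list(matrix = x, samples = samples, truth = truth,
                   config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic LC-MS cohort: %d case + %d control samples, %d ions, %d planted markers\n",
              x$config$n_case, x$config$n_control, x$config$n_ions,
              nrow(x$truth)))
  if (nrow(x$truth)) {
    cat("Planted markers (linear fold change in cases):\n")
    print(data.frame(ion = x$truth$ion, fold = round(x$truth$true_fold, 2)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a simulated cohort to tab-delimited files
#'
#' Writes `matrix.tsv`, `samples.tsv` and `truth.tsv` into `dir`.
#'
#' @param cohort A `"cohort"` object from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_samples(cohort$samples, file.path(dir, "samples.tsv"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
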