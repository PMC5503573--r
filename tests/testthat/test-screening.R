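# The four-stage screening cascade and its statistical primitives.

test_that("detection filter keeps ions detected in strictly more than half of training samples", {
  # 105 training samples; boundary cases around 52.5
  n <- 105
  groups <- rep(c("case", "control"), c(55, 50))
  det <- function(k) c(rep(1, k), rep(0, n - k))
  m <- toy_matrix(c(det(71), det(53), det(52), det(0)), n_samples = n)
  st <- toy_samples(groups)
  kept <- detection_filter(m, st)
  expect_true(colnames(m)[1] %in% kept)   # 71 > 52.5 (46 case + 25 control style)
  expect_true(colnames(m)[2] %in% kept)   # 53 > 52.5
  expect_false(colnames(m)[3] %in% kept)  # 52 < 52.5
  expect_false(colnames(m)[4] %in% kept)

  expect_error(detection_filter(m, toy_samples(groups, split = "test")),
               "training")
})

test_that("detection filter matches a brute-force recount on random dropout matrices", {
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(20:40, 1)
    m <- toy_matrix(rbinom(n * 30, 1, 0.5) * 10^runif(n * 30, 2, 5), n)
    st <- toy_samples(rep(c("case", "control"), length.out = n))
    kept <- detection_filter(m, st)
    oracle <- colnames(m)[vapply(seq_len(ncol(m)), function(j) {
      sum(m[, j] > 0) > n / 2
    }, logical(1))]
    expect_identical(kept, oracle)
  }
})

test_that("fold change is the ratio of training group means, zeros included", {
  ctrl_vals <- c(2, 4, 6)
  m <- toy_matrix(c(2 * ctrl_vals, ctrl_vals,   # exact 2x scaling
                    ctrl_vals, ctrl_vals),      # identical groups
                  n_samples = 6)
  st <- toy_samples(rep(c("case", "control"), each = 3))
  fc <- fold_change(m, st)
  expect_equal(fc$ratio, c(2, 1))
  expect_equal(fc$log_ratio, c(log10(2), 0))

  # zero control mean -> NA with warning
  m2 <- toy_matrix(c(1, 1, 1, 0, 0, 0), n_samples = 6)
  expect_warning(fc2 <- fold_change(m2, st), "control mean is zero")
  expect_true(is.na(fc2$ratio))

  # only training samples enter the means
  st3 <- st
  st3$split[c(1, 4)] <- "test"
  fc3 <- fold_change(m, st3)
  expect_equal(fc3$ratio[1], mean(c(8, 12)) / mean(c(4, 6)))
})

test_that("planted tenfold marker yields an empirical ratio near 10", {
  co <- simulate_cohort(cohort_config(
    n_case = 55, n_control = 50, n_ions = 30, n_markers = 5,
    marker_fold_range = c(10, 10), base_log10_sd_range = c(0.2, 0.2),
    dropout_prob_range = c(0, 0), marker_dropout_prob = 0, seed = 21
  ))
  fc <- fold_change(co$matrix, co$samples)
  ratios <- fc$ratio[match(co$truth$ion, fc$ion)]
  expect_true(all(ratios > 8 & ratios < 12.5))
})

test_that("Gaussian histogram fit recovers a noiseless curve to 6 decimals", {
  xs <- seq(-2, 3, length.out = 50)
  ys <- 100 * exp(-(xs - 0.2)^2 / (2 * 0.5^2))
  fit <- metabscreen:::fit_gaussian_curve(xs, ys)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$mean, 0.2, tolerance = 1e-6)
  expect_equal(fit$sd, 0.5, tolerance = 1e-6)
  expect_false(fit$fallback)
})

test_that("Gaussian fit recovers the parameters of simulated log ratios", {
  set.seed(6)
  x <- rnorm(1e5, 0, 0.5)
  fit <- fit_gaussian_log_ratios(x, bins = 60)
  expect_gt(fit$mean, -0.02); expect_lt(fit$mean, 0.02)
  expect_gt(fit$sd, 0.48); expect_lt(fit$sd, 0.52)
})

test_that("degenerate log ratios fall back to sample moments with a warning", {
  expect_warning(fit <- fit_gaussian_log_ratios(rep(0.3, 10), bins = 20),
                 "falling back")
  expect_true(fit$fallback)
  expect_equal(fit$mean, 0.3)
  expect_error(fit_gaussian_log_ratios(c(0.1, 0.2), bins = 10), "at least 10")
})

test_that("fold filter keeps only positive log-ratios beyond the SD band", {
  fit <- structure(list(amplitude = 1, mean = 0, sd = 0.3, fallback = FALSE),
                   class = "gaussian_fit")
  stats <- data.frame(ion = c("a", "b"), ratio = 10^c(0.31, 0.29),
                      log_ratio = c(0.31, 0.29))
  expect_equal(fold_filter(stats, fit, 1), "a")

  # beyond one SD but negative: the positivity clause removes it
  fit2 <- structure(list(amplitude = 1, mean = -0.5, sd = 0.2, fallback = FALSE),
                    class = "gaussian_fit")
  stats2 <- data.frame(ion = "c", ratio = 10^-0.1, log_ratio = -0.1)
  expect_equal(fold_filter(stats2, fit2, 1), character(0))
})

test_that("kept fraction under a Gaussian null matches the closed-form tail", {
  set.seed(8)
  mu <- 0.4; s <- 0.3  # mu + s > 0, so the positivity clause is inactive in the tail
  n <- 20000
  lr <- rnorm(n, mu, s)
  fit <- fit_gaussian_log_ratios(lr, bins = 80)
  stats <- data.frame(ion = as.character(seq_len(n)), ratio = 10^lr,
                      log_ratio = lr)
  frac <- length(fold_filter(stats, fit, 1)) / n
  expected <- 1 - pnorm(1)
  se <- sqrt(expected * (1 - expected) / n)
  # fitted-parameter noise adds a little on top of the binomial SE
  expect_lt(abs(frac - expected), 3 * se + 0.01)
})

test_that("rank-sum p matches exact enumeration on small tie-free samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(enumerate_rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2)
    if (n1 + n2 <= 12) {
      expect_equal(rank_sum_test(x1, x2), enumerate_rank_sum_p(x1, x2),
                   tolerance = 1e-12)
    }
  }
  # identical multisets: symmetric, p = 1
  expect_equal(rank_sum_test(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1.0)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("AUC obeys its closed forms and symmetries", {
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1.0)     # perfect separation
  expect_equal(auc(rep(2, 4), rep(2, 6)), 0.5)       # all ties
  set.seed(12)
  for (i in 1:30) {
    case <- round(rnorm(sample(5:20, 1), 0.5), 1)    # rounding induces ties
    ctrl <- round(rnorm(sample(5:20, 1)), 1)
    a <- auc(case, ctrl)
    expect_equal(a, pair_count_auc(case, ctrl), tolerance = 1e-12)
    expect_equal(a + auc(ctrl, case), 1, tolerance = 1e-12)
  }
  expect_error(auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC equals U/(n1 n2) of the rank-sum statistic on tie-free data", {
  set.seed(14)
  for (i in 1:20) {
    case <- rnorm(12, 0.3); ctrl <- rnorm(10)
    w <- wilcox.test(case, ctrl)$statistic  # Mann-Whitney U, case first
    expect_equal(auc(case, ctrl), unname(w) / (12 * 10), tolerance = 1e-12)
  }
})

test_that("screening recovers planted markers and respects stage monotonicity", {
  co <- tiny_cohort(seed = 31, n_case = 55, n_control = 50, n_ions = 400,
                    n_markers = 4)
  scr <- screen_markers(co$matrix, co$samples)
  expect_true(all(co$truth$ion %in% candidates(scr)$ion))
  expect_true(all(scr$passed_stage %in% 1:4))
  funnel <- attr(scr, "funnel")
  expect_true(all(diff(funnel) <= 0))  # each stage only shrinks the set
  # candidates sorted by ascending p
  expect_false(is.unsorted(candidates(scr)$p_value))
  # stats are within their ranges
  expect_true(all(scr$auc >= 0 & scr$auc <= 1))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_true(all(scr$n_detect_case <= 55 & scr$n_detect_control <= 50))
})

test_that("screening output is invariant under sample and ion reordering", {
  co <- tiny_cohort(seed = 33, n_ions = 80, n_markers = 2)
  scr <- screen_markers(co$matrix, co$samples)
  perm_s <- sample(nrow(co$matrix))
  perm_i <- sample(ncol(co$matrix))
  scr2 <- screen_markers(co$matrix[perm_s, perm_i],
                         co$samples[perm_s, ], screen_config())
  expect_equal(as.data.frame(scr), as.data.frame(scr2))
})

test_that("an impossible AUC threshold yields zero candidates", {
  co <- tiny_cohort(seed = 35, n_ions = 60, n_markers = 2)
  scr <- screen_markers(co$matrix, co$samples,
                        screen_config(auc_min = 1.01))
  expect_equal(nrow(candidates(scr)), 0)
  expect_true(all(scr$passed_stage <= 3))
})

test_that("ionstats file round-trips the screening table", {
  co <- tiny_cohort(seed = 37, n_ions = 50, n_markers = 1)
  scr <- screen_markers(co$matrix, co$samples)
  f <- tempfile()
  write_ionstats(scr, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$ion, scr$ion)
  expect_equal(back$p_value, scr$p_value, tolerance = 1e-10)
  expect_equal(back$passed_stage, scr$passed_stage)
})
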