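# Shared fixtures and independent oracles used across test files.

# small, fast synthetic cohort
tiny_cohort <- function(seed = 1L, n_case = 30L, n_control = 30L,
                        n_ions = 200L, n_markers = 3L,
                        fold = c(10, 10), dropout = c(0, 0.3)) {
  simulate_cohort(cohort_config(
    n_case = n_case, n_control = n_control, n_ions = n_ions,
    n_markers = n_markers, marker_fold_range = fold,
    dropout_prob_range = dropout, marker_dropout_prob = 0.05, seed = seed
  ))
}

# hand-built feature matrix with labelled ions
toy_matrix <- function(values, n_samples, ion_rt = NULL, ion_mz = NULL) {
  n_ions <- length(values) / n_samples
  if (is.null(ion_rt)) ion_rt <- seq(1, by = 1, length.out = n_ions)
  if (is.null(ion_mz)) ion_mz <- seq(100, by = 10, length.out = n_ions)
  m <- matrix(values, nrow = n_samples)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      ion_label(ion_rt, ion_mz))
  m
}

toy_samples <- function(groups, split = "train") {
  data.frame(sample_id = sprintf("s%02d", seq_along(groups)),
             group = groups, split = split, stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# exact two-sided rank-sum p by enumerating every group-1 subset of ranks
enumerate_rank_sum_p <- function(x1, x2) {
  n1 <- length(x1)
  r <- rank(c(x1, x2))
  combos <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  obs <- sum(r[seq_len(n1)])
  center <- n1 * (length(r) + 1) / 2
  mean(abs(sums - center) >= abs(obs - center) - 1e-9)
}

# Monte-Carlo permutation two-sided rank-sum p (B random relabellings)
permutation_rank_sum_p <- function(x1, x2, B = 1e5L) {
  n1 <- length(x1)
  n <- n1 + length(x2)
  r <- rank(c(x1, x2))
  center <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - center)
  idx <- order(rep(seq_len(B), each = n), runif(n * B))
  perm <- matrix(((idx - 1L) %% n) + 1L, n, B)
  w <- colSums(matrix(r[perm[seq_len(n1), ]], n1, B))
  mean(abs(w - center) >= obs - 1e-9)
}

# AUC by explicit pair counting (the definition, not the rank identity)
pair_count_auc <- function(case, control) {
  gt <- sum(outer(case, control, `>`))
  eq <- sum(outer(case, control, `==`))
  (gt + 0.5 * eq) / (length(case) * length(control))
}

# exhaustive best-threshold search by direct gain-ratio evaluation of every
# midpoint (C4.5 mean-gain guard applied), independent of best_split internals
brute_force_best_split <- function(values, labels, min_leaf = 2L) {
  uv <- sort(unique(values))
  if (length(uv) < 2L || length(unique(labels)) < 2L) return(NULL)
  thr <- (uv[-length(uv)] + uv[-1L]) / 2
  lev <- sort(unique(labels))
  res <- lapply(thr, function(t) {
    l <- labels[values <= t]
    rgt <- labels[values > t]
    if (length(l) < min_leaf || length(rgt) < min_leaf) return(NULL)
    counts <- function(lbl) vapply(lev, function(cl) sum(lbl == cl), numeric(1))
    p <- counts(labels)
    ent <- function(cnt) {
      q <- cnt[cnt > 0] / sum(cnt)
      -sum(q * log2(q))
    }
    gain <- ent(p) - (length(l) / length(labels)) * ent(counts(l)) -
      (length(rgt) / length(labels)) * ent(counts(rgt))
    si <- ent(c(length(l), length(rgt)))
    list(threshold = t, gain = gain,
         gain_ratio = if (si > 0) gain / si else 0)
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(NULL)
  gains <- vapply(res, `[[`, numeric(1), "gain")
  admissible <- gains >= mean(gains) - 1e-12 & gains > 1e-12
  if (!any(admissible)) return(NULL)
  res <- res[admissible]
  ratios <- vapply(res, `[[`, numeric(1), "gain_ratio")
  res[[which.max(ratios)]]
}

# plain PLS1 via NIPALS, written independently of the opls() internals
nipals_pls1 <- function(X, y) {
  Xs <- scale(X)
  yc <- y - mean(y)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  drop(Xs %*% w)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
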