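#' Orthogonal projections to latent structures discriminant analysis
#'
#' Fits an OPLS-DA model for a two-class response: orthogonal components
#' (systematic X-variation uncorrelated with the class) are extracted and
#' removed by NIPALS-style deflation, then a single predictive component is
#' fitted to the deflated matrix.  The class is encoded +1 (case) / -1
#' (control), so positive predictive scores lean towards the case class.
#'
#' Columns are mean-centred and, by default, scaled to unit variance before
#' fitting; constant columns are dropped with a warning.  Fit quality is
#' summarised by the cumulative fractions of X- and y-variance explained
#' (`r2x_cum`, `r2y_cum`) and by `q2_cum`, the cross-validated fraction of
#' y-variance predicted (k-fold over samples, folds stratified by class).
#'
#' @param X Numeric matrix, samples x variables (e.g. the training slice of
#'   a feature matrix).
#' @param y Class labels: a factor/character with values `"case"` and
#'   `"control"`, or a numeric +1/-1 vector.
#' @param n_pred Number of predictive components (only 1 is supported, the
#'   usual choice for a two-class model).
#' @param n_orth Number of orthogonal components (default 2).
#' @param scale Column scaling: `"uv"` (unit variance, default), `"pareto"`
#'   or `"none"`; columns are always mean-centred.
#' @param cv_folds Folds for the Q2 cross-validation (default 7).
#' @param cv_seed Seed for the CV fold assignment.
#' @return An object of class `"opls"` with elements `scores` (predictive
#'   scores per sample), `orthogonal_scores` (samples x `n_orth`),
#'   `weights`, `loadings`, `y_loading`, `orthogonal_weights`,
#'   `orthogonal_loadings`, `r2x_cum`, `r2y_cum`, `q2_cum`, `r2x_per_component`
#'   and the preprocessing parameters.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 8), 40, 8)
#' y <- rep(c("case", "control"), each = 20)
#' X[y == "case", 1] <- X[y == "case", 1] + 2
#' m <- opls(X, y, n_orth = 1)
#' m
#' @export
opls <- function(X, y, n_pred = 1L, n_orth = 2L, scale = c("uv", "pareto", "none"),
                 cv_folds = 7L, cv_seed = 1L) {
  scale <- match.arg(scale)
  if (n_pred != 1L) ms_stop("only one predictive component is supported", "argument_error")
  stopifnot_scalar_count(n_orth, "n_orth", 0L)
  X <- as.matrix(X)
  y_num <- encode_class(y)
  if (nrow(X) != length(y_num)) ms_stop("X and y disagree in length", "argument_error")
  if (min(table(y_num)) < 3L) ms_stop("need at least 3 samples per class", "argument_error")
  if (nrow(X) < n_orth + n_pred + 1L) {
    ms_stop("fewer samples than components", "argument_error")
  }

  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  const <- apply(X, 2L, function(v) var(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant column(s) before scaling", sum(const)),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  pp <- list(center = colMeans(X),
             scale = switch(scale,
                            uv = apply(X, 2L, stats::sd),
                            pareto = sqrt(apply(X, 2L, stats::sd)),
                            none = rep(1, ncol(X))),
             kind = scale, kept = colnames(X))
  Xs <- sweep(sweep(X, 2L, pp$center), 2L, pp$scale, `/`)
  yc <- y_num - mean(y_num)

  core <- opls_core(Xs, yc, n_orth)
  ss_x <- sum(Xs^2)
  # per-component explained X sums of squares (scores are mutually orthogonal)
  r2x_comp <- c(predictive = sum(core$t^2) * sum(core$p^2) / ss_x)
  if (n_orth > 0L) {
    orth <- vapply(seq_len(n_orth), function(j) {
      sum(core$t_orth[, j]^2) * sum(core$p_orth[, j]^2)
    }, numeric(1)) / ss_x
    names(orth) <- paste0("orthogonal", seq_len(n_orth))
    r2x_comp <- c(r2x_comp, orth)
  }
  y_hat <- core$t * core$c
  r2y <- 1 - sum((yc - y_hat)^2) / sum(yc^2)

  q2 <- opls_q2(Xs, yc, n_orth, cv_folds, cv_seed)

  out <- list(scores = core$t, orthogonal_scores = core$t_orth,
              weights = core$w, loadings = core$p, y_loading = core$c,
              orthogonal_weights = core$w_orth,
              orthogonal_loadings = core$p_orth,
              r2x_per_component = r2x_comp,
              r2x_cum = sum(r2x_comp), r2y_cum = r2y, q2_cum = q2,
              n_orth = n_orth, preprocessing = pp,
              y = y_num, y_mean = mean(y_num),
              classes = c(pos = "case", neg = "control"))
  class(out) <- "opls"
  out
}

encode_class <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) ms_stop("numeric y must be +1/-1", "argument_error")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("case", "control"))) {
    ms_stop("y must be 'case'/'control' (or +1/-1)", "argument_error")
  }
  ifelse(y == "case", 1, -1)
}

# NIPALS O-PLS for a single centred response: extract n_orth orthogonal
# components with deflation, then one predictive component.
opls_core <- function(Xs, yc, n_orth) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  t_orth <- matrix(0, n, 0)
  p_orth <- matrix(0, p, 0)
  w_orth <- matrix(0, p, 0)
  Xd <- Xs
  for (j in seq_len(n_orth)) {
    w <- crossprod(Xd, yc)[, 1L]
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    pv <- crossprod(Xd, t)[, 1L] / sum(t^2)
    wo <- pv - sum(w * pv) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to)[, 1L] / sum(to^2)
    Xd <- Xd - to %*% t(po)
    t_orth <- cbind(t_orth, to)
    p_orth <- cbind(p_orth, po)
    w_orth <- cbind(w_orth, wo)
  }
  w <- crossprod(Xd, yc)[, 1L]
  w <- w / sqrt(sum(w^2))
  t <- (Xd %*% w)[, 1L]
  pv <- crossprod(Xd, t)[, 1L] / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  list(t = t, p = pv, w = w, c = cc,
       t_orth = t_orth, p_orth = p_orth, w_orth = w_orth)
}

# stratified k-fold Q2: refit on k-1 folds, predict the held-out fold
opls_q2 <- function(Xs, yc, n_orth, cv_folds, cv_seed) {
  n <- nrow(Xs)
  cls <- yc > 0
  folds <- integer(n)
  with_seed(cv_seed, {
    for (g in unique(cls)) {
      idx <- sample_vec(which(cls == g))
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })
  press <- 0
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    if (sum(tr) <= n_orth + 2L || length(unique(yc[tr])) < 2L) next
    core <- opls_core(Xs[tr, , drop = FALSE], yc[tr] - mean(yc[tr]), n_orth)
    Xnew <- Xs[!tr, , drop = FALSE]
    if (n_orth > 0L && ncol(core$t_orth) > 0L) {
      for (j in seq_len(ncol(core$t_orth))) {
        tno <- Xnew %*% core$w_orth[, j]
        Xnew <- Xnew - tno %*% t(core$p_orth[, j])
      }
    }
    pred <- (Xnew %*% core$w)[, 1L] * core$c + mean(yc[tr])
    press <- press + sum((yc[!tr] - pred)^2)
  }
  1 - press / sum(yc^2)
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), %d samples x %d variables\n",
              x$n_orth, length(x$scores), length(x$weights)))
  cat(sprintf("  R2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f\n",
              x$r2x_cum, x$r2y_cum, x$q2_cum))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  print(object)
  cat("Explained X-variance per component:\n")
  print(round(object$r2x_per_component, 4))
  invisible(object)
}

#' Predict class scores for new samples from an OPLS-DA model
#'
#' Applies the stored centring/scaling, strips the orthogonal components
#' and projects onto the predictive component.
#'
#' @param object An `"opls"` model.
#' @param newdata Numeric matrix with the same variables the model was
#'   fitted on.
#' @param ... Unused.
#' @return data.frame with `t_pred` (predictive score), `y_hat` (numeric
#'   prediction on the +1/-1 scale) and `class` (`"case"` iff `y_hat > 0`).
#' @export
predict.opls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  }
  newdata <- newdata[, object$preprocessing$kept, drop = FALSE]
  Xn <- sweep(sweep(newdata, 2L, object$preprocessing$center), 2L,
              object$preprocessing$scale, `/`)
  if (object$n_orth > 0L && ncol(object$orthogonal_weights) > 0L) {
    for (j in seq_len(ncol(object$orthogonal_weights))) {
      tno <- Xn %*% object$orthogonal_weights[, j]
      Xn <- Xn - tno %*% t(object$orthogonal_loadings[, j])
    }
  }
  t_pred <- (Xn %*% object$weights)[, 1L]
  y_hat <- t_pred * object$y_loading + object$y_mean
  data.frame(t_pred = t_pred, y_hat = y_hat,
             class = ifelse(y_hat > 0, "case", "control"),
             stringsAsFactors = FALSE)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index if
#' the model has no orthogonal component), coloured by class.
#'
#' @param x An `"opls"` model.
#' @param ... Passed to [plot.default()].
#' @export
plot.opls <- function(x, ...) {
  t2 <- if (x$n_orth > 0L && ncol(x$orthogonal_scores) > 0L) {
    x$orthogonal_scores[, 1L]
  } else {
    seq_along(x$scores)
  }
  col <- ifelse(x$y > 0, "#2166ac", "#b2182b")
  plot.default(x$scores, t2, col = col, pch = 19,
               xlab = "t[1] (predictive)",
               ylab = if (x$n_orth > 0L) "t[o1] (orthogonal)" else "sample index",
               main = sprintf("OPLS-DA scores (R2Y %.2f, Q2 %.2f)",
                              x$r2y_cum, x$q2_cum), ...)
  abline(v = 0, lty = 3)
  legend("topright", legend = c("case", "control"), col = c("#2166ac", "#b2182b"),
         pch = 19, bty = "n")
  invisible(x)
}
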