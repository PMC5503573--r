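#' Locally linear embedding
#'
#' Standard LLE: each sample is reconstructed as a convex-free linear
#' combination of its `k` nearest Euclidean neighbours (weights constrained
#' to sum to 1, local Gram matrix regularised by `reg * trace` Tikhonov
#' damping), and the `d`-dimensional embedding is given by the bottom `d`
#' non-constant eigenvectors of `(I - W)'(I - W)`.  Because the weight rows
#' sum to 1, the embedding is translation invariant and has zero mean per
#' coordinate.
#'
#' Inputs are standardised per variable (mean 0, SD 1) before the neighbour
#' search unless `standardize = FALSE`; constant variables are dropped.
#'
#' @param X Numeric matrix, samples x variables (typically samples over the
#'   selected candidate ions).
#' @param k Number of neighbours (default 12); must be smaller than the
#'   number of samples.
#' @param d Embedding dimension (default 2).
#' @param reg Relative Tikhonov regularisation of the local Gram matrix
#'   (default 1e-3); guards against singular neighbourhoods (e.g. duplicate
#'   points or k exceeding the local intrinsic dimension).
#' @param standardize Standardise variables first? Default `TRUE`.
#' @return Object of class `"lle"` with `coordinates` (samples x d),
#'   `weights` (samples x samples, row-sparse), `k`, `reg` and the
#'   eigenvalues of the embedding problem.
#' @examples
#' set.seed(1)
#' X <- cbind(matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 5), 2, 5))
#' emb <- lle(X, k = 8)
#' colMeans(emb$coordinates) # ~ 0
#' @export
lle <- function(X, k = 12L, d = 2L, reg = 1e-3, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot_scalar_count(k, "k", 1L)
  stopifnot_scalar_count(d, "d", 1L)
  if (k >= n) ms_stop("k must be smaller than the number of samples", "argument_error")
  if (d > k) ms_stop("embedding dimension cannot exceed k", "argument_error")
  if (standardize) {
    s <- apply(X, 2L, stats::sd)
    keep <- s > 0
    X <- sweep(sweep(X[, keep, drop = FALSE], 2L, colMeans(X[, keep, drop = FALSE])),
               2L, s[keep], `/`)
  }

  D2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- ord[ord != i][seq_len(k)]
    Z <- sweep(X[nb, , drop = FALSE], 2L, X[i, ])
    G <- tcrossprod(Z)
    G <- G + diag(reg * max(sum(diag(G)), .Machine$double.eps), k)
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }

  M <- crossprod(diag(n) - W)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- seq(n, 1L)  # ascending eigenvalues
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # discard the constant eigenvector (eigenvalue ~0), keep next d
  coords <- vecs[, 1L + seq_len(d), drop = FALSE] * sqrt(n)
  dimnames(coords) <- list(rownames(X), paste0("LLE", seq_len(d)))
  structure(list(coordinates = coords, weights = W, k = k, d = d, reg = reg,
                 eigenvalues = vals[seq_len(d + 1L)]),
            class = "lle")
}

#' @export
print.lle <- function(x, ...) {
  cat(sprintf("LLE embedding: %d samples -> %d dims (k = %d, reg = %g)\n",
              nrow(x$coordinates), x$d, x$k, x$reg))
  cat("bottom eigenvalues:", signif(x$eigenvalues, 3), "\n")
  invisible(x)
}

#' Plot an LLE embedding
#'
#' @param x An `"lle"` object.
#' @param groups Optional case/control labels for colouring.
#' @param ... Passed to [plot.default()].
#' @export
plot.lle <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "black" else
    ifelse(as.character(groups) == "case", "#2166ac", "#b2182b")
  plot.default(x$coordinates[, 1L], x$coordinates[, 2L], col = col, pch = 19,
               xlab = "LLE1", ylab = "LLE2", main = "LLE embedding", ...)
  if (!is.null(groups)) {
    legend("topright", legend = c("case", "control"),
           col = c("#2166ac", "#b2182b"), pch = 19, bty = "n")
  }
  invisible(x)
}
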