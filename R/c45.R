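# Gain-ratio (C4.5-style) decision-tree induction over continuous ion
# intensities, with J48-flavoured defaults and confidence-based
# subtree-replacement pruning.

#' Shannon entropy of class counts, in bits
#'
#' @param class_counts Nonnegative numeric vector of per-class counts.
#' @return Entropy in bits (log base 2); zero counts contribute nothing.
#' @examples
#' entropy(c(2, 2)) # 1 bit
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) ms_stop("counts must be nonnegative", "argument_error")
  n <- sum(class_counts)
  if (n == 0) return(0)
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Gain ratio of a candidate split
#'
#' Information gain (parent entropy minus the size-weighted mean child
#' entropy) divided by the split information (entropy of the child sizes).
#' A zero split information yields a gain ratio of 0 by definition.
#'
#' @param parent_counts Class counts at the parent node.
#' @param child_counts_list List of class-count vectors, one per child;
#'   they must sum to the parent counts.
#' @return List with `gain`, `split_info` and `gain_ratio`.
#' @examples
#' gain_ratio(c(2, 2), list(c(2, 0), c(0, 2)))$gain_ratio # 1
#' @export
gain_ratio <- function(parent_counts, child_counts_list) {
  if (any(parent_counts < 0) ||
      any(vapply(child_counts_list, function(x) any(x < 0), logical(1)))) {
    ms_stop("counts must be nonnegative", "argument_error")
  }
  total <- Reduce(`+`, child_counts_list)
  if (!isTRUE(all.equal(unname(total), unname(parent_counts)))) {
    ms_stop("child counts must sum to the parent counts", "argument_error")
  }
  n <- sum(parent_counts)
  sizes <- vapply(child_counts_list, sum, numeric(1))
  gain <- entropy(parent_counts) -
    sum(sizes / n * vapply(child_counts_list, entropy, numeric(1)))
  split_info <- entropy(sizes)
  list(gain = gain, split_info = split_info,
       gain_ratio = if (split_info > 0) gain / split_info else 0)
}

#' Tree induction configuration
#'
#' Defaults mirror the common J48 settings: minimum 2 training samples per
#' leaf, pruning on, pruning confidence 0.25.
#'
#' @param min_leaf Minimum samples in each child of a split (default 2).
#' @param prune Apply confidence-based subtree replacement? Default `TRUE`.
#' @param prune_confidence Confidence level for the pessimistic error
#'   estimate, in (0, 0.5] (default 0.25).
#' @return List of class `"tree_config"`.
#' @export
tree_config <- function(min_leaf = 2L, prune = TRUE, prune_confidence = 0.25) {
  stopifnot_scalar_count(min_leaf, "min_leaf", 1L)
  if (prune_confidence <= 0 || prune_confidence > 0.5) {
    ms_stop("prune_confidence must lie in (0, 0.5]", "config_error")
  }
  structure(list(min_leaf = as.integer(min_leaf), prune = isTRUE(prune),
                 prune_confidence = prune_confidence),
            class = "tree_config")
}

#' Best binary threshold split of one continuous attribute
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values.  Following the C4.5 convention, only splits whose
#' information gain reaches the mean gain over all size-admissible
#' candidates compete, and among those the split with the highest gain
#' ratio wins; ties go to the smaller threshold.
#'
#' @param values Numeric attribute values.
#' @param labels Class labels (`"case"`/`"control"` or any two levels).
#' @param cfg A [tree_config()] (only `min_leaf` is used).
#' @return List `(threshold, gain_ratio, gain)` or `NULL` when no
#'   admissible split exists (pure node, constant attribute, or min_leaf
#'   unsatisfiable).
#' @examples
#' best_split(c(1, 2, 3, 4), c("A", "A", "B", "B"))$threshold # 2.5
#' @export
best_split <- function(values, labels, cfg = tree_config()) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) return(NULL)
  ord <- order(values)
  v <- values[ord]
  l <- labels[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(NULL)
  thr <- (uv[-length(uv)] + uv[-1L]) / 2
  n <- length(v)
  # cumulative class counts along the sorted order -> counts left of each threshold
  left_n <- vapply(thr, function(t) sum(v <= t), integer(1))
  ok <- left_n >= cfg$min_leaf & (n - left_n) >= cfg$min_leaf
  if (!any(ok)) return(NULL)
  thr <- thr[ok]
  left_n <- left_n[ok]
  cum <- vapply(lev, function(cl) cumsum(l == cl), integer(n))
  parent <- cum[n, ]
  stats <- lapply(seq_along(thr), function(i) {
    lc <- cum[left_n[i], ]
    gain_ratio(parent, list(lc, parent - lc))
  })
  gains <- vapply(stats, `[[`, numeric(1), "gain")
  ratios <- vapply(stats, `[[`, numeric(1), "gain_ratio")
  admissible <- gains >= mean(gains) - 1e-12
  if (!any(admissible & gains > 1e-12)) return(NULL)
  ratios[!admissible] <- -Inf
  best <- which.max(ratios)  # which.max takes the first (smallest threshold) on ties
  list(threshold = thr[best], gain_ratio = ratios[best], gain = gains[best])
}

#' Fit a gain-ratio decision tree on candidate-ion intensities
#'
#' Recursive binary induction: at each node the (ion, threshold) pair with
#' the highest admissible gain ratio is chosen (see [best_split()]);
#' recursion stops on class purity, on the `min_leaf` constraint, or when
#' no admissible split remains.  Leaves predict the majority class, with
#' ties going to `"case"` (favouring sensitivity).  With `cfg$prune`,
#' bottom-up subtree replacement prunes any internal node whose pessimistic
#' error as a leaf -- the upper `prune_confidence` binomial confidence
#' bound on its training error -- does not exceed the summed pessimistic
#' errors of its subtree.
#'
#' @param matrix Feature matrix restricted to the candidate ions (columns).
#' @param samples Sample table; training-split rows are used.
#' @param cfg A [tree_config()].
#' @return Object of class `"c45"`: a nested node structure (`kind`
#'   `"internal"` with `ion`, `threshold`, `left`, `right`; or `"leaf"`
#'   with `class` and `counts`) plus the fitted ion set.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_case = 25, n_control = 25,
#'                                         n_ions = 20, n_markers = 2,
#'                                         marker_fold_range = c(10, 10),
#'                                         dropout_prob_range = c(0, 0.1)))
#' fit <- c45(cohort$matrix[, cohort$truth$ion], cohort$samples)
#' print(fit)
#' @export
c45 <- function(matrix, samples, cfg = tree_config()) {
  tr <- samples[samples$split == "train", , drop = FALSE]
  if (!nrow(tr)) ms_stop("empty training data", "argument_error")
  X <- matrix[tr$sample_id, , drop = FALSE]
  y <- tr$group
  if (length(unique(y)) < 2L) {
    ms_stop("need both classes in the training data", "argument_error")
  }
  node <- grow_node(X, y, cfg)
  if (cfg$prune) node <- prune_node(node, cfg$prune_confidence)
  structure(list(root = node, ions = colnames(X), cfg = cfg,
                 n_train = nrow(X)),
            class = "c45")
}

node_counts <- function(y) {
  c(case = sum(y == "case"), control = sum(y == "control"))
}

leaf_node <- function(y) {
  cnt <- node_counts(y)
  cls <- if (cnt["case"] >= cnt["control"]) "case" else "control"
  list(kind = "leaf", class = cls, counts = cnt)
}

grow_node <- function(X, y, cfg) {
  if (length(unique(y)) < 2L || nrow(X) < 2L * cfg$min_leaf) {
    return(leaf_node(y))
  }
  splits <- lapply(seq_len(ncol(X)), function(j) best_split(X[, j], y, cfg))
  ratios <- vapply(splits, function(s) if (is.null(s)) -Inf else s$gain_ratio,
                   numeric(1))
  if (!any(is.finite(ratios))) return(leaf_node(y))
  j <- which.max(ratios)  # ties -> first ion in column order
  s <- splits[[j]]
  go_left <- X[, j] <= s$threshold
  list(kind = "internal", ion = colnames(X)[j], threshold = s$threshold,
       gain_ratio = s$gain_ratio, counts = node_counts(y),
       left = grow_node(X[go_left, , drop = FALSE], y[go_left], cfg),
       right = grow_node(X[!go_left, , drop = FALSE], y[!go_left], cfg))
}

# pessimistic error count: N * upper confidence bound of the binomial error
# rate at confidence cf (Clopper-Pearson style upper bound)
pessimistic_errors <- function(errors, n, cf) {
  if (n == 0) return(0)
  if (errors >= n) return(n)
  n * qbeta(1 - cf, errors + 1, n - errors)
}

node_train_errors <- function(node) {
  if (node$kind == "leaf") {
    sum(node$counts) - node$counts[[node$class]]
  } else {
    node_train_errors(node$left) + node_train_errors(node$right)
  }
}

subtree_pessimistic <- function(node, cf) {
  if (node$kind == "leaf") {
    n <- sum(node$counts)
    pessimistic_errors(n - node$counts[[node$class]], n, cf)
  } else {
    subtree_pessimistic(node$left, cf) + subtree_pessimistic(node$right, cf)
  }
}

prune_node <- function(node, cf) {
  if (node$kind == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  cnt <- node$counts
  maj <- if (cnt[["case"]] >= cnt[["control"]]) "case" else "control"
  n <- sum(cnt)
  as_leaf_err <- pessimistic_errors(n - cnt[[maj]], n, cf)
  if (as_leaf_err <= subtree_pessimistic(node, cf) + 1e-9) {
    return(list(kind = "leaf", class = maj, counts = cnt))
  }
  node
}

tree_size <- function(node) {
  if (node$kind == "leaf") 1L else 1L + tree_size(node$left) + tree_size(node$right)
}

#' Predict classes from a fitted tree
#'
#' Samples are routed left when the split ion's intensity is `<=` the node
#' threshold.  Every ion used by the tree must be present in `newdata`.
#'
#' @param object A `"c45"` fit.
#' @param newdata Numeric matrix (samples x ions) or a named numeric vector
#'   for a single sample.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.c45 <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  route <- function(node, x) {
    if (node$kind == "leaf") return(node$class)
    if (!node$ion %in% names(x)) {
      ms_stop(sprintf("sample is missing ion '%s'", node$ion), "argument_error")
    }
    if (x[[node$ion]] <= node$threshold) route(node$left, x)
    else route(node$right, x)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    route(object$root, setNames(as.numeric(newdata[i, ]), colnames(newdata)))
  }, character(1))
}

#' Printable rule listing of a tree
#'
#' Indented listing in the style of J48 output; thresholds carry full
#' precision so that [parse_c45_text()] reproduces an identically
#' predicting tree.
#'
#' @param tree A `"c45"` fit.
#' @return Character vector of listing lines.
#' @export
to_text <- function(tree) {
  lines <- character(0)
  walk <- function(node, depth) {
    pre <- paste(rep("|   ", depth), collapse = "")
    if (node$kind == "leaf") {
      lines <<- c(lines, sprintf("%s-> %s (%d/%d)", pre, node$class,
                                 sum(node$counts),
                                 sum(node$counts) - node$counts[[node$class]]))
      return(invisible())
    }
    thr <- gsub(" ", "", formatC(node$threshold, format = "g", digits = 17))
    lines <<- c(lines, sprintf("%s%s <= %s", pre, node$ion, thr))
    walk(node$left, depth + 1L)
    lines <<- c(lines, sprintf("%s%s > %s", pre, node$ion, thr))
    walk(node$right, depth + 1L)
  }
  walk(tree$root, 0L)
  lines
}

#' Parse a rule listing back into a tree
#'
#' Inverse of [to_text()]: the returned object predicts identically to the
#' tree that produced the listing.
#'
#' @param lines Character vector from [to_text()].
#' @return A `"c45"` object (leaf counts are restored from the listing).
#' @export
parse_c45_text <- function(lines) {
  pos <- 1L
  depth_of <- function(line) {
    d <- 0L
    while (startsWith(line, "|   ")) {
      line <- substring(line, 5L)
      d <- d + 1L
    }
    d
  }
  strip <- function(line) gsub("^(\\|   )*", "", line)
  parse_node <- function(depth) {
    line <- strip(lines[pos])
    if (startsWith(line, "-> ")) {
      m <- regmatches(line, regexec("^-> (case|control) \\((\\d+)/(\\d+)\\)$", line))[[1L]]
      pos <<- pos + 1L
      n <- as.integer(m[3L])
      err <- as.integer(m[4L])
      cnt <- if (m[2L] == "case") c(case = n - err, control = err)
      else c(case = err, control = n - err)
      return(list(kind = "leaf", class = m[2L], counts = cnt))
    }
    m <- regmatches(line, regexec("^(.+) <= (.+)$", line))[[1L]]
    ion <- m[2L]
    thr <- as.numeric(m[3L])
    pos <<- pos + 1L
    left <- parse_node(depth + 1L)
    pos <<- pos + 1L  # skip the "> threshold" line
    right <- parse_node(depth + 1L)
    list(kind = "internal", ion = ion, threshold = thr,
         counts = left$counts + right$counts, left = left, right = right)
  }
  root <- parse_node(0L)
  ions <- unique(unlist(collect_ions(root)))
  structure(list(root = root, ions = ions, cfg = tree_config(),
                 n_train = sum(root$counts)),
            class = "c45")
}

collect_ions <- function(node) {
  if (node$kind == "leaf") return(character(0))
  c(node$ion, collect_ions(node$left), collect_ions(node$right))
}

#' @export
print.c45 <- function(x, ...) {
  cat(sprintf("Gain-ratio decision tree: %d node(s), %d leaf/leaves, %d training samples\n",
              tree_size(x$root), (tree_size(x$root) + 1L) %/% 2L, x$n_train))
  cat(to_text(x), sep = "\n")
  invisible(x)
}

#' @export
summary.c45 <- function(object, ...) {
  print(object)
  cat(sprintf("Training error: %d/%d\n", node_train_errors(object$root),
              object$n_train))
  invisible(object)
}
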