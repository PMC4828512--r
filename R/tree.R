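#' Fit a weighted decision-tree weak learner
#'
#' Grows a depth-limited CART-style binary tree on weighted Gini impurity.
#' Leaf confidences are the weighted class fractions in the leaf, so the
#' resulting hypothesis h satisfies h(x, +1) + h(x, -1) = 1 for every x
#' (confidence-rated, complementary). Thresholds are midpoints between
#' consecutive distinct values; ties between equally good splits are broken
#' by the lowest feature index, then the lowest threshold.
#'
#' For nodes larger than \code{exact_cutoff} rows and when a binned context
#' is supplied (as done internally by \code{\link{rusboost}} on large
#' training sets), the split search uses precomputed quantile-bin histograms
#' with thresholds at bin edges.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y labels in \{-1, +1\}.
#' @param weights nonnegative example weights; default uniform. They are
#'   normalised internally.
#' @param max_depth maximum tree depth (0 = single leaf; 1 = stump).
#' @param idx optional integer subset of rows to train on (1-based);
#'   \code{weights} must align with \code{idx} when given.
#' @param binctx optional binning context from \code{make_bin_context}.
#' @param exact_cutoff node size above which the histogram search is used.
#' @return an object of class \code{boost_tree}.
#' @export
fit_weak_learner <- function(x, y, weights = NULL, max_depth = 3L,
                             idx = NULL, binctx = NULL,
                             exact_cutoff = 4096L) {
  if (!is.matrix(x) || !is.double(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
  }
  if (nrow(x) == 0L) stop("empty dataset")
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be in {-1, +1}")
  if (is.null(idx)) idx <- seq_len(nrow(x))
  if (is.null(weights)) weights <- rep(1 / length(idx), length(idx))
  if (length(weights) != length(idx))
    stop("weights must align with the (subset of the) dataset")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and nonnegative")
  weights <- weights / sum(weights)
  if (is.null(binctx)) {
    xbin <- matrix(raw(0), 0L, 0L)
    edges <- vector("list", ncol(x))
    for (f in seq_along(edges)) edges[[f]] <- numeric(0)
  } else {
    xbin <- binctx$xbin
    edges <- binctx$edges
  }
  tree <- fit_tree_cpp(x, y, as.integer(idx), as.numeric(weights),
                       as.integer(max_depth), xbin, edges,
                       as.integer(exact_cutoff))
  structure(list(tree = tree, p = ncol(x), max_depth = max_depth),
            class = "boost_tree")
}

#' Precompute quantile bins for the histogram split search
#'
#' @param x numeric feature matrix.
#' @param n_bins maximum number of bins per feature.
#' @param sample_rows number of rows sampled (without replacement) to
#'   estimate the quantile edges; uses the current RNG state.
#' @return list with \code{edges} (per-feature candidate thresholds) and
#'   \code{xbin} (raw matrix of bin codes).
#' @export
make_bin_context <- function(x, n_bins = 256L, sample_rows = 50000L) {
  n <- nrow(x)
  rows <- if (n > sample_rows) sort(sample.int(n, sample_rows)) else seq_len(n)
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- lapply(seq_len(ncol(x)), function(f) {
    q <- unique(unname(stats::quantile(x[rows, f], probs, type = 7L)))
    q[q < max(x[, f])] # the top edge would send everything left
  })
  list(edges = edges, xbin = bin_matrix_cpp(x, edges))
}

#' Evaluate a weak hypothesis
#'
#' @param object a \code{boost_tree}.
#' @param newdata feature matrix.
#' @param label the label whose confidence is requested (+1 or -1).
#' @param ... unused.
#' @return numeric vector of confidences h(x, label) in [0, 1].
#' @export
predict.boost_tree <- function(object, newdata, label = 1L, ...) {
  if (!is.matrix(newdata) || !is.double(newdata)) {
    newdata <- as.matrix(newdata)
    storage.mode(newdata) <- "double"
  }
  if (ncol(newdata) != object$p)
    stop("feature matrix has ", ncol(newdata), " columns; model expects ",
         object$p)
  conf_pos <- predict_tree_cpp(object$tree, newdata)
  if (label > 0) conf_pos else 1 - conf_pos
}

#' @export
print.boost_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$tree$feature))
  cat("Weighted decision tree:", length(x$tree$feature), "nodes,",
      n_leaf, "leaves, max depth", x$max_depth, "\n")
  invisible(x)
}
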