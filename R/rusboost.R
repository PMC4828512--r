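#' Initialize boosting weights
#'
#' Uniform starting distribution over the m training examples.
#'
#' @param m number of examples (>= 1).
#' @return numeric vector of length m, each entry 1/m.
#' @export
initialize_weights <- function(m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a positive integer")
  rep(1 / m, as.integer(m))
}

#' Random undersampling of the majority class
#'
#' Removes randomly chosen majority-class (-1) examples, uniformly and
#' without replacement, until the minority class (+1, the hippocampus)
#' makes up the fraction \code{minority_fraction} of the retained set. All
#' minority examples are always kept; if the majority count is already at or
#' below its target nothing is removed. Retained weights are renormalised to
#' sum 1.
#'
#' @param y labels in \{-1, +1\}; +1 is the minority class by convention.
#' @param weights current weight distribution over the examples.
#' @param minority_fraction target minority fraction N in (0, 1].
#' @return list with \code{indices} (retained example indices, sorted) and
#'   \code{weights} (renormalised weights aligned with \code{indices}).
#' @export
random_undersample <- function(y, weights, minority_fraction = 0.5) {
  if (minority_fraction <= 0 || minority_fraction > 1)
    stop("minority_fraction must be in (0, 1]")
  if (length(y) != length(weights))
    stop("weights must align with the dataset")
  minority <- which(y > 0)
  majority <- which(y < 0)
  if (length(minority) == 0L)
    stop("dataset has no minority (+1) examples")
  target <- round(length(minority) *
                    (1 - minority_fraction) / minority_fraction)
  keep_maj <- if (length(majority) > target)
    sample(majority, target) else majority
  idx <- sort(c(minority, keep_maj))
  w <- weights[idx]
  list(indices = idx, weights = w / sum(w))
}

#' Pseudo-loss of a confidence-rated hypothesis
#'
#' Computes the boosting round loss
#' \deqn{\epsilon_t = \tfrac12 \sum_{(i,y): y \ne y_i} D_t(i)\,
#'   (1 - h_t(x_i, y_i) + h_t(x_i, y)),}
#' which for binary labels and complementary confidences reduces to
#' \eqn{\sum_i D_t(i)(1 - h_t(x_i, y_i))}. The 1/2 factor makes an
#' uninformative hypothesis (h = 0.5 for both labels) score exactly 0.5;
#' \code{half_factor = FALSE} drops it (the literal displayed form of the
#' update family this loss derives from).
#'
#' @param hypothesis a \code{boost_tree} (or any object whose
#'   \code{predict} returns h(x, +1)).
#' @param x feature matrix.
#' @param y labels in \{-1, +1\}.
#' @param weights normalised weight distribution D_t.
#' @param half_factor include the 1/2 scaling (default TRUE).
#' @return the pseudo-loss, in [0, 1] when \code{half_factor} is TRUE.
#' @export
pseudo_loss <- function(hypothesis, x, y, weights, half_factor = TRUE) {
  if (length(y) != length(weights) || NROW(x) != length(y))
    stop("weights must align with the dataset")
  hpos <- predict(hypothesis, x, label = 1L)
  h_true <- ifelse(y > 0, hpos, 1 - hpos)
  h_wrong <- 1 - h_true
  f <- if (half_factor) 0.5 else 1
  f * sum(weights * (1 - h_true + h_wrong))
}

#' Weight-update parameter from the pseudo-loss
#'
#' \eqn{\alpha_t = \epsilon_t / (1 - \epsilon_t)}, with \eqn{\epsilon_t}
#' clipped from below at \code{eps_floor} so that a zero-loss round yields a
#' finite voting weight \eqn{\log(1/\alpha_t)}. \eqn{\alpha_t \le 1} exactly
#' when \eqn{\epsilon_t \le 1/2}.
#'
#' @param eps pseudo-loss in [0, 1).
#' @param eps_floor lower clip for eps.
#' @return alpha, a positive real.
#' @export
alpha_from_loss <- function(eps, eps_floor = 1e-10) {
  if (!is.finite(eps) || eps < 0 || eps >= 1)
    stop("eps must lie in [0, 1)")
  e <- max(eps, eps_floor)
  e / (1 - e)
}

#' Boosting weight update
#'
#' Multiplies each example weight by
#' \eqn{\alpha^{\eta \cdot \frac12 (1 + h(x_i, y_i) - h(x_i, \bar y_i))}}
#' and renormalises. With hard confidences (0/1) and \eqn{\eta = 1} this is
#' the classical piecewise rule: correctly labeled examples are multiplied
#' by \eqn{\alpha}, misclassified ones are left unchanged (hence, after
#' normalisation, upweighted when \eqn{\alpha < 1}). The learning rate
#' \eqn{\eta} shrinks the exponent only; prediction votes are unaffected.
#'
#' @param weights current distribution D_t (normalised).
#' @param h_true confidences h(x_i, y_i) assigned to the true labels.
#' @param alpha weight-update parameter (> 0).
#' @param eta learning rate in (0, 1].
#' @param h_wrong confidences on the wrong label; defaults to the
#'   complementary \code{1 - h_true}.
#' @return the renormalised distribution D_{t+1}.
#' @export
update_weights <- function(weights, h_true, alpha, eta = 1,
                           h_wrong = 1 - h_true) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  w <- weights * alpha^(eta * 0.5 * (1 + h_true - h_wrong))
  w / sum(w)
}

#' Boosted voxel classifier with random undersampling (RUSBoost)
#'
#' Fits an ensemble of confidence-rated, depth-limited decision trees by
#' boosting. Each round t: (1) optionally undersample the majority class to
#' the target minority fraction N; (2) fit the weak learner on the
#' undersampled set with its renormalised weights; (3) evaluate the
#' pseudo-loss of the hypothesis on the FULL training set under the current
#' distribution D_t; (4) set alpha_t = eps_t/(1-eps_t); (5) update and
#' renormalise the weights. Prediction aggregates
#' \eqn{\sum_t h_t(x, y) \log(1/\alpha_t)} and takes the argmax over the two
#' labels. With \code{rus = FALSE} the identical loop is the plain
#' (confidence-rated) Adaboost baseline.
#'
#' A round whose pseudo-loss reaches 0.5 is retried with a fresh undersample
#' (up to 3 attempts); if the loss stays at or above 0.5 training stops
#' early and the rounds accumulated so far are returned.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y labels in \{-1, +1\}; +1 must be present (and is treated as the
#'   minority class under undersampling).
#' @param n_rounds number of boosting rounds T.
#' @param minority_fraction target minority fraction N in (0, 1] for the
#'   per-round undersampling.
#' @param learning_rate shrinkage eta in (0, 1] applied to the weight
#'   update exponent.
#' @param max_depth weak-learner tree depth.
#' @param rus enable per-round random undersampling (FALSE = Adaboost
#'   baseline).
#' @param eps_floor lower clip for the pseudo-loss.
#' @param half_factor see \code{\link{pseudo_loss}}.
#' @param n_bins,exact_cutoff histogram split-search controls (see
#'   \code{\link{fit_weak_learner}}); binning engages only when the training
#'   set exceeds \code{exact_cutoff} rows.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the fit is reproducible in isolation.
#' @param verbose print per-round eps_t and alpha_t.
#' @return an object of class \code{rusboost}: list with \code{rounds}
#'   (each a \code{boost_tree} plus its alpha), \code{history} (per-round
#'   eps, alpha, subset size), the parameters, and the feature names.
#' @seealso \code{\link{predict.rusboost}}, \code{\link{boost_to_json}}
#' @export
rusboost <- function(x, y, n_rounds = 150L, minority_fraction = 0.5,
                     learning_rate = 0.1, max_depth = 3L, rus = TRUE,
                     eps_floor = 1e-10, half_factor = TRUE,
                     n_bins = 256L, exact_cutoff = 4096L, seed = NULL,
                     verbose = FALSE) {
  if (!is.matrix(x) || !is.double(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
  }
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be in {-1, +1}")
  if (length(unique(y)) < 2L)
    stop("dataset must contain both classes")
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(x)
  binctx <- if (m > exact_cutoff) make_bin_context(x, n_bins) else NULL

  D <- initialize_weights(m)
  rounds <- vector("list", n_rounds)
  hist_eps <- hist_alpha <- hist_n <- numeric(n_rounds)
  t_done <- 0L
  for (t in seq_len(n_rounds)) {
    eps <- Inf
    h <- NULL
    hpos <- NULL
    for (attempt in seq_len(if (rus) 3L else 1L)) {
      sub <- if (rus) random_undersample(y, D, minority_fraction)
             else list(indices = seq_len(m), weights = D)
      h_try <- fit_weak_learner(x, y, weights = sub$weights,
                                max_depth = max_depth, idx = sub$indices,
                                binctx = binctx,
                                exact_cutoff = exact_cutoff)
      hpos_try <- predict(h_try, x, label = 1L)
      h_true <- ifelse(y > 0, hpos_try, 1 - hpos_try)
      eps_try <- if (half_factor) sum(D * (1 - h_true))
                 else sum(D * 2 * (1 - h_true))
      if (eps_try < eps) {
        eps <- eps_try; h <- h_try; hpos <- hpos_try
      }
      if (eps < 0.5) break
    }
    if (eps >= 0.5) break # no learnable round left; keep what we have
    alpha <- alpha_from_loss(eps, eps_floor)
    h_true <- ifelse(y > 0, hpos, 1 - hpos)
    D <- update_weights(D, h_true, alpha, eta = learning_rate)
    t_done <- t
    rounds[[t]] <- list(tree = h, alpha = alpha)
    hist_eps[t] <- eps; hist_alpha[t] <- alpha
    hist_n[t] <- if (rus) length(sub$indices) else m
    if (verbose)
      message(sprintf("round %3d: eps = %.5f  alpha = %.5g  |S'| = %d",
                      t, eps, alpha, hist_n[t]))
  }
  structure(list(
    rounds = rounds[seq_len(t_done)],
    history = data.frame(t = seq_len(t_done), eps = hist_eps[seq_len(t_done)],
                         alpha = hist_alpha[seq_len(t_done)],
                         n_subset = hist_n[seq_len(t_done)]),
    n_rounds_requested = as.integer(n_rounds),
    minority_fraction = minority_fraction,
    learning_rate = learning_rate,
    max_depth = as.integer(max_depth),
    rus_enabled = isTRUE(rus),
    eps_floor = eps_floor,
    half_factor = isTRUE(half_factor),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    feature_names = colnames(x),
    p = ncol(x),
    call = match.call()),
    class = "rusboost")
}

#' Ensemble voting scores
#'
#' \eqn{score_y(x) = \sum_t h_t(x, y) \log(1/\alpha_t)} for both labels.
#'
#' @param model a fitted \code{\link{rusboost}} model.
#' @param x feature matrix (or single feature vector).
#' @return two-column matrix \code{(score_pos, score_neg)}.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "rusboost"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.double(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
  }
  if (ncol(x) != model$p)
    stop("feature vector length ", ncol(x), "; model expects ", model$p)
  pos <- neg <- numeric(nrow(x))
  for (r in model$rounds) {
    v <- log(1 / r$alpha)
    hp <- predict(r$tree, x, label = 1L)
    pos <- pos + hp * v
    neg <- neg + (1 - hp) * v
  }
  cbind(score_pos = pos, score_neg = neg)
}

#' Predicted labels
#'
#' Argmax of the two voting scores; an exact tie returns -1 (background),
#' biasing toward the majority class on zero evidence.
#'
#' @inheritParams predict_scores
#' @return integer vector of labels in \{-1, +1\}.
#' @export
predict_label <- function(model, x) {
  s <- predict_scores(model, x)
  unname(ifelse(s[, 1L] > s[, 2L], 1L, -1L))
}

#' Predict method for rusboost models
#'
#' @param object fitted \code{\link{rusboost}} model.
#' @param newdata feature matrix.
#' @param type \code{"class"} for labels in \{-1, +1\}, \code{"score"} for
#'   the two voting scores.
#' @param ... unused.
#' @export
predict.rusboost <- function(object, newdata,
                             type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") predict_scores(object, newdata)
  else predict_label(object, newdata)
}

#' @export
print.rusboost <- function(x, ...) {
  cat(if (x$rus_enabled) "RUSBoost" else "Adaboost (no undersampling)",
      "ensemble\n")
  cat(sprintf("  rounds: %d of %d requested; depth-%d trees; eta = %g; N = %g\n",
              length(x$rounds), x$n_rounds_requested, x$max_depth,
              x$learning_rate, x$minority_fraction))
  if (length(x$rounds))
    cat(sprintf("  pseudo-loss: first %.4f, last %.4f\n",
                x$history$eps[1L], x$history$eps[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.rusboost <- function(object, ...) {
  out <- list(n_rounds = length(object$rounds),
              requested = object$n_rounds_requested,
              rus = object$rus_enabled,
              history = object$history,
              alphas = vapply(object$rounds, `[[`, numeric(1), "alpha"))
  class(out) <- "summary.rusboost"
  out
}

#' @export
print.summary.rusboost <- function(x, ...) {
  cat("Boosted ensemble:", x$n_rounds, "rounds (requested", x$requested, ")\n")
  if (x$n_rounds) {
    cat("pseudo-loss quartiles:\n")
    print(stats::quantile(x$history$eps))
  }
  invisible(x)
}

#' @export
coef.rusboost <- function(object, ...) {
  vapply(object$rounds, function(r) log(1 / r$alpha), numeric(1))
}

# FNV-1a hash of a string, as 8 hex digits (schema fingerprinting).
# Arithmetic is kept under 2^53 by splitting the 32-bit state in half.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4L),
         format(as.hexmode(as.integer(h %% 65536)), width = 4L))
}

#' Serialize a boosted model to JSON
#'
#' Writes the full ensemble (per-round tree structure, alpha_t, parameters,
#' feature-name hash) with maximal numeric precision so that a reloaded
#' model reproduces predictions bit-exactly.
#'
#' @param model fitted \code{\link{rusboost}} model.
#' @param path optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @export
boost_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rusboost"))
  js <- jsonlite::toJSON(boost_obj(model), auto_unbox = TRUE,
                         digits = I(17), na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# plain-list form of a rusboost model, shared by the model and segmenter
# serializers
boost_obj <- function(model) {
  list(
    format = "hippoboost-rusboost-1",
    schema_hash = fnv1a(paste(model$feature_names, collapse = ",")),
    p = model$p,
    n_rounds_requested = model$n_rounds_requested,
    minority_fraction = model$minority_fraction,
    learning_rate = model$learning_rate,
    max_depth = model$max_depth,
    rus_enabled = model$rus_enabled,
    eps_floor = model$eps_floor,
    half_factor = model$half_factor,
    seed = model$seed,
    feature_names = if (is.null(model$feature_names)) character(0)
                    else model$feature_names,
    history = as.list(model$history),
    rounds = lapply(model$rounds, function(r)
      list(alpha = r$alpha, tree = r$tree$tree)))
}

#' Load a boosted model from JSON
#'
#' @param path file path or a JSON string from \code{\link{boost_to_json}}.
#' @return a \code{rusboost} model.
#' @export
boost_from_json <- function(path) {
  boost_from_obj(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

# rebuild a rusboost model from the parsed (simplifyVector = FALSE) list
boost_from_obj <- function(obj) {
  if (!identical(obj$format, "hippoboost-rusboost-1"))
    stop("not a serialized hippoboost model")
  int_vec <- function(v) vapply(v, function(e)
    if (is.null(e)) NA_integer_ else as.integer(e), integer(1))
  num_vec <- function(v) vapply(v, function(e)
    if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
  rounds <- lapply(obj$rounds, function(r) {
    tr <- list(feature = int_vec(r$tree$feature),
               threshold = num_vec(r$tree$threshold),
               left = int_vec(r$tree$left), right = int_vec(r$tree$right),
               conf_pos = num_vec(r$tree$conf_pos),
               n_node = int_vec(r$tree$n_node))
    list(tree = structure(list(tree = tr, p = obj$p,
                               max_depth = obj$max_depth),
                          class = "boost_tree"),
         alpha = r$alpha)
  })
  fn <- unlist(obj$feature_names)
  structure(list(
    rounds = rounds,
    history = as.data.frame(lapply(obj$history, num_vec)),
    n_rounds_requested = as.integer(obj$n_rounds_requested),
    minority_fraction = obj$minority_fraction,
    learning_rate = obj$learning_rate,
    max_depth = as.integer(obj$max_depth),
    rus_enabled = obj$rus_enabled,
    eps_floor = obj$eps_floor,
    half_factor = obj$half_factor,
    seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
    feature_names = if (length(fn)) fn else NULL,
    p = as.integer(obj$p),
    call = NULL), class = "rusboost")
}
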