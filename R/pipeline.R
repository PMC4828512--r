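#' Assemble a voxelwise training set
#'
#' Selects \code{m} training subjects from a cohort (uniformly at random,
#' RNG-driven), builds the rVOI from their masks, and extracts the feature
#' matrix at every rVOI voxel of every training image. Labels are +1 where
#' the subject's manual mask is set, -1 elsewhere, so the sample count is
#' exactly \code{m * nrow(rvoi$voxels)}.
#'
#' @param cohort a \code{\link{generate_cohort}} result, or any list with a
#'   \code{subjects} element of (id, volume, mask) entries.
#' @param m number of training subjects (1 <= m <= cohort size).
#' @param schema a \code{\link{feature_schema}}.
#' @param dilation_kernel structuring element for \code{\link{build_rvoi}}.
#' @param subjects optional explicit subject indices (overrides the random
#'   selection; used by \code{\link{cross_validate}}).
#' @return list with \code{x} (feature matrix), \code{y} (labels),
#'   \code{rvoi}, \code{schema}, \code{subject_idx} and \code{subject_ids}.
#' @export
assemble_training_set <- function(cohort, m, schema = feature_schema(),
                                  dilation_kernel = c(2L, 2L, 2L),
                                  subjects = NULL) {
  subs <- cohort$subjects
  if (is.null(subjects)) {
    if (m < 1L || m > length(subs))
      stop("m must be between 1 and the cohort size (", length(subs), ")")
    subjects <- sample.int(length(subs), m)
  }
  train <- subs[subjects]
  rvoi <- build_rvoi(lapply(train, `[[`, "mask"), dilation_kernel)
  xs <- vector("list", length(train))
  ys <- vector("list", length(train))
  lin <- rvoi$voxels[, 1L] + rvoi$shape[1L] *
    (rvoi$voxels[, 2L] + rvoi$shape[2L] * rvoi$voxels[, 3L]) + 1L
  for (i in seq_along(train)) {
    xs[[i]] <- extract_feature_matrix(train[[i]]$volume, rvoi$voxels, schema)
    ys[[i]] <- ifelse(train[[i]]$mask[lin] > 0, 1L, -1L)
  }
  list(x = do.call(rbind, xs), y = unlist(ys), rvoi = rvoi,
       schema = schema, subject_idx = subjects,
       subject_ids = vapply(train, `[[`, character(1), "id"))
}

#' Train a hippocampus segmenter
#'
#' End-to-end training: subject selection, rVOI construction, feature
#' extraction and boosted-classifier fitting. The default boosting
#' operating point is T = 150 rounds, learning rate 0.1, minority target
#' N = 50 percent, depth-3 trees.
#'
#' @inheritParams assemble_training_set
#' @param boost_params named list of overrides passed to
#'   \code{\link{rusboost}} (e.g. \code{n_rounds}, \code{learning_rate},
#'   \code{rus}).
#' @param voxel_subsample optional fraction in (0, 1] of training voxels to
#'   keep (uniform random); the default (1) trains on all rVOI voxels, and
#'   any subsampling is recorded in the provenance.
#' @param seed optional seed for the whole training run.
#' @return an object of class \code{hipposeg}: the rVOI, the schema, the
#'   fitted \code{rusboost} ensemble and a provenance record.
#' @export
train_segmenter <- function(cohort, m, boost_params = list(),
                            schema = feature_schema(),
                            dilation_kernel = c(2L, 2L, 2L),
                            voxel_subsample = 1,
                            subjects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- assemble_training_set(cohort, m, schema, dilation_kernel, subjects)
  x <- ts$x; y <- ts$y
  if (voxel_subsample < 1) {
    keep <- sort(sample.int(nrow(x), max(2L, round(voxel_subsample * nrow(x)))))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  defaults <- list(n_rounds = 150L, minority_fraction = 0.5,
                   learning_rate = 0.1, max_depth = 3L, rus = TRUE)
  args <- utils::modifyList(defaults, boost_params)
  boost <- do.call(rusboost, c(list(x = x, y = y), args))
  structure(list(
    rvoi = ts$rvoi, schema = ts$schema, boost = boost,
    provenance = list(seed = if (is.null(seed)) NA_integer_ else seed,
                      subject_ids = ts$subject_ids,
                      subject_idx = ts$subject_idx,
                      n_samples = length(y),
                      voxel_subsample = voxel_subsample,
                      boost_params = args)),
    class = "hipposeg")
}

#' @export
print.hipposeg <- function(x, ...) {
  cat("Hippocampus segmenter\n")
  print(x$rvoi)
  print(x$boost)
  cat("  trained on:", paste(x$provenance$subject_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Segment a volume
#'
#' Classifies every rVOI voxel of a co-registered volume with the boosted
#' ensemble; voxels outside the rVOI are background by construction, so the
#' predicted mask is always contained in the rVOI.
#'
#' @param model a \code{\link{train_segmenter}} result.
#' @param volume 3D array on the model's VOI grid.
#' @return 0/1 integer mask array.
#' @export
segment_image <- function(model, volume) {
  stopifnot(inherits(model, "hipposeg"))
  if (!identical(dim(volume), model$rvoi$shape))
    stop("volume grid ", paste(dim(volume), collapse = "x"),
         " does not match the model grid ",
         paste(model$rvoi$shape, collapse = "x"))
  x <- extract_feature_matrix(volume, model$rvoi$voxels, model$schema)
  lab <- predict_label(model$boost, x)
  out <- array(0L, model$rvoi$shape)
  out[model$rvoi$mask] <- as.integer(lab > 0)
  out
}

#' @rdname segment_image
#' @param object a \code{hipposeg} model.
#' @param newdata 3D array to segment.
#' @param ... unused.
#' @export
predict.hipposeg <- function(object, newdata, ...) {
  segment_image(object, newdata)
}

#' Repeated random-split cross-validation
#'
#' Each round draws a fresh partition (m training subjects, the rest as
#' test), trains a segmenter and evaluates all four overlap metrics on the
#' test subjects; per-metric means and standard deviations are reported
#' across rounds, together with the mean rVOI size.
#'
#' @inheritParams train_segmenter
#' @param n_rounds number of cross-validation rounds.
#' @param seed seed controlling partitions and training.
#' @return an object of class \code{hipposeg_cv}: \code{summary} (data
#'   frame metric/mean/sd), \code{per_round} (round x metric data frame),
#'   \code{mean_rvoi_size} and the call parameters.
#' @export
cross_validate <- function(cohort, m, n_rounds = 10L, boost_params = list(),
                           schema = feature_schema(),
                           dilation_kernel = c(2L, 2L, 2L),
                           voxel_subsample = 1, seed = 1L) {
  n <- length(cohort$subjects)
  if (m >= n) stop("m must be smaller than the cohort size")
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  set.seed(seed)
  metric_names <- c("dice", "precision", "recall", "relative_overlap")
  per_round <- matrix(NA_real_, n_rounds, length(metric_names),
                      dimnames = list(NULL, metric_names))
  rvoi_sizes <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    train_idx <- sample.int(n, m)
    test_idx <- setdiff(seq_len(n), train_idx)
    model <- train_segmenter(cohort, m, boost_params, schema,
                             dilation_kernel, voxel_subsample,
                             subjects = train_idx)
    rvoi_sizes[r] <- nrow(model$rvoi$voxels)
    vals <- sapply(test_idx, function(i) {
      rep_ <- overlap_metrics(segment_image(model, cohort$subjects[[i]]$volume),
                              cohort$subjects[[i]]$mask)
      unlist(rep_[metric_names])
    })
    per_round[r, ] <- rowMeans(vals)
  }
  structure(list(
    summary = data.frame(metric = metric_names,
                         mean = colMeans(per_round),
                         sd = apply(per_round, 2L, stats::sd),
                         row.names = NULL),
    per_round = as.data.frame(per_round),
    mean_rvoi_size = mean(rvoi_sizes),
    m = m, n_rounds = n_rounds, seed = seed),
    class = "hipposeg_cv")
}

#' @export
print.hipposeg_cv <- function(x, ...) {
  cat(sprintf("Cross-validation: %d rounds, m = %d training subjects\n",
              x$n_rounds, x$m))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-17s %.4f +- %.4f\n", s$metric[i], s$mean[i],
                if (is.na(s$sd[i])) 0 else s$sd[i]))
  cat(sprintf("  mean rVOI size: %.0f voxels\n", x$mean_rvoi_size))
  invisible(x)
}

#' Serialize a trained segmenter to JSON
#'
#' Self-contained artifact: the boosted ensemble, the rVOI voxel list and
#' the schema parameters. Reload with \code{\link{load_segmenter}};
#' reloaded models reproduce segmentations exactly.
#'
#' @param model a \code{hipposeg} model.
#' @param path output file (or \code{NULL} for the JSON string).
#' @export
save_segmenter <- function(model, path = NULL) {
  stopifnot(inherits(model, "hipposeg"))
  obj <- list(
    format = "hippoboost-segmenter-1",
    shape = model$rvoi$shape,
    rvoi_voxels = unname(model$rvoi$voxels),
    schema = list(haar_scales = attr(model$schema, "haar_scales"),
                  haralick_sizes = attr(model$schema, "haralick_sizes"),
                  glcm_levels = attr(model$schema, "glcm_levels"),
                  gradient_dists = attr(model$schema, "gradient_dists")),
    provenance = model$provenance,
    boost = boost_obj(model$boost))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "hippoboost-segmenter-1"))
    stop("not a serialized hippoboost segmenter")
  shape <- as.integer(unlist(obj$shape))
  vox <- do.call(rbind, lapply(obj$rvoi_voxels, function(v)
    as.integer(unlist(v))))
  colnames(vox) <- c("x", "y", "z")
  mask <- array(FALSE, shape)
  mask[vox[, 1L] + shape[1L] * (vox[, 2L] + shape[2L] * vox[, 3L]) + 1L] <- TRUE
  schema <- feature_schema(
    haar_scales = as.integer(unlist(obj$schema$haar_scales)),
    haralick_sizes = as.integer(unlist(obj$schema$haralick_sizes)),
    glcm_levels = as.integer(obj$schema$glcm_levels),
    gradient_dists = as.integer(unlist(obj$schema$gradient_dists)))
  boost <- boost_from_obj(obj$boost)
  structure(list(
    rvoi = structure(list(mask = mask, voxels = vox, shape = shape),
                     class = "rvoi"),
    schema = schema,
    boost = boost,
    provenance = obj$provenance), class = "hipposeg")
}
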