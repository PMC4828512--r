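#' Segmentation overlap metrics
#'
#' Voxel-count agreement between a predicted and a reference (manual)
#' binary mask: Dice = 2|A&B| / (|A|+|B|); Precision = TP/(TP+FP), 0 when
#' the prediction is empty; Recall = TP/(TP+FN); Relative Overlap (Jaccard)
#' = |A&B| / |A|B|. Dice and relative overlap are linked by
#' Dice = 2 RO / (1 + RO).
#'
#' @param pred predicted binary mask (3D array or logical/0-1 vector).
#' @param truth reference mask on the same grid; must be non-empty.
#' @return an object of class \code{metrics_report}: list with the counts
#'   (TP, FP, FN, TN) and the four metrics.
#' @export
overlap_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      length(pred) != length(truth))
    stop("masks are not on a common grid: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  p <- pred > 0; t_ <- truth > 0
  if (!any(t_)) stop("reference mask is empty")
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  tn <- length(p) - tp - fp - fn
  inter <- tp; uni <- tp + fp + fn
  structure(list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    dice = if (tp + fp + fn > 0) 2 * inter / (2 * tp + fp + fn) else 1,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = tp / (tp + fn),
    relative_overlap = if (uni > 0) inter / uni else 1),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f | Precision %.4f | Recall %.4f | R.O. %.4f\n",
              x$dice, x$precision, x$recall, x$relative_overlap))
  cat(sprintf("counts: TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Agreement between automated and manual volumes
#'
#' Pearson correlation and the ordinary least-squares line of the manual
#' volumes regressed on the automated ones.
#'
#' @param auto_volumes automated volumes (one per subject).
#' @param manual_volumes manual volumes, same length (>= 3).
#' @return list with \code{pearson_r}, \code{slope}, \code{intercept} and
#'   \code{n}.
#' @export
volume_agreement <- function(auto_volumes, manual_volumes) {
  if (length(auto_volumes) != length(manual_volumes) ||
      length(auto_volumes) < 3L)
    stop("need two equal-length volume lists with at least 3 entries")
  if (stats::var(auto_volumes) == 0 || stats::var(manual_volumes) == 0)
    stop("volumes have zero variance")
  r <- stats::cor(auto_volumes, manual_volumes)
  slope <- stats::cov(auto_volumes, manual_volumes) /
    stats::var(auto_volumes)
  intercept <- mean(manual_volumes) - slope * mean(auto_volumes)
  list(pearson_r = r, slope = slope, intercept = intercept,
       n = length(auto_volumes))
}

#' Paired two-sided sign test
#'
#' Exact binomial test of the null hypothesis that paired differences come
#' from a continuous distribution with zero median. Exact zero differences
#' are dropped (the classical convention); the two-sided p-value is twice
#' the smaller tail of Binomial(n, 1/2) on the count of positive signs,
#' capped at 1.
#'
#' @param differences numeric vector of paired differences.
#' @return the p-value.
#' @export
sign_test <- function(differences) {
  d <- differences[differences != 0]
  if (length(d) == 0L)
    stop("all differences are zero; the sign test is undefined")
  n <- length(d)
  k <- sum(d > 0)
  p <- 2 * min(stats::pbinom(k, n, 0.5),
               stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
  min(p, 1)
}
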