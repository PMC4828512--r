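# --- synthetic 3D phantoms -------------------------------------------------
# The phantom is a statistical stand-in for a peri-hippocampal VOI, not an
# anatomical simulation: a compact, irregular minority-class structure with
# textured tissue intensities, smooth inhomogeneity and additive noise, with
# across-subject shape and volume variability.

# Separable box blur (repeated `passes` times along each axis), used to make
# smooth random fields. Edge handling: renormalised running mean.
box_blur3 <- function(a, width = 5L, passes = 2L) {
  d <- dim(a)
  k <- rep(1 / width, width)
  blur1 <- function(m) {
    # m: matrix, smooth down columns with edge renormalisation
    n <- nrow(m)
    cs <- apply(m, 2L, cumsum)
    h <- (width - 1L) %/% 2L
    lo <- pmax(seq_len(n) - h - 1L, 0L)
    hi <- pmin(seq_len(n) + h, n)
    cnt <- hi - lo
    top <- cs[hi, , drop = FALSE]
    bot <- rbind(0, cs)[lo + 1L, , drop = FALSE]
    (top - bot) / cnt
  }
  for (pass in seq_len(passes)) {
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      a <- aperm(a, perm)
      da <- dim(a)
      dim(a) <- c(da[1L], da[2L] * da[3L])
      a <- blur1(a)
      dim(a) <- da
      a <- aperm(a, order(perm))
    }
  }
  a
}

smooth_noise_field <- function(shape, width = 7L, passes = 2L) {
  f <- array(stats::rnorm(prod(shape)), shape)
  f <- box_blur3(f, width, passes)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# Single-component check by vectorised flood fill (6-connectivity).
mask_connected <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  inmask <- logical(n); inmask[idx] <- TRUE
  visited <- logical(n)
  frontier <- idx[1L]
  visited[frontier] <- TRUE
  sx <- 1L; sy <- d[1L]; sz <- d[1L] * d[2L]
  coords <- arrayInd(idx, d)
  # strides are safe because masks are strictly interior (checked by caller)
  while (length(frontier)) {
    nb <- c(frontier + sx, frontier - sx, frontier + sy, frontier - sy,
            frontier + sz, frontier - sz)
    nb <- nb[nb >= 1L & nb <= n]
    nb <- nb[inmask[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  sum(visited) == length(idx)
}

mask_touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[c(1L, d[1L]), , ]) || any(mask[, c(1L, d[2L]), ]) ||
    any(mask[, , c(1L, d[3L])])
}

#' Phantom cohort specification
#'
#' Parameters of the synthetic peri-hippocampal VOI generator. Defaults
#' describe a 50 x 60 x 60 grid with an irregular ellipsoidal foreground
#' occupying roughly 3-9 percent of the grid (comfortably the minority
#' class), a foreground/background contrast of 40 intensity units against
#' voxel noise of standard deviation 10, tissue texture of amplitude 8, a
#' smooth polynomial bias field of amplitude 10, and subject-level size
#' scaling spanning roughly a factor 2 in volume together with a few voxels
#' of residual translation - the across-subject spread expected of a mixed
#' normal/MCI/Alzheimer cohort after affine registration.
#'
#' @param shape grid extent.
#' @param semi_axes base ellipsoid semi-axes in voxels.
#' @param center ellipsoid centre (defaults to the grid centre).
#' @param deform_amp amplitude of the smooth random deformation of the
#'   implicit surface (relative units; 0 disables).
#' @param translate_max maximum uniform random translation per axis
#'   (voxels).
#' @param vol_scale_range range of the subject-level linear scale factor,
#'   within (0.5, 1.5).
#' @param fg_mean,bg_mean mean foreground / background intensities.
#' @param texture_amp amplitude of the smooth tissue texture fields.
#' @param bias_amp amplitude of the low-order polynomial bias field.
#' @param noise_sd standard deviation of the additive voxelwise Gaussian
#'   noise.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(50L, 60L, 60L),
                         semi_axes = c(11, 15, 13),
                         center = NULL,
                         deform_amp = 0.25,
                         translate_max = 4,
                         vol_scale_range = c(0.85, 1.18),
                         fg_mean = 140, bg_mean = 100,
                         texture_amp = 8, bias_amp = 10, noise_sd = 10) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape - 1) / 2
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(semi_axes) == 3L, all(semi_axes > 0),
            all(semi_axes < shape / 2),
            noise_sd >= 0, texture_amp >= 0, bias_amp >= 0,
            vol_scale_range[1L] > 0.5, vol_scale_range[2L] < 1.5,
            vol_scale_range[1L] <= vol_scale_range[2L])
  structure(list(shape = shape, semi_axes = semi_axes, center = center,
                 deform_amp = deform_amp, translate_max = translate_max,
                 vol_scale_range = vol_scale_range, fg_mean = fg_mean,
                 bg_mean = bg_mean, texture_amp = texture_amp,
                 bias_amp = bias_amp, noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Generate one synthetic phantom
#'
#' Draws a subject: the ground-truth mask is a randomly scaled, translated
#' and smoothly deformed ellipsoid (implicit surface plus a low-frequency
#' random field); the image is background plus a foreground offset on the
#' mask, independent smooth texture fields per tissue, a low-order
#' polynomial bias field and voxelwise Gaussian noise. Masks that touch the
#' grid boundary or break into several components are regenerated (up to 10
#' tries). Uses the current RNG state; seed the RNG for reproducibility.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{volume} (3D array), \code{mask} (0/1 integer
#'   array) and \code{true_volume} (foreground voxel count).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  xs <- seq_len(d[1L]) - 1; ys <- seq_len(d[2L]) - 1; zs <- seq_len(d[3L]) - 1
  X <- array(rep(xs, times = d[2L] * d[3L]), d)
  Y <- array(rep(rep(ys, each = d[1L]), times = d[3L]), d)
  Z <- array(rep(zs, each = d[1L] * d[2L]), d)

  mask <- NULL
  for (try in 1:10) {
    s <- stats::runif(1, spec$vol_scale_range[1L], spec$vol_scale_range[2L])
    ctr <- spec$center + stats::runif(3, -spec$translate_max,
                                      spec$translate_max)
    ax <- spec$semi_axes * s
    f <- 1 - ((X - ctr[1L]) / ax[1L])^2 - ((Y - ctr[2L]) / ax[2L])^2 -
      ((Z - ctr[3L]) / ax[3L])^2
    if (spec$deform_amp > 0)
      f <- f + spec$deform_amp * smooth_noise_field(d)
    cand <- f > 0
    if (!mask_touches_boundary(cand) && mask_connected(cand)) {
      mask <- cand
      break
    }
  }
  if (is.null(mask))
    stop("could not generate an interior, connected mask in 10 tries")

  vol <- array(spec$bg_mean, d)
  vol[mask] <- spec$fg_mean
  if (spec$texture_amp > 0) {
    tex_bg <- smooth_noise_field(d)
    tex_fg <- smooth_noise_field(d)
    vol <- vol + spec$texture_amp * ifelse(mask, tex_fg, tex_bg)
  }
  if (spec$bias_amp > 0) {
    xn <- 2 * X / (d[1L] - 1) - 1
    yn <- 2 * Y / (d[2L] - 1) - 1
    zn <- 2 * Z / (d[3L] - 1) - 1
    cf <- stats::runif(9, -1, 1)
    vol <- vol + spec$bias_amp *
      (cf[1] * xn + cf[2] * yn + cf[3] * zn + cf[4] * xn^2 + cf[5] * yn^2 +
         cf[6] * zn^2 + cf[7] * xn * yn + cf[8] * xn * zn + cf[9] * yn * zn)
  }
  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)

  list(volume = vol, mask = array(as.integer(mask), d),
       true_volume = sum(mask))
}

#' Generate a phantom cohort
#'
#' @param n number of subjects.
#' @param spec a \code{\link{phantom_spec}} shared by all subjects.
#' @param seed cohort seed; subject-level seeds are derived from it so the
#'   cohort (and its true-volume table) is fully reproducible.
#' @return an object of class \code{phantom_cohort}: list with
#'   \code{subjects} (each: id, volume, mask, true_volume), \code{spec},
#'   \code{seed} and \code{true_volumes} (data frame).
#' @export
generate_cohort <- function(n, spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    ph <- generate_phantom(spec)
    subjects[[i]] <- list(id = sprintf("phantom%03d", i),
                          volume = ph$volume, mask = ph$mask,
                          true_volume = ph$true_volume)
  }
  structure(list(
    subjects = subjects, spec = spec, seed = seed,
    true_volumes = data.frame(
      id = vapply(subjects, `[[`, character(1), "id"),
      true_volume = vapply(subjects, `[[`, numeric(1), "true_volume"))),
    class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tv <- x$true_volumes$true_volume
  cat("Phantom cohort:", length(x$subjects), "subjects on a",
      paste(x$spec$shape, collapse = " x "), "grid\n")
  cat(sprintf("  true volumes: %d-%d voxels (mean %.0f, cv %.1f%%)\n",
              min(tv), max(tv), mean(tv), 100 * stats::sd(tv) / mean(tv)))
  invisible(x)
}
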