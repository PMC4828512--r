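#' Peri-hippocampal VOI box
#'
#' Describes the fixed crop applied to a co-registered whole volume. The
#' default shape is 50 x 60 x 60 (180000 voxels).
#'
#' @param origin 0-based integer triple: low corner of the box in the parent
#'   grid.
#' @param shape box extent (nx, ny, nz).
#' @param side \code{"left"} or \code{"right"} hemisphere tag.
#' @return an object of class \code{voi_box}.
#' @export
voi_box <- function(origin = c(0L, 0L, 0L), shape = c(50L, 60L, 60L),
                    side = c("left", "right")) {
  side <- match.arg(side)
  origin <- as.integer(origin); shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(shape) == 3L, all(shape > 0L),
            all(origin >= 0L))
  structure(list(origin = origin, shape = shape, side = side),
            class = "voi_box")
}

#' Crop a VOI from a volume
#'
#' @param volume 3D numeric array (the co-registered scan).
#' @param box a \code{\link{voi_box}}.
#' @return the cropped subvolume (3D array of \code{prod(box$shape)}
#'   voxels).
#' @export
extract_voi <- function(volume, box) {
  stopifnot(inherits(box, "voi_box"), is.array(volume),
            length(dim(volume)) == 3L)
  d <- dim(volume)
  hi <- box$origin + box$shape
  if (any(hi > d))
    stop("VOI box [", paste(box$origin, collapse = ","), "]+[",
         paste(box$shape, collapse = ","), "] exceeds volume extent [",
         paste(d, collapse = ","), "]")
  volume[box$origin[1L] + seq_len(box$shape[1L]),
         box$origin[2L] + seq_len(box$shape[2L]),
         box$origin[3L] + seq_len(box$shape[3L]), drop = FALSE]
}

# Binary dilation by a rectangular structuring element whose offsets run
# 0 .. k-1 along each axis (anchored at the low-index corner): a set voxel v
# turns on v + offset for every offset.
dilate_mask <- function(mask, kernel) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in 0:(kernel[1L] - 1L))
    for (dy in 0:(kernel[2L] - 1L))
      for (dz in 0:(kernel[3L] - 1L)) {
        sx <- seq_len(d[1L] - dx); sy <- seq_len(d[2L] - dy)
        sz <- seq_len(d[3L] - dz)
        out[sx + dx, sy + dy, sz + dz] <-
          out[sx + dx, sy + dy, sz + dz] | (mask[sx, sy, sz] > 0)
      }
  out
}

#' Build the reduced VOI (rVOI) from training masks
#'
#' The voxelwise logical OR of the training hippocampus masks, dilated by a
#' small cubic structuring element (default 2 x 2 x 2, anchored at its
#' low-index corner, so a single voxel dilates to the 2^3 cube towards
#' increasing indices). Classification is restricted to the rVOI: voxels
#' outside it are definitely background, while the added shell admits test
#' hippocampi extending slightly beyond the training bounding region.
#'
#' @param training_masks list of binary 3D arrays on the common VOI grid.
#' @param dilation_kernel integer triple, the structuring element size; a
#'   unit kernel (1,1,1) is the identity.
#' @return an object of class \code{rvoi}: list with \code{mask} (logical
#'   array), \code{voxels} (0-based index triples in raster order, x
#'   fastest) and \code{shape}.
#' @export
build_rvoi <- function(training_masks, dilation_kernel = c(2L, 2L, 2L)) {
  if (!is.list(training_masks) || length(training_masks) == 0L)
    stop("need at least one training mask")
  d <- dim(training_masks[[1L]])
  stopifnot(length(d) == 3L, length(dilation_kernel) == 3L,
            all(dilation_kernel >= 1L))
  un <- array(FALSE, d)
  for (m in training_masks) {
    if (!identical(dim(m), d))
      stop("training masks are not on a common grid")
    un <- un | (m > 0)
  }
  if (!any(un)) stop("union of training masks is empty")
  mask <- dilate_mask(un, as.integer(dilation_kernel))
  voxels <- arrayInd(which(mask), d) - 1L
  colnames(voxels) <- c("x", "y", "z")
  structure(list(mask = mask, voxels = voxels, shape = d),
            class = "rvoi")
}

#' @export
print.rvoi <- function(x, ...) {
  cat("rVOI:", nrow(x$voxels), "voxels on a",
      paste(x$shape, collapse = " x "), "grid (",
      sprintf("%.1f%%", 100 * nrow(x$voxels) / prod(x$shape)), ")\n")
  invisible(x)
}

#' rVOI size and class balance
#'
#' @param rvoi an \code{\link{build_rvoi}} result.
#' @param training_masks the masks it was built from.
#' @return list with \code{size} (number of rVOI voxels) and
#'   \code{minority_pct} (mean hippocampal voxel count across masks as a
#'   percentage of the rVOI size).
#' @export
rvoi_stats <- function(rvoi, training_masks) {
  stopifnot(inherits(rvoi, "rvoi"))
  size <- nrow(rvoi$voxels)
  hip <- vapply(training_masks, function(m) sum(m[rvoi$mask] > 0), numeric(1))
  list(size = size, minority_pct = 100 * mean(hip) / size)
}

#' Export rVOI voxel indices as CSV
#'
#' @param rvoi an \code{rvoi} object.
#' @param path output file.
#' @export
rvoi_to_csv <- function(rvoi, path) {
  utils::write.csv(as.data.frame(rvoi$voxels), path, row.names = FALSE)
  invisible(path)
}
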