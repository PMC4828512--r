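#' @useDynLib hippoboost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Edge-replicated padding of a 3D array.
pad_volume <- function(vol, pad) {
  d <- dim(vol)
  ix <- pmin(pmax(seq_len(d[1L] + 2L * pad) - pad, 1L), d[1L])
  iy <- pmin(pmax(seq_len(d[2L] + 2L * pad) - pad, 1L), d[2L])
  iz <- pmin(pmax(seq_len(d[3L] + 2L * pad) - pad, 1L), d[3L])
  vol[ix, iy, iz]
}

# Inclusive 3D prefix sums along all axes.
integral_volume <- function(a) {
  d <- dim(a)
  a <- apply(a, c(2L, 3L), cumsum)
  dim(a) <- d
  a <- aperm(apply(a, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  a <- aperm(apply(a, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  a
}

check_voxels <- function(voxels, shape) {
  voxels <- matrix(as.integer(round(voxels)), ncol = 3L,
                   dimnames = NULL)
  bad <- which(voxels[, 1L] < 0L | voxels[, 1L] >= shape[1L] |
               voxels[, 2L] < 0L | voxels[, 2L] >= shape[2L] |
               voxels[, 3L] < 0L | voxels[, 3L] >= shape[3L])
  if (length(bad))
    stop("voxels out of bounds at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  voxels
}

schema_pad <- function(schema) {
  max((max(attr(schema, "haar_scales")) - 1L) %/% 2L,
      (max(attr(schema, "haralick_sizes")) - 1L) %/% 2L,
      max(attr(schema, "gradient_dists")) *
        max(abs(attr(schema, "gradient_dirs"))))
}

#' Extract the per-voxel feature matrix
#'
#' Computes the full feature vector (Haar-like, Haralick, gradient, position
#' groups, in schema order) at each query voxel of a 3D volume. All
#' neighbourhood operations use edge replication at the volume border, so
#' features are defined at every voxel.
#'
#' @param volume 3D numeric array (the image, on the VOI grid).
#' @param voxels integer matrix with one 0-based (x, y, z) voxel index per
#'   row.
#' @param schema a \code{\link{feature_schema}}.
#' @return numeric matrix, \code{nrow(voxels)} x \code{nrow(schema)}, with
#'   columns named after the schema.
#' @export
extract_feature_matrix <- function(volume, voxels, schema = feature_schema()) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            inherits(schema, "feature_schema"))
  voxels <- check_voxels(voxels, dim(volume))
  nv <- nrow(voxels)
  if (nv == 0L) {
    out <- matrix(numeric(0), 0L, nrow(schema))
    colnames(out) <- schema$name
    return(out)
  }
  pad <- schema_pad(schema)
  P <- pad_volume(volume, pad)

  # Haar bank via integral volume
  scales <- attr(schema, "haar_scales")
  cat62 <- attr(schema, "haar_catalogue")
  ntpl <- nrow(cat62$templates)
  blocks <- do.call(rbind, lapply(seq_along(scales), function(k) {
    b <- haar_blocks_for_scale(cat62, scales[k])
    b[, 1L] <- b[, 1L] + (k - 1L) * ntpl
    b
  }))
  I <- integral_volume(P)
  haar <- haar_eval_cpp(I, dim(P), voxels, pad, blocks,
                        ntpl * length(scales))

  # Haralick statistics on projection subimages
  har <- haralick_eval_cpp(P, dim(P), voxels, pad,
                           attr(schema, "haralick_sizes"),
                           attr(schema, "glcm_levels"))

  # Symmetric gradients, vectorised over voxels through the padded array
  dirs <- attr(schema, "gradient_dirs")
  dists <- attr(schema, "gradient_dists")
  pd <- dim(P)
  lin <- function(dx, dy, dz) {
    (voxels[, 1L] + pad + dx) +
      pd[1L] * ((voxels[, 2L] + pad + dy) +
                  pd[2L] * (voxels[, 3L] + pad + dz)) + 1L
  }
  grad <- matrix(0, nv, nrow(dirs) * length(dists))
  col <- 1L
  for (j in seq_len(nrow(dirs))) {
    u <- dirs[j, ]
    for (d in dists) {
      grad[, col] <- P[lin(u[1L] * d, u[2L] * d, u[3L] * d)] -
                     P[lin(-u[1L] * d, -u[2L] * d, -u[3L] * d)]
      col <- col + 1L
    }
  }

  out <- cbind(haar, har, grad, voxels)
  colnames(out) <- schema$name
  out
}

#' Single-voxel feature group extractors
#'
#' Convenience accessors returning one feature group at a single voxel; they
#' share the extraction path of \code{\link{extract_feature_matrix}}.
#'
#' @param volume 3D numeric array.
#' @param voxel 0-based (x, y, z) integer triple.
#' @param schema a \code{\link{feature_schema}}.
#' @return named numeric vector (length 248, 48 or 16 for the default
#'   schema).
#' @name feature_groups
NULL

group_slice <- function(volume, voxel, schema, group) {
  m <- extract_feature_matrix(volume, matrix(voxel, 1L, 3L), schema)
  m[1L, schema$group == group]
}

#' @rdname feature_groups
#' @export
haar_features <- function(volume, voxel, schema = feature_schema())
  group_slice(volume, voxel, schema, "haar")

#' @rdname feature_groups
#' @export
haralick_features <- function(volume, voxel, schema = feature_schema())
  group_slice(volume, voxel, schema, "haralick")

#' @rdname feature_groups
#' @export
gradient_features <- function(volume, voxel, schema = feature_schema())
  group_slice(volume, voxel, schema, "gradient")

#' Voxel position features
#'
#' The 0-based (x, y, z) indices of a voxel within the VOI grid. The VOIs are
#' co-registered across subjects, so grid indices are comparable and act as a
#' spatial prior.
#'
#' @param voxel 0-based integer triple.
#' @param voi_shape grid extent (nx, ny, nz).
#' @return numeric triple.
#' @export
position_features <- function(voxel, voi_shape) {
  v <- check_voxels(matrix(voxel, 1L, 3L), voi_shape)
  c(pos_x = v[1L, 1L], pos_y = v[1L, 2L], pos_z = v[1L, 3L])
}

#' Gray level co-occurrence matrix
#'
#' Quantises a 2D subimage to \code{levels} gray levels (min-max, per
#' subimage; a constant subimage maps to level 0) and accumulates symmetric
#' co-occurrence counts at the given offset and its negation, normalised to
#' sum 1.
#'
#' @param subimage 2D numeric matrix, at least 2 pixels along the offset
#'   direction.
#' @param levels number of gray levels G.
#' @param offset integer pair (row step, column step).
#' @return G x G matrix of class \code{glcm} summing to 1.
#' @export
glcm_matrix <- function(subimage, levels = 8L, offset = c(1L, 0L)) {
  stopifnot(is.matrix(subimage), levels >= 2L, length(offset) == 2L)
  nr <- nrow(subimage); nc <- ncol(subimage)
  dr <- as.integer(offset[1L]); dc <- as.integer(offset[2L])
  if (nr - abs(dr) < 1L || nc - abs(dc) < 1L || (dr == 0L && dc == 0L) ||
      nr < 2L || nc < 2L)
    stop("subimage degenerate for offset (", dr, ",", dc, ")")
  mn <- min(subimage); mx <- max(subimage)
  q <- if (mx > mn) pmin(floor((subimage - mn) / (mx - mn) * levels),
                         levels - 1L)
       else array(0L, dim(subimage))
  P <- matrix(0, levels, levels)
  rows <- seq_len(nr - abs(dr)) + max(0L, -dr)
  cols <- seq_len(nc - abs(dc)) + max(0L, -dc)
  for (i in rows)
    for (j in cols) {
      a <- q[i, j] + 1L
      b <- q[i + dr, j + dc] + 1L
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  P <- P / sum(P)
  class(P) <- c("glcm", "matrix")
  P
}

#' Haralick statistics of a GLCM
#'
#' @param glcm a normalised gray level co-occurrence matrix (entries sum
#'   to 1).
#' @return named vector: \code{energy} = sum p_ij^2; \code{contrast} =
#'   sum (i-j)^2 p_ij; \code{correlation} = sum (i-mu_i)(j-mu_j) p_ij /
#'   (sigma_i sigma_j), 0 when either marginal is degenerate; \code{idm} =
#'   sum p_ij / (1+(i-j)^2). Indices are 0-based gray levels.
#' @export
haralick_stats <- function(glcm) {
  stopifnot(is.matrix(glcm), nrow(glcm) == ncol(glcm))
  if (abs(sum(glcm) - 1) > 1e-9)
    stop("GLCM is not normalised (entries must sum to 1)")
  G <- nrow(glcm)
  i <- matrix(0:(G - 1L), G, G)
  j <- t(i)
  energy <- sum(glcm^2)
  contrast <- sum((i - j)^2 * glcm)
  idm <- sum(glcm / (1 + (i - j)^2))
  pi_ <- rowSums(glcm); pj_ <- colSums(glcm)
  mi <- sum((0:(G - 1L)) * pi_); mj <- sum((0:(G - 1L)) * pj_)
  vi <- sum(((0:(G - 1L)) - mi)^2 * pi_)
  vj <- sum(((0:(G - 1L)) - mj)^2 * pj_)
  corr <- if (vi > 0 && vj > 0)
    sum((i - mi) * (j - mj) * glcm) / (sqrt(vi) * sqrt(vj)) else 0
  c(energy = energy, contrast = contrast, correlation = corr, idm = idm)
}

#' Write a feature matrix as headered CSV
#'
#' @param x feature matrix from \code{\link{extract_feature_matrix}}.
#' @param path output file.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
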