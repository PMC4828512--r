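#' Per-voxel feature schema
#'
#' Builds the ordered description of the 315-dimensional per-voxel feature
#' vector used for voxel classification: 248 3D Haar-like responses (62
#' templates at each of four odd cubic window sizes), 48 Haralick texture
#' statistics (four neighbourhood sizes x three mean-projection subimages x
#' four GLCM statistics), 16 symmetric directional gradients (four directions
#' x four distances) and the 3 voxel position indices.
#'
#' The group counts (248, 48, 16, 3) and the total length are asserted at
#' construction.
#'
#' @param haar_scales odd cubic window sizes for the Haar-like bank.
#' @param haralick_sizes odd neighbourhood sizes for the Haralick features.
#' @param glcm_levels number of gray levels G used for GLCM quantisation.
#' @param gradient_dirs integer matrix, one direction per row.
#' @param gradient_dists integer distances (voxels) for the gradients.
#' @return An object of class \code{feature_schema}: a data frame with
#'   columns \code{group} and \code{name} (one row per feature, in extraction
#'   order) carrying the parameter set and the Haar block catalogue as
#'   attributes.
#' @export
feature_schema <- function(haar_scales = c(3L, 5L, 7L, 9L),
                           haralick_sizes = c(3L, 5L, 7L, 9L),
                           glcm_levels = 8L,
                           gradient_dirs = rbind(x = c(1L, 0L, 0L),
                                                 y = c(0L, 1L, 0L),
                                                 z = c(0L, 0L, 1L),
                                                 diag = c(1L, 1L, 1L)),
                           gradient_dists = 1:4) {
  stopifnot(all(haar_scales %% 2L == 1L), all(haar_scales >= 3L),
            all(haralick_sizes %% 2L == 1L), all(haralick_sizes >= 3L),
            glcm_levels >= 2L, is.matrix(gradient_dirs),
            ncol(gradient_dirs) == 3L, all(gradient_dists >= 1L))

  cat62 <- haar_catalogue()
  haar <- do.call(rbind, lapply(haar_scales, function(s) {
    data.frame(group = "haar",
               name = sprintf("haar_s%d_t%02d_%s", s, seq_len(nrow(cat62$templates)),
                              cat62$templates$tag),
               stringsAsFactors = FALSE)
  }))

  dirn <- rownames(gradient_dirs)
  if (is.null(dirn)) dirn <- apply(gradient_dirs, 1L, paste0, collapse = "")
  stats <- c("energy", "contrast", "correlation", "idm")
  haralick <- expand.grid(stat = stats, proj = c("x", "y", "z"),
                          n = haralick_sizes, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  haralick <- data.frame(group = "haralick",
                         name = sprintf("haralick_n%d_p%s_%s", haralick$n,
                                        haralick$proj, haralick$stat),
                         stringsAsFactors = FALSE)
  gradient <- expand.grid(d = gradient_dists, dir = dirn,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gradient <- data.frame(group = "gradient",
                         name = sprintf("grad_%s_d%d", gradient$dir, gradient$d),
                         stringsAsFactors = FALSE)
  position <- data.frame(group = "position",
                         name = c("pos_x", "pos_y", "pos_z"),
                         stringsAsFactors = FALSE)

  schema <- rbind(haar, haralick, gradient, position)
  counts <- table(factor(schema$group,
                         levels = c("haar", "haralick", "gradient", "position")))
  if (anyDuplicated(schema$name))
    stop("feature names are not unique")
  if (length(haar_scales) == 4L && length(haralick_sizes) == 4L &&
      nrow(gradient_dirs) == 4L && length(gradient_dists) == 4L) {
    stopifnot(counts[["haar"]] == 248L, counts[["haralick"]] == 48L,
              counts[["gradient"]] == 16L, counts[["position"]] == 3L,
              nrow(schema) == 315L)
  }
  structure(schema,
            haar_scales = as.integer(haar_scales),
            haralick_sizes = as.integer(haralick_sizes),
            glcm_levels = as.integer(glcm_levels),
            gradient_dirs = gradient_dirs,
            gradient_dists = as.integer(gradient_dists),
            haar_catalogue = cat62,
            class = c("feature_schema", "data.frame"))
}

#' The 62-template Haar-like catalogue
#'
#' Enumerates, as data, the fixed set of 62 Haar-like templates applied at
#' every window scale. Blocks are axis-aligned sub-regions of the cubic
#' window, coded per axis as F (full extent), L (low half, excluding the
#' centre plane), H (high half) or C (the centre plane/line/voxel). A
#' template response is \eqn{\sum_b w_b \, \mathrm{mean}(block_b)}.
#'
#' Families: window mean (1); each of the 26 L/H/F blocks minus the window
#' mean (26); the 13 mirror-pair differences (13); the 12 single-axis-flip
#' quadrant differences (12); centre plane, centre line minus window (3+3);
#' centre voxel minus window (1); three quadrant checkerboards (3).
#'
#' @return list with \code{templates} (data frame: template id, tag) and
#'   \code{terms} (data frame: template id, per-axis codes, weight).
#' @keywords internal
#' @export
haar_catalogue <- function() {
  codes <- c("F", "L", "H")
  blocks <- expand.grid(z = codes, y = codes, x = codes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- blocks[, c("x", "y", "z")]
  blocks <- blocks[order(match(blocks$x, codes), match(blocks$y, codes),
                         match(blocks$z, codes)), , drop = FALSE]
  key <- function(b) paste0(b[1L], b[2L], b[3L])
  nonfull <- blocks[-1L, , drop = FALSE]  # drop FFF

  tags <- character(0)
  terms <- list()
  add <- function(tag, blk, w) {
    tags[[length(tags) + 1L]] <<- tag
    id <- length(tags)
    terms[[length(terms) + 1L]] <<-
      data.frame(template = id, x = blk[, 1L], y = blk[, 2L], z = blk[, 3L],
                 weight = w, stringsAsFactors = FALSE)
  }
  mirror <- function(b) vapply(b, function(a) switch(a, L = "H", H = "L", a), "")

  # 1. window mean
  add("mean", rbind(c("F", "F", "F")), 1)
  # 2. block vs window (26)
  for (i in seq_len(nrow(nonfull))) {
    b <- as.character(nonfull[i, ])
    add(paste0("blk_", key(b)), rbind(b, c("F", "F", "F")), c(1, -1))
  }
  # 3. mirror-pair differences (13)
  for (i in seq_len(nrow(nonfull))) {
    b <- as.character(nonfull[i, ])
    mb <- mirror(b)
    if (key(b) < key(mb))
      add(paste0("mir_", key(b)), rbind(b, mb), c(1, -1))
  }
  # 4. single-axis-flip differences between quadrant blocks (12)
  for (i in seq_len(nrow(nonfull))) {
    b <- as.character(nonfull[i, ])
    if (sum(b != "F") != 2L) next
    for (ax in which(b != "F")) {
      fb <- b
      fb[ax] <- if (b[ax] == "L") "H" else "L"
      if (key(b) < key(fb))
        add(paste0("flip", c("x", "y", "z")[ax], "_", key(b)),
            rbind(b, fb), c(1, -1))
    }
  }
  # 5. centre planes vs window (3)
  for (ax in 1:3) {
    b <- c("F", "F", "F"); b[ax] <- "C"
    add(paste0("plane_", c("x", "y", "z")[ax]), rbind(b, c("F", "F", "F")),
        c(1, -1))
  }
  # 6. centre lines vs window (3)
  for (ax in 1:3) {
    b <- c("C", "C", "C"); b[ax] <- "F"
    add(paste0("line_", c("x", "y", "z")[ax]), rbind(b, c("F", "F", "F")),
        c(1, -1))
  }
  # 7. centre voxel vs window (1)
  add("centervox", rbind(c("C", "C", "C"), c("F", "F", "F")), c(1, -1))
  # 8. quadrant checkerboards (3)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (pr in pairs) {
    mk <- function(a, b) { v <- c("F", "F", "F"); v[pr[1L]] <- a; v[pr[2L]] <- b; v }
    add(paste0("checker_", paste0(c("x", "y", "z")[pr], collapse = "")),
        rbind(mk("L", "L"), mk("H", "H"), mk("L", "H"), mk("H", "L")),
        c(0.5, 0.5, -0.5, -0.5))
  }

  templates <- data.frame(template = seq_along(tags), tag = tags,
                          stringsAsFactors = FALSE)
  stopifnot(nrow(templates) == 62L)
  list(templates = templates, terms = do.call(rbind, terms))
}

# Expand the symbolic catalogue to integer block offsets for window size s
# (odd): inclusive [lo, hi] offsets per axis relative to the centre voxel.
haar_blocks_for_scale <- function(catalogue, s) {
  r <- (s - 1L) %/% 2L
  lims <- list(F = c(-r, r), L = c(-r, -1L), H = c(1L, r), C = c(0L, 0L))
  tm <- catalogue$terms
  out <- matrix(0, nrow(tm), 8L)
  for (i in seq_len(nrow(tm))) {
    lx <- lims[[tm$x[i]]]; ly <- lims[[tm$y[i]]]; lz <- lims[[tm$z[i]]]
    out[i, ] <- c(tm$template[i] - 1L, lx[1L], lx[2L], ly[1L], ly[2L],
                  lz[1L], lz[2L], tm$weight[i])
  }
  out
}

#' @export
print.feature_schema <- function(x, ...) {
  counts <- table(x$group)
  cat("Per-voxel feature schema:", nrow(x), "features\n")
  cat(sprintf("  %-9s %d\n", names(counts), as.integer(counts)), sep = "")
  invisible(x)
}

#' Serialize a feature schema to JSON
#'
#' @param schema a \code{feature_schema}.
#' @param path optional file path; if \code{NULL} the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
schema_to_json <- function(schema, path = NULL) {
  obj <- list(
    n_features = nrow(schema),
    groups = as.list(table(schema$group)),
    names = schema$name,
    glcm_levels = attr(schema, "glcm_levels"),
    haar_scales = attr(schema, "haar_scales"),
    haralick_sizes = attr(schema, "haralick_sizes"),
    gradient_dists = attr(schema, "gradient_dists"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
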