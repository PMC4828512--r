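# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package's extraction /
# prediction paths: plain loops, clamped indexing, no integral images,
# no vectorisation tricks.

# clamped voxel lookup, 0-based coordinates
ref_at <- function(vol, x, y, z) {
  d <- dim(vol)
  vol[min(max(x, 0L), d[1L] - 1L) + 1L,
      min(max(y, 0L), d[2L] - 1L) + 1L,
      min(max(z, 0L), d[3L] - 1L) + 1L]
}

ref_block_mean <- function(vol, voxel, lims) {
  s <- 0; n <- 0L
  for (dx in lims[1L]:lims[2L])
    for (dy in lims[3L]:lims[4L])
      for (dz in lims[5L]:lims[6L]) {
        s <- s + ref_at(vol, voxel[1L] + dx, voxel[2L] + dy, voxel[3L] + dz)
        n <- n + 1L
      }
  s / n
}

ref_axis_lims <- function(code, r) {
  switch(code, F = c(-r, r), L = c(-r, -1L), H = c(1L, r), C = c(0L, 0L))
}

ref_haar <- function(vol, voxel, scales = c(3L, 5L, 7L, 9L)) {
  cat62 <- haar_catalogue()
  out <- numeric(0)
  for (s in scales) {
    r <- (s - 1L) %/% 2L
    for (tid in cat62$templates$template) {
      tm <- cat62$terms[cat62$terms$template == tid, , drop = FALSE]
      resp <- 0
      for (i in seq_len(nrow(tm))) {
        lims <- c(ref_axis_lims(tm$x[i], r), ref_axis_lims(tm$y[i], r),
                  ref_axis_lims(tm$z[i], r))
        resp <- resp + tm$weight[i] * ref_block_mean(vol, voxel, lims)
      }
      out <- c(out, resp)
    }
  }
  out
}

ref_neighborhood <- function(vol, voxel, n) {
  r <- (n - 1L) %/% 2L
  cube <- array(0, c(n, n, n))
  for (dx in -r:r)
    for (dy in -r:r)
      for (dz in -r:r)
        cube[dx + r + 1L, dy + r + 1L, dz + r + 1L] <-
          ref_at(vol, voxel[1L] + dx, voxel[2L] + dy, voxel[3L] + dz)
  cube
}

ref_haralick <- function(vol, voxel, sizes = c(3L, 5L, 7L, 9L), G = 8L) {
  out <- numeric(0)
  for (n in sizes) {
    cube <- ref_neighborhood(vol, voxel, n)
    projs <- list(apply(cube, c(2L, 3L), mean),   # along x -> (y, z)
                  apply(cube, c(1L, 3L), mean),   # along y -> (x, z)
                  apply(cube, c(1L, 2L), mean))   # along z -> (x, y)
    for (P in projs)
      out <- c(out, haralick_stats(glcm_matrix(P, G, c(1L, 0L))))
  }
  unname(out)
}

ref_gradient <- function(vol, voxel,
                         dirs = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                      c(1, 1, 1)),
                         dists = 1:4) {
  out <- numeric(0)
  for (j in seq_len(nrow(dirs)))
    for (d in dists) {
      u <- dirs[j, ] * d
      out <- c(out, ref_at(vol, voxel[1L] + u[1L], voxel[2L] + u[2L],
                           voxel[3L] + u[3L]) -
                    ref_at(vol, voxel[1L] - u[1L], voxel[2L] - u[2L],
                           voxel[3L] - u[3L]))
    }
  out
}

# independent tree evaluation: walk the stored node vectors in R
ref_tree_conf_pos <- function(tree, xrow) {
  node <- 1L
  while (!is.na(tree$feature[node])) {
    node <- if (xrow[tree$feature[node]] <= tree$threshold[node])
      tree$left[node] else tree$right[node]
  }
  tree$conf_pos[node]
}

# independent final-vote accumulator for a boosted model
ref_vote <- function(model, xrow) {
  spos <- 0; sneg <- 0
  for (r in model$rounds) {
    hp <- ref_tree_conf_pos(r$tree$tree, xrow)
    spos <- spos + hp * log(1 / r$alpha)
    sneg <- sneg + (1 - hp) * log(1 / r$alpha)
  }
  if (spos > sneg) 1L else -1L
}

# exhaustive sign-test oracle: enumerate all 2^n equally likely sign
# patterns and accumulate the probability of an outcome at least as
# extreme (in either direction) as the observed positive count
ref_sign_test <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  k <- sum(d > 0)
  lo <- min(k, n - k); hi <- max(k, n - k)
  extreme <- 0L
  for (code in 0:(2^n - 1)) {
    kk <- sum(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    if (kk <= lo || kk >= hi) extreme <- extreme + 1L
  }
  extreme / 2^n
}

# small-grid phantom spec for fast pipeline tests
small_spec <- function(noise_sd = 6, texture_amp = 4, bias_amp = 5) {
  phantom_spec(shape = c(24L, 28L, 28L), semi_axes = c(5, 7, 6),
               deform_amp = 0.15, translate_max = 1.5,
               vol_scale_range = c(0.9, 1.1), noise_sd = noise_sd,
               texture_amp = texture_amp, bias_amp = bias_amp)
}

# random binary mask pair on a small grid with controllable overlap
random_mask_pair <- function(nvox = 200L) {
  d <- c(12L, 12L, 12L)
  a <- array(0L, d); b <- array(0L, d)
  a[sample.int(prod(d), nvox)] <- 1L
  b[sample.int(prod(d), nvox)] <- 1L
  list(a = a, b = b)
}
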