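# Independent oracles and small fixtures shared across tests.

# exhaustive triple-loop sphere scan: voxel-center distance rule
brute_sphere <- function(shape, affine, center, radius) {
  out <- array(FALSE, dim = shape)
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      for (k in seq_len(shape[3])) {
        xyz <- affine[1:3, 1:3] %*% c(i - 1, j - 1, k - 1) + affine[1:3, 4]
        out[i, j, k] <- sqrt(sum((xyz - center)^2)) <= radius + 1e-9
      }
    }
  }
  out
}

# breadth-first flood fill: returns an integer label array (0 = background)
flood_fill_components <- function(mask, connectivity) {
  shape <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  labels <- array(0L, dim = shape)
  lab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(v, shape)
      nb <- offs + matrix(ci, nrow(offs), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1L) * shape[1] * shape[2] +
        (nb[, 2] - 1L) * shape[1] + nb[, 1]
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

# closed-form simple linear regression y ~ 1 + x with Student-t inference
simple_regression_oracle <- function(x, y, sided = "two.sided") {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  t <- beta / se
  p <- switch(sided,
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df),
              two.sided = 2 * pt(abs(t), df, lower.tail = FALSE))
  list(beta = beta, t = t, p = p, df = df)
}

# textbook Benjamini-Hochberg step-up selection, written from the definition
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  if (k == 0L) return(rep(FALSE, m))
  p <= ps[k]
}

# small single-seed simulation config on a compact grid; the seed sits at
# the MNI origin with one remote target blob
small_sim_config <- function(n_met = 15, n_val = 15, slope_met = 2,
                             slope_val = 1, noise_sd = 0.02,
                             smoothing_fwhm_mm = 0, rng_seed = 1,
                             shape = c(20L, 20L, 20L),
                             target_xyz = c(-16, 16, 0),
                             target_radius = 8) {
  seeds <- data.frame(name = "ctr", model = "striatal",
                      x = 0, y = 0, z = 0, radius_mm = 4)
  tpl <- network_template(
    "ctr",
    data.frame(name = "blob", x = target_xyz[1], y = target_xyz[2],
               z = target_xyz[3], radius_mm = target_radius, amplitude = 1),
    slope_met = slope_met, slope_val = slope_val)
  simulation_config(
    n_met = n_met, n_val = n_val, shape = shape,
    affine = mni_affine(shape), baseline_margin_vox = 2L,
    noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
    templates = list(tpl), behavior_couplings = NULL,
    seed_specs = seeds, rng_seed = rng_seed)
}

# linear (column-major) voxel index of the voxel nearest an MNI point
nearest_voxel_index <- function(shape, affine, xyz) {
  v <- round(mni_to_voxel(affine, xyz))
  (v[3] - 1) * shape[1] * shape[2] + (v[2] - 1) * shape[1] + v[1]
}
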