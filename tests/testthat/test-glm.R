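test_that("noiseless linear voxel hits the zero-residual sentinel", {
  seedvol <- c(1, 2, 3, 4, 5, 6)
  Y <- cbind(3 * seedvol + 5)
  X <- cbind(1, seedvol)
  sm <- fit_voxelwise(Y, X, contrast_index = 2, sided = "greater")
  expect_equal(sm$beta, 3)
  expect_equal(sm$tstat, Inf)
  expect_equal(sm$p, 0)
  expect_equal(sm$n_zero_residual, 1)
  # an exactly constant voxel is reported as no effect
  sm0 <- fit_voxelwise(cbind(rep(2, 6)), X, 2, "two.sided")
  expect_equal(sm0$beta, 0)
  expect_equal(sm0$tstat, 0)
})

test_that("voxel-wise fit matches the closed-form regression oracle", {
  # fixed 6-subject, 1-voxel dataset
  x <- c(0.21, 0.30, 0.25, 0.40, 0.33, 0.28)
  y <- c(0.52, 0.61, 0.55, 0.70, 0.68, 0.54)
  for (sided in c("two.sided", "greater", "less")) {
    sm <- fit_voxelwise(cbind(y), cbind(1, x), 2, sided)
    or <- simple_regression_oracle(x, y, sided)
    expect_equal(sm$beta, or$beta, tolerance = 1e-12)
    expect_equal(sm$tstat, or$t, tolerance = 1e-12)
    expect_equal(sm$p, or$p, tolerance = 1e-12)
    expect_equal(sm$df, or$df)
  }
})

test_that("vectorized fit equals independent per-voxel lm fits", {
  set.seed(41)
  n <- 25; V <- 60
  X <- cbind(1, rnorm(n), rnorm(n), rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * V), n, V) + outer(X[, 2], runif(V))
  sm <- fit_voxelwise(Y, X, contrast_index = 2, sided = "two.sided")
  for (v in seq_len(V)) {
    fit <- lm(Y[, v] ~ X[, 2] + X[, 3] + X[, 4])
    cf <- summary(fit)$coefficients[2, ]
    expect_equal(sm$beta[v], unname(cf[1]), tolerance = 1e-8)
    expect_equal(sm$tstat[v], unname(cf[3]), tolerance = 1e-8)
    expect_equal(sm$p[v], unname(cf[4]), tolerance = 1e-8)
  }
  expect_equal(sm$df, n - 4)
})

test_that("null covariate yields uniform p-values", {
  set.seed(42)
  n <- 60; V <- 4000
  X <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  sm <- fit_voxelwise(Y, X, 2, "two.sided")
  ks <- suppressWarnings(ks.test(sm$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate designs are rejected", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_voxelwise(cbind(rnorm(4)), X, 2), "rank deficient")
  expect_error(fit_voxelwise(cbind(rnorm(3)), cbind(1, rnorm(3), rnorm(3))),
               "more subjects")
})

test_that("subject order permutation leaves the fit unchanged", {
  set.seed(43)
  n <- 20; V <- 30
  X <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  sm1 <- fit_voxelwise(Y, X, 2, "greater")
  perm <- sample(n)
  sm2 <- fit_voxelwise(Y[perm, ], X[perm, , drop = FALSE], 2, "greater")
  expect_equal(sm1$tstat, sm2$tstat, tolerance = 1e-10)
})

test_that("BH selection matches its definition", {
  expect_identical(fdr_select(c(0.001, 0.02, 0.03, 0.5), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_select(rep(1, 10), 0.05)))
  expect_true(fdr_select(0.04, 0.05))
  expect_false(fdr_select(0.06, 0.05))
  expect_error(fdr_select(c(0.1), 0), "\\(0, 1\\)")
  expect_error(fdr_select(c(1.2), 0.05), "\\[0, 1\\]")

  # exhaustive check: all 2^10 combinations over a fixed two-value grid
  lo <- c(0.001, 0.004, 0.008, 0.012, 0.02, 0.03, 0.04, 0.06, 0.1, 0.2)
  hi <- c(0.15, 0.3, 0.45, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1)
  for (bits in 0:1023) {
    pick <- as.logical(bitwAnd(bits, 2^(0:9)))
    p <- ifelse(pick, hi, lo)
    expect_identical(fdr_select(p, 0.05), bh_oracle(p, 0.05))
  }
})

test_that("FDR selection grows with q", {
  set.seed(44)
  for (r in 1:20) {
    p <- runif(50)^2
    s1 <- fdr_select(p, 0.01)
    s2 <- fdr_select(p, 0.1)
    expect_true(all(s2[s1]))
  }
})

test_that("cluster extraction applies the extent threshold", {
  shape <- c(12L, 12L, 12L)
  m <- array(FALSE, dim = shape)
  m[2:7, 2:6, 2:6] <- TRUE               # 150 voxels
  m[10:12, 10:12, 8:12] <- TRUE          # 45 voxels, disjoint
  tt <- array(0, dim = shape); tt[m] <- 1; tt[4, 4, 4] <- 9
  cl <- extract_clusters(m, tt, min_size = 100, connectivity = 6)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_voxels, 150)
  expect_equal(cl$peak_t, 9)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), c(4, 4, 4))
  empty <- extract_clusters(array(FALSE, dim = shape), tt, 1)
  expect_equal(nrow(empty), 0)
})

test_that("peak ties break on the smallest linear voxel index", {
  shape <- c(6L, 6L, 6L)
  m <- array(FALSE, dim = shape); m[2:4, 3, 3] <- TRUE
  tt <- array(0, dim = shape); tt[2:4, 3, 3] <- 5  # three-way tie
  cl <- extract_clusters(m, tt, min_size = 1, connectivity = 6)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), c(2, 3, 3))
})

test_that("components match the flood-fill oracle across connectivities", {
  set.seed(45)
  for (trial in 1:15) {
    shape <- c(10L, 10L, 10L)
    m <- array(runif(prod(shape)) < 0.35, dim = shape)
    tt <- array(rnorm(prod(shape)), dim = shape)
    for (conn in c(6L, 18L, 26L)) {
      cl <- extract_clusters(m, tt, min_size = 1, connectivity = conn)
      lab <- flood_fill_components(m, conn)
      expect_equal(nrow(cl), max(lab))
      got <- lapply(cl$members, sort)
      want <- unname(lapply(split(which(m), lab[lab > 0]), sort))
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(want, paste, "", collapse = ","))
    }
  }
})

test_that("raising min_size never increases the cluster count", {
  set.seed(46)
  shape <- c(12L, 12L, 12L)
  m <- array(runif(prod(shape)) < 0.4, dim = shape)
  tt <- array(rnorm(prod(shape)), dim = shape)
  counts <- vapply(c(1, 3, 5, 10, 20),
                   function(ms) nrow(extract_clusters(m, tt, ms, 18L)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SCN recovers the planted network and excludes the seed sphere", {
  cfg <- small_sim_config(n_met = 40, n_val = 0, slope_met = 1,
                          slope_val = 1, noise_sd = 0.01, rng_seed = 7)
  cht <- generate_cohort(cfg)
  seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 4)
  acfg <- analysis_config(min_cluster_voxels = 20)
  res <- build_scn(cht, "ctr", acfg, seeds)
  expect_gte(nrow(res$clusters), 1)
  # Dice overlap between the top cluster and the planted blob
  blob <- cht$ground_truth$templates[[1]]$target_idx
  got <- res$clusters$members[[1]]
  dice <- 2 * length(intersect(got, blob)) / (length(got) + length(blob))
  expect_gte(dice, 0.5)
  # the seed's own sphere must not be reported
  smask <- which(sphere_mask(cht$shape, cht$affine, c(0, 0, 0), 4))
  for (mem in res$clusters$members) {
    expect_length(intersect(mem, smask), 0)
  }
})
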