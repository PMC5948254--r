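test_that("genotype sampling respects Hardy-Weinberg proportions", {
  set.seed(31)
  expect_true(all(sample_genotypes(50, 0) == "VV"))
  expect_true(all(sample_genotypes(50, 1) == "MM"))
  expect_error(sample_genotypes(10, 1.2), "\\[0, 1\\]")
  expect_error(sample_genotypes(-1, 0.5), ">= 0")

  # frequency implied by pooled genotype counts 20/71/101
  p <- 111 / 384
  n <- 192
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  reps <- 40
  counts <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    g <- sample_genotypes(n, p)
    counts[r, ] <- c(sum(g == "MM"), sum(g == "MV"), sum(g == "VV"))
  }
  # mean counts within 3 binomial SDs of the HWE expectation (SE / sqrt(reps))
  se <- sqrt(expected * (1 - expected / n) / reps)
  expect_true(all(abs(colMeans(counts) - expected) <= 3 * se))
  expect_identical(genotype_group(c("MM", "MV", "VV")),
                   c("Met", "Met", "Val"))
})

test_that("HWE chi-square on generated genotypes rejects at the nominal rate", {
  set.seed(32)
  reps <- 200
  rej <- vapply(seq_len(reps), function(r) {
    g <- sample_genotypes(400, 0.3)
    hwe_test(sum(g == "MM"), sum(g == "MV"), sum(g == "VV"))$p < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("generation is deterministic given the seed", {
  cfg <- small_sim_config(n_met = 5, n_val = 5, rng_seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$phenotypes, b$phenotypes)
  c2 <- generate_cohort(small_sim_config(n_met = 5, n_val = 5,
                                         rng_seed = 100))
  expect_false(identical(a$volumes, c2$volumes))
})

test_that("noiseless equal-slope cohort gives R^2 = 1 voxel regressions", {
  cfg <- small_sim_config(n_met = 8, n_val = 8, slope_met = 1.5,
                          slope_val = 1.5, noise_sd = 0)
  cht <- generate_cohort(cfg)
  seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 4)
  sv <- extract_volumes(cht, seeds)[, 1]
  blob <- cht$ground_truth$templates[[1]]$target_idx
  for (g in c("Met", "Val")) {
    rows <- cht$phenotypes$group == g
    for (v in blob[c(1, length(blob) %/% 2, length(blob))]) {
      y <- cht$volumes[rows, v]
      r2 <- suppressWarnings(summary(lm(y ~ sv[rows]))$r.squared)
      expect_gt(r2, 1 - 1e-9)
    }
  }
})

test_that("seed volume reads out the latent score", {
  cfg <- small_sim_config(n_met = 30, n_val = 30, noise_sd = 0.01)
  cht <- generate_cohort(cfg)
  seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 4)
  sv <- extract_volumes(cht, seeds)[, 1]
  expect_gt(cor(sv, cht$ground_truth$latents[, 1]), 0.9)
})

test_that("planted seed-target correlation rises with the slope/noise ratio", {
  cors <- vapply(c(0.4, 0.1, 0.02), function(ns) {
    cfg <- small_sim_config(n_met = 25, n_val = 25, slope_met = 1,
                            slope_val = 1, noise_sd = ns, rng_seed = 5)
    cht <- generate_cohort(cfg)
    seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 4)
    sv <- extract_volumes(cht, seeds)[, 1]
    blob <- cht$ground_truth$templates[[1]]$target_idx
    cor(sv, rowMeans(cht$volumes[, blob]))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("behavior scores are linear readouts of seed volume", {
  seeds <- data.frame(name = "ctr", model = "striatal",
                      x = 0, y = 0, z = 0, radius_mm = 4)
  tpl <- network_template("ctr",
                          data.frame(name = "b", x = -16, y = 16, z = 0,
                                     radius_mm = 8, amplitude = 1), 1, 1)
  bc <- data.frame(score = "mmse", seed_name = "ctr", intercept = 10,
                   slope = 50, noise_sd = 0)
  cfg <- simulation_config(n_met = 10, n_val = 10, shape = c(20L, 20L, 20L),
                           affine = mni_affine(c(20L, 20L, 20L)),
                           baseline_margin_vox = 2L, noise_sd = 0.01,
                           smoothing_fwhm_mm = 0, templates = list(tpl),
                           behavior_couplings = bc, seed_specs = seeds,
                           rng_seed = 3)
  cht <- generate_cohort(cfg)
  sv <- extract_volumes(cht, seeds)[, 1]
  expect_equal(cht$phenotypes$mmse, 10 + 50 * sv, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cohort write/read round-trips and reproduces SCN maps", {
  cfg <- small_sim_config(n_met = 6, n_val = 6, noise_sd = 0.02,
                          rng_seed = 17)
  cht <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cht, dir)
  back1 <- read_cohort(dir)
  back2 <- read_cohort(dir)
  expect_equal(back1$phenotypes, cht$phenotypes)
  expect_identical(back1$volumes, back2$volumes)
  # sidecar ground truth survives serialization
  gt <- back1$ground_truth
  expect_equal(gt$templates[[1]]$k, cht$ground_truth$templates[[1]]$k)
  expect_equal(unlist(gt$templates[[1]]$target_idx),
               cht$ground_truth$templates[[1]]$target_idx,
               ignore_attr = TRUE)
  # identical analysis config on the reloaded cohort: identical maps
  seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 4)
  cfg_a <- analysis_config(min_cluster_voxels = 5)
  r1 <- build_scn(cohort_group(back1, "Met"), "ctr", cfg_a, seeds)
  r2 <- build_scn(cohort_group(back2, "Met"), "ctr", cfg_a, seeds)
  expect_identical(r1$statmap$tstat, r2$statmap$tstat)
  expect_identical(r1$clusters$peak_t, r2$clusters$peak_t)
})

test_that("invalid simulation inputs fail with named errors", {
  seeds <- data.frame(name = "ctr", model = "striatal",
                      x = 0, y = 0, z = 0, radius_mm = 4)
  tpl_out <- network_template("ctr",
                              data.frame(name = "b", x = 500, y = 0, z = 0,
                                         radius_mm = 8, amplitude = 1), 1, 1)
  cfg <- simulation_config(n_met = 2, n_val = 2, shape = c(20L, 20L, 20L),
                           affine = mni_affine(c(20L, 20L, 20L)),
                           templates = list(tpl_out),
                           behavior_couplings = NULL, seed_specs = seeds)
  expect_error(generate_cohort(cfg), "outside the field of view")
  expect_error(simulation_config(n_met = -1), ">= 0")
  expect_error(generate_cohort(small_sim_config(n_met = 0, n_val = 0)),
               "zero subjects")
})
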