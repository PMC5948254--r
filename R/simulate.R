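#' Sample COMT-style genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes are drawn i.i.d. with probabilities (p^2, 2pq, q^2) for
#' (MM, MV, VV), where p is the Met allele frequency. Uses the current RNG
#' state; call \code{set.seed} for reproducibility.
#'
#' @param n number of subjects (>= 0).
#' @param met_allele_freq Met allele frequency p in [0, 1].
#' @return character vector of genotypes in \{"MM", "MV", "VV"\}.
#' @export
sample_genotypes <- function(n, met_allele_freq) {
  if (n < 0) stop("n must be >= 0")
  p <- met_allele_freq
  if (p < 0 || p > 1) stop("met_allele_freq must lie in [0, 1]")
  q <- 1 - p
  sample(c("MM", "MV", "VV"), size = n, replace = TRUE,
         prob = c(p^2, 2 * p * q, q^2))
}

#' Pool genotypes into carrier groups
#'
#' Met/Met and Val/Met subjects are pooled as Met-carriers; Val homozygotes
#' form the Val group.
#'
#' @param genotype character vector in \{"MM", "MV", "VV"\}.
#' @return character vector in \{"Met", "Val"\}.
#' @export
genotype_group <- function(genotype) {
  stopifnot(all(genotype %in% c("MM", "MV", "VV")))
  ifelse(genotype == "VV", "Val", "Met")
}

#' Network template for the cohort simulator
#'
#' Describes one planted structural covariance network: a seed whose sphere
#' tracks a latent network score, and remote target blobs whose gray-matter
#' density follows the seed volume with a group-specific regression slope.
#' \code{slope_met}/\code{slope_val} are in gray-matter density units per mL
#' of seed volume, so a voxel-wise regression of target density on extracted
#' seed volume recovers them directly.
#'
#' @param seed_name name of a seed in the simulation's seed table.
#' @param targets data.frame with columns \code{name, x, y, z, radius_mm,
#'   amplitude}; amplitude scales the blob profile (peak 1 after smoothing).
#' @param slope_met,slope_val covariance slope in each genotype group.
#' @return a list of class \code{network_template}.
#' @export
network_template <- function(seed_name, targets, slope_met, slope_val) {
  need <- c("name", "x", "y", "z", "radius_mm", "amplitude")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns: ", paste(need, collapse = ", "))
  }
  if (any(targets$radius_mm <= 0)) stop("blob radii must be > 0")
  structure(list(seed_name = seed_name, targets = targets,
                 slope_met = slope_met, slope_val = slope_val),
            class = "network_template")
}

#' Default planted networks and behavior couplings
#'
#' \code{default_templates} returns the two default striatal network
#' templates (dorsal caudal and dorsal rostral putamen seeds, two remote
#' target blobs each, covariance slope 2 in Met-carriers vs 1 in Val
#' homozygotes). \code{default_behavior_couplings} couples the MMSE score to
#' the dorsal caudal putamen seed volume and an attention score to the
#' dorsal rostral putamen seed volume.
#'
#' @return a list of \code{\link{network_template}} objects, resp. a
#'   data.frame of couplings.
#' @export
default_templates <- function() {
  list(
    network_template(
      "dorsal_caudal_putamen",
      data.frame(name = c("middle_occipital", "middle_temporal"),
                 x = c(-24, 36), y = c(-44, -20), z = c(12, -8),
                 radius_mm = c(14, 12), amplitude = c(1, 0.8)),
      slope_met = 2, slope_val = 1),
    network_template(
      "dorsal_rostral_putamen",
      data.frame(name = c("supplementary_motor", "superior_frontal"),
                 x = c(-4, 28), y = c(-4, 28), z = c(48, 28),
                 radius_mm = c(12, 12), amplitude = c(1, 0.8)),
      slope_met = 2, slope_val = 1)
  )
}

#' @rdname default_templates
#' @export
default_behavior_couplings <- function() {
  data.frame(
    score = c("mmse", "attention"),
    seed_name = c("dorsal_caudal_putamen", "dorsal_rostral_putamen"),
    intercept = c(12, 3),
    slope = c(30, 10),           # score units per mL of seed volume
    noise_sd = c(4, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults emulate the target study conditions: 91 Met-carriers and 101 Val
#' homozygotes, a Met allele frequency of 111/384 (the frequency implied by
#' genotype counts 20 MM / 71 MV / 101 VV), 8-mm FWHM smoothed maps on a
#' 40 x 48 x 40 grid of 4-mm voxels centered on MNI (0,0,0), and two planted
#' striatal networks (dorsal caudal and dorsal rostral putamen) whose
#' covariance slope is twice as large in Met-carriers.
#'
#' @param n_met,n_val genotype group sizes.
#' @param met_allele_freq Met allele frequency in [0, 1].
#' @param shape,affine image geometry (see \code{\link{mni_affine}}).
#' @param baseline gray-matter density of the brain ellipsoid.
#' @param baseline_margin_vox empty margin (voxels) around the ellipsoid;
#'   keeps zero-padded smoothing mass-preserving.
#' @param latent_sd SD of each template's latent network score.
#' @param noise_sd per-voxel Gaussian noise SD (density units).
#' @param seed_gain density added in the seed sphere per latent-SD unit;
#'   sets the dynamic range of the seed readout.
#' @param smoothing_fwhm_mm Gaussian FWHM applied to baseline, blob profiles
#'   and (variance-preserving) noise; 0 disables smoothing.
#' @param templates list of \code{\link{network_template}} objects.
#' @param behavior_couplings data.frame with columns \code{score, seed_name,
#'   intercept, slope, noise_sd}; each score is a linear readout of one
#'   seed's extracted volume plus noise.
#' @param seed_specs seed table (\code{\link{seed_table}}-like data.frame).
#' @param sphere_radius_mm radius of the seed spheres used for planting.
#' @param rng_seed integer; fixes every generated byte.
#' @return a list of class \code{sim_config}.
#' @export
simulation_config <- function(n_met = 91L, n_val = 101L,
                              met_allele_freq = 111 / 384,
                              shape = c(40L, 48L, 40L),
                              affine = mni_affine(shape),
                              baseline = 0.8, baseline_margin_vox = 4L,
                              latent_sd = 1, noise_sd = 0.05,
                              seed_gain = 0.25, smoothing_fwhm_mm = 8,
                              templates = default_templates(),
                              behavior_couplings =
                                default_behavior_couplings(),
                              seed_specs = seed_table(),
                              sphere_radius_mm = 4, rng_seed = 1L) {
  if (n_met < 0 || n_val < 0) stop("group sizes must be >= 0")
  if (met_allele_freq < 0 || met_allele_freq > 1) {
    stop("met_allele_freq must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (latent_sd < 0) stop("latent_sd must be >= 0")
  structure(list(
    n_met = as.integer(n_met), n_val = as.integer(n_val),
    met_allele_freq = met_allele_freq, shape = as.integer(shape),
    affine = unname(as.matrix(affine)), baseline = baseline,
    baseline_margin_vox = as.integer(baseline_margin_vox),
    latent_sd = latent_sd, noise_sd = noise_sd, seed_gain = seed_gain,
    smoothing_fwhm_mm = smoothing_fwhm_mm, templates = templates,
    behavior_couplings = behavior_couplings, seed_specs = seed_specs,
    sphere_radius_mm = sphere_radius_mm, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# brain ellipsoid indicator inscribed in the grid with a fixed empty margin
brain_support <- function(shape, margin_vox) {
  semi <- pmax((shape - 1) / 2 - margin_vox, 1)
  ctr <- (shape + 1) / 2
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  d2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 +
    ((idx[, 2] - ctr[2]) / semi[2])^2 +
    ((idx[, 3] - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim = shape)
}

# variance of iid N(0,1) noise after separable smoothing (interior voxels)
smoothed_noise_var <- function(sigma_vox) {
  prod(vapply(sigma_vox, function(s) sum(gaussian_kernel_1d(s)^2), 1))
}

#' Generate a synthetic cohort
#'
#' Builds, for each subject i and template t, the image
#' \code{baseline + s_it * seed_profile_t + slope_group(i) * k_t * s_it *
#' target_profile_t + noise}, where \code{s_it ~ N(0, latent_sd)} is the
#' latent network score and \code{k_t} (mL per latent unit) is the exact
#' noiseless gain of the extracted seed volume. The seed sphere therefore
#' reads out the latent score, and target blobs follow the seed volume with
#' the group's slope. Behavior scores are linear readouts of the extracted
#' seed volumes plus Gaussian noise. All randomness derives from
#' \code{config$rng_seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{cohort}} whose \code{ground_truth} element records
#'   the generating latent scores, template gains and voxel supports.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_met + config$n_val
  if (n == 0) stop("zero subjects")
  shape <- config$shape; affine <- config$affine
  set.seed(config$rng_seed)

  # genotypes conditional on fixed group sizes: P(MM | Met) = p^2/(p^2+2pq)
  p <- config$met_allele_freq
  geno_met <- if (config$n_met > 0) {
    if (p == 0) rep("MV", config$n_met)
    else sample(c("MM", "MV"), config$n_met, TRUE,
                prob = c(p^2, 2 * p * (1 - p)))
  } else character(0)
  genotype <- c(geno_met, rep("VV", config$n_val))
  group <- genotype_group(genotype)

  age <- round(pmax(stats::rnorm(n, 73.6, 7.9), 50), 1)
  education <- round(pmax(stats::rnorm(n, 7.35, 4.9), 0), 1)
  sex <- sample(c("M", "F"), n, TRUE, prob = c(95, 97))
  apoe4 <- stats::rbinom(n, 1, 66 / 192)

  sigma_vox <- if (config$smoothing_fwhm_mm > 0) {
    config$smoothing_fwhm_mm / (voxel_size(affine) * 2 * sqrt(2 * log(2)))
  } else c(0, 0, 0)
  smooth_if <- function(a) {
    if (config$smoothing_fwhm_mm > 0) smooth_array(a, sigma_vox) else a
  }

  support <- brain_support(shape, config$baseline_margin_vox)
  baseline_map <- smooth_if(support * config$baseline)
  vv_ml <- voxel_volume_ml(affine)

  # per-template profiles and exact seed-volume gain k_t (mL per latent unit)
  tinfo <- lapply(config$templates, function(tp) {
    row <- config$seed_specs[config$seed_specs$name == tp$seed_name, ]
    if (nrow(row) != 1) stop("unknown template seed: ", tp$seed_name)
    smask <- sphere_mask(shape, affine, c(row$x, row$y, row$z),
                         config$sphere_radius_mm)
    target <- array(0, dim = shape)
    for (b in seq_len(nrow(tp$targets))) {
      ctr <- c(tp$targets$x[b], tp$targets$y[b], tp$targets$z[b])
      if (!in_field_of_view(shape, affine, ctr)) {
        stop("template blob '", tp$targets$name[b],
             "' lies outside the field of view")
      }
      prof <- smooth_if(sphere_mask(shape, affine, ctr,
                                    tp$targets$radius_mm[b]) * 1)
      mx <- max(prof)
      if (mx > 0) prof <- prof / mx      # peak re-normalized to 1
      target <- target + tp$targets$amplitude[b] * prof
    }
    list(seed_name = tp$seed_name,
         seed_profile = config$seed_gain * smask,
         seed_idx = which(smask),
         target_profile = target, target_idx = which(target > 1e-6),
         k = config$seed_gain * sum(smask) * vv_ml,
         slope_met = tp$slope_met, slope_val = tp$slope_val)
  })

  n_t <- length(tinfo)
  latents <- matrix(stats::rnorm(n * n_t, 0, config$latent_sd),
                    nrow = n, ncol = n_t)

  noise_scale <- if (config$smoothing_fwhm_mm > 0) {
    1 / sqrt(smoothed_noise_var(sigma_vox))
  } else 1

  volumes <- matrix(0, nrow = n, ncol = prod(shape))
  for (i in seq_len(n)) {
    img <- baseline_map
    for (t in seq_len(n_t)) {
      slope <- if (group[i] == "Met") tinfo[[t]]$slope_met
               else tinfo[[t]]$slope_val
      img <- img + latents[i, t] *
        (tinfo[[t]]$seed_profile +
           slope * tinfo[[t]]$k * tinfo[[t]]$target_profile)
    }
    if (config$noise_sd > 0) {
      eps <- array(stats::rnorm(prod(shape)), dim = shape)
      eps <- smooth_if(eps) * noise_scale
      img <- img + config$noise_sd * eps
    }
    volumes[i, ] <- pmax(as.numeric(img), 0)  # density cannot go negative
  }

  phenotypes <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    genotype = genotype, group = group, age = age,
    education = education, sex = sex, apoe4 = apoe4,
    stringsAsFactors = FALSE
  )

  cht <- cohort(volumes, phenotypes, shape = shape, affine = affine)

  # behavior scores: linear readout of the extracted seed volume + noise
  bc <- config$behavior_couplings
  if (!is.null(bc) && nrow(bc) > 0) {
    for (j in seq_len(nrow(bc))) {
      row <- config$seed_specs[config$seed_specs$name == bc$seed_name[j], ]
      if (nrow(row) != 1) stop("unknown coupling seed: ", bc$seed_name[j])
      roi <- data.frame(name = row$name, x = row$x, y = row$y, z = row$z,
                        radius_mm = config$sphere_radius_mm)
      sv <- extract_volumes(cht, roi)[, 1]
      cht$phenotypes[[bc$score[j]]] <-
        bc$intercept[j] + bc$slope[j] * sv +
        stats::rnorm(n, 0, bc$noise_sd[j])
    }
  }

  cht$ground_truth <- list(
    rng_seed = config$rng_seed, n_met = config$n_met, n_val = config$n_val,
    met_allele_freq = config$met_allele_freq, baseline = config$baseline,
    latent_sd = config$latent_sd, noise_sd = config$noise_sd,
    seed_gain = config$seed_gain,
    smoothing_fwhm_mm = config$smoothing_fwhm_mm,
    support_idx = which(support), latents = latents,
    templates = lapply(tinfo, function(ti) {
      ti[c("seed_name", "seed_idx", "target_idx", "k",
           "slope_met", "slope_val")]
    }),
    template_targets = lapply(config$templates, function(tp) tp$targets),
    behavior_couplings = bc
  )
  cht
}

#' Write / read a cohort on disk
#'
#' \code{write_cohort} writes one NIfTI image per subject
#' (\code{<subject_id>_gm.nii.gz}), the phenotype table
#' (\code{phenotypes.tsv}) and, for simulated cohorts, a JSON sidecar
#' (\code{simulation.json}) recording the generating ground truth.
#' \code{read_cohort} reloads the set.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param dir directory (created if needed).
#' @return the directory (write) or an \code{scn_cohort} (read).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "scn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort$volumes))) {
    write_gm_volume(cohort_volume(cohort, i),
                    file.path(dir, paste0(cohort$phenotypes$subject_id[i],
                                          "_gm.nii.gz")))
  }
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "simulation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  vols <- lapply(ph$subject_id, function(id) {
    read_gm_volume(file.path(dir, paste0(id, "_gm.nii.gz")))
  })
  gt <- NULL
  sidecar <- file.path(dir, "simulation.json")
  if (file.exists(sidecar)) {
    gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  }
  cohort(vols, ph, ground_truth = gt)
}
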