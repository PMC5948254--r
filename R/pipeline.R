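#' Read analysis / simulation configuration from JSON
#'
#' Plain-JSON configuration files: each top-level key must be a formal
#' argument of \code{\link{analysis_config}} (resp.
#' \code{\link{simulation_config}}); unknown keys are an error. Keys that
#' are omitted keep their defaults. For the simulation config,
#' \code{templates} is a list of objects with \code{seed_name, slope_met,
#' slope_val} and a \code{targets} data frame, and \code{behavior_couplings}
#' is a data frame in the documented column schema.
#'
#' @param path JSON file.
#' @return an \code{scn_config} / \code{sim_config}.
#' @export
read_analysis_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(bad)) stop("unknown analysis config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @export
read_simulation_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  bad <- setdiff(names(vals), names(formals(simulation_config)))
  if (length(bad)) stop("unknown simulation config key(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(vals$affine) && !is.matrix(vals$affine)) {
    # accept a flat length-16 vector or list of 4 rows, row-major
    vals$affine <- matrix(unlist(vals$affine), 4, 4, byrow = TRUE)
  }
  if (!is.null(vals$templates)) {
    vals$templates <- lapply(vals$templates, function(tp) {
      network_template(tp$seed_name,
                       as.data.frame(tp$targets,
                                     stringsAsFactors = FALSE),
                       tp$slope_met, tp$slope_val)
    })
  }
  for (nm in c("behavior_couplings", "seed_specs")) {
    if (!is.null(vals[[nm]])) {
      vals[[nm]] <- as.data.frame(vals[[nm]], stringsAsFactors = FALSE)
    }
  }
  do.call(simulation_config, vals)
}

#' Simulate a cohort to disk
#'
#' Wraps \code{\link{generate_cohort}} and \code{\link{write_cohort}}.
#'
#' @param config a \code{\link{simulation_config}} or path to its JSON.
#' @param out_dir output directory.
#' @return the cohort, invisibly.
#' @export
simulate_cohort <- function(config, out_dir) {
  if (is.character(config)) config <- read_simulation_config(config)
  cht <- generate_cohort(config)
  write_cohort(cht, out_dir)
  invisible(cht)
}

write_tsv <- function(df, path) {
  df <- df[, setdiff(names(df), "members"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) the voxel-wise group-difference map (two-sided,
#' FDR at \code{group_q}, cluster extent filter); (2) per-group, per-seed
#' structural covariance networks (one-sided positive, FDR at
#' \code{scn_q}); (3) per-seed genotype interaction maps, reported in the
#' Met > Val direction; (4) sphere volumes at interaction-cluster peaks;
#' (5) seed-volume group comparisons and seed/peak-volume x behavior
#' correlation tables; (6) the demographics report. Statistic maps are
#' written as NIfTI, tables as TSV (one directory per seed), and a JSON
#' manifest records the configuration, input checksums, stage timings and
#' package version.
#'
#' @param cohort a \code{\link{cohort}} or a cohort directory path.
#' @param config an \code{\link{analysis_config}} or path to its JSON.
#' @param out_dir output directory (created).
#' @param seeds seed table (default \code{\link{seed_table}()}).
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(cohort, config = analysis_config(), out_dir,
                         seeds = seed_table()) {
  t0 <- Sys.time()
  input_files <- character(0)
  if (is.character(cohort)) {
    input_files <- sort(list.files(cohort, full.names = TRUE))
    cohort <- read_cohort(cohort)
  }
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(cohort, "scn_cohort"), inherits(config, "scn_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t1 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t1, units = "secs"))
    out
  }

  mask <- stage("analysis_mask",
                analysis_mask(cohort, config$mask_threshold))
  met <- cohort_group(cohort, "Met")
  val <- cohort_group(cohort, "Val")

  # 1. voxel-wise group comparison
  gd <- stage("group_difference", group_difference_map(cohort, config, mask))
  write_stat_nifti(vector_to_array(gd$statmap$tstat, mask), cohort$affine,
                   file.path(out_dir, "group_difference_t.nii.gz"))
  write_tsv(gd$clusters, file.path(out_dir, "group_difference_clusters.tsv"))

  # 2. seed volumes: per-group comparison + behavior correlations
  rois <- data.frame(name = seeds$name, x = seeds$x, y = seeds$y,
                     z = seeds$z, radius_mm = config$sphere_radius_mm)
  seed_vols <- stage("seed_volumes", extract_volumes(cohort, rois))
  seed_tests <- do.call(rbind, lapply(seeds$name, function(s) {
    cmp <- compare_groups_scalar(seed_vols[, s], cohort$phenotypes$group,
                                 "continuous")
    data.frame(seed = s, mean_met = cmp$means[["Met"]],
               mean_val = cmp$means[["Val"]], t = cmp$statistic,
               df = cmp$df, p = cmp$p)
  }))
  write_tsv(seed_tests, file.path(out_dir, "seed_volume_group_tests.tsv"))
  seed_cors <- stage("seed_correlations",
                     correlate_volumes_scores(seed_vols, cohort$phenotypes))
  write_tsv(seed_cors, file.path(out_dir, "seed_score_correlations.tsv"))

  # 3. per-seed SCNs and interaction maps
  seed_results <- list()
  for (s in seeds$name) {
    sdir <- file.path(out_dir, "seeds", s)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    res <- list()
    for (g in c("Met", "Val")) {
      grp_cht <- if (g == "Met") met else val
      scn <- stage(paste0("scn_", s, "_", g),
                   build_scn(grp_cht, s, config, seeds))
      write_stat_nifti(vector_to_array(scn$statmap$tstat, scn$statmap$mask),
                       cohort$affine,
                       file.path(sdir, sprintf("scn_%s_q%g_t.nii.gz",
                                               g, config$scn_q)))
      write_tsv(scn$clusters,
                file.path(sdir, sprintf("scn_%s_q%g_clusters.tsv",
                                        g, config$scn_q)))
      res[[paste0("scn_", g)]] <- scn
    }
    ia <- stage(paste0("interaction_", s),
                fit_interaction(cohort, s, config, seeds))
    write_stat_nifti(vector_to_array(ia$statmap$tstat, mask), cohort$affine,
                     file.path(sdir, sprintf("interaction_met_gt_val_q%g_t.nii.gz",
                                             config$scn_q)))
    write_tsv(ia$clusters,
              file.path(sdir, sprintf("interaction_met_gt_val_q%g_clusters.tsv",
                                      config$scn_q)))
    res$interaction <- ia

    # 4-5. peak-sphere volumes and their behavior correlations
    if (nrow(ia$clusters) > 0) {
      pv <- peak_sphere_volumes(cohort, ia$clusters,
                                config$sphere_radius_mm,
                                prefix = paste0(s, "_peak"))
      pc <- correlate_volumes_scores(pv, cohort$phenotypes)
      write_tsv(as.data.frame(pv) |>
                  cbind(subject_id = cohort$phenotypes$subject_id),
                file.path(sdir, "peak_sphere_volumes.tsv"))
      write_tsv(pc, file.path(sdir, "peak_score_correlations.tsv"))
      res$peak_volumes <- pv
      res$peak_correlations <- pc
    }
    seed_results[[s]] <- res
  }

  # 6. demographics
  demo <- stage("demographics", demographics_report(cohort$phenotypes))
  write_tsv(demo, file.path(out_dir, "demographics.tsv"))

  manifest <- list(
    package = "scnvbm",
    version = as.character(utils::packageVersion("scnvbm")),
    config = unclass(config),
    n_subjects = nrow(cohort$volumes),
    n_met = sum(cohort$phenotypes$group == "Met"),
    n_val = sum(cohort$phenotypes$group == "Val"),
    shape = cohort$shape,
    mask_voxels = sum(mask),
    seeds = seeds,
    input_files = if (length(input_files)) {
      data.frame(file = basename(input_files),
                 md5 = unname(tools::md5sum(input_files)))
    } else NULL,
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(mask = mask, group_difference = gd,
                 seed_volumes = seed_vols, seed_tests = seed_tests,
                 seed_correlations = seed_cors, seeds = seed_results,
                 demographics = demo, manifest = manifest))
}
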