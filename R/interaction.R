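#' Genotype-by-seed slope interaction map
#'
#' Pooled model over both genotype groups,
#' \code{voxel = b0 + b1 seed + b2 group + b3 (seed x group)}, with the
#' group coded Val = 0, Met = 1 so that b3 > 0 means the seed-voxel
#' covariance slope is larger in Met-carriers. A one-sided T contrast on b3
#' (direction \code{"met_gt_val"} by default; both directions are
#' computable) is thresholded with Benjamini-Hochberg FDR at
#' \code{config$scn_q} within the analysis mask, followed by the
#' cluster-extent filter. The pooled formulation assumes equal residual
#' variance across groups (the usual interaction-contrast idiom).
#'
#' @param cohort a two-group \code{\link{cohort}}.
#' @param seed_name name of a seed in \code{seeds}.
#' @param config an \code{\link{analysis_config}}.
#' @param seeds seed table.
#' @param direction \code{"met_gt_val"}, \code{"val_gt_met"} or
#'   \code{"two.sided"}.
#' @param mask optional precomputed analysis mask.
#' @return list with \code{statmap} (b3 map; includes \code{q_mask}),
#'   \code{clusters} (MNI peak table, seed sphere excluded) and
#'   \code{seed_volumes}.
#' @export
fit_interaction <- function(cohort, seed_name, config = analysis_config(),
                            seeds = seed_table(),
                            direction = c("met_gt_val", "val_gt_met",
                                          "two.sided"),
                            mask = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  direction <- match.arg(direction)
  n_by_group <- table(factor(cohort$phenotypes$group,
                             levels = c("Met", "Val")))
  if (any(n_by_group < 3)) {
    stop("each genotype group needs at least 3 subjects (insufficient df)")
  }
  row <- seeds[seeds$name == seed_name, ]
  if (nrow(row) != 1) stop("unknown seed: ", seed_name)
  if (is.null(mask)) mask <- analysis_mask(cohort, config$mask_threshold)
  if (!any(mask)) stop("analysis mask is empty")

  roi <- data.frame(name = row$name, x = row$x, y = row$y, z = row$z,
                    radius_mm = config$sphere_radius_mm)
  sv <- extract_volumes(cohort, roi)[, 1]
  gi <- as.numeric(cohort$phenotypes$group == "Met")
  X <- cbind(intercept = 1, seed = sv, group = gi, seed_x_group = sv * gi)
  for (nm in config$nuisance) {
    v <- cohort$phenotypes[[nm]]
    if (is.null(v)) stop("nuisance column not in phenotypes: ", nm)
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v); colnames(X)[ncol(X)] <- nm
  }
  sided <- switch(direction, met_gt_val = "greater",
                  val_gt_met = "less", two.sided = "two.sided")
  sm <- fit_voxelwise(cohort$volumes[, as.vector(mask), drop = FALSE], X,
                      contrast_index = 4, sided = sided,
                      contrast_label = paste0("interaction:", seed_name,
                                              ":", direction))
  sm$shape <- cohort$shape; sm$affine <- cohort$affine; sm$mask <- mask
  sel <- fdr_select(sm$p, config$scn_q)
  sm$q_mask <- vector_to_array(sel, mask)
  sm$q_mask[is.na(sm$q_mask)] <- FALSE
  sm$q_mask <- array(as.logical(sm$q_mask), dim = dim(mask))

  smask <- sphere_mask(cohort$shape, cohort$affine,
                       c(row$x, row$y, row$z), config$sphere_radius_mm)
  sel_arr <- sm$q_mask & !smask
  tarr <- vector_to_array(if (sided == "less") -sm$tstat
                          else if (sided == "two.sided") abs(sm$tstat)
                          else sm$tstat, mask)
  tarr[is.na(tarr)] <- -Inf
  clusters <- extract_clusters(sel_arr, tarr, config$min_cluster_voxels,
                               config$connectivity, cohort$affine)
  list(statmap = sm, clusters = clusters, seed_volumes = sv)
}

#' Gray-matter volumes of spheres at cluster peaks
#'
#' Places a sphere on each cluster's peak voxel and extracts per-subject
#' gray-matter volumes (mL), one column per cluster.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param clusters a cluster table from \code{\link{extract_clusters}} (peak
#'   coordinates in MNI mm).
#' @param radius_mm sphere radius (default 4).
#' @param prefix column-name prefix.
#' @return numeric matrix, subjects x clusters (zero columns when the
#'   cluster table is empty).
#' @export
peak_sphere_volumes <- function(cohort, clusters, radius_mm = 4,
                                prefix = "peak") {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (nrow(clusters) == 0) {
    out <- matrix(numeric(0), nrow = nrow(cohort$volumes), ncol = 0)
    rownames(out) <- cohort$phenotypes$subject_id
    return(out)
  }
  rois <- data.frame(
    name = sprintf("%s_%d_x%g_y%g_z%g", prefix, clusters$cluster_id,
                   clusters$peak_x, clusters$peak_y, clusters$peak_z),
    x = clusters$peak_x, y = clusters$peak_y, z = clusters$peak_z,
    radius_mm = radius_mm
  )
  extract_volumes(cohort, rois)
}
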