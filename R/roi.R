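#' Default seed table
#'
#' The ten seeds used throughout the analysis: the six-seed striatal
#' parcellation (ventral/dorsal caudate and putamen subdivisions) and four
#' triple-network seeds (default-mode, salience and executive control
#' representatives). Coordinates are MNI mm; spheres default to 4 mm radius.
#'
#' @param model \code{"all"}, \code{"striatal"} or \code{"triple"}.
#' @param radius_mm sphere radius applied to every seed (default 4).
#' @return data.frame with columns \code{name, model, x, y, z, radius_mm}.
#' @export
seed_table <- function(model = c("all", "striatal", "triple"),
                       radius_mm = 4) {
  model <- match.arg(model)
  seeds <- data.frame(
    name = c("inferior_ventral_striatum", "superior_ventral_striatum",
             "dorsal_caudate", "ventral_rostral_putamen",
             "dorsal_caudal_putamen", "dorsal_rostral_putamen",
             "right_entorhinal", "left_pcc", "right_frontoinsular",
             "right_dlpfc"),
    model = c(rep("striatal", 6), rep("triple", 4)),
    x = c(9, 10, 13, 20, 28, 25, 25, -2, 38, 44),
    y = c(9, 15, 15, 12, 1, 8, -9, -36, 26, 36),
    z = c(-8, 0, 9, -3, 3, 6, -28, 35, -10, 20),
    stringsAsFactors = FALSE
  )
  seeds$radius_mm <- radius_mm
  if (model != "all") seeds <- seeds[seeds$model == model, , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

#' Sphere mask at an MNI coordinate
#'
#' A voxel is included iff the Euclidean distance from its center (mapped
#' through the affine) to \code{center_mni} is at most \code{radius_mm}
#' (boundary-closed). The center must map inside the field of view; an
#' out-of-view center is an error rather than a silently truncated sphere.
#'
#' @param shape grid dimensions.
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param center_mni length-3 mm coordinate.
#' @param radius_mm sphere radius in mm (>= 0).
#' @return logical 3D array.
#' @export
sphere_mask <- function(shape, affine, center_mni, radius_mm) {
  if (radius_mm < 0) stop("radius must be >= 0")
  if (!in_field_of_view(shape, affine, center_mni)) {
    stop("sphere center (", paste(center_mni, collapse = ", "),
         ") lies outside the field of view")
  }
  cen <- voxel_centers_mni(shape, affine)
  d2 <- (cen[, 1] - center_mni[1])^2 + (cen[, 2] - center_mni[2])^2 +
    (cen[, 3] - center_mni[3])^2
  array(d2 <= radius_mm^2 + 1e-9, dim = shape)
}

#' Extract per-subject ROI gray-matter volumes
#'
#' For each region of interest the gray-matter volume is the sum of density
#' over the sphere voxels times the voxel volume, reported in milliliters.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param rois data.frame with columns \code{name, x, y, z, radius_mm}
#'   (e.g. \code{\link{seed_table}()} or a cluster-peak table).
#' @return numeric matrix, subjects x ROIs, in mL; column names are ROI
#'   names, row names subject ids.
#' @export
extract_volumes <- function(cohort, rois) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (nrow(rois) == 0) {
    out <- matrix(numeric(0), nrow = nrow(cohort$volumes), ncol = 0)
    rownames(out) <- cohort$phenotypes$subject_id
    return(out)
  }
  vv <- voxel_volume_ml(cohort$affine)
  out <- vapply(seq_len(nrow(rois)), function(r) {
    m <- sphere_mask(cohort$shape, cohort$affine,
                     c(rois$x[r], rois$y[r], rois$z[r]), rois$radius_mm[r])
    rowSums(cohort$volumes[, as.vector(m), drop = FALSE]) * vv
  }, numeric(nrow(cohort$volumes)))
  out <- matrix(out, nrow = nrow(cohort$volumes))
  dimnames(out) <- list(cohort$phenotypes$subject_id, rois$name)
  out
}
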