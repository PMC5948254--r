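#' Gray-matter volume object
#'
#' A single subject's spatially normalized, modulated gray-matter density
#' image: a 3D array of unitless tissue density (non-negative, typically in
#' [0, ~1.5] after modulation) together with the 4 x 4 voxel-to-MNI affine.
#'
#' @param data 3D numeric array of gray-matter density.
#' @param affine 4 x 4 invertible voxel-index (0-based) to MNI-mm transform.
#' @return an object of class \code{gm_volume} with elements \code{data},
#'   \code{affine} and \code{voxel_size} (mm per axis, derived from the
#'   affine).
#' @export
gm_volume <- function(data, affine) {
  if (length(dim(data)) != 3) stop("expected 3D volume")
  if (!all(is.finite(data))) stop("volume contains non-finite voxels")
  if (any(data < 0)) stop("gray-matter density must be non-negative")
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 64) {
    stop("affine is not invertible")
  }
  structure(
    list(data = data, affine = affine, voxel_size = voxel_size(affine)),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("gm_volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "),
      "mm, density range [", signif(min(x$data), 4), ",",
      signif(max(x$data), 4), "]\n")
  invisible(x)
}

#' Read a gray-matter volume from a NIfTI-1 file
#'
#' @param path path to a .nii or .nii.gz file holding a 3D image.
#' @return a \code{\link{gm_volume}}.
#' @export
read_gm_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected 3D volume, got ",
                                  length(dim(img)), "D: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  dat <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(dat))) stop("volume contains NaN/Inf voxels: ", path)
  gm_volume(dat, aff)
}

#' Write a gray-matter volume as NIfTI-1
#'
#' Data are stored as float32 on disk (the NIfTI convention); computation in
#' the package is double precision.
#'
#' @param vol a \code{\link{gm_volume}}.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
write_gm_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# write an arbitrary 3D statistic array (may be negative / NA) as NIfTI
write_stat_nifti <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# sampled, normalized 1D Gaussian kernel; radius 4 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# zero-padded separable convolution of a 3D array along one axis
convolve_axis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1) return(arr * kernel)
  r <- (nk - 1L) / 2L
  out <- array(0, dim = dim(arr))
  n <- dim(arr)[axis]
  idx <- list(TRUE, TRUE, TRUE)
  for (j in seq_len(nk)) {
    off <- j - 1L - r                     # source = dest + off
    src <- idx; dst <- idx
    lo <- max(1L, 1L - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst[[axis]] <- lo:hi
    src[[axis]] <- (lo + off):(hi + off)
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] +
      kernel[j] * arr[src[[1]], src[[2]], src[[3]]]
  }
  out
}

# core smoother on a plain array given per-axis sigma in voxels
smooth_array <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_vox[axis]), axis)
    }
  }
  arr
}

#' Gaussian smoothing of a gray-matter volume
#'
#' Separable zero-padded Gaussian convolution. Anisotropic voxels are handled
#' with a per-axis sigma of \code{fwhm / (voxel_size * 2 sqrt(2 log 2))}.
#' For images whose non-zero support leaves a margin of at least 3 sigma the
#' total voxel sum is preserved to high relative accuracy.
#'
#' @param vol a \code{\link{gm_volume}}.
#' @param fwhm_mm full width at half maximum of the kernel, in mm
#'   (\code{0} returns the input unchanged).
#' @return a smoothed \code{\link{gm_volume}} with identical geometry.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (vol$voxel_size * 2 * sqrt(2 * log(2)))
  out <- smooth_array(vol$data, sigma_vox)
  gm_volume(pmax(out, 0), vol$affine)
}

#' Analysis mask from a cohort
#'
#' A voxel enters the analysis if the mean gray-matter density across
#' subjects is positive and at least \code{threshold} (so \code{threshold =
#' 0} selects every voxel with positive mean). The rule is deterministic
#' given the cohort and threshold; the threshold is configurable because
#' published VBM pipelines rarely state their implicit mask.
#'
#' @param cohort a \code{\link{cohort}} object.
#' @param threshold minimum mean density for inclusion (default 0.1).
#' @return a logical 3D array with the cohort geometry.
#' @export
analysis_mask <- function(cohort, threshold = 0.1) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (nrow(cohort$volumes) == 0) stop("empty cohort")
  mu <- colMeans(cohort$volumes)
  array(mu > 0 & mu >= threshold, dim = cohort$shape)
}

#' Analysis configuration
#'
#' Collects every statistical threshold used by the pipeline: the FDR level
#' for covariance (SCN) and interaction maps, the FDR level for the
#' voxel-wise group comparison, the cluster-extent threshold, sphere radius,
#' smoothing kernel, cluster connectivity and the scalar-test alpha.
#'
#' @param scn_q FDR level for SCN and interaction maps (default 0.01).
#' @param group_q FDR level for the voxel-wise group comparison (default
#'   0.05).
#' @param min_cluster_voxels minimum cluster extent in voxels (default 100).
#' @param sphere_radius_mm seed / peak sphere radius in mm (default 4).
#' @param smoothing_fwhm_mm Gaussian kernel FWHM in mm (default 8).
#' @param connectivity cluster neighborhood: 6, 18 or 26 (default 18).
#' @param alpha significance level for scalar tests (default 0.05).
#' @param mask_threshold mean-density threshold for the analysis mask.
#' @param nuisance character vector of phenotype columns to add as nuisance
#'   covariates in the voxel-wise models (default none).
#' @param rng_seed integer seed for any randomized step.
#' @return a list of class \code{scn_config}.
#' @export
analysis_config <- function(scn_q = 0.01, group_q = 0.05,
                            min_cluster_voxels = 100L,
                            sphere_radius_mm = 4, smoothing_fwhm_mm = 8,
                            connectivity = 18L, alpha = 0.05,
                            mask_threshold = 0.1,
                            nuisance = character(0), rng_seed = 1L) {
  if (scn_q <= 0 || scn_q >= 1) stop("scn_q must lie in (0,1)")
  if (group_q <= 0 || group_q >= 1) stop("group_q must lie in (0,1)")
  if (min_cluster_voxels < 1) stop("min_cluster_voxels must be >= 1")
  if (sphere_radius_mm < 0) stop("sphere_radius_mm must be >= 0")
  if (smoothing_fwhm_mm < 0) stop("smoothing_fwhm_mm must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  structure(list(
    scn_q = scn_q, group_q = group_q,
    min_cluster_voxels = as.integer(min_cluster_voxels),
    sphere_radius_mm = sphere_radius_mm,
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    connectivity = as.integer(connectivity), alpha = alpha,
    mask_threshold = mask_threshold, nuisance = nuisance,
    rng_seed = as.integer(rng_seed)
  ), class = "scn_config")
}

# fixed phenotype schema (leading columns; score columns follow)
phenotype_id_cols <- c("subject_id", "genotype", "group", "age",
                       "education", "sex", "apoe4")

check_phenotypes <- function(ph) {
  missing <- setdiff(phenotype_id_cols, names(ph))
  if (length(missing)) {
    stop("phenotype table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!all(ph$genotype %in% c("MM", "MV", "VV"))) {
    stop("genotype must be one of MM, MV, VV")
  }
  if (!all(ph$group %in% c("Met", "Val"))) stop("group must be Met or Val")
  pooled <- ifelse(ph$genotype == "VV", "Val", "Met")
  if (!all(pooled == ph$group)) {
    stop("group column inconsistent with genotype pooling (MM/MV -> Met)")
  }
  invisible(ph)
}

#' Read / write a phenotype table
#'
#' Tab-separated text with one header row. The schema fixes the leading
#' columns \code{subject_id, genotype (MM/MV/VV), group (Met/Val), age,
#' education, sex, apoe4}; any further columns are treated as behavioral
#' scores. The \code{group} column must equal the genotype pooling rule
#' MM/MV -> Met, VV -> Val.
#'
#' @param path file path.
#' @return \code{read_phenotypes}: a data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ph <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  check_phenotypes(ph)
}

#' @rdname read_phenotypes
#' @param phenotypes a phenotype data.frame following the schema.
#' @return \code{write_phenotypes}: \code{path}, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  check_phenotypes(phenotypes)
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
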