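#' Default image geometry affine
#'
#' Builds a NIfTI-style affine (0-based voxel index to MNI mm, RAS) for an
#' isotropic grid positioned so that the MNI origin falls exactly on a voxel
#' center. The default 40 x 48 x 40 grid at 4 mm spacing spans roughly
#' -76..80 mm per axis, which contains all ten default seed coordinates.
#'
#' @param shape integer vector of length 3, grid dimensions.
#' @param voxel_mm voxel edge length in mm (isotropic).
#' @return a 4 x 4 affine matrix.
#' @export
mni_affine <- function(shape = c(40L, 48L, 40L), voxel_mm = 4) {
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_mm > 0)
  origin <- -voxel_mm * floor((shape - 1) / 2)
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

#' Voxel size from an affine
#'
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @return length-3 vector of mm per voxel along each array axis.
#' @export
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# volume of one voxel in milliliters (|det| of the linear part, mm^3 -> mL)
voxel_volume_ml <- function(affine) {
  abs(det(affine[1:3, 1:3])) / 1000
}

#' MNI coordinates of every voxel center
#'
#' @param shape grid dimensions.
#' @param affine 4 x 4 voxel-to-mm matrix (0-based voxel indices).
#' @return an (prod(shape)) x 3 matrix of mm coordinates, rows in R array
#'   (column-major) order.
#' @export
voxel_centers_mni <- function(shape, affine) {
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape) - 1L
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

#' Map an MNI coordinate to (continuous, 1-based) voxel index
#'
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param xyz length-3 mm coordinate.
#' @return length-3 continuous voxel index (1-based).
#' @export
mni_to_voxel <- function(affine, xyz) {
  stopifnot(length(xyz) == 3)
  as.numeric(solve(affine[1:3, 1:3], as.numeric(xyz) - affine[1:3, 4])) + 1
}

# checks an MNI point lies within the voxel-center bounding box of the grid
in_field_of_view <- function(shape, affine, xyz) {
  v <- mni_to_voxel(affine, xyz)
  all(v >= 1 - 1e-9) && all(v <= shape + 1e-9)
}

# all volumes entering one analysis must share shape and affine
check_same_geometry <- function(shape_a, affine_a, shape_b, affine_b,
                                what = "volumes") {
  if (!identical(as.integer(shape_a), as.integer(shape_b)) ||
      max(abs(affine_a - affine_b)) > 1e-6) {
    stop("geometry mismatch across ", what,
         ": all volumes in one analysis must share shape and affine")
  }
  invisible(TRUE)
}
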