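#' Cohort of gray-matter volumes with phenotypes
#'
#' Bundles the subjects' images (one row per subject, voxels flattened in R
#' array order) with the shared geometry and the phenotype table. All images
#' in one cohort must share shape and affine; this is checked at
#' construction.
#'
#' @param volumes list of \code{\link{gm_volume}} objects, or a numeric
#'   matrix of subjects x voxels (then \code{shape}/\code{affine} are
#'   required).
#' @param phenotypes phenotype data.frame (see \code{\link{read_phenotypes}});
#'   row order matches \code{volumes}.
#' @param shape,affine geometry, required when \code{volumes} is a matrix.
#' @param ground_truth optional list recording the simulation that produced
#'   the cohort (kept as-is; used by validation code).
#' @return an object of class \code{scn_cohort} with elements
#'   \code{volumes} (n x V matrix), \code{shape}, \code{affine},
#'   \code{phenotypes}, \code{ground_truth}.
#' @export
cohort <- function(volumes, phenotypes, shape = NULL, affine = NULL,
                   ground_truth = NULL) {
  check_phenotypes(phenotypes)
  if (is.list(volumes)) {
    if (length(volumes) == 0) stop("empty cohort")
    stopifnot(all(vapply(volumes, inherits, TRUE, "gm_volume")))
    shape <- dim(volumes[[1]]$data)
    affine <- volumes[[1]]$affine
    for (v in volumes) {
      check_same_geometry(shape, affine, dim(v$data), v$affine)
    }
    volumes <- do.call(rbind, lapply(volumes, function(v) as.numeric(v$data)))
  } else {
    if (is.null(shape) || is.null(affine)) {
      stop("shape and affine are required for matrix input")
    }
    volumes <- as.matrix(volumes)
    if (ncol(volumes) != prod(shape)) stop("volume matrix does not match shape")
  }
  if (nrow(volumes) != nrow(phenotypes)) {
    stop("number of volumes (", nrow(volumes),
         ") differs from phenotype rows (", nrow(phenotypes), ")")
  }
  rownames(volumes) <- phenotypes$subject_id
  structure(list(
    volumes = volumes, shape = as.integer(shape),
    affine = unname(as.matrix(affine)), phenotypes = phenotypes,
    ground_truth = ground_truth
  ), class = "scn_cohort")
}

#' @export
print.scn_cohort <- function(x, ...) {
  cat("scn_cohort:", nrow(x$volumes), "subjects (",
      sum(x$phenotypes$group == "Met"), "Met /",
      sum(x$phenotypes$group == "Val"), "Val ),",
      paste(x$shape, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Extract one subject's image from a cohort
#'
#' @param cohort a \code{\link{cohort}}.
#' @param i subject row index or subject_id.
#' @return a \code{\link{gm_volume}}.
#' @export
cohort_volume <- function(cohort, i) {
  stopifnot(inherits(cohort, "scn_cohort"))
  gm_volume(array(cohort$volumes[i, ], dim = cohort$shape), cohort$affine)
}

#' Subset a cohort to one genotype group
#'
#' @param cohort a \code{\link{cohort}}.
#' @param group \code{"Met"} (Met/Met and Val/Met carriers pooled) or
#'   \code{"Val"} (Val homozygotes).
#' @return a new \code{scn_cohort}.
#' @export
cohort_group <- function(cohort, group = c("Met", "Val")) {
  stopifnot(inherits(cohort, "scn_cohort"))
  group <- match.arg(group)
  keep <- cohort$phenotypes$group == group
  if (!any(keep)) stop("no subjects in group ", group)
  structure(list(
    volumes = cohort$volumes[keep, , drop = FALSE], shape = cohort$shape,
    affine = cohort$affine,
    phenotypes = cohort$phenotypes[keep, , drop = FALSE],
    ground_truth = cohort$ground_truth
  ), class = "scn_cohort")
}
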