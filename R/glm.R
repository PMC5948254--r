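#' Mass-univariate voxel-wise ordinary least squares
#'
#' Fits, at every voxel, an OLS regression of voxel intensity on the design
#' matrix, and returns the slope, T statistic and p-value of one design
#' column. The computation is vectorized over voxels but numerically
#' identical to fitting each voxel separately. Voxels with zero residual
#' variance yield T = +/-Inf with p 0 or 1 under the requested sidedness;
#' their count is recorded in \code{n_zero_residual}.
#'
#' @param volumes numeric matrix, subjects x voxels (typically the masked
#'   columns of \code{cohort$volumes}).
#' @param design numeric design matrix, subjects x columns, full column rank.
#' @param contrast_index column of interest (T = beta / SE for that column).
#' @param sided \code{"greater"} (one-sided positive), \code{"less"} or
#'   \code{"two.sided"}.
#' @param contrast_label free-text label stored on the result.
#' @return an object of class \code{scn_statmap}: list with \code{beta},
#'   \code{tstat}, \code{p} (vectors over the supplied voxels), \code{df},
#'   \code{sided}, \code{contrast_label}, \code{n_zero_residual}.
#' @export
fit_voxelwise <- function(volumes, design,
                          contrast_index = ncol(design),
                          sided = c("greater", "two.sided", "less"),
                          contrast_label = "") {
  sided <- match.arg(sided)
  Y <- as.matrix(volumes)
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("design rows must match number of subjects")
  if (n <= p) stop("need more subjects than design columns")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qx))
  beta_all <- xtx_inv %*% crossprod(X, Y)          # p x V
  resid <- Y - X %*% beta_all
  df <- n - p
  rss <- colSums(resid^2)
  # residuals indistinguishable from exact fit at double precision
  scale_y <- colSums(Y^2)
  zero_var <- rss <= scale_y * 1e-20 | scale_y == 0
  rss[zero_var] <- 0
  se <- sqrt(rss / df * xtx_inv[contrast_index, contrast_index])
  beta <- beta_all[contrast_index, ]
  tstat <- beta / se                               # se = 0 -> +/-Inf or NaN
  beta_null <- abs(beta) <= sqrt(scale_y) * 1e-10
  tstat[zero_var & beta_null] <- 0                 # exactly constant voxel
  p_val <- switch(sided,
    greater = stats::pt(tstat, df, lower.tail = FALSE),
    less = stats::pt(tstat, df, lower.tail = TRUE),
    two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  )
  structure(list(
    beta = unname(beta), tstat = unname(tstat), p = unname(p_val),
    df = df, sided = sided, contrast_label = contrast_label,
    n_zero_residual = sum(zero_var)
  ), class = "scn_statmap")
}

#' @export
print.scn_statmap <- function(x, ...) {
  cat("scn_statmap '", x$contrast_label, "': ", length(x$tstat),
      " voxels, df = ", x$df, ", ", x$sided, "; max T = ",
      signif(max(x$tstat[is.finite(x$tstat)]), 4), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up rule: with sorted p-values, find the largest k such that
#' p_(k) <= k q / m and select every p at or below p_(k); nothing is
#' selected when no such k exists.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return logical vector of the same length.
#' @export
fdr_select <- function(p_values, q) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  if (is.null(keep)) stop("connectivity must be 6, 18 or 26")
  g[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters
#'
#' Connected components of the selection mask under the chosen voxel
#' neighborhood; components smaller than \code{min_size} voxels are
#' discarded. Each cluster's peak is its member voxel with maximal T (ties
#' broken by the smallest linear voxel index). Records are sorted by
#' descending peak T.
#'
#' @param selection logical 3D array of suprathreshold voxels.
#' @param tstat numeric 3D array of T values (same shape).
#' @param min_size minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param affine optional 4 x 4 affine; when given, peak coordinates are
#'   reported in MNI mm, otherwise in (1-based) voxel indices.
#' @return data.frame with columns \code{cluster_id, size_voxels, peak_x,
#'   peak_y, peak_z, peak_t} and a list column \code{members} of linear
#'   voxel indices.
#' @export
extract_clusters <- function(selection, tstat, min_size = 100L,
                             connectivity = 18L, affine = NULL) {
  stopifnot(identical(dim(selection), dim(tstat)))
  shape <- dim(selection)
  empty <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0))
  empty$members <- list()
  supra <- which(selection)
  if (length(supra) == 0) return(empty)

  rank_of <- array(0L, dim = shape)
  rank_of[supra] <- seq_along(supra)
  coords <- arrayInd(supra, .dim = shape)
  offs <- connectivity_offsets(connectivity)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0),
               , drop = FALSE]              # half the offsets suffice
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * shape[1] * shape[2] +
      (nb[ok, 2] - 1L) * shape[1] + nb[ok, 1]
    r <- rank_of[lin]
    hit <- r > 0L
    if (any(hit)) {
      edges[[o]] <- cbind(which(ok)[hit], r[hit])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  membership <- igraph::components(g)$membership

  tv <- tstat[supra]
  recs <- lapply(split(seq_along(supra), membership), function(ix) {
    if (length(ix) < min_size) return(NULL)
    tt <- tv[ix]
    best <- ix[which(tt == max(tt))]
    peak <- best[which.min(supra[best])]     # lexicographic tie-break
    pc <- coords[peak, ]
    if (!is.null(affine)) {
      pc <- as.numeric(affine[1:3, 1:3] %*% (pc - 1) + affine[1:3, 4])
    }
    list(size = length(ix), peak_xyz = pc, peak_t = tv[peak],
         members = supra[ix])
  })
  recs <- unname(Filter(Negate(is.null), recs))
  if (length(recs) == 0) return(empty)
  recs <- recs[order(vapply(recs, `[[`, 1, "peak_t"), decreasing = TRUE)]
  out <- data.frame(
    cluster_id = seq_along(recs),
    size_voxels = vapply(recs, `[[`, 1, "size"),
    peak_x = vapply(recs, function(r) r$peak_xyz[1], 1),
    peak_y = vapply(recs, function(r) r$peak_xyz[2], 1),
    peak_z = vapply(recs, function(r) r$peak_xyz[3], 1),
    peak_t = vapply(recs, `[[`, 1, "peak_t")
  )
  out$members <- lapply(recs, `[[`, "members")
  out
}

# place a masked-voxel vector into a full 3D array (NA outside the mask)
vector_to_array <- function(values, mask) {
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- values
  out
}

# design matrix: intercept + covariate (+ phenotype nuisance columns)
scn_design <- function(covariate, phenotypes, nuisance) {
  X <- cbind(intercept = 1, seed = covariate)
  for (nm in nuisance) {
    v <- phenotypes[[nm]]
    if (is.null(v)) stop("nuisance column not in phenotypes: ", nm)
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  X
}

#' Build one seed's structural covariance network for one group
#'
#' Extracts the seed sphere volume per subject, regresses every in-mask
#' voxel on it (one-sided positive T contrast), applies Benjamini-Hochberg
#' FDR at \code{config$scn_q} within the analysis mask, and reports
#' suprathreshold clusters of at least \code{config$min_cluster_voxels}
#' voxels. The seed's own sphere is excluded from cluster reporting
#' (self-covariance is trivial).
#'
#' @param cohort_group a single-group \code{\link{cohort}} (see
#'   \code{\link{cohort_group}}).
#' @param seed_name name of a seed in \code{seeds}.
#' @param config an \code{\link{analysis_config}}.
#' @param seeds seed table (default \code{\link{seed_table}()}).
#' @param mask optional precomputed analysis mask (logical 3D array).
#' @return list with \code{statmap} (an \code{scn_statmap} augmented with
#'   \code{mask}, \code{q_mask}, \code{shape}, \code{affine}),
#'   \code{clusters} (cluster table in MNI mm) and \code{seed_volumes}.
#' @export
build_scn <- function(cohort_group, seed_name, config = analysis_config(),
                      seeds = seed_table(), mask = NULL) {
  stopifnot(inherits(cohort_group, "scn_cohort"))
  if (nrow(cohort_group$volumes) == 0) stop("empty group")
  row <- seeds[seeds$name == seed_name, ]
  if (nrow(row) != 1) stop("unknown seed: ", seed_name)
  if (is.null(mask)) {
    mask <- analysis_mask(cohort_group, config$mask_threshold)
  }
  if (!any(mask)) stop("analysis mask is empty")
  roi <- data.frame(name = row$name, x = row$x, y = row$y, z = row$z,
                    radius_mm = config$sphere_radius_mm)
  sv <- extract_volumes(cohort_group, roi)[, 1]
  X <- scn_design(sv, cohort_group$phenotypes, config$nuisance)
  sm <- fit_voxelwise(cohort_group$volumes[, as.vector(mask), drop = FALSE],
                      X, contrast_index = 2, sided = "greater",
                      contrast_label = paste0("scn:", seed_name))
  sm$shape <- cohort_group$shape
  sm$affine <- cohort_group$affine
  sm$mask <- mask
  sel <- fdr_select(sm$p, config$scn_q)
  sm$q_mask <- vector_to_array(sel, mask)
  sm$q_mask[is.na(sm$q_mask)] <- FALSE
  sm$q_mask <- array(as.logical(sm$q_mask), dim = dim(mask))

  smask <- sphere_mask(cohort_group$shape, cohort_group$affine,
                       c(row$x, row$y, row$z), config$sphere_radius_mm)
  sel_arr <- sm$q_mask & !smask
  tarr <- vector_to_array(sm$tstat, mask)
  tarr[is.na(tarr)] <- -Inf
  clusters <- extract_clusters(sel_arr, tarr, config$min_cluster_voxels,
                               config$connectivity, cohort_group$affine)
  list(statmap = sm, clusters = clusters, seed_volumes = sv)
}

#' Voxel-wise group difference map
#'
#' Two-sided T contrast on the group indicator (Met = 1, Val = 0) of the
#' model \code{voxel ~ 1 + group (+ nuisance)}, with FDR control at
#' \code{config$group_q} and cluster-extent filtering.
#'
#' @inheritParams build_scn
#' @param cohort a two-group \code{\link{cohort}}.
#' @return list with \code{statmap} and \code{clusters}.
#' @export
group_difference_map <- function(cohort, config = analysis_config(),
                                 mask = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (is.null(mask)) mask <- analysis_mask(cohort, config$mask_threshold)
  if (!any(mask)) stop("analysis mask is empty")
  gi <- as.numeric(cohort$phenotypes$group == "Met")
  if (length(unique(gi)) < 2) stop("both genotype groups are required")
  X <- scn_design(gi, cohort$phenotypes, config$nuisance)
  colnames(X)[2] <- "group"
  sm <- fit_voxelwise(cohort$volumes[, as.vector(mask), drop = FALSE], X,
                      contrast_index = 2, sided = "two.sided",
                      contrast_label = "group:Met-Val")
  sm$shape <- cohort$shape; sm$affine <- cohort$affine; sm$mask <- mask
  sel <- fdr_select(sm$p, config$group_q)
  sm$q_mask <- vector_to_array(sel, mask)
  sm$q_mask[is.na(sm$q_mask)] <- FALSE
  sm$q_mask <- array(as.logical(sm$q_mask), dim = dim(mask))
  tarr <- vector_to_array(abs(sm$tstat), mask)
  tarr[is.na(tarr)] <- -Inf
  clusters <- extract_clusters(sm$q_mask, tarr, config$min_cluster_voxels,
                               config$connectivity, cohort$affine)
  list(statmap = sm, clusters = clusters)
}
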