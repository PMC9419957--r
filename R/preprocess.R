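#' Network specification
#'
#' Named ROIs with MNI sphere centers. The default is the 8-node network of
#' the default mode (mPFC, PCC, bilateral IPC), salience (AI, ACC) and
#' central executive (dlPFC, pPFC) networks, each a 6 mm-radius sphere.
#'
#' @param roi_names Character vector.
#' @param mni_centers Numeric matrix, ROIs x 3 (mm).
#' @param radius_mm Sphere radius in mm.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(
    roi_names = c("mPFC", "PCC", "rIPC", "lIPC", "AI", "ACC", "dlPFC", "pPFC"),
    mni_centers = rbind(c(3, 54, -2), c(0, -52, 26), c(48, -69, 35),
                        c(-50, -63, 32), c(37, 25, -4), c(4, 30, 30),
                        c(45, 16, 45), c(54, -50, 50)),
    radius_mm = 6) {
  mni_centers <- as.matrix(mni_centers)
  stopifnot(length(roi_names) == nrow(mni_centers), ncol(mni_centers) == 3,
            radius_mm > 0)
  structure(list(roi_names = roi_names, mni_centers = mni_centers,
                 radius_mm = radius_mm), class = "network_spec")
}

#' MNI coordinates of the white-matter and CSF reference spheres
#' @return 2 x 3 matrix.
#' @export
wm_csf_centers <- function() {
  rbind(WM = c(0, -24, -33), CSF = c(0, -40, -5))
}

#' Voxel indices of a sphere in a gridded volume
#'
#' Returns the 0-based voxel indices (and their array subscripts) whose
#' centers lie within `radius_mm` of `center_mm` under the given voxel-to-mm
#' affine. The affine is authoritative for the mm/voxel mapping; no
#' orientation is assumed.
#'
#' @param center_mm Length-3 center in mm.
#' @param radius_mm Sphere radius in mm.
#' @param affine 4 x 4 voxel-to-mm map (0-based voxel indices).
#' @param grid_shape Integer length-3 array dimensions.
#' @return List with `index` (0-based linear indices, column-major) and
#'   `subscripts` (n x 3 matrix of 0-based voxel subscripts).
#' @export
sphere_mask <- function(center_mm, radius_mm, affine, grid_shape) {
  stopifnot(length(center_mm) == 3, length(grid_shape) == 3,
            all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine not invertible", call. = FALSE)
  # voxel coordinate of the center; search a bounding box around it
  cv <- solve(affine, c(center_mm, 1))[1:3]
  vox_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  half <- ceiling(radius_mm / vox_size) + 1
  rng <- lapply(1:3, function(d)
    max(0, floor(cv[d] - half[d])):min(grid_shape[d] - 1, ceiling(cv[d] + half[d])))
  if (any(lengths(rng) == 0))
    stop("sphere entirely outside the grid", call. = FALSE)
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- t(affine %*% t(cbind(grid, 1)))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  keep <- d2 <= radius_mm^2
  if (!any(keep))
    stop("sphere entirely outside the grid", call. = FALSE)
  sub <- grid[keep, , drop = FALSE]
  idx <- sub[, 1] + grid_shape[1] * (sub[, 2] + grid_shape[2] * sub[, 3])
  list(index = as.integer(idx), subscripts = unname(sub))
}

#' First eigenvariate of a voxel block
#'
#' The first principal-component time course of the column-demeaned block,
#' scaled to unit variance, with the sign fixed so that the mean voxel
#' loading is positive.
#'
#' @param block Numeric matrix, volumes x voxels.
#' @return Numeric vector of length `nrow(block)`.
#' @export
eigenvariate <- function(block) {
  block <- as.matrix(block)
  stopifnot(nrow(block) >= 2, ncol(block) >= 1)
  Xc <- sweep(block, 2, colMeans(block))
  if (max(abs(Xc)) == 0)
    stop("all-constant voxel block has no eigenvariate", call. = FALSE)
  sv <- svd(Xc, nu = 1, nv = 1)
  u <- sv$u[, 1]
  if (mean(sv$v[, 1]) < 0) u <- -u
  u / stats::sd(u)
}

#' Nuisance regression
#'
#' Least-squares residuals of each ROI column after projecting out an
#' intercept and all confound columns; residuals are orthogonal to every
#' confound column.
#'
#' @param series Volumes x ROI matrix.
#' @param confounds Volumes x K matrix (or a list with element `matrix`).
#' @return Residual matrix of the same shape as `series`.
#' @export
nuisance_regress <- function(series, confounds) {
  if (is.list(confounds) && !is.data.frame(confounds) &&
      !is.matrix(confounds)) confounds <- confounds$matrix
  series <- as.matrix(series); confounds <- as.matrix(confounds)
  stopifnot(nrow(series) == nrow(confounds))
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qr.resid(qx, series)
}

#' Extract ROI eigenvariate series from a 4-D volume
#'
#' For each ROI sphere: voxel time courses are nuisance-regressed against
#' the motion confounds plus the WM/CSF sphere eigenvariates, then
#' summarized by their first eigenvariate.
#'
#' @param volume_series 4-D array (x, y, z, time).
#' @param affine 4 x 4 voxel-to-mm map.
#' @param spec A [network_spec()].
#' @param motion Optional volumes x 12 motion-parameter matrix.
#' @param wm_csf Either `"spheres"` (extract eigenvariates at the canonical
#'   WM/CSF coordinates; the default) or a volumes x 2 matrix of precomputed
#'   regressors, or `NULL` to omit them.
#' @return Volumes x ROI matrix with columns in `spec$roi_names` order.
#' @export
extract_roi_series <- function(volume_series, affine, spec = network_spec(),
                               motion = NULL, wm_csf = "spheres") {
  stopifnot(length(dim(volume_series)) == 4)
  shp <- dim(volume_series)[1:3]
  n_vol <- dim(volume_series)[4]
  vmat <- matrix(volume_series, prod(shp), n_vol)
  block_of <- function(center, label) {
    m <- tryCatch(sphere_mask(center, spec$radius_mm, affine, shp),
                  error = function(e)
                    stop("empty sphere for ", label, ": ", conditionMessage(e),
                         call. = FALSE))
    t(vmat[m$index + 1L, , drop = FALSE])
  }
  conf <- NULL
  if (identical(wm_csf, "spheres")) {
    ctr <- wm_csf_centers()
    conf <- cbind(WM = eigenvariate(block_of(ctr[1, ], "WM")),
                  CSF = eigenvariate(block_of(ctr[2, ], "CSF")))
  } else if (is.matrix(wm_csf)) conf <- wm_csf
  if (!is.null(motion)) conf <- cbind(motion, conf)
  out <- sapply(seq_along(spec$roi_names), function(r) {
    blk <- block_of(spec$mni_centers[r, ], spec$roi_names[r])
    if (!is.null(conf)) blk <- nuisance_regress(blk, conf)
    eigenvariate(blk)
  })
  colnames(out) <- spec$roi_names
  out
}

#' Read a 4-D NIfTI volume and its affine
#'
#' Thin wrapper around the RNifti reader (suggested dependency).
#'
#' @param path NIfTI file path.
#' @return List with `data` (4-D array) and `affine` (4 x 4 voxel-to-mm,
#'   0-based voxel indices).
#' @export
read_nifti_series <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unname(RNifti::xform(img)))
}
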