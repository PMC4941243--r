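#' Default scanner-space affine for a voxel grid
#'
#' Builds a 4x4 RAS affine for an isotropic grid centred near the origin,
#' so that (0-based) voxel index `(i, j, k)` maps to millimetre coordinates
#' `origin + voxel_size_mm * (i, j, k)`.
#'
#' @param grid_shape Integer vector of three voxel counts.
#' @param voxel_size_mm Isotropic voxel edge length in millimetres.
#' @param origin Millimetre coordinate of voxel (0, 0, 0). Defaults to
#'   `-voxel_size_mm * grid_shape / 2`, placing the grid centre at MNI-style
#'   coordinates close to zero.
#' @return A 4x4 numeric affine matrix.
#' @export
default_affine <- function(grid_shape, voxel_size_mm = 3,
                           origin = -voxel_size_mm * grid_shape / 2) {
  stopifnot(length(grid_shape) == 3, voxel_size_mm > 0, length(origin) == 3)
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

#' Map voxel indices to scanner (MNI) millimetre coordinates
#'
#' Accepts 1-based R array indices; the affine follows the NIfTI convention
#' of 0-based voxel indices, so 1 is subtracted internally.
#'
#' @param ijk Integer vector of three 1-based voxel indices, or an n x 3
#'   matrix of them.
#' @param affine 4x4 affine matrix.
#' @return Millimetre coordinates, same shape as the input.
#' @export
voxel_to_mni <- function(ijk, affine) {
  m <- rbind(t(matrix(as.numeric(ijk), ncol = 3)) - 1, 1)
  out <- t(affine %*% m)[, 1:3, drop = FALSE]
  if (is.null(dim(ijk))) drop(out) else out
}

#' Voxel volume implied by an affine
#' @param affine 4x4 affine matrix.
#' @return Volume of one voxel in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(affine) {
  abs(det(affine[1:3, 1:3]))
}

#' Convert a cluster extent from voxels to cubic millimetres
#' @param n_voxels Cluster extent in voxels.
#' @param voxel_size_mm Isotropic voxel edge length in millimetres.
#' @return Extent in cubic millimetres.
#' @export
extent_to_mm3 <- function(n_voxels, voxel_size_mm = 3) {
  stopifnot(n_voxels >= 0, voxel_size_mm > 0)
  n_voxels * voxel_size_mm^3
}

#' Central ellipsoid brain mask for a desk-scale grid
#'
#' @param grid_shape Integer vector of three voxel counts.
#' @param margin_vox Number of voxels to leave clear of each face.
#' @return Logical 3D array, `TRUE` inside the ellipsoid.
#' @export
ellipsoid_mask <- function(grid_shape, margin_vox = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape > 2 * margin_vox))
  centre <- (grid_shape + 1) / 2
  semi <- grid_shape / 2 - margin_vox
  idx <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - centre[a]) / semi[a])^2)
  d2 <- outer(outer(idx[[1]], idx[[2]], "+"), idx[[3]], "+")
  array(d2 <= 1, dim = grid_shape)
}

#' Spherical blob mask around a voxel centre
#' @param grid_shape Three voxel counts.
#' @param center_voxel Three 1-based voxel indices.
#' @param radius_vox Radius in voxels.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(grid_shape, center_voxel, radius_vox) {
  stopifnot(length(grid_shape) == 3, length(center_voxel) == 3, radius_vox >= 0)
  idx <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - center_voxel[a])^2)
  d2 <- outer(outer(idx[[1]], idx[[2]], "+"), idx[[3]], "+")
  array(d2 <= radius_vox^2, dim = grid_shape)
}

# Derive a reproducible sub-stream seed from a master seed. Streams are named
# so any stage can be replayed in isolation; the result stays inside the
# 32-bit integer range R requires of set.seed().
stream_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 1e6) * 2017 + h * 131 + index) %% 2147483647L
}

#' Write a 3D or 4D volume as NIfTI-1
#'
#' @param data Numeric 3D or 4D array.
#' @param affine 4x4 affine matrix.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param tr_s Repetition time in seconds, stored in the header for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, affine, path, tr_s = NULL) {
  img <- RNifti::asNifti(data)
  scales <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- if (!is.null(tr_s) && length(dim(data)) == 4) c(scales, tr_s) else scales
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume with its affine
#' @param path NIfTI file path.
#' @return List with `data` (numeric array) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.vector(img), dim = dim(img)),
       affine = matrix(as.vector(aff), 4, 4))
}
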