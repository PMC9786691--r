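#' Inter-slice smoothing of a segmentation mask
#'
#' Manual slice-wise drawing leaves step discontinuities between slices; this
#' smooths the binary mask with a 1D Gaussian along the slice axis only
#' (sigma in mm, converted to voxels via the axis spacing) and re-thresholds
#' at 0.5. The 0.5 level is volume-preserving for symmetric edges; thin
#' single-slice plates (peak Gaussian weight below 0.5) vanish.
#'
#' @param mask A binary `pf_volume`.
#' @param sigma Gaussian sigma in mm (default 1.25).
#' @param axis slice axis (1, 2 or 3; default 3).
#' @return Smoothed binary `pf_volume` on the same grid.
#' @export
smooth_interslice <- function(mask, sigma = 1.25, axis = 3L) {
  if (sigma <= 0) stop("sigma must be > 0")
  sig_vox <- sigma / mask$spacing[axis]
  k <- gaussian_kernel(sig_vox)
  sm <- conv_axis(mask$values, k, axis, pad = "replicate")
  label_mask(sm >= 0.5, mask$spacing, mask$origin)
}

#' Morphological dilation by a Euclidean ball
#'
#' Dilation with a ball of physical radius in mm, via the exact Euclidean
#' distance transform: a voxel is set when its centre lies within `radius`
#' of a mask voxel centre. `radius = 0` is the identity; the result always
#' contains the input.
#'
#' @param mask A binary `pf_volume`.
#' @param radius ball radius in mm (default 3).
#' @export
dilate_mask <- function(mask, radius = 3.0) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0 || mask_count(mask) == 0) return(mask)
  d <- distance_map(mask)
  label_mask(d$values <= radius + 1e-9, mask$spacing, mask$origin)
}

#' Morphological erosion by a Euclidean ball
#'
#' Dual of [dilate_mask()] under the same lattice convention: a voxel
#' survives when no background voxel centre lies within `radius` of it.
#' @inheritParams dilate_mask
#' @export
erode_mask <- function(mask, radius = 3.0) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(mask)
  bg <- label_mask(mask$values == 0, mask$spacing, mask$origin)
  if (mask_count(bg) == 0) return(mask)
  d <- distance_map(bg)
  label_mask(mask$values != 0 & d$values > radius + 1e-9,
             mask$spacing, mask$origin)
}

#' Isosurface mesh of a binary mask
#'
#' The mask is padded with background, smoothed with a small 3D Gaussian
#' (1 voxel, a fixed constant of the pipeline chosen so that the voxel
#' staircase does not bias the mesh area) and contoured at level 0.5 with a marching-tetrahedra
#' isosurfacer. The result is a watertight mesh in world mm with outward
#' normals; its area converges to the analytic surface area as spacing
#' shrinks.
#'
#' @param mask A nonempty binary `pf_volume`.
#' @param presmooth_sigma_vox 3D pre-smoothing sigma in voxels.
#' @return A `pf_mesh`.
#' @export
extract_surface <- function(mask, presmooth_sigma_vox = 1.0) {
  if (mask_count(mask) == 0) stop("cannot extract a surface from an empty mask")
  pad <- max(3L, ceiling(4 * presmooth_sigma_vox) + 1L)
  d <- dim(mask$values)
  padded <- array(0, d + 2L * pad)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$values
  if (presmooth_sigma_vox > 0)
    padded <- smooth3d(padded, presmooth_sigma_vox, pad = "zero")
  res <- .march_tets_cpp(as.numeric(padded), dim(padded), mask$spacing,
                         mask$origin - pad * mask$spacing, 0.5)
  surface_mesh(res$vertices, res$faces)
}

#' Articular (mutually facing) subsurface of a cartilage mesh
#'
#' Keeps the faces of `cart_mesh` that look toward the opposing cartilage:
#' the outward normal must have a positive component along the direction to
#' the closest opposing point, and the opposing face must look back. Used to
#' restrict contact measurements to the two opposing articular surfaces.
#'
#' @param cart_mesh measurement-side cartilage `pf_mesh`.
#' @param opposing_mesh opposing cartilage `pf_mesh`.
#' @return A `pf_mesh` face subset (possibly empty, with a warning).
#' @export
articular_subsurface <- function(cart_mesh, opposing_mesh) {
  if (nrow(cart_mesh$faces) == 0 || nrow(opposing_mesh$faces) == 0)
    stop("both meshes must be nonempty")
  cen <- face_centroids(cart_mesh)
  cl <- mesh_closest_points(opposing_mesh, cen)
  dir <- cl$point - cen
  nrm <- sqrt(rowSums(dir^2))
  ok_dist <- nrm > 1e-12
  dir[ok_dist, ] <- dir[ok_dist, , drop = FALSE] / nrm[ok_dist]
  n_meas <- face_normals(cart_mesh)
  n_opp <- face_normals(opposing_mesh)[cl$face, , drop = FALSE]
  facing <- rowSums(n_meas * dir) > 0 & rowSums(n_opp * dir) < 0
  facing <- facing | !ok_dist  # touching faces count as facing
  if (!any(facing)) {
    warning("no mutually facing faces; returning an empty subsurface")
    return(surface_mesh(matrix(numeric(0), 0, 3),
                        matrix(integer(0), 0, 3)))
  }
  mesh_subset(cart_mesh, facing)
}
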