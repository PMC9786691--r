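#' Apply a rigid transform to a mesh or volume
#'
#' Meshes are mapped exactly (vertices transformed). Volumes are resampled
#' onto their own grid with trilinear interpolation through the inverse
#' transform; binary masks (detected automatically) are re-thresholded at
#' 0.5 after interpolation.
#'
#' @param obj A `pf_mesh` or `pf_volume`.
#' @param t A `pf_transform`.
#' @param ... passed to methods.
#' @return Object of the same class as `obj`.
#' @export
apply_transform <- function(obj, t, ...) UseMethod("apply_transform")

#' @rdname apply_transform
#' @export
apply_transform.pf_mesh <- function(obj, t, ...) {
  surface_mesh(transform_points(t, obj$vertices), obj$faces)
}

#' @rdname apply_transform
#' @param outside fill value for voxels that map outside the source grid.
#' @export
apply_transform.pf_volume <- function(obj, t, outside = 0, ...) {
  binary <- is_binary_volume(obj)
  ti <- invert_transform(t)
  d <- dim(obj$values)
  ax <- grid_axes(obj)
  n <- prod(d)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  vals <- sample_volume(obj, transform_points(ti, pts), outside = outside)
  out <- array(vals, d)
  if (binary) out <- array(as.numeric(out >= 0.5), d)
  image_volume(out, obj$spacing, obj$origin)
}

#' Trimmed iterative closest point alignment of two surface meshes
#'
#' Alternates exact closest-point correspondence (point-to-surface, via the
#' mesh grid query) with the closed-form least-squares rigid update (Kabsch,
#' via SVD), discarding the worst 10% of correspondences each iteration for
#' robustness to partial overlap. Iterates until the mean correspondence
#' distance changes by less than `tol` mm or `max_iter` is reached.
#'
#' @param source,target `pf_mesh` objects with at least 100 vertices.
#' @param init initial `pf_transform` (source into target frame).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence threshold on the change of the mean trimmed
#'   correspondence distance, in mm.
#' @param trim fraction of worst correspondences discarded per iteration.
#' @param sample maximum number of source vertices used (deterministic
#'   uniform subsample).
#' @return A `pf_transform` mapping source into the target frame, with
#'   attributes `residual_rms` (mm) and `iterations`.
#' @export
icp_align <- function(source, target, init = rigid_transform(),
                      max_iter = 200L, tol = 1e-4, trim = 0.1,
                      sample = 5000L) {
  if (nrow(source$vertices) < 100 || nrow(target$vertices) < 100)
    stop("icp_align needs meshes with at least 100 vertices")
  p <- source$vertices
  if (nrow(p) > sample) {
    idx <- unique(round(seq(1, nrow(p), length.out = sample)))
    p <- p[idx, , drop = FALSE]
  }
  tr <- init
  prev_mean <- Inf
  iter <- 0L
  rms <- NA_real_
  for (iter in seq_len(max_iter)) {
    moved <- transform_points(tr, p)
    cl <- mesh_closest_points(target, moved)
    d <- cl$distance
    keep <- d <= stats::quantile(d, 1 - trim)
    ps <- p[keep, , drop = FALSE]
    qs <- cl$point[keep, , drop = FALSE]
    cp <- colMeans(ps)
    cq <- colMeans(qs)
    H <- crossprod(sweep(ps, 2, cp), sweep(qs, 2, cq))
    sv <- svd(H)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
      stop("degenerate (collinear) vertex configuration in icp_align")
    s <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
    tvec <- cq - as.numeric(R %*% cp)
    tr <- rigid_transform(rotation = R, translation = tvec)
    mean_d <- mean(d[keep])
    rms <- sqrt(mean(d[keep]^2))
    if (abs(prev_mean - mean_d) < tol) break
    prev_mean <- mean_d
  }
  attr(tr, "residual_rms") <- rms
  attr(tr, "iterations") <- iter
  tr
}

#' NGF optimiser parameters
#'
#' @param epsilon edge parameter of the normalized gradient fields measure,
#'   in intensity/mm. `NULL` (default) selects it automatically per problem
#'   as `eta` times the median masked gradient magnitude (a robust estimate
#'   of the noise gradient level), floored at 1e-3 of the maximum gradient.
#' @param eta multiplier for the automatic epsilon.
#' @param pyramid_levels number of multi-resolution levels (>= 1).
#' @param max_iterations simplex iteration caps, coarsest level first
#'   (recycled if shorter than `pyramid_levels`).
#' @param presmooth_vox Gaussian smoothing (in voxels) applied to both
#'   images before gradients are taken; damps rasterisation and noise
#'   gradients so the measure reflects anatomy, not voxelisation.
#' @param reltol relative convergence tolerance of the optimiser.
#' @export
ngf_params <- function(epsilon = NULL, eta = 10, pyramid_levels = 3L,
                       max_iterations = c(240L, 120L, 48L),
                       presmooth_vox = 1.0, reltol = 1e-9) {
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be > 0")
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  structure(list(epsilon = epsilon, eta = eta,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 presmooth_vox = presmooth_vox,
                 reltol = reltol),
            class = "pf_ngf_params")
}

## central-difference gradient volumes (intensity per mm)
gradient_volumes <- function(vol) {
  v <- vol$values
  d <- dim(v)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    den <- (ip - im) * vol$spacing[ax]
    gax <- switch(ax,
                  (v[ip, , , drop = FALSE] - v[im, , , drop = FALSE]),
                  (v[, ip, , drop = FALSE] - v[, im, , drop = FALSE]),
                  (v[, , ip, drop = FALSE] - v[, , im, drop = FALSE]))
    gax <- sweep(gax, ax, den, "/")
    g[[ax]] <- gax
  }
  g
}

## crop a volume to a 1-based index box (clamped)
crop_volume <- function(vol, lo, hi) {
  d <- dim(vol$values)
  lo <- pmax(1L, pmin(d, as.integer(lo)))
  hi <- pmax(1L, pmin(d, as.integer(hi)))
  image_volume(vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                          drop = FALSE],
               vol$spacing, vol$origin + (lo - 1) * vol$spacing)
}

## internal: precompute everything NGF needs at one resolution
ngf_setup <- function(fixed, moving, mask, params) {
  lin <- which(mask$values != 0)
  if (length(lin) == 0) stop("NGF mask is empty")
  if (params$presmooth_vox > 0) {
    fixed <- image_volume(smooth3d(fixed$values, params$presmooth_vox,
                                   pad = "replicate"),
                          fixed$spacing, fixed$origin)
    moving <- image_volume(smooth3d(moving$values, params$presmooth_vox,
                                    pad = "replicate"),
                           moving$spacing, moving$origin)
  }
  gf <- gradient_volumes(fixed)
  GF <- cbind(gf[[1]][lin], gf[[2]][lin], gf[[3]][lin])
  gm <- gradient_volumes(moving)
  X <- voxel_world_coords(fixed, lin)
  magF <- sqrt(rowSums(GF^2))
  eps <- params$epsilon
  if (is.null(eps)) {
    allmagM <- sqrt(gm[[1]]^2 + gm[[2]]^2 + gm[[3]]^2)
    med <- 0.5 * (stats::median(magF) + stats::median(allmagM[lin]))
    eps <- max(params$eta * med, 1e-3 * max(magF, 1e-12), 1e-8)
  }
  list(X = X, GF = GF,
       gm = lapply(gm, as.numeric),   # plain vectors: no per-eval copies
       moving = moving, eps = eps,
       voxvol = voxel_volume(fixed), n = length(lin))
}

ngf_value <- function(setup, transform) {
  .ngf_value_cpp(setup$X, setup$GF,
                 setup$gm[[1]], setup$gm[[2]], setup$gm[[3]],
                 dim(setup$moving$values), setup$moving$spacing,
                 setup$moving$origin,
                 transform_matrix(transform)[1:3, , drop = FALSE],
                 setup$eps, setup$voxvol)
}

#' Normalized gradient fields distance between two volumes
#'
#' Computes `D = sum over masked voxels of
#' (1 - ((grad F . grad M' + eps^2) / (|grad F|_eps |grad M'|_eps))^2) * v`,
#' where `M'` is the moving image resampled through the transform (trilinear
#' interpolation), gradients are central differences in 1/mm,
#' `|g|_eps = sqrt(|g|^2 + eps^2)` and `v` is the voxel volume. The measure
#' vanishes exactly where the two gradient fields are parallel, which makes
#' it invariant to monotone intensity differences between scans.
#'
#' @param fixed,moving `pf_volume` intensity images.
#' @param transform `pf_transform` mapping fixed-frame points into the
#'   moving frame.
#' @param mask binary `pf_volume` on the fixed grid restricting the sum
#'   (typically the bone mask dilated by 3 mm).
#' @param params [ngf_params()].
#' @return Nonnegative scalar distance.
#' @export
ngf_distance <- function(fixed, moving, transform = rigid_transform(),
                         mask, params = ngf_params()) {
  setup <- ngf_setup(fixed, moving, mask, params)
  ngf_value(setup, transform)
}

## 6-vector (rx, ry, rz in radians; tx, ty, tz in mm) to transform about centre
params_to_transform <- function(p, centre) {
  ang <- sqrt(sum(p[1:3]^2))
  rot <- if (ang < 1e-14) rigid_transform(centre = centre)
  else rotation_about_axis(p[1:3] / ang, ang * 180 / pi, centre)
  rot$translation <- rot$translation + p[4:6]
  rot
}

#' Rigid refinement by minimising the masked NGF distance
#'
#' Multi-resolution local optimisation of the six rigid parameters (three
#' rotations about the mask centroid, three translations) with a Nelder-Mead
#' simplex per pyramid level, coarse to fine. The returned transform never
#' has a larger full-resolution NGF distance than the initialisation; if the
#' optimiser fails to improve within its iteration budget the best visited
#' transform is returned with a `converged = FALSE` attribute.
#'
#' @param fixed,moving `pf_volume` intensity images.
#' @param init initial `pf_transform` (from [icp_align()]; the capture range
#'   of the refinement is local by design).
#' @param mask binary `pf_volume` on the fixed grid (bone mask + dilation).
#' @param params [ngf_params()].
#' @return A `pf_transform` with attributes `ngf_init`, `ngf_final`,
#'   `converged`.
#' @export
ngf_refine <- function(fixed, moving, init, mask, params = ngf_params()) {
  if (mask_count(mask) == 0) stop("NGF mask is empty")
  centre <- colMeans(voxel_world_coords(mask, which(mask$values != 0)))
  nlev <- params$pyramid_levels
  maxit <- rep_len(params$max_iterations, nlev)
  ## crop both volumes to the mask region (plus margin): the measure only
  ## ever looks at masked voxels and where the transform sends them
  lin <- which(mask$values != 0)
  d <- dim(mask$values)
  ijk <- cbind((lin - 1L) %% d[1],
               ((lin - 1L) %/% d[1]) %% d[2],
               (lin - 1L) %/% (d[1] * d[2])) + 1L
  pad <- ceiling(8 / min(mask$spacing)) + 4L
  lo <- apply(ijk, 2, min) - pad
  hi <- apply(ijk, 2, max) + pad
  ## world-space corners of the fixed crop box, mapped through the
  ## initialisation, bound the moving region that can ever be sampled
  corners <- as.matrix(expand.grid(c1 = 0:1, c2 = 0:1, c3 = 0:1))
  cw <- t(apply(corners, 1, function(b) {
    fixed$origin + (ifelse(b == 1, hi, lo) - 1) * fixed$spacing
  }))
  cm <- transform_points(init, cw)
  mlo <- floor(world_to_index(moving, matrix(apply(cm, 2, min), 1))) - pad
  mhi <- ceiling(world_to_index(moving, matrix(apply(cm, 2, max), 1))) + pad
  fixed <- crop_volume(fixed, lo, hi)
  mask <- crop_volume(mask, lo, hi)
  moving <- crop_volume(moving, mlo + 1, mhi + 1)
  if (any(dim(moving$values) < 8))
    stop("initial transform places the mask outside the moving image")
  ## smooth once at full resolution; the pyramid inherits it
  if (params$presmooth_vox > 0) {
    fixed <- image_volume(smooth3d(fixed$values, params$presmooth_vox,
                                   pad = "replicate"),
                          fixed$spacing, fixed$origin)
    moving <- image_volume(smooth3d(moving$values, params$presmooth_vox,
                                    pad = "replicate"),
                           moving$spacing, moving$origin)
    params$presmooth_vox <- 0
  }
  fx <- list(fixed)
  mv <- list(moving)
  mk <- list(mask)
  for (l in seq_len(nlev - 1)) {
    fx[[l + 1]] <- downsample2(fx[[l]])
    mv[[l + 1]] <- downsample2(mv[[l]])
    mkd <- downsample2(mk[[l]])
    mk[[l + 1]] <- label_mask(mkd$values > 0.25, mkd$spacing, mkd$origin)
  }
  cur <- init
  for (l in rev(seq_len(nlev))) {
    setup <- ngf_setup(fx[[l]], mv[[l]], mk[[l]], params)
    obj <- function(p) {
      ngf_value(setup, compose_transforms(cur, params_to_transform(p, centre)))
    }
    f <- 2^(l - 1)
    scale <- c(rep(0.01 * f, 3), rep(0.4 * f, 3))
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[l],
                                       reltol = params$reltol,
                                       parscale = scale))
    if (opt$value <= obj(rep(0, 6)))
      cur <- compose_transforms(cur, params_to_transform(opt$par, centre))
  }
  full <- ngf_setup(fixed, moving, mask, params)
  d_init <- ngf_value(full, init)
  d_cur <- ngf_value(full, cur)
  converged <- TRUE
  if (d_cur > d_init) {          # descent guarantee relative to init
    cur <- init
    d_cur <- d_init
    converged <- FALSE
    warning("NGF refinement did not improve on its initialisation")
  }
  attr(cur, "ngf_init") <- d_init
  attr(cur, "ngf_final") <- d_cur
  attr(cur, "converged") <- converged
  cur
}

#' Two-stage rigid bone registration between scenes
#'
#' Reproduces the bone alignment chain of the measurement pipeline: surface
#' meshes of the bone masks are pre-aligned with trimmed ICP, then the rigid
#' pose is refined by minimising the NGF distance between the intensity
#' images inside the base bone mask dilated by `dilate_mm`. The composed
#' transform maps base-scene world points into the target scene, so applying
#' it to the base cartilage carries the cartilage into the target state.
#'
#' @param base base scene (extended knee, segmented).
#' @param target target scene (flexed/loaded state; its bone mask may come
#'   from the phantom ground truth or an external segmentation).
#' @param bone `"femur_bone"` or `"patella_bone"`.
#' @param ngf [ngf_params()].
#' @param dilate_mm dilation of the NGF evaluation mask around the bone.
#' @param ... passed to [icp_align()].
#' @return A `pf_transform` with attribute `provenance` recording both
#'   stages' residuals.
#' @export
register_bone <- function(base, target,
                          bone = c("femur_bone", "patella_bone"),
                          ngf = ngf_params(), dilate_mm = 3.0, ...) {
  bone <- match.arg(bone)
  if (is.null(base$masks[[bone]]) || is.null(target$masks[[bone]]))
    stop("both scenes must carry the mask ", bone)
  ## the coarse stage only needs surfaces good to a fraction of a voxel:
  ## mesh 2x-downsampled masks, which is plenty for the NGF capture range
  half <- function(m) {
    d <- downsample2(m)
    label_mask(d$values > 0.25, d$spacing, d$origin)
  }
  src <- extract_surface(half(base$masks[[bone]]))
  tgt <- extract_surface(half(target$masks[[bone]]))
  t_icp <- icp_align(src, tgt, ...)
  mask <- dilate_mask(base$masks[[bone]], dilate_mm)
  t_ref <- ngf_refine(base$intensity, target$intensity, t_icp, mask, ngf)
  attr(t_ref, "provenance") <- list(
    bone = bone,
    icp_residual_rms = attr(t_icp, "residual_rms"),
    icp_iterations = attr(t_icp, "iterations"),
    ngf_init = attr(t_ref, "ngf_init"),
    ngf_final = attr(t_ref, "ngf_final"),
    ngf_converged = attr(t_ref, "converged"),
    target_mask_source = "provided (phantom truth or external segmentation)")
  t_ref
}
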