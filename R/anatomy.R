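#' Anatomical femoral reference frame
#'
#' Builds the femoral coordinate frame used for all patellar measurements:
#' the proximodistal axis is the shaft principal axis (PCA of the shaft
#' vertices, iterated so the condyles do not bias it), the mediolateral axis
#' is the posterior condylar tangent direction (posterior-most condylar
#' points of the medial and lateral halves) projected orthogonal to the
#' shaft axis, and the anteroposterior axis completes the right-handed
#' triad. Lateral is identified as the side whose condyle reaches less far
#' distally (the medial condyle is the larger, more distal one). The origin
#' is the deepest point of the trochlear groove, found from the anterior
#' crest-height profile. Deterministic for a given mesh and equivariant
#' under rigid motion of the mesh.
#'
#' @param femur_mesh femur `pf_mesh` including both condyles.
#' @return Object of class `pf_femoral_frame` with `origin` (mm) and unit
#'   axes `ml`, `ap`, `pd` (columns of `axes`).
#' @export
femoral_frame <- function(femur_mesh) {
  if (nrow(femur_mesh$vertices) < 100) stop("femur mesh too small")
  ## area-weighted face centroids: unbiased surface integrals regardless of
  ## the tessellation's vertex density
  v <- face_centroids(femur_mesh)
  w <- face_areas(femur_mesh)
  w <- w / sum(w)
  wmean <- function(p, wt) colSums(p * wt) / sum(wt)
  wcov <- function(p, wt) crossprod(p * sqrt(wt)) / sum(wt)
  c0 <- wmean(v, w)
  vc <- sweep(v, 2, c0)
  ez <- eigen(wcov(vc, w), symmetric = TRUE)$vectors[, 1]

  radial_spread <- function(axis, sel) {
    p <- vc[sel, , drop = FALSE]
    t <- p %*% axis
    sum(sqrt(rowSums((p - t %*% t(axis))^2)) * w[sel]) / sum(w[sel])
  }
  ## orient: the condylar (fat) end is distal, the shaft (thin) end proximal
  orient <- function(ez) {
    proj <- as.numeric(vc %*% ez)
    qs <- stats::quantile(proj, c(0.2, 0.8))
    if (radial_spread(ez, proj >= qs[2]) > radial_spread(ez, proj <= qs[1]))
      -ez else ez
  }
  ez <- orient(ez)
  ## shaft axis through the centroids of cross-sectional slabs of the
  ## proximal tube (robust regardless of the tube's aspect ratio)
  for (it in 1:2) {
    proj <- as.numeric(vc %*% ez)
    zmin <- min(proj)
    lz <- diff(range(proj))
    band <- proj >= zmin + 0.55 * lz & proj <= zmin + 0.95 * lz
    if (sum(band) < 50) stop("femoral shaft not found")
    bins <- cut(proj[band], 8, labels = FALSE)
    cen <- vapply(1:8, function(b) {
      sel <- band
      sel[band] <- bins == b
      if (!any(sel)) return(rep(NA_real_, 3))
      wmean(vc[sel, , drop = FALSE], w[sel])
    }, numeric(3))
    cen <- t(cen[, colSums(is.na(cen)) == 0, drop = FALSE])
    cc <- colMeans(cen)
    e2 <- eigen(crossprod(sweep(cen, 2, cc)), symmetric = TRUE)$vectors[, 1]
    if (sum(e2 * ez) < 0) e2 <- -e2
    ez <- orient(e2)
  }
  proj <- as.numeric(vc %*% ez)
  zmin <- min(proj)
  lz <- diff(range(proj))
  condylar <- proj < zmin + 0.25 * lz
  if (sum(condylar) < 50) stop("condyles not separable from the shaft")
  cvert <- vc[condylar, , drop = FALSE]
  cw <- w[condylar]
  ccen <- wmean(cvert, cw)
  cflat <- sweep(cvert, 2, ccen)
  cflat <- cflat - (cflat %*% ez) %*% t(ez)
  m0 <- eigen(wcov(cflat, cw), symmetric = TRUE)$vectors[, 1]
  m0 <- m0 - sum(m0 * ez) * ez
  m0 <- m0 / sqrt(sum(m0^2))

  ## provisional anterior: the distal-most slab (condyle undersides) sits
  ## posterior of the shaft axis
  y0 <- c(ez[2] * m0[3] - ez[3] * m0[2],
          ez[3] * m0[1] - ez[1] * m0[3],
          ez[1] * m0[2] - ez[2] * m0[1])
  bottom <- proj < zmin + 0.08 * lz
  sh <- proj >= zmin + 0.55 * lz
  shaft_centroid <- wmean(vc[sh, , drop = FALSE], w[sh])
  bc <- wmean(vc[bottom, , drop = FALSE], w[bottom])
  offset <- bc - (shaft_centroid +
                    sum((bc - shaft_centroid) * ez) * ez)
  if (sum(offset * y0) > 0) y0 <- -y0

  mlc <- as.numeric(cflat %*% m0)
  half_a <- mlc < 0
  half_b <- !half_a
  if (!any(half_a) || !any(half_b)) stop("condyles not separable")
  post_extreme <- function(sel) {
    sub <- cvert[sel, , drop = FALSE]
    sub[which.min(sub %*% y0), ]
  }
  pa <- post_extreme(half_a)
  pb <- post_extreme(half_b)
  ## lateral condyle ends less distally than the medial one
  da <- min(cvert[half_a, , drop = FALSE] %*% ez)
  db <- min(cvert[half_b, , drop = FALSE] %*% ez)
  if (da < db) { p_med <- pa; p_lat <- pb } else { p_med <- pb; p_lat <- pa }
  ml <- p_lat - p_med
  ml <- ml - sum(ml * ez) * ez
  ml <- ml / sqrt(sum(ml^2))
  ap <- c(ez[2] * ml[3] - ez[3] * ml[2],
          ez[3] * ml[1] - ez[1] * ml[3],
          ez[1] * ml[2] - ez[2] * ml[1])

  ## origin: deepest trochlear point from the anterior crest profile
  band <- proj > zmin + 0.15 * lz & proj < zmin + 0.45 * lz
  bx <- as.numeric(vc[band, , drop = FALSE] %*% ml)
  by <- as.numeric(vc[band, , drop = FALSE] %*% ap)
  prof <- crest_profile(bx, by, bin = 1.0)
  sulcus <- profile_sulcus(prof)
  if (is.null(sulcus)) stop("trochlear groove not found on the femur mesh")
  zmid <- zmin + 0.30 * lz
  origin <- c0 + sulcus$x * ml + sulcus$y * ap + zmid * ez
  structure(list(origin = origin,
                 axes = cbind(ml = ml, ap = ap, pd = ez)),
            class = "pf_femoral_frame")
}

#' @export
print.pf_femoral_frame <- function(x, ...) {
  cat("Femoral frame at", paste(format(x$origin, digits = 4),
                                collapse = ", "), "mm\n")
  invisible(x)
}

## max anterior height per mediolateral bin
crest_profile <- function(x, y, bin = 1.0) {
  bx <- round(x / bin)
  tab <- tapply(y, bx, max)
  xs <- as.numeric(names(tab)) * bin
  ord <- order(xs)
  list(x = xs[ord], y = as.numeric(tab)[ord])
}

## locate medial/lateral rim peaks and the sulcus between them;
## parabolic sub-bin refinement of the sulcus position
profile_sulcus <- function(prof) {
  n <- length(prof$x)
  if (n < 5) return(NULL)
  mid <- (min(prof$x) + max(prof$x)) / 2
  left <- which(prof$x < mid)
  right <- which(prof$x >= mid)
  if (length(left) < 2 || length(right) < 2) return(NULL)
  i_m <- left[which.max(prof$y[left])]
  i_l <- right[which.max(prof$y[right])]
  if (i_l - i_m < 2) return(NULL)
  between <- (i_m + 1):(i_l - 1)
  i_s <- between[which.min(prof$y[between])]
  xs <- prof$x[i_s]
  ys <- prof$y[i_s]
  if (i_s > 1 && i_s < n) {
    y0 <- prof$y[i_s - 1]; y1 <- prof$y[i_s]; y2 <- prof$y[i_s + 1]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den > 1e-12) {
      dx <- 0.5 * (y0 - y2) / den
      if (abs(dx) <= 1) xs <- xs + dx * (prof$x[2] - prof$x[1])
    }
  }
  list(x = xs, y = ys, i_med = i_m, i_lat = i_l,
       x_med = prof$x[i_m], y_med = prof$y[i_m],
       x_lat = prof$x[i_l], y_lat = prof$y[i_l],
       depth = min(prof$y[i_m], prof$y[i_l]) - ys)
}

## express points in frame coordinates (columns ml, ap, pd)
to_frame_coords <- function(frame, pts) {
  sweep(matrix(as.numeric(pts), ncol = 3), 2, frame$origin) %*% frame$axes
}

## area-weighted surface centroid
mesh_centroid <- function(mesh) {
  a <- face_areas(mesh)
  colSums(face_centroids(mesh) * a) / sum(a)
}

#' Patellar tilt angle
#'
#' The axial-plane angle between the patellar mediolateral axis (the widest
#' principal direction of the patellar outline projected onto the femoral
#' axial plane) and the femoral mediolateral axis (posterior condylar
#' line). Positive tilt is lateral tilt: the lateral patellar edge rotated
#' posteriorly. Invariant to translation and to joint rigid motion of the
#' whole scene when the frame comes from the same scene.
#'
#' @param patella_mesh patellar `pf_mesh`.
#' @param frame [femoral_frame()] of the same scene.
#' @return Tilt in degrees.
#' @export
patellar_tilt <- function(patella_mesh, frame) {
  u <- to_frame_coords(frame, face_centroids(patella_mesh))[, 1:2,
                                                            drop = FALSE]
  w <- face_areas(patella_mesh)
  w <- w / sum(w)
  u <- sweep(u, 2, colSums(u * w))
  ev <- eigen(crossprod(u * sqrt(w)), symmetric = TRUE)
  ## the projected outline must have a cm-scale dominant axis: an
  ## area-weighted SD below 0.5 mm or a near-isotropic outline is degenerate
  if (!all(is.finite(ev$values)) || ev$values[1] < 0.25 ||
      ev$values[1] / max(ev$values[2], 1e-12) < 1.05)
    stop("degenerate axial projection: no dominant patellar axis")
  dir <- ev$vectors[, 1]
  if (dir[1] < 0) dir <- -dir
  -atan2(dir[2], dir[1]) * 180 / pi
}

#' Medial-lateral patellar translation
#'
#' Signed mediolateral offset (mm, positive lateral) of the patellar
#' surface centroid from the trochlear-groove origin of the femoral frame.
#'
#' @inheritParams patellar_tilt
#' @export
lateral_translation <- function(patella_mesh, frame) {
  as.numeric(to_frame_coords(frame,
                             matrix(mesh_centroid(patella_mesh), 1))[, 1])
}

## resampled axial crest profiles through the trochlea, one per slice
trochlear_slices <- function(scene, frame = NULL, z_range = c(-7, 7),
                             dz = 1.0, dx = 0.25, dy = 0.1) {
  if (is.null(frame)) frame <- femoral_frame(extract_surface(scene$masks$femur_bone))
  mask <- scene$masks$femur_bone
  xs <- seq(-24, 24, by = dx)
  ys <- seq(-20, 12, by = dy)
  zs <- seq(z_range[1], z_range[2], by = dz)
  slices <- list()
  for (z in zs) {
    pts_f <- cbind(rep(xs, times = length(ys)),
                   rep(ys, each = length(xs)), z)
    pts_w <- sweep(pts_f %*% t(frame$axes), 2, frame$origin, "+")
    val <- matrix(sample_volume(mask, pts_w) >= 0.5,
                  nrow = length(xs))
    crest <- rep(NA_real_, length(xs))
    hasany <- rowSums(val) > 0
    if (any(hasany)) {
      rev_first <- max.col(val[, rev(seq_along(ys)), drop = FALSE],
                           ties.method = "first")
      crest[hasany] <- ys[length(ys) + 1 - rev_first][hasany]
    }
    ok <- is.finite(crest)
    if (sum(ok) >= 5)
      slices[[length(slices) + 1]] <-
        profile_sulcus(list(x = xs[ok], y = crest[ok]))
  }
  slices <- Filter(Negate(is.null), slices)
  if (length(slices) == 0)
    stop("axial sections do not intersect the trochlea")
  list(frame = frame, slices = slices)
}

## keep slices with a well-defined groove (depth >= half the deepest slice)
valid_slices <- function(slices) {
  depths <- vapply(slices, function(s) s$depth, numeric(1))
  dmax <- max(depths)
  slices[depths >= 0.5 * dmax]
}

#' Mean osseous sulcus angle
#'
#' On each axial section through the trochlea, the angle at the deepest
#' trochlear point between the lines to the highest medial and lateral
#' facet points; averaged over the sections where the groove is
#' well-defined (depth at least half the deepest section). A flat trochlea
#' tends to 180 degrees.
#'
#' @param scene a `pf_scene` (its `femur_bone` mask is resampled on
#'   frame-aligned axial sections).
#' @param frame optional precomputed [femoral_frame()].
#' @return Angle in degrees.
#' @export
sulcus_angle <- function(scene, frame = NULL) {
  tr <- trochlear_slices(scene, frame)
  sl <- valid_slices(tr$slices)
  angs <- vapply(sl, function(s) {
    v1 <- c(s$x_med - s$x, s$y_med - s$y)
    v2 <- c(s$x_lat - s$x, s$y_lat - s$y)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) return(180)
    acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }, numeric(1))
  mean(angs)
}

#' Lateral trochlear inclination angle
#'
#' Angle between the lateral facet line (deepest trochlear point to the
#' lateral facet peak) and the posterior condylar line, averaged over the
#' well-defined axial sections.
#'
#' @inheritParams sulcus_angle
#' @return Angle in degrees.
#' @export
lateral_trochlear_inclination <- function(scene, frame = NULL) {
  tr <- trochlear_slices(scene, frame)
  sl <- valid_slices(tr$slices)
  incs <- vapply(sl, function(s) {
    atan2(s$y_lat - s$y, s$x_lat - s$x) * 180 / pi
  }, numeric(1))
  mean(incs)
}

#' Patellotrochlear index
#'
#' Sagittal cartilage overlap ratio: in the sagittal slab through the
#' patellar cartilage centre, the proximodistal overlap length of patellar
#' and trochlear (femoral) cartilage divided by the patellar cartilage
#' length. 1 means the patellar cartilage is fully engaged with the
#' trochlear cartilage.
#'
#' @param scene a `pf_scene` with both cartilage masks.
#' @param frame optional precomputed [femoral_frame()].
#' @param slab_halfwidth half-width (mm) of the mid-sagittal slab.
#' @return Ratio in `[0, 1]`.
#' @export
patellotrochlear_index <- function(scene, frame = NULL,
                                   slab_halfwidth = 1.5) {
  if (is.null(frame))
    frame <- femoral_frame(extract_surface(scene$masks$femur_bone))
  pat <- scene$masks$patellar_cartilage
  fem <- scene$masks$femoral_cartilage
  if (mask_count(pat) == 0 || mask_count(fem) == 0)
    stop("both cartilage masks are required")
  pw <- voxel_world_coords(pat, which(pat$values != 0))
  fw <- voxel_world_coords(fem, which(fem$values != 0))
  pf <- to_frame_coords(frame, pw)
  ff <- to_frame_coords(frame, fw)
  xc <- stats::median(pf[, 1])
  psel <- abs(pf[, 1] - xc) <= slab_halfwidth
  fsel <- abs(ff[, 1] - xc) <= slab_halfwidth
  if (!any(psel) || !any(fsel))
    stop("sagittal section misses the trochlea")
  prange <- range(pf[psel, 3])
  frange <- range(ff[fsel, 3])
  ov <- max(0, min(prange[2], frange[2]) - max(prange[1], frange[1]))
  max(0, min(1, ov / diff(prange)))
}

#' Bundle of trochlear morphology indices
#'
#' @inheritParams sulcus_angle
#' @return List of class `pf_morphology` with `sulcus_angle`,
#'   `lateral_trochlear_inclination`, `patellotrochlear_index`.
#' @export
trochlear_morphology <- function(scene, frame = NULL) {
  if (is.null(frame))
    frame <- femoral_frame(extract_surface(scene$masks$femur_bone))
  structure(list(
    sulcus_angle = sulcus_angle(scene, frame),
    lateral_trochlear_inclination = lateral_trochlear_inclination(scene, frame),
    patellotrochlear_index = patellotrochlear_index(scene, frame)),
    class = "pf_morphology")
}

#' Dysplasia severity grouping
#'
#' Deterministic binary mild/severe grouping from configured cut-offs. The
#' package ships no default thresholds (clinical cut-offs belong to the
#' study configuration, not the code): all cut-offs must be supplied, and a
#' structure is graded severe when any configured criterion is met. The
#' boundary convention is closed on the severe side: `sulcus_angle >=
#' sulcus_angle_max` and `lateral_trochlear_inclination <=
#' lateral_inclination_min` count as severe.
#'
#' @param indices list with any of `sulcus_angle`,
#'   `lateral_trochlear_inclination` (e.g. from [trochlear_morphology()]).
#' @param thresholds list with at least one of `sulcus_angle_max`,
#'   `lateral_inclination_min`.
#' @return `"mild"` or `"severe"`.
#' @export
severity_group <- function(indices, thresholds) {
  if (missing(thresholds) || is.null(thresholds) || length(thresholds) == 0)
    stop("severity thresholds must be configured explicitly")
  known <- c("sulcus_angle_max", "lateral_inclination_min")
  if (!any(known %in% names(thresholds)))
    stop("no recognised severity thresholds supplied")
  severe <- FALSE
  if (!is.null(thresholds$sulcus_angle_max) &&
      !is.null(indices$sulcus_angle))
    severe <- severe || indices$sulcus_angle >= thresholds$sulcus_angle_max
  if (!is.null(thresholds$lateral_inclination_min) &&
      !is.null(indices$lateral_trochlear_inclination))
    severe <- severe ||
      indices$lateral_trochlear_inclination <= thresholds$lateral_inclination_min
  if (severe) "severe" else "mild"
}
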