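#' Specification of a synthetic knee scene
#'
#' The phantom emulates a 3D TSE-like knee acquisition at 0.5 mm isotropic
#' resolution: a distal femur (shaft, two posterior condyles with the medial
#' one reaching further distally, and a V-shaped trochlear groove) and a
#' wedge-backed ellipsoidal patella, with uniform-thickness cartilage shells
#' on the articular surfaces. Trochlear geometry is set by three clinical
#' parameters: the osseous sulcus angle, the lateral trochlear inclination
#' and the groove depth, from which the medial/lateral facet widths follow
#' as `w_lat = depth / tan(inclination)` and
#' `w_med = depth * tan(sulcus - 90 + inclination)`. Patellar pose is set by
#' the tilt (degrees, positive = lateral tilt, lateral edge posterior), the
#' lateral shift (mm) and the flexion angle, which slides the patella
#' distally along the groove. The loaded state adds a small prescribed extra
#' tilt/shift (load is an acquisition condition, not a mechanical model).
#' Intensities are bone-dark / cartilage-bright over a mid background, with
#' a smooth multiplicative bias field and additive Gaussian noise (the
#' high-SNR Rician approximation); identical spec + seed gives bit-identical
#' scenes.
#'
#' @param voxel_spacing isotropic voxel spacing in mm (default 0.5).
#' @param volume_shape voxel counts per axis.
#' @param cartilage_thickness cartilage shell thickness in mm.
#' @param trochlear_depth groove depth in mm (>= 0; small values give a
#'   dysplastic, effectively flat trochlea).
#' @param sulcus_angle_true osseous sulcus angle in degrees.
#' @param lateral_inclination_true lateral trochlear inclination in degrees.
#' @param patella_tilt_true patellar tilt in degrees (positive lateral).
#' @param patella_lateral_shift_true lateral patellar shift in mm.
#' @param flexion_angle knee flexion angle, one of 0, 15, 30 degrees.
#' @param load_state `"unloaded"` or `"loaded_50N"`.
#' @param load_tilt_delta,load_shift_delta extra patellar tilt (deg) and
#'   lateral shift (mm) applied in the loaded state.
#' @param noise_sigma additive noise SD in intensity units (background is
#'   110, so 5.5 gives SNR around 20).
#' @param bias_field_amplitude relative amplitude of the multiplicative
#'   bias field.
#' @param seed integer seed controlling noise, bias and repositioning
#'   jitter.
#' @return An object of class `pf_phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing = 0.5,
                         volume_shape = c(112L, 112L, 160L),
                         cartilage_thickness = 3.0,
                         trochlear_depth = 5.0,
                         sulcus_angle_true = 140.0,
                         lateral_inclination_true = 20.0,
                         patella_tilt_true = 0.0,
                         patella_lateral_shift_true = 0.0,
                         flexion_angle = 0,
                         load_state = c("unloaded", "loaded_50N"),
                         load_tilt_delta = 1.5,
                         load_shift_delta = 0.8,
                         noise_sigma = 5.5,
                         bias_field_amplitude = 0.05,
                         seed = 1L) {
  load_state <- match.arg(load_state)
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0")
  if (cartilage_thickness <= 0) stop("cartilage_thickness must be > 0")
  if (trochlear_depth < 0) stop("trochlear_depth must be >= 0")
  if (!flexion_angle %in% c(0, 15, 30))
    stop("flexion_angle must be 0, 15 or 30")
  if (abs(patella_tilt_true) >= 90) stop("|patella_tilt_true| must be < 90")
  phi <- lateral_inclination_true
  th <- sulcus_angle_true
  if (!(th > 90 && th < 180)) stop("sulcus_angle_true must be in (90, 180)")
  med_ang <- th - 90 + phi
  if (!(phi > 2 && phi < 88 && med_ang > 2 && med_ang < 88))
    stop("sulcus angle and inclination are geometrically inconsistent")
  if (trochlear_depth > 0) {
    w_l <- trochlear_depth / tan(phi * pi / 180)
    w_m <- trochlear_depth * tan(med_ang * pi / 180)
    if (max(w_l, w_m) > 18)
      stop("sulcus angle and inclination are geometrically inconsistent ",
           "with this trochlear depth (facet width ",
           round(max(w_l, w_m), 1), " mm exceeds the condylar region)")
  }
  structure(list(voxel_spacing = voxel_spacing,
                 volume_shape = as.integer(volume_shape),
                 cartilage_thickness = cartilage_thickness,
                 trochlear_depth = trochlear_depth,
                 sulcus_angle_true = sulcus_angle_true,
                 lateral_inclination_true = lateral_inclination_true,
                 patella_tilt_true = patella_tilt_true,
                 patella_lateral_shift_true = patella_lateral_shift_true,
                 flexion_angle = flexion_angle,
                 load_state = load_state,
                 load_tilt_delta = load_tilt_delta,
                 load_shift_delta = load_shift_delta,
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "pf_phantom_spec")
}

## derived canonical geometry (all mm, in the shared world convention)
phantom_geometry <- function(spec) {
  d <- spec$trochlear_depth
  phi <- spec$lateral_inclination_true * pi / 180
  med_ang <- (spec$sulcus_angle_true - 90 +
                spec$lateral_inclination_true) * pi / 180
  w_l <- if (d > 0) d / tan(phi) else 0
  w_m <- if (d > 0) d * tan(med_ang) else 0
  t <- spec$cartilage_thickness
  apex_y <- (14 - d) + 2 * t + 0.4
  slope <- if (d > 0) 0.85 * 0.5 * (d / w_l + d / w_m) else 0
  list(
    shaft_centre = c(0, -4), shaft_radius = 9, shaft_z = c(8, 38),
    condyle_med = list(centre = c(-10.5, -6, 0), radius = 11),
    condyle_lat = list(centre = c(10, -7.5, 1), radius = 9.5),
    troch_z = c(-4, 14), troch_y_floor = -8, troch_crest = 14,
    w_m = w_m, w_l = w_l, depth = d,
    patella_half_axes = c(14, 7, 16),
    patella_centre = c(0, apex_y + 6.9, 2),
    wedge_apex_local = -6.9, wedge_slope = slope,
    content_lo = c(-23.5, -18, -23),
    content_hi = c(23.5, apex_y + 6.9 + 8, 48))
}

## anterior trochlear crest height A(x) in canonical coordinates
troch_crest_height <- function(x, geo) {
  d <- geo$depth
  w_m <- geo$w_m
  w_l <- geo$w_l
  crest <- geo$troch_crest
  if (d <= 0 || w_m <= 0 || w_l <= 0) return(rep(crest - d, length(x)))
  ifelse(x < -w_m, crest - 0.8 * (-x - w_m),
         ifelse(x < 0, crest - d * (1 + x / w_m),
                ifelse(x <= w_l, crest - d * (1 - x / w_l),
                       crest - 0.8 * (x - w_l))))
}

## run code with a private, restored RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## deterministic acquisition repositioning for non-base states
default_scene_pose <- function(spec, geo) {
  loaded <- spec$load_state == "loaded_50N"
  if (spec$flexion_angle == 0 && !loaded) return(rigid_transform())
  flex <- rotation_about_axis(c(1, 0, 0), 0.6 * spec$flexion_angle,
                              centre = c(0, -6.8, 0))
  seed2 <- (spec$seed + 131L * spec$flexion_angle + 17L * loaded) %% .Machine$integer.max
  jitter <- with_local_seed(seed2, random_rigid_transform(2, 2, c(0, -6.8, 0)))
  compose_transforms(jitter, flex)
}

#' Build a synthetic knee scene
#'
#' Rasterises the phantom geometry of a [phantom_spec()] onto the voxel
#' grid, producing an intensity volume, the four structure masks
#' (`femur_bone`, `patella_bone`, `femoral_cartilage`,
#' `patellar_cartilage`) on the same grid, and the ground truth (rigid
#' femur/patella poses, tilt, lateral shift). The grid is centred on the
#' posed anatomy, emulating a scanner FOV placed around the joint.
#'
#' @param spec A [phantom_spec()].
#' @param scene_pose optional `pf_transform` applied to the whole scene
#'   (acquisition repositioning). By default derived from the flexion angle,
#'   load state and seed.
#' @return An object of class `pf_scene` with elements `intensity`,
#'   `masks`, `truth`, `spec`.
#' @export
build_scene <- function(spec, scene_pose = NULL) {
  geo <- phantom_geometry(spec)
  sp <- spec$voxel_spacing
  dims <- spec$volume_shape
  fov <- (dims - 1) * sp
  ## explicit sizing check against the canonical content box (margins included)
  need <- geo$content_hi - geo$content_lo
  if (any(fov < need))
    stop("volume_shape too small to contain the phantom geometry: need >= ",
         paste(ceiling(need / sp) + 1, collapse = " x "), " voxels")
  anatomy_centre <- (geo$content_lo + geo$content_hi) / 2

  if (is.null(scene_pose)) scene_pose <- default_scene_pose(spec, geo)
  centre_world <- as.numeric(transform_points(scene_pose,
                                              matrix(anatomy_centre, 1)))
  origin <- centre_world - fov / 2

  ax <- list(x = origin[1] + sp * (seq_len(dims[1]) - 1),
             y = origin[2] + sp * (seq_len(dims[2]) - 1),
             z = origin[3] + sp * (seq_len(dims[3]) - 1))
  n <- prod(dims)
  pts <- cbind(rep(ax$x, times = dims[2] * dims[3]),
               rep(rep(ax$y, each = dims[1]), times = dims[3]),
               rep(ax$z, each = dims[1] * dims[2]))

  ## femur in canonical coordinates
  pc <- transform_points(invert_transform(scene_pose), pts)
  xc <- pc[, 1]; yc <- pc[, 2]; zc <- pc[, 3]
  shaft_r2 <- xc^2 + (yc + 4)^2
  femur <- (shaft_r2 <= 81 & zc >= 8 & zc <= 38) |
    (shaft_r2 + (zc - 38)^2 <= 81 & zc > 38) |
    ((xc + 10.5)^2 + (yc + 6)^2 + zc^2 <= 121) |
    ((xc - 10)^2 + (yc + 7.5)^2 + (zc - 1)^2 <= 90.25)
  in_troch <- zc >= geo$troch_z[1] & zc <= geo$troch_z[2] &
    yc >= geo$troch_y_floor &
    xc >= -(geo$w_m + 3) & xc <= geo$w_l + 3
  if (any(in_troch)) {
    crest <- troch_crest_height(xc[in_troch], geo)
    femur[in_troch] <- femur[in_troch] | yc[in_troch] <= crest
  }

  ## patella: local frame -> canonical -> world
  loaded <- spec$load_state == "loaded_50N"
  tilt_total <- spec$patella_tilt_true + if (loaded) spec$load_tilt_delta else 0
  shift_total <- spec$patella_lateral_shift_true +
    if (loaded) spec$load_shift_delta else 0
  flex <- spec$flexion_angle
  r_rel <- compose_transforms(
    rotation_about_axis(c(0, 0, 1), -tilt_total),
    rotation_about_axis(c(1, 0, 0), -0.3 * flex))
  rel <- rigid_transform(rotation = r_rel$rotation,
                         translation = geo$patella_centre +
                           c(shift_total, -0.05 * flex, -0.20 * flex))
  patella_pose <- compose_transforms(scene_pose, rel)
  pl <- transform_points(invert_transform(patella_pose), pts)
  ha <- geo$patella_half_axes
  patella <- (pl[, 1] / ha[1])^2 + (pl[, 2] / ha[2])^2 +
    (pl[, 3] / ha[3])^2 <= 1 &
    pl[, 2] >= geo$wedge_apex_local + geo$wedge_slope * abs(pl[, 1])
  patella <- patella & !femur

  mk <- function(v) label_mask(array(v, dims), sp, origin)
  femur_mask <- mk(femur)
  patella_mask <- mk(patella)

  ## cartilage shells from the exact distance transform of each bone
  tthick <- spec$cartilage_thickness
  ef <- distance_map(femur_mask)$values
  fem_cart <- ef > 1e-9 & ef <= tthick + 1e-9 &
    yc > 4 & zc > -5.5 & zc < 14.5 &
    xc > -(geo$w_m + 3) & xc < geo$w_l + 3 & !patella
  ep <- distance_map(patella_mask)$values
  pat_cart <- ep > 1e-9 & ep <= tthick + 1e-9 &
    pl[, 2] < -2.5 & abs(pl[, 1]) < 12.5 & abs(pl[, 3]) < 14.5 &
    !femur & !fem_cart

  ## intensity: TSE-like contrast (bone dark, cartilage bright)
  inten <- rep(110, n)
  inten[femur | patella] <- 40
  inten[fem_cart | pat_cart] <- 190
  seed2 <- (spec$seed + 131L * spec$flexion_angle + 17L * loaded +
              7L) %% .Machine$integer.max
  noise_etc <- with_local_seed(seed2, {
    cf <- stats::runif(6, -1, 1)
    noi <- if (spec$noise_sigma > 0) stats::rnorm(n, 0, spec$noise_sigma)
    else NULL
    list(cf = cf, noi = noi)
  })
  if (spec$bias_field_amplitude > 0) {
    xn <- (pts[, 1] - centre_world[1]) / (fov[1] / 2)
    yn <- (pts[, 2] - centre_world[2]) / (fov[2] / 2)
    zn <- (pts[, 3] - centre_world[3]) / (fov[3] / 2)
    cf <- noise_etc$cf
    b <- cf[1] * xn + cf[2] * yn + cf[3] * zn +
      cf[4] * xn * yn + cf[5] * xn * zn + cf[6] * yn * zn
    mb <- max(abs(b))
    if (mb > 0) inten <- inten * (1 + spec$bias_field_amplitude * b / mb)
  }
  if (!is.null(noise_etc$noi)) inten <- inten + noise_etc$noi

  structure(list(
    intensity = image_volume(array(inten, dims), sp, origin),
    masks = list(femur_bone = femur_mask,
                 patella_bone = patella_mask,
                 femoral_cartilage = mk(fem_cart),
                 patellar_cartilage = mk(pat_cart)),
    truth = list(femur_pose = scene_pose,
                 patella_pose = patella_pose,
                 tilt = tilt_total,
                 lateral_shift = shift_total,
                 expected_contact_area = NA_real_),
    spec = spec), class = "pf_scene")
}

#' @export
print.pf_scene <- function(x, ...) {
  cat("Knee scene:", paste(dim(x$intensity$values), collapse = " x "),
      "voxels at", x$spec$voxel_spacing, "mm; flexion",
      x$spec$flexion_angle, "deg,", x$spec$load_state, "\n")
  invisible(x)
}

## watertight box mesh whose top/bottom surfaces follow per-x heights
slab_mesh <- function(xs, ys, zlo, zhi) {
  nx <- length(xs); ny <- length(ys)
  vid <- function(i, j, top) (top * nx * ny) + (j - 1) * nx + i
  vx <- rep(xs, times = ny)
  vy <- rep(ys, each = nx)
  verts <- rbind(cbind(vx, vy, rep(zlo, times = ny)),
                 cbind(vx, vy, rep(zhi, times = ny)))
  faces <- list()
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    v00b <- vid(i, j, 0); v10b <- vid(i + 1, j, 0)
    v01b <- vid(i, j + 1, 0); v11b <- vid(i + 1, j + 1, 0)
    v00t <- vid(i, j, 1); v10t <- vid(i + 1, j, 1)
    v01t <- vid(i, j + 1, 1); v11t <- vid(i + 1, j + 1, 1)
    faces[[length(faces) + 1]] <- cbind(v00t, v10t, v11t)
    faces[[length(faces) + 1]] <- cbind(v00t, v11t, v01t)
    faces[[length(faces) + 1]] <- cbind(v00b, v11b, v10b)
    faces[[length(faces) + 1]] <- cbind(v00b, v01b, v11b)
  }
  i <- seq_len(nx - 1)
  faces[[length(faces) + 1]] <- cbind(vid(i, 1, 0), vid(i + 1, 1, 0),
                                      vid(i + 1, 1, 1))
  faces[[length(faces) + 1]] <- cbind(vid(i, 1, 0), vid(i + 1, 1, 1),
                                      vid(i, 1, 1))
  faces[[length(faces) + 1]] <- cbind(vid(i, ny, 0), vid(i + 1, ny, 1),
                                      vid(i + 1, ny, 0))
  faces[[length(faces) + 1]] <- cbind(vid(i, ny, 0), vid(i, ny, 1),
                                      vid(i + 1, ny, 1))
  j <- seq_len(ny - 1)
  faces[[length(faces) + 1]] <- cbind(vid(1, j, 0), vid(1, j, 1),
                                      vid(1, j + 1, 1))
  faces[[length(faces) + 1]] <- cbind(vid(1, j, 0), vid(1, j + 1, 1),
                                      vid(1, j + 1, 0))
  faces[[length(faces) + 1]] <- cbind(vid(nx, j, 0), vid(nx, j + 1, 1),
                                      vid(nx, j, 1))
  faces[[length(faces) + 1]] <- cbind(vid(nx, j, 0), vid(nx, j + 1, 0),
                                      vid(nx, j + 1, 1))
  surface_mesh(verts, do.call(rbind, faces))
}

## evaluate a piecewise-linear gap profile at x
eval_gap_profile <- function(profile, x) {
  if (is.numeric(profile) && length(profile) == 1)
    return(rep(profile, length(x)))
  stats::approx(profile$x, profile$gap, xout = x, rule = 2)$y
}

## analytic area with gap < threshold for a piecewise-linear profile
analytic_contact_area <- function(profile, patch_size, threshold = 1.0) {
  lx <- patch_size[1]; ly <- patch_size[2]
  if (is.numeric(profile) && length(profile) == 1)
    return(if (profile < threshold) lx * ly else 0)
  xs <- sort(unique(c(profile$x, 0, lx)))
  xs <- xs[xs >= 0 & xs <= lx]
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    x0 <- xs[s]; x1 <- xs[s + 1]
    g0 <- eval_gap_profile(profile, x0)
    g1 <- eval_gap_profile(profile, x1)
    if (g0 < threshold && g1 < threshold) total <- total + (x1 - x0)
    else if (g0 < threshold || g1 < threshold) {
      xc <- x0 + (threshold - g0) / (g1 - g0) * (x1 - x0)
      total <- total + if (g0 < threshold) (xc - x0) else (x1 - xc)
    }
  }
  total * ly
}

#' Analytic two-slab contact fixture
#'
#' Builds two parallel cartilage slabs whose separation follows a prescribed
#' gap profile along x, together with the closed-form area where the gap is
#' below the contact threshold. The meshes are exact (not voxelised), so
#' contact-area estimates can be compared against the analytic truth;
#' voxelised masks on a scene grid are included for voxel-based
#' cross-checks.
#'
#' @param gap_profile either a single nonnegative number (constant gap in
#'   mm) or a data.frame with columns `x` and `gap` defining a
#'   piecewise-linear profile over the patch.
#' @param patch_size c(length, width) of the patch in mm.
#' @param spacing grid step for the slab meshes and voxel masks (mm).
#' @param thickness slab thickness in mm.
#' @return A list of class `pf_contact_pair` with `meshes` (named
#'   `patellar` = upper slab, `femoral` = lower slab), voxel `masks`,
#'   `intensity`, and `truth$expected_contact_area` (mm^2, threshold 1 mm).
#' @export
build_analytic_contact_pair <- function(gap_profile, patch_size = c(10, 10),
                                        spacing = 0.5, thickness = 2.0) {
  gx <- seq(0, patch_size[1], by = spacing)
  gap <- eval_gap_profile(gap_profile, gx)
  if (any(gap < 0)) stop("gap_profile must be >= 0")
  ys <- seq(0, patch_size[2], by = spacing)
  lower <- slab_mesh(gx, ys, rep(-thickness, length(gx)), rep(0, length(gx)))
  upper <- slab_mesh(gx, ys, gap, gap + thickness)

  pad <- 2
  zmax <- max(gap) + thickness + pad
  origin <- c(-pad, -pad, -thickness - pad)
  dims <- ceiling((c(patch_size[1], patch_size[2], zmax) - origin) /
                    spacing) + 1L
  ax <- lapply(1:3, function(a) origin[a] + spacing * (seq_len(dims[a]) - 1))
  xg <- rep(ax[[1]], times = dims[2] * dims[3])
  yg <- rep(rep(ax[[2]], each = dims[1]), times = dims[3])
  zg <- rep(ax[[3]], each = dims[1] * dims[2])
  inpatch <- xg >= 0 & xg <= patch_size[1] & yg >= 0 & yg <= patch_size[2]
  gz <- eval_gap_profile(gap_profile, xg)
  low_m <- inpatch & zg >= -thickness & zg <= 0
  up_m <- inpatch & zg >= gz & zg <= gz + thickness
  inten <- rep(110, prod(dims))
  inten[low_m | up_m] <- 190
  structure(list(
    meshes = list(femoral = lower, patellar = upper),
    masks = list(
      femoral_cartilage = label_mask(array(low_m, dims), spacing, origin),
      patellar_cartilage = label_mask(array(up_m, dims), spacing, origin)),
    intensity = image_volume(array(inten, dims), spacing, origin),
    truth = list(expected_contact_area =
                   analytic_contact_area(gap_profile, patch_size))),
    class = "pf_contact_pair")
}

#' Simulate a paired pre/post cohort
#'
#' Draws per-patient paired (pre, post) measurements from a bivariate normal
#' with the stated marginal moments and pre/post correlation `rho`, for every
#' row of `group_params`. The study only reports marginal moments, so `rho`
#' is a simulation knob (default 0.8, a typical test-retest correlation for
#' within-patient imaging measures).
#'
#' @param group_params data.frame with columns `group`, `state`, `measure`,
#'   `pre_mean`, `pre_sd`, `post_mean`, `post_sd` (see
#'   [reference_cohort_moments()]).
#' @param n_patients number of patients per group: a single count, or a
#'   named vector like `c(mild = 8, severe = 5)`.
#' @param pre_post_correlation correlation between paired draws (-1, 1).
#' @param seed RNG seed.
#' @return data.frame of class `pf_cohort` with columns `patient`, `group`,
#'   `state`, `measure`, `pre`, `post`.
#' @export
simulate_cohort <- function(group_params, n_patients,
                            pre_post_correlation = 0.8, seed = 1L) {
  rho <- pre_post_correlation
  if (!(rho > -1 && rho < 1)) stop("pre_post_correlation must be in (-1, 1)")
  if (any(group_params$pre_sd < 0) || any(group_params$post_sd < 0))
    stop("SDs must be >= 0")
  groups <- unique(group_params$group)
  if (length(n_patients) == 1 && is.null(names(n_patients)))
    n_patients <- stats::setNames(rep(n_patients, length(groups)), groups)
  if (any(n_patients < 2)) stop("n_patients must be >= 2")
  with_local_seed(seed, {
    out <- list()
    for (g in groups) {
      ng <- n_patients[[g]]
      rows <- group_params[group_params$group == g, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        z1 <- stats::rnorm(ng)
        z2 <- stats::rnorm(ng)
        pre <- rows$pre_mean[r] + rows$pre_sd[r] * z1
        post <- rows$post_mean[r] +
          rows$post_sd[r] * (rho * z1 + sqrt(1 - rho^2) * z2)
        out[[length(out) + 1]] <- data.frame(
          patient = paste0(g, "_", seq_len(ng)),
          group = g, state = rows$state[r], measure = rows$measure[r],
          pre = pre, post = post, stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("pf_cohort", "data.frame")
    res
  })
}

#' Write a scene to disk
#'
#' Intensity and one mask per structure as NIfTI, plus a JSON sidecar with
#' the phantom spec and ground-truth poses (4x4 world-mm matrices).
#' @param scene A `pf_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(scene$intensity, file.path(dir, paste0(prefix, "_intensity.nii.gz")))
  for (nm in names(scene$masks))
    write_volume(scene$masks[[nm]],
                 file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))
  sidecar <- list(
    spec = unclass(scene$spec),
    truth = list(femur_pose = transform_matrix(scene$truth$femur_pose),
                 patella_pose = transform_matrix(scene$truth$patella_pose),
                 tilt = scene$truth$tilt,
                 lateral_shift = scene$truth$lateral_shift))
  jsonlite::write_json(sidecar, file.path(dir, paste0(prefix, "_meta.json")),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#' @param dir directory containing the scene files.
#' @param prefix file name prefix used when writing.
#' @export
read_scene <- function(dir, prefix = "scene") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  masks <- list()
  for (nm in c("femur_bone", "patella_bone", "femoral_cartilage",
               "patellar_cartilage")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    if (file.exists(p)) masks[[nm]] <- read_volume(p)
  }
  structure(list(
    intensity = read_volume(file.path(dir, paste0(prefix, "_intensity.nii.gz"))),
    masks = masks,
    truth = list(
      femur_pose = transform_from_matrix(matrix(meta$truth$femur_pose, 4, 4)),
      patella_pose = transform_from_matrix(matrix(meta$truth$patella_pose, 4, 4)),
      tilt = meta$truth$tilt,
      lateral_shift = meta$truth$lateral_shift,
      expected_contact_area = NA_real_),
    spec = do.call(phantom_spec, as.list(meta$spec))),
    class = "pf_scene")
}
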