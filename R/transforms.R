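#' Rigid transforms in world millimetres
#'
#' A rigid transform is a rotation about an explicit centre followed by a
#' translation: `T(x) = R (x - c) + c + t`. The same object acts on surface
#' meshes (exact vertex mapping) and on image grids (resampling), always in
#' world coordinates. The world convention throughout the package is
#' right-handed millimetres with axes (medial-to-lateral,
#' posterior-to-anterior, distal-to-proximal).
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation in mm.
#' @param centre length-3 rotation centre in mm.
#' @return An object of class `pf_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            centre = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  centre <- as.numeric(centre)
  stopifnot(length(translation) == 3, length(centre) == 3)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) stop("rotation matrix is not orthonormal (error ", err, ")")
  if (det(rotation) < 0) stop("rotation matrix must have determinant +1")
  structure(list(rotation = rotation, translation = translation,
                 centre = centre),
            class = "pf_transform")
}

#' @export
print.pf_transform <- function(x, ...) {
  cat("Rigid transform (mm): rotation angle",
      format(rotation_angle(x), digits = 4), "deg, translation",
      paste(format(x$translation, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param t A `pf_transform`.
#' @return 4x4 matrix acting on column vectors `(x, y, z, 1)`.
#' @export
transform_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$centre + t$translation - t$rotation %*% t$centre
  m
}

#' Build a rigid transform from a homogeneous 4x4 matrix
#' @param m 4x4 homogeneous matrix with a rigid upper-left block.
#' @return A `pf_transform` with centre at the origin.
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(rotation = m[1:3, 1:3], translation = m[1:3, 4],
                  centre = c(0, 0, 0))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first: `(a o b)(x) = a(b(x))`.
#' @param a,b `pf_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  transform_from_matrix(transform_matrix(a) %*% transform_matrix(b))
}

#' Invert a rigid transform
#' @param t A `pf_transform`.
#' @export
invert_transform <- function(t) {
  m <- transform_matrix(t)
  mi <- diag(4)
  mi[1:3, 1:3] <- t(m[1:3, 1:3])
  mi[1:3, 4] <- -t(m[1:3, 1:3]) %*% m[1:3, 4]
  transform_from_matrix(mi)
}

#' Apply a rigid transform to a matrix of points
#' @param t A `pf_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  offset <- t$centre + t$translation - as.numeric(t$rotation %*% t$centre)
  sweep(pts %*% t(t$rotation), 2, offset, "+")
}

#' Rotation about an axis through a centre
#' @param axis length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @param centre rotation centre in mm.
#' @export
rotation_about_axis <- function(axis, angle_deg, centre = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(rotation = R, centre = centre)
}

#' Translation transform
#' @param v length-3 translation in mm.
#' @export
translation_transform <- function(v) {
  rigid_transform(translation = v)
}

#' Rotation angle of a rigid transform
#' @param t A `pf_transform`.
#' @return Angle of the rotation part in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(t) {
  ct <- (sum(diag(t$rotation)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Pose error between two rigid transforms
#'
#' Reports the rotation angle of `a o b^-1` and the displacement of a
#' reference point, i.e. how differently the two transforms move that point.
#' @param a,b `pf_transform` objects.
#' @param point reference point (mm) at which translation error is measured.
#' @return Named vector `c(rot_deg, trans_mm)`.
#' @export
transform_error <- function(a, b, point = c(0, 0, 0)) {
  d <- compose_transforms(a, invert_transform(b))
  pa <- transform_points(a, matrix(point, 1))
  pb <- transform_points(b, matrix(point, 1))
  c(rot_deg = rotation_angle(d), trans_mm = sqrt(sum((pa - pb)^2)))
}

#' Random rigid transform (for perturbation studies)
#'
#' Draws a uniformly random rotation axis, an angle uniform on
#' `[0, max_angle_deg]` and a translation uniform in the ball of radius
#' `max_translation_mm`. Uses the current RNG stream.
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation_mm maximum translation norm (mm).
#' @param centre rotation centre (mm).
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation_mm,
                                   centre = c(0, 0, 0)) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_angle_deg)
  tr <- stats::rnorm(3)
  tr <- tr / sqrt(sum(tr^2)) * max_translation_mm * stats::runif(1)^(1 / 3)
  tt <- rotation_about_axis(ax, ang, centre)
  tt$translation <- tr
  tt
}

#' Serialize / deserialize rigid transforms as JSON sidecars
#'
#' The convention is a 4x4 homogeneous matrix acting on world-mm column
#' vectors `(x, y, z, 1)`.
#' @param t A `pf_transform`.
#' @param path output / input file path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(matrix = transform_matrix(t),
                            convention = "world-mm, column vectors"),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_from_matrix(matrix(obj$matrix, 4, 4))
}
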