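#' Euclidean distances between opposing cartilage surfaces
#'
#' For each face centroid of the measurement surface, the exact Euclidean
#' distance to the closest point on any face of the opposing surface
#' (point-to-triangle, never point-to-vertex).
#'
#' @param meas measurement-side `pf_mesh` (typically the articular
#'   subsurface of the patellar cartilage).
#' @param opposing opposing `pf_mesh`.
#' @return Numeric vector of distances (mm), one per face of `meas`.
#' @export
surface_distances <- function(meas, opposing) {
  if (nrow(meas$faces) == 0 || nrow(opposing$faces) == 0)
    stop("both surfaces must be nonempty")
  mesh_closest_points(opposing, face_centroids(meas))$distance
}

#' Cartilage contact area below a distance threshold
#'
#' The contact area is the summed area of measurement faces whose
#' inter-cartilage distance is strictly below the threshold (default 1 mm).
#' Faces are counted whole at their centroid distance; the estimate
#' converges to the analytic area as the mesh is refined.
#'
#' @param distances per-face distances from [surface_distances()].
#' @param face_areas per-face areas (mm^2), same length.
#' @param threshold contact threshold in mm (default 1.0, strict `<`).
#' @param mesh optional `pf_mesh` the faces belong to; enables patch
#'   topology (component count, holes) in the result.
#' @param measurement_surface label recorded in the result.
#' @return An object of class `pf_contact` with fields `distances`, `cca`
#'   (mm^2), `threshold`, `n_components`, `has_holes`,
#'   `measurement_surface`.
#' @export
contact_area <- function(distances, face_areas, threshold = 1.0,
                         mesh = NULL, measurement_surface = "patellar") {
  if (length(distances) != length(face_areas))
    stop("distances and face_areas must have the same length")
  sel <- distances < threshold
  cca <- sum(face_areas[sel])
  n_components <- NA_integer_
  has_holes <- NA
  if (!is.null(mesh) && any(sel)) {
    topo <- contact_topology(sel, mesh)
    n_components <- topo$n_components
    has_holes <- topo$has_holes
  } else if (!is.null(mesh)) {
    n_components <- 0L
    has_holes <- FALSE
  }
  structure(list(distances = distances, cca = cca, threshold = threshold,
                 n_components = n_components, has_holes = has_holes,
                 measurement_surface = measurement_surface),
            class = "pf_contact")
}

#' @export
print.pf_contact <- function(x, ...) {
  cat("Contact: CCA", format(x$cca, digits = 6), "mm^2 below",
      x$threshold, "mm on the", x$measurement_surface, "surface")
  if (!is.na(x$n_components))
    cat(";", x$n_components, "patch(es),",
        if (isTRUE(x$has_holes)) "with holes" else "no holes")
  cat("\n")
  invisible(x)
}

#' Topology of the contact patch
#'
#' Connected components over edge-adjacent contact faces, and hole detection
#' from the Euler characteristic of each patch: a disc-like patch has
#' `V - E + F = 1`; `0` or less indicates holes (an annulus has 0). A
#' component that is itself a closed surface (`V - E + F = 2`) has no holes.
#'
#' @param contact_faces logical vector marking contact faces.
#' @param mesh the `pf_mesh` the faces belong to.
#' @return List with `n_components` and `has_holes`.
#' @export
contact_topology <- function(contact_faces, mesh) {
  if (!any(contact_faces)) return(list(n_components = 0L, has_holes = FALSE))
  patch <- mesh_subset(mesh, contact_faces)
  comp <- face_components(patch)
  ncomp <- max(comp)
  holes <- FALSE
  for (ci in seq_len(ncomp)) {
    sub <- mesh_subset(patch, comp == ci)
    chi <- euler_characteristic(sub)
    if (chi <= 0) holes <- TRUE
  }
  list(n_components = ncomp, has_holes = holes)
}

#' Cartilage contact between two cartilage surfaces
#'
#' Convenience wrapper chaining articular-subsurface selection,
#' point-to-triangle distances and the thresholded contact area. The
#' measurement side defaults to the patellar cartilage; the femoral-side
#' area is obtained by swapping the arguments.
#'
#' @param patellar,femoral cartilage `pf_mesh` surfaces.
#' @param threshold contact threshold in mm.
#' @param measurement_surface which side the area is summed on.
#' @return A `pf_contact` (see [contact_area()]); the articular subsurface
#'   used is attached as attribute `surface`.
#' @export
measure_contact <- function(patellar, femoral, threshold = 1.0,
                            measurement_surface = c("patellar", "femoral")) {
  measurement_surface <- match.arg(measurement_surface)
  if (measurement_surface == "patellar") {
    meas <- articular_subsurface(patellar, femoral)
    opp <- femoral
  } else {
    meas <- articular_subsurface(femoral, patellar)
    opp <- patellar
  }
  if (nrow(meas$faces) == 0)
    return(structure(list(distances = numeric(0), cca = 0,
                          threshold = threshold, n_components = 0L,
                          has_holes = FALSE,
                          measurement_surface = measurement_surface),
                     class = "pf_contact"))
  d <- surface_distances(meas, opp)
  res <- contact_area(d, face_areas(meas), threshold, mesh = meas,
                      measurement_surface = measurement_surface)
  attr(res, "surface") <- meas
  res
}

#' Export per-face contact distances for visual QC
#'
#' Writes the measurement surface as ASCII PLY with the inter-cartilage
#' distance attached as a per-face `quality` property.
#' @param contact a `pf_contact` produced by [measure_contact()].
#' @param path output PLY path.
#' @export
write_contact_ply <- function(contact, path) {
  mesh <- attr(contact, "surface")
  if (is.null(mesh)) stop("contact result carries no surface")
  write_ply(mesh, path, face_scalar = contact$distances)
}
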