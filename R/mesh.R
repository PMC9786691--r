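#' Triangulated surface meshes
#'
#' Surfaces are stored as vertex/face index arrays in world millimetres, with
#' consistently oriented outward normals (guaranteed by the isosurfacer).
#' Per-face areas, normals and centroids are computed on demand and cached.
#'
#' @param vertices n x 3 matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `pf_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, cache = new.env()),
            class = "pf_mesh")
}

#' @export
print.pf_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, area", format(mesh_area(x), digits = 6), "mm^2\n")
  invisible(x)
}

mesh_cached <- function(mesh, key, fn) {
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  val <- fn(mesh)
  assign(key, val, envir = mesh$cache)
  val
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face areas in square millimetres
#' @param mesh A `pf_mesh`.
#' @export
face_areas <- function(mesh) {
  mesh_cached(mesh, "areas", function(m) {
    cr <- face_cross(m)
    0.5 * sqrt(rowSums(cr^2))
  })
}

#' Per-face outward unit normals
#' @param mesh A `pf_mesh`.
#' @export
face_normals <- function(mesh) {
  mesh_cached(mesh, "normals", function(m) {
    cr <- face_cross(m)
    n <- sqrt(rowSums(cr^2))
    n[n == 0] <- 1
    cr / n
  })
}

#' Per-face centroids
#' @param mesh A `pf_mesh`.
#' @export
face_centroids <- function(mesh) {
  mesh_cached(mesh, "centroids", function(m) {
    v <- m$vertices
    f <- m$faces
    (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
       v[f[, 3], , drop = FALSE]) / 3
  })
}

#' Total surface area
#' @param mesh A `pf_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Keep a subset of faces (vertices are reindexed)
#' @param mesh A `pf_mesh`.
#' @param keep logical or integer face selector.
#' @export
mesh_subset <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3))
}

## undirected edge keys for every face edge (3 per face)
mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  (lo - 1) * as.numeric(nrow(mesh$vertices)) + hi
}

#' Watertightness check
#'
#' A closed oriented surface has every edge shared by exactly two faces.
#' @param mesh A `pf_mesh`.
#' @export
is_watertight <- function(mesh) {
  tab <- table(mesh_edge_keys(mesh))
  all(tab == 2)
}

#' Euler characteristic `V - E + F`
#' @param mesh A `pf_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  ne <- length(unique(mesh_edge_keys(mesh)))
  nrow(mesh$vertices) - ne + nrow(mesh$faces)
}

## face adjacency as an edge list of face pairs sharing a mesh edge
face_adjacency_pairs <- function(mesh) {
  keys <- mesh_edge_keys(mesh)
  fid <- rep(seq_len(nrow(mesh$faces)), 3)
  ord <- order(keys)
  keys <- keys[ord]
  fid <- fid[ord]
  same <- which(keys[-1] == keys[-length(keys)])
  cbind(fid[same], fid[same + 1])
}

## connected components of faces over shared edges (union-find)
face_components <- function(mesh) {
  n <- nrow(mesh$faces)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pr <- face_adjacency_pairs(mesh)
  if (nrow(pr) > 0)
    for (r in seq_len(nrow(pr))) {
      a <- find(pr[r, 1]); b <- find(pr[r, 2])
      if (a != b) parent[a] <- b
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Write / read an ASCII PLY mesh
#'
#' Optionally attaches one scalar per face as a `quality` property, used to
#' export inter-cartilage distances for visual QC.
#' @param mesh A `pf_mesh`.
#' @param path file path.
#' @param face_scalar optional numeric vector, one value per face.
#' @export
write_ply <- function(mesh, path, face_scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices")
  if (!is.null(face_scalar)) {
    stopifnot(length(face_scalar) == nf)
    hdr <- c(hdr, "property double quality")
  }
  hdr <- c(hdr, "end_header")
  vtxt <- apply(format(mesh$vertices, digits = 17, trim = TRUE,
                       scientific = FALSE), 1, paste, collapse = " ")
  fmat <- cbind(3L, mesh$faces - 1L)
  ftxt <- apply(fmat, 1, paste, collapse = " ")
  if (!is.null(face_scalar))
    ftxt <- paste(ftxt, format(face_scalar, digits = 17, trim = TRUE,
                               scientific = FALSE))
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  verts <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  fparts <- strsplit(fl, " ", fixed = TRUE)
  faces <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L,
                    integer(3)))
  scal <- NULL
  if (length(fparts[[1]]) >= 5)
    scal <- vapply(fparts, function(p) as.numeric(p[5]), numeric(1))
  m <- surface_mesh(verts, faces)
  if (!is.null(scal)) attr(m, "face_scalar") <- scal
  m
}

#' Write / read an ASCII STL mesh
#'
#' STL stores unshared triangle soup; `read_stl` re-welds identical vertex
#' coordinates.
#' @param mesh A `pf_mesh`.
#' @param path file path.
#' @export
write_stl <- function(mesh, path) {
  n <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = TRUE), collapse = " ")
  for (i in seq_len(nrow(f))) {
    writeLines(c(paste("facet normal", fmt(n[i, ])),
                 "  outer loop",
                 paste("    vertex", fmt(v[f[i, 1], ])),
                 paste("    vertex", fmt(v[f[i, 2], ])),
                 paste("    vertex", fmt(v[f[i, 3], ])),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- matrix(scan(text = gsub("^\\s*vertex\\s+", "", vl),
                        quiet = TRUE), ncol = 3, byrow = TRUE)
  key <- apply(coords, 1, paste, collapse = ",")
  uidx <- !duplicated(key)
  verts <- coords[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Exact closest points on a mesh
#'
#' For each query point, the closest point on the surface (point-to-triangle,
#' using a uniform-grid search that is exact, not approximate).
#' @param mesh A `pf_mesh`.
#' @param points n x 3 matrix of query points (mm).
#' @return List with `distance` (mm), `point` (n x 3) and `face` (index).
#' @export
mesh_closest_points <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  .mesh_closest_cpp(mesh$vertices, mesh$faces, points)
}
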