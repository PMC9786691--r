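test_that("inter-slice smoothing preserves constants and removes thin plates", {
  arr <- array(1, c(8, 8, 20))
  ones <- label_mask(arr, 0.5)
  sm <- smooth_interslice(ones, 1.25)
  expect_equal(sm$values, ones$values)

  ## a 1-slice plate: peak 1D Gaussian weight at sigma = 2.5 voxels is
  ## ~0.16 < 0.5, so the plate must vanish after re-thresholding
  plate <- array(0, c(12, 12, 21))
  plate[, , 11] <- 1
  pm <- label_mask(plate, 0.5)
  expect_equal(sum(smooth_interslice(pm, 1.25)$values), 0)

  ## a thick blob keeps its volume within 10%
  blob <- box_mask(c(8, 8, 8), spacing = 0.5)
  sb <- smooth_interslice(blob, 1.25)
  expect_lt(abs(mask_volume_mm3(sb) - mask_volume_mm3(blob)) /
              mask_volume_mm3(blob), 0.10)

  expect_error(smooth_interslice(blob, -1), "sigma")
})

test_that("smoothing is idempotent within one voxel layer on smooth masks", {
  blob <- box_mask(c(10, 10, 10), spacing = 0.5)
  s1 <- smooth_interslice(blob, 1.25)
  s2 <- smooth_interslice(s1, 1.25)
  changed <- sum(abs(s2$values - s1$values))
  layer <- sum(s1$values) - sum(erode_mask(s1, 0.5)$values)
  expect_lte(changed, layer)
})

test_that("ball dilation matches brute-force lattice enumeration", {
  arr <- array(0, c(31, 31, 31))
  arr[16, 16, 16] <- 1
  mk <- label_mask(arr, 0.5)
  dil <- dilate_mask(mk, 3)
  g <- expand.grid(i = -15:15, j = -15:15, k = -15:15)
  brute <- sum(sqrt(g$i^2 + g$j^2 + g$k^2) * 0.5 <= 3)
  expect_equal(sum(dil$values), brute)
  expect_equal(brute, 925)
})

test_that("dilation is the identity at radius 0, extensive and monotone", {
  box <- box_mask(c(6, 6, 6))
  expect_equal(dilate_mask(box, 0)$values, box$values)
  d1 <- dilate_mask(box, 1)
  d2 <- dilate_mask(box, 2.5)
  expect_true(all(d1$values >= box$values))
  expect_true(all(d2$values >= d1$values))
})

test_that("closing (dilate then erode) contains the original cube", {
  cube <- box_mask(c(10, 10, 10), spacing = 0.5)
  closed <- erode_mask(dilate_mask(cube, 3), 3)
  expect_true(all(closed$values >= cube$values))
})

test_that("sphere mesh area is within 3% of the analytic value", {
  mk <- sphere_mask(radius = 10, spacing = 0.5)
  mesh <- extract_surface(mk)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.03)
  expect_true(is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2L)
})

test_that("surface area error shrinks with finer spacing", {
  errs <- vapply(c(1.0, 0.5), function(sp) {
    mesh <- extract_surface(sphere_mask(radius = 10, spacing = sp))
    abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("a slab meshes into two dominant opposite-normal patches", {
  slab <- box_mask(c(20, 20, 2), spacing = 0.5)
  mesh <- extract_surface(slab)
  n <- face_normals(mesh)
  a <- face_areas(mesh)
  up <- sum(a[n[, 3] > 0.9])
  down <- sum(a[n[, 3] < -0.9])
  expect_gt(up / sum(a), 0.35)
  expect_gt(down / sum(a), 0.35)
  expect_error(extract_surface(label_mask(array(0, c(4, 4, 4)), 1)),
               "empty")
})

test_that("articular subsurface selects mutually facing faces", {
  lower <- slabs <- build_analytic_contact_pair(0.5)
  meas <- articular_subsurface(slabs$meshes$patellar, slabs$meshes$femoral)
  ## only the underside of the upper slab faces the lower slab
  expect_true(all(face_normals(meas)[, 3] < -0.9))
  expect_equal(mesh_area(meas), 100, tolerance = 0.01)

  ## orthogonal open sheets: the dot-product criterion empties the selection
  sheet <- function() {
    g <- expand.grid(x = 0:10, y = 0:10)
    verts <- cbind(g$x, g$y, 0)
    id <- function(i, j) (j - 1) * 11 + i
    f <- list()
    for (j in 1:10) {
      i <- 1:10
      f[[length(f) + 1]] <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
      f[[length(f) + 1]] <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
    }
    surface_mesh(verts, do.call(rbind, f))  # normals +z
  }
  a <- sheet()
  b <- apply_transform(sheet(), compose_transforms(
    translation_transform(c(0, 0, 5)),
    rotation_about_axis(c(1, 0, 0), 90, centre = c(5, 5, 0))))
  expect_warning(sel <- articular_subsurface(a, b), "no mutually facing")
  expect_equal(nrow(sel$faces), 0L)
})

test_that("the whole inner sphere faces a concentric outer sphere", {
  inner <- extract_surface(sphere_mask(10, spacing = 0.5, margin = 2))
  outerm <- sphere_mask(14, spacing = 0.5, margin = 2)
  hole <- sphere_mask(12, spacing = 0.5, margin = 4)
  ## build a spherical shell 12..14 mm as the opposing surface
  n <- dim(outerm$values)[1]
  ax <- outerm$origin[1] + 0.5 * (seq_len(n) - 1)
  a2 <- outer(ax^2, ax^2, "+")
  shell <- array(0, dim(outerm$values))
  for (k in seq_len(n))
    shell[, , k] <- (a2 + ax[k]^2 > 12^2) & (a2 + ax[k]^2 <= 14^2)
  opp <- extract_surface(label_mask(shell, 0.5, outerm$origin))
  sel <- articular_subsurface(inner, opp)
  expect_gt(mesh_area(sel) / mesh_area(inner), 0.98)
})
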