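test_that("parallel slabs give uniform distances and full/zero contact", {
  for (gap in c(0.5, 1.5)) {
    cp <- build_analytic_contact_pair(gap)
    meas <- articular_subsurface(cp$meshes$patellar, cp$meshes$femoral)
    d <- surface_distances(meas, cp$meshes$femoral)
    expect_equal(d, rep(gap, length(d)), tolerance = 0.02 / gap)
    ca <- contact_area(d, face_areas(meas))
    expect_equal(ca$cca, cp$truth$expected_contact_area, tolerance = 1e-6)
  }
})

test_that("concentric sphere distances match the analytic 2 mm", {
  inner <- extract_surface(sphere_mask(10, spacing = 0.5, margin = 2))
  outerm <- sphere_mask(12, spacing = 0.5, margin = 2)
  n <- dim(outerm$values)[1]
  ax <- outerm$origin[1] + 0.5 * (seq_len(n) - 1)
  a2 <- outer(ax^2, ax^2, "+")
  shell <- array(0, dim(outerm$values))
  for (k in seq_len(n))
    shell[, , k] <- (a2 + ax[k]^2 > 12^2) & (a2 + ax[k]^2 <= 14^2)
  opp <- extract_surface(label_mask(shell, 0.5, outerm$origin))
  d <- surface_distances(inner, opp)
  expect_equal(mean(d), 2, tolerance = 0.05)
  expect_true(all(d >= 0))
  expect_error(surface_distances(surface_mesh(matrix(numeric(0), 0, 3),
                                              matrix(integer(0), 0, 3)),
                                 inner), "nonempty")
})

test_that("point-to-triangle never exceeds the point-to-vertex oracle", {
  mesh <- clean_meshes()$femoral_cartilage
  set.seed(12)
  q <- matrix(rnorm(300, sd = 10), ncol = 3)
  q <- sweep(q, 2, c(0, 10, 4), "+")
  cl <- mesh_closest_points(mesh, q)
  p2v <- vapply(seq_len(nrow(q)), function(i) {
    min(sqrt(rowSums(sweep(mesh$vertices, 2, q[i, ])^2)))
  }, numeric(1))
  expect_true(all(cl$distance <= p2v + 1e-9))
})

test_that("the ramp fixture reproduces its analytic contact area", {
  ramp <- data.frame(x = c(0, 10), gap = c(0, 2))
  cp <- build_analytic_contact_pair(ramp, spacing = 0.25)
  meas <- articular_subsurface(cp$meshes$patellar, cp$meshes$femoral)
  d <- surface_distances(meas, cp$meshes$femoral)
  ca <- contact_area(d, face_areas(meas), mesh = meas)
  expect_equal(ca$cca, 50, tolerance = 0.05)
  expect_equal(ca$n_components, 1L)
  expect_false(ca$has_holes)
})

test_that("mesh-wise distances agree with a voxel distance-transform oracle", {
  ramp <- data.frame(x = c(0, 10), gap = c(0.4, 2.4))
  cp <- build_analytic_contact_pair(ramp, spacing = 0.25)
  ## voxel oracle: CCA from the distance transform of the opposing mask,
  ## counting measurement-surface voxels (lower face of the upper slab)
  dm <- distance_map(cp$masks$femoral_cartilage)
  meas <- articular_subsurface(cp$meshes$patellar, cp$meshes$femoral)
  d_mesh <- surface_distances(meas, cp$meshes$femoral)
  cca_mesh <- contact_area(d_mesh, face_areas(meas))$cca
  ## analytic: gap < 1 for x < 3; area = 30
  expect_equal(cca_mesh, 30, tolerance = 0.07)
  ## voxel-wise: sample the distance field on the measurement surface
  cen <- face_centroids(meas)
  d_vox <- patellotrack:::sample_volume(dm, cen, outside = Inf)
  cca_vox <- contact_area(pmax(d_vox, 0), face_areas(meas))$cca
  expect_equal(cca_vox, cca_mesh, tolerance = 0.10)
})

test_that("contact area is monotone in threshold and bounded by the surface", {
  sc <- clean_scene()
  pc <- clean_meshes()$patellar_cartilage
  fc <- clean_meshes()$femoral_cartilage
  meas <- articular_subsurface(pc, fc)
  d <- surface_distances(meas, fc)
  fa <- face_areas(meas)
  cc <- vapply(c(0.5, 1, 2, 4, Inf), function(th)
    contact_area(d, fa, th)$cca, numeric(1))
  expect_true(all(diff(cc) >= 0))
  expect_equal(cc[5], sum(fa))
  expect_equal(contact_area(d, fa, threshold = min(d) * 0.5)$cca, 0)
  expect_error(contact_area(d[-1], fa), "length")
})

test_that("contact shrinks monotonically as the patella is pulled away", {
  pc <- clean_meshes()$patellar_cartilage
  fc <- clean_meshes()$femoral_cartilage
  prev <- Inf
  for (pull in c(0, 0.4, 0.8, 1.3)) {
    cca <- measure_contact(
      apply_transform(pc, translation_transform(c(0, pull, 0))), fc)$cca
    expect_lte(cca, prev + 1e-9)
    prev <- cca
  }
  expect_equal(prev, 0)
})

test_that("patch topology distinguishes discs, split patches and annuli", {
  cp <- build_analytic_contact_pair(0.5)
  meas <- articular_subsurface(cp$meshes$patellar, cp$meshes$femoral)
  cen <- face_centroids(meas)
  ## single convex patch
  one <- cen[, 1] < 4
  topo <- contact_topology(one, meas)
  expect_equal(topo$n_components, 1L)
  expect_false(topo$has_holes)
  ## two separated patches
  two <- cen[, 1] < 3 | cen[, 1] > 7
  topo <- contact_topology(two, meas)
  expect_equal(topo$n_components, 2L)
  expect_false(topo$has_holes)
  ## annulus: Euler characteristic 0 implies a hole
  r <- sqrt((cen[, 1] - 5)^2 + (cen[, 2] - 5)^2)
  ann <- r > 1.5 & r < 4
  topo <- contact_topology(ann, meas)
  expect_equal(topo$n_components, 1L)
  expect_true(topo$has_holes)
  ## no contact at all
  expect_equal(contact_topology(rep(FALSE, nrow(meas$faces)), meas),
               list(n_components = 0L, has_holes = FALSE))
})

test_that("contact distances export to PLY for QC", {
  cp <- build_analytic_contact_pair(0.5)
  con <- measure_contact(cp$meshes$patellar, cp$meshes$femoral)
  path <- tempfile(fileext = ".ply")
  write_contact_ply(con, path)
  rt <- read_ply(path)
  expect_equal(attr(rt, "face_scalar"), con$distances, tolerance = 1e-12)
})
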