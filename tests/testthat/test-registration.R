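test_that("ICP on an identical mesh returns the identity", {
  mesh <- clean_meshes()$femur_bone
  tr <- icp_align(mesh, mesh)
  e <- transform_error(tr, rigid_transform(), point = c(0, 0, 0))
  expect_lt(e["rot_deg"], 1e-3)
  expect_lt(e["trans_mm"], 1e-3)
  expect_lt(attr(tr, "residual_rms"), 1e-3)
})

test_that("ICP recovers a known rotation + translation of the femur", {
  mesh <- clean_meshes()$femur_bone
  truth <- compose_transforms(
    translation_transform(c(3, -2, 5)),
    rotation_about_axis(c(0, 0, 1), 10, centre = c(0, -4, 20)))
  target <- apply_transform(mesh, truth)
  tr <- icp_align(mesh, target)
  e <- transform_error(tr, truth, point = c(0, -4, 20))
  expect_lt(e["rot_deg"], 0.1)
  expect_lt(e["trans_mm"], 0.05)
})

test_that("ICP is inverse-consistent", {
  mesh <- clean_meshes()$femur_bone
  set.seed(6)
  truth <- random_rigid_transform(12, 8, centre = c(0, -4, 15))
  target <- apply_transform(mesh, truth)
  fwd <- icp_align(mesh, target)
  bwd <- icp_align(target, mesh)
  round <- compose_transforms(bwd, fwd)
  e <- transform_error(round, rigid_transform(), point = c(0, -4, 15))
  expect_lt(e["rot_deg"], 0.2)
  expect_lt(e["trans_mm"], 0.1)
})

test_that("ICP rejects degenerate vertex configurations", {
  z <- seq(0, 10, length.out = 300)
  line <- surface_mesh(cbind(z * 0, z * 0, z),
                       cbind(1:298, 2:299, 3:300))
  expect_error(icp_align(line, line), "degenerate")
})

test_that("NGF distance vanishes for identical aligned images", {
  sc <- clean_scene()
  mask <- dilate_mask(sc$masks$femur_bone, 3)
  d <- ngf_distance(sc$intensity, sc$intensity, rigid_transform(), mask)
  expect_lt(abs(d), 1e-8)
})

test_that("orthogonal strong gradients score the full masked volume", {
  n <- 24
  ax <- seq_len(n)
  xr <- image_volume(array(rep(ax * 50, times = n * n), c(n, n, n)), 1)
  yr <- image_volume(array(rep(rep(ax * 50, each = n), times = n),
                           c(n, n, n)), 1)
  mv <- array(0, c(n, n, n))
  mv[8:16, 8:16, 8:16] <- 1
  mask <- label_mask(mv, 1)
  d <- ngf_distance(xr, yr, rigid_transform(), mask,
                    ngf_params(epsilon = 1e-3, presmooth_vox = 0))
  expect_equal(d, sum(mv), tolerance = 1e-3)
  expect_error(ngf_distance(xr, yr, rigid_transform(),
                            label_mask(array(0, c(n, n, n)), 1)),
               "empty")
})

test_that("NGF distance is symmetric at the identity", {
  sc <- clean_scene()
  sc2 <- build_scene(clean_spec(seed = 5, patella_tilt_true = 4))
  mask <- dilate_mask(sc$masks$patella_bone, 3)
  p <- ngf_params(epsilon = 1.0)
  d12 <- ngf_distance(sc$intensity, sc2$intensity, rigid_transform(), mask, p)
  d21 <- ngf_distance(sc2$intensity, sc$intensity, rigid_transform(), mask, p)
  expect_equal(d12, d21, tolerance = 1e-9)
  expect_gt(d12, 0)
})

test_that("NGF has its minimum at the true translation (sweep oracle)", {
  spec <- coarse_spec()
  base <- build_scene(spec)
  shift <- translation_transform(c(3.1, 0, 0))
  target <- build_scene(spec, scene_pose = shift)
  mask <- dilate_mask(base$masks$femur_bone, 3)
  tx <- seq(1.6, 4.6, by = 0.25)
  dd <- vapply(tx, function(t) {
    ngf_distance(base$intensity, target$intensity,
                 translation_transform(c(t, 0, 0)), mask)
  }, numeric(1))
  expect_lt(abs(tx[which.min(dd)] - 3.1), 0.5)  # half a (1 mm) voxel
})

test_that("NGF refinement never worsens the distance and recovers truth", {
  spec <- clean_spec()
  base <- cached("reg_base", function() build_scene(clean_spec()))
  set.seed(9)
  truth <- random_rigid_transform(10, 8, centre = c(0, -4.5, 15))
  target <- cached("reg_target", function() build_scene(spec,
                                                        scene_pose = truth))
  mask <- dilate_mask(base$masks$femur_bone, 3)
  ## init = truth: no worsening allowed
  t0 <- ngf_refine(base$intensity, target$intensity, truth, mask)
  expect_lte(attr(t0, "ngf_final"), attr(t0, "ngf_init") + 1e-9)
  ## init perturbed by ~1 deg / 1 mm: recovered below a quarter voxel
  pert <- compose_transforms(
    rotation_about_axis(c(0, 1, 0), 1, centre = c(0, -4.5, 15)), truth)
  pert$translation <- pert$translation + c(1, 0, 0)
  t1 <- ngf_refine(base$intensity, target$intensity, pert, mask)
  e <- transform_error(t1, truth, point = c(0, -4.5, 15))
  expect_lt(e["rot_deg"], 0.25)
  expect_lt(e["trans_mm"], 0.25)
})

test_that("register_bone composes ICP + NGF and transfers cartilage", {
  spec <- clean_spec()
  base <- cached("reg_base", function() build_scene(clean_spec()))
  set.seed(9)
  truth <- random_rigid_transform(10, 8, centre = c(0, -4.5, 15))
  target <- cached("reg_target", function() build_scene(spec,
                                                        scene_pose = truth))
  tr <- register_bone(base, target, "femur_bone")
  e <- transform_error(tr, truth, point = c(0, -4.5, 15))
  expect_lt(e["rot_deg"], 0.5)
  expect_lt(e["trans_mm"], 0.25)
  prov <- attr(tr, "provenance")
  expect_true(is.finite(prov$icp_residual_rms))
  expect_true(is.finite(prov$ngf_final))
  ## base cartilage carried by the femur transform lands on the target's
  fc <- extract_surface(base$masks$femoral_cartilage)
  fc_t <- apply_transform(fc, tr)
  fc_true <- extract_surface(target$masks$femoral_cartilage)
  d <- mesh_closest_points(fc_true, face_centroids(fc_t))$distance
  expect_lt(mean(d), 0.5)
})

test_that("registering a scene to itself returns the identity", {
  base <- cached("reg_base", function() build_scene(clean_spec()))
  tr <- register_bone(base, base, "patella_bone")
  e <- transform_error(tr, rigid_transform(), point = c(0, 22, 2))
  expect_lt(e["rot_deg"], 0.1)
  expect_lt(e["trans_mm"], 0.05)
})
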