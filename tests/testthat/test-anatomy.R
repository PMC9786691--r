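test_that("the femoral frame matches the world axes on the canonical femur", {
  fr <- clean_frame()
  for (i in 1:3) {
    ang <- acos(min(1, abs(sum(fr$axes[, i] * diag(3)[, i])))) * 180 / pi
    expect_lt(ang, 1)
  }
  ## right-handed and orthonormal
  expect_equal(unname(crossprod(fr$axes)), diag(3), tolerance = 1e-9)
  expect_gt(det(fr$axes), 0)
  ## origin sits in the trochlear groove (near the canonical midline)
  expect_lt(abs(fr$origin[1]), 1)
})

test_that("the frame is deterministic and equivariant under rotation", {
  fm <- clean_meshes()$femur_bone
  f1 <- femoral_frame(fm)
  f2 <- femoral_frame(fm)
  expect_identical(f1$axes, f2$axes)
  expect_identical(f1$origin, f2$origin)
  set.seed(21)
  rot <- random_rigid_transform(30, 10)
  f3 <- femoral_frame(apply_transform(fm, rot))
  expect_equal(f3$axes, rot$rotation %*% f1$axes, tolerance = 0.02)
  expect_equal(as.numeric(f3$origin),
               as.numeric(transform_points(rot, matrix(f1$origin, 1))),
               tolerance = 0.5)
})

test_that("prescribed tilt and shift are recovered on noiseless phantoms", {
  sc <- build_scene(clean_spec(patella_tilt_true = 20,
                               patella_lateral_shift_true = 5))
  fm <- extract_surface(sc$masks$femur_bone)
  pm <- extract_surface(sc$masks$patella_bone)
  fr <- femoral_frame(fm)
  expect_equal(patellar_tilt(pm, fr), 20, tolerance = 1 / 20)
  expect_equal(lateral_translation(pm, fr), 5, tolerance = 0.5 / 5)
})

test_that("tilt is translation-invariant and equivariant in axial rotation", {
  pm <- clean_meshes()$patella_bone
  fr <- clean_frame()
  t0 <- patellar_tilt(pm, fr)
  moved <- apply_transform(pm, translation_transform(c(2, -3, 4)))
  expect_equal(patellar_tilt(moved, fr), t0, tolerance = 1e-6)
  ## adding delta degrees of axial rotation changes tilt by delta
  for (delta in c(5, 12)) {
    rotated <- apply_transform(pm, rotation_about_axis(
      fr$axes[, 3], -delta, centre = mesh_centroid(pm)))
    expect_equal(patellar_tilt(rotated, fr), t0 + delta, tolerance = 0.5)
  }
})

test_that("translation is unchanged by patellar rotation about its centroid", {
  pm <- clean_meshes()$patella_bone
  fr <- clean_frame()
  l0 <- lateral_translation(pm, fr)
  rot <- rotation_about_axis(c(0, 1, 0), 15, centre = mesh_centroid(pm))
  expect_equal(lateral_translation(apply_transform(pm, rot), fr), l0,
               tolerance = 0.1)
})

test_that("tilt measurement rejects degenerate projections", {
  fr <- clean_frame()
  z <- seq(0, 10, length.out = 200)
  rod <- surface_mesh(cbind(z * 0 + 1e-6 * sin(z), z * 0, z),
                      cbind(1:198, 2:199, 3:200))
  expect_error(patellar_tilt(rod, fr), "degenerate")
})

test_that("sulcus angle and inclination recover the construction", {
  sc <- clean_scene()
  expect_equal(sulcus_angle(sc), 140, tolerance = 2 / 140)
  expect_equal(lateral_trochlear_inclination(sc), 20, tolerance = 2 / 20)
  sev <- build_scene(clean_spec(sulcus_angle_true = 152,
                                lateral_inclination_true = 14,
                                trochlear_depth = 2.5))
  expect_equal(sulcus_angle(sev), 152, tolerance = 2 / 152)
  expect_equal(lateral_trochlear_inclination(sev), 14, tolerance = 2 / 14)
})

test_that("a flat trochlea tends to the 180 degree limit", {
  flat <- build_scene(clean_spec(trochlear_depth = 0.2))
  expect_gt(sulcus_angle(flat), 170)
})

test_that("patellotrochlear index is 1 for fully engaged cartilage", {
  sc0 <- clean_scene()
  pti0 <- patellotrochlear_index(sc0, clean_frame())
  expect_gte(pti0, 0)
  expect_lte(pti0, 1)
  ## trim the patellar cartilage to the femoral cartilage's z-range:
  ## full overlap by construction
  sc <- build_scene(clean_spec())
  fr <- femoral_frame(extract_surface(sc$masks$femur_bone))
  fem <- sc$masks$femoral_cartilage
  pat <- sc$masks$patellar_cartilage
  fz <- range(to_frame_z(fr, fem))
  pz <- to_frame_z(fr, pat)
  keep <- which(pat$values != 0)[pz > fz[1] + 1 & pz < fz[2] - 1]
  trimmed <- pat
  trimmed$values[] <- 0
  trimmed$values[keep] <- 1
  sc$masks$patellar_cartilage <- trimmed
  expect_equal(patellotrochlear_index(sc, fr), 1.0, tolerance = 1e-6)
})

test_that("severity grouping applies configured cut-offs deterministically", {
  thr <- test_severity_thresholds()
  mild <- list(sulcus_angle = 140, lateral_trochlear_inclination = 20)
  severe <- list(sulcus_angle = 152, lateral_trochlear_inclination = 8)
  expect_equal(severity_group(mild, thr), "mild")
  expect_equal(severity_group(severe, thr), "severe")
  ## boundary convention: closed on the severe side
  expect_equal(severity_group(list(sulcus_angle = 145,
                                   lateral_trochlear_inclination = 20), thr),
               "severe")
  expect_equal(severity_group(list(sulcus_angle = 144.99,
                                   lateral_trochlear_inclination = 11), thr),
               "severe")
  expect_equal(severity_group(list(sulcus_angle = 144.99,
                                   lateral_trochlear_inclination = 11.01),
                              thr), "mild")
  expect_error(severity_group(mild, NULL), "thresholds")
  expect_error(severity_group(mild, list(unrelated = 1)), "thresholds")
})
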