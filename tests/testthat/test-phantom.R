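test_that("identical spec and seed give bit-identical scenes", {
  spec <- phantom_spec(seed = 42)
  s1 <- build_scene(spec)
  s2 <- build_scene(spec)
  expect_identical(s1$intensity$values, s2$intensity$values)
  for (nm in names(s1$masks))
    expect_identical(s1$masks[[nm]]$values, s2$masks[[nm]]$values)
  s3 <- build_scene(phantom_spec(seed = 43))
  expect_false(identical(s1$intensity$values, s3$intensity$values))
})

test_that("scene masks share the grid, are disjoint and cartilage hugs bone", {
  sc <- clean_scene()
  geom_ok <- vapply(sc$masks, function(m) {
    identical(dim(m$values), dim(sc$intensity$values)) &&
      all(m$spacing == sc$intensity$spacing) &&
      all(m$origin == sc$intensity$origin)
  }, logical(1))
  expect_true(all(geom_ok))
  overlap <- Reduce(`+`, lapply(sc$masks, function(m) m$values))
  expect_lte(max(overlap), 1)
  ## each cartilage shell is adjacent to its bone (within ~1 voxel)
  for (pair in list(c("femoral_cartilage", "femur_bone"),
                    c("patellar_cartilage", "patella_bone"))) {
    dm <- distance_map(sc$masks[[pair[2]]])
    cart <- sc$masks[[pair[1]]]$values != 0
    expect_lte(min(dm$values[cart]), 1.01 * sc$intensity$spacing[1])
    expect_gt(sum(cart), 0)
  }
})

test_that("a symmetric spec yields zero measured tilt and shift", {
  sc <- clean_scene()
  fr <- clean_frame()
  expect_lt(abs(patellar_tilt(clean_meshes()$patella_bone, fr)), 1)
  expect_lt(abs(lateral_translation(clean_meshes()$patella_bone, fr)), 0.5)
  expect_equal(sc$truth$tilt, 0)
})

test_that("ground-truth poses are valid rigid transforms", {
  sc <- build_scene(phantom_spec(flexion_angle = 30, patella_tilt_true = 12,
                                 noise_sigma = 0))
  for (tp in list(sc$truth$femur_pose, sc$truth$patella_pose)) {
    expect_lt(max(abs(crossprod(tp$rotation) - diag(3))), 1e-9)
    expect_gt(det(tp$rotation), 0)
  }
})

test_that("a too-small volume raises an explicit sizing error", {
  expect_error(build_scene(phantom_spec(volume_shape = c(30L, 30L, 40L))),
               "too small")
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(phantom_spec(voxel_spacing = 0), "voxel_spacing")
  expect_error(phantom_spec(flexion_angle = 10), "flexion_angle")
  expect_error(phantom_spec(trochlear_depth = -1), "trochlear_depth")
  expect_error(phantom_spec(sulcus_angle_true = 100,
                            lateral_inclination_true = 5),
               "inconsistent")
})

test_that("analytic contact pairs carry closed-form truth", {
  expect_equal(build_analytic_contact_pair(0.5)$truth$expected_contact_area,
               100)
  expect_equal(build_analytic_contact_pair(1.5)$truth$expected_contact_area,
               0)
  ramp <- data.frame(x = c(0, 10), gap = c(0, 2))
  expect_equal(build_analytic_contact_pair(ramp)$truth$expected_contact_area,
               50)
  expect_error(build_analytic_contact_pair(
    data.frame(x = c(0, 10), gap = c(-0.5, 2))), "gap_profile")
  ## slab meshes are watertight with consistent outward orientation
  cp <- build_analytic_contact_pair(0.5)
  expect_true(is_watertight(cp$meshes$patellar))
  expect_true(is_watertight(cp$meshes$femoral))
})

test_that("simulated cohorts reproduce the prescribed moments", {
  mom <- reference_cohort_moments()
  row <- mom[mom$group == "severe" & mom$measure == "tilt" &
               mom$state == "flexion_0", ]
  ## severe group, 5 patients, 200 seeds: the average of the sample means
  ## must sit within 3 SE of the prescribed mean
  pres <- posts <- numeric(200)
  for (s in 1:200) {
    co <- simulate_cohort(row, c(severe = 5), seed = s)
    pres[s] <- mean(co$pre)
    posts[s] <- mean(co$post)
  }
  se_pre <- row$pre_sd / sqrt(5 * 200)
  se_post <- row$post_sd / sqrt(5 * 200)
  expect_lt(abs(mean(pres) - row$pre_mean), 3 * se_pre)
  expect_lt(abs(mean(posts) - row$post_mean), 3 * se_post)
})

test_that("degenerate SDs give identical patients", {
  gp <- data.frame(group = "severe", state = "flexion_0", measure = "tilt",
                   pre_mean = 30, pre_sd = 0, post_mean = 20, post_sd = 0)
  co <- simulate_cohort(gp, c(severe = 4), seed = 1)
  expect_true(all(co$pre == 30))
  expect_true(all(co$post == 20))
})

test_that("paired-difference variance decreases with correlation", {
  gp <- data.frame(group = "g", state = "flexion_0", measure = "tilt",
                   pre_mean = 30, pre_sd = 10, post_mean = 20, post_sd = 8)
  v <- vapply(c(0, 0.9), function(rho) {
    ds <- unlist(lapply(1:50, function(s) {
      co <- simulate_cohort(gp, c(g = 20), pre_post_correlation = rho,
                            seed = s)
      co$post - co$pre
    }))
    stats::var(ds)
  }, numeric(1))
  expect_lt(v[2], v[1])
  ## var(d) = s1^2 + s2^2 - 2 rho s1 s2
  expect_equal(v[1], 164, tolerance = 0.15)
  expect_equal(v[2], 164 - 2 * 0.9 * 80, tolerance = 0.3)
})

test_that("cohort simulation validates its inputs", {
  gp <- data.frame(group = "g", state = "flexion_0", measure = "tilt",
                   pre_mean = 30, pre_sd = 10, post_mean = 20, post_sd = 8)
  expect_error(simulate_cohort(gp, 1), "n_patients")
  expect_error(simulate_cohort(gp, 5, pre_post_correlation = 1), "correlation")
})

test_that("scenes round-trip through NIfTI + JSON sidecars", {
  sc <- build_scene(phantom_spec(volume_shape = c(64L, 64L, 96L),
                                 voxel_spacing = 1.0, seed = 9))
  dir <- tempfile()
  write_scene(sc, dir, "t")
  rt <- read_scene(dir, "t")
  expect_equal(rt$intensity$values, sc$intensity$values, tolerance = 1e-6)
  expect_equal(rt$intensity$spacing, sc$intensity$spacing, tolerance = 1e-6)
  expect_equal(rt$intensity$origin, sc$intensity$origin, tolerance = 1e-4)
  expect_equal(rt$masks$femur_bone$values, sc$masks$femur_bone$values)
  expect_equal(transform_matrix(rt$truth$femur_pose),
               transform_matrix(sc$truth$femur_pose), tolerance = 1e-8)
  expect_equal(rt$truth$tilt, sc$truth$tilt)
})
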