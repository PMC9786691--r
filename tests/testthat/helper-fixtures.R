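## Shared fixtures, built once per test session and cached. All fixtures are
## generated in code; nothing is read from disk.

.pf_test_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.pf_test_cache[[key]]))
    assign(key, fn(), envir = .pf_test_cache)
  .pf_test_cache[[key]]
}

## noiseless default phantom scene and its surfaces
clean_spec <- function(...) {
  phantom_spec(noise_sigma = 0, bias_field_amplitude = 0, ...)
}

clean_scene <- function() cached("clean_scene", function() {
  build_scene(clean_spec())
})

clean_meshes <- function() cached("clean_meshes", function() {
  sc <- clean_scene()
  lapply(sc$masks, extract_surface)
})

clean_frame <- function() cached("clean_frame", function() {
  femoral_frame(clean_meshes()$femur_bone)
})

## small digital sphere mask, centred at the origin
sphere_mask <- function(radius = 10, spacing = 0.5, margin = 5) {
  half <- radius + margin
  n <- 2L * as.integer(round(half / spacing)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  a2 <- outer(ax^2, ax^2, "+")
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- (a2 + ax[k]^2) <= radius^2
  label_mask(arr, spacing, origin = rep(ax[1], 3))
}

## axis-aligned solid box mask
box_mask <- function(size_mm = c(10, 10, 10), spacing = 0.5, margin = 4) {
  dims <- as.integer(ceiling((size_mm + 2 * margin) / spacing)) + 1L
  ax <- lapply(1:3, function(a) spacing * (seq_len(dims[a]) - 1) - margin)
  arr <- array(0, dims)
  inx <- ax[[1]] >= 0 & ax[[1]] <= size_mm[1]
  iny <- ax[[2]] >= 0 & ax[[2]] <= size_mm[2]
  inz <- ax[[3]] >= 0 & ax[[3]] <= size_mm[3]
  arr[inx, iny, inz] <- 1
  label_mask(arr, spacing, origin = c(-margin, -margin, -margin))
}

## coarse low-noise scene pair for quick registration tests
coarse_spec <- function(...) {
  phantom_spec(voxel_spacing = 1.0, volume_shape = c(56L, 58L, 80L),
               noise_sigma = 0, bias_field_amplitude = 0, ...)
}

## brute-force Wilcoxon oracle: full 2^n enumeration by explicit subsets
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

## mild/severe grouping thresholds used in tests (study configuration)
test_severity_thresholds <- function() {
  list(sulcus_angle_max = 145, lateral_inclination_min = 11)
}

dice <- function(a, b) {
  2 * sum(a$values * b$values) / (sum(a$values) + sum(b$values))
}

## proximodistal frame coordinate of every set voxel of a mask
to_frame_z <- function(frame, mask) {
  w <- patellotrack:::voxel_world_coords(mask, which(mask$values != 0))
  (sweep(w, 2, frame$origin) %*% frame$axes)[, 3]
}
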