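# patellotrack

Patellofemoral kinematics and cartilage contact from segmented knee MRI.

In patients with patellar instability and trochlear dysplasia, two numbers
summarise how the patella engages the femoral groove: the **patellar tilt**
(axial-plane angle between the patellar mediolateral axis and the posterior
condylar line, degrees) and the **patellofemoral cartilage contact area**
(CCA, mm² of cartilage whose Euclidean distance to the opposing cartilage is
strictly below 1 mm). Measuring them in situ — across knee flexion angles
(0°/15°/30°), with and without a ~50 N quadriceps load, before and after
MPFL reconstruction — takes a chain of steps between the segmentations and
the clinical numbers. This package implements that chain:

- **Mask conditioning**: inter-slice Gaussian smoothing (σ = 1.25 mm) of
  slice-wise hand-drawn masks; morphology with physical-radius Euclidean
  balls (exact distance transform).
- **Meshing**: watertight marching-tetrahedra isosurfaces of binary masks,
  in world millimetres with outward normals.
- **Two-stage rigid bone registration**: trimmed iterative closest point on
  the bone surfaces, refined by minimising the normalized gradient fields
  (NGF) distance
  `D(T) = Σ_Ω [1 − ((∇F·∇M∘T + ε²)/(|∇F|_ε |∇M∘T|_ε))²]·v`
  inside the bone mask dilated by 3 mm. Transforms map the extended-knee
  base scan into each flexed/loaded state and carry the base cartilage with
  them.
- **Contact**: articular-subsurface selection, exact point-to-triangle
  inter-cartilage distances, CCA below the 1 mm threshold, contact-patch
  topology (components, holes).
- **Anatomy**: a femoral reference frame from the shaft axis and posterior
  condylar line; patellar tilt, medial-lateral translation; trochlear
  morphology (mean osseous sulcus angle, lateral trochlear inclination,
  patellotrochlear index) with configurable mild/severe dysplasia grouping.
- **Statistics**: paired Wilcoxon signed-rank in the SPSS convention (zeros
  dropped, tie-corrected variance, no continuity correction), an exact
  2ⁿ-enumeration method, and per-group pre/post summary tables.
- **A synthetic knee phantom** (`phantom_spec()`/`build_scene()`): a
  parametric distal femur + patella with known rigid poses, tilt, shift,
  trochlear angles, cartilage shells, bias field and noise — plus analytic
  two-slab contact fixtures with closed-form expected areas — so that every
  stage of the chain is validated against ground truth without patient
  data. `simulate_cohort()` draws paired pre/post cohorts from published
  group moments.

## Worked example

```r
library(patellotrack)

## a noiseless phantom knee with 20 deg lateral tilt and 5 mm lateral shift
spec  <- phantom_spec(patella_tilt_true = 20, patella_lateral_shift_true = 5,
                      noise_sigma = 0, bias_field_amplitude = 0)
scene <- build_scene(spec)

femur   <- extract_surface(scene$masks$femur_bone)
patella <- extract_surface(scene$masks$patella_bone)
frame   <- femoral_frame(femur)

patellar_tilt(patella, frame)        # 20.00054  (truth: 20)
lateral_translation(patella, frame)  #  5.038947 (truth: 5)
sulcus_angle(scene, frame)           # 139.9665  (truth: 140)

measure_contact(extract_surface(scene$masks$patellar_cartilage),
                extract_surface(scene$masks$femoral_cartilage))
#> Contact: CCA 193.361 mm^2 below 1 mm on the patellar surface;
#> 3 patch(es), with holes

## register the femur of a flexed, noisy acquisition back to the base scan
flexed <- build_scene(phantom_spec(flexion_angle = 15,
                                   patella_tilt_true = 20,
                                   patella_lateral_shift_true = 5))
tr    <- register_bone(scene, flexed, "femur_bone")
truth <- compose_transforms(flexed$truth$femur_pose,
                            invert_transform(scene$truth$femur_pose))
transform_error(tr, truth, point = c(0, -4.5, 15))
#>    rot_deg   trans_mm
#> 0.21620719 0.05245097

## the SPSS-convention paired Wilcoxon: 5 patients, all improved
wilcoxon_signed_rank(pre = c(34, 41, 29, 38, 30),
                     post = c(33.5, 38, 25, 31, 20))
#> Wilcoxon signed-rank (asymptotic): n = 5, W+ = 0, W- = 15,
#> z = -2.0226, p = 0.04311
```

The maltracking configuration above (high tilt, large lateral shift) breaks
the contact into three small patches; at neutral tilt the phantom shows a
single contiguous, hole-free patch of ~525 mm².

`run_pipeline(run_config(...))` chains phantom generation, registration,
cartilage transfer, contact/tilt/translation measurement, morphology and
the paired summary tables for a whole simulated cohort, writes CSV results
with a provenance log, and is bit-reproducible for a fixed config and seed.
A thin CLI (`inst/scripts/patellotrack simulate|run|stats`) wraps the same
functions. See the vignette
(`vignettes/patellofemoral-measurement.Rmd`) for the models, conventions
and numerical choices.

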