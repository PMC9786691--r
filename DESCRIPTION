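Package: patellotrack
Title: Patellofemoral Kinematics and Cartilage Contact from Segmented Knee MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measurement chain for in-situ patellofemoral imaging studies:
    conditioning of bone and cartilage segmentation masks, isosurface meshing,
    two-stage rigid bone registration (trimmed iterative closest point followed
    by masked normalized-gradient-fields refinement), cartilage transfer
    between acquisition states, cartilage contact area under a millimetre
    distance threshold, patellar tilt and medial-lateral translation in a
    femoral reference frame, trochlear morphology indices with mild/severe
    dysplasia grouping, and paired Wilcoxon signed-rank summaries. A
    parametric synthetic knee phantom with known rigid poses, tilt, shift and
    analytic contact areas allows every stage to be validated without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
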