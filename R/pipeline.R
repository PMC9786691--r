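#' Pipeline run configuration
#'
#' Bundles every knob of the measurement chain with the defaults used
#' throughout: contact threshold 1 mm, NGF mask dilation 3 mm, inter-slice
#' smoothing sigma 1.25 mm, base state = extended unloaded knee. The
#' configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param cohort list of patients as produced by [make_cohort_config()].
#' @param states subset of [acquisition_states()] to acquire.
#' @param base_state state registered against (the segmented base image).
#' @param voxel_spacing,volume_shape phantom grid geometry.
#' @param cartilage_thickness,noise_sigma,bias_field_amplitude phantom
#'   imaging parameters.
#' @param cca_threshold_mm contact threshold (mm).
#' @param dilation_mm NGF mask dilation around the bone (mm).
#' @param smooth_sigma_mm inter-slice mask smoothing sigma (mm).
#' @param smooth_masks apply inter-slice smoothing to base masks before
#'   meshing (emulates hand-drawn segmentation conditioning).
#' @param registration `"icp_ngf"` (full two-stage chain) or `"icp"`
#'   (coarse alignment only, for quick runs).
#' @param ngf,icp parameter lists forwarded to [ngf_params()] and
#'   [icp_align()].
#' @param severity_thresholds optional list for [severity_group()].
#' @param seed master seed; every scene derives its own stream from it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return List of class `pf_run_config`.
#' @export
run_config <- function(cohort,
                       states = acquisition_states(),
                       base_state = "flexion_0",
                       voxel_spacing = 0.5,
                       volume_shape = c(112L, 112L, 160L),
                       cartilage_thickness = 3.0,
                       noise_sigma = 5.5,
                       bias_field_amplitude = 0.05,
                       cca_threshold_mm = 1.0,
                       dilation_mm = 3.0,
                       smooth_sigma_mm = 1.25,
                       smooth_masks = TRUE,
                       registration = c("icp_ngf", "icp"),
                       ngf = list(),
                       icp = list(),
                       severity_thresholds = NULL,
                       seed = 1L,
                       out_dir = NULL) {
  registration <- match.arg(registration)
  stopifnot(base_state %in% states)
  bad <- setdiff(states, acquisition_states())
  if (length(bad) > 0) stop("unknown states: ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, states = states, base_state = base_state,
                 voxel_spacing = voxel_spacing,
                 volume_shape = as.integer(volume_shape),
                 cartilage_thickness = cartilage_thickness,
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 cca_threshold_mm = cca_threshold_mm,
                 dilation_mm = dilation_mm,
                 smooth_sigma_mm = smooth_sigma_mm,
                 smooth_masks = smooth_masks,
                 registration = registration,
                 ngf = ngf, icp = icp,
                 severity_thresholds = severity_thresholds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pf_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname run_config
#' @param config a `pf_run_config` (for writing).
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Simulated patient cohort configuration
#'
#' Draws per-patient phantom parameters for a paired pre/post MPFL-graft
#' cohort: trochlear geometry per dysplasia group (mild: 5 mm groove,
#' sulcus 142 deg, inclination 20 deg; severe: 2.5 mm groove, sulcus
#' 152 deg, inclination 14 deg) and per-session patellar tilt drawn from
#' the reference cohort moments (surgery reduces tilt), with a lateral
#' shift that shrinks post-operatively.
#'
#' @param n_mild,n_severe patients per group.
#' @param pre_post_correlation correlation of the paired tilt draws.
#' @param seed RNG seed.
#' @return List of patient configurations for [run_config()].
#' @export
make_cohort_config <- function(n_mild = 1L, n_severe = 1L,
                               pre_post_correlation = 0.8, seed = 1L) {
  mom <- reference_cohort_moments()
  geo <- list(mild = list(trochlear_depth = 5.0, sulcus_angle_true = 142,
                          lateral_inclination_true = 20),
              severe = list(trochlear_depth = 2.5, sulcus_angle_true = 152,
                            lateral_inclination_true = 14))
  rho <- pre_post_correlation
  with_local_seed(seed, {
    out <- list()
    for (g in c("mild", "severe")) {
      ng <- if (g == "mild") n_mild else n_severe
      if (ng == 0) next
      m <- mom[mom$group == g & mom$measure == "tilt" &
                 mom$state == "flexion_0", ]
      for (i in seq_len(ng)) {
        z1 <- stats::rnorm(1)
        z2 <- stats::rnorm(1)
        tilt_pre <- m$pre_mean + m$pre_sd * z1
        tilt_post <- m$post_mean +
          m$post_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
        clamp <- function(x) max(-10, min(40, x))
        out[[length(out) + 1]] <- c(
          list(id = sprintf("%s_%02d", g, i), group = g,
               sessions = list(
                 pre = list(tilt = clamp(tilt_pre),
                            shift = 4 + stats::rnorm(1, 0, 0.5)),
                 post = list(tilt = clamp(tilt_post),
                             shift = 1 + stats::rnorm(1, 0, 0.5)))),
          geo[[g]])
      }
    }
    out
  })
}

state_params <- function(state) {
  flex <- as.numeric(sub("flexion_(\\d+).*", "\\1", state))
  loaded <- grepl("load50N", state)
  list(flexion = flex,
       load_state = if (loaded) "loaded_50N" else "unloaded")
}

scene_for <- function(config, patient, session, state, pidx, sesidx) {
  sp <- state_params(state)
  seed <- (config$seed + 1000L * pidx + 100L * sesidx) %% .Machine$integer.max
  spec <- phantom_spec(
    voxel_spacing = config$voxel_spacing,
    volume_shape = config$volume_shape,
    cartilage_thickness = config$cartilage_thickness,
    trochlear_depth = patient$trochlear_depth,
    sulcus_angle_true = patient$sulcus_angle_true,
    lateral_inclination_true = patient$lateral_inclination_true,
    patella_tilt_true = patient$sessions[[session]]$tilt,
    patella_lateral_shift_true = patient$sessions[[session]]$shift,
    flexion_angle = sp$flexion,
    load_state = sp$load_state,
    noise_sigma = config$noise_sigma,
    bias_field_amplitude = config$bias_field_amplitude,
    seed = seed)
  build_scene(spec)
}

#' Run the full measurement pipeline on a simulated cohort
#'
#' For every patient, session (pre/post surgery) and acquisition state:
#' builds the phantom scene, registers femur and patella from the session's
#' base scene (extended unloaded knee) into the state with trimmed ICP and
#' optional NGF refinement, transfers the base cartilage and bone surfaces
#' through the recovered transforms, and measures cartilage contact area
#' (both patellar- and femoral-side), patellar tilt and medial-lateral
#' translation in the femoral frame. Trochlear morphology is measured once
#' per session on the base scene. Scene-level failures are recorded and the
#' pipeline continues. Identical configuration and seed reproduce the
#' results bit-exactly.
#'
#' @param config a [run_config()].
#' @return List of class `pf_run` with `results` (one row per
#'   patient/session/state), `morphology`, `cohort` (paired long format),
#'   `summary` (per-group tables), `failures`, `provenance`. When
#'   `config$out_dir` is set, `results.csv`, `morphology.csv`,
#'   `cohort.csv`, `summary.txt` and `provenance.json` are written there.
#' @export
run_pipeline <- function(config) {
  results <- list()
  morph_rows <- list()
  failures <- list()
  prov_scenes <- list()
  ngf <- do.call(ngf_params, config$ngf)

  for (pidx in seq_along(config$cohort)) {
    patient <- config$cohort[[pidx]]
    for (sesidx in seq_along(patient$sessions)) {
      session <- names(patient$sessions)[sesidx]
      base <- tryCatch(
        scene_for(config, patient, session, config$base_state,
                  pidx, sesidx),
        error = function(e) {
          failures[[length(failures) + 1]] <<- list(
            patient = patient$id, session = session, stage = "base_scene",
            message = conditionMessage(e))
          NULL
        })
      if (is.null(base)) next
      prep_mask <- function(mask) {
        if (config$smooth_masks)
          smooth_interslice(mask, config$smooth_sigma_mm) else mask
      }
      base_meshes <- lapply(base$masks, function(m)
        extract_surface(prep_mask(m)))
      frame_base <- femoral_frame(base_meshes$femur_bone)
      morph <- tryCatch({
        mo <- trochlear_morphology(base, frame_base)
        sev <- if (!is.null(config$severity_thresholds))
          severity_group(mo, config$severity_thresholds) else NA_character_
        data.frame(patient = patient$id, session = session,
                   sulcus_angle = mo$sulcus_angle,
                   lateral_trochlear_inclination =
                     mo$lateral_trochlear_inclination,
                   patellotrochlear_index = mo$patellotrochlear_index,
                   severity = sev, stringsAsFactors = FALSE)
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- list(
          patient = patient$id, session = session, stage = "morphology",
          message = conditionMessage(e))
        NULL
      })
      if (!is.null(morph)) morph_rows[[length(morph_rows) + 1]] <- morph

      for (state in config$states) {
        res <- tryCatch({
          if (state == config$base_state) {
            target <- base
            t_fem <- rigid_transform()
            t_pat <- rigid_transform()
            prov <- list(identity = TRUE)
          } else {
            target <- scene_for(config, patient, session, state,
                                pidx, sesidx)
            reg1 <- function(bone) {
              if (config$registration == "icp_ngf") {
                do.call(register_bone,
                        c(list(base, target, bone, ngf = ngf,
                               dilate_mm = config$dilation_mm),
                          config$icp))
              } else {
                src <- extract_surface(base$masks[[bone]])
                tgt <- extract_surface(target$masks[[bone]])
                do.call(icp_align, c(list(src, tgt), config$icp))
              }
            }
            t_fem <- reg1("femur_bone")
            t_pat <- reg1("patella_bone")
            prov <- list(femur = attr(t_fem, "provenance"),
                         patella = attr(t_pat, "provenance"))
          }
          femur_t <- apply_transform(base_meshes$femur_bone, t_fem)
          patella_t <- apply_transform(base_meshes$patella_bone, t_pat)
          fcart_t <- apply_transform(base_meshes$femoral_cartilage, t_fem)
          pcart_t <- apply_transform(base_meshes$patellar_cartilage, t_pat)
          frame <- femoral_frame(femur_t)
          tilt <- patellar_tilt(patella_t, frame)
          lat <- lateral_translation(patella_t, frame)
          con_p <- measure_contact(pcart_t, fcart_t,
                                   config$cca_threshold_mm, "patellar")
          con_f <- measure_contact(pcart_t, fcart_t,
                                   config$cca_threshold_mm, "femoral")
          prov_scenes[[length(prov_scenes) + 1]] <- c(
            list(patient = patient$id, session = session, state = state),
            prov)
          sp <- state_params(state)
          data.frame(
            patient = patient$id, group = patient$group, session = session,
            state = state, flexion = sp$flexion,
            load = sp$load_state,
            tilt_deg = tilt, lateral_translation_mm = lat,
            cca_mm2 = con_p$cca, cca_femoral_mm2 = con_f$cca,
            contact_components = con_p$n_components,
            contact_has_holes = con_p$has_holes,
            truth_tilt_deg = target$truth$tilt,
            truth_shift_mm = target$truth$lateral_shift,
            stringsAsFactors = FALSE)
        }, error = function(e) {
          failures[[length(failures) + 1]] <<- list(
            patient = patient$id, session = session, stage = state,
            message = conditionMessage(e))
          NULL
        })
        if (!is.null(res)) results[[length(results) + 1]] <- res
      }
    }
  }

  results <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(results)) rownames(results) <- NULL
  morphology <- if (length(morph_rows)) do.call(rbind, morph_rows) else NULL
  cohort <- pipeline_cohort(results)
  summary <- if (!is.null(cohort) && nrow(cohort) > 0)
    cohort_summary(cohort) else NULL
  prov <- list(package = "patellotrack",
               version = as.character(utils::packageVersion("patellotrack")),
               seed = config$seed,
               registration = config$registration,
               n_failures = length(failures),
               scenes = prov_scenes)
  out <- structure(list(results = results, morphology = morphology,
                        cohort = cohort, summary = summary,
                        failures = failures, provenance = prov,
                        config = config),
                   class = "pf_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(results))
      utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                       row.names = FALSE)
    if (!is.null(morphology))
      utils::write.csv(morphology,
                       file.path(config$out_dir, "morphology.csv"),
                       row.names = FALSE)
    if (!is.null(cohort))
      write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    if (!is.null(summary))
      writeLines(format_summary_table(summary),
                 file.path(config$out_dir, "summary.txt"))
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  out
}

#' @export
print.pf_run <- function(x, ...) {
  cat("Pipeline run:", if (is.null(x$results)) 0 else nrow(x$results),
      "scene measurements,", length(x$failures), "failures\n")
  invisible(x)
}

## reshape per-scene results into the paired pre/post cohort format
pipeline_cohort <- function(results) {
  if (is.null(results)) return(NULL)
  rows <- list()
  for (meas in c("tilt", "cca")) {
    col <- if (meas == "tilt") "tilt_deg" else "cca_mm2"
    pre <- results[results$session == "pre", ]
    post <- results[results$session == "post", ]
    key <- function(d) paste(d$patient, d$state)
    m <- match(key(pre), key(post))
    ok <- !is.na(m)
    if (!any(ok)) next
    rows[[length(rows) + 1]] <- data.frame(
      patient = pre$patient[ok], group = pre$group[ok],
      state = pre$state[ok], measure = meas,
      pre = pre[[col]][ok], post = post[[col]][m[ok]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pf_cohort", "data.frame")
  out
}
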