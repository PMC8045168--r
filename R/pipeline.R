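#' Planning configuration
#'
#' All geometric tolerances of the pipeline in one place.
#'
#' @param spacing pixel size of the final safe map (mm).
#' @param opt_spacing pixel size used during direction search (mm).
#' @param min_chord minimum in-bone chord for a safe pixel (mm).
#' @param cone_half_angle,coarse_step,refine_tol direction-search cone and
#'   grid (degrees), see [optimize_direction()].
#' @param align_frac chord fraction of the alignment objective.
#' @param clearance required gap between the two screws (mm).
#' @param min_diameter smallest acceptable screw diameter (mm).
#' @param optimize logical; `FALSE` keeps the landmark-derived direction
#'   (fast screening mode).
#' @param t_method `"pooled"` or `"welch"`.
#' @return list of class `plan_config`.
#' @export
plan_config <- function(spacing = 0.25, opt_spacing = 0.5, min_chord = 10,
                        cone_half_angle = 30, coarse_step = 3,
                        refine_tol = 0.5, align_frac = 0.75, clearance = 0,
                        min_diameter = 2, optimize = TRUE,
                        t_method = "pooled") {
  cfg <- as.list(environment())
  stopifnot(spacing > 0, spacing <= 1, opt_spacing > 0, opt_spacing <= 1,
            min_chord >= 0, cone_half_angle > 0, coarse_step > 0,
            refine_tol > 0, align_frac > 0.5, align_frac <= 1,
            clearance >= 0, min_diameter > 0)
  structure(cfg, class = "plan_config")
}

# Landmark-derived anatomical long-axis initialization: the first
# principal direction of the superior patch (the flat strip runs along the
# distal acromion), oriented from the anterior edge posteriorly.
landmark_axis <- function(mesh, landmarks) {
  P <- mesh$vertices[landmarks$superior_patch, , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  ref <- unit3(ctr - landmarks$anterior_edge)
  # among the two in-plane principal directions, take the one running
  # anterior-posteriorly (the strip can be wider than it is long)
  cand <- sv$v[, 1:2]
  dots <- abs(drop(ref %*% cand))
  ax <- cand[, which.max(dots)]
  if (sum(ax * ref) < 0) ax <- -ax
  unit3(ax)
}

stage_call <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] stage %s: %s", id, stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Plan both screws for one subject
#'
#' End-to-end pipeline: superior reference plane from the landmark patch,
#' landmark-derived axis initialization, corridor direction optimization,
#' safe-zone extraction, even split, maximal screw fitting, and the
#' measurement row (lengths, diameters, L1-L4, alpha, beta).
#'
#' @param mesh watertight [triangle_mesh()] (or pass `subject`).
#' @param landmarks a [landmark_set()].
#' @param config a [plan_config()].
#' @param subject alternatively, a generated subject from
#'   [generate_acromion()] / [sample_cohort()] (supplies mesh, landmarks,
#'   id and sex).
#' @param subject_id,sex row annotations when passing mesh + landmarks.
#' @return list with `measurement` (one-row tibble), `screws`, `zone`,
#'   `map`, `direction`, `planeA`, `planeB`, `init`.
#' @export
run_subject <- function(mesh = NULL, landmarks = NULL,
                        config = plan_config(), subject = NULL,
                        subject_id = "subject", sex = NA_character_) {
  if (!is.null(subject)) {
    mesh <- subject$mesh; landmarks <- subject$landmarks
    if (!is.null(subject$id)) subject_id <- subject$id
    if (!is.null(subject$sex)) sex <- subject$sex
  }
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(landmarks,
                                                      "landmark_set"))
  val <- validate_mesh(mesh)
  if (!val$watertight)
    stop(sprintf("[%s] stage validate: mesh is not watertight", subject_id))
  mesh$provenance$validation <- val

  planeA <- stage_call("plane_A", subject_id, fit_plane_A(mesh, landmarks))
  init <- stage_call("init_axis", subject_id, landmark_axis(mesh, landmarks))
  if (config$optimize) {
    opt <- stage_call("optimize_direction", subject_id,
      optimize_direction(mesh, init, up_hint = planeA$normal,
                         cone_half_angle = config$cone_half_angle,
                         coarse_step = config$coarse_step,
                         refine_tol = config$refine_tol,
                         spacing = config$opt_spacing,
                         final_spacing = config$spacing,
                         min_chord = config$min_chord,
                         align_frac = config$align_frac))
    dir <- opt$direction; map <- opt$map
    thr <- opt$chord_threshold
  } else {
    dir <- init
    map <- stage_call("safe_map", subject_id,
      safe_map(mesh, dir, spacing = config$spacing,
               min_chord = config$min_chord, up_hint = planeA$normal,
               .validated = TRUE))
    ok <- map$count == 1L & !is.na(map$chord)
    thr <- if (any(ok))
      max(config$min_chord, config$align_frac * max(map$chord[ok]))
      else config$min_chord
  }
  # the screws live in the long-chord oval, not merely where any >=
  # min_chord purchase exists
  zone_map <- map_with_min_chord(map, thr)
  zone <- stage_call("safe_zone", subject_id, extract_safe_zone(zone_map))
  screws <- stage_call("screw_fit", subject_id,
    plan_two_screws(mesh, zone_map, zone, landmarks = landmarks,
                    clearance = config$clearance,
                    min_diameter = config$min_diameter))
  planeB <- stage_call("plane_B", subject_id,
    define_plane_B(planeA, zone, map$frame, axis_ref = init))
  row <- stage_call("measure", subject_id,
    measure_subject(screws, landmarks, planeA, planeB,
                    subject_id = subject_id, sex = sex))
  list(measurement = row, screws = screws, zone = zone, map = map,
       direction = dir, planeA = planeA, planeB = planeB, init = init)
}

#' Run the pipeline over a synthetic cohort
#'
#' Generates (or accepts) a cohort, plans every subject, and assembles the
#' measurement table and the three sex-comparison tables. Failed subjects
#' are logged and excluded; more than 20% failures aborts.
#'
#' @param spec a [cohort_spec()], or a pre-generated list of subjects.
#' @param config a [plan_config()].
#' @param out_dir optional directory for CSV outputs (measurements, the
#'   three tables, and a JSON manifest).
#' @param quiet suppress per-subject progress.
#' @return list with `measurements` (tibble), `tables`
#'   ([build_tables()] output), `failures` (named character vector of
#'   error messages).
#' @export
run_cohort <- function(spec = cohort_spec(), config = plan_config(),
                       out_dir = NULL, quiet = TRUE) {
  subjects <- if (inherits(spec, "cohort_spec")) sample_cohort(spec) else spec
  rows <- list(); failures <- character()
  for (s in subjects) {
    res <- tryCatch(run_subject(subject = s, config = config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[s$id] <- conditionMessage(res)
      if (!quiet) message("FAIL ", s$id, ": ", conditionMessage(res))
    } else {
      rows[[s$id]] <- res$measurement
      if (!quiet) message("ok   ", s$id)
    }
  }
  if (length(failures) > 0.2 * length(subjects))
    stop(sprintf("cohort aborted: %d of %d subjects failed (first: %s)",
                 length(failures), length(subjects), failures[1]))
  measurements <- do.call(rbind, rows)
  tables <- stage_call("statistics", "cohort",
                       build_tables(measurements, method = config$t_method))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    for (tb in c("medial", "lateral", "angles"))
      utils::write.csv(tables[[tb]],
                       file.path(out_dir, paste0("table_", tb, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(n_subjects = length(subjects), n_failed = length(failures),
           failures = as.list(failures), config = unclass(config)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(measurements = measurements, tables = tables, failures = failures)
}
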