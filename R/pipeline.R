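# Umbrella pipeline: stimuli -> rendering -> rarity -> model scores ->
# synthetic judgments -> statistical report, reproducible from one global
# seed, with a manifest hashing every file written.

#' Pipeline configuration
#'
#' Every random stage derives its own seed deterministically from the global
#' seed plus a stage tag, so one integer reproduces the full run.
#'
#' @param seed Global integer seed (default 1).
#' @param output_dir Directory for stage outputs (default a tempdir).
#' @param model An [model_config()].
#' @param linking An [linking_params()]; its seed field is overridden by the
#'   derived stage seed.
#' @param n_boot,n_perm Resampling sizes for the analysis stage.
#' @param exclude_classes Movement classes whose paths are excluded in the
#'   correlation-increase permutation test (default `c("B", "D")`, the
#'   repetitive and single-quadrant classes where model and raters are
#'   expected to disagree most).
#' @param quiet Suppress stage progress messages.
#' @return A list of class `effcomm_run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("effcomm-run-"),
                       model = model_config(), linking = linking_params(),
                       n_boot = 2000L, n_perm = 2000L,
                       exclude_classes = c("B", "D"), quiet = FALSE) {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 model = model, linking = linking,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 exclude_classes = exclude_classes, quiet = isTRUE(quiet)),
            class = "effcomm_run_config")
}

#' Derive a stage seed from a global seed and a stage tag
#'
#' Deterministic, stays within the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param tag Character stage tag.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, tag) {
  hash <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + hash) %% 2147483647L)
}

.pipe_msg <- function(config, ...) {
  if (!config$quiet) message("[effcomm] ", ...)
}

#' Run the full pipeline
#'
#' Builds the 23-path stimulus set, renders trajectories, computes rarity and
#' inverse-planner communicativeness scores, simulates Likert judgments from
#' rarity, and runs the analysis stage: the rarity-judgment correlation with
#' a bootstrap CI, linear calibration of model scores to mean ratings, the
#' model-judgment correlation, per-class discrepancies, and the permutation
#' test for the correlation increase after excluding the configured classes.
#' Writes the stimulus set, trajectories, judgments and report under
#' `config$output_dir` together with a manifest of seeds, parameters and
#' file hashes.
#'
#' @param config An [run_config()].
#' @return The report, invisibly also written to `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "effcomm_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  .pipe_msg(config, "stage stimuli: building 23-path set")
  set <- build_study1_set(stage_seed(config$seed, "stimuli"))
  ids <- set$items$path_id

  .pipe_msg(config, "stage render: composing trajectories")
  trajs <- lapply(set$paths, compose_path,
                  frames_per_primitive = config$model$frames_per_primitive)
  traj_df <- do.call(rbind, lapply(ids, function(pid) {
    cbind(path_id = pid, trajs[[pid]]$frames)
  }))
  utils::write.csv(traj_df, out("trajectories.csv"), row.names = FALSE,
                   quote = FALSE)

  .pipe_msg(config, "stage model: scoring ", length(ids), " trajectories")
  curves <- lapply(trajs, function(tr) {
    world <- world_for(tr, goal_spacing = config$model$goal_spacing,
                       grid_resolution = config$model$grid_resolution)
    world_directedness_curve(world, tr, config$model)
  })
  scores <- vapply(curves, function(cv) cv$score, numeric(1))

  .pipe_msg(config, "stage judgments: simulating ratings")
  linking <- config$linking
  linking$seed <- stage_seed(config$seed, "judgments")
  judgments <- simulate_judgments(ids, set$items$rarity, linking)
  write_judgments_csv(judgments, out("judgments.csv"))
  means <- path_means(judgments)
  mean_rating <- means$mean_rating[match(ids, means$path_id)]

  .pipe_msg(config, "stage analysis")
  cor_rarity <- pearson_bootstrap(set$items$rarity, mean_rating,
                                  n_boot = config$n_boot,
                                  seed = stage_seed(config$seed, "boot-rarity"))
  cor_model <- pearson_bootstrap(scores, mean_rating,
                                 n_boot = config$n_boot,
                                 seed = stage_seed(config$seed, "boot-model"))
  calib <- calibrate_linear(scores, mean_rating)
  disc <- class_discrepancy(calib, set$items$class)
  excl <- ids[set$items$class %in% config$exclude_classes]
  perm <- correlation_increase_permutation(
    scores, mean_rating, ids, excl, n_perm = config$n_perm,
    seed = stage_seed(config$seed, "perm"))

  report <- list(
    seed = config$seed,
    parameters = list(model = unclass(config$model),
                      linking = unclass(linking),
                      n_boot = config$n_boot, n_perm = config$n_perm,
                      exclude_classes = config$exclude_classes),
    stimuli = list(study = set$study, seed = set$seed,
                   n_items = nrow(set$items)),
    paths = data.frame(path_id = ids, class = set$items$class,
                       rarity = set$items$rarity, score = unname(scores),
                       mean_rating = mean_rating,
                       calibrated = calib$fitted),
    correlation_rarity = unclass(cor_rarity),
    correlation_model = unclass(cor_model),
    calibration = list(slope = calib$slope, intercept = calib$intercept),
    class_discrepancy = disc,
    permutation = unclass(perm)
  )
  write_report(report, out("report.json"))

  files <- c("trajectories.csv", "judgments.csv", "report.json")
  manifest <- list(seed = config$seed,
                   stage_seeds = list(
                     stimuli = stage_seed(config$seed, "stimuli"),
                     judgments = stage_seed(config$seed, "judgments"),
                     boot_rarity = stage_seed(config$seed, "boot-rarity"),
                     boot_model = stage_seed(config$seed, "boot-model"),
                     perm = stage_seed(config$seed, "perm")),
                   files = as.list(tools::md5sum(vapply(files, out,
                                                        character(1)))))
  names(manifest$files) <- files
  write_report(manifest, out("manifest.json"))
  invisible(report)
}

#' Write a small end-to-end fixture bundle
#'
#' Generates, under `outdir`: the 23-path stimulus set (JSON), its rendered
#' trajectories (CSV), a synthetic judgment table (30 participants x 23
#' paths), one bordered world (JSON), and a manifest recording every seed,
#' parameter and file hash. Deterministic given `seed`.
#'
#' @param outdir Writable directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  set <- build_study1_set(stage_seed(seed, "stimuli"))
  ids <- set$items$path_id
  jsonlite::write_json(
    list(study = set$study, seed = set$seed,
         items = cbind(set$items,
                       segments = I(lapply(set$paths, function(p) p$segments)))),
    out("study1_set.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  trajs <- lapply(set$paths, compose_path)
  traj_df <- do.call(rbind, lapply(ids, function(pid) {
    cbind(path_id = pid, trajs[[pid]]$frames)
  }))
  utils::write.csv(traj_df, out("trajectories.csv"), row.names = FALSE,
                   quote = FALSE)
  linking <- linking_params(seed = stage_seed(seed, "judgments"))
  judgments <- simulate_judgments(ids, set$items$rarity, linking)
  write_judgments_csv(judgments, out("judgments.csv"))
  write_world(make_bordered_world(trajs[[ids[3]]]), out("bordered_world.json"))
  files <- c("study1_set.json", "trajectories.csv", "judgments.csv",
             "bordered_world.json")
  manifest <- list(seed = as.integer(seed),
                   stage_seeds = list(stimuli = stage_seed(seed, "stimuli"),
                                      judgments = stage_seed(seed, "judgments")),
                   linking = unclass(linking),
                   files = as.list(tools::md5sum(vapply(files, out,
                                                        character(1)))))
  names(manifest$files) <- files
  write_report(manifest, out("manifest.json"))
  invisible(manifest)
}
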