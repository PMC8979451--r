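TRIAL_COLUMNS <- c("participant_id", "trial_index", "block_index",
                   "clamp_deg", "jump_deg", "jump_event", "feedback_type",
                   "hand_angle_deg")
ANGLE_COLUMNS <- c("clamp_deg", "jump_deg", "hand_angle_deg")

#' Derive a component seed from a master seed
#'
#' Deterministic stream splitting: the master seed and a stage label are
#' combined with a polynomial string hash modulo 2^31 - 1, so every stage of
#' a pipeline can be re-run in isolation with a reproducible seed.
#'
#' @param master Integer master seed.
#' @param label Character stage label (e.g. `"schedule"`,
#'   `"participant_7"`).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, label) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h + 1)
}

#' Read a trial-record table
#'
#' Reads the comma-separated interchange format (header mandatory). Angle
#' columns are parsed as degrees; unknown columns are preserved.
#'
#' @param path File path.
#' @return `data.frame` of trial records (with an `excluded` column,
#'   initialized `FALSE` if absent).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in ANGLE_COLUMNS) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1L], " of ", path, call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df$jump_event <- as.logical(df$jump_event)
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  df
}

#' Write a trial-record table
#' @param trials Trial-record `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write / read group condition means
#'
#' Tabular text with columns `clamp_mag`, `jump_rel`, `jump_event`,
#' `feedback`, `mean`, `sd`, `sem`, `n`.
#'
#' @param means Group condition-mean `data.frame`.
#' @param path File path.
#' @return `path` (write) or the `data.frame` (read).
#' @export
write_condition_means <- function(means, path) {
  utils::write.csv(means, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_means
#' @export
read_condition_means <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$jump_event <- as.logical(df$jump_event)
  df$feedback <- as.logical(df$feedback)
  df
}

#' Export a schedule as tabular text
#' @param schedule A `de_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule$trials, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. All stochastic components
#' derive their seeds from `seed` via [derive_seed()]. The configuration
#' round-trips through YAML unchanged ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param experiments Experiment ids to simulate (one cohort each).
#' @param n_per_experiment Participants per experiment (recycled).
#' @param model Generative model id.
#' @param params Named list of generative parameter values; must include
#'   `u0` as a named vector/list keyed by clamp magnitude.
#' @param u0_composition `"literal"` or `"constrained"`.
#' @param noise_sd,retention,between_subject_sd Simulation settings; see
#'   [sim_config()].
#' @param fit_models Model ids to fit (default all six).
#' @param n_starts Optimizer starts per fit.
#' @param weighting `"none"` or `"inverse_sem"`.
#' @param B Bootstrap resamples for the winning model (0 = skip bootstrap).
#' @param seed Master seed.
#' @param out_dir Optional artifact directory (created if needed).
#' @return List of class `de_run_config`.
#' @export
run_config <- function(experiments = c("exp4a", "exp4b", "exp4c", "exp4d"),
                       n_per_experiment = c(53L, 53L, 52L, 52L),
                       model = "distracted_spe_te",
                       params = list(u0 = c("3" = 0.5, "7" = 0.9),
                                     c_j = 0.84, sigma_d = 11.8,
                                     beta_te = 0.02),
                       u0_composition = "constrained",
                       noise_sd = 0.15, retention = 1,
                       between_subject_sd = 0.2,
                       fit_models = model_ids(), n_starts = 10L,
                       weighting = "none", B = 0L, seed = 1L,
                       out_dir = NULL) {
  cfg <- list(experiments = experiments,
              n_per_experiment = rep_len(as.integer(n_per_experiment),
                                         length(experiments)),
              model = model, params = params,
              u0_composition = u0_composition, noise_sd = noise_sd,
              retention = retention, between_subject_sd = between_subject_sd,
              fit_models = fit_models, n_starts = as.integer(n_starts),
              weighting = weighting, B = as.integer(B),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "de_run_config"
  cfg
}

#' @rdname run_config
#' @param config A `de_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$params$u0 <- as.list(cfg$params$u0)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$params$u0 <- unlist(cfg$params$u0)
  do.call(run_config, cfg[setdiff(names(cfg), character(0))])
}

config_params <- function(config) {
  args <- config$params
  args$u0 <- stats::setNames(as.numeric(args$u0), names(args$u0))
  args$u0_composition <- config$u0_composition
  do.call(model_params, args)
}

stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes schedule generation, cohort simulation, the model-free analysis
#' chain, fitting of the requested models to the pooled group condition
#' means, model comparison, derived quantities for the winning model (or the
#' Distracted SPE+TE fit when present), and an optional participant-level
#' bootstrap. Artifacts are written to `config$out_dir` when set, together
#' with a manifest of seeds and settings; on failure a `MANIFEST.partial`
#' marker is left in the output directory.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return List with `config`, `schedules`, `trials`, `deltas`, `medians`
#'   (per-participant + group condition means), `u0`, `fits`, `comparison`,
#'   `best_fit`, `derived`, `bootstrap` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "de_run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  mark_partial <- function() {
    if (!is.null(out_dir)) file.create(file.path(out_dir, "MANIFEST.partial"))
  }
  on.exit(mark_partial())
  spec <- model_spec(config$model)
  gen_params <- config_params(config)

  schedules <- stage("schedule", quiet, {
    lapply(config$experiments, function(e) {
      generate_schedule(e, seed = derive_seed(config$seed,
                                              paste0("schedule_", e)))
    })
  })
  names(schedules) <- config$experiments

  trials <- stage("simulate", quiet, {
    cohorts <- lapply(seq_along(schedules), function(i) {
      cfg_i <- sim_config(spec, gen_params, noise_sd = config$noise_sd,
                          retention = config$retention,
                          n_participants = config$n_per_experiment[i],
                          between_subject_sd = config$between_subject_sd,
                          seed = derive_seed(config$seed,
                                             paste0("cohort_",
                                                    config$experiments[i])))
      co <- simulate_cohort(schedules[[i]], cfg_i,
                            id_prefix = paste0(config$experiments[i], "_p"))
      co$experiment_id <- config$experiments[i]
      co
    })
    do.call(rbind, cohorts)
  })

  analysis <- stage("analyze", quiet, {
    flagged <- flag_outliers(trials)
    deltas <- normalize_signs(compute_deltas(flagged))
    med <- condition_medians(deltas)
    list(flagged = flagged, deltas = deltas, medians = med)
  })

  u0 <- stage("u0", quiet, u0_from_means(analysis$medians$group))

  fits <- stage("fit", quiet, {
    out <- lapply(config$fit_models, function(m) {
      fit_model(model_spec(m), analysis$medians$group, u0_fixed = u0,
                n_starts = config$n_starts,
                seed = derive_seed(config$seed, paste0("fit_", m)),
                weighting = config$weighting,
                u0_composition = config$u0_composition)
    })
    names(out) <- config$fit_models
    out
  })

  comparison <- stage("compare", quiet, compare_models(fits))
  best_id <- if ("distracted_spe_te" %in% names(fits)) "distracted_spe_te"
             else comparison$model_id[1L]
  best_fit <- fits[[best_id]]
  derived <- stage("derived", quiet, derived_quantities(best_fit, u0))

  boot <- NULL
  if (config$B > 0L) {
    boot <- stage("bootstrap", quiet, {
      grp <- stats::setNames(trials$experiment_id, trials$participant_id)
      grp <- grp[!duplicated(names(grp))]
      bootstrap_ci(trials, best_fit$spec, B = config$B,
                   seed = derive_seed(config$seed, "bootstrap"),
                   groups = grp, n_starts = config$n_starts,
                   u0_composition = config$u0_composition,
                   weighting = config$weighting)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dualerror")),
    seed = config$seed,
    stage_seeds = list(
      schedules = vapply(config$experiments, function(e)
        derive_seed(config$seed, paste0("schedule_", e)), integer(1)),
      cohorts = vapply(config$experiments, function(e)
        derive_seed(config$seed, paste0("cohort_", e)), integer(1)),
      bootstrap = derive_seed(config$seed, "bootstrap")),
    n_trials = nrow(trials),
    n_excluded = sum(analysis$flagged$excluded),
    n_delta_pairs = nrow(analysis$deltas),
    n_bootstrap_dropped = if (is.null(boot)) 0L else boot$n_dropped)

  if (!is.null(out_dir)) {
    stage("write", quiet, {
      for (e in names(schedules)) {
        write_schedule(schedules[[e]], file.path(out_dir,
                                                 paste0("schedule_", e, ".csv")))
      }
      write_trials(analysis$flagged, file.path(out_dir, "cohort.csv"))
      write_condition_means(analysis$medians$group,
                            file.path(out_dir, "condition_means.csv"))
      report <- list(comparison = comparison,
                     best_model = best_fit$spec$model_id,
                     free_params = as.list(best_fit$free),
                     u0 = as.list(u0), derived = derived,
                     manifest = manifest)
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      yaml::write_yaml(manifest, file.path(out_dir, "MANIFEST.yaml"))
    })
  }
  on.exit()  # completed: clear the partial marker hook
  list(config = config, schedules = schedules, trials = analysis$flagged,
       deltas = analysis$deltas, medians = analysis$medians, u0 = u0,
       fits = fits, comparison = comparison, best_fit = best_fit,
       derived = derived, bootstrap = boot, manifest = manifest)
}
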