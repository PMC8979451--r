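#' Configuration for the synthetic-cohort generator
#'
#' The generator stands in for raw reaching data: hand angles are produced
#' from a latent state-space process driven by a chosen generative model.
#' On trial n the observed hand angle is `x_n + eps_n` with
#' `eps_n ~ Normal(0, noise_sd^2)` motor noise, and the latent state evolves
#' as `x_{n+1} = retention * x_n + s_n * U(cond_n)`, where `U` is the
#' generative model's total update in the normalized frame and `s_n` maps it
#' back to the raw sign convention (updates move away from the clamp, or
#' along the jump on TE-only trials).
#'
#' @param spec Generative [model_spec()].
#' @param params Generative [model_params()].
#' @param noise_sd Per-trial motor noise SD (degrees, `>= 0`). The default
#'   0.15 makes group-level condition SEMs land in the ~0.1--0.2 degree range
#'   typical of trial-pair analyses at these trial counts.
#' @param retention Trial-to-trial state persistence in `(0, 1]`; 1 treats
#'   each update as fully persistent over one trial, matching the trial-pair
#'   statistic used by the analysis.
#' @param n_participants Cohort size (`>= 1`).
#' @param between_subject_sd SD of the participant-level multiplicative gain
#'   applied to the `u0` entries (dimensionless; 0 = homogeneous cohort).
#' @param seed Integer master seed; all participant streams derive from it.
#' @return An object of class `de_sim_config`.
#' @export
sim_config <- function(spec, params, noise_sd = 0.15, retention = 1,
                       n_participants = 1L, between_subject_sd = 0,
                       seed = 1L) {
  stopifnot(inherits(spec, "de_model_spec"),
            inherits(params, "de_model_params"),
            noise_sd >= 0, retention > 0, retention <= 1,
            n_participants >= 1, between_subject_sd >= 0)
  structure(list(spec = spec, params = params, noise_sd = noise_sd,
                 retention = retention,
                 n_participants = as.integer(n_participants),
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "de_sim_config")
}

# Normalized condition frame plus the sign restoring the raw direction:
# clamp trials: positive update = away from the clamp (raw sign -sign(clamp));
# TE-only (0 deg clamp, jump != 0): positive update = along the jump.
trial_conditions <- function(trials) {
  clamp <- trials$clamp_deg
  jump <- trials$jump_deg
  cond <- data.frame(
    clamp_mag = abs(clamp),
    jump_rel = ifelse(clamp != 0, jump * sign(clamp), abs(jump)),
    jump_event = trials$jump_event,
    feedback = trials$feedback_type != "none")
  sgn <- ifelse(clamp != 0, -sign(clamp), ifelse(jump != 0, sign(jump), 1))
  list(cond = cond, sign = sgn)
}

#' Simulate one participant over a schedule
#'
#' @param schedule A `de_schedule` from [generate_schedule()].
#' @param config A [sim_config()].
#' @param participant_seed Seed for this participant's noise stream.
#' @param participant_id Identifier stored in the output.
#' @param u0_gain Multiplicative gain applied to the `u0` entries (the
#'   between-subject factor; cohort-level code draws it).
#' @return `data.frame` of trial records: `participant_id`, `trial_index`,
#'   `block_index`, `clamp_deg`, `jump_deg`, `jump_event`, `feedback_type`,
#'   `hand_angle_deg`, `excluded` (initialized `FALSE`).
#' @export
simulate_participant <- function(schedule, config,
                                 participant_seed = config$seed,
                                 participant_id = "p1", u0_gain = 1) {
  stopifnot(inherits(schedule, "de_schedule"), inherits(config, "de_sim_config"))
  trials <- schedule$trials
  params <- config$params
  params$u0 <- params$u0 * u0_gain
  tc <- trial_conditions(trials)
  u_norm <- predict_total_update(config$spec, params, tc$cond)
  u_raw <- tc$sign * u_norm
  n <- nrow(trials)
  y <- stats::filter(u_raw, config$retention, method = "recursive")
  x <- c(0, as.numeric(y)[-n])
  set.seed(as.integer(participant_seed))
  eps <- stats::rnorm(n, 0, config$noise_sd)
  data.frame(participant_id = participant_id,
             trial_index = trials$trial,
             block_index = trials$block,
             clamp_deg = trials$clamp_deg,
             jump_deg = trials$jump_deg,
             jump_event = trials$jump_event,
             feedback_type = trials$feedback_type,
             hand_angle_deg = x + eps,
             excluded = FALSE)
}

#' Simulate a cohort of participants
#'
#' Draws `n_participants` independent participants over one schedule. The
#' master seed determines the schedule seed (when an experiment id is
#' given), every participant's noise stream and the between-subject `u0`
#' gains, so a cohort is fully reproducible from `config$seed`.
#'
#' @param x A `de_schedule`, or an experiment id passed to
#'   [generate_schedule()] with a seed derived from `config$seed`.
#' @param config A [sim_config()].
#' @param id_prefix Prefix for participant identifiers.
#' @return `data.frame` of trial records for all participants (columns as in
#'   [simulate_participant()]).
#' @examples
#' cfg <- sim_config(model_spec("invariant_spe"),
#'                   model_params(u0 = c("0" = 0, "3" = 0.5, "7" = 0.9)),
#'                   noise_sd = 0, n_participants = 2)
#' cohort <- simulate_cohort("exp4a", cfg)
#' @export
simulate_cohort <- function(x, config, id_prefix = "p") {
  stopifnot(inherits(config, "de_sim_config"))
  schedule <- if (inherits(x, "de_schedule")) x else
    generate_schedule(x, seed = derive_seed(config$seed, "schedule"))
  n <- config$n_participants
  set.seed(derive_seed(config$seed, "u0_gain"))
  gains <- pmax(1 + stats::rnorm(n, 0, config$between_subject_sd), 0.05)
  out <- lapply(seq_len(n), function(i) {
    simulate_participant(
      schedule, config,
      participant_seed = derive_seed(config$seed, paste0("participant_", i)),
      participant_id = sprintf("%s%03d", id_prefix, i),
      u0_gain = gains[i])
  })
  do.call(rbind, out)
}
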