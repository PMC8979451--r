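#' Model specifications for the dual-error model family
#'
#' Six candidate models describe how the trial-to-trial motor update depends
#' on the error-clamp angle (the sensory prediction error, SPE) and on target
#' jumps (which manipulate task error, TE). Three SPE families --
#' `"invariant"`, `"rewarded"` and `"distracted"` -- are each available with
#' (`*_spe_te`) or without (`*_spe`) an additive linear TE learning process.
#'
#' Free parameters per model:
#' * `invariant_spe` -- none (the baseline update `u0` is fixed empirically).
#' * `invariant_spe_te` -- `beta_te`.
#' * `rewarded_spe` -- `gamma_r`, `sigma_r`.
#' * `rewarded_spe_te` -- `gamma_r`, `sigma_r`, `beta_te`.
#' * `distracted_spe` -- `c_j`, `sigma_d`.
#' * `distracted_spe_te` -- `c_j`, `sigma_d`, `beta_te`.
#'
#' @param model Model identifier, one of [model_ids()].
#' @return An object of class `de_model_spec`: a list with `model_id`,
#'   `family` (`"invariant"`, `"rewarded"` or `"distracted"`), `te` (logical,
#'   whether the additive TE process is included), `free_params` (ordered
#'   character vector) and `k` (free-parameter count).
#' @examples
#' model_spec("distracted_spe_te")
#' @export
model_spec <- function(model) {
  stopifnot(is.character(model), length(model) == 1L)
  if (!model %in% model_ids()) {
    stop("unknown model id '", model, "'; supported: ",
         paste(model_ids(), collapse = ", "), call. = FALSE)
  }
  te <- grepl("_te$", model)
  family <- sub("_spe(_te)?$", "", model)
  free <- switch(family,
    invariant  = character(0),
    rewarded   = c("gamma_r", "sigma_r"),
    distracted = c("c_j", "sigma_d"))
  if (te) free <- c(free, "beta_te")
  structure(list(model_id = model, family = family, te = te,
                 free_params = free, k = length(free)),
            class = "de_model_spec")
}

#' All supported model identifiers
#' @return Character vector of the six model ids.
#' @export
model_ids <- function() {
  c("invariant_spe", "invariant_spe_te",
    "rewarded_spe", "rewarded_spe_te",
    "distracted_spe", "distracted_spe_te")
}

#' @export
print.de_model_spec <- function(x, ...) {
  cat("<model spec>", x$model_id, "\n")
  cat("  family:", x$family, " TE process:", x$te, "\n")
  cat("  free parameters (k = ", x$k, "): ",
      if (x$k) paste(x$free_params, collapse = ", ") else "(none)", "\n",
      sep = "")
  invisible(x)
}

#' Parameter set for the dual-error models
#'
#' Holds every parameter any of the six models may use. `u0` is the baseline
#' no-jump update per clamp magnitude (degrees), fixed from empirical data
#' during fitting; the remaining entries are the (potentially free) model
#' parameters.
#'
#' The `u0_composition` switch controls how `u0` combines with the TE process
#' in `*_spe_te` models:
#' * `"literal"` -- `u0` is the SPE process's own baseline, so the predicted
#'   no-jump total is `u0 + beta_te * clamp_mag`.
#' * `"constrained"` -- `u0` is the empirical no-jump *total*; the SPE
#'   baseline is re-derived as `u0 - beta_te * clamp_mag` so the no-jump
#'   total equals `u0` exactly.
#'
#' @param u0 Named numeric vector mapping clamp magnitude (degrees, the name)
#'   to the baseline no-jump update (degrees).
#' @param gamma_r Reward attenuation gain (degrees), `>= 0`.
#' @param sigma_r Reward attenuation width (degrees), `> 0` when used.
#' @param c_j Fixed attentional cost multiplier, in `(0, 1.5]`.
#' @param sigma_d Attentional Gaussian-decay width (degrees), `> 0` when used.
#' @param beta_te TE learning-rate slope (dimensionless).
#' @param u0_composition `"literal"` or `"constrained"` (see Details).
#' @return An object of class `de_model_params`.
#' @examples
#' model_params(u0 = c("3" = 0.5, "7" = 0.9),
#'              c_j = 0.84, sigma_d = 11.8, beta_te = 0.02)
#' @export
model_params <- function(u0, gamma_r = 0, sigma_r = NA_real_, c_j = 1,
                         sigma_d = NA_real_, beta_te = 0,
                         u0_composition = c("literal", "constrained")) {
  u0_composition <- match.arg(u0_composition)
  stopifnot(is.numeric(u0), length(u0) >= 1L, !is.null(names(u0)))
  keys <- suppressWarnings(as.numeric(names(u0)))
  if (anyNA(keys)) stop("u0 names must be numeric clamp magnitudes", call. = FALSE)
  if (any(keys < 0)) stop("u0 clamp magnitudes must be >= 0", call. = FALSE)
  structure(list(u0 = u0, gamma_r = gamma_r, sigma_r = sigma_r, c_j = c_j,
                 sigma_d = sigma_d, beta_te = beta_te,
                 u0_composition = u0_composition),
            class = "de_model_params")
}

#' @export
print.de_model_params <- function(x, ...) {
  cat("<model params> u0 composition:", x$u0_composition, "\n")
  cat("  u0:", paste(sprintf("%s° -> %.3g°", names(x$u0), x$u0),
                     collapse = ", "), "\n")
  cat(sprintf("  gamma_r = %.4g  sigma_r = %.4g  c_j = %.4g  sigma_d = %.4g  beta_te = %.4g\n",
              x$gamma_r, x$sigma_r, x$c_j, x$sigma_d, x$beta_te))
  invisible(x)
}

#' Build a normalized condition table
#'
#' Conditions are expressed in the sign-normalized frame: `clamp_mag` is the
#' clamp magnitude (degrees, `>= 0`), `jump_rel` the signed target jump
#' relative to the clamp direction (positive = toward/past the clamp,
#' negative = away), `jump_event` whether any target perturbation occurred
#' (including a jump-in-place flicker, which has `jump_rel = 0`), and
#' `feedback` whether cursor feedback was shown.
#'
#' @param clamp_mag Numeric vector of clamp magnitudes (degrees, `>= 0`).
#' @param jump_rel Numeric vector of relative jump sizes (degrees, signed).
#' @param jump_event Logical vector; must be `TRUE` wherever `jump_rel != 0`.
#' @param feedback Logical vector; `FALSE` for no-feedback trials.
#' @return A `data.frame` with the four columns, recycled to equal length.
#' @export
conditions <- function(clamp_mag, jump_rel = 0, jump_event = jump_rel != 0,
                       feedback = TRUE) {
  n <- max(length(clamp_mag), length(jump_rel), length(jump_event),
           length(feedback))
  cond <- data.frame(clamp_mag = rep_len(as.numeric(clamp_mag), n),
                     jump_rel = rep_len(as.numeric(jump_rel), n),
                     jump_event = rep_len(as.logical(jump_event), n),
                     feedback = rep_len(as.logical(feedback), n))
  if (any(cond$clamp_mag < 0)) stop("clamp_mag must be >= 0", call. = FALSE)
  if (any(cond$jump_rel != 0 & !cond$jump_event)) {
    stop("jump_rel != 0 requires jump_event = TRUE", call. = FALSE)
  }
  cond
}

# Look up u0 entries by clamp magnitude with a small numeric tolerance.
u0_lookup <- function(params, clamp_mag, tol = 1e-8) {
  keys <- as.numeric(names(params$u0))
  idx <- vapply(clamp_mag, function(cm) {
    hit <- which(abs(keys - cm) <= tol)
    if (!length(hit)) {
      stop("no u0 entry for clamp magnitude ", format(cm),
           " (available: ", paste(format(keys), collapse = ", "), ")",
           call. = FALSE)
    }
    hit[1L]
  }, integer(1))
  unname(params$u0[idx])
}

# SPE baseline after the u0-composition rule (constrained subtracts the TE
# share so the no-jump total reproduces the empirical mean).
spe_baseline <- function(spec, params, cond) {
  u0v <- u0_lookup(params, cond$clamp_mag)
  if (spec$te && identical(params$u0_composition, "constrained")) {
    u0v <- u0v - params$beta_te * cond$clamp_mag
  }
  u0v
}

check_sigma <- function(value, name) {
  if (!is.finite(value) || value <= 0) {
    stop(name, " must be strictly positive for this model (got ",
         format(value), ")", call. = FALSE)
  }
}

#' Predicted SPE-driven update
#'
#' Evaluates the SPE learning process of a model on normalized conditions:
#' * Invariant SPE: `u0[clamp_mag]`, impervious to target jumps.
#' * Rewarded SPE: `u0 - gamma_r * exp(-(clamp_mag - jump_rel)^2 / (2 sigma_r^2))`
#'   -- attenuation is maximal when the target jumps onto the cursor.
#' * Distracted SPE: `c_j * u0 * exp(-jump_rel^2 / (2 sigma_d^2))` on
#'   perturbation-event trials (fixed cost `c_j` plus a Gaussian decay with
#'   jump size), and plain `u0` on no-jump trials.
#'
#' Rows with `feedback = FALSE` (no cursor, hence no SPE) return 0.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()]; `u0` must cover every clamp magnitude in
#'   `cond`.
#' @param cond A condition table from [conditions()].
#' @return Numeric vector of predicted updates (degrees).
#' @examples
#' p <- model_params(u0 = c("3" = 0.5), c_j = 0.84, sigma_d = 11.8)
#' # jump-in-place isolates the fixed cost: 0.84 * 0.5 = 0.42
#' predict_spe_update(model_spec("distracted_spe"), p,
#'                    conditions(3, 0, jump_event = TRUE))
#' @export
predict_spe_update <- function(spec, params, cond) {
  stopifnot(inherits(spec, "de_model_spec"), inherits(params, "de_model_params"))
  base <- spe_baseline(spec, params, cond)
  out <- switch(spec$family,
    invariant = base,
    rewarded = {
      check_sigma(params$sigma_r, "sigma_r")
      base - params$gamma_r *
        exp(-(cond$clamp_mag - cond$jump_rel)^2 / (2 * params$sigma_r^2))
    },
    distracted = {
      check_sigma(params$sigma_d, "sigma_d")
      ifelse(cond$jump_event,
             params$c_j * base * exp(-cond$jump_rel^2 / (2 * params$sigma_d^2)),
             base)
    })
  out[!cond$feedback] <- 0
  out
}

#' Predicted TE-driven update
#'
#' The linear TE learning process `beta_te * (clamp_mag - jump_rel)`: zero
#' when the target jumps onto the cursor (TE nullified), increased by
#' jump-away, reduced by jump-past.
#'
#' @inheritParams predict_spe_update
#' @return Numeric vector of predicted updates (degrees).
#' @examples
#' p <- model_params(u0 = c("3" = 0.5), beta_te = 0.02)
#' predict_te_update(p, conditions(3, 0))  # 0.06
#' @export
predict_te_update <- function(params, cond) {
  stopifnot(inherits(params, "de_model_params"))
  params$beta_te * (cond$clamp_mag - cond$jump_rel)
}

#' Predicted total update
#'
#' The net motor update: for `*_spe` models just the SPE process; for
#' `*_spe_te` models the sum of the SPE and TE processes. On no-feedback
#' trials the SPE term is 0, so `*_spe` models predict 0 and `*_spe_te`
#' models predict the TE term alone.
#'
#' @inheritParams predict_spe_update
#' @return Numeric vector of predicted updates (degrees).
#' @export
predict_total_update <- function(spec, params, cond) {
  spe <- predict_spe_update(spec, params, cond)
  if (spec$te) spe + predict_te_update(params, cond) else spe
}

#' Predicted update curve over a grid of target jumps
#'
#' Evaluates [predict_total_update()] for one clamp magnitude across a grid
#' of relative jump sizes (the model signature curves: constant for
#' Invariant, a localized dip for Rewarded, a symmetric Gaussian attenuation
#' for Distracted SPE-only, and an asymmetric curve once the TE process is
#' added).
#'
#' @inheritParams predict_spe_update
#' @param clamp_mag Single clamp magnitude (degrees).
#' @param jump_grid Numeric vector of relative jump sizes (degrees). Nonzero
#'   entries are perturbation events; zero entries are no-jump unless
#'   `zero_jump_event = TRUE` (jump-in-place).
#' @param zero_jump_event Whether `jump_grid == 0` entries are flicker
#'   (jump-in-place) trials rather than no-jump trials.
#' @return `data.frame` with columns `jump_rel` and `update` (input order
#'   preserved).
#' @export
predict_condition_curve <- function(spec, params, clamp_mag, jump_grid,
                                    zero_jump_event = FALSE) {
  stopifnot(length(clamp_mag) == 1L, is.numeric(jump_grid))
  cond <- conditions(clamp_mag, jump_grid,
                     jump_event = jump_grid != 0 | zero_jump_event)
  data.frame(jump_rel = jump_grid,
             update = predict_total_update(spec, params, cond))
}
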