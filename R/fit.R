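#' Default free-parameter bounds for fitting
#'
#' Generous boxes around plausible values: `gamma_r` in \[0, 5\] degrees,
#' `sigma_r` in (0, 30\] degrees, `c_j` in (0, 1.5\], `sigma_d` in (0, 90\]
#' degrees, `beta_te` in \[-0.5, 0.5\].
#'
#' @return List with numeric vectors `lower` and `upper`, named by parameter.
#' @export
default_bounds <- function() {
  list(lower = c(gamma_r = 0, sigma_r = 1e-3, c_j = 1e-3, sigma_d = 1e-3,
                 beta_te = -0.5),
       upper = c(gamma_r = 5, sigma_r = 30, c_j = 1.5, sigma_d = 90,
                 beta_te = 0.5))
}

# Extract fixed u0 (baseline no-jump update per clamp magnitude) from a group
# condition-mean table.
u0_from_means <- function(group_means) {
  nj <- group_means[group_means$jump_rel == 0 & !group_means$jump_event &
                      group_means$feedback, ]
  if (!nrow(nj)) stop("no no-jump condition means to derive u0 from", call. = FALSE)
  stats::setNames(nj$mean, format(nj$clamp_mag, trim = TRUE))
}

build_params <- function(spec, theta, u0_fixed, u0_composition) {
  args <- list(u0 = u0_fixed, u0_composition = u0_composition)
  args[names(theta)] <- theta
  # fixed sensible values for parameters the model does not use
  if (!"sigma_r" %in% names(theta)) args$sigma_r <- 1
  if (!"sigma_d" %in% names(theta)) args$sigma_d <- 1
  do.call(model_params, args)
}

#' Fit one model to group-averaged condition means
#'
#' Bounded multi-start least squares: minimizes the (optionally
#' inverse-SEM-weighted) sum of squared differences between observed
#' condition means and [predict_total_update()], jointly over all clamp
#' magnitudes in the data. Starts are drawn uniformly within the bounds from
#' a seeded RNG; the best of `n_starts` local optimizations (L-BFGS-B) is
#' returned, ties broken by lowest SSE then lowest start index.
#'
#' `R^2 = 1 - SSE / SST` with SST taken against the grand mean of the fitted
#' data points (so the grand-mean predictor scores exactly 0 and a model
#' worse than it scores negative). `AIC = n * log(SSE / n) + 2k` with `n` the
#' number of fitted condition means and `k` the free-parameter count.
#'
#' @param spec A [model_spec()].
#' @param condition_means Group condition-mean table (the `group` element of
#'   [condition_medians()], or any data frame with columns `clamp_mag`,
#'   `jump_rel`, `jump_event`, `feedback`, `mean`, optionally `sem`).
#' @param u0_fixed Named numeric vector of baseline no-jump updates per clamp
#'   magnitude; defaults to the no-jump means of `condition_means`.
#' @param n_starts Number of random starts (default 10).
#' @param seed RNG seed for the starts.
#' @param bounds Bounds list as from [default_bounds()].
#' @param weighting `"none"` (default) or `"inverse_sem"` (weights
#'   `1/sem^2`; rows with `sem == 0` get the largest finite weight present).
#' @param u0_composition How `u0` combines with the TE process; see
#'   [model_params()].
#' @return An object of class `de_fit`: list with `spec`, `params` (full
#'   parameter object at the optimum), `free` (named estimates), `sse`,
#'   `r2`, `aic`, `k`, `n_points`, `n_starts`, `best_start`, `converged`,
#'   and `starts` (per-start diagnostics).
#' @export
fit_model <- function(spec, condition_means, u0_fixed = NULL, n_starts = 10L,
                      seed = 1L, bounds = default_bounds(),
                      weighting = c("none", "inverse_sem"),
                      u0_composition = c("literal", "constrained")) {
  weighting <- match.arg(weighting)
  u0_composition <- match.arg(u0_composition)
  stopifnot(inherits(spec, "de_model_spec"), nrow(condition_means) >= 1L)
  cm <- condition_means
  if (!"feedback" %in% names(cm)) cm$feedback <- TRUE
  if (is.null(u0_fixed)) u0_fixed <- u0_from_means(cm)
  cond <- conditions(cm$clamp_mag, cm$jump_rel, cm$jump_event, cm$feedback)
  y <- cm$mean
  w <- rep(1, length(y))
  if (weighting == "inverse_sem") {
    if (!"sem" %in% names(cm)) stop("weighting = 'inverse_sem' needs a sem column",
                                    call. = FALSE)
    w <- 1 / cm$sem^2
    if (any(!is.finite(w))) {
      w[!is.finite(w)] <- if (any(is.finite(w))) max(w[is.finite(w)]) else 1
    }
  }
  free <- spec$free_params
  objective <- function(theta) {
    params <- build_params(spec, stats::setNames(theta, free), u0_fixed,
                           u0_composition)
    sum(w * (y - predict_total_update(spec, params, cond))^2)
  }
  if (spec$k == 0L) {
    sse <- objective(numeric(0))
    est <- stats::setNames(numeric(0), character(0))
    starts <- data.frame(start = 1L, sse = sse, convergence = 0L)
    best_start <- 1L
    converged <- TRUE
  } else {
    lower <- bounds$lower[free]
    upper <- bounds$upper[free]
    set.seed(as.integer(seed))
    inits <- matrix(stats::runif(n_starts * spec$k, lower, upper),
                    nrow = n_starts, byrow = TRUE,
                    dimnames = list(NULL, free))
    runs <- lapply(seq_len(n_starts), function(i) {
      res <- tryCatch(
        stats::optim(inits[i, ], objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) list(par = inits[i, ], value = Inf,
                                 convergence = 99L, message = conditionMessage(e)))
      res
    })
    sses <- vapply(runs, function(r) r$value, numeric(1))
    convs <- vapply(runs, function(r) as.integer(r$convergence), integer(1))
    starts <- data.frame(start = seq_len(n_starts), sse = sses,
                         convergence = convs)
    converged <- any(convs == 0L & is.finite(sses))
    best_start <- order(sses, seq_len(n_starts))[1L]
    est <- stats::setNames(runs[[best_start]]$par, free)
    sse <- sses[best_start]
  }
  params <- build_params(spec, est, u0_fixed, u0_composition)
  sst <- sum(w * (y - stats::weighted.mean(y, w))^2)
  n <- length(y)
  structure(list(spec = spec, params = params, free = est, sse = sse,
                 r2 = 1 - sse / sst, aic = n * log(sse / n) + 2 * spec$k,
                 k = spec$k, n_points = n, n_starts = nrow(starts),
                 best_start = best_start, converged = converged,
                 starts = starts, u0_fixed = u0_fixed,
                 u0_composition = u0_composition, weighting = weighting),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat("<fit>", x$spec$model_id, if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  sse = %.5g  R2 = %.3f  AIC = %.2f  (n = %d, k = %d, starts = %d)\n",
              x$sse, x$r2, x$aic, x$n_points, x$k, x$n_starts))
  if (length(x$free)) {
    cat("  ", paste(sprintf("%s = %.4g", names(x$free), x$free),
                    collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Rank a set of fitted models
#'
#' Sorts fits by AIC (ascending), reports delta-AIC relative to the best, and
#' flags any disagreement between the AIC winner and the R-squared winner.
#' All fits must be on identical data (equal `n_points`).
#'
#' @param fits List of `de_fit` objects on the same condition means.
#' @return `data.frame` with columns `model_id`, `k`, `sse`, `r2`, `aic`,
#'   `delta_aic`, `rank`; attribute `aic_r2_disagree` (logical).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "de_fit")))
  np <- vapply(fits, function(f) f$n_points, numeric(1))
  if (length(unique(np)) != 1L) {
    stop("fits are not comparable: n_points differ (",
         paste(unique(np), collapse = ", "), ")", call. = FALSE)
  }
  tab <- data.frame(
    model_id = vapply(fits, function(f) f$spec$model_id, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    sse = vapply(fits, function(f) f$sse, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "aic_r2_disagree") <- tab$model_id[1L] !=
    tab$model_id[which.max(tab$r2)]
  tab
}

#' Participant-level bootstrap confidence intervals
#'
#' Resamples participants with replacement within each group, rebuilds the
#' group-averaged condition means from the resampled participants' condition
#' medians, re-derives the fixed `u0` from the resample's no-jump means, and
#' refits the model; repeated `B` times. Resamples missing a condition
#' present in the full data are dropped (their count is reported).
#'
#' @param trials Trial-record table for the full cohort (multiple
#'   experiments may be concatenated; see `groups`).
#' @param spec Model to refit on each resample.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param groups Optional named character vector mapping participant id to a
#'   resampling group (e.g. the clamp-size group); default puts everyone in
#'   one group.
#' @param n_starts Starts per refit (default 10).
#' @param u0_composition,weighting,bounds Passed to [fit_model()].
#' @return An object of class `de_bootstrap`: list with `B`, `samples`
#'   (matrix of free-parameter draws), `ci` (2.5/97.5 percentiles), `mean`,
#'   `sd`, `n_dropped`.
#' @export
bootstrap_ci <- function(trials, spec, B = 1000L, seed = 1L, groups = NULL,
                         n_starts = 10L,
                         u0_composition = c("literal", "constrained"),
                         weighting = c("none", "inverse_sem"),
                         bounds = default_bounds()) {
  u0_composition <- match.arg(u0_composition)
  weighting <- match.arg(weighting)
  deltas <- normalize_signs(compute_deltas(flag_outliers(trials)))
  med <- condition_medians(deltas)
  pm <- med$participant
  full_conds <- unique(med$group[, cond_key_cols])
  ids <- unique(pm$participant_id)
  grp_of <- if (is.null(groups)) stats::setNames(rep("all", length(ids)), ids)
            else groups
  by_group <- split(ids, grp_of[ids])
  set.seed(as.integer(seed))
  pm_by_id <- split(pm, pm$participant_id)
  samples <- matrix(NA_real_, nrow = B, ncol = spec$k,
                    dimnames = list(NULL, spec$free_params))
  n_dropped <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(by_group, function(g) sample(g, length(g),
                                                       replace = TRUE)),
                   use.names = FALSE)
    res <- do.call(rbind, pm_by_id[take])
    gkey <- interaction(res$clamp_mag, res$jump_rel, res$jump_event,
                        res$feedback, drop = TRUE, sep = "\r")
    gfirst <- !duplicated(gkey)
    cm <- res[gfirst, cond_key_cols]
    cm$mean <- as.numeric(tapply(res$median_delta, gkey, mean)[gkey[gfirst]])
    cm$n <- as.integer(tapply(res$median_delta, gkey, length)[gkey[gfirst]])
    cm$sd <- as.numeric(tapply(res$median_delta, gkey, stats::sd)[gkey[gfirst]])
    cm$sd[cm$n == 1L] <- 0
    cm$sem <- cm$sd / sqrt(cm$n)
    if (nrow(merge(full_conds, cm[, cond_key_cols])) < nrow(full_conds)) {
      n_dropped <- n_dropped + 1L
      next
    }
    fit <- fit_model(spec, cm, n_starts = n_starts,
                     seed = derive_seed(seed, paste0("refit_", b)),
                     bounds = bounds, weighting = weighting,
                     u0_composition = u0_composition)
    if (spec$k) samples[b, ] <- fit$free
  }
  keep <- if (spec$k) stats::complete.cases(samples) else rep(TRUE, B)
  kept <- samples[keep, , drop = FALSE]
  ci <- if (spec$k && nrow(kept)) {
    apply(kept, 2, stats::quantile, probs = c(0.025, 0.975), names = TRUE)
  } else NULL
  structure(list(B = B, samples = kept, ci = ci,
                 mean = if (spec$k && nrow(kept)) colMeans(kept) else NULL,
                 sd = if (spec$k && nrow(kept)) apply(kept, 2, stats::sd) else NULL,
                 n_dropped = n_dropped, spec = spec),
            class = "de_bootstrap")
}

#' @export
print.de_bootstrap <- function(x, ...) {
  cat("<bootstrap>", x$spec$model_id, "- B =", x$B,
      "(", x$n_dropped, "resamples dropped )\n")
  if (!is.null(x$ci)) print(round(x$ci, 4))
  invisible(x)
}

#' Derived summary quantities from a fitted dual-error model
#'
#' Computes the headline interpretable quantities:
#' * `te_fraction_pct` per clamp magnitude: the percentage of the observed
#'   no-jump update attributable to the TE process,
#'   `100 * beta_te * clamp_mag / no_jump_mean`.
#' * `fixed_cost_pct`: the percent reduction of SPE-driven learning from the
#'   mere presence of a target perturbation, `100 * (1 - c_j)`.
#' * `effective_jump_range_deg`: the jump size beyond which SPE-driven
#'   learning is effectively abolished, `3 * sigma_d`.
#'
#' @param fit A `de_fit` (a Distracted SPE+TE fit exposes all three
#'   quantities; other models expose the ones their parameters define).
#' @param no_jump_means Named numeric vector of observed no-jump condition
#'   means per clamp magnitude (degrees); defaults to the fit's fixed `u0`
#'   under the constrained composition, where the two coincide.
#' @return List with `te_fraction_pct` (named by clamp magnitude; only for
#'   `*_spe_te` fits), `fixed_cost_pct` and `effective_jump_range_deg` (only
#'   for distracted-family fits).
#' @examples
#' cm <- data.frame(clamp_mag = c(3, 7), jump_rel = 0, jump_event = FALSE,
#'                  feedback = TRUE, mean = c(0.5, 0.9))
#' f <- fit_model(model_spec("invariant_spe"), cm)
#' @export
derived_quantities <- function(fit, no_jump_means = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  if (is.null(no_jump_means)) no_jump_means <- fit$u0_fixed
  out <- list()
  if (fit$spec$te) {
    cm <- as.numeric(names(no_jump_means))
    if (any(no_jump_means == 0)) {
      stop("TE fraction undefined: zero no-jump mean for clamp magnitude ",
           paste(cm[no_jump_means == 0], collapse = ", "), call. = FALSE)
    }
    out$te_fraction_pct <- stats::setNames(
      100 * fit$params$beta_te * cm / as.numeric(no_jump_means),
      names(no_jump_means))
  }
  if (fit$spec$family == "distracted") {
    out$fixed_cost_pct <- 100 * (1 - fit$params$c_j)
    out$effective_jump_range_deg <- 3 * fit$params$sigma_d
  }
  out
}
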