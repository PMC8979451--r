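#' Flag outlier reaches with a moving-window criterion
#'
#' A trial is excluded when its hand angle deviates by more than `z` standard
#' deviations from the mean of a moving `window`-trial window centered on it
#' (truncated at block edges), the mean computed over the window *excluding*
#' the trial itself (leave-one-out). The SD scale is estimated once per
#' participant and block over all trials of the raw pass (a windowed SD from
#' only four samples behaves like a 3-df t criterion and would flag several
#' percent of perfectly clean trials; the block-level SD keeps the
#' false-positive rate of clean Gaussian data well under 1%, the order of
#' magnitude reported for this style of filter). The SD is floored at `1e-9`
#' to avoid zero division, and flags are decided in a single pass (no
#' iterative re-flagging).
#'
#' @param trials Trial-record `data.frame` (see [simulate_participant()] for
#'   the column layout), ordered by `trial_index` within participant.
#' @param window Window length in trials (centered; default 5).
#' @param z Exclusion threshold in window SDs (default 3).
#' @return The input with the `excluded` column set.
#' @export
flag_outliers <- function(trials, window = 5L, z = 3) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  trials$excluded <- FALSE
  grp <- interaction(trials$participant_id, trials$block_index, drop = TRUE)
  for (idx in split(seq_len(nrow(trials)), grp)) {
    idx <- idx[order(trials$trial_index[idx])]
    h <- trials$hand_angle_deg[idx]
    n <- length(h)
    if (n < 3L) {
      warning("block with fewer than 3 trials: no outlier flags set",
              call. = FALSE)
      next
    }
    h0 <- h - mean(h)  # center for numerical stability
    cs <- cumsum(c(0, h0))
    i <- seq_len(n)
    lo <- pmax(1L, i - half)
    hi <- pmin(n, i + half)
    k <- hi - lo + 1L                       # window size incl. the trial
    S <- cs[hi + 1L] - cs[lo]
    m <- (S - h0) / (k - 1L)                # leave-one-out window mean
    sd_blk <- max(stats::sd(h0), 1e-9)      # raw-pass block SD
    trials$excluded[idx] <- abs(h0 - m) > z * sd_blk
  }
  trials
}

#' Trial-to-trial hand-angle changes
#'
#' For each adjacent pair of non-excluded trials (n, n+1) within the same
#' block, computes `delta_raw = hand[n+1] - hand[n]`, attributed to the
#' perturbation condition of trial n. Pairs spanning an excluded trial or a
#' block boundary are dropped.
#'
#' @param trials Trial records with outlier flags set ([flag_outliers()]).
#' @return `data.frame` of delta records: `participant_id`,
#'   `source_trial_index`, `clamp_deg`, `jump_deg`, `jump_event`,
#'   `feedback_type`, `delta_raw`.
#' @export
compute_deltas <- function(trials) {
  o <- order(trials$participant_id, trials$block_index, trials$trial_index)
  t2 <- trials[o, ]
  n <- nrow(t2)
  if (n < 2L) {
    return(data.frame(participant_id = character(0),
                      source_trial_index = integer(0), clamp_deg = numeric(0),
                      jump_deg = numeric(0), jump_event = logical(0),
                      feedback_type = character(0), delta_raw = numeric(0)))
  }
  a <- seq_len(n - 1L)
  b <- a + 1L
  ok <- t2$participant_id[a] == t2$participant_id[b] &
    t2$block_index[a] == t2$block_index[b] &
    t2$trial_index[b] - t2$trial_index[a] == 1L &
    !t2$excluded[a] & !t2$excluded[b]
  a <- a[ok]
  data.frame(participant_id = t2$participant_id[a],
             source_trial_index = t2$trial_index[a],
             clamp_deg = t2$clamp_deg[a],
             jump_deg = t2$jump_deg[a],
             jump_event = t2$jump_event[a],
             feedback_type = t2$feedback_type[a],
             delta_raw = t2$hand_angle_deg[a + 1L] - t2$hand_angle_deg[a])
}

#' Sign-normalize delta records
#'
#' Maps raw signed conditions into the normalized frame in which a positive
#' change in hand angle signifies recalibration in the expected direction:
#' for non-zero clamps, `clamp_mag = |clamp|`, `jump_rel = jump * sign(clamp)`
#' (positive = toward/past the clamp) and `delta = -sign(clamp) * delta_raw`
#' (positive = away from the clamp). For TE-only trials (`clamp == 0`,
#' `jump != 0`), `jump_rel = |jump|` and `delta = sign(jump) * delta_raw`.
#' The (0, 0) condition is left unchanged.
#'
#' @param deltas Delta records from [compute_deltas()].
#' @return The input plus columns `clamp_mag`, `jump_rel`, `feedback`
#'   (logical) and `delta` (normalized change, degrees).
#' @export
normalize_signs <- function(deltas) {
  clamp <- deltas$clamp_deg
  jump <- deltas$jump_deg
  deltas$clamp_mag <- abs(clamp)
  deltas$jump_rel <- ifelse(clamp != 0, jump * sign(clamp), abs(jump))
  deltas$delta <- ifelse(clamp != 0, -sign(clamp) * deltas$delta_raw,
                         ifelse(jump != 0, sign(jump) * deltas$delta_raw,
                                deltas$delta_raw))
  deltas$feedback <- deltas$feedback_type != "none"
  deltas
}

cond_key_cols <- c("clamp_mag", "jump_rel", "jump_event", "feedback")

#' Per-participant condition medians and group means
#'
#' Computes each participant's median normalized hand-angle change per
#' condition, then the group mean, SD and SEM of those medians across
#' participants. Conditions a participant never experienced are simply
#' absent from that participant's rows (never zero-filled).
#'
#' @param deltas Normalized delta records from [normalize_signs()].
#' @return List with `participant` (columns: `participant_id`, condition
#'   key, `median_delta`, `n_pairs`) and `group` (condition key, `mean`,
#'   `sd`, `sem`, `n` participants), both plain data frames sorted by
#'   condition.
#' @export
condition_medians <- function(deltas) {
  stopifnot(all(c(cond_key_cols, "delta", "participant_id") %in% names(deltas)))
  key <- interaction(deltas$participant_id,
                     deltas$clamp_mag, deltas$jump_rel,
                     deltas$jump_event, deltas$feedback,
                     drop = TRUE, sep = "\r")
  first <- !duplicated(key)
  pm <- deltas[first, c("participant_id", cond_key_cols)]
  pm$median_delta <- as.numeric(tapply(deltas$delta, key, stats::median)[key[first]])
  pm$n_pairs <- as.integer(tapply(deltas$delta, key, length)[key[first]])
  pm <- pm[order(pm$clamp_mag, pm$jump_rel, pm$jump_event, pm$feedback,
                 pm$participant_id), ]
  rownames(pm) <- NULL
  gkey <- interaction(pm$clamp_mag, pm$jump_rel, pm$jump_event, pm$feedback,
                      drop = TRUE, sep = "\r")
  gfirst <- !duplicated(gkey)
  grp <- pm[gfirst, cond_key_cols]
  grp$mean <- as.numeric(tapply(pm$median_delta, gkey, mean)[gkey[gfirst]])
  grp$sd <- as.numeric(tapply(pm$median_delta, gkey, stats::sd)[gkey[gfirst]])
  grp$n <- as.integer(tapply(pm$median_delta, gkey, length)[gkey[gfirst]])
  grp$sd[grp$n == 1L] <- 0
  grp$sem <- grp$sd / sqrt(grp$n)
  grp <- grp[order(grp$clamp_mag, grp$jump_rel, grp$jump_event, grp$feedback), ]
  rownames(grp) <- NULL
  list(participant = pm, group = grp)
}

#' Per-participant regression slopes and group inference
#'
#' Regresses each participant's raw trial-to-trial change on perturbation
#' size, separately per perturbation type (clamp vs target jump) or with a
#' size-by-type interaction. Perturbation size is the signed clamp for clamp
#' trials and the sign-flipped target jump for jump trials (so that, were TE
#' to drive learning, both types would show a negative slope). Group-level
#' summaries are the mean slope, its SEM, and a one-sample t-test against 0.
#'
#' @param deltas Delta records from [compute_deltas()].
#' @param design `"per_type"` (one OLS fit per type per participant) or
#'   `"interaction"` (one fit per participant with `size * type`).
#' @return List with `participant` (per-participant coefficients) and
#'   `group` (per coefficient: mean, sem, t, df, p).
#' @export
participant_slopes <- function(deltas, design = c("per_type", "interaction")) {
  design <- match.arg(design)
  d <- deltas
  d$type <- ifelse(d$jump_event | d$feedback_type == "none", "jump", "clamp")
  d$size <- ifelse(d$type == "clamp", d$clamp_deg, -d$jump_deg)
  rows <- list()
  for (pid in unique(d$participant_id)) {
    dp <- d[d$participant_id == pid, ]
    if (design == "per_type") {
      for (ty in unique(dp$type)) {
        dt <- dp[dp$type == ty, ]
        if (length(unique(dt$size)) < 2L) {
          stop("participant ", pid, " has fewer than 2 distinct ", ty,
               " perturbation sizes; slope is not estimable", call. = FALSE)
        }
        fit <- stats::lm(delta_raw ~ size, data = dt)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, coef = paste0("slope_", ty),
          estimate = unname(stats::coef(fit)["size"]))
      }
    } else {
      X <- stats::model.matrix(~ size * type, data = dp)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("rank-deficient design for participant ", pid,
             "; collinear column(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      fit <- stats::lm(delta_raw ~ size * type, data = dp)
      cf <- stats::coef(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, coef = names(cf), estimate = unname(cf))
    }
  }
  pm <- do.call(rbind, rows)
  grp <- do.call(rbind, lapply(split(pm, pm$coef), function(g) {
    est <- g$estimate
    tt <- if (length(est) > 1L && stats::sd(est) > 0) {
      stats::t.test(est)
    } else {
      list(statistic = c(t = if (all(est == 0)) 0 else Inf),
           parameter = c(df = length(est) - 1), p.value = NA_real_)
    }
    data.frame(coef = g$coef[1], mean = mean(est),
               sem = stats::sd(est) / sqrt(length(est)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(est))
  }))
  rownames(grp) <- NULL
  list(participant = pm, group = grp)
}
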