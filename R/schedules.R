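#' Supported experiment identifiers
#'
#' Ten perturbation-block designs: the mini-blocked in-person error-clamp /
#' target-jump study (`exp1a`), its online no-feedback replication (`exp1b`),
#' the fully interleaved in-person sets (`exp2a`, `exp2b`), the
#' jump-in-place flicker sets at two clamp sizes (`exp3a`, `exp3b`) and the
#' wide jump-range sets at two clamp sizes (`exp4a`--`exp4d`).
#'
#' @return Character vector of experiment ids.
#' @export
experiment_ids <- function() {
  c("exp1a", "exp1b", "exp2a", "exp2b", "exp3a", "exp3b",
    "exp4a", "exp4b", "exp4c", "exp4d")
}

# Per-combination design tables. Columns: clamp_deg, jump_deg (raw, signed),
# jump_event, feedback_type, n. exp1a is described per mini-block.
# Relative jumps are realized per signed clamp: jump_deg = jump_rel * sign(clamp).
expand_signed <- function(clamp_mag, jump_rel, n_each, flicker_rel = numeric(0)) {
  rows <- list()
  for (s in c(1, -1)) {
    rows[[length(rows) + 1L]] <- data.frame(
      clamp_deg = s * clamp_mag, jump_deg = s * jump_rel,
      jump_event = jump_rel != 0, feedback_type = "clamp", n = n_each)
    if (length(flicker_rel)) {
      rows[[length(rows) + 1L]] <- data.frame(
        clamp_deg = s * clamp_mag, jump_deg = 0,
        jump_event = TRUE, feedback_type = "clamp", n = n_each)
    }
  }
  do.call(rbind, rows)
}

schedule_design <- function(experiment_id) {
  jump4 <- c(-10, -3, 0, 3, 7, 10, 17)   # relative jumps, narrow-range sets
  jump4w <- c(-30, -17, -10, 0, 10, 17, 30)  # wide-range sets
  switch(experiment_id,
    exp1a = list(
      window = 20, miniblocks = TRUE,
      spe_te = data.frame(clamp_deg = c(0, 4, -4, 16, -16), jump_deg = 0,
                          jump_event = FALSE, feedback_type = "clamp",
                          n = c(41, 40, 40, 40, 40)),
      te_only = data.frame(clamp_deg = 0, jump_deg = c(0, 4, -4, 16, -16),
                           jump_event = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                           feedback_type = "clamp",
                           n = c(41, 40, 40, 40, 40))),
    exp1b = list(
      window = NA_integer_, miniblocks = FALSE,
      combos = rbind(
        data.frame(clamp_deg = c(0, 4, -4, 16, -16), jump_deg = 0,
                   jump_event = FALSE, feedback_type = "clamp", n = 20),
        data.frame(clamp_deg = 0, jump_deg = c(0, 4, -4, 16, -16),
                   jump_event = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                   feedback_type = "none", n = 20))),
    exp2a = list(
      window = 24, miniblocks = FALSE,
      combos = rbind(
        data.frame(clamp_deg = rep(c(-4, 4), each = 3),
                   jump_deg = c(0, -4, -8, 0, 4, 8),
                   jump_event = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
                   feedback_type = "clamp", n = 80),
        data.frame(clamp_deg = 0, jump_deg = c(0, 4, -4),
                   jump_event = c(FALSE, TRUE, TRUE),
                   feedback_type = "clamp", n = c(84, 80, 80)))),
    exp2b = list(
      window = 24, miniblocks = FALSE,
      combos = rbind(
        data.frame(clamp_deg = rep(c(-4, 4), each = 3),
                   jump_deg = c(0, -8, 8, 0, 8, -8),
                   jump_event = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
                   feedback_type = "clamp", n = 80),
        data.frame(clamp_deg = 0, jump_deg = c(0, 8, -8),
                   jump_event = c(FALSE, TRUE, TRUE),
                   feedback_type = "clamp", n = c(84, 80, 80)))),
    exp3a = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(3, c(3, -3, 0), 15, flicker_rel = 0)),
    exp3b = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(7, c(3, -3, 0), 15, flicker_rel = 0)),
    exp4a = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(3, jump4, 18)),
    exp4b = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(7, jump4, 18)),
    exp4c = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(3, jump4w, 18)),
    exp4d = list(window = NA_integer_, miniblocks = FALSE,
                 combos = expand_signed(7, jump4w, 18)),
    stop("unknown experiment_id '", experiment_id, "'; supported: ",
         paste(experiment_ids(), collapse = ", "), call. = FALSE))
}

expand_combos <- function(combos) {
  idx <- rep(seq_len(nrow(combos)), combos$n)
  out <- combos[idx, c("clamp_deg", "jump_deg", "jump_event", "feedback_type")]
  rownames(out) <- NULL
  out
}

# Signed perturbation error of a trial: the clamp for clamp trials, the jump
# for TE-only (0 deg clamp) trials.
trial_error <- function(trials) {
  ifelse(trials$clamp_deg != 0, trials$clamp_deg, trials$jump_deg)
}

# Order trials so that every consecutive disjoint window of `window` trials
# has zero mean signed error. Trials with error +v and -v are paired, zeros
# are paired with zeros; pairs are shuffled into window/2-pair bins and
# shuffled within bins. With window = NA the whole block is one window and a
# plain shuffle is used (the designs are sign-symmetric, so the block sum is
# zero by construction).
balance_shuffle <- function(trials, window) {
  n <- nrow(trials)
  if (n == 0L) return(trials)
  if (is.na(window)) {
    return(trials[sample.int(n), , drop = FALSE])
  }
  if (window %% 2L != 0L) {
    stop("zero-mean window length must be even, got ", window, call. = FALSE)
  }
  err <- trial_error(trials)
  units <- list()
  for (v in unique(abs(err[err != 0]))) {
    pos <- sample(which(err == v))
    neg <- sample(which(err == -v))
    if (length(pos) != length(neg)) {
      stop("infeasible design: unequal counts of +", v, " and -", v,
           " perturbations cannot satisfy zero-mean windows", call. = FALSE)
    }
    units <- c(units, mapply(c, pos, neg, SIMPLIFY = FALSE))
  }
  zeros <- sample(which(err == 0))
  leftover <- integer(0)
  if (length(zeros) %% 2L == 1L) {
    leftover <- zeros[length(zeros)]
    zeros <- zeros[-length(zeros)]
  }
  if (length(zeros)) {
    units <- c(units, split(zeros, rep(seq_len(length(zeros) / 2), each = 2)))
  }
  units <- units[sample.int(length(units))]
  per_bin <- window %/% 2L
  bin <- rep(seq_len(ceiling(length(units) / per_bin)),
             each = per_bin)[seq_along(units)]
  ord <- unlist(lapply(split(units, bin), function(u) sample(unlist(u))),
                use.names = FALSE)
  trials[c(ord, leftover), , drop = FALSE]
}

#' Generate a perturbation schedule
#'
#' Builds the ordered trial list for one experiment design: per-combination
#' trial counts, mini-block structure (exp1a: four alternating homogeneous
#' 201-trial mini-blocks), and pseudo-randomization under the zero-mean
#' constraint (every disjoint 20-trial window for exp1a and 24-trial window
#' for exp2 has mean signed perturbation 0; the remaining experiments are
#' zero-mean over the whole block).
#'
#' @param experiment_id One of [experiment_ids()].
#' @param seed Integer RNG seed; schedules are deterministic given the seed.
#' @param counterbalance_order For `exp1a`: if `TRUE` the TE-only mini-block
#'   comes first, otherwise the SPE+TE mini-block.
#' @return An object of class `de_schedule`: list with `experiment_id`,
#'   `seed`, `window` (zero-mean window length, `NA` = whole block) and
#'   `trials`, a `data.frame` with columns `trial`, `block`, `clamp_deg`,
#'   `jump_deg`, `jump_event`, `feedback_type`.
#' @examples
#' sched <- generate_schedule("exp4a", seed = 3)
#' nrow(sched$trials)  # 252
#' @export
generate_schedule <- function(experiment_id, seed = 1L,
                              counterbalance_order = FALSE) {
  design <- schedule_design(experiment_id)
  set.seed(as.integer(seed))
  if (isTRUE(design$miniblocks)) {
    types <- if (counterbalance_order) c("te_only", "spe_te") else
      c("spe_te", "te_only")
    types <- rep(types, 2)
    blocks <- lapply(seq_along(types), function(b) {
      blk <- balance_shuffle(expand_combos(design[[types[b]]]), design$window)
      blk$block <- b
      blk
    })
    trials <- do.call(rbind, blocks)
  } else {
    trials <- balance_shuffle(expand_combos(design$combos), design$window)
    trials$block <- 1L
  }
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial", "block", "clamp_deg", "jump_deg",
                       "jump_event", "feedback_type")]
  structure(list(experiment_id = experiment_id, seed = as.integer(seed),
                 window = design$window, trials = trials),
            class = "de_schedule")
}

#' @export
print.de_schedule <- function(x, ...) {
  cat("<schedule>", x$experiment_id, "-", nrow(x$trials), "trials,",
      length(unique(x$trials$block)), "block(s), seed", x$seed, "\n")
  invisible(x)
}

# Disjoint-window means of the signed error, computed within each block.
window_means <- function(trials, window) {
  out <- lapply(split(trials, trials$block), function(blk) {
    err <- trial_error(blk)
    w <- if (is.na(window)) length(err) else window
    bins <- (seq_along(err) - 1L) %/% w
    tapply(err, bins, mean)
  })
  unlist(out, use.names = FALSE)
}

#' Validate a schedule against its experiment design
#'
#' Checks per-combination counts, zero-mean windows and (for exp1a) the
#' homogeneous mini-block structure. Content problems are reported, never
#' thrown.
#'
#' @param schedule A `de_schedule` (or a list with `experiment_id`, `window`
#'   and a `trials` data frame in the same layout).
#' @return List with `n_trials`, `counts` (observed vs expected trials per
#'   combination), `max_window_dev` (largest absolute disjoint-window mean of
#'   the signed perturbation), `block_sizes`, and `violations`, a character
#'   vector that is empty for generator output.
#' @export
validate_schedule <- function(schedule) {
  design <- schedule_design(schedule$experiment_id)
  trials <- schedule$trials
  expected <- if (isTRUE(design$miniblocks)) {
    both <- rbind(design$spe_te, design$te_only)
    both$n <- both$n * 2L  # each mini-block type appears twice
    both
  } else design$combos
  key <- function(d) paste(d$clamp_deg, d$jump_deg, d$jump_event,
                           d$feedback_type, sep = "/")
  violations <- character(0)
  if (nrow(trials)) {
    obs <- as.data.frame(table(key = key(trials)), stringsAsFactors = FALSE)
  } else {
    obs <- data.frame(key = character(0), Freq = integer(0))
  }
  counts <- aggregate(list(expected = expected$n),
                      by = list(key = key(expected)), FUN = sum)
  counts$observed <- obs$Freq[match(counts$key, obs$key)]
  counts$observed[is.na(counts$observed)] <- 0L
  extra <- setdiff(obs$key, counts$key)
  if (length(extra)) {
    violations <- c(violations,
                    paste0("unexpected combination(s): ",
                           paste(extra, collapse = "; ")))
  }
  bad <- counts$observed != counts$expected
  if (any(bad)) {
    violations <- c(violations,
                    paste0("count mismatch for ", counts$key[bad], ": got ",
                           counts$observed[bad], ", expected ",
                           counts$expected[bad]))
  }
  max_dev <- if (nrow(trials)) max(abs(window_means(trials, design$window))) else 0
  if (nrow(trials) && max_dev > 1e-9) {
    violations <- c(violations,
                    sprintf("zero-mean window violated: max |window mean| = %.4g deg",
                            max_dev))
  }
  block_sizes <- if (nrow(trials)) as.integer(table(trials$block)) else integer(0)
  if (isTRUE(design$miniblocks) && nrow(trials)) {
    if (length(block_sizes) != 4L || any(block_sizes != 201L)) {
      violations <- c(violations, "exp1a must have 4 mini-blocks of 201 trials")
    }
    mixed <- vapply(split(trials, trials$block), function(blk) {
      any(blk$clamp_deg != 0) && any(blk$jump_deg != 0)
    }, logical(1))
    if (any(mixed)) {
      violations <- c(violations,
                      "mini-block mixes clamp and target-jump perturbations")
    }
  }
  list(n_trials = nrow(trials), counts = counts, max_window_dev = max_dev,
       block_sizes = block_sizes, violations = violations)
}
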