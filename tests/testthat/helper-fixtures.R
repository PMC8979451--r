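# Shared fixtures: parameter sets and small synthetic tables built in code.

# u0 covering every clamp magnitude any experiment design uses.
full_u0 <- function() {
  c("0" = 0, "3" = 0.5, "4" = 0.6, "7" = 0.9, "16" = 1.0)
}

paper_params <- function(u0 = c("3" = 0.5, "7" = 0.9),
                         u0_composition = "constrained") {
  model_params(u0 = u0, c_j = 0.84, sigma_d = 11.8, beta_te = 0.02,
               u0_composition = u0_composition)
}

all_params <- function(u0 = full_u0(), ...) {
  model_params(u0 = u0, gamma_r = 0.3, sigma_r = 2, c_j = 0.84,
               sigma_d = 11.8, beta_te = 0.02, ...)
}

# Hand-written trial table with a known layout.
make_trials <- function(hand, participant_id = "p1", block = 1L,
                        clamp = 0, jump = 0, feedback = "clamp") {
  n <- length(hand)
  data.frame(participant_id = participant_id,
             trial_index = seq_len(n),
             block_index = block,
             clamp_deg = rep_len(clamp, n),
             jump_deg = rep_len(jump, n),
             jump_event = rep_len(jump, n) != 0,
             feedback_type = rep_len(feedback, n),
             hand_angle_deg = hand,
             excluded = FALSE)
}

# Independent brute-force oracle for the outlier rule: leave-one-out
# centered window mean, raw-pass block SD, single pass.
brute_force_outliers <- function(hand, window = 5L, z = 3) {
  n <- length(hand)
  half <- (window - 1L) %/% 2L
  sd_blk <- max(stats::sd(hand), 1e-9)
  vapply(seq_len(n), function(i) {
    win <- setdiff(max(1L, i - half):min(n, i + half), i)
    abs(hand[i] - mean(hand[win])) > z * sd_blk
  }, logical(1))
}

# Group condition means predicted exactly by a model over the exp4 designs.
exact_exp4_means <- function(spec, params) {
  grids <- list(`3` = c(-30, -17, -10, -3, 0, 3, 7, 10, 17, 30),
                `7` = c(-30, -17, -10, -3, 0, 3, 7, 10, 17, 30))
  rows <- lapply(names(grids), function(cm) {
    g <- grids[[cm]]
    data.frame(clamp_mag = as.numeric(cm), jump_rel = g,
               jump_event = g != 0, feedback = TRUE)
  })
  cm <- do.call(rbind, rows)
  cm$mean <- predict_total_update(spec, params,
                                  conditions(cm$clamp_mag, cm$jump_rel,
                                             cm$jump_event, cm$feedback))
  cm$sem <- 0.01
  cm
}

# Independent brute-force lattice oracle for the 3-parameter fits: the model
# curves are re-derived here from the algebra (not via the package's predict
# functions), evaluated on every lattice point over the fitting bounds.
lattice_oracle <- function(model_id, cm, u0, n_grid = 41L) {
  b <- default_bounds()
  free <- model_spec(model_id)$free_params
  grids <- lapply(stats::setNames(free, free), function(pn)
    seq(b$lower[[pn]], b$upper[[pn]], length.out = n_grid))
  pts <- as.matrix(expand.grid(grids))
  u0v <- u0[as.character(format(cm$clamp_mag, trim = TRUE))]
  sse <- numeric(nrow(pts))
  for (i in seq_len(nrow(cm))) {
    base <- u0v[i] - pts[, "beta_te"] * cm$clamp_mag[i]  # constrained u0
    spe <- if (model_id == "distracted_spe_te") {
      if (cm$jump_event[i]) {
        pts[, "c_j"] * base * exp(-cm$jump_rel[i]^2 / (2 * pts[, "sigma_d"]^2))
      } else base
    } else {
      base - pts[, "gamma_r"] *
        exp(-(cm$clamp_mag[i] - cm$jump_rel[i])^2 / (2 * pts[, "sigma_r"]^2))
    }
    pred <- spe + pts[, "beta_te"] * (cm$clamp_mag[i] - cm$jump_rel[i])
    sse <- sse + (cm$mean[i] - pred)^2
  }
  best <- which.min(sse)
  list(sse = sse[best], par = pts[best, ],
       cell = vapply(grids, function(g) diff(g[1:2]), numeric(1)))
}
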