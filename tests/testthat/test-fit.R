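test_that("a model fitted to its own noiseless predictions is perfect", {
  spec <- model_spec("invariant_spe")
  cm <- exact_exp4_means(spec, model_params(c("3" = 0.5, "7" = 0.9)))
  fit <- fit_model(spec, cm)
  expect_equal(fit$sse, 0)
  expect_equal(fit$r2, 1)
  expect_true(fit$converged)
})

test_that("free parameters are recovered from exact model curves", {
  spec <- model_spec("distracted_spe_te")
  truth <- paper_params()
  cm <- exact_exp4_means(spec, truth)
  fit <- fit_model(spec, cm, n_starts = 10, seed = 2,
                   u0_composition = "constrained")
  expect_equal(unname(fit$free["c_j"]), 0.84, tolerance = 1e-4)
  expect_equal(unname(fit$free["sigma_d"]), 11.8, tolerance = 1e-3)
  expect_equal(unname(fit$free["beta_te"]), 0.02, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-8)
  # row order and seed do not move a unique optimum
  perm <- cm[rev(seq_len(nrow(cm))), ]
  fit2 <- fit_model(spec, perm, n_starts = 10, seed = 77,
                    u0_composition = "constrained")
  expect_equal(fit2$free, fit$free, tolerance = 1e-3)
})

test_that("nesting: the larger model never fits worse", {
  set.seed(5)
  cm <- exact_exp4_means(model_spec("distracted_spe_te"), paper_params())
  cm$mean <- cm$mean + rnorm(nrow(cm), 0, 0.05)
  u0 <- c("3" = cm$mean[cm$clamp_mag == 3 & cm$jump_rel == 0],
                           "7" = cm$mean[cm$clamp_mag == 7 & cm$jump_rel == 0])
  for (fam in c("invariant", "rewarded", "distracted")) {
    small <- fit_model(model_spec(paste0(fam, "_spe")), cm, u0_fixed = u0,
                       seed = 3)
    large <- fit_model(model_spec(paste0(fam, "_spe_te")), cm, u0_fixed = u0,
                       seed = 3)
    expect_true(large$sse <= small$sse + 1e-9, info = fam)
  }
})

test_that("R2 and AIC follow the stated conventions", {
  # the grand-mean predictor scores exactly R2 = 0
  cm <- data.frame(clamp_mag = 3, jump_rel = c(-3, 0, 3),
                   jump_event = c(TRUE, FALSE, TRUE), feedback = TRUE,
                   mean = c(0.2, 0.5, 0.4))
  u0_flat <- c("3" = mean(cm$mean))
  fit_flat <- fit_model(model_spec("invariant_spe"), cm, u0_fixed = u0_flat)
  expect_equal(fit_flat$r2, 0)
  # a constant model pinned away from the grand mean scores negative R2
  fit_bad <- fit_model(model_spec("invariant_spe"), cm,
                       u0_fixed = c("3" = 0.9))
  expect_lt(fit_bad$r2, 0)
  # an extra free parameter that cannot reduce SSE costs exactly +2 AIC
  cm2 <- exact_exp4_means(model_spec("invariant_spe"),
                          model_params(c("3" = 0.5, "7" = 0.9)))
  set.seed(8)
  cm2$mean <- cm2$mean + rnorm(nrow(cm2), 0, 0.1)
  u0 <- stats::setNames(cm2$mean[cm2$jump_rel == 0], c("3", "7"))
  f0 <- fit_model(model_spec("invariant_spe"), cm2, u0_fixed = u0)
  f1 <- fit_model(model_spec("invariant_spe_te"), cm2, u0_fixed = u0,
                  bounds = list(lower = c(beta_te = 0),
                                upper = c(beta_te = 1e-12)))
  expect_equal(f1$sse, f0$sse, tolerance = 1e-8)
  expect_equal(f1$aic - f0$aic, 2, tolerance = 1e-6)
})

test_that("model comparison ranks by AIC and rejects mixed data", {
  cm <- exact_exp4_means(model_spec("distracted_spe_te"), paper_params())
  set.seed(10)
  cm$mean <- cm$mean + rnorm(nrow(cm), 0, 0.03)
  fits <- lapply(model_ids(), function(m)
    fit_model(model_spec(m), cm, seed = 4, u0_composition = "constrained"))
  tab <- compare_models(fits)
  expect_identical(tab$model_id[1], "distracted_spe_te")
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  short <- fit_model(model_spec("invariant_spe"), cm[1:10, ],
                     u0_fixed = c("3" = 0.5, "7" = 0.9))
  expect_error(compare_models(list(fits[[1]], short)), "not comparable")
})

test_that("optimizer matches a brute-force lattice for 3-parameter models", {
  cases <- list(
    distracted_spe_te = paper_params(),
    rewarded_spe_te = model_params(c("3" = 0.5, "7" = 0.9), gamma_r = 0.3,
                                   sigma_r = 5, beta_te = 0.02,
                                   u0_composition = "constrained"))
  for (m in names(cases)) {
    spec <- model_spec(m)
    cm <- exact_exp4_means(spec, cases[[m]])
    cm$mean <- cm$mean + rep_len(c(0.01, -0.01), nrow(cm))  # fixed jitter
    u0 <- c("3" = 0.5, "7" = 0.9)
    brute <- lattice_oracle(m, cm, u0)
    fit <- fit_model(spec, cm, u0_fixed = u0, n_starts = 10, seed = 6,
                     u0_composition = "constrained")
    expect_true(fit$sse <= brute$sse + 1e-9, info = m)
    expect_true(all(abs(brute$par - fit$free[names(brute$par)]) <=
                      brute$cell + 1e-9), info = m)
  }
})

test_that("bootstrap is deterministic and degenerates correctly", {
  spec <- model_spec("distracted_spe_te")
  cfg <- sim_config(spec, paper_params(), noise_sd = 0.1,
                    n_participants = 8, between_subject_sd = 0.1, seed = 31)
  co <- simulate_cohort("exp4a", cfg)
  co2 <- simulate_cohort("exp4b", cfg)
  co2$participant_id <- paste0("b_", co2$participant_id)
  trials <- rbind(co, co2)
  b1 <- bootstrap_ci(trials, spec, B = 3, seed = 12, n_starts = 3,
                     u0_composition = "constrained")
  b2 <- bootstrap_ci(trials, spec, B = 3, seed = 12, n_starts = 3,
                     u0_composition = "constrained")
  expect_identical(b1$samples, b2$samples)
  expect_identical(dim(b1$samples), c(3L, 3L))
  # noiseless homogeneous cohort: every resample refits identically
  cfg0 <- sim_config(spec, paper_params(), noise_sd = 0, n_participants = 4,
                     between_subject_sd = 0, seed = 7)
  tr0 <- rbind(simulate_cohort("exp4a", cfg0),
               transform(simulate_cohort("exp4b", cfg0),
                         participant_id = paste0("b_", participant_id)))
  b0 <- bootstrap_ci(tr0, spec, B = 3, seed = 5, n_starts = 3,
                     u0_composition = "constrained")
  expect_lt(max(apply(b0$samples, 2, stats::sd)), 1e-4)
  expect_lt(max(abs(b0$ci["97.5%", ] - b0$ci["2.5%", ])), 1e-4)
})

test_that("derived quantities reproduce the worked examples", {
  spec <- model_spec("distracted_spe_te")
  cm <- exact_exp4_means(spec, paper_params())
  fit <- fit_model(spec, cm, n_starts = 10, seed = 2,
                   u0_composition = "constrained")
  dq <- derived_quantities(fit, c("3" = 0.5, "7" = 0.9))
  expect_equal(unname(dq$te_fraction_pct["3"]), 12.0, tolerance = 0.01)
  expect_equal(unname(dq$te_fraction_pct["7"]), 100 * 0.02 * 7 / 0.9,
               tolerance = 0.01)
  expect_equal(dq$fixed_cost_pct, 16, tolerance = 0.01)
  expect_equal(dq$effective_jump_range_deg, 35.4, tolerance = 0.01)
  expect_error(derived_quantities(fit, c("3" = 0)), "zero no-jump mean")
  # c_j = 1 means no fixed cost
  p1 <- model_params(c("3" = 0.5, "7" = 0.9), c_j = 1, sigma_d = 11.8,
                     beta_te = 0.02, u0_composition = "constrained")
  cm1 <- exact_exp4_means(spec, p1)
  f1 <- fit_model(spec, cm1, u0_fixed = c("3" = 0.5, "7" = 0.9), seed = 3,
                  u0_composition = "constrained")
  expect_equal(derived_quantities(f1)$fixed_cost_pct, 0, tolerance = 0.1)
})
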