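test_that("model specs carry the documented free-parameter counts", {
  k <- vapply(model_ids(), function(m) model_spec(m)$k, integer(1))
  expect_identical(unname(k[c("invariant_spe", "invariant_spe_te",
                              "rewarded_spe", "rewarded_spe_te",
                              "distracted_spe", "distracted_spe_te")]),
                   c(0L, 1L, 2L, 3L, 2L, 3L))
  expect_error(model_spec("dual_error"), "unknown model id")
})

test_that("SPE predictions follow the three family equations", {
  u0 <- c("3" = 0.5)
  inv <- model_spec("invariant_spe")
  # invariance to the jump by definition
  expect_equal(predict_spe_update(inv, model_params(u0),
                                  conditions(3, 17)), 0.5)
  # jump-in-place isolates the fixed cost: 0.84 * 0.5 = 0.42
  dis <- model_spec("distracted_spe")
  p_dis <- model_params(u0, c_j = 0.84, sigma_d = 11.8)
  expect_equal(predict_spe_update(dis, p_dis,
                                  conditions(3, 0, jump_event = TRUE)),
               0.84 * 0.5)
  # no-jump trials bypass the attentional cost entirely
  expect_equal(predict_spe_update(dis, p_dis, conditions(3, 0)), 0.5)
  # direct evaluation of the Gaussian decay on a jump trial
  expect_equal(predict_spe_update(dis, p_dis, conditions(3, 10)),
               0.84 * 0.5 * exp(-100 / (2 * 11.8^2)))
  # rewarded attenuation maximal at jump-to, symmetric about it
  rew <- model_spec("rewarded_spe")
  p_rew <- model_params(u0, gamma_r = 0.4, sigma_r = 2)
  at <- function(j) predict_spe_update(rew, p_rew, conditions(3, j))
  expect_lt(at(3), at(0))
  expect_lt(at(3), at(6))
  expect_equal(at(3 - 1.5), at(3 + 1.5))
})

test_that("parameter reductions collapse onto Invariant SPE", {
  grid <- c(-20, -7, -3, 0, 3, 7, 20)
  cond <- conditions(3, grid, jump_event = grid != 0)
  u0 <- c("3" = 0.5)
  base <- predict_spe_update(model_spec("invariant_spe"), model_params(u0), cond)
  rew0 <- predict_spe_update(model_spec("rewarded_spe"),
                             model_params(u0, gamma_r = 0, sigma_r = 5), cond)
  dis0 <- predict_spe_update(model_spec("distracted_spe"),
                             model_params(u0, c_j = 1, sigma_d = 1e6), cond)
  expect_equal(rew0, base)
  expect_equal(dis0, base, tolerance = 1e-6)
})

test_that("the TE process is linear in clamp-minus-jump", {
  p <- model_params(c("3" = 0.5), beta_te = 0.02)
  expect_equal(predict_te_update(p, conditions(3, 0)), 0.06)
  expect_equal(predict_te_update(p, conditions(3, 3)), 0)   # jump-to nullifies TE
  expect_equal(predict_te_update(p, conditions(3, -3)), 0.12)
  p4 <- model_params(c("4" = 1.5), beta_te = 0.02)
  # jump-past reduces the total update: 1.5 + 0.02 * (4 - 8)
  expect_equal(predict_total_update(model_spec("invariant_spe_te"), p4,
                                    conditions(4, 8)), 1.42)
})

test_that("total update composes SPE and TE additively", {
  p <- paper_params(u0 = c("3" = 0.5), u0_composition = "literal")
  # literal composition: no-jump total = u0 + beta_te * clamp
  expect_equal(predict_total_update(model_spec("distracted_spe_te"), p,
                                    conditions(3, 0)), 0.5 + 0.06)
  pc <- paper_params(u0 = c("3" = 0.5), u0_composition = "constrained")
  # constrained composition: no-jump total reproduces u0 exactly
  expect_equal(predict_total_update(model_spec("distracted_spe_te"), pc,
                                    conditions(3, 0)), 0.5)
  # beta_te = 0 collapses every spe_te model onto its spe_only counterpart
  grid <- seq(-30, 30, by = 3)
  cond <- conditions(7, grid, jump_event = grid != 0)
  for (fam in c("invariant", "rewarded", "distracted")) {
    p0 <- model_params(c("7" = 0.9), gamma_r = 0.3, sigma_r = 2,
                       c_j = 0.84, sigma_d = 11.8, beta_te = 0)
    expect_equal(
      predict_total_update(model_spec(paste0(fam, "_spe_te")), p0, cond),
      predict_total_update(model_spec(paste0(fam, "_spe")), p0, cond),
      info = fam)
  }
})

test_that("no-feedback conditions zero the SPE process only", {
  p <- paper_params(u0 = c("0" = 0, "3" = 0.5))
  cond <- conditions(0, 16, feedback = FALSE)
  expect_equal(predict_total_update(model_spec("distracted_spe"), p, cond), 0)
  expect_equal(predict_total_update(model_spec("distracted_spe_te"), p, cond),
               predict_te_update(p, cond))
})

test_that("condition curves show the documented symmetry signatures", {
  g <- c(-24, -12, -6, 6, 12, 24)
  p <- all_params()
  sym <- predict_condition_curve(model_spec("distracted_spe"), p, 7, g)
  expect_equal(sym$update[1:3], rev(sym$update[4:6]))  # even in jump_rel
  asym <- predict_condition_curve(model_spec("distracted_spe_te"), p, 7, g)
  # jump-away branch exceeds jump-toward by exactly 2 * beta_te * |jump|
  expect_equal(asym$update[1:3] - rev(asym$update[4:6]),
               2 * 0.02 * c(24, 12, 6))
  flat <- predict_condition_curve(model_spec("invariant_spe"), p, 7, g)
  expect_equal(flat$update, rep(flat$update[1], 6))
  # monotone decreasing in jump_rel on [0, clamp] for distracted spe+te
  fine <- predict_condition_curve(model_spec("distracted_spe_te"), p, 7,
                                  seq(0.5, 7, by = 0.5))
  expect_true(all(diff(fine$update) < 0))
  # jump-in-place vs no-jump isolates c_j for distracted spe-only
  jip <- predict_condition_curve(model_spec("distracted_spe"), p, 7, 0,
                                 zero_jump_event = TRUE)$update
  nj <- predict_condition_curve(model_spec("distracted_spe"), p, 7, 0)$update
  expect_equal(jip / nj, 0.84)
})

test_that("configuration and domain errors are informative", {
  p <- model_params(c("3" = 0.5), c_j = 0.84, sigma_d = 11.8)
  expect_error(predict_spe_update(model_spec("distracted_spe"), p,
                                  conditions(5, 0)),
               "no u0 entry for clamp magnitude 5")
  bad <- model_params(c("3" = 0.5), c_j = 0.84, sigma_d = -1)
  expect_error(predict_spe_update(model_spec("distracted_spe"), bad,
                                  conditions(3, 2)),
               "sigma_d must be strictly positive")
  expect_error(conditions(3, jump_rel = 4, jump_event = FALSE),
               "jump_event")
  expect_error(conditions(-3, 0), "clamp_mag")
})
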