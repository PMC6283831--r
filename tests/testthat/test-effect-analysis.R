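resp_from_values <- function(design, values) {
  response_table(data.frame(run_id = design$run_id, dry_cell_mass = values,
                            titer = values, yield = 1))
}

test_that("main-effect REM matches the hand formula", {
  d <- full_factorial(toy_factors(2))  # codes f1: -,+,-,+ ; f2: -,-,+,+
  rt <- resp_from_values(d, c(10, 20, 10, 20))
  e <- rem_main(d, rt, "f1", "dry_cell_mass")
  expect_equal(e$rem, abs(20 - 10) / 15)  # 0.6667
  expect_equal(e$signed_effect, 10)
  expect_equal(e$denominator, 15)
  # constant response -> zero effect
  e0 <- rem_main(d, resp_from_values(d, rep(5, 4)), "f1", "dry_cell_mass")
  expect_equal(e0$rem, 0)
  # scale invariance under positive rescaling
  e2 <- rem_main(d, resp_from_values(d, 17 * c(10, 20, 10, 20)),
                 "f1", "dry_cell_mass")
  expect_equal(e2$rem, e$rem)
  # zero overall mean is an error
  expect_error(rem_main(d, resp_from_values(d, c(-1, 1, -1, 1)),
                        "f1", "dry_cell_mass"), "zero")
})

test_that("interaction REM is the printed four-cell contrast over the mean", {
  d <- full_factorial(toy_factors(2))
  # cells: (-,-)=1, (+,-)=2, (-,+)=2, (+,+)=4; mean 2.25
  rt <- resp_from_values(d, c(1, 2, 2, 4))
  e <- rem_interaction(d, rt, "f1", "f2", "dry_cell_mass")
  expect_equal(e$rem, abs(4 + 1 - 2 - 2) / 2.25)  # 0.4444, no /2
  # symmetry in the two factors
  e_swap <- rem_interaction(d, rt, "f2", "f1", "dry_cell_mass")
  expect_equal(e_swap$rem, e$rem)
  expect_equal(e_swap$signed_effect, e$signed_effect)
  # additive response has exactly zero interaction
  add <- resp_from_values(d, 5 + 2 * d$f1 + 3 * d$f2)
  expect_equal(rem_interaction(d, add, "f1", "f2", "dry_cell_mass")$rem, 0)
})

test_that("REM equals |2 beta| / mean on orthogonal designs (dual route)", {
  for (seed in 1:5) {
    ff <- fractional_factorial(toy_factors(6), p = 2)
    config <- toy_config(
      dcm_beta = c(f1 = 0.9, f2 = -0.5, f3 = 0.2, f4 = 0.1),
      titer_beta = c(f1 = 1.4, f5 = -0.7),
      noise_cv = c(dry_cell_mass = 0.05, titer = 0.08))
    rt <- sim_quiet(ff$design, config, seed = seed)
    for (rsp in c("dry_cell_mass", "titer")) {
      fit <- fit_response_model(ff$design, rt, rsp)
      beta <- coef(fit$fit)
      ybar <- mean(rt[[rsp]])
      for (fn in paste0("f", 1:6)) {
        rem <- rem_main(ff$design, rt, fn, rsp)$rem
        expect_equal(rem, abs(2 * beta[[fn]]) / ybar, tolerance = 1e-10)
      }
    }
  }
})

test_that("REM is invariant to run reordering", {
  d <- full_factorial(toy_factors(3))
  rt <- sim_quiet(d, toy_config(dcm_beta = c(f1 = 1, f2 = 0.4),
                                noise_cv = c(dry_cell_mass = 0.1, titer = 0)),
                  seed = 2)
  e1 <- rem_main(d, rt, "f1", "dry_cell_mass")
  perm <- sample(nrow(rt))
  e2 <- rem_main(d, rt[perm, ], "f1", "dry_cell_mass")
  expect_equal(e2$rem, e1$rem)
})

test_that("centerpoints are excluded from REM means and denominators", {
  d <- add_centerpoints(full_factorial(toy_factors(2)), 4)
  vals <- c(10, 20, 10, 20, 1000, 1000, 1000, 1000)
  rt <- resp_from_values(d, vals)
  e <- rem_main(d, rt, "f1", "dry_cell_mass")
  expect_equal(e$denominator, 15)  # unmoved by the wild centerpoints
  expect_equal(e$n_runs, 4)
})

test_that("all_effects enumerates mains plus pairs and matches element ops", {
  d5 <- full_factorial(toy_factors(5))
  rt <- sim_quiet(d5, toy_config(dcm_beta = c(f1 = 1),
                                 titer_beta = c(f2 = 0.5),
                                 noise_cv = c(dry_cell_mass = 0.03,
                                              titer = 0.03)), seed = 9)
  et <- all_effects(d5, rt, response = c("dry_cell_mass", "titer"))
  expect_equal(nrow(et), 2 * (5 + choose(5, 2)))
  mains <- et[is.na(et$factor2) & et$response == "dry_cell_mass", ]
  for (i in seq_len(nrow(mains))) {
    expect_equal(mains$rem[i],
                 rem_main(d5, rt, mains$factor1[i], "dry_cell_mass")$rem)
  }
  d4 <- full_factorial(toy_factors(4))
  rt4 <- resp_from_values(d4, seq_len(16))
  expect_equal(nrow(all_effects(d4, rt4, response = "dry_cell_mass")),
               4 + 6)
})

test_that("noise-free main-effects-only data has all interaction REMs at 0", {
  d <- full_factorial(toy_factors(5))
  rt <- sim_quiet(d, toy_config(
    dcm_beta = c(f1 = 1.2, f2 = -0.8, f3 = 0.3, f4 = 0.05, f5 = 0.6)),
    seed = 1)
  et <- all_effects(d, rt, response = "dry_cell_mass")
  inter <- et[!is.na(et$factor2), ]
  expect_equal(nrow(inter), 10)
  expect_true(all(inter$rem < 1e-12))
})

test_that("aliased interaction pairs report identical contrasts", {
  # resolution III: D=AB aliases f4 with f1:f2, E=AC aliases f5 with f1:f3
  ff <- fractional_factorial(toy_factors(5), p = 2,
                             generators = c("D=AB", "E=AC"))
  rt <- sim_quiet(ff$design, toy_config(
    dcm_beta = c(f1 = 1, f2 = 0.5),
    dcm_inter = c("f1:f2" = 0.4),
    noise_cv = c(dry_cell_mass = 0.05, titer = 0)), seed = 3)
  e_inter <- rem_interaction(ff$design, rt, "f1", "f2", "dry_cell_mass")
  e_main <- rem_main(ff$design, rt, "f4", "dry_cell_mass")
  # the f1:f2 contrast is twice the f4 column contrast on the same runs
  expect_equal(e_inter$rem, 2 * e_main$rem, tolerance = 1e-10)
  et <- all_effects(ff$design, rt, response = "dry_cell_mass")
  row <- et[!is.na(et$factor2) & et$factor1 == "f1" & et$factor2 == "f2", ]
  expect_match(row$aliased_with, "f4")
})

test_that("normal plot coordinates follow the Blom convention", {
  coords <- normal_plot_coords(c(a = -1, b = 0, c = 1))
  p <- (1:3 - 0.375) / (3 + 0.25)
  expect_equal(p, c(0.1923, 0.5, 0.8077), tolerance = 1e-4)
  expect_equal(coords$quantile, qnorm(p))
  expect_equal(coords$effect, c(-1, 0, 1))
  # symmetric set: median effect maps to quantile 0
  expect_equal(coords$quantile[2], 0)
  expect_error(normal_plot_coords(c(1, 2)), "at least 3")
  # half-normal variant orders absolute effects on positive quantiles
  h <- normal_plot_coords(c(-3, 1, 2, -0.5), half = TRUE)
  expect_equal(h$effect, c(0.5, 1, 2, 3))
  expect_true(all(h$quantile > 0))
  # deterministic tie-break by label
  tie <- normal_plot_coords(c(b = 1, a = 1, c = 0))
  expect_equal(tie$label, c("c", "a", "b"))
})

test_that("an injected large effect lands at the extreme of the null line", {
  d <- full_factorial(toy_factors(5))
  hits <- vapply(1:50, function(seed) {
    rt <- sim_quiet(d, toy_config(
      dcm_beta = c(f3 = 1.5),
      noise_cv = c(dry_cell_mass = 0.03, titer = 0)), seed = seed)
    et <- all_effects(d, rt, response = "dry_cell_mass")
    coords <- normal_plot_coords(et, half = TRUE)
    coords$label[nrow(coords)] == "f3"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("min-max normalization maps each response onto [0, 1] monotonically", {
  rt <- response_table(data.frame(run_id = c("a", "b", "c"),
                                  dry_cell_mass = c(4, 8, 12),
                                  titer = c(2, 1, 16),
                                  yield = c(2, 1, 16) / c(4, 8, 12)))
  nn <- normalize_responses(rt)
  expect_equal(nn$dry_cell_mass, c(0, 0.5, 1))
  expect_equal(range(nn$titer), c(0, 1))
  expect_identical(order(nn$titer), order(rt$titer))
  const <- response_table(data.frame(run_id = "a", dry_cell_mass = 1,
                                     titer = 1, yield = 1))
  expect_error(normalize_responses(rbind(const, const)), "constant")
})

test_that("linear screening models recover structure and r-squared", {
  d <- full_factorial(toy_factors(5))
  # perfect linear data: train and test r2 are 1
  rt <- sim_quiet(d, toy_config(dcm_beta = c(f1 = 1, f2 = -0.5)), seed = 1)
  fit <- fit_response_model(d, rt, "dry_cell_mass")
  expect_equal(fit$train_r2, 1, tolerance = 1e-12)
  expect_equal(score_response_model(fit, d, rt), 1, tolerance = 1e-12)
  pred <- predict(fit, d)
  expect_equal(unname(pred), rt$dry_cell_mass, tolerance = 1e-10)
  # known coefficients recovered within 3 standard errors
  cfg <- toy_config(dcm_beta = c(f1 = 0.8, f2 = -0.4, f3 = 0.2),
                    noise_cv = c(dry_cell_mass = 0.05, titer = 0))
  ok <- 0L
  for (seed in 1:20) {
    rtn <- sim_quiet(d, cfg, seed = seed)
    f <- fit_response_model(d, rtn, "dry_cell_mass")
    sm <- summary(f$fit)$coefficients
    ok <- ok + all(abs(sm[c("f1", "f2", "f3"), "Estimate"] -
                         c(0.8, -0.4, 0.2)) <=
                     3 * sm[c("f1", "f2", "f3"), "Std. Error"])
  }
  expect_gte(ok, 19)
})

test_that("pure-noise responses give near-chance train r2 and ~0 test r2", {
  d <- full_factorial(toy_factors(5))
  cfg <- toy_config(noise_cv = c(dry_cell_mass = 0.1, titer = 0))
  train_r2 <- test_r2 <- numeric(40)
  for (seed in 1:40) {
    rt <- sim_quiet(d, cfg, seed = seed)
    rt_test <- sim_quiet(d, cfg, seed = 1000 + seed)
    f <- fit_response_model(d, rt, "dry_cell_mass")
    train_r2[seed] <- f$train_r2
    test_r2[seed] <- score_response_model(f, d, rt_test)
  }
  # E[train r2] ~ p/(n-1) for p noise regressors on n runs; out of sample
  # there is no skill (slightly negative in the variance-explained form,
  # which charges the prediction variance ~ (p+1)/n)
  expect_equal(mean(train_r2), 5 / 31, tolerance = 0.35)
  expect_lt(mean(test_r2), 0.05)
  expect_gt(mean(test_r2), -0.5)
})

test_that("rank-deficient term sets are reported with the aliased culprits", {
  ff <- fractional_factorial(toy_factors(5), p = 2,
                             generators = c("D=AB", "E=AC"))
  rt <- sim_quiet(ff$design, toy_config(dcm_beta = c(f1 = 1)), seed = 1)
  # f4 = f1*f2 in this fraction: including both breaks full rank
  expect_error(fit_response_model(ff$design, rt, "dry_cell_mass",
                                  factors = paste0("f", 1:5),
                                  interactions = "f1:f2"),
               "aliased|rank")
  # squared-correlation alternative available behind the method flag
  f <- fit_response_model(ff$design, rt, "dry_cell_mass")
  expect_equal(score_response_model(f, ff$design, rt, method = "cor"), 1,
               tolerance = 1e-10)
})
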