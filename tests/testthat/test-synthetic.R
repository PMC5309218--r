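test_that("simulated outcomes are deterministic per seed and saturate correctly", {
  d <- generate_session_design(seed = 2)
  p <- reference_group_params("pe_ev", "20min")
  r1 <- simulate_participant(d, "pe_ev", p, seed = 5)
  r2 <- simulate_participant(d, "pe_ev", p, seed = 5)
  expect_identical(r1$y, r2$y)
  r3 <- simulate_participant(d, "pe_ev", p, seed = 6)
  expect_false(identical(r1$y, r3$y))
  # saturation: a maximal constant signal makes hits near-certain
  psat <- model_params("baseline", C0 = 2)
  rs <- simulate_participant(d, "baseline", psat, seed = 1)
  expect_gte(mean(rs$y), plogis(2) - 3 * sqrt(plogis(2) * (1 - plogis(2)) / 60))
  expect_true(all(encoding_probability(1e6) == 1))
})

test_that("a neutral baseline generator yields a near-half hit rate", {
  cfg <- design_config(trials_per_character = 10)
  p0 <- model_params("baseline", C0 = 0)
  hits <- unlist(lapply(1:170, function(i) {
    d <- generate_session_design(seed = i, config = cfg)
    simulate_participant(d, "baseline", p0, seed = 1000 + i)$y
  }))
  expect_gte(length(hits), 10000)
  expect_equal(mean(hits), 0.5, tolerance = 0.02)
})

test_that("cohort simulation is reproducible and sized correctly", {
  p <- reference_group_params("pe_ev", "20min")
  c1 <- simulate_cohort(25, "pe_ev", p, base_seed = 7)
  expect_length(c1, 25)
  expect_true(all(vapply(c1, function(r) length(r$y), integer(1)) == 60))
  c2 <- simulate_cohort(25, "pe_ev", p, base_seed = 7)
  expect_identical(attr(c1, "manifest"), attr(c2, "manifest"))
  expect_identical(cohort_trials(c1), cohort_trials(c2))
  expect_length(simulate_cohort(1, "pe_ev", p, base_seed = 1), 1)
  expect_error(simulate_cohort(0, "pe_ev", p, base_seed = 1), "positive")
})

test_that("cohort hit rates are calibrated to the generative probabilities", {
  p <- reference_group_params("pe_ev", "20min")
  cohort <- simulate_cohort(50, "pe_ev", p, base_seed = 31)
  tr <- cohort_trials(cohort)
  se <- sqrt(sum(tr$p_encoding * (1 - tr$p_encoding))) / nrow(tr)
  expect_lte(abs(mean(tr$test_correct) - mean(tr$p_encoding)), 3 * se)
})

test_that("fitting the generating model beats the baseline on its own data", {
  sampler <- reference_param_sampler("pe_ev", "20min")
  cohort <- simulate_cohort(25, "pe_ev", sampler, base_seed = 77)
  opt <- fit_options(grid_step_scale = 0.25, grid_step_alpha = 0.1)
  fits <- fit_cohort(cohort, models = c("baseline", "pe_ev"), options = opt)
  mean_lle <- tapply(fits$lle, fits$model, mean)
  expect_lt(mean_lle[["pe_ev"]], mean_lle[["baseline"]])
})

test_that("trait coupling hits its target Spearman correlation", {
  p <- reference_group_params("pe_ev", "20min")
  cohort19 <- simulate_cohort(19, "pe_ev", p, base_seed = 3)
  stat <- vapply(cohort19, function(r) mean(r$y), numeric(1))
  # comonotone limit
  c1 <- simulate_traits(cohort19, target_rho = 1, couple_to = stat, seed = 1)
  traits <- data.frame(participant_id = names(c1),
                       SR = vapply(c1, function(r) r$traits$SR, numeric(1)),
                       SP = vapply(c1, function(r) r$traits$SP, numeric(1)))
  bias <- sensitivity_bias(traits)
  expect_equal(spearman_rho(bias$bias, stat), 1)
  # null coupling stays inside the n = 100 sampling band
  cohort100 <- simulate_cohort(100, "pe_ev", p, base_seed = 5)
  stat100 <- vapply(cohort100, function(r) mean(r$y), numeric(1))
  c0 <- simulate_traits(cohort100, target_rho = 0, couple_to = stat100, seed = 2)
  b0 <- sensitivity_bias(data.frame(participant_id = names(c0),
                                    SR = vapply(c0, function(r) r$traits$SR, numeric(1)),
                                    SP = vapply(c0, function(r) r$traits$SP, numeric(1))))
  expect_lte(abs(spearman_rho(b0$bias, stat100)), 0.25)
  # intermediate target, mean over replicates
  rhos <- vapply(1:1000, function(i) {
    ci <- simulate_traits(cohort19, target_rho = 0.55, couple_to = stat, seed = i)
    bi <- sensitivity_bias(data.frame(
      participant_id = names(ci),
      SR = vapply(ci, function(r) r$traits$SR, numeric(1)),
      SP = vapply(ci, function(r) r$traits$SP, numeric(1))))
    spearman_rho(bi$bias, stat)
  }, numeric(1))
  expect_equal(mean(rhos), 0.55, tolerance = 0.05)
  expect_error(simulate_traits(cohort19, target_rho = 1.2, couple_to = stat,
                               seed = 1), "target_rho")
})

test_that("confidence labels are monotone in encoding probability and reproducible", {
  d <- generate_session_design(seed = 6)
  # near-certain encoding: "certain" is the modal label
  rec <- simulate_participant(d, "baseline", model_params("baseline", C0 = 2),
                              seed = 9)
  rec$p_encoding <- rep(0.999, 60)
  rec <- simulate_confidence(rec, seed = 4)
  expect_equal(names(which.max(table(rec$confidence))), "certain")
  # spread probabilities: all three labels occur at n = 600
  rec2 <- simulate_participant(d, "pe_ev", reference_group_params("pe_ev", "20min"),
                               seed = 10)
  rec2$p_encoding <- rep(seq(0.05, 0.95, length.out = 60), 10)[1:60]
  labs <- unlist(lapply(1:10, function(i) {
    simulate_confidence(rec2, seed = i)$confidence
  }))
  expect_setequal(unique(labs), c("guess", "quite_certain", "certain"))
  # determinism
  expect_identical(simulate_confidence(rec2, seed = 3)$confidence,
                   simulate_confidence(rec2, seed = 3)$confidence)
})

test_that("one session carries less likelihood information than the AIC penalty", {
  # independent logistic-regression oracle: at the reference effect sizes the
  # expected LLE advantage of the delta+V regressors (true learning rate)
  # over an intercept-only fit stays below the AIC penalty difference of 3,
  # which is why single-session cohorts cannot select the generating model
  # by mean AIC
  p <- reference_group_params("pe_ev", "20min")
  gains <- vapply(1:40, function(i) {
    d <- generate_session_design(seed = 7000 + i)
    rec <- simulate_participant(d, "pe_ev", p, seed = 8000 + i)
    tj <- trajectory_table(d, alpha = p[["alpha"]])
    g1 <- suppressWarnings(glm(rec$y ~ tj$delta + tj$V_before, family = binomial))
    g0 <- glm(rec$y ~ 1, family = binomial)
    (deviance(g0) - deviance(g1)) / 2
  }, numeric(1))
  expect_gt(mean(gains), 0.5)   # the reward terms do carry signal
  expect_lt(mean(gains), 3)     # but less than the AIC penalty difference
})
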