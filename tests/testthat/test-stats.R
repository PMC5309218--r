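make_trials <- function(participant_id, feedback, level, test_correct) {
  data.frame(participant_id = participant_id, feedback = feedback,
             level = level, test_correct = test_correct,
             stringsAsFactors = FALSE)
}

test_that("condition means aggregate per participant first", {
  # toy: 1 participant, positive feedback hits 2/2, negative 0/2
  tr <- make_trials("p1", c(1, 1, 0, 0), rep("high", 4), c(1, 1, 0, 0))
  ct <- condition_means(tr, "feedback")
  expect_equal(ct$proportion_correct[ct$feedback == 1], 1)
  expect_equal(ct$proportion_correct[ct$feedback == 0], 0)
  # all hits
  tr2 <- make_trials(rep(c("p1", "p2"), each = 4), rep(c(1, 0), 4),
                     rep(c("high", "low"), each = 2, times = 2), rep(1, 8))
  ct2 <- condition_means(tr2, c("feedback", "level"))
  expect_true(all(ct2$proportion_correct == 1))
  # participant-as-unit: unequal trial counts do not skew the cohort mean
  tr3 <- rbind(make_trials("p1", rep(1, 6), rep("high", 6), rep(1, 6)),
               make_trials("p2", rep(1, 2), rep("high", 2), rep(0, 2)))
  ct3 <- condition_means(tr3, "feedback")
  expect_equal(ct3$proportion_correct, 0.5)  # mean of 1.0 and 0.0
  expect_equal(ct3$n_trials, 8)
  # empty cells are reported, not dropped
  tr4 <- make_trials("p1", c(1, 1), c("high", "high"), c(1, 0))
  ct4 <- condition_means(tr4, "feedback")
  expect_equal(nrow(ct4), 1)  # only observed levels of the factor exist here
  expect_error(condition_means(tr4, "confidence"), "confidence")
})

test_that("sign-flip tests behave at the degenerate extremes", {
  a <- c(0.7, 0.6, 0.8, 0.55, 0.9)
  r <- paired_mc_test(a, a, n_perm = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  x0 <- rep(0, 10)
  expect_equal(one_sample_mc_test(x0, n_perm = 500, seed = 1)$p_value, 1)
  # constant unit difference at n = 25: only all-same-sign flips tie
  r2 <- paired_mc_test(rep(1, 25), rep(0, 25), n_perm = 10000, seed = 2)
  expect_equal(r2$statistic, 1)
  expect_lte(r2$p_value, 0.001)
  r3 <- one_sample_mc_test(rep(0.062, 25), n_perm = 10000, seed = 3)
  expect_lte(r3$p_value, 0.001)
  expect_gte(r3$p_value, 1 / 10001)
  expect_error(paired_mc_test(1:3, 1:4, n_perm = 10, seed = 1), "equal length")
})

test_that("sign-flip p-values are invariant to relabeling and match exact enumeration", {
  withr::with_seed(5, {
    a <- runif(12)
    b <- runif(12)
  })
  pab <- paired_mc_test(a, b, n_perm = 20000, seed = 7)
  pba <- paired_mc_test(b, a, n_perm = 20000, seed = 7)
  expect_equal(pab$p_value, pba$p_value)
  expect_equal(pab$statistic, -pba$statistic)
  exact <- oracle_exact_signflip_p(a - b)
  expect_equal(pab$p_value, exact, tolerance = 0.01)
})

test_that("type-I error of the sign-flip test is calibrated near 0.05", {
  rejections <- withr::with_seed(11, vapply(1:500, function(i) {
    x <- rnorm(25)
    one_sample_mc_test(x, n_perm = 399, seed = sample.int(1e6, 1))$p_value < 0.05
  }, logical(1)))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("character slopes reproduce exact linear fits", {
  lvl <- rep(c("low", "medium", "high"), each = 4)
  mk <- function(props) {
    y <- unlist(lapply(props, function(p) rep(c(1, 0), c(p * 4, 4 - p * 4))))
    data.frame(participant_id = "p1", feedback = rep(1, 12), level = lvl,
               test_correct = y, stringsAsFactors = FALSE)
  }
  tr <- mk(c(0.25, 0.5, 0.75))
  sl <- character_slopes(tr)
  expect_equal(sl$slope_positive, 0.25)
  expect_true(is.na(sl$slope_negative))  # no negative-feedback trials at all
  tr2 <- mk(c(0.5, 0.5, 0.5))
  expect_equal(character_slopes(tr2)$slope_positive, 0)
  # published-style level means: slope is half the high-low difference
  props <- c(low = 0.632, medium = 0.714, high = 0.756)
  x <- c(-1, 0, 1)
  slope <- sum((x - mean(x)) * (props - mean(props))) / sum((x - mean(x))^2)
  expect_equal(slope, 0.062, tolerance = 1e-3)
  expect_error(character_slopes(tr, level_coding = c(low = -1, medium = 0.5, high = 1)),
               "equally spaced")
})

test_that("scale-factor sign tests flag generative effects and respect nulls", {
  fits0 <- data.frame(participant_id = sprintf("p%d", 1:10), model = "pe",
                      C_delta = rep(0, 10), stringsAsFactors = FALSE)
  r0 <- scale_factor_sign_tests(fits0, n_perm = 500, seed = 1)
  expect_named(r0, "C_delta")
  expect_equal(r0$C_delta$p_value, 1)
  fits1 <- data.frame(participant_id = sprintf("p%d", 1:25), model = "pe_ev",
                      C_delta = withr::with_seed(2, rnorm(25, 0.725, 0.7)),
                      C_V = withr::with_seed(3, rnorm(25, 1.156, 0.9)),
                      stringsAsFactors = FALSE)
  r1 <- scale_factor_sign_tests(fits1, n_perm = 2000, seed = 4)
  expect_named(r1, c("C_delta", "C_V"))
  expect_lt(r1$C_delta$p_value, 0.05)
  expect_lt(r1$C_V$p_value, 0.05)
  mixed <- rbind(fits0, transform(fits0[1, ], model = "ev"))
  expect_error(scale_factor_sign_tests(mixed, n_perm = 10, seed = 1), "one model")
})

test_that("sensitivity bias is a centered z-score difference", {
  tr <- data.frame(participant_id = sprintf("p%d", 1:19),
                   SR = withr::with_seed(1, rnorm(19, 10, 3)),
                   SP = withr::with_seed(2, rnorm(19, 12, 4)))
  b <- sensitivity_bias(tr)
  expect_equal(mean(b$bias), 0, tolerance = 1e-12)
  # identical profiles cancel
  tr2 <- data.frame(participant_id = c("a", "b", "c"), SR = c(1, 2, 3),
                    SP = c(2, 4, 6))
  expect_equal(sensitivity_bias(tr2)$bias, rep(0, 3), tolerance = 1e-12)
  # antisymmetric cohort of two
  tr3 <- data.frame(participant_id = c("a", "b"), SR = c(1, -1), SP = c(-1, 1))
  b3 <- sensitivity_bias(tr3)$bias
  expect_equal(b3, -rev(b3))
  expect_equal(abs(b3), rep(2 * abs((1 - 0) / sd(c(1, -1))), 2))
  # missing traits excluded, zero variance rejected
  tr4 <- rbind(tr, data.frame(participant_id = "p20", SR = NA, SP = 1))
  expect_equal(nrow(sensitivity_bias(tr4)), 19)
  expect_error(sensitivity_bias(data.frame(participant_id = c("a", "b"),
                                           SR = c(1, 1), SP = c(1, 2))),
               "variance")
})

test_that("spearman correlation handles ranks, ties and degenerate input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_rho(1:5, rep(1, 5)), "constant")
  expect_error(spearman_rho(1:5, 1:4), "equal length")
})
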