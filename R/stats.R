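#' Condition-wise memory performance
#'
#' Computes the proportion of correct test responses per condition cell,
#' first within each participant (the participant is the statistical unit),
#' then averaged across the cohort with its standard error. Conditions are
#' any combination of the trial-table factors, typically `feedback`
#' (reward delivery: positive vs negative), `level` (reward anticipation:
#' high/medium/low feedback ratio), and `confidence`.
#'
#' @param trials a cohort trial table (see [cohort_trials()]) with
#'   `participant_id`, `test_correct`, and the requested factor columns.
#' @param factors character vector of factor column names.
#' @return A data.frame of class `condition_table`: one row per cell with
#'   `n_trials`, `n_participants`, `proportion_correct` (cohort mean of the
#'   per-participant proportions), and `sem`. Cells observed in no
#'   participant appear with `NA` proportions rather than being dropped.
#' @export
condition_means <- function(trials, factors) {
  missing <- setdiff(c(factors, "participant_id", "test_correct"), names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  by_pp <- aggregate(trials$test_correct,
                     by = trials[c(factors, "participant_id")],
                     FUN = mean)
  names(by_pp)[ncol(by_pp)] <- "prop"
  counts <- aggregate(trials$test_correct,
                      by = trials[c(factors)], FUN = length)
  names(counts)[ncol(counts)] <- "n_trials"
  cells <- expand.grid(lapply(trials[factors], function(f) sort(unique(f))),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(cells, counts, by = factors, all.x = TRUE)
  agg <- aggregate(by_pp$prop, by = by_pp[factors],
                   FUN = function(v) c(mean = mean(v),
                                       sem = sd(v) / sqrt(length(v)),
                                       n = length(v)))
  agg <- cbind(agg[factors], as.data.frame(agg$x))
  out <- merge(out, agg, by = factors, all.x = TRUE)
  names(out)[match(c("mean", "sem", "n"), names(out))] <-
    c("proportion_correct", "sem", "n_participants")
  out$n_trials[is.na(out$n_trials)] <- 0L
  out <- out[do.call(order, out[factors]),
             c(factors, "n_trials", "n_participants", "proportion_correct", "sem")]
  rownames(out) <- NULL
  class(out) <- c("condition_table", "data.frame")
  out
}

# Shared sign-flip engine: two-sided Monte-Carlo permutation test of
# mean(d) against 0 by randomly flipping the sign of each element.
.sign_flip_test <- function(d, n_perm, seed) {
  n <- length(d)
  obs <- mean(d)
  perm <- withr::with_seed(as.integer(seed), {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    as.numeric(signs %*% d) / n
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_permutations = as.integer(n_perm),
                 seed = as.integer(seed), sided = "two"),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> statistic %.4f, p = %.4g (%d sign-flips, seed %d)\n",
              x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Paired Monte-Carlo permutation test
#'
#' Two-sided sign-flip test of the mean paired difference `mean(a - b)`
#' against 0: the null distribution is built by randomly flipping the sign
#' of each participant's difference, and the p-value uses the add-one
#' correction `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so it is never
#' smaller than `1 / (n_perm + 1)`. Less sensitive to non-normality than a
#' paired t-test, which matters at small cohort sizes.
#'
#' @param a,b per-participant values, equal length >= 2.
#' @param n_perm number of random sign-flips.
#' @param seed integer seed.
#' @return A list of class `permutation_result`: `statistic`, `p_value`,
#'   `n_permutations`, `seed`, `sided`.
#' @export
paired_mc_test <- function(a, b, n_perm = 10000, seed) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  .sign_flip_test(a - b, n_perm, seed)
}

#' One-sample Monte-Carlo permutation test
#'
#' Two-sided sign-flip test of `mean(x)` against 0, with the same null
#' construction and add-one correction as [paired_mc_test()].
#'
#' @param x per-participant values, length >= 2.
#' @inheritParams paired_mc_test
#' @return A `permutation_result`.
#' @export
one_sample_mc_test <- function(x, n_perm = 10000, seed) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  .sign_flip_test(x, n_perm, seed)
}

#' Memory-vs-anticipation regression slopes
#'
#' For each participant, regresses the per-level proportion correct on a
#' numeric coding of the anticipation level (default equally spaced
#' -1/0/+1 for low/medium/high) by ordinary least squares, separately for
#' positive and negative feedback trials, and also pooled as the mean of
#' the two feedback-specific slopes. A slope is `NA` when a level is
#' entirely missing for that participant/feedback combination.
#'
#' @param trials a cohort trial table.
#' @param level_coding named numeric vector mapping `low`, `medium`, `high`
#'   to equally spaced codes.
#' @return A data.frame, one row per participant: `slope_positive`,
#'   `slope_negative`, `slope_pooled`.
#' @export
character_slopes <- function(trials,
                             level_coding = c(low = -1, medium = 0, high = 1)) {
  if (!setequal(names(level_coding), c("low", "medium", "high"))) {
    stop("`level_coding` must be named low/medium/high", call. = FALSE)
  }
  d <- diff(sort(level_coding))
  if (length(unique(round(d, 12))) != 1L) {
    stop("`level_coding` must be equally spaced", call. = FALSE)
  }
  slope_of <- function(df) {
    props <- tapply(df$test_correct, df$level, mean)
    lv <- names(props)[!is.na(props)]
    if (length(lv) < length(level_coding)) return(NA_real_)
    x <- level_coding[lv]
    yv <- as.numeric(props[lv])
    sum((x - mean(x)) * (yv - mean(yv))) / sum((x - mean(x))^2)
  }
  out <- lapply(split(trials, trials$participant_id), function(df) {
    sp <- slope_of(df[df$feedback == 1, ])
    sn <- slope_of(df[df$feedback == 0, ])
    data.frame(participant_id = df$participant_id[1],
               slope_positive = sp, slope_negative = sn,
               slope_pooled = mean(c(sp, sn)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[unique(trials$participant_id)])
  rownames(out) <- NULL
  out
}

#' Sign tests on fitted scale factors
#'
#' Applies the one-sample sign-flip test to each fitted free scale factor of
#' one model across the cohort, testing whether its average differs from 0
#' (i.e., whether that reward term contributes to memory formation).
#'
#' @param fits a fit table (see [fit_cohort()]) restricted to one model.
#' @inheritParams paired_mc_test
#' @return A named list of `permutation_result`, one per free scale factor.
#' @export
scale_factor_sign_tests <- function(fits, n_perm = 10000, seed) {
  if (length(unique(fits$model)) != 1L) {
    stop("`fits` must contain exactly one model", call. = FALSE)
  }
  spec <- model_spec(fits$model[1])
  terms <- setdiff(spec$uses, "C0")
  out <- lapply(seq_along(terms), function(i) {
    one_sample_mc_test(fits[[terms[i]]], n_perm = n_perm,
                       seed = derive_seed(seed, i))
  })
  setNames(out, terms)
}

#' Reward-vs-punishment sensitivity bias
#'
#' The bias score is the cohort-z-scored Sensitivity to Reward minus the
#' cohort-z-scored Sensitivity to Punishment (z-scores use the cohort mean
#' and the n-1 standard deviation), so its cohort mean is 0 by construction.
#'
#' @param traits data.frame with columns `participant_id`, `SR`, `SP`;
#'   participants with a missing trait are excluded.
#' @return A data.frame `participant_id`, `bias` for the complete cases.
#' @export
sensitivity_bias <- function(traits) {
  keep <- stats::complete.cases(traits[c("SR", "SP")])
  tr <- traits[keep, ]
  if (nrow(tr) < 2) stop("need at least 2 participants with both traits", call. = FALSE)
  if (sd(tr$SR) == 0 || sd(tr$SP) == 0) {
    stop("zero variance in SR or SP; bias is undefined", call. = FALSE)
  }
  zSR <- (tr$SR - mean(tr$SR)) / sd(tr$SR)
  zSP <- (tr$SP - mean(tr$SP)) / sd(tr$SP)
  data.frame(participant_id = tr$participant_id, bias = zSR - zSP,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), used to
#' relate trait scores to memory and model parameters.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input; Spearman correlation is undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}
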