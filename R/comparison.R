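#' Compare encoding models across a cohort
#'
#' Aggregates per-participant fits into mean +/- SEM of LLE and AIC per
#' model, declares the model with the lowest mean AIC the winner, and tests
#' it against every competitor with a paired sign-flip permutation test on
#' the per-participant AIC differences. Ties in mean AIC are broken by fewer
#' free parameters, then by fixed model-name order (with a message).
#'
#' @param fits a fit table covering every participant under every model
#'   (see [fit_cohort()]).
#' @param n_perm permutations for the pairwise tests.
#' @param seed integer seed for the permutation tests.
#' @return A list of class `comparison_result`: `summary` (data.frame:
#'   `model`, `k`, `mean_lle`, `sem_lle`, `mean_aic`, `sem_aic`,
#'   `p_vs_best`), `best_model`, `n_participants`.
#' @export
compare_models <- function(fits, n_perm = 10000, seed = 1L) {
  models <- intersect(model_names(), unique(fits$model))
  if (length(models) < 2) {
    stop("model comparison needs fits from at least two models", call. = FALSE)
  }
  participants <- unique(fits$participant_id)
  grid <- expand.grid(participant_id = participants, model = models,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(fits$participant_id, fits$model)
  gaps <- grid[!paste(grid$participant_id, grid$model) %in% have, ]
  if (nrow(gaps)) {
    stop("missing fits for: ",
         paste(sprintf("%s/%s", gaps$participant_id, gaps$model), collapse = ", "),
         call. = FALSE)
  }

  sem <- function(v) sd(v) / sqrt(length(v))
  summary <- do.call(rbind, lapply(models, function(m) {
    f <- fits[fits$model == m, ]
    data.frame(model = m, k = f$k[1], mean_lle = mean(f$lle), sem_lle = sem(f$lle),
               mean_aic = mean(f$aic), sem_aic = sem(f$aic),
               p_vs_best = NA_real_, stringsAsFactors = FALSE)
  }))

  eps <- 1e-12
  best_aic <- min(summary$mean_aic)
  cand <- summary[summary$mean_aic <= best_aic + eps, ]
  if (nrow(cand) > 1L) {
    cand <- cand[order(cand$k, match(cand$model, model_names())), ]
    message("mean AIC tie; broken by parameter count then model-name order")
  }
  best <- cand$model[1]

  aic_of <- function(m) {
    f <- fits[fits$model == m, ]
    f$aic[match(participants, f$participant_id)]
  }
  best_aics <- aic_of(best)
  for (i in seq_len(nrow(summary))) {
    m <- summary$model[i]
    if (m == best) next
    res <- paired_mc_test(best_aics, aic_of(m), n_perm = n_perm,
                          seed = derive_seed(seed, i))
    summary$p_vs_best[i] <- res$p_value
  }
  rownames(summary) <- NULL
  structure(list(summary = summary, best_model = best,
                 n_participants = length(participants)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d participants; best model: %s\n",
              x$n_participants, x$best_model))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Final expected values per anticipation level under fitted learning rates
#'
#' Recomputes each participant's value trajectories using that participant's
#' fitted learning rate, takes the final expected value of every character,
#' averages within participant by anticipation level, and reports cohort
#' mean +/- SEM per level. With reward learning present the levels order as
#' high > medium > low.
#'
#' @param fits a fit table restricted to one model that fits `alpha`.
#' @param cohort the cohort the fits came from (list of
#'   `participant_record`s), providing each participant's design.
#' @param V0 initial expected value.
#' @return A data.frame: `level`, `mean_V_final`, `sem_V_final`,
#'   `n_participants`.
#' @export
aggregate_final_values <- function(fits, cohort, V0 = 0.5) {
  if (length(unique(fits$model)) != 1L) {
    stop("`fits` must contain exactly one model", call. = FALSE)
  }
  if (!model_spec(fits$model[1])$needs_alpha) {
    stop("model '", fits$model[1], "' has no learning rate", call. = FALSE)
  }
  per_pp <- lapply(seq_len(nrow(fits)), function(i) {
    rec <- cohort[[fits$participant_id[i]]]
    if (is.null(rec)) stop("cohort has no record for ", fits$participant_id[i],
                           call. = FALSE)
    tj <- value_trajectories(rec$design, alpha = fits$alpha[i], V0 = V0)
    vf <- vapply(tj, function(t) t$V_final, numeric(1))
    lv <- rec$design$characters$level[match(names(vf), rec$design$characters$character_id)]
    tapply(vf, lv, mean)
  })
  levels <- c("high", "medium", "low")
  mat <- do.call(rbind, lapply(per_pp, function(v) v[levels]))
  data.frame(level = levels,
             mean_V_final = colMeans(mat),
             sem_V_final = apply(mat, 2, sd) / sqrt(nrow(mat)),
             n_participants = nrow(mat),
             row.names = NULL, stringsAsFactors = FALSE)
}
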