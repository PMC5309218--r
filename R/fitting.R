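#' Bernoulli negative log-likelihood
#'
#' The quantity minimized when fitting an encoding model:
#' `-sum(y * log(p) + (1 - y) * log(1 - p))` over trials. It is the
#' cross-entropy between observed hits/misses and the model's per-trial
#' encoding probabilities; bounded parameter vectors keep `p` strictly inside
#' (0, 1) so the value is always finite.
#'
#' @param y binary outcomes (1 = hit, 0 = miss).
#' @param p predicted encoding probabilities, strictly inside (0, 1).
#' @return Non-negative scalar; 0 only if every trial is predicted with
#'   certainty and correctly.
#' @export
negative_log_likelihood <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` must have equal length", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  if (any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Akaike Information Criterion from a fitted deviance
#'
#' `AIC = 2 * k + 2 * nll`, where `nll` is the minimized negative
#' log-likelihood and `k` the number of free parameters.
#'
#' @param k number of free parameters.
#' @param lle minimized negative log-likelihood.
#' @return The AIC value.
#' @export
aic_from_lle <- function(k, lle) 2 * k + 2 * lle

#' Options controlling the two-stage maximum-likelihood fit
#'
#' Fitting proceeds in two stages: an exhaustive scan of the bounded
#' parameter grid, then a Nelder-Mead refinement restricted to a box of one
#' grid step around the grid optimum (clipped to the global bounds). The
#' default grid uses steps of 0.1 for the scale factors over \[-2, 2\] and
#' 0.05 for the learning rate over \[0, 1\]; a finer grid (down to the 0.01
#' step that makes the refinement box +/-0.01) can be requested for models
#' with few free parameters, subject to `eval_budget`.
#'
#' @param grid_step_scale grid step for the scale factors.
#' @param grid_step_alpha grid step for the learning rate.
#' @param V0 initial expected value for the trajectories.
#' @param refine logical; run the Nelder-Mead refinement stage.
#' @param refine_radius half-width of the refinement box; defaults to one
#'   grid step per dimension.
#' @param eval_budget maximum number of grid points scanned per fit.
#' @param simplex_reltol,simplex_maxit Nelder-Mead convergence controls.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(grid_step_scale = 0.1, grid_step_alpha = 0.05,
                        V0 = 0.5, refine = TRUE, refine_radius = NULL,
                        eval_budget = 2.5e7,
                        simplex_reltol = 1e-8, simplex_maxit = 2000) {
  stopifnot(grid_step_scale > 0, grid_step_alpha > 0, eval_budget > 0)
  .assert_scalar_in(V0, 0, 1, "V0")
  structure(list(grid_step_scale = grid_step_scale,
                 grid_step_alpha = grid_step_alpha, V0 = V0, refine = refine,
                 refine_radius = refine_radius, eval_budget = eval_budget,
                 simplex_reltol = simplex_reltol, simplex_maxit = simplex_maxit),
            class = "fit_options")
}

# Negative log-likelihood of one full parameter vector on one session.
nll_for_params <- function(model, design, y, params, V0 = 0.5) {
  model <- as_model_spec(model)
  alpha <- if (model$needs_alpha) params[["alpha"]] else 0
  traj <- trajectory_table(design, alpha = alpha, V0 = V0)
  R <- params[["C0"]] + params[["C_delta"]] * traj$delta +
    params[["C_absdelta"]] * abs(traj$delta) + params[["C_V"]] * traj$V_before
  negative_log_likelihood(y, plogis(R))
}

# Regressor matrix for the model's free scale factors at a given alpha:
# columns ordered as model$uses (C0 first).
free_regressors <- function(model, design, alpha, V0) {
  traj <- trajectory_table(design, alpha = alpha, V0 = V0)
  cols <- list(C0 = rep(1, nrow(traj)), C_delta = traj$delta,
               C_absdelta = abs(traj$delta), C_V = traj$V_before)
  do.call(cbind, cols[model$uses])
}

# Scale-factor grid in lexicographic order (C0 most significant), one row per
# combination, columns ordered as model$uses.
scale_grid <- function(model, step) {
  vals <- seq(SCALE_BOUNDS[1], SCALE_BOUNDS[2], by = step)
  nm <- model$uses
  g <- expand.grid(rev(replicate(length(nm), vals, simplify = FALSE)),
                   KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g)[, rev(seq_along(nm)), drop = FALSE]
  colnames(g) <- nm
  g
}

#' Stage one: exhaustive grid search
#'
#' Scans every combination of the model's free scale factors (step
#' `grid_step_scale` over \[-2, 2\]) and, for models using the value
#' trajectory, every learning-rate value (step `grid_step_alpha` over
#' \[0, 1\]), and returns the grid point minimizing the negative
#' log-likelihood. The scan is deterministic; ties are broken by the first
#' minimum encountered in lexicographic parameter order (learning rate most
#' significant, then scale factors with `C0` outermost).
#'
#' @param model a `model_spec` or name.
#' @param design a `session_design`.
#' @param y binary test outcomes, one per design trial.
#' @param options a [fit_options()].
#' @return A list with `params` (full named vector at the grid optimum),
#'   `grid_lle`, and `n_points` scanned.
#' @export
grid_search <- function(model, design, y, options = fit_options()) {
  model <- as_model_spec(model)
  if (length(y) != nrow(design$trials)) {
    stop("`y` must have one entry per design trial", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  alphas <- if (model$needs_alpha) {
    seq(ALPHA_BOUNDS[1], ALPHA_BOUNDS[2], by = options$grid_step_alpha)
  } else NA_real_
  n_vals <- length(seq(SCALE_BOUNDS[1], SCALE_BOUNDS[2], by = options$grid_step_scale))
  n_points <- n_vals^length(model$uses) * length(alphas)
  if (n_points > options$eval_budget) {
    stop(sprintf(paste0(
      "grid of %.3g points exceeds the evaluation budget (%.3g); ",
      "use the coarser default steps (scale 0.1, alpha 0.05) or raise `eval_budget`"),
      n_points, options$eval_budget), call. = FALSE)
  }
  G <- scale_grid(model, options$grid_step_scale)
  sgn <- 1 - 2 * y
  # Warm-start pruning bound: the intercept-only fit at the grid point
  # nearest logit(mean(y)) is an upper bound on the grid minimum, so rows
  # whose partial sums exceed it are discarded early without affecting the
  # argmin (the bound carries a 1e-9 slack so the bounding point itself is
  # still recorded when scanned).
  c0_snap <- round(qlogis(max(min(mean(y), 0.999), 0.001)) / options$grid_step_scale) *
    options$grid_step_scale
  c0_snap <- min(max(c0_snap, SCALE_BOUNDS[1]), SCALE_BOUNDS[2])
  warm <- c(C0 = c0_snap, C_delta = 0, C_absdelta = 0, C_V = 0,
            alpha = if (model$needs_alpha) alphas[1] else NA_real_)
  bound <- nll_for_params(model, design, y, warm, V0 = options$V0) + 1e-9
  best <- list(nll = bound, alpha = if (model$needs_alpha) alphas[1] else NA_real_,
               index = NA_integer_)
  for (a in alphas) {
    X <- free_regressors(model, design, alpha = if (is.na(a)) 0 else a,
                         V0 = options$V0)
    res <- grid_nll_min(X * sgn, G, best$nll)
    if (res$index > 0) best <- list(nll = res$nll, alpha = a, index = res$index)
  }
  if (is.na(best$index)) {
    # nothing on the grid beat the warm-start bound; rescan the warm alpha
    # slice without it (can only happen within the 1e-9 slack)
    X <- free_regressors(model, design,
                         alpha = if (model$needs_alpha) alphas[1] else 0,
                         V0 = options$V0)
    res <- grid_nll_min(X * sgn, G, Inf)
    best <- list(nll = res$nll, alpha = best$alpha, index = res$index)
  }
  params <- c(C0 = 0, C_delta = 0, C_absdelta = 0, C_V = 0, alpha = NA_real_)
  params[colnames(G)] <- G[best$index, ]
  if (model$needs_alpha) params[["alpha"]] <- best$alpha
  validate_params(model, params)
  list(params = params, grid_lle = best$nll, n_points = n_points)
}

#' Stage two: bounded Nelder-Mead refinement
#'
#' Refines the grid optimum inside a box of half-width `radius` around it
#' (clipped to the global parameter bounds); candidate points outside the box
#' are clipped before evaluation, which enforces the constraint. The returned
#' parameters never fit worse than the starting point; with `radius = 0` the
#' start is returned unchanged.
#'
#' @inheritParams grid_search
#' @param start full parameter vector at the grid optimum.
#' @param radius scalar or named vector (`scale`, `alpha`) box half-width.
#' @return A list with `params` and `lle`.
#' @export
refine_simplex <- function(model, design, y, start, radius,
                           options = fit_options()) {
  model <- as_model_spec(model)
  if (is.null(names(radius))) radius <- c(scale = radius[[1]], alpha = radius[[1]])
  free <- model$uses
  if (model$needs_alpha) free <- c(free, "alpha")
  rad <- ifelse(free == "alpha", radius[["alpha"]], radius[["scale"]])
  lo_g <- ifelse(free == "alpha", ALPHA_BOUNDS[1], SCALE_BOUNDS[1])
  hi_g <- ifelse(free == "alpha", ALPHA_BOUNDS[2], SCALE_BOUNDS[2])
  lo <- pmax(start[free] - rad, lo_g)
  hi <- pmin(start[free] + rad, hi_g)
  start_lle <- nll_for_params(model, design, y, start, V0 = options$V0)
  if (all(hi - lo <= 0)) {
    return(list(params = start, lle = start_lle))
  }

  tracker <- new.env(parent = emptyenv())
  tracker$best_par <- start[free]
  tracker$best_val <- start_lle
  fn <- function(par) {
    par <- pmin(pmax(par, lo), hi)
    full <- start
    full[free] <- par
    val <- nll_for_params(model, design, y, full, V0 = options$V0)
    if (val < tracker$best_val) {
      tracker$best_val <- val
      tracker$best_par <- par
    }
    val
  }

  if (length(free) == 1L) {
    opt <- optimize(fn, interval = c(lo, hi), tol = 1e-8)
  } else {
    opt <- tryCatch(
      optim(start[free], fn, method = "Nelder-Mead",
            control = list(reltol = options$simplex_reltol,
                           maxit = options$simplex_maxit)),
      error = function(e) NULL
    )
    if (is.null(opt) ||
        (!is.null(opt$convergence) && opt$convergence != 0 &&
         tracker$best_val >= start_lle)) {
      warning("simplex refinement did not converge; returning best evaluated point",
              call. = FALSE)
    }
  }
  params <- start
  params[free] <- pmin(pmax(tracker$best_par, lo), hi)
  list(params = params, lle = tracker$best_val)
}

#' Fit one encoding model to one participant's session
#'
#' Runs the two-stage maximum-likelihood estimation (exhaustive grid scan,
#' then bounded Nelder-Mead refinement) on all trials of the session jointly
#' and reports the optimum together with its AIC.
#'
#' @inheritParams grid_search
#' @param participant_id label carried into the result.
#' @return A list of class `fit_result`: `participant_id`, `model`, `params`,
#'   `lle`, `grid_lle`, `k`, `aic`, `n_trials`.
#' @examples
#' d <- generate_session_design(seed = 1)
#' y <- rep(c(1, 0), 30)
#' f <- fit_participant("baseline", d, y)
#' f$aic  # 2 * 1 + 2 * 60 * log(2)
#' @export
fit_participant <- function(model, design, y, options = fit_options(),
                            participant_id = "p1") {
  model <- as_model_spec(model)
  g <- grid_search(model, design, y, options)
  if (isTRUE(options$refine)) {
    radius <- options$refine_radius
    if (is.null(radius)) {
      radius <- c(scale = options$grid_step_scale, alpha = options$grid_step_alpha)
    }
    r <- refine_simplex(model, design, y, g$params, radius, options)
  } else {
    r <- list(params = g$params,
              lle = nll_for_params(model, design, y, g$params, V0 = options$V0))
  }
  lle <- min(r$lle, g$grid_lle)
  structure(list(participant_id = participant_id, model = model$name,
                 params = r$params, lle = lle, grid_lle = g$grid_lle,
                 k = model$k, aic = aic_from_lle(model$k, lle),
                 n_trials = length(y)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, model %s: LLE %.3f, k %d, AIC %.3f\n",
              x$participant_id, x$model, x$lle, x$k, x$aic))
  invisible(x)
}

#' Fit models to every participant of a cohort
#'
#' @param cohort a list of `participant_record`s (see [simulate_cohort()]) or
#'   a trial table from [cohort_trials()].
#' @param models character vector of model names to fit.
#' @param options a [fit_options()].
#' @return A data.frame with one row per participant x model: the fitted
#'   parameters, `lle`, `k`, `aic`, and the grid steps used.
#' @export
fit_cohort <- function(cohort, models = model_names(), options = fit_options()) {
  if (is.data.frame(cohort)) cohort <- cohort_from_trials(cohort)
  rows <- lapply(cohort, function(rec) {
    do.call(rbind, lapply(models, function(m) {
      f <- fit_participant(m, rec$design, rec$y, options,
                           participant_id = rec$participant_id)
      fit_result_row(f, rec$design, options)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_result_row <- function(f, design, options) {
  data.frame(participant_id = f$participant_id, session_id = design$session_id,
             delay = design$delay, model = f$model,
             C0 = f$params[["C0"]], C_delta = f$params[["C_delta"]],
             C_absdelta = f$params[["C_absdelta"]], C_V = f$params[["C_V"]],
             alpha = f$params[["alpha"]], lle = f$lle, k = f$k, aic = f$aic,
             grid_step_scale = options$grid_step_scale,
             grid_step_alpha = options$grid_step_alpha,
             stringsAsFactors = FALSE)
}
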