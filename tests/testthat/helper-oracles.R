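# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's fitting path: plain R loops, direct formulas.

# Small session: 3 characters (one per level), 4 trials each = 12 trials.
toy_config <- function() {
  design_config(characters_per_level = c(high = 1, medium = 1, low = 1),
                positives_per_level = c(high = 3, medium = 2, low = 1),
                trials_per_character = 4)
}

# Delta-rule trajectories computed independently of the package.
oracle_trajectory <- function(design, alpha, V0 = 0.5) {
  tr <- design$trials
  v <- setNames(rep(V0, nrow(design$characters)), design$characters$character_id)
  V <- delta <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    id <- tr$character_id[i]
    V[i] <- v[[id]]
    delta[i] <- tr$feedback[i] - V[i]
    v[[id]] <- v[[id]] + alpha * delta[i]
  }
  list(V = V, delta = delta)
}

# Negative log-likelihood of a full parameter vector, by direct formula.
oracle_nll <- function(design, y, C0, Cd = 0, Cad = 0, Cv = 0, alpha = 0, V0 = 0.5) {
  tj <- oracle_trajectory(design, alpha, V0)
  R <- C0 + Cd * tj$delta + Cad * abs(tj$delta) + Cv * tj$V
  p <- 1 / (1 + exp(-R))
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# Brute-force enumeration of the (C0, C_delta, alpha) grid for the signed
# prediction-error model: first strict minimum in the same lexicographic
# order the estimator documents (alpha outermost ascending, then C0, then
# C_delta).
oracle_grid_pe <- function(design, y, step_scale, step_alpha, V0 = 0.5) {
  vals <- seq(-2, 2, by = step_scale)
  alphas <- seq(0, 1, by = step_alpha)
  best <- Inf
  best_par <- NULL
  for (a in alphas) {
    tj <- oracle_trajectory(design, a, V0)
    for (c0 in vals) for (cd in vals) {
      p <- 1 / (1 + exp(-(c0 + cd * tj$delta)))
      nll <- -sum(y * log(p) + (1 - y) * log(1 - p))
      if (nll < best) {
        best <- nll
        best_par <- c(C0 = c0, C_delta = cd, alpha = a)
      }
    }
  }
  list(params = best_par, nll = best)
}

# Exact two-sided sign-flip p-value by full enumeration (n <= 12 or so).
oracle_exact_signflip_p <- function(d) {
  n <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- abs(signs %*% d) / n
  mean(perm >= obs - 1e-12)
}

# Reference group-level model fits (mean LLE and mean AIC as printed for the
# n = 25 cohort), used for the AIC-identity checks.
reference_fit_table <- function() {
  data.frame(
    delay = rep(c("20min", "24h"), each = 6),
    model = rep(c("baseline", "pe", "abs_pe", "ev", "pe_ev", "abs_pe_ev"), 2),
    k = rep(c(1, 3, 3, 3, 4, 4), 2),
    lle = c(70.755, 60.440, 61.718, 61.593, 57.828, 59.625,
            76.445, 64.079, 65.270, 64.267, 61.165, 62.943),
    aic = c(143.510, 126.881, 129.436, 129.186, 123.656, 127.250,
            154.889, 134.159, 136.539, 134.535, 130.329, 133.887),
    stringsAsFactors = FALSE
  )
}

# Draw a random bound-respecting parameter vector for a model.
random_params <- function(model, seed) {
  spec <- model_spec(model)
  withr::with_seed(seed, {
    args <- setNames(as.list(runif(length(spec$uses), -2, 2)), spec$uses)
    if (spec$needs_alpha) args$alpha <- runif(1)
    do.call(model_params, c(list(model = model), args))
  })
}
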