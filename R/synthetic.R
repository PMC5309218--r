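# Group-mean parameter estimates (with their standard errors, n = 25) for
# each encoding model and delay condition, used as the package's reference
# generative conditions for synthetic cohorts.
.reference_params <- list(
  "20min" = list(
    baseline  = list(mean = c(C0 = 0.721),
                     sem  = c(C0 = 0.075)),
    pe        = list(mean = c(C0 = 0.735, C_delta = 0.369, alpha = 0.395),
                     sem  = c(C0 = 0.071, C_delta = 0.158, alpha = 0.077)),
    abs_pe    = list(mean = c(C0 = 0.562, C_absdelta = 0.503, alpha = 0.583),
                     sem  = c(C0 = 0.107, C_absdelta = 0.166, alpha = 0.074)),
    ev        = list(mean = c(C0 = 0.584, C_V = 0.501, alpha = 0.372),
                     sem  = c(C0 = 0.104, C_V = 0.221, alpha = 0.064)),
    pe_ev     = list(mean = c(C0 = 0.350, C_delta = 0.725, C_V = 1.156, alpha = 0.329),
                     sem  = c(C0 = 0.132, C_delta = 0.154, C_V = 0.180, alpha = 0.057)),
    abs_pe_ev = list(mean = c(C0 = 0.530, C_absdelta = 0.361, C_V = 0.360, alpha = 0.456),
                     sem  = c(C0 = 0.099, C_absdelta = 0.212, C_V = 0.239, alpha = 0.075))
  ),
  "24h" = list(
    baseline  = list(mean = c(C0 = 0.496),
                     sem  = c(C0 = 0.026)),
    pe        = list(mean = c(C0 = 0.507, C_delta = 0.215, alpha = 0.333),
                     sem  = c(C0 = 0.073, C_delta = 0.171, alpha = 0.068)),
    abs_pe    = list(mean = c(C0 = 0.417, C_absdelta = 0.292, alpha = 0.404),
                     sem  = c(C0 = 0.108, C_absdelta = 0.202, alpha = 0.085)),
    ev        = list(mean = c(C0 = 0.402, C_V = 0.268, alpha = 0.456),
                     sem  = c(C0 = 0.117, C_V = 0.265, alpha = 0.080)),
    pe_ev     = list(mean = c(C0 = 0.223, C_delta = 0.469, C_V = 0.729, alpha = 0.312),
                     sem  = c(C0 = 0.123, C_delta = 0.173, C_V = 0.274, alpha = 0.066)),
    abs_pe_ev = list(mean = c(C0 = 0.284, C_absdelta = 0.327, C_V = 0.277, alpha = 0.433),
                     sem  = c(C0 = 0.146, C_absdelta = 0.199, C_V = 0.257, alpha = 0.078))
  )
)

#' Reference group-level parameters
#'
#' Group-mean parameter estimates for each encoding model under the two
#' delay conditions, used throughout the package as the default generative
#' conditions for synthetic cohorts (e.g., the signed-prediction-error +
#' expected-value model at the 20-min delay has `C0 = 0.350`,
#' `C_delta = 0.725`, `C_V = 1.156`, `alpha = 0.329`).
#'
#' @param model model name (see [model_names()]).
#' @param delay `"20min"` or `"24h"`.
#' @param what `"mean"` for the group means (as a full [model_params()]
#'   vector) or `"sem"` for their standard errors (named, free terms only).
#' @return A named numeric vector.
#' @export
reference_group_params <- function(model, delay = c("20min", "24h"),
                                   what = c("mean", "sem")) {
  delay <- match.arg(delay)
  what <- match.arg(what)
  model <- as_model_spec(model)
  entry <- .reference_params[[delay]][[model$name]]
  if (what == "sem") return(entry$sem)
  do.call(model_params, c(list(model = model), as.list(entry$mean)))
}

#' Sampler of heterogeneous per-participant generative parameters
#'
#' Draws each participant's generative parameters from truncated Gaussians
#' centered on the reference group means with standard deviation equal to
#' the reference standard error times `sqrt(25)` (i.e., the implied
#' between-participant SD at the reference cohort size), truncated at the
#' parameter bounds by resampling.
#'
#' @inheritParams reference_group_params
#' @return A function `f(seed)` returning one full parameter vector.
#' @export
reference_param_sampler <- function(model, delay = c("20min", "24h")) {
  model <- as_model_spec(model)
  delay <- match.arg(delay)
  mu <- .reference_params[[delay]][[model$name]]$mean
  sdv <- .reference_params[[delay]][[model$name]]$sem * sqrt(25)
  function(seed) {
    withr::with_seed(as.integer(seed), {
      draw <- vapply(names(mu), function(nm) {
        b <- if (nm == "alpha") ALPHA_BOUNDS else SCALE_BOUNDS
        repeat {
          x <- rnorm(1, mu[[nm]], sdv[[nm]])
          if (x >= b[1] && x <= b[2]) return(x)
        }
      }, numeric(1))
    })
    do.call(model_params, c(list(model = model), as.list(draw)))
  }
}

#' Simulate one participant's test outcomes
#'
#' Plays the generative encoding model forward over one session: per trial
#' the expected value and prediction error are computed by the delta rule,
#' mapped to a reward signal and a logistic encoding probability, and the
#' binary test outcome (hit/miss) is drawn as an independent Bernoulli with
#' that probability. Deterministic per seed.
#'
#' @param design a `session_design`.
#' @param model generative model name or `model_spec`.
#' @param params generative parameter vector from [model_params()].
#' @param seed integer seed for the Bernoulli draws.
#' @param participant_id label.
#' @param V0 initial expected value.
#' @return A `participant_record`: list with `participant_id`, `design`,
#'   `generative_model`, `generative_params`, `p_encoding`, `y`, `seed`, and
#'   optionally `confidence` and `traits`.
#' @export
simulate_participant <- function(design, model, params, seed,
                                 participant_id = "p1", V0 = 0.5) {
  model <- as_model_spec(model)
  validate_params(model, params)
  alpha <- if (model$needs_alpha) params[["alpha"]] else 0
  traj <- trajectory_table(design, alpha = alpha, V0 = V0)
  R <- reward_signal(model, params, traj$V_before, traj$delta)
  p <- encoding_probability(R)
  y <- withr::with_seed(as.integer(seed), rbinom(length(p), 1L, p))
  structure(list(participant_id = participant_id, design = design,
                 generative_model = model$name, generative_params = params,
                 trajectory = traj, p_encoding = p, y = y,
                 confidence = NULL, traits = NULL, seed = as.integer(seed),
                 V0 = V0),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s: %d trials, generative model %s, hit rate %.2f\n",
              x$participant_id, length(x$y), x$generative_model, mean(x$y)))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Generates `n` participants, each with a fresh session design (seeds
#' derived deterministically from `base_seed`) and test outcomes drawn from
#' the generative model. `param_source` is either one fixed parameter vector
#' shared by all participants or a sampler function `f(seed)` (e.g., from
#' [reference_param_sampler()]) drawing heterogeneous parameters.
#'
#' @param n number of participants (>= 1).
#' @param model generative model name or `model_spec`.
#' @param param_source fixed [model_params()] vector or `function(seed)`.
#' @param base_seed integer; all per-participant seeds derive from it.
#' @param config a [design_config()].
#' @param delay delay condition label for the sessions.
#' @param V0 initial expected value.
#' @return A list of `participant_record`s with attribute `"manifest"`, a
#'   data.frame logging the seeds used per participant.
#' @export
simulate_cohort <- function(n, model, param_source, base_seed,
                            config = design_config(), delay = "20min",
                            V0 = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  model <- as_model_spec(model)
  sampler <- if (is.function(param_source)) {
    param_source
  } else {
    validate_params(model, param_source)
    function(seed) param_source
  }
  records <- vector("list", n)
  manifest <- data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                         design_seed = NA_integer_, param_seed = NA_integer_,
                         outcome_seed = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ds <- derive_seed(base_seed, 3L * i)
    ps <- derive_seed(base_seed, 3L * i + 1L)
    os <- derive_seed(base_seed, 3L * i + 2L)
    design <- generate_session_design(seed = ds, config = config,
                                      session_id = sprintf("s%03d", i),
                                      delay = delay)
    params <- sampler(ps)
    records[[i]] <- simulate_participant(design, model, params, seed = os,
                                         participant_id = manifest$participant_id[i],
                                         V0 = V0)
    manifest[i, c("design_seed", "param_seed", "outcome_seed")] <- c(ds, ps, os)
  }
  names(records) <- manifest$participant_id
  attr(records, "manifest") <- manifest
  records
}

#' Flatten a cohort to (or rebuild one from) a trial table
#'
#' `cohort_trials()` produces one row per participant x trial with the design
#' columns plus `V_before`, `delta`, `p_encoding` (simulation-only ground
#' truth, never an input to fitting), `test_correct`, and `confidence`.
#' `cohort_from_trials()` inverts it (without `p_encoding`/trajectories,
#' which are generative quantities).
#'
#' @param cohort list of `participant_record`s.
#' @param trials a trial table as produced by `cohort_trials()`.
#' @return A data.frame, or a list of `participant_record`s.
#' @export
cohort_trials <- function(cohort) {
  out <- lapply(cohort, function(rec) {
    data.frame(participant_id = rec$participant_id,
               session_id = rec$design$session_id, delay = rec$design$delay,
               rec$design$trials,
               V_before = rec$trajectory$V_before, delta = rec$trajectory$delta,
               p_encoding = rec$p_encoding, test_correct = rec$y,
               confidence = if (is.null(rec$confidence)) NA_character_ else rec$confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname cohort_trials
#' @export
cohort_from_trials <- function(trials) {
  needed <- c("participant_id", "session_id", "delay", "trial_index",
              "character_id", "level", "pair_id", "feedback", "test_correct")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  recs <- lapply(split(trials, trials$participant_id), function(df) {
    df <- df[order(df$trial_index), ]
    design <- design_from_trials(df, session_id = df$session_id[1],
                                 delay = df$delay[1])
    structure(list(participant_id = df$participant_id[1], design = design,
                   generative_model = NA_character_, generative_params = NULL,
                   trajectory = NULL, p_encoding = NULL,
                   y = as.integer(df$test_correct),
                   confidence = if ("confidence" %in% names(df) &&
                                    !all(is.na(df$confidence))) df$confidence else NULL,
                   traits = NULL, seed = NA_integer_, V0 = 0.5),
              class = "participant_record")
  })
  recs[unique(trials$participant_id)]
}

#' Attach trait scores correlated with a behavioral statistic
#'
#' Draws Sensitivity to Reward (SR) and Sensitivity to Punishment (SP)
#' scores so that the cohort's sensitivity-bias score (z-scored SR minus
#' z-scored SP) has a target Spearman rank correlation, in expectation, with
#' a chosen per-participant statistic. The coupling uses a Gaussian copula
#' on the ranks of the statistic: the latent bias is a Gaussian mixture of
#' the statistic's normal scores and independent noise, with the Pearson
#' coefficient `2 * sin(pi * target_rho / 6)` so that the implied Spearman
#' correlation equals `target_rho`. SR and SP are emitted on a
#' questionnaire-like scale symmetric around the latent bias, so the bias
#' score reconstructed downstream is an exact monotone image of the latent
#' (at `|target_rho| = 1` the observed correlation is exactly +/-1).
#'
#' @param cohort list of `participant_record`s.
#' @param target_rho target Spearman correlation in \[-1, 1\].
#' @param couple_to numeric vector, one statistic per participant (e.g.,
#'   fitted `C_delta`, or positive-minus-negative memory difference).
#' @param seed integer seed.
#' @return The cohort with `traits` (`SR`, `SP`) set on every record.
#' @export
simulate_traits <- function(cohort, target_rho, couple_to, seed) {
  .assert_scalar_in(target_rho, -1, 1, "target_rho")
  n <- length(cohort)
  if (length(couple_to) != n) {
    stop("`couple_to` must have one value per participant", call. = FALSE)
  }
  rho_latent <- min(max(2 * sin(pi * target_rho / 6), -1), 1)
  z <- qnorm((rank(couple_to, ties.method = "average") - 0.5) / n)
  G <- if (abs(target_rho) == 1) {
    sign(target_rho) * z  # exact (anti)comonotone limit, no noise
  } else {
    withr::with_seed(as.integer(seed), {
      eps <- rnorm(n)
      rho_latent * z + sqrt(1 - rho_latent^2) * eps
    })
  }
  # SR/SP symmetric around the latent bias: their z-score difference is an
  # exact monotone image of G (equal spreads by construction).
  SR <- 12 + 3 * G / 2
  SP <- 12 - 3 * G / 2
  for (i in seq_len(n)) {
    cohort[[i]]$traits <- list(SR = SR[i], SP = SP[i])
  }
  cohort
}

#' Attach confidence ratings
#'
#' Draws a 3-level confidence label ("guess", "quite_certain", "certain")
#' per trial from a distribution whose "certain" share increases with the
#' trial's generative encoding probability. Trials are binned at the
#' terciles of the record's `p_encoding` (falling back to fixed thirds of
#' \[0, 1\] when the probabilities are too uniform to define terciles), and
#' each bin has a fixed label distribution with monotonically increasing
#' confidence.
#'
#' @param record a `participant_record` with `p_encoding` present.
#' @param mapping 3 x 3 matrix of label probabilities (rows: low/mid/high
#'   probability bin; columns: guess/quite_certain/certain).
#' @param seed integer seed.
#' @return The record with `confidence` filled in.
#' @export
simulate_confidence <- function(record, seed,
                                mapping = rbind(c(0.5, 0.3, 0.2),
                                                c(0.3, 0.4, 0.3),
                                                c(0.2, 0.3, 0.5))) {
  p <- record$p_encoding
  if (is.null(p)) stop("record has no `p_encoding`; simulate outcomes first",
                       call. = FALSE)
  stopifnot(is.matrix(mapping), dim(mapping) == c(3, 3),
            all(abs(rowSums(mapping) - 1) < 1e-8))
  br <- unique(stats::quantile(p, c(1 / 3, 2 / 3), names = FALSE))
  bin <- if (length(br) == 2L && br[1] < br[2]) {
    findInterval(p, br, left.open = TRUE) + 1L
  } else {
    findInterval(p, c(1 / 3, 2 / 3), left.open = TRUE) + 1L
  }
  labels <- c("guess", "quite_certain", "certain")
  record$confidence <- withr::with_seed(as.integer(seed), {
    vapply(bin, function(b) sample(labels, 1L, prob = mapping[b, ]), character(1))
  })
  record
}
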