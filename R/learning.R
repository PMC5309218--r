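#' Reward prediction error
#'
#' The mismatch between the delivered outcome and the current expected value
#' of the character, `delta = r - V`. With binary outcomes and `V` in
#' \[0, 1\] the prediction error lies in \[-1, 1\].
#'
#' @param V current expected value, in \[0, 1\].
#' @param r delivered feedback, 0 (negative) or 1 (positive).
#' @return The prediction error, `delta = r - V`.
#' @export
prediction_error <- function(V, r) {
  .assert_scalar_in(V, 0, 1, "V")
  if (!r %in% c(0, 1)) stop("`r` must be 0 or 1", call. = FALSE)
  r - V
}

#' Delta-rule value update
#'
#' One step of the Rescorla-Wagner / Q-learning update,
#' `V <- V + alpha * delta`. When `delta = r - V` with `r` in \{0, 1\} and
#' `V` in \[0, 1\], the updated value stays in \[0, 1\].
#'
#' @param V current expected value.
#' @param delta prediction error for this trial.
#' @param alpha learning rate in \[0, 1\].
#' @return The updated value.
#' @export
update_value <- function(V, delta, alpha) {
  .assert_scalar_in(alpha, 0, 1, "alpha")
  V + alpha * delta
}

#' Expected-value and prediction-error trajectories for a session
#'
#' Each character carries its own expected value, initialized at `V0` and
#' updated by the delta rule across that character's trials in session order.
#' `V_before` is the value holding when the trial is presented (before that
#' trial's update) and `delta` is that trial's prediction error; both are the
#' quantities the encoding models consume for trial `t`.
#'
#' @param design a `session_design`.
#' @param alpha learning rate in \[0, 1\].
#' @param V0 initial expected value, in \[0, 1\] (default 0.5, the neutral
#'   midpoint between the two outcomes).
#' @return A named list, one `value_trajectory` per character: `character_id`,
#'   `V_before`, `delta`, `alpha`, `V_final`.
#' @seealso [trajectory_table()] for the same quantities aligned to the trial
#'   table.
#' @export
value_trajectories <- function(design, alpha, V0 = 0.5) {
  .assert_scalar_in(alpha, 0, 1, "alpha")
  .assert_scalar_in(V0, 0, 1, "V0")
  out <- lapply(split(design$trials$feedback, design$trials$character_id), function(r) {
    n <- length(r)
    V <- numeric(n)
    delta <- numeric(n)
    v <- V0
    for (i in seq_len(n)) {
      V[i] <- v
      delta[i] <- r[i] - v
      v <- v + alpha * delta[i]
    }
    structure(list(V_before = V, delta = delta, alpha = alpha, V_final = v),
              class = "value_trajectory")
  })
  for (id in names(out)) out[[id]]$character_id <- id
  out
}

#' Per-trial value/prediction-error table
#'
#' Computes `V_before` and `delta` for every trial of the session, in trial
#' order, ready to be joined to the design trial table or fed to the encoding
#' models.
#'
#' @inheritParams value_trajectories
#' @return A data.frame with columns `character_id`, `within_trial`,
#'   `V_before`, `delta`, row-aligned with `design$trials`.
#' @export
trajectory_table <- function(design, alpha, V0 = 0.5) {
  .assert_scalar_in(alpha, 0, 1, "alpha")
  .assert_scalar_in(V0, 0, 1, "V0")
  tr <- design$trials
  n <- nrow(tr)
  V <- numeric(n)
  delta <- numeric(n)
  within <- integer(n)
  v_cur <- setNames(rep(V0, nrow(design$characters)), design$characters$character_id)
  n_seen <- setNames(rep(0L, nrow(design$characters)), design$characters$character_id)
  for (i in seq_len(n)) {
    id <- tr$character_id[i]
    V[i] <- v_cur[[id]]
    delta[i] <- tr$feedback[i] - V[i]
    v_cur[[id]] <- V[i] + alpha * delta[i]
    n_seen[[id]] <- n_seen[[id]] + 1L
    within[i] <- n_seen[[id]]
  }
  data.frame(character_id = tr$character_id, within_trial = within,
             V_before = V, delta = delta, stringsAsFactors = FALSE)
}
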