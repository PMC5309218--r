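#' The six candidate encoding models
#'
#' Each model defines a linear reward signal
#' `R(t) = C0 + C_delta * delta(t) + C_absdelta * |delta(t)| + C_V * V(t)`
#' with only a subset of terms free, and the probability of encoding the
#' trial's character-object association is `plogis(R(t))`. The candidates
#' are:
#'
#' * `baseline` — constant `C0` only (no reward influence)
#' * `pe` — signed prediction error: `C0 + C_delta * delta`
#' * `abs_pe` — unsigned prediction error: `C0 + C_absdelta * |delta|`
#' * `ev` — expected value: `C0 + C_V * V`
#' * `pe_ev` — signed prediction error and expected value
#' * `abs_pe_ev` — unsigned prediction error and expected value
#'
#' The learning rate `alpha` is a free parameter of every model whose signal
#' depends on the value trajectory, so `k` (the number of free parameters
#' entering the AIC penalty) is 1 for `baseline`, 3 for the single-term
#' models, and 4 for the two-term models.
#'
#' @param name one of `"baseline"`, `"pe"`, `"abs_pe"`, `"ev"`, `"pe_ev"`,
#'   `"abs_pe_ev"`.
#' @return A list of class `model_spec` with fields `name`, `uses` (free
#'   scale-factor names), `needs_alpha`, `k`.
#' @export
model_spec <- function(name = model_names()) {
  name <- match.arg(name)
  uses <- switch(name,
    baseline  = "C0",
    pe        = c("C0", "C_delta"),
    abs_pe    = c("C0", "C_absdelta"),
    ev        = c("C0", "C_V"),
    pe_ev     = c("C0", "C_delta", "C_V"),
    abs_pe_ev = c("C0", "C_absdelta", "C_V")
  )
  needs_alpha <- name != "baseline"
  structure(list(name = name, uses = uses, needs_alpha = needs_alpha,
                 k = length(uses) + as.integer(needs_alpha)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_names <- function() {
  c("baseline", "pe", "abs_pe", "ev", "pe_ev", "abs_pe_ev")
}

SCALE_PARAM_NAMES <- c("C0", "C_delta", "C_absdelta", "C_V")

#' Parameter vector for an encoding model
#'
#' Builds a full, validated parameter vector. Scale factors are bounded in
#' \[-2, 2\] and the learning rate in \[0, 1\]; parameters a model does not
#' use are frozen at 0 (and `alpha` at `NA` for `baseline`).
#'
#' @param model a `model_spec` or model name.
#' @param C0,C_delta,C_absdelta,C_V scale factors.
#' @param alpha learning rate (required whenever the model uses the value
#'   trajectory).
#' @return A named numeric vector with elements `C0, C_delta, C_absdelta,
#'   C_V, alpha`.
#' @export
model_params <- function(model, C0 = 0, C_delta = 0, C_absdelta = 0, C_V = 0,
                         alpha = NA_real_) {
  model <- as_model_spec(model)
  p <- c(C0 = C0, C_delta = C_delta, C_absdelta = C_absdelta, C_V = C_V,
         alpha = alpha)
  validate_params(model, p)
  p
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

validate_params <- function(model, params) {
  model <- as_model_spec(model)
  for (nm in SCALE_PARAM_NAMES) {
    v <- params[[nm]]
    if (nm %in% model$uses) {
      .assert_scalar_in(v, SCALE_BOUNDS[1], SCALE_BOUNDS[2], nm)
    } else if (!isTRUE(v == 0)) {
      stop(sprintf("model '%s' does not use `%s`; it must be 0", model$name, nm),
           call. = FALSE)
    }
  }
  if (model$needs_alpha) {
    .assert_scalar_in(params[["alpha"]], ALPHA_BOUNDS[1], ALPHA_BOUNDS[2], "alpha")
  }
  invisible(params)
}

#' Linear reward signal R(t)
#'
#' Evaluates the model's reward signal for given expected value and
#' prediction error. Vectorized over `V` and `delta`. Under the parameter
#' bounds the signal satisfies `|R| <= 6`, which keeps the encoding
#' probability strictly inside (0, 1) and the log-likelihood finite.
#'
#' @param model a `model_spec` or model name.
#' @param params a parameter vector from [model_params()].
#' @param V expected value(s) in \[0, 1\].
#' @param delta prediction error(s) in \[-1, 1\].
#' @return Numeric vector of reward signals.
#' @export
reward_signal <- function(model, params, V, delta) {
  model <- as_model_spec(model)
  validate_params(model, params)
  params[["C0"]] + params[["C_delta"]] * delta +
    params[["C_absdelta"]] * abs(delta) + params[["C_V"]] * V
}

#' Logistic encoding probability
#'
#' Maps the reward signal to the probability that the trial's association is
#' later remembered: `p = 1 / (1 + exp(-R))`.
#'
#' @param R reward signal(s).
#' @return Probabilities in (0, 1), strictly increasing in `R`.
#' @export
encoding_probability <- function(R) {
  stopifnot(is.numeric(R), all(is.finite(R)))
  plogis(R)
}
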