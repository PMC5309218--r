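#' Configuration for the associative memory task design
#'
#' The encoding session pairs six cartoon characters with object pairs under
#' predetermined feedback ratios. Each character belongs to one of three
#' reward-anticipation levels defined by how many of its 10 trials deliver
#' positive feedback: high characters receive positive feedback on 8/10
#' trials, medium on 5/10, low on 2/10. Two characters are assigned to each
#' level, giving 60 trials in total, blocked by character.
#'
#' @param characters_per_level named integer vector, characters per
#'   anticipation level (names `high`, `medium`, `low`).
#' @param positives_per_level named integer vector, positive feedbacks out of
#'   `trials_per_character` for each level.
#' @param trials_per_character number of trials (object pairs) per character.
#' @return A list of class `design_config`.
#' @export
design_config <- function(characters_per_level = c(high = 2L, medium = 2L, low = 2L),
                          positives_per_level = c(high = 8L, medium = 5L, low = 2L),
                          trials_per_character = 10L) {
  levels <- c("high", "medium", "low")
  if (!setequal(names(characters_per_level), levels) ||
      !setequal(names(positives_per_level), levels)) {
    stop("`characters_per_level` and `positives_per_level` must be named high/medium/low",
         call. = FALSE)
  }
  characters_per_level <- as.integer(characters_per_level[levels])
  positives_per_level <- as.integer(positives_per_level[levels])
  trials_per_character <- as.integer(trials_per_character)
  if (any(characters_per_level < 1L)) {
    stop("character counts per level must be positive", call. = FALSE)
  }
  if (trials_per_character < 1L) {
    stop("`trials_per_character` must be positive", call. = FALSE)
  }
  if (any(positives_per_level < 0L) || any(positives_per_level > trials_per_character)) {
    stop(sprintf("positives per level must lie in [0, %d]", trials_per_character),
         call. = FALSE)
  }
  structure(list(characters_per_level = setNames(characters_per_level, levels),
                 positives_per_level = setNames(positives_per_level, levels),
                 trials_per_character = trials_per_character),
            class = "design_config")
}

#' Generate one encoding-session design
#'
#' Builds the fixed trial schedule for one session: characters are assigned
#' to anticipation levels, presented in a random block order, and within each
#' character's block the positions of its predetermined positive feedbacks
#' are a uniformly random permutation. Feedback never depends on any choice,
#' so the schedule fully determines the learning signal. Identical
#' `seed` + `config` yield bit-identical designs.
#'
#' @param seed integer seed driving all randomization of the design.
#' @param config a [design_config()].
#' @param session_id label for the session.
#' @param delay delay condition, `"20min"` or `"24h"`.
#' @param label_prefix prefix for character/pair labels, so two sessions can
#'   use disjoint label sets.
#' @return An object of class `session_design`: a list with `session_id`,
#'   `delay`, `characters` (data.frame: `character_id`, `level`,
#'   `n_positive`) and `trials` (data.frame: `trial_index`, `character_id`,
#'   `level`, `pair_id`, `feedback`).
#' @examples
#' d <- generate_session_design(seed = 1)
#' nrow(d$trials)            # 60
#' table(d$trials$feedback)  # 30 positive, 30 negative under defaults
#' @export
generate_session_design <- function(seed, config = design_config(),
                                    session_id = "s1", delay = c("20min", "24h"),
                                    label_prefix = "") {
  if (!inherits(config, "design_config")) config <- do.call(design_config, config)
  delay <- match.arg(delay)
  seed <- as.integer(seed)

  levels <- rep(names(config$characters_per_level), config$characters_per_level)
  n_char <- length(levels)
  n_per <- config$trials_per_character
  char_ids <- sprintf("%schar%02d", label_prefix, seq_len(n_char))
  characters <- data.frame(
    character_id = char_ids,
    level = levels,
    n_positive = config$positives_per_level[levels],
    stringsAsFactors = FALSE, row.names = NULL
  )

  withr::with_seed(seed, {
    block_order <- sample.int(n_char)
    feedback <- lapply(seq_len(n_char), function(i) {
      np <- characters$n_positive[block_order[i]]
      r <- c(rep(1L, np), rep(0L, n_per - np))
      sample(r)
    })
  })

  trials <- data.frame(
    trial_index = seq_len(n_char * n_per),
    character_id = rep(characters$character_id[block_order], each = n_per),
    level = rep(characters$level[block_order], each = n_per),
    pair_id = sprintf("%spair%03d", label_prefix, seq_len(n_char * n_per)),
    feedback = unlist(feedback),
    stringsAsFactors = FALSE, row.names = NULL
  )

  design <- structure(list(session_id = session_id, delay = delay,
                           characters = characters, trials = trials,
                           seed = seed),
                      class = "session_design")
  validate_session_design(design)
  design
}

#' Validate the invariants of a session design
#'
#' Checks that every character has the configured number of trials, that the
#' per-character positive-feedback counts match its level's ratio, that trials
#' are blocked by character, and that pair labels are unique.
#'
#' @param design a `session_design`.
#' @return `design`, invisibly; errors on violation.
#' @export
validate_session_design <- function(design) {
  tr <- design$trials
  ch <- design$characters
  counts <- table(tr$character_id)
  if (length(unique(counts)) != 1L) {
    stop("unequal trial counts across characters", call. = FALSE)
  }
  if (anyDuplicated(tr$pair_id)) stop("duplicated pair_id", call. = FALSE)
  pos <- tapply(tr$feedback, tr$character_id, sum)
  if (!all(pos[ch$character_id] == ch$n_positive)) {
    stop("positive feedback counts do not match the configured ratios", call. = FALSE)
  }
  # blocked: each character occupies one contiguous run
  runs <- rle(tr$character_id)
  if (anyDuplicated(runs$values)) {
    stop("trials are not blocked by character", call. = FALSE)
  }
  if (!all(tr$trial_index == seq_len(nrow(tr)))) {
    stop("trial_index must be 1..n in order", call. = FALSE)
  }
  invisible(design)
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %s (%s): %d characters, %d trials, %d positive feedbacks\n",
              x$session_id, x$delay, nrow(x$characters), nrow(x$trials),
              sum(x$trials$feedback)))
  invisible(x)
}

#' Write or read a design as CSV
#'
#' The interchange schema is one row per trial with columns `session_id,
#' delay, trial_index, character_id, level, pair_id, feedback`.
#'
#' @param design a `session_design`.
#' @param path file path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `session_design`.
#' @export
write_design_csv <- function(design, path) {
  df <- cbind(session_id = design$session_id, delay = design$delay,
              design$trials, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("session_id", "delay", "trial_index", "character_id", "level",
              "pair_id", "feedback")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("design CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design_from_trials(df[order(df$trial_index), ],
                     session_id = df$session_id[1], delay = df$delay[1])
}

# Rebuild a session_design from a trial table (already in trial order).
design_from_trials <- function(trials, session_id, delay) {
  ch_ids <- unique(trials$character_id)
  characters <- data.frame(
    character_id = ch_ids,
    level = trials$level[match(ch_ids, trials$character_id)],
    n_positive = as.integer(tapply(trials$feedback, trials$character_id, sum)[ch_ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  characters <- characters[order(characters$character_id), ]
  rownames(characters) <- NULL
  design <- structure(list(session_id = session_id, delay = delay,
                           characters = characters,
                           trials = trials[, c("trial_index", "character_id",
                                               "level", "pair_id", "feedback")],
                           seed = NA_integer_),
                      class = "session_design")
  validate_session_design(design)
  design
}
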