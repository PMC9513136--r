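# Logic of the four non-rest intervention tasks: associative-memory
# encoding/retrieval schedules (delay and control variants), the Serial-7s
# working-memory validator, and the spatial-attention trial scorer.

AM_TARGET_DELAYS <- c(1L, 10L, 21L, 50L, 90L, 180L)

# Six anchor countries paired with the target delays, ordered by geographic
# distance from Seoul (ascending), plus a synthetic pool of 24 further
# countries in approximate ascending-distance order used to fill the
# non-target slots.  Only the six anchors are part of the task contract.
AM_ANCHORS <- data.frame(
  country = c("Japan", "Vietnam", "Taiwan", "The Philippines",
              "New Zealand", "Brazil"),
  delay = AM_TARGET_DELAYS,
  stringsAsFactors = FALSE)

AM_COUNTRY_POOL <- c(
  "China", "Mongolia", "Hong Kong", "Thailand", "Laos", "Cambodia",
  "Malaysia", "Singapore", "Indonesia", "India", "Nepal", "Kazakhstan",
  "Sri Lanka", "Maldives", "United Arab Emirates", "Australia", "Turkey",
  "Kenya", "Germany", "France", "United Kingdom", "Spain", "Portugal",
  "Argentina")

# Office-supply lexicon for the control variant.  `kr_length` annotates the
# word length of the (synthetic) Korean label; the control schedule matches
# it to the digit count of the delay it replaces.
OFFICE_SUPPLY_LEXICON <- data.frame(
  label = c(
    # length 1
    "pen", "ink", "glue", "tape", "clip", "pad", "ruler", "band",
    # length 2
    "eraser", "stapler", "scissors", "notebook", "pencil", "marker",
    "folder", "binder", "envelope", "sticker", "magnet", "sharpener",
    "crayon", "chalk", "compass", "divider", "stamp", "ledger", "diary",
    "planner", "cutter", "punch", "tray", "clipboard", "calculator",
    "whiteboard", "paperweight", "highlighter", "postit", "corrector",
    # length 3
    "ballpoint pen", "fountain pen", "mechanical pencil", "paper clip",
    "rubber band", "index card", "sticky note", "binder clip",
    "file cabinet", "desk organizer", "letter opener", "tape dispenser",
    "pencil case", "document tray", "name card", "label maker",
    "glue stick", "card holder", "book stand", "memo board",
    "pin cushion", "seal stamp", "ring binder", "laser pointer",
    "staple remover", "correction tape", "writing pad", "drawing pen",
    "colored pencil", "mouse controller"),
  kr_length = c(rep(1L, 8L), rep(2L, 30L), rep(3L, 30L)),
  stringsAsFactors = FALSE)

# Draw the 24 non-target delays: distinct integers in 2..179, at least 2
# away from every target delay, seeded through the current RNG stream.
sample_nontarget_delays <- function() {
  excluded <- unique(c(AM_TARGET_DELAYS - 1L, AM_TARGET_DELAYS,
                       AM_TARGET_DELAYS + 1L))
  candidates <- setdiff(2:179, excluded)
  sort(sample(candidates, 24L))
}

#' Build an associative-memory task schedule
#'
#' Constructs the 30 association pairs and the encoding and retrieval trial
#' lists. In the `"delay"` variant, 30 countries (sorted by ascending
#' distance rank from Seoul) are paired with 30 unique temporal delays in
#' ascending order; six delays (1, 10, 21, 50, 90, 180 days) are targets
#' shared with the ITC task and anchored to their printed countries (Japan,
#' Vietnam, Taiwan, The Philippines, New Zealand, Brazil). The `"control"`
#' variant replaces each delay with an office-supply label whose annotated
#' word length matches the digit count of the replaced delay.
#'
#' The encoding phase presents each of the 30 pairs exactly twice (60 trials,
#' order randomized); the retrieval phase cues each target three times and
#' each non-target once (42 trials, intermixed).
#'
#' @param variant `"delay"` or `"control"`.
#' @param seed Optional integer seed for the schedule draw.
#' @return List with `pairs` (30 rows: `country`, `cue_value`, `delay_days`,
#'   `is_target`), `encoding` (60 rows), `retrieval` (42 rows).
#' @export
build_am_schedule <- function(variant = c("delay", "control"), seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  delays <- sort(c(AM_TARGET_DELAYS, sample_nontarget_delays()))
  is_target <- delays %in% AM_TARGET_DELAYS
  countries <- character(30L)
  countries[is_target] <- AM_ANCHORS$country[match(delays[is_target],
                                                   AM_ANCHORS$delay)]
  countries[!is_target] <- AM_COUNTRY_POOL
  cue <- as.character(delays)
  if (variant == "control") {
    digits <- nchar(as.character(delays))
    cue <- character(30L)
    for (len in unique(digits)) {
      pool <- OFFICE_SUPPLY_LEXICON$label[OFFICE_SUPPLY_LEXICON$kr_length == len]
      need <- sum(digits == len)
      cue[digits == len] <- sample(pool, need)
    }
  }
  pairs <- data.frame(country = countries,
                      cue_value = cue,
                      delay_days = delays,
                      is_target = is_target,
                      stringsAsFactors = FALSE)
  enc_idx <- sample(rep(seq_len(30L), 2L))
  encoding <- data.frame(trial = seq_len(60L),
                         country = pairs$country[enc_idx],
                         cue_value = pairs$cue_value[enc_idx],
                         stringsAsFactors = FALSE)
  ret_idx <- sample(c(rep(which(is_target), 3L), which(!is_target)))
  retrieval <- data.frame(trial = seq_len(42L),
                          cue_value = pairs$cue_value[ret_idx],
                          country = pairs$country[ret_idx],
                          is_target = pairs$is_target[ret_idx],
                          stringsAsFactors = FALSE)
  list(pairs = pairs, encoding = encoding, retrieval = retrieval)
}

#' Serial-7s expected answer
#'
#' The answer expected on the next trial of the Serial-7s subtraction task:
#' seven less than the previous answer.
#'
#' @param previous_answer Integer `>= 100` (the task resets before the
#'   running value can drop below 100).
#' @return `previous_answer - 7`.
#' @export
serial7s_expected <- function(previous_answer) {
  if (any(previous_answer < 100)) {
    stop("previous answer below 100: the task must have been reset")
  }
  previous_answer - 7L
}

#' Start (or reset) a Serial-7s state
#'
#' Draws a fresh initial number uniformly in 107..999 from the R random
#' stream.
#'
#' @param resets Reset counter carried over (0 for a fresh task).
#' @return A `"serial7s_state"`: `current_expected`, `initial_number`,
#'   `resets`, `correct_streak`.
#' @export
serial7s_new_state <- function(resets = 0L) {
  init <- sample(107:999, 1L)
  structure(list(current_expected = init,
                 initial_number = init,
                 resets = as.integer(resets),
                 correct_streak = 0L),
            class = "serial7s_state")
}

#' Score one Serial-7s trial and advance the state
#'
#' A response is correct iff it equals the expected value. The task resets
#' with a new random initial number (107..999) after a wrong answer, a
#' timeout (`response = NA`), or whenever the next expected value would fall
#' below 100; otherwise the expected value advances by -7.
#'
#' @param state A `"serial7s_state"`.
#' @param response Integer answer, or `NA` for a timeout.
#' @return List `verdict` (`"correct"`, `"wrong"` or `"timeout"`) and
#'   `state` (the advanced state).
#' @export
serial7s_step <- function(state, response) {
  stopifnot(inherits(state, "serial7s_state"))
  if (length(response) != 1L) stop("response must be a single value or NA")
  if (is.na(response)) {
    verdict <- "timeout"
  } else if (response == state$current_expected) {
    verdict <- "correct"
  } else {
    verdict <- "wrong"
  }
  if (verdict == "correct") {
    nxt <- state$current_expected - 7L
    if (nxt < 100L) {
      new_state <- serial7s_new_state(state$resets + 1L)
    } else {
      new_state <- state
      new_state$current_expected <- nxt
      new_state$correct_streak <- state$correct_streak + 1L
    }
  } else {
    new_state <- serial7s_new_state(state$resets + 1L)
  }
  list(verdict = verdict, state = new_state)
}

#' Simulate a Serial-7s accuracy trace
#'
#' Generates `n_trials` Serial-7s trials where trial `t` is answered
#' correctly with probability `p[t]` (a wrong answer of expected - 1 is
#' entered otherwise) and replays them through the task validator, so the
#' trace obeys all reset rules.
#'
#' @param n_trials Number of trials.
#' @param p Scalar or length-`n_trials` vector of per-trial correctness
#'   probabilities.
#' @return Data frame with `trial`, `expected`, `response`, `verdict`,
#'   `correct` (0/1).
#' @export
simulate_serial7s_trace <- function(n_trials, p) {
  p <- rep_len(p, n_trials)
  stopifnot(all(p >= 0 & p <= 1))
  state <- serial7s_new_state()
  expected <- integer(n_trials); response <- integer(n_trials)
  verdict <- character(n_trials)
  for (t in seq_len(n_trials)) {
    expected[t] <- state$current_expected
    ok <- stats::runif(1L) < p[t]
    response[t] <- if (ok) state$current_expected else state$current_expected - 1L
    out <- serial7s_step(state, response[t])
    verdict[t] <- out$verdict
    state <- out$state
  }
  data.frame(trial = seq_len(n_trials),
             expected = expected,
             response = response,
             verdict = verdict,
             correct = as.integer(verdict == "correct"),
             stringsAsFactors = FALSE)
}

#' Score a spatial-attention trial
#'
#' The control task for the working-memory intervention: a lateralised
#' stimulus must be answered with the matching arrow key within 1.5 s.
#'
#' @param stimulus_side `"left"` or `"right"`.
#' @param response `"left"`, `"right"` or `"none"`.
#' @param rt Response time in seconds (ignored when `response = "none"`).
#' @param deadline Response deadline in seconds (default 1.5).
#' @return `"correct"`, `"incorrect"` or `"timeout"`.
#' @export
attention_score <- function(stimulus_side = c("left", "right"),
                            response = c("left", "right", "none"),
                            rt = NA_real_, deadline = 1.5) {
  stimulus_side <- match.arg(stimulus_side)
  response <- match.arg(response)
  if (response == "none") return("timeout")
  if (is.na(rt) || rt < 0) stop("rt must be a non-negative number")
  if (rt > deadline) return("timeout")
  if (response == stimulus_side) "correct" else "incorrect"
}
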