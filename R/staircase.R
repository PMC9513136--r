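# Adaptive staircase engine for the intertemporal-choice (ITC) task:
# 12 arms (6 delays x 2 initial delayed rewards), 5 titration steps per arm
# per block, 3 blocks of 60 trials, randomized interleaving of arms.

ITC_DELAYS <- c(1L, 10L, 21L, 50L, 90L, 180L)
ITC_INITIAL_VALUES <- c(15000L, 20000L)
ITC_IMMEDIATE <- 10000L

#' Staircase configuration
#'
#' Settings that control the titration update rule of the adaptive
#' intertemporal-choice staircase.
#'
#' Two exponent schedules are supported for the adjustment
#' `10,000 x (1/2)^e` applied after the choice at step `t` (t = 1..5):
#'
#' * `"halving"` (default): `e = t`, so the first adjustment is +/-5,000 KRW
#'   and the adjustment halves on every subsequent step. Choices of the
#'   delayed option on a 15,000-KRW arm halve the gap to the immediate
#'   reward instead (`next = 10,000 + (current - 10,000)/2`). Together with
#'   `floor100` this schedule reproduces the canonical offered-reward range
#'   10,300--29,300 KRW.
#' * `"literal"`: `e = t - 1`, so the first adjustment is +/-10,000 KRW and a
#'   delayed choice on a 15,000-KRW arm at step 1 drives the next offer to
#'   exactly 10,000 KRW (equality with the immediate reward permitted).
#'
#' @param exponent_mode `"halving"` or `"literal"` (see Details).
#' @param floor100 Logical; round every updated offer down to the nearest
#'   100 KRW (default `TRUE`).
#' @param min_margin Non-negative numeric; enforce
#'   `delayed >= 10,000 + min_margin` on updated offers. Default 0.
#' @return An object of class `"staircase_config"`.
#' @export
staircase_config <- function(exponent_mode = c("halving", "literal"),
                             floor100 = TRUE,
                             min_margin = 0) {
  exponent_mode <- match.arg(exponent_mode)
  stopifnot(is.logical(floor100), length(floor100) == 1L,
            is.numeric(min_margin), length(min_margin) == 1L, min_margin >= 0)
  structure(list(exponent_mode = exponent_mode,
                 floor100 = floor100,
                 min_margin = min_margin),
            class = "staircase_config")
}

new_arm <- function(delay_days, initial_value) {
  structure(list(delay_days = as.integer(delay_days),
                 initial_value = as.integer(initial_value),
                 step = 1L,
                 current_delayed_reward = as.numeric(initial_value),
                 offer_history = list()),
            class = "staircase_arm")
}

#' Initialise one staircase block
#'
#' @return A list of 12 `"staircase_arm"` objects, the Cartesian product of
#'   the six delays (1, 10, 21, 50, 90, 180 days) and the two initial delayed
#'   rewards (15,000 and 20,000 KRW), each with `step = 1` and the current
#'   delayed reward equal to its initial value.
#' @export
init_block <- function() {
  arms <- vector("list", length(ITC_DELAYS) * length(ITC_INITIAL_VALUES))
  i <- 1L
  for (d in ITC_DELAYS) {
    for (v in ITC_INITIAL_VALUES) {
      arms[[i]] <- new_arm(d, v)
      i <- i + 1L
    }
  }
  arms
}

arm_exhausted <- function(arm) length(arm$offer_history) >= 5L

#' Draw the next trial offer from a block of staircase arms
#'
#' Picks uniformly at random among arms that still have steps remaining
#' (the arm used on the previous trial is a legal candidate) and returns its
#' current offer. Uses the R random number stream; seed the session for
#' reproducibility.
#'
#' @param arms List of `"staircase_arm"` objects (as from [init_block()]).
#' @return A `"trial_offer"` list: `immediate_krw` (always 10,000),
#'   `delayed_krw`, `delay_days`, `arm_index`, `arm_initial`, `step`.
#' @export
next_offer <- function(arms) {
  open <- which(!vapply(arms, arm_exhausted, logical(1L)))
  if (length(open) == 0L) {
    stop("block exhausted: all 12 arms have completed their 5 steps")
  }
  idx <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
  arm <- arms[[idx]]
  structure(list(immediate_krw = ITC_IMMEDIATE,
                 delayed_krw = arm$current_delayed_reward,
                 delay_days = arm$delay_days,
                 arm_index = idx,
                 arm_initial = arm$initial_value,
                 step = arm$step),
            class = "trial_offer")
}

# Titration rule for the reward offered at step t+1 given the choice at step
# t.  `current` is the delayed reward offered at step t.
next_delayed_reward <- function(current, initial_value, choice, t, config) {
  e <- if (config$exponent_mode == "halving") t else t - 1L
  if (choice == "immediate") {
    nxt <- current + 10000 * 0.5^e
  } else if (initial_value == 15000L) {
    # exception rule keeps the delayed offer above the immediate reward
    f <- if (config$exponent_mode == "halving") 0.5 else 0.5^(t - 1L)
    nxt <- current - (current - 10000) * f
  } else {
    nxt <- current - 10000 * 0.5^e
  }
  if (config$floor100) nxt <- floor(nxt / 100) * 100
  max(nxt, 10000 + config$min_margin)
}

#' Apply a choice to a staircase arm
#'
#' Records the answered offer in the arm's history, advances its step and
#' titrates the delayed reward for the arm's next offer. Answering the 5th
#' offer exhausts the arm (no 6th offer is computed).
#'
#' @param arm A `"staircase_arm"`.
#' @param choice `"immediate"` or `"delayed"`.
#' @param config A [staircase_config()].
#' @return The updated arm.
#' @export
update_arm <- function(arm, choice, config = staircase_config()) {
  if (arm_exhausted(arm)) {
    stop("cannot update an exhausted arm (5 offers already answered)")
  }
  choice <- match.arg(choice, c("immediate", "delayed"))
  t <- arm$step
  arm$offer_history[[t]] <- list(delayed_reward = arm$current_delayed_reward,
                                 choice = choice)
  if (t < 5L) {
    arm$current_delayed_reward <- next_delayed_reward(
      arm$current_delayed_reward, arm$initial_value, choice, t, config)
  }
  arm$step <- t + 1L
  arm
}

#' Simulate one 180-trial ITC session
#'
#' Runs three blocks of 60 trials. Within each block every one of the 12
#' arms is presented exactly 5 times, interleaved uniformly at random.
#'
#' @param policy A function mapping a `"trial_offer"` to `"immediate"` or
#'   `"delayed"`; it may consume the R random stream (see
#'   [policy_softmax()]).
#' @param config A [staircase_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the session (arm order and any stochastic policy) is reproducible.
#' @param participant_id,phase Provenance labels copied into every record.
#' @return A data frame of 180 trial records with columns `participant_id`,
#'   `phase`, `block`, `trial_index`, `delay_days`, `immediate_krw`,
#'   `delayed_krw`, `arm_delay`, `arm_initial`, `step`, `choice`.
#' @export
generate_session <- function(policy, config = staircase_config(),
                             seed = NULL, participant_id = "sim",
                             phase = "pre") {
  if (!is.null(seed)) set.seed(seed)
  n <- 180L
  block <- integer(n); delay <- integer(n); delayed <- numeric(n)
  initial <- integer(n); step <- integer(n); choice <- character(n)
  i <- 0L
  for (b in 1:3) {
    arms <- init_block()
    for (trial in 1:60) {
      off <- next_offer(arms)
      ch <- policy(off)
      ch <- match.arg(ch, c("immediate", "delayed"))
      i <- i + 1L
      block[i] <- b
      delay[i] <- off$delay_days
      delayed[i] <- off$delayed_krw
      initial[i] <- off$arm_initial
      step[i] <- off$step
      choice[i] <- ch
      arms[[off$arm_index]] <- update_arm(arms[[off$arm_index]], ch, config)
    }
  }
  data.frame(participant_id = participant_id,
             phase = phase,
             block = block,
             trial_index = seq_len(n),
             delay_days = delay,
             immediate_krw = ITC_IMMEDIATE,
             delayed_krw = delayed,
             arm_delay = delay,
             arm_initial = initial,
             step = step,
             choice = choice,
             stringsAsFactors = FALSE)
}

#' Choice policies for simulated agents
#'
#' `policy_softmax()` samples choices from the softmax rule given hyperbolic
#' discounting parameters; `policy_threshold()` is the deterministic limit
#' (choose delayed iff its subjective value strictly exceeds the immediate
#' reward's); `policy_always()` always returns a fixed choice.
#'
#' @param k Discount rate in (0, 1) per day.
#' @param mu Inverse temperature (per KRW), `mu >= 0`.
#' @return A function mapping a `"trial_offer"` to a choice label.
#' @seealso [p_immediate()], [subjective_value()]
#' @export
policy_softmax <- function(k, mu) {
  function(offer) {
    sv_d <- subjective_value(offer$delayed_krw, offer$delay_days, k)
    p <- p_immediate(offer$immediate_krw, sv_d, mu)
    if (stats::runif(1L) < p) "immediate" else "delayed"
  }
}

#' @rdname policy_softmax
#' @export
policy_threshold <- function(k) {
  function(offer) {
    sv_d <- subjective_value(offer$delayed_krw, offer$delay_days, k)
    if (sv_d > offer$immediate_krw) "delayed" else "immediate"
  }
}

#' @rdname policy_softmax
#' @param choice Fixed choice label for `policy_always()`.
#' @export
policy_always <- function(choice = c("immediate", "delayed")) {
  choice <- match.arg(choice)
  function(offer) choice
}

#' Enumerate every reachable offer of a staircase arm
#'
#' Walks all `2^4` choice paths of a single arm and collects the delayed
#' rewards offered at each of its 5 steps. Used to verify the reachable
#' offer range of a configuration.
#'
#' @param delay_days,initial_value Arm identity.
#' @param config A [staircase_config()].
#' @return A data frame with one row per (path, step): columns `path`
#'   (choice string such as `"IDDI"`), `step`, `delayed_krw`.
#' @export
enumerate_arm_offers <- function(delay_days, initial_value,
                                 config = staircase_config()) {
  paths <- expand.grid(rep(list(c("immediate", "delayed")), 4L),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(paths))
  for (p in seq_len(nrow(paths))) {
    choices <- unlist(paths[p, ], use.names = FALSE)
    cur <- as.numeric(initial_value)
    offers <- numeric(5L)
    offers[1L] <- cur
    for (t in 1:4) {
      cur <- next_delayed_reward(cur, as.integer(initial_value),
                                 choices[t], t, config)
      offers[t + 1L] <- cur
    }
    out[[p]] <- data.frame(
      path = paste(toupper(substr(choices, 1L, 1L)), collapse = ""),
      step = 1:5,
      delayed_krw = offers,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reachable offer range over all 12 arms
#'
#' @param config A [staircase_config()].
#' @return Named numeric vector `c(min = , max = )` of the delayed rewards
#'   offered on any choice path of any arm.
#' @export
staircase_offer_range <- function(config = staircase_config()) {
  offers <- unlist(lapply(ITC_DELAYS, function(d) {
    lapply(ITC_INITIAL_VALUES, function(v) {
      enumerate_arm_offers(d, v, config)$delayed_krw
    })
  }))
  c(min = min(offers), max = max(offers))
}
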