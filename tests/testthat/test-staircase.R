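test_that("a fresh block holds the 12-arm Cartesian product in initial state", {
  arms <- init_block()
  expect_length(arms, 12L)
  ids <- vapply(arms, function(a) paste(a$delay_days, a$initial_value),
                character(1L))
  expect_length(unique(ids), 12L)
  expect_setequal(vapply(arms, `[[`, integer(1L), "delay_days"),
                  c(1L, 10L, 21L, 50L, 90L, 180L))
  for (a in arms) {
    expect_identical(a$step, 1L)
    expect_identical(a$current_delayed_reward, as.numeric(a$initial_value))
    expect_length(a$offer_history, 0L)
  }
})

test_that("titration follows the halving schedule with floor-to-100 rounding", {
  cfg <- staircase_config()
  arms <- init_block()
  a20 <- arms[[which(vapply(arms, function(a) {
    a$delay_days == 1L && a$initial_value == 20000L
  }, logical(1L)))]]
  # immediate at step 1: 20,000 + 10,000 * (1/2)^1
  a20 <- update_arm(a20, "immediate", cfg)
  expect_equal(a20$current_delayed_reward, 25000)
  expect_identical(a20$step, 2L)
  expect_length(a20$offer_history, 1L)

  a15 <- init_block()[[which(vapply(arms, function(a) {
    a$delay_days == 1L && a$initial_value == 15000L
  }, logical(1L)))]]
  # delayed at step 1 on the 15,000 arm: gap-halving to 12,500
  a15 <- update_arm(a15, "delayed", cfg)
  expect_equal(a15$current_delayed_reward, 12500)

  # full all-immediate path on the 20,000 arm reaches the printed maximum
  arm <- init_block()[[which(vapply(arms, function(a) {
    a$delay_days == 1L && a$initial_value == 20000L
  }, logical(1L)))]]
  offers <- numeric(5L)
  for (t in 1:5) {
    offers[t] <- arm$current_delayed_reward
    arm <- update_arm(arm, "immediate", cfg)
  }
  expect_equal(offers, c(20000, 25000, 27500, 28700, 29300))
  expect_error(update_arm(arm, "immediate", cfg), "exhausted")
})

test_that("the literal schedule reproduces the printed formula verbatim", {
  cfg <- staircase_config("literal", floor100 = FALSE)
  arms <- init_block()
  a15 <- arms[[which(vapply(arms, function(a) {
    a$delay_days == 10L && a$initial_value == 15000L
  }, logical(1L)))]]
  # delayed at step 1: current - (current - 10,000) * (1/2)^0 = 10,000 exactly
  a15 <- update_arm(a15, "delayed", cfg)
  expect_equal(a15$current_delayed_reward, 10000)
  a20 <- arms[[which(vapply(arms, function(a) {
    a$delay_days == 10L && a$initial_value == 20000L
  }, logical(1L)))]]
  a20 <- update_arm(a20, "immediate", cfg)
  expect_equal(a20$current_delayed_reward, 30000)
})

test_that("reachable offer range under halving + floor100 is 10,300..29,300", {
  rng <- staircase_offer_range(staircase_config())
  expect_equal(unname(rng["min"]), 10300)
  expect_equal(unname(rng["max"]), 29300)
})

test_that("min_margin enforces strict dominance of the delayed offer", {
  rng <- staircase_offer_range(staircase_config("literal", min_margin = 300))
  expect_gte(unname(rng["min"]), 10300)
})

test_that("next_offer draws uniformly among open arms and errors when spent", {
  arms <- init_block()
  set.seed(7)
  draws <- replicate(6000L, next_offer(arms)$arm_index)
  freq <- tabulate(draws, nbins = 12L) / 6000
  se <- sqrt((1 / 12) * (11 / 12) / 6000)
  expect_true(all(abs(freq - 1 / 12) < 3.3 * se))

  # exhaust all arms but one: the survivor must be offered
  cfg <- staircase_config()
  for (i in 1:11) {
    for (t in 1:5) arms[[i]] <- update_arm(arms[[i]], "immediate", cfg)
  }
  expect_identical(next_offer(arms)$arm_index, 12L)
  for (t in 1:5) arms[[12L]] <- update_arm(arms[[12L]], "immediate", cfg)
  expect_error(next_offer(arms), "exhausted")
})

test_that("a session has 180 trials, 60 per block, 15 per arm, reproducibly", {
  s <- generate_session(policy_always("immediate"), seed = 11L)
  expect_identical(nrow(s), 180L)
  expect_true(all(table(s$block) == 60L))
  expect_true(all(table(s$arm_delay, s$arm_initial) == 15L))
  expect_true(all(s$immediate_krw == 10000))
  # within a block each arm is offered exactly 5 times at steps 1..5
  per_arm <- split(s$step, list(s$block, s$arm_delay, s$arm_initial))
  expect_true(all(vapply(per_arm, function(x) identical(sort(x), 1:5),
                         logical(1L))))
  # all-immediate: delayed rewards non-decreasing within every block arm
  ordered_ok <- vapply(
    split(s, list(s$block, s$arm_delay, s$arm_initial)),
    function(d) !is.unsorted(d$delayed_krw[order(d$step)]),
    logical(1L))
  expect_true(all(ordered_ok))

  s2 <- generate_session(policy_always("immediate"), seed = 11L)
  expect_identical(s, s2)
  s3 <- generate_session(policy_always("immediate"), seed = 12L)
  expect_false(identical(s$arm_delay, s3$arm_delay))
})

test_that("offered rewards bracket a threshold agent's indifference point", {
  # R* = 10,000 * (1 + k * D) is the reward making the agent indifferent.
  # Over a dense sweep the offers must bracket R*; the 20,000 arm is a true
  # bisection (final offer within one terminal step, 625 + 100 rounding).
  for (delay in c(1L, 21L, 180L)) {
    for (Rstar in seq(10600, 14900, by = 177)) {
      k <- (Rstar / 10000 - 1) / delay
      offers <- threshold_arm_offers(k, delay, 15000L)
      expect_gte(Rstar, min(offers))
      expect_lte(Rstar, max(offers))
      expect_lte(abs(offers[5L] - Rstar), 2500)
    }
    for (Rstar in seq(10600, 19900, by = 311)) {
      k <- (Rstar / 10000 - 1) / delay
      offers <- threshold_arm_offers(k, delay, 20000L)
      expect_gte(Rstar, min(offers))
      expect_lte(Rstar, max(offers))
      expect_lte(abs(offers[5L] - Rstar), 625 + 100)
    }
  }
})
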